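#' Read a triangulated surface mesh
#'
#' Supports the three common ASCII formats for small surface meshes: OFF,
#' PLY (ascii 1.0) and VTK legacy POLYDATA. File vertex indices (0-based in
#' all three formats) are normalized to R's 1-based indexing; vertex order is
#' preserved. Outward orientation is enforced on read (windings are flipped
#' if the enclosed signed volume is negative).
#'
#' @param path file path.
#' @param format one of `"off"`, `"ply"`, `"vtk"`; guessed from the file
#'   extension when `NULL`.
#' @param role mesh role, `"heart"` or `"torso"`.
#' @return a [surface_mesh()].
#' @export
read_mesh <- function(path, format = NULL, role = c("heart", "torso")) {
  role <- match.arg(role)
  if (!file.exists(path)) stop("cannot read mesh file: ", path)
  if (is.null(format))
    format <- tolower(tools::file_ext(path))
  format <- match.arg(tolower(format), c("off", "ply", "vtk"))
  parsed <- switch(format,
                   off = parse_off(readLines(path)),
                   ply = parse_ply(readLines(path)),
                   vtk = parse_vtk(readLines(path)))
  surface_mesh(parsed$vertices, parsed$faces + 1L, role = role)
}

#' Write a triangulated surface mesh
#'
#' ASCII writer mirroring [read_mesh()]; floats are written with 17
#' significant digits so a write/read round trip is bit-exact.
#'
#' @param mesh a [surface_mesh()].
#' @param path output file path.
#' @param format `"off"`, `"ply"` or `"vtk"`; guessed from the extension when
#'   `NULL`.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = NULL) {
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  format <- match.arg(tolower(format), c("off", "ply", "vtk"))
  v <- apply(mesh$vertices, 1, function(r)
    paste(sprintf("%.17g", r), collapse = " "))
  f0 <- mesh$triangles - 1L
  f <- paste(3L, f0[, 1], f0[, 2], f0[, 3])
  lines <- switch(format,
    off = c("OFF",
            paste(nrow(mesh$vertices), nrow(mesh$triangles), 0),
            v, f),
    ply = c("ply", "format ascii 1.0",
            paste("element vertex", nrow(mesh$vertices)),
            "property double x", "property double y", "property double z",
            paste("element face", nrow(mesh$triangles)),
            "property list uchar int vertex_indices",
            "end_header", v, f),
    vtk = c("# vtk DataFile Version 3.0", "surface mesh", "ASCII",
            "DATASET POLYDATA",
            paste("POINTS", nrow(mesh$vertices), "double"), v,
            paste("POLYGONS", nrow(mesh$triangles),
                  4L * nrow(mesh$triangles)), f))
  writeLines(lines, path)
  invisible(path)
}

split_nums <- function(lines) {
  toks <- unlist(strsplit(trimws(lines), "[[:space:]]+"))
  as.numeric(toks[nzchar(toks)])
}

# faces are returned 0-based; each face line is "k i1 ... ik"
parse_face_block <- function(lines, nf) {
  faces <- matrix(0L, nf, 3)
  row <- 0L
  for (ln in lines) {
    toks <- split_nums(ln)
    i <- 1L
    while (i <= length(toks) && row < nf) {
      k <- as.integer(toks[i])
      if (k != 3L)
        stop("non-triangular cell with ", k, " vertices (",
             switch(as.character(k), "4" = "quad", "2" = "line segment",
                    paste0(k, "-gon")), ") is not supported")
      faces[row + 1L, ] <- as.integer(toks[(i + 1):(i + 3)])
      row <- row + 1L
      i <- i + k + 1L
    }
    if (row >= nf) break
  }
  if (row < nf) stop("truncated face block: expected ", nf, " faces")
  faces
}

parse_off <- function(lines) {
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (toupper(trimws(lines[1])) != "OFF") stop("not an OFF file")
  counts <- split_nums(lines[2])
  nv <- counts[1]; nf <- counts[2]
  nums <- split_nums(lines[3:(2 + nv)])
  vertices <- matrix(nums, nv, 3, byrow = TRUE)
  faces <- parse_face_block(lines[(3 + nv):length(lines)], nf)
  list(vertices = vertices, faces = faces)
}

parse_ply <- function(lines) {
  endh <- which(trimws(lines) == "end_header")[1]
  if (is.na(endh)) stop("not an ascii PLY file (no end_header)")
  header <- lines[seq_len(endh)]
  if (!any(grepl("^format\\s+ascii", header)))
    stop("only ascii PLY is supported")
  nv <- as.integer(sub(".*element\\s+vertex\\s+", "",
                       grep("element\\s+vertex", header, value = TRUE)[1]))
  nf <- as.integer(sub(".*element\\s+face\\s+", "",
                       grep("element\\s+face", header, value = TRUE)[1]))
  body <- lines[(endh + 1):length(lines)]
  body <- body[nzchar(trimws(body))]
  vert_lines <- body[seq_len(nv)]
  vertices <- matrix(unlist(lapply(vert_lines,
                                   function(l) split_nums(l)[1:3])),
                     nv, 3, byrow = TRUE)
  faces <- parse_face_block(body[(nv + 1):length(body)], nf)
  list(vertices = vertices, faces = faces)
}

parse_vtk <- function(lines) {
  up <- toupper(lines)
  if (!any(grepl("DATASET\\s+POLYDATA", up)))
    stop("only VTK legacy POLYDATA is supported")
  ip <- grep("^POINTS", up)[1]
  nv <- as.integer(strsplit(trimws(lines[ip]), "\\s+")[[1]][2])
  nums <- c(); i <- ip + 1L
  while (length(nums) < 3 * nv) {
    nums <- c(nums, split_nums(lines[i]))
    i <- i + 1L
  }
  vertices <- matrix(nums[1:(3 * nv)], nv, 3, byrow = TRUE)
  ifc <- grep("^POLYGONS|^TRIANGLE_STRIPS|^LINES|^VERTICES", up)
  ifc <- ifc[ifc > ip][1]
  kind <- strsplit(trimws(lines[ifc]), "\\s+")[[1]][1]
  if (toupper(kind) != "POLYGONS")
    stop("unsupported VTK cell block: ", kind)
  nf <- as.integer(strsplit(trimws(lines[ifc]), "\\s+")[[1]][2])
  faces <- parse_face_block(lines[(ifc + 1):length(lines)], nf)
  list(vertices = vertices, faces = faces)
}
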