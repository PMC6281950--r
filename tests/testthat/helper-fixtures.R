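# Shared fixtures. Expensive objects (FEM builds, phantoms) are constructed
# lazily and cached for the whole test run.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

octahedron_off <- function() {
  c("OFF", "6 8 0",
    "1 0 0", "-1 0 0", "0 1 0", "0 -1 0", "0 0 1", "0 0 -1",
    "3 0 2 4", "3 2 1 4", "3 1 3 4", "3 3 0 4",
    "3 2 0 5", "3 1 2 5", "3 3 1 5", "3 0 3 5")
}

# small two-sphere pair for fast forward-model tests (42 vertices)
small_pair <- function() fixture("small_pair", function() {
  list(heart = icosphere(1, 1), torso = icosphere(2, 1, role = "torso"))
})

small_fem <- function() fixture("small_fem", function() {
  p <- small_pair()
  build_fem_transfer(p$heart, p$torso, refinement = 6)
})

small_dtn <- function() fixture("small_dtn", function() {
  p <- small_pair()
  build_dtn_operator(p$heart, p$torso, refinement = 6)
})

# default-scale pair (162 vertices) and operators, shared with acceptance
default_pair <- function() fixture("default_pair", function() {
  list(heart = icosphere(1, 2), torso = icosphere(2, 2, role = "torso"))
})

default_fem <- function() fixture("default_fem", function() {
  p <- default_pair()
  build_fem_transfer(p$heart, p$torso)
})

default_dtn <- function() fixture("default_dtn", function() {
  p <- default_pair()
  build_dtn_operator(p$heart, p$torso)
})

default_phantom <- function() fixture("default_phantom", function() {
  phantom_dataset()
})

random_system <- function(seed, m = 15, n = 8, with_L = FALSE) {
  set.seed(seed)
  A <- matrix(stats::rnorm(m * n), m, n)
  b <- stats::rnorm(m)
  if (!with_L) return(list(A = A, b = b))
  repeat {
    L <- matrix(stats::rnorm(n * n), n, n)
    if (abs(det(L)) > 1e-6) break
  }
  list(A = A, b = b, L = L)
}

# dense Tikhonov solve: (A'A + lambda^2 L'L) x = A'b
dense_tikhonov <- function(A, b, lambda, L = diag(ncol(A))) {
  drop(solve(crossprod(A) + lambda^2 * crossprod(L), crossprod(A, b)))
}
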