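#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a selection curve into long format
#'
#' @param x a `selection_curve`.
#' @param ... unused.
#' @return tibble with columns `lambda`, `quantity`, `value`.
#' @method tidy selection_curve
#' @export
tidy.selection_curve <- function(x, ...) {
  tidyr::pivot_longer(tibble::as_tibble(x), -"lambda",
                      names_to = "quantity", values_to = "value")
}

#' @rdname tidy.selection_curve
#' @method glance lambda_choice
#' @export
glance.lambda_choice <- function(x, ...) {
  tibble::tibble(criterion = x$criterion, lambda = x$lambda,
                 index = x$index,
                 flags = paste(x$flags, collapse = ";"))
}

#' Tidy evaluation reports
#'
#' `tidy()` returns the per-frame spatial metrics; `glance()` the one-row
#' summary (means and standard deviations).
#'
#' @param x an `evaluation_report`.
#' @param ... unused.
#' @method tidy evaluation_report
#' @export
tidy.evaluation_report <- function(x, ...) x$spatial

#' @rdname tidy.evaluation_report
#' @method glance evaluation_report
#' @export
glance.evaluation_report <- function(x, ...) x$summary

#' @rdname tidy.evaluation_report
#' @method tidy ecgi_experiment
#' @export
tidy.ecgi_experiment <- function(x, ...) x$results

#' Plot selection-curve quantities against lambda
#'
#' Log-log facetted view of the criterion functions; the shape a user
#' inspects to understand why a criterion picked its lambda.
#'
#' @param object a `selection_curve`.
#' @param quantities which columns to show.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot selection_curve
#' @export
autoplot.selection_curve <- function(object,
                                     quantities = c("rho", "eta", "G", "R",
                                                    "C", "Ucurve", "xi"),
                                     ...) {
  df <- tidy.selection_curve(object)
  df <- dplyr::filter(df, .data$quantity %in% quantities,
                      is.finite(.data$value))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lambda, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = expression(lambda), y = NULL)
}

#' Bar chart of experiment results
#'
#' Mean spatial relative error and correlation coefficient with standard
#' deviations, per numerical method and criterion.
#'
#' @param object an `ecgi_experiment`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot ecgi_experiment
#' @export
autoplot.ecgi_experiment <- function(object, ...) {
  df <- dplyr::filter(object$results, .data$status == "ok")
  df <- tidyr::pivot_longer(
    df, c("re_mean", "cc_mean"), names_to = "metric", values_to = "mean")
  df$sd <- ifelse(df$metric == "re_mean", df$re_sd, df$cc_sd)
  df$metric <- ifelse(df$metric == "re_mean", "relative error",
                      "correlation coefficient")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$criterion, y = .data$mean,
                                   fill = .data$method)) +
    ggplot2::geom_col(position = ggplot2::position_dodge()) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sd,
                   ymax = .data$mean + .data$sd),
      position = ggplot2::position_dodge(width = 0.9), width = 0.3) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL)
}

#' @importFrom rlang .data
NULL
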