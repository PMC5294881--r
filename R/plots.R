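#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a coverage curve
#'
#' Coverage probability against the true response rate, with the nominal
#' level drawn as a dashed reference line. Dips below the line reveal
#' non-exactness (only the `RR` ordering can show them).
#'
#' @param object A [coverage_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot coverage_curve
#' @export
autoplot.coverage_curve <- function(object, ...) {
  alpha <- attr(object, "alpha") %||% NA_real_
  p <- ggplot2::ggplot(tibble::as_tibble(object),
                       ggplot2::aes(x = .data$pi, y = .data$coverage)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(
      x = expression(pi), y = "coverage probability",
      title = sprintf("Coverage, %s ordering", attr(object, "ordering") %||% "")
    ) +
    ggplot2::theme_minimal()
  if (!is.na(alpha)) {
    p <- p + ggplot2::geom_hline(yintercept = 1 - alpha,
                                 linetype = "dashed", colour = "grey40")
  }
  p
}

#' Plot per-outcome interval lengths
#'
#' Interval length `1 - L(x1, x2)` of every completed two-stage outcome, in
#' canonical outcome order, coloured by stage-1 response count. Useful for
#' comparing orderings point by point.
#'
#' @param object A [limit_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot limit_table
#' @export
autoplot.limit_table <- function(object, ...) {
  g2 <- tibble::as_tibble(object)[object$group == "G2", ]
  g2$index <- seq_len(nrow(g2))
  ggplot2::ggplot(g2, ggplot2::aes(x = .data$index,
                                   y = 1 - .data$lower_limit,
                                   colour = factor(.data$x1))) +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(
      x = "two-stage outcome (canonical order)",
      y = "interval length 1 - L",
      colour = "x1",
      title = sprintf("%s ordering, alpha = %g",
                      attr(object, "ordering"), attr(object, "alpha"))
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn limit_table `tidy()` returns the table as a plain tibble.
#' @method tidy limit_table
#' @export
tidy.limit_table <- function(x, ...) {
  tibble::as_tibble(unclass_tbl(x))
}

#' @describeIn coverage_curve `tidy()` returns the curve as a plain tibble.
#' @method tidy coverage_curve
#' @export
tidy.coverage_curve <- function(x, ...) {
  tibble::as_tibble(unclass_tbl(x))
}

unclass_tbl <- function(x) {
  class(x) <- setdiff(class(x), c("limit_table", "coverage_curve", "adaptive_space"))
  attr(x, "design") <- NULL
  attr(x, "alpha") <- NULL
  attr(x, "ordering") <- NULL
  attr(x, "min_coverage") <- NULL
  attr(x, "pi_min") <- NULL
  x
}
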