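#' Exact coverage probability of a limit table
#'
#' The coverage probability of the one-sided intervals `(L(x1, x2), 1]` at a
#' true rate `pi` is `P(L(X1, X2) < pi | pi)`: the exact probability of the
#' outcomes whose lower limit falls strictly below `pi`. An interval method
#' is exact when this is at least `1 - alpha` for every `pi`. Coverage is a
#' piecewise-smooth function of `pi` with downward jumps just past each
#' distinct limit value, so the supplied grid is augmented with every limit
#' value plus `1e-9` to capture the jump lows.
#'
#' @param space An [sample_space()] tibble.
#' @param limits A [limit_table()] for that space.
#' @param pi_grid Strictly increasing grid in (0, 1); default
#'   `seq(0.001, 0.999, by = 0.001)`.
#' @param design Optional explicit design.
#' @return A tibble of class `coverage_curve` with columns `pi`, `coverage`;
#'   attributes `min_coverage`, `pi_min`, `ordering`, `alpha`.
#' @examples
#' toy <- adaptive_design(2, 0, 2, n2 = 2, r = 2, pi0 = 0.5)
#' sp <- sample_space(toy)
#' cov <- coverage_curve(sp, limit_table(sp, "PV"), seq(0.01, 0.99, 0.01))
#' glance(cov)
#' @export
coverage_curve <- function(space, limits, pi_grid = seq(0.001, 0.999, by = 0.001),
                           design = NULL) {
  design <- space_design(space, design)
  if (any(pi_grid <= 0 | pi_grid >= 1)) {
    rlang::abort("pi_grid must lie strictly inside (0, 1)")
  }
  if (is.unsorted(pi_grid, strictly = TRUE)) {
    rlang::abort("pi_grid must be strictly increasing")
  }
  L <- align_limits(space, limits)
  # coverage is lowest where pi sits exactly at a limit value (the outcome
  # with L = pi is not yet covered); evaluate at the limits and just around
  jumps <- unique(L[L > 0 & L < 1])
  extra <- c(jumps, jumps - 1e-9, jumps + 1e-9)
  extra <- extra[extra > 0 & extra < 1]
  grid <- sort(unique(c(pi_grid, extra)))
  pmat <- probability_matrix(space, grid, design)
  covered <- outer(L, grid, FUN = "<") # strict: pi in (L, 1]
  coverage <- pmin(1, pmax(0, colSums(pmat * covered))) # guard float noise
  out <- tibble::tibble(pi = grid, coverage = coverage)
  i <- which.min(coverage)
  attr(out, "min_coverage") <- coverage[i]
  attr(out, "pi_min") <- grid[i]
  attr(out, "ordering") <- attr(limits, "ordering")
  attr(out, "alpha") <- attr(limits, "alpha")
  class(out) <- c("coverage_curve", class(out))
  out
}

# match limit-table rows to space rows (canonical order is shared, but be
# robust to reordered tables)
align_limits <- function(space, limits) {
  idx <- purrr::map2_int(limits$x1, limits$x2, \(a, b) locate_point(space, a, b))
  L <- numeric(nrow(space))
  L[idx] <- limits$lower_limit
  if (length(idx) != nrow(space) || anyDuplicated(idx)) {
    rlang::abort("limit table does not cover the sample space exactly once")
  }
  L
}

#' @describeIn coverage_curve `glance()` returns the minimum coverage and
#'   the rate at which it is attained.
#' @param x A `coverage_curve`.
#' @param ... Unused.
#' @method glance coverage_curve
#' @export
glance.coverage_curve <- function(x, ...) {
  tibble::tibble(
    ordering = attr(x, "ordering") %||% NA_character_,
    alpha = attr(x, "alpha") %||% NA_real_,
    min_coverage = attr(x, "min_coverage"),
    pi_min = attr(x, "pi_min")
  )
}

#' Simple average interval length
#'
#' The unweighted mean of the interval lengths `1 - L(x1, x2)` over the
#' completed two-stage outcomes `G2` (denominator `M`, the size of `G2`), or
#' over a supplied subset such as [g2_ci_subset()] (denominator `M(CI)`).
#'
#' @param limits A [limit_table()].
#' @param subset Optional tibble with columns `x1`, `x2` selecting a
#'   nonempty subset of `G2`; default: all of `G2`.
#' @return A single number in (0, 1].
#' @examples
#' toy <- adaptive_design(2, 0, 2, n2 = 2, r = 2, pi0 = 0.5)
#' sp <- sample_space(toy)
#' average_length(limit_table(sp, "RR-B"))
#' @export
average_length <- function(limits, subset = NULL) {
  g2 <- limits[limits$group == "G2", , drop = FALSE]
  if (!is.null(subset)) {
    key <- paste(g2$x1, g2$x2)
    want <- paste(subset$x1, subset$x2)
    if (!all(want %in% key)) rlang::abort("subset must be contained in G2")
    g2 <- g2[key %in% want, , drop = FALSE]
  }
  if (nrow(g2) == 0) rlang::abort("no completed two-stage outcomes to average over")
  mean(1 - g2$lower_limit)
}

#' Expected interval length
#'
#' The probability-weighted interval length at a true rate `pi`:
#' `EL(pi) = sum over (x1, x2) in G2 of (1 - L(x1, x2)) * b(x1; n1, pi) *
#' b(x2; n2(x1), pi)`. Stage-1 stops are excluded, so `EL(pi)` is bounded by
#' the probability of reaching stage 2.
#'
#' @param space An [sample_space()] tibble.
#' @param limits A [limit_table()] for that space.
#' @param pi True response rate(s) in `[0, 1]` (vectorised).
#' @param design Optional explicit design.
#' @return Numeric vector, one expected length per element of `pi`.
#' @examples
#' toy <- adaptive_design(2, 0, 2, n2 = 2, r = 2, pi0 = 0.5)
#' sp <- sample_space(toy)
#' expected_length(sp, limit_table(sp, "PV"), 0.5)
#' @export
expected_length <- function(space, limits, pi, design = NULL) {
  design <- space_design(space, design)
  L <- align_limits(space, limits)
  g2 <- space$group == "G2"
  sub <- space[g2, , drop = FALSE]
  len <- 1 - L[g2]
  vapply(pi, function(p) sum(len * point_probability(sub, p, design)),
         numeric(1))
}

#' Pointwise ratio of expected lengths
#'
#' Compares two interval methods by the ratio `EL_a(pi) / EL_b(pi)` on a
#' grid; the expected lengths of competing exact orderings differ little, so
#' the ratio is the informative scale. Grid points where `EL_b(pi) = 0` are
#' masked as `NA`.
#'
#' @param space An [sample_space()] tibble.
#' @param limits_a,limits_b Two [limit_table()]s for the same space.
#' @param pi_grid Rates at which to evaluate the ratio.
#' @param design Optional explicit design.
#' @return A tibble with columns `pi`, `el_a`, `el_b`, `ratio`.
#' @export
el_ratio <- function(space, limits_a, limits_b,
                     pi_grid = seq(0.01, 0.99, by = 0.01), design = NULL) {
  design <- space_design(space, design)
  a <- expected_length(space, limits_a, pi_grid, design)
  b <- expected_length(space, limits_b, pi_grid, design)
  tibble::tibble(
    pi = pi_grid,
    el_a = a,
    el_b = b,
    ratio = ifelse(b == 0, NA_real_, a / b)
  )
}

#' Practically plausible subset of the two-stage outcomes
#'
#' The subset `G2(CI)` of completed outcomes whose second-stage response
#' rate `x2 / n2(x1)` lies inside the exact two-sided Clopper-Pearson
#' interval for the first-stage rate `x1 / n1` at the given confidence
#' level. Outcomes outside it have stage rates so discordant that the study
#' population itself is suspect; evaluation restricted to `G2(CI)` asks how
#' the interval methods compare on the outcomes a practitioner would
#' actually trust. The subset does not depend on the ordering; at
#' `level = 1` it is all of `G2`.
#'
#' @param space An [sample_space()] tibble.
#' @param level Two-sided confidence level in (0, 1]; default 0.95.
#' @param design Optional explicit design.
#' @return The rows of `space` in `G2(CI)` (membership at the closed
#'   endpoints, with tolerance 1e-12).
#' @examples
#' toy <- adaptive_design(2, 0, 2, n2 = 2, r = 2, pi0 = 0.5)
#' g2_ci_subset(sample_space(toy), 0.95)
#' @export
g2_ci_subset <- function(space, level = 0.95, design = NULL) {
  design <- space_design(space, design)
  g2 <- space$group == "G2"
  sub <- space[g2, , drop = FALSE]
  if (nrow(sub) == 0) return(sub)
  ci <- cp_binomial_two_sided(sub$x1, design$n1, level)
  n2 <- as.numeric(design$n2[as.character(sub$x1)])
  rate2 <- sub$x2 / n2
  keep <- rate2 >= ci$lower - 1e-12 & rate2 <= ci$upper + 1e-12
  sub[keep, , drop = FALSE]
}
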