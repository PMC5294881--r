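#' Clopper-Pearson one-sided lower limit for a binomial proportion
#'
#' The exact `1 - alpha` lower limit after observing `x` successes in `n`
#' trials: the unique `L` with `P(X >= x | n, L) = alpha` for `x >= 1`
#' (equivalently the `alpha` quantile of `Beta(x, n - x + 1)`), and `0` when
#' `x = 0`.
#'
#' @param x Number of successes (vectorised).
#' @param n Number of trials.
#' @param alpha One-sided significance level in (0, 1).
#' @return Lower limit(s) in `[0, 1)`.
#' @examples
#' cp_binomial_lower(2, 2, 0.05)  # sqrt(0.05)
#' @export
cp_binomial_lower <- function(x, n, alpha = 0.05) {
  if (any(x < 0 | x > n)) rlang::abort("need 0 <= x <= n")
  if (alpha <= 0 || alpha >= 1) rlang::abort("alpha must lie in (0, 1)")
  out <- numeric(length(x))
  pos <- x > 0
  out[pos] <- stats::qbeta(alpha, x[pos], n - x[pos] + 1)
  out
}

#' Clopper-Pearson equal-tailed two-sided interval
#'
#' Exact two-sided interval for a binomial proportion at confidence `level`,
#' placing `(1 - level) / 2` in each tail. The endpoints are 0 at `x = 0`
#' and 1 at `x = n`.
#'
#' @inheritParams cp_binomial_lower
#' @param level Confidence level in (0, 1]; `level = 1` gives `[0, 1]`.
#' @return A tibble with columns `x`, `n`, `level`, `lower`, `upper`.
#' @examples
#' cp_binomial_two_sided(11, 22, 0.95)
#' @export
cp_binomial_two_sided <- function(x, n, level = 0.95) {
  if (any(x < 0 | x > n)) rlang::abort("need 0 <= x <= n")
  if (level <= 0 || level > 1) rlang::abort("level must lie in (0, 1]")
  tail <- (1 - level) / 2
  lower <- ifelse(x == 0, 0, stats::qbeta(tail, x, n - x + 1))
  upper <- ifelse(x == n, 1, stats::qbeta(1 - tail, x + 1, n - x))
  tibble::tibble(x = x, n = n, level = level, lower = lower, upper = upper)
}

# normalise an omega (tibble of rows, logical mask, or integer indices)
# to a logical membership vector over the rows of `space`
omega_index <- function(space, omega) {
  if (is.logical(omega)) {
    stopifnot(length(omega) == nrow(space))
    return(omega)
  }
  if (is.numeric(omega)) {
    keep <- rep(FALSE, nrow(space))
    keep[omega] <- TRUE
    return(keep)
  }
  if (is.data.frame(omega)) {
    keep <- rep(FALSE, nrow(space))
    for (i in seq_len(nrow(omega))) {
      keep[locate_point(space, omega$x1[i], omega$x2[i])] <- TRUE
    }
    return(keep)
  }
  rlang::abort("omega must be a logical mask, row indices, or a tibble of points")
}

#' Probability of a confidence set at a given response rate
#'
#' `P(Omega | pi)`: the sum of exact outcome probabilities over a subset of
#' the sample space.
#'
#' @param space An [sample_space()] tibble.
#' @param omega A subset of the space: a logical mask over its rows, row
#'   indices, or a tibble of points with columns `x1`, `x2`.
#' @param pi True response rate in `[0, 1]` (vectorised).
#' @param design Optional explicit design.
#' @return Numeric vector of probabilities, one per element of `pi`.
#' @examples
#' toy <- adaptive_design(2, 0, 2, n2 = 2, r = 2, pi0 = 0.5)
#' sp <- sample_space(toy)
#' omega_probability(sp, sp$group == "G3", 0.5)  # 0.25
#' @export
omega_probability <- function(space, omega, pi, design = NULL) {
  design <- space_design(space, design)
  keep <- omega_index(space, omega)
  sub <- space[keep, , drop = FALSE]
  vapply(pi, function(p) sum(point_probability(sub, p, design)), numeric(1))
}

# Invert P(omega | pi) = alpha for the lower limit, given the profile of
# P on an increasing grid: L = inf{pi : P(omega | pi) > alpha}, the left
# endpoint of the smallest one-sided interval (L, 1] containing the
# collection {pi : P(omega | pi) > alpha}. Identical to the unique root of
# P = alpha when the profile is monotone (the usual case: every confidence
# set that is an upper set of the sample space has a non-decreasing
# profile); for non-monotone profiles this choice is the one that keeps the
# coverage guarantee. Returns a list so callers can aggregate diagnostics:
#   value      the limit (1 when no pi has P > alpha: empty interval)
#   monotone   profile non-decreasing on the grid?
#   degenerate profile never exceeds alpha?
invert_profile <- function(f, grid, profile, alpha, tol = 1e-10) {
  monotone <- !any(diff(profile) < -1e-9)
  if (profile[1] > alpha) {
    return(list(value = 0, monotone = monotone, degenerate = FALSE))
  }
  above <- which(profile > alpha)
  if (length(above) == 0) {
    # Eq.-(1) collection empty: no pi makes the set probable enough
    return(list(value = 1, monotone = monotone, degenerate = TRUE))
  }
  i <- min(above) - 1L # first upcrossing lies in (grid[i], grid[i+1]]
  root <- stats::uniroot(function(p) f(p) - alpha, c(grid[i], grid[i + 1L]),
                         tol = tol)$root
  list(value = root, monotone = monotone, degenerate = FALSE)
}

#' Exact one-sided lower confidence limit for a confidence set
#'
#' Inverts the exact probability of a confidence set: the `1 - alpha`
#' interval is `(L, 1]`, the smallest one-sided interval containing the
#' collection `{pi : P(omega | pi) > alpha}`, so
#' `L = inf{pi in [0, 1] : P(omega | pi) > alpha}`. When the profile
#' `P(omega | .)` is increasing (always the case when the set is an upper
#' set of the sample space, as under `RR`, `PV`, `RR-A` and `RR-B`) this is
#' the unique root of `P(omega | pi) = alpha`, found to absolute tolerance
#' better than 1e-8; when the set already has probability above `alpha` at
#' `pi = 0` the limit is 0. Monotonicity is checked on a 512-point
#' diagnostic grid and a non-monotone profile (possible for the uncentered
#' `RR-LR`/`RR-Score` statistics) is reported with a warning; the
#' first-upcrossing definition above is exactly what keeps the coverage
#' guarantee in that case.
#'
#' @inheritParams omega_probability
#' @param alpha One-sided significance level in (0, 1).
#' @return The lower limit, a single value in `[0, 1)`.
#' @examples
#' toy <- adaptive_design(2, 0, 2, n2 = 2, r = 2, pi0 = 0.5)
#' sp <- sample_space(toy)
#' lower_limit(sp, sp$group == "G3", alpha = 0.05)  # sqrt(0.05)
#' @export
lower_limit <- function(space, omega, alpha = 0.05, design = NULL) {
  design <- space_design(space, design)
  if (alpha <= 0 || alpha >= 1) rlang::abort("alpha must lie in (0, 1)")
  keep <- omega_index(space, omega)
  if (!any(keep)) rlang::abort("omega must be nonempty")
  sub <- space[keep, , drop = FALSE]
  f <- function(p) sum(point_probability(sub, p, design))
  grid <- seq(0, 1, length.out = 512)
  profile <- vapply(grid, f, numeric(1))
  res <- invert_profile(f, grid, profile, alpha)
  if (res$degenerate) {
    rlang::abort(c(
      "lower-limit inversion failed: P(omega | pi) never exceeds alpha",
      sprintf("profile maximum %.3g over a %d-point diagnostic grid",
              max(profile), length(grid))
    ))
  }
  if (!res$monotone) {
    rlang::warn("P(omega | pi) is not monotone in pi; using the first upcrossing of alpha")
  }
  res$value
}

#' Exact lower limits for every terminal outcome
#'
#' Computes the `1 - alpha` one-sided lower confidence limit of every
#' terminal outcome under a chosen sample-space ordering, by
#' Clopper-Pearson inversion of the ordering's confidence sets. Stage-1
#' stops (futility and efficacy) have limits equal to the Clopper-Pearson
#' binomial lower limit at `n1` under every ordering. The `RR` ordering is
#' only a partial order, so its limits are not exact (coverage may fall
#' below `1 - alpha`); the five total orderings are exact.
#'
#' @param space An [sample_space()] tibble.
#' @param ordering One of `"RR"`, `"PV"`, `"RR-A"`, `"RR-B"`, `"RR-LR"`,
#'   `"RR-Score"`.
#' @param alpha One-sided significance level; defaults to the design's.
#' @param pi0 Null rate for the `PV` ordering; defaults to the design's.
#' @param design Optional explicit design.
#' @return A tibble of class `limit_table` with columns `x1`, `x2`, `group`,
#'   `ordering`, `lower_limit`, `exact`; attributes `alpha`, `ordering`,
#'   `design`.
#' @examples
#' toy <- adaptive_design(2, 0, 2, n2 = 2, r = 2, pi0 = 0.5)
#' limit_table(sample_space(toy), "PV")
#' @export
limit_table <- function(space, ordering, alpha = NULL, pi0 = NULL,
                        design = NULL) {
  design <- space_design(space, design)
  ordering <- match_ordering(ordering)
  alpha <- alpha %||% design$alpha
  if (alpha <= 0 || alpha >= 1) rlang::abort("alpha must lie in (0, 1)")
  n <- nrow(space)
  L <- numeric(n)
  stage1 <- is.na(space$x2)
  L[stage1] <- cp_binomial_lower(space$x1[stage1], design$n1, alpha)

  g2_rows <- which(!stage1)
  if (length(g2_rows) > 0) {
    # shared diagnostic grid: probability of every point at every grid pi
    grid <- seq(0, 1, length.out = 512)
    pmat <- probability_matrix(space, grid, design)
    if (ordering == "RR") {
      members <- lapply(g2_rows, function(i) {
        tail_members(space, space$x1[i], space$x2[i], design)
      })
    } else {
      key <- ordering_key(space, ordering, alpha = alpha, pi0 = pi0,
                          design = design,
                          tie_tol = if (ordering == "RR-A") 1e-10 else 0)
      members <- lapply(g2_rows, function(i) key$rank >= key$rank[i])
    }
    n_nonmono <- 0L
    n_degen <- 0L
    for (j in seq_along(g2_rows)) {
      keep <- members[[j]]
      sub <- space[keep, , drop = FALSE]
      f <- function(p) sum(point_probability(sub, p, design))
      profile <- colSums(pmat[keep, , drop = FALSE])
      res <- invert_profile(f, grid, profile, alpha)
      if (!res$monotone) n_nonmono <- n_nonmono + 1L
      if (res$degenerate) n_degen <- n_degen + 1L
      L[g2_rows[j]] <- res$value
    }
    if (n_nonmono > 0) {
      rlang::warn(sprintf(
        "%s ordering: %d confidence-set profile(s) not monotone in pi; used the first upcrossing of alpha",
        ordering, n_nonmono
      ))
    }
    if (n_degen > 0) {
      rlang::warn(sprintf(
        "%s ordering: %d outcome(s) whose confidence set never reaches probability alpha; reported the empty interval (lower limit 1)",
        ordering, n_degen
      ))
    }
  }

  out <- tibble::tibble(
    x1 = space$x1, x2 = space$x2, group = space$group,
    ordering = ordering, lower_limit = L, exact = ordering != "RR"
  )
  attr(out, "alpha") <- alpha
  attr(out, "ordering") <- ordering
  attr(out, "design") <- design
  class(out) <- c("limit_table", class(out))
  out
}

#' @describeIn limit_table `glance()` summarises a limit table: ordering,
#'   `alpha`, exactness flag and the simple average interval length over the
#'   completed two-stage outcomes.
#' @param x A `limit_table`.
#' @param ... Unused.
#' @method glance limit_table
#' @export
glance.limit_table <- function(x, ...) {
  tibble::tibble(
    ordering = attr(x, "ordering"),
    alpha = attr(x, "alpha"),
    exact = attr(x, "ordering") != "RR",
    m2 = sum(x$group == "G2"),
    average_length = average_length(x)
  )
}
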