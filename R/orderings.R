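#' Exact p-value of each terminal outcome
#'
#' The p-value of a completed two-stage outcome is the null probability of
#' its tail area: `P(x1, x2) = sum over (x1', x2') in Theta(x1, x2) of
#' b(x1'; n1, pi0) * b(x2'; n2(x1'), pi0)`. For a stage-1 stop it is the
#' marginal upper tail `P(X1 >= x1 | n1, pi0)`, so futility stops carry the
#' largest p-values and efficacy stops the smallest.
#'
#' @param space An [sample_space()] tibble.
#' @param pi0 Null response rate in (0, 1); defaults to the design's `pi0`.
#' @param design Optional explicit design.
#' @return `space` with an added `p_value` column.
#' @examples
#' toy <- adaptive_design(2, 0, 2, n2 = 2, r = 2, pi0 = 0.5)
#' p_values(sample_space(toy))
#' @export
p_values <- function(space, pi0 = NULL, design = NULL) {
  design <- space_design(space, design)
  pi0 <- pi0 %||% design$pi0
  if (length(pi0) != 1 || is.na(pi0) || pi0 <= 0 || pi0 >= 1) {
    rlang::abort("pi0 must be a single value in (0, 1)")
  }
  probs <- point_probability(space, pi0, design)
  pv <- numeric(nrow(space))
  for (i in seq_len(nrow(space))) {
    if (is.na(space$x2[i])) {
      pv[i] <- stats::pbinom(space$x1[i] - 1L, design$n1, pi0, lower.tail = FALSE)
    } else {
      pv[i] <- sum(probs[tail_members(space, space$x1[i], space$x2[i], design)])
    }
  }
  out <- space
  out$p_value <- pv
  out
}

#' Scalar ordering statistics for completed two-stage outcomes
#'
#' The three classical orderings reduce each completed outcome to a scalar
#' computed from the average response rate
#' `rate = (x1 + x2) / (n1 + n2(x1))`:
#' `RR-B` uses the rate itself (equivalently, the MLE ordering), `RR-LR`
#' uses `rate * sqrt(n2(x1))` and `RR-Score` uses `rate * n2(x1)`. When
#' `n2` is constant the three are monotone transforms of each other and
#' induce the same ordering; with an adaptive `n2(x1)` they differ.
#'
#' @param space An [sample_space()] tibble; rows outside `G2` get `NA`.
#' @param ordering One of `"RR-B"`, `"RR-LR"`, `"RR-Score"`.
#' @param design Optional explicit design.
#' @return Numeric vector of statistics, one per row of `space` (`NA` for
#'   stage-1 stops).
#' @examples
#' toy <- adaptive_design(2, 0, 2, n2 = 2, r = 2, pi0 = 0.5)
#' ordering_metric(sample_space(toy), "RR-B")
#' @export
ordering_metric <- function(space, ordering, design = NULL) {
  design <- space_design(space, design)
  if (!ordering %in% c("RR-B", "RR-LR", "RR-Score")) {
    rlang::abort("ordering_metric is defined for RR-B, RR-LR and RR-Score")
  }
  out <- rep(NA_real_, nrow(space))
  g2 <- space$group == "G2"
  if (!any(g2)) return(out)
  n2 <- as.numeric(design$n2[as.character(space$x1[g2])])
  rate <- (space$x1[g2] + space$x2[g2]) / (design$n1 + n2)
  out[g2] <- switch(ordering,
    "RR-B" = rate,
    "RR-LR" = rate * sqrt(n2),
    "RR-Score" = rate * n2
  )
  out
}

# Composite ordering key for the five total orderings.
#
# Futility stops always rank lowest (by x1), then completed outcomes by the
# ordering statistic, then efficacy stops (by x1). Larger key = more extreme
# evidence = larger lower limit. Returns a list with the per-row numeric
# within-group statistic and an integer dense rank (ties share a rank).
ordering_key <- function(space, ordering, alpha = NULL, pi0 = NULL,
                         design = NULL, tie_tol = 0) {
  design <- space_design(space, design)
  ordering <- match_ordering(ordering)
  if (ordering == "RR") {
    rlang::abort("RR is a partial order; it has no scalar ordering key")
  }
  stat <- switch(ordering,
    "PV" = -p_values(space, pi0, design)$p_value,
    "RR-A" = {
      alpha <- alpha %||% design$alpha
      limit_table(space, "RR", alpha = alpha, design = design)$lower_limit
    },
    ordering_metric(space, ordering, design)
  )
  # stage-1 stops ordered marginally by x1 within their group
  stat[is.na(stat)] <- space$x1[is.na(stat)]
  grp <- match(space$group, c("G1", "G2", "G3"))
  rank <- integer(nrow(space))
  pos <- 0L
  for (g in 1:3) {
    idx <- which(grp == g)
    if (length(idx) == 0) next
    s <- stat[idx]
    o <- order(s)
    rk <- integer(length(idx))
    last <- -Inf
    cur <- 0L
    for (j in o) {
      if (s[j] > last + tie_tol) {
        cur <- cur + 1L
        last <- s[j]
      }
      rk[j] <- cur
    }
    rank[idx] <- pos + rk
    pos <- pos + max(rk)
  }
  list(stat = stat, rank = rank)
}

#' Confidence set of an outcome under a sample-space ordering
#'
#' The confidence set `Omega(x1, x2)` collects the outcomes at least as
#' extreme as the observed one; inverting its probability (see
#' [lower_limit()]) yields the exact one-sided lower confidence limit.
#' Under `RR` the set is the tail area itself (a partial order: two
#' completed outcomes are comparable only when one lies in the other's
#' tail). Under the five total orderings (`PV`, `RR-A`, `RR-B`, `RR-LR`,
#' `RR-Score`) the set contains every outcome whose ordering statistic is at
#' least the observed one, ties included, so the sets are nested. Every
#' confidence set contains the outcome itself and all efficacy stops.
#'
#' @param space An [sample_space()] tibble.
#' @param x1,x2 Observed outcome (`x2 = NA` for a stage-1 stop).
#' @param ordering One of `"RR"`, `"PV"`, `"RR-A"`, `"RR-B"`, `"RR-LR"`,
#'   `"RR-Score"`.
#' @param alpha Significance level used by the first pass of `RR-A`;
#'   defaults to the design's `alpha`.
#' @param pi0 Null rate used by `PV`; defaults to the design's `pi0`.
#' @param design Optional explicit design.
#' @return The rows of `space` forming the confidence set.
#' @examples
#' toy <- adaptive_design(2, 0, 2, n2 = 2, r = 2, pi0 = 0.5)
#' sp <- sample_space(toy)
#' confidence_set(sp, 1, 1, "PV")
#' @export
confidence_set <- function(space, x1, x2 = NA_integer_, ordering = "PV",
                           alpha = NULL, pi0 = NULL, design = NULL) {
  design <- space_design(space, design)
  ordering <- match_ordering(ordering)
  if (ordering == "RR") {
    return(tail_set(space, x1, x2, design))
  }
  i <- locate_point(space, x1, x2)
  key <- ordering_key(space, ordering, alpha = alpha, pi0 = pi0,
                      design = design,
                      tie_tol = if (ordering == "RR-A") 1e-10 else 0)
  space[key$rank >= key$rank[i], , drop = FALSE]
}

#' Rank every outcome under a total ordering
#'
#' Adds the per-outcome ordering statistic, its dense rank (1 = least
#' extreme; ties share a rank) and the size of the induced confidence set to
#' the sample-space tibble. Futility stops always rank below completed
#' outcomes, which rank below efficacy stops.
#'
#' @inheritParams confidence_set
#' @return `space` with added columns `statistic`, `rank`, `omega_size`.
#' @examples
#' toy <- adaptive_design(2, 0, 2, n2 = 2, r = 2, pi0 = 0.5)
#' order_space(sample_space(toy), "RR-B")
#' @export
order_space <- function(space, ordering, alpha = NULL, pi0 = NULL,
                        design = NULL) {
  design <- space_design(space, design)
  ordering <- match_ordering(ordering)
  if (ordering == "RR") {
    rlang::abort("RR is a partial order; use tail_set() for its sets")
  }
  key <- ordering_key(space, ordering, alpha = alpha, pi0 = pi0,
                      design = design,
                      tie_tol = if (ordering == "RR-A") 1e-10 else 0)
  out <- space
  out$statistic <- key$stat
  out$rank <- key$rank
  out$omega_size <- vapply(key$rank, function(r) sum(key$rank >= r), integer(1))
  out
}
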