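# Shared fixtures and independent oracles.
#
# The oracles deliberately avoid the package's own code paths: binomial-tail
# bisection instead of qbeta, dense-grid scans instead of uniroot.

toy_design <- function() {
  adaptive_design(
    n1 = 2, r1_futility = 0, r1_efficacy = 2,
    n2 = c(`1` = 2), r = c(`1` = 2),
    pi0 = 0.5, pi1 = 0.8, alpha = 0.05, beta = 0.2
  )
}

# solve P(X >= x | n, p) = target by bisection on the binomial tail
oracle_binom_tail_root <- function(x, n, target, upper_tail = TRUE, iters = 60) {
  f <- function(p) {
    tail <- if (upper_tail) {
      stats::pbinom(x - 1, n, p, lower.tail = FALSE) # P(X >= x)
    } else {
      stats::pbinom(x, n, p) # P(X <= x)
    }
    tail - target
  }
  lo <- 0
  hi <- 1
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    # upper tail increases in p, lower tail decreases
    rising <- if (upper_tail) f(mid) < 0 else f(mid) > 0
    if (rising) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

oracle_cp_lower <- function(x, n, alpha) {
  if (x == 0) return(0)
  oracle_binom_tail_root(x, n, alpha, upper_tail = TRUE)
}

oracle_cp_two_sided <- function(x, n, level) {
  tail <- (1 - level) / 2
  lower <- if (x == 0) 0 else oracle_binom_tail_root(x, n, tail, upper_tail = TRUE)
  upper <- if (x == n) 1 else oracle_binom_tail_root(x, n, tail, upper_tail = FALSE)
  c(lower, upper)
}

# first upcrossing of alpha by P(omega | pi), located by a dense grid scan
# (step 1e-5) with linear interpolation inside the bracketing cell
oracle_lower_limit <- function(space, omega, alpha, design = NULL,
                               step = 1e-5) {
  if (is.null(design)) design <- attr(space, "design")
  sub <- space[adaptci:::omega_index(space, omega), , drop = FALSE]
  grid <- seq(0, 1, by = step)
  profile <- rep(0, length(grid))
  for (i in seq_len(nrow(sub))) {
    p1 <- stats::dbinom(sub$x1[i], design$n1, grid)
    if (!is.na(sub$x2[i])) {
      n2 <- design$n2[[as.character(sub$x1[i])]]
      p1 <- p1 * stats::dbinom(sub$x2[i], n2, grid)
    }
    profile <- profile + p1
  }
  if (profile[1] > alpha) return(0)
  above <- which(profile > alpha)
  if (length(above) == 0) return(1)
  i <- min(above)
  # linear interpolation across the bracketing cell
  g0 <- grid[i - 1]
  g1 <- grid[i]
  f0 <- profile[i - 1]
  f1 <- profile[i]
  g0 + (alpha - f0) / (f1 - f0) * (g1 - g0)
}

# designs small enough for the dense-grid oracle
tiny_designs <- function(seeds = 1:8) {
  lapply(seeds, function(s) {
    generate_design(s, n1_range = c(4L, 6L), n2_max = 3L, pi0 = 0.4, alpha = 0.1)
  })
}

TOTAL_ORDERINGS <- c("PV", "RR-A", "RR-B", "RR-LR", "RR-Score")
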