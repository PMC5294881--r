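#' Synthesize a random valid adaptive two-stage design
#'
#' Draws a structurally valid design for testing and simulation studies.
#' The generator deliberately mixes the qualitative shapes an adaptive
#' design can take: with probability 0.25 the efficacy bound is the
#' sentinel `n1 + 1` (no efficacy stop, empty `G3`); with probability 0.15
#' the continuation region is a single `X1` value; with probability 0.2 the
#' second-stage size is constant (the non-adaptive special case), otherwise
#' `n2` is a non-increasing random step function. Critical values are drawn
#' so that the number of tolerated failures `x1 + n2(x1) + 1 - r(x1)` is
#' non-decreasing in `x1`, which keeps the decision rule monotone (the
#' rejection probability is then non-decreasing in the true rate).
#'
#' The draw is deterministic for a fixed `seed` and leaves the global RNG
#' state untouched.
#'
#' @param seed Integer seed.
#' @param n1_range Length-2 integer range for the stage-1 sample size.
#' @param n2_max Largest second-stage size per continuation value.
#' @param pi0 Null response rate of the generated design.
#' @param alpha One-sided significance level of the generated design.
#' @param pi1 Alternative rate; default `pi0 + 0.2`.
#' @param beta Type II error target stored on the design.
#' @return A valid [adaptive_design()].
#' @examples
#' d <- generate_design(1)
#' validate_design(d)  # character(0)
#' @export
generate_design <- function(seed, n1_range = c(6L, 15L), n2_max = 10L,
                            pi0 = 0.3, alpha = 0.05, pi1 = pi0 + 0.2,
                            beta = 0.1) {
  if (length(n1_range) != 2 || n1_range[1] < 3 || n1_range[2] < n1_range[1]) {
    rlang::abort("n1_range must be an increasing pair with minimum >= 3")
  }
  if (n2_max < 1) rlang::abort("n2_max must be >= 1")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  draw1 <- function(v) v[sample.int(length(v), 1L)] # sample() misbehaves on scalars

  n1 <- draw1(n1_range[1]:n1_range[2])
  empty_g3 <- stats::runif(1) < 0.25
  single_cont <- stats::runif(1) < 0.15
  # continuation region {r1f+1, ..., r1e-1}, always nonempty
  if (empty_g3) {
    r1e <- n1 + 1L
    r1f <- if (single_cont) n1 - 1L else draw1(-1:(n1 - 2L))
  } else {
    r1f <- draw1(-1:(n1 - 3L))
    r1e <- if (single_cont) r1f + 2L else draw1((r1f + 3L):n1)
  }
  cont <- cont_domain(r1f, r1e)
  k <- length(cont)

  n2 <- if (stats::runif(1) < 0.2) {
    rep(draw1(1:n2_max), k)
  } else {
    sort(sample(1:n2_max, k, replace = TRUE), decreasing = TRUE)
  }
  # tolerated-failure counts, non-decreasing in x1, within every bound
  a <- sort(sample(0:(min(n2) + 1L), k, replace = TRUE))
  r <- cont + n2 + 1L - a

  design <- adaptive_design(
    n1 = n1, r1_futility = r1f, r1_efficacy = r1e,
    n2 = n2, r = r, pi0 = pi0, pi1 = pi1, alpha = alpha, beta = beta
  )
  stop_if_invalid(design)
  design
}
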