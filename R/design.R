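#' Specify an adaptive one-arm two-stage design
#'
#' An adaptive two-stage design enrols `n1` participants in stage 1 and stops
#' early for futility when the response count `X1 <= r1_futility`, or for
#' efficacy when `X1 >= r1_efficacy`. For intermediate `X1` the trial
#' continues with `n2[X1]` further participants and the treatment is declared
#' active when `X1 + X2 >= r[X1]`. The second-stage size must be a
#' non-increasing function of `X1`: the more responses already seen, the fewer
#' additional participants are needed.
#'
#' Sentinels: `r1_futility = -1` means the trial never stops early for
#' futility; `r1_efficacy = n1 + 1` means it never stops early for efficacy
#' (the efficacy-stop group G3 is then empty).
#'
#' @param n1 Stage-1 sample size (positive integer).
#' @param r1_futility Futility bound `r1(f)`; stop after stage 1 when
#'   `X1 <= r1_futility`. Use `-1` for no futility stop.
#' @param r1_efficacy Efficacy bound `r1(e)`; stop after stage 1 when
#'   `X1 >= r1_efficacy`. Use `n1 + 1` for no efficacy stop.
#' @param n2 Integer vector of second-stage sizes, one per continuation value
#'   `X1 = r1_futility + 1, ..., r1_efficacy - 1`, in that order. Names, if
#'   present, must be those `X1` values.
#' @param r Integer vector of critical values `r(X1)` on the same domain as
#'   `n2`; the null is rejected at the end of stage 2 when `X1 + X2 >= r(X1)`.
#' @param pi0 Historical (null) response rate, in (0, 1).
#' @param pi1 Alternative response rate, in (`pi0`, 1).
#' @param alpha One-sided significance level, in (0, 1).
#' @param beta Targeted type II error rate, in (0, 1).
#'
#' @return An object of class `adaptive_design`: a list with the fields above,
#'   `n2` and `r` stored as integer vectors named by continuation `X1`.
#' @examples
#' # a deliberately tiny design used throughout the documentation
#' toy <- adaptive_design(
#'   n1 = 2, r1_futility = 0, r1_efficacy = 2,
#'   n2 = c(`1` = 2), r = c(`1` = 2),
#'   pi0 = 0.5, pi1 = 0.8, alpha = 0.05, beta = 0.2
#' )
#' validate_design(toy)
#' @seealso [validate_design()], [sample_space()], [generate_design()]
#' @export
adaptive_design <- function(n1, r1_futility, r1_efficacy, n2, r,
                            pi0 = 0.3, pi1 = 0.5, alpha = 0.05, beta = 0.1) {
  cont <- cont_domain(r1_futility, r1_efficacy)
  n2 <- as.integer(n2)
  r <- as.integer(r)
  if (length(n2) == length(cont)) names(n2) <- as.character(cont)
  if (length(r) == length(cont)) names(r) <- as.character(cont)
  design <- structure(
    list(
      n1 = as.integer(n1),
      r1_futility = as.integer(r1_futility),
      r1_efficacy = as.integer(r1_efficacy),
      n2 = n2, r = r,
      pi0 = as.numeric(pi0), pi1 = as.numeric(pi1),
      alpha = as.numeric(alpha), beta = as.numeric(beta)
    ),
    class = "adaptive_design"
  )
  design
}

# continuation domain {r1(f)+1, ..., r1(e)-1}; empty when bounds touch
cont_domain <- function(r1_futility, r1_efficacy) {
  lo <- r1_futility + 1L
  hi <- r1_efficacy - 1L
  if (hi < lo) integer(0) else seq.int(lo, hi)
}

#' Continuation values of a design
#'
#' Stage-1 response counts for which the trial proceeds to stage 2.
#'
#' @param design An [adaptive_design()].
#' @return Integer vector `r1_futility + 1, ..., r1_efficacy - 1`.
#' @export
continuation_values <- function(design) {
  cont_domain(design$r1_futility, design$r1_efficacy)
}

#' Validate an adaptive two-stage design
#'
#' Checks every structural constraint an adaptive design must satisfy and
#' reports the violations; it never throws. An empty return value means the
#' design is valid.
#'
#' Constraints: `-1 <= r1_futility < r1_efficacy <= n1 + 1`; the domains of
#' `n2` and `r` are exactly the continuation values; `n2` is non-increasing in
#' `X1` and at least 1; `X1 <= r(X1) <= X1 + n2(X1) + 1`; `0 < pi0 < pi1 < 1`;
#' `alpha`, `beta` in (0, 1).
#'
#' @param design An [adaptive_design()].
#' @return Character vector of human-readable violation descriptions
#'   (zero-length when the design is valid).
#' @examples
#' toy <- adaptive_design(2, 0, 2, n2 = 2, r = 2, pi0 = 0.5)
#' validate_design(toy)  # character(0)
#' @export
validate_design <- function(design) {
  v <- character(0)
  n1 <- design$n1
  f <- design$r1_futility
  e <- design$r1_efficacy
  bad_scalar <- function(x) !is.numeric(x) || length(x) != 1L || is.na(x)
  if (bad_scalar(n1) || n1 < 1) {
    v <- c(v, "n1: must be a positive integer")
    return(v)
  }
  if (bad_scalar(f) || bad_scalar(e)) {
    return(c(v, "r1_futility/r1_efficacy: must be single integers"))
  }
  if (f < -1) v <- c(v, "r1_futility: must be >= -1")
  if (!(f < e)) v <- c(v, "r1_futility/r1_efficacy: need r1_futility < r1_efficacy")
  if (e > n1 + 1) v <- c(v, "r1_efficacy: must be <= n1 + 1")
  cont <- cont_domain(f, e)
  for (field in c("n2", "r")) {
    dom <- suppressWarnings(as.integer(names(design[[field]])))
    if (length(design[[field]]) != length(cont) ||
        (length(cont) > 0 && (anyNA(dom) || !identical(dom, cont)))) {
      v <- c(v, sprintf(
        "%s: domain must be exactly the continuation values {%s}",
        field, paste(cont, collapse = ", ")
      ))
    }
  }
  if (length(design$n2) == length(cont) && length(cont) > 0) {
    n2 <- as.integer(design$n2)
    if (any(n2 < 1)) v <- c(v, "n2: every second-stage size must be >= 1")
    if (is.unsorted(rev(n2), strictly = FALSE)) {
      v <- c(v, "n2: must be non-increasing in X1")
    }
    if (length(design$r) == length(cont)) {
      r <- as.integer(design$r)
      low <- cont
      high <- cont + n2 + 1L
      if (any(r < low | r > high)) {
        v <- c(v, "r: need X1 <= r(X1) <= X1 + n2(X1) + 1 for every continuation X1")
      }
    }
  }
  if (bad_scalar(design$pi0) || design$pi0 <= 0 || design$pi0 >= 1) {
    v <- c(v, "pi0: must lie in (0, 1)")
  } else if (!bad_scalar(design$pi1) &&
             (design$pi1 <= design$pi0 || design$pi1 >= 1)) {
    v <- c(v, "pi1: must lie in (pi0, 1)")
  }
  if (bad_scalar(design$alpha) || design$alpha <= 0 || design$alpha >= 1) {
    v <- c(v, "alpha: must lie in (0, 1)")
  }
  if (bad_scalar(design$beta) || design$beta <= 0 || design$beta >= 1) {
    v <- c(v, "beta: must lie in (0, 1)")
  }
  v
}

stop_if_invalid <- function(design) {
  v <- validate_design(design)
  if (length(v) > 0) {
    rlang::abort(c("invalid adaptive design", v))
  }
  invisible(design)
}

#' @export
print.adaptive_design <- function(x, ...) {
  cat(sprintf(
    "Adaptive two-stage design: n1 = %d, r1(f) = %d, r1(e) = %d\n",
    x$n1, x$r1_futility, x$r1_efficacy
  ))
  cat(sprintf(
    "  pi0 = %g, pi1 = %g, alpha = %g, beta = %g\n",
    x$pi0, x$pi1, x$alpha, x$beta
  ))
  cont <- continuation_values(x)
  if (length(cont) == 0) {
    cat("  no continuation region (stage 1 always terminal)\n")
  } else {
    cat("  continuation:\n")
    tab <- tibble::tibble(x1 = cont, n2 = unname(x$n2), r = unname(x$r))
    print(tab, n = Inf)
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @describeIn adaptive_design `tidy()` returns the continuation table, one
#'   row per continuation `X1` with its `n2` and `r`.
#' @param x An `adaptive_design`.
#' @param ... Unused; for generic consistency.
#' @method tidy adaptive_design
#' @export
tidy.adaptive_design <- function(x, ...) {
  cont <- continuation_values(x)
  tibble::tibble(x1 = cont, n2 = as.integer(x$n2), r = as.integer(x$r))
}

#' @describeIn adaptive_design `glance()` returns a one-row summary
#'   (design parameters, group sizes and maximum total sample size).
#' @method glance adaptive_design
#' @export
glance.adaptive_design <- function(x, ...) {
  cont <- continuation_values(x)
  tibble::tibble(
    n1 = x$n1,
    r1_futility = x$r1_futility,
    r1_efficacy = x$r1_efficacy,
    n_continuation = length(cont),
    m2 = if (length(cont)) sum(as.integer(x$n2) + 1L) else 0L,
    n_max = x$n1 + if (length(cont)) max(as.integer(x$n2)) else 0L,
    pi0 = x$pi0, pi1 = x$pi1, alpha = x$alpha, beta = x$beta
  )
}

#' Apply the trial decision rule to an observed outcome
#'
#' Returns whether the null hypothesis `pi <= pi0` is rejected (the treatment
#' is declared promising) for a terminal outcome of the design: rejection when
#' the trial stops for efficacy (`x1 >= r1_efficacy`), or when it continues
#' and the combined responses reach the critical value, `x1 + x2 >= r(x1)`.
#'
#' @param design An [adaptive_design()].
#' @param x1 Stage-1 response count.
#' @param x2 Stage-2 response count, or `NA` for an outcome that stopped at
#'   stage 1.
#' @return `TRUE` if the null is rejected, `FALSE` otherwise.
#' @examples
#' toy <- adaptive_design(2, 0, 2, n2 = 2, r = 2, pi0 = 0.5)
#' reject_null(toy, x1 = 2)          # efficacy stop
#' reject_null(toy, x1 = 1, x2 = 1)  # 1 + 1 >= r(1) = 2
#' @export
reject_null <- function(design, x1, x2 = NA_integer_) {
  stop_if_invalid(design)
  x1 <- as.integer(x1)
  x2 <- as.integer(x2)
  if (is.na(x1) || x1 < 0 || x1 > design$n1) {
    rlang::abort(sprintf("x1 = %s is not a stage-1 outcome of this design", x1))
  }
  if (x1 <= design$r1_futility) {
    if (!is.na(x2)) {
      rlang::abort(sprintf("(%d, %d): the trial stops at stage 1 for futility, x2 must be absent", x1, x2))
    }
    return(FALSE)
  }
  if (x1 >= design$r1_efficacy) {
    if (!is.na(x2)) {
      rlang::abort(sprintf("(%d, %d): the trial stops at stage 1 for efficacy, x2 must be absent", x1, x2))
    }
    return(TRUE)
  }
  key <- as.character(x1)
  if (is.na(x2) || x2 < 0 || x2 > design$n2[[key]]) {
    rlang::abort(sprintf(
      "(%d, %s): continuation outcome needs 0 <= x2 <= n2(%d) = %d",
      x1, x2, x1, design$n2[[key]]
    ))
  }
  x1 + x2 >= design$r[[key]]
}

#' Exact operating characteristics of a design
#'
#' Rejection probability, probability of early termination (PET) and expected
#' total sample size at one or more true response rates, all computed by exact
#' binomial enumeration. For an arbitrary input design the rejection
#' probability need not respect the nominal `alpha`/`beta`; the values are
#' reported as-is.
#'
#' @param design An [adaptive_design()].
#' @param pi Numeric vector of true response rates in `[0, 1]`.
#' @return A tibble with columns `pi`, `reject_prob`, `pet`,
#'   `expected_sample_size`.
#' @examples
#' toy <- adaptive_design(2, 0, 2, n2 = 2, r = 2, pi0 = 0.5)
#' operating_characteristics(toy, c(0, 0.5, 1))
#' @export
operating_characteristics <- function(design, pi) {
  stop_if_invalid(design)
  if (any(pi < 0 | pi > 1)) rlang::abort("pi must lie in [0, 1]")
  space <- sample_space(design)
  rejects <- purrr::map2_lgl(space$x1, space$x2, \(a, b) reject_null(design, a, b))
  cont <- continuation_values(design)
  purrr::map_dfr(pi, function(p) {
    probs <- point_probability(space, p)
    pet <- sum(probs[space$group != "G2" & is.na(space$x2)])
    # stage-1 stop rows are unique in x1, so pet is P(X1 <= r1f) + P(X1 >= r1e)
    en <- design$n1 +
      sum(stats::dbinom(cont, design$n1, p) * as.numeric(design$n2))
    tibble::tibble(
      pi = p,
      reject_prob = sum(probs[rejects]),
      pet = pet,
      expected_sample_size = en
    )
  })
}
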