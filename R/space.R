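#' Enumerate the terminal sample space of an adaptive design
#'
#' Every trial run ends in exactly one terminal outcome: a stage-1 futility
#' stop (`G1`, identified by `x1` alone), a completed two-stage run (`G2`,
#' identified by `(x1, x2)`), or a stage-1 efficacy stop (`G3`). The three
#' groups partition the sample space. Rows are in canonical order: `G1` by
#' `x1`, then `G2` lexicographically by `(x1, x2)`, then `G3` by `x1`.
#'
#' @param design A valid [adaptive_design()].
#' @return A tibble of class `adaptive_space` with columns `x1`, `x2` (`NA`
#'   for stage-1 stops) and `group`, carrying the design in attribute
#'   `"design"`.
#' @examples
#' toy <- adaptive_design(2, 0, 2, n2 = 2, r = 2, pi0 = 0.5)
#' sample_space(toy)
#' @export
sample_space <- function(design) {
  stop_if_invalid(design)
  g1 <- if (design$r1_futility >= 0) {
    tibble::tibble(x1 = 0:design$r1_futility, x2 = NA_integer_, group = "G1")
  } else {
    tibble::tibble(x1 = integer(0), x2 = integer(0), group = character(0))
  }
  cont <- continuation_values(design)
  g2 <- purrr::map_dfr(cont, function(k) {
    tibble::tibble(
      x1 = k,
      x2 = 0:design$n2[[as.character(k)]],
      group = "G2"
    )
  })
  g3 <- if (design$r1_efficacy <= design$n1) {
    tibble::tibble(x1 = design$r1_efficacy:design$n1, x2 = NA_integer_, group = "G3")
  } else {
    tibble::tibble(x1 = integer(0), x2 = integer(0), group = character(0))
  }
  space <- dplyr::bind_rows(g1, g2, g3)
  space$x1 <- as.integer(space$x1)
  space$x2 <- as.integer(space$x2)
  attr(space, "design") <- design
  class(space) <- c("adaptive_space", class(space))
  space
}

space_design <- function(space, design = NULL) {
  design <- design %||% attr(space, "design")
  if (is.null(design)) {
    rlang::abort("no design attached to this sample space; pass `design =` explicitly")
  }
  design
}

#' Exact probability of each terminal outcome
#'
#' The probability of a stage-1 stop at `x1` is the binomial mass
#' `b(x1; n1, pi)`; a completed two-stage outcome has probability
#' `b(x1; n1, pi) * b(x2; n2(x1), pi)`. Summed over the whole space these
#' equal 1 for any `pi`.
#'
#' @param space An [sample_space()] tibble (any subset of its rows works, as
#'   long as `design` is recoverable).
#' @param pi Scalar true response rate in `[0, 1]`.
#' @param design The design, if `space` has lost its `"design"` attribute.
#' @return Numeric vector of probabilities, one per row of `space`.
#' @examples
#' toy <- adaptive_design(2, 0, 2, n2 = 2, r = 2, pi0 = 0.5)
#' sp <- sample_space(toy)
#' sum(point_probability(sp, 0.37))  # 1
#' @export
point_probability <- function(space, pi, design = NULL) {
  design <- space_design(space, design)
  if (length(pi) != 1 || is.na(pi) || pi < 0 || pi > 1) {
    rlang::abort("pi must be a single value in [0, 1]")
  }
  p1 <- stats::dbinom(space$x1, design$n1, pi)
  cont <- !is.na(space$x2)
  if (any(cont)) {
    n2 <- as.numeric(design$n2[as.character(space$x1[cont])])
    p1[cont] <- p1[cont] * stats::dbinom(space$x2[cont], n2, pi)
  }
  p1
}

# probability matrix: rows = points of `space`, cols = values of `pi_grid`
probability_matrix <- function(space, pi_grid, design = NULL) {
  design <- space_design(space, design)
  m <- vapply(pi_grid, function(p) point_probability(space, p, design),
              numeric(nrow(space)))
  matrix(m, nrow = nrow(space), ncol = length(pi_grid))
}

#' Tail area of an outcome under the response-rate partial order
#'
#' For a completed two-stage outcome `(x1, x2)` the tail area collects every
#' outcome at least as extreme in both the stage-1 rate and the combined
#' rate, together with all efficacy stops:
#' all of `G3` plus the `(x1', x2')` in `G2` with `x1/n1 <= x1'/n1` and
#' `(x1 + x2) / (n1 + n2(x1)) <= (x1' + x2') / (n1 + n2(x1'))`.
#' Rate comparisons use integer cross-multiplication, so exact ties are
#' counted as inside the tail. For a stage-1 stop the tail is taken
#' marginally: all outcomes with `x1' >= x1` for a futility stop, and the
#' efficacy stops with `x1' >= x1` for an efficacy stop, which makes their
#' inverted limits coincide with the Clopper-Pearson binomial limits.
#'
#' @param space An [sample_space()] tibble.
#' @param x1,x2 The reference outcome; `x2 = NA` for a stage-1 stop.
#' @param design Optional explicit design.
#' @return The rows of `space` belonging to the tail area (always including
#'   the reference outcome).
#' @examples
#' toy <- adaptive_design(2, 0, 2, n2 = 2, r = 2, pi0 = 0.5)
#' sp <- sample_space(toy)
#' tail_set(sp, 1, 1)  # (1,1), (1,2) and the efficacy stop
#' @export
tail_set <- function(space, x1, x2 = NA_integer_, design = NULL) {
  design <- space_design(space, design)
  space[tail_members(space, x1, x2, design), , drop = FALSE]
}

# logical membership vector for the tail area Theta(x1, x2)
tail_members <- function(space, x1, x2, design) {
  x1 <- as.integer(x1)
  x2 <- as.integer(x2)
  locate_point(space, x1, x2) # errors if not a sample point
  if (is.na(x2)) {
    if (x1 <= design$r1_futility) {
      return(space$x1 >= x1)
    }
    return(space$group == "G3" & space$x1 >= x1)
  }
  n2 <- as.integer(design$n2)
  names(n2) <- names(design$n2)
  n2_ref <- n2[[as.character(x1)]]
  keep <- space$group == "G3"
  g2 <- space$group == "G2"
  if (any(g2)) {
    n2_other <- n2[as.character(space$x1[g2])]
    # exact rational comparison via cross multiplication
    rate_ok <- (x1 + x2) * (design$n1 + n2_other) <=
      (space$x1[g2] + space$x2[g2]) * (design$n1 + n2_ref)
    keep[g2] <- (space$x1[g2] >= x1) & rate_ok
  }
  keep
}

# row index of a point in the canonical space; errors when absent
locate_point <- function(space, x1, x2) {
  hit <- if (is.na(x2)) {
    which(space$x1 == x1 & is.na(space$x2))
  } else {
    which(space$x1 == x1 & !is.na(space$x2) & space$x2 == x2)
  }
  if (length(hit) != 1) {
    rlang::abort(sprintf(
      "(%s, %s) is not a terminal outcome of this design",
      x1, ifelse(is.na(x2), "-", x2)
    ))
  }
  hit
}

#' @describeIn sample_space `glance()` returns the group sizes, including
#'   `m2 = sum(n2(x1) + 1)`, the number of completed two-stage outcomes.
#' @param x An `adaptive_space`.
#' @param ... Unused.
#' @method glance adaptive_space
#' @export
glance.adaptive_space <- function(x, ...) {
  tibble::tibble(
    n_points = nrow(x),
    g1 = sum(x$group == "G1"),
    m2 = sum(x$group == "G2"),
    g3 = sum(x$group == "G3")
  )
}
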