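test_that("coverage uses the strict inequality and finds its worst case", {
  toy <- toy_design()
  sp <- sample_space(toy)
  lt <- limit_table(sp, "PV")
  cov <- coverage_curve(sp, lt, seq(0.01, 0.99, by = 0.01))
  expect_true(all(cov$coverage >= 0 & cov$coverage <= 1))
  # at pi exactly equal to a limit, the outcome with that limit is NOT covered
  Lmax <- max(lt$lower_limit)
  at <- cov$coverage[which(abs(cov$pi - Lmax) < 1e-12)]
  just_above <- cov$coverage[which(abs(cov$pi - (Lmax + 1e-9)) < 1e-12)]
  expect_length(at, 1)
  expect_true(just_above > at)
  # below every positive limit only zero-limit outcomes are covered
  small_pi <- min(lt$lower_limit[lt$lower_limit > 0]) / 2
  expect_equal(
    omega_probability(sp, lt$lower_limit == 0, small_pi),
    sum(point_probability(sp, small_pi)[lt$lower_limit < small_pi])
  )
  expect_error(coverage_curve(sp, lt, c(0, 0.5)), "pi_grid")
  g <- glance(cov)
  expect_equal(g$min_coverage, attr(cov, "min_coverage"))
})

test_that("the five total orderings are exact; the RR partial order is not", {
  # deeper sweep lives in the acceptance suite; spot-check here
  exact_ok <- TRUE
  rr_dip <- FALSE
  for (s in 1:5) {
    d <- generate_design(s)
    sp <- sample_space(d)
    for (o in c("PV", "RR-B")) {
      mc <- attr(coverage_curve(sp, limit_table(sp, o)), "min_coverage")
      exact_ok <- exact_ok && mc >= 1 - d$alpha - 1e-9
    }
    mc_rr <- attr(coverage_curve(sp, limit_table(sp, "RR")), "min_coverage")
    rr_dip <- rr_dip || mc_rr < 1 - d$alpha - 1e-9
  }
  expect_true(exact_ok)
  expect_true(rr_dip)
})

test_that("average length is the plain mean of interval lengths over the subset", {
  toy <- toy_design()
  sp <- sample_space(toy)
  lt <- limit_table(sp, "RR-B")
  # hand average from independently obtained limits of the three G2 outcomes
  L <- vapply(0:2, function(x2) {
    oracle_lower_limit(sp, confidence_set(sp, 1, x2, "RR-B"), toy$alpha)
  }, numeric(1))
  expect_equal(average_length(lt), mean(1 - L), tolerance = 1e-6)

  # degenerate table: zero limits give unit lengths
  lt0 <- lt
  lt0$lower_limit <- 0
  expect_equal(average_length(lt0), 1)

  # G2(CI) subset changes the denominator, never the numerator terms
  sub <- g2_ci_subset(sp, 0.95)
  expect_equal(average_length(lt, sub),
               mean(1 - lt$lower_limit[lt$group == "G2"][match(
                 paste(sub$x1, sub$x2),
                 paste(lt$x1[lt$group == "G2"], lt$x2[lt$group == "G2"])
               )]))
  expect_error(average_length(lt, tibble::tibble(x1 = 9, x2 = 9)), "subset")
})

test_that("expected length weights G2 lengths by exact outcome probabilities", {
  toy <- toy_design()
  sp <- sample_space(toy)
  lt <- limit_table(sp, "PV")
  # hand 3-term sum at pi = 0.5
  g2 <- lt[lt$group == "G2", ]
  hand <- sum((1 - g2$lower_limit) *
                dbinom(g2$x1, 2, 0.5) * dbinom(g2$x2, 2, 0.5))
  expect_equal(expected_length(sp, lt, 0.5), hand)
  # vanishing continuation probability at the boundary
  expect_lt(expected_length(sp, lt, 1e-4), 1e-3)
  expect_equal(expected_length(sp, lt, 0), 0)
  # all-zero limits recover the probability of reaching stage 2
  lt0 <- lt
  lt0$lower_limit <- 0
  for (pi in c(0.3, 0.8)) {
    expect_equal(expected_length(sp, lt0, pi),
                 omega_probability(sp, sp$group == "G2", pi))
  }
  # EL never exceeds the continuation probability
  for (s in c(5, 11)) {
    d <- generate_design(s)
    spg <- sample_space(d)
    ltg <- limit_table(spg, "RR-B")
    grid <- seq(0.05, 0.95, by = 0.05)
    expect_true(all(expected_length(spg, ltg, grid) <=
                      omega_probability(spg, spg$group == "G2", grid) + 1e-12))
  }
})

test_that("expected-length ratios are unity for identical tables and well-behaved", {
  d <- generate_design(7)
  sp <- sample_space(d)
  lt_b <- limit_table(sp, "RR-B")
  lt_pv <- limit_table(sp, "PV")
  same <- el_ratio(sp, lt_b, lt_b)
  expect_true(all(abs(same$ratio - 1) < 1e-12, na.rm = TRUE))
  cmp <- el_ratio(sp, lt_b, lt_pv)
  expect_true(all(cmp$ratio > 0, na.rm = TRUE))
  # near the boundary the two methods agree closely
  edge <- el_ratio(sp, lt_b, lt_pv, pi_grid = c(0.005, 0.995))
  expect_true(all(abs(edge$ratio - 1) < 0.05, na.rm = TRUE))
})

test_that("shorter RR intervals follow from their larger limits", {
  for (s in c(2, 9)) {
    sp <- sample_space(generate_design(s))
    expect_lte(average_length(limit_table(sp, "RR")),
               average_length(limit_table(sp, "PV")) + 1e-12)
  }
})

test_that("the practical subset keeps outcomes with concordant stage rates", {
  toy <- toy_design()
  sp <- sample_space(toy)
  # oracle: direct two-sided CP membership per outcome
  sub <- g2_ci_subset(sp, 0.95)
  ci <- oracle_cp_two_sided(1, 2, 0.95)
  g2 <- sp[sp$group == "G2", ]
  keep <- g2$x2 / 2 >= ci[1] - 1e-9 & g2$x2 / 2 <= ci[2] + 1e-9
  expect_setequal(paste(sub$x1, sub$x2), paste(g2$x1[keep], g2$x2[keep]))
  # full level keeps everything; subset is always within G2
  expect_equal(nrow(g2_ci_subset(sp, 1)), sum(sp$group == "G2"))
  for (s in c(4, 16)) {
    spg <- sample_space(generate_design(s))
    subg <- g2_ci_subset(spg, 0.95)
    expect_true(all(subg$group == "G2"))
    expect_lte(nrow(subg), sum(spg$group == "G2"))
  }
})
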