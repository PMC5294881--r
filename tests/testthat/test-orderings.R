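test_that("p-values are null tail-area sums with the marginal stage-1 convention", {
  sp <- p_values(sample_space(toy_design())) # pi0 = 0.5
  key <- paste(sp$x1, sp$x2)
  pv <- stats::setNames(sp$p_value, key)
  # hand sums over the tail areas at pi0 = 0.5
  expect_equal(pv[["1 1"]], 0.25 + 0.5 * 0.75)
  expect_equal(pv[["1 2"]], 0.25 + 0.5 * 0.25)
  expect_equal(pv[["1 0"]], 0.75)
  expect_equal(pv[["0 NA"]], 1.0)
  expect_equal(pv[["2 NA"]], 0.25)
  expect_error(p_values(sample_space(toy_design()), pi0 = 1.5), "pi0")
})

test_that("p-values separate the groups: futility largest, efficacy smallest", {
  for (s in c(3, 8, 21)) {
    sp <- p_values(sample_space(generate_design(s)))
    if (any(sp$group == "G1") && any(sp$group == "G2")) {
      expect_true(min(sp$p_value[sp$group == "G1"]) >
                    max(sp$p_value[sp$group == "G2"]))
    }
    if (any(sp$group == "G3") && any(sp$group == "G2")) {
      expect_true(max(sp$p_value[sp$group == "G3"]) <
                    min(sp$p_value[sp$group == "G2"]))
    }
  }
})

test_that("ordering statistics match their printed formulas", {
  sp <- sample_space(toy_design())
  i11 <- which(sp$x1 == 1 & sp$x2 == 1)
  i12 <- which(sp$x1 == 1 & sp$x2 == 2)
  expect_equal(ordering_metric(sp, "RR-B")[i11], 2 / 4)
  expect_equal(ordering_metric(sp, "RR-LR")[i11], 0.5 * sqrt(2))
  expect_equal(ordering_metric(sp, "RR-Score")[i12], 0.75 * 2)
  expect_true(all(is.na(ordering_metric(sp, "RR-B")[is.na(sp$x2)])))
  expect_error(ordering_metric(sp, "PV"), "RR-B")
})

test_that("confidence sets contain their point and all of G3, and RR equals the tail area", {
  sp <- sample_space(toy_design())
  expect_identical(
    confidence_set(sp, 1, 1, "RR")[, c("x1", "x2")],
    tail_set(sp, 1, 1)[, c("x1", "x2")]
  )
  om <- confidence_set(sp, 1, 1, "PV")
  expect_setequal(paste(om$x1, om$x2), c("1 1", "1 2", "2 NA"))

  for (s in c(4, 14)) {
    spg <- sample_space(generate_design(s))
    g3 <- paste(spg$x1, spg$x2)[spg$group == "G3"]
    picks <- which(spg$group == "G2")
    picks <- picks[seq(1, length(picks), length.out = min(5, length(picks)))]
    for (o in c("RR", TOTAL_ORDERINGS)) {
      for (i in picks) {
        om <- suppressWarnings(confidence_set(spg, spg$x1[i], spg$x2[i], o))
        ids <- paste(om$x1, om$x2)
        expect_true(paste(spg$x1[i], spg$x2[i]) %in% ids)
        expect_true(all(g3 %in% ids))
      }
    }
  }
})

test_that("PV confidence sets are exactly the small-p-value collections, ties included", {
  for (s in c(6, 19)) {
    sp <- p_values(sample_space(generate_design(s)))
    for (i in which(sp$group == "G2")) {
      om <- confidence_set(sp, sp$x1[i], sp$x2[i], "PV")
      direct <- sp[sp$p_value <= sp$p_value[i] + 1e-12, ]
      expect_setequal(paste(om$x1, om$x2), paste(direct$x1, direct$x2))
    }
  }
})

test_that("RR confidence sets are contained in PV ones (Theorem-1 inclusion)", {
  for (s in 1:6) {
    d <- generate_design(s)
    sp <- sample_space(d)
    key <- adaptci:::ordering_key(sp, "PV", design = d)
    for (i in which(sp$group == "G2")) {
      rr <- adaptci:::tail_members(sp, sp$x1[i], sp$x2[i], d)
      pv <- key$rank >= key$rank[i]
      expect_true(all(pv[rr]), label = sprintf("seed %d point %d", s, i))
    }
  }
})

test_that("the PV set is never less probable than the RR set at any rate", {
  grid <- seq(0.01, 0.99, by = 0.01)
  for (s in c(2, 7, 13)) {
    d <- generate_design(s)
    sp <- sample_space(d)
    key <- adaptci:::ordering_key(sp, "PV", design = d)
    pmat <- adaptci:::probability_matrix(sp, grid, d)
    for (i in which(sp$group == "G2")) {
      rr <- adaptci:::tail_members(sp, sp$x1[i], sp$x2[i], d)
      pv <- key$rank >= key$rank[i]
      p_rr <- colSums(pmat[rr, , drop = FALSE])
      p_pv <- colSums(pmat[pv, , drop = FALSE])
      expect_true(all(p_pv >= p_rr - 1e-12))
    }
  }
})

test_that("total orderings give nested families and a two-step RR-A order", {
  d <- generate_design(9)
  sp <- sample_space(d)
  for (o in TOTAL_ORDERINGS) {
    os <- suppressWarnings(order_space(sp, o))
    # nested: omega sizes weakly decrease as rank increases
    expect_true(all(diff(os$omega_size[order(os$rank)]) <= 0))
    # ties share both rank and set size
    split_sizes <- split(os$omega_size, os$rank)
    expect_true(all(vapply(split_sizes, function(v) length(unique(v)) == 1, logical(1))))
  }
  # RR-A ranks are the RR limits re-ranked (ties at 1e-10)
  lt_rr <- limit_table(sp, "RR")
  os <- order_space(sp, "RR-A")
  g2 <- os$group == "G2"
  expect_equal(order(os$rank[g2]), order(rank(lt_rr$lower_limit[g2], ties.method = "first")))
})

test_that("constant second-stage size collapses RR-B, RR-LR and RR-Score to one order", {
  d <- adaptive_design(6, 1, 5, n2 = c(4, 4, 4), r = c(5, 5, 6), pi0 = 0.3)
  sp <- sample_space(d)
  ranks <- lapply(c("RR-B", "RR-LR", "RR-Score"), function(o) order_space(sp, o)$rank)
  expect_identical(ranks[[1]], ranks[[2]])
  expect_identical(ranks[[1]], ranks[[3]])
})

test_that("unknown orderings are rejected by name", {
  sp <- sample_space(toy_design())
  expect_error(limit_table(sp, "RR-X"), "unknown ordering")
  expect_error(confidence_set(sp, 1, 1, "mle"), "unknown ordering")
})
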