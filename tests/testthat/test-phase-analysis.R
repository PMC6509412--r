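test_that("dilution factor maps to mortality rate via per-cycle survival", {
  expect_equal(dilution_to_delta(1), 0)
  expect_equal(dilution_to_delta(1e3, 24), log(1000) / 24, tolerance = 1e-12)
  expect_equal(round(dilution_to_delta(1e3, 24), 5), 0.28782)
  expect_equal(dilution_to_delta(10, 24), log(10) / 24, tolerance = 1e-12)
  expect_equal(delta_to_dilution(dilution_to_delta(123.4)), 123.4,
               tolerance = 1e-12)
})

test_that("effective coefficients follow the mortality re-parameterization", {
  p <- worked_pair()  # alpha_fs = 2, alpha_sf = 0.4, r = (1, 0.5)
  expect_equal(effective_params(p, 0)$alpha_eff, p$alpha)
  # closed-form unit crossings of each coefficient
  expect_equal(effective_params(p, 1/3)$alpha_eff["fast", "slow"], 1,
               tolerance = 1e-12)
  expect_equal(effective_params(p, 0.375)$alpha_eff["slow", "fast"], 1,
               tolerance = 1e-12)
  expect_equal(unname(effective_params(p, 0.2)$r_eff), c(0.8, 0.3))
  expect_error(effective_params(p, 0.6), "slow")
  # species-specific mortality reduces to the uniform case when equal
  eff_u <- effective_params(p, 0.3)
  eff_v <- effective_params(p, c(0.3, 0.3))
  expect_equal(eff_u$alpha_eff, eff_v$alpha_eff)
})

test_that("classification obeys the both-coefficients-vs-one rule", {
  expect_identical(classify_pair(0.5, 0.8)$category, "coexistence")
  expect_identical(classify_pair(1.5, 1.2)$category, "bistability")
  expect_identical(classify_pair(2, 0.4)$category, "species_2_excludes_1")
  expect_identical(classify_pair(0.4, 2)$category, "species_1_excludes_2")
  expect_identical(classify_pair(1 + 1e-12, 0.5)$category, "degenerate")
  # interior fraction: symmetric 0.5/0.5 pair sits at one half
  expect_equal(classify_pair(0.5, 0.5)$interior_fraction, 0.5)
  # bistable separatrix is reported too
  expect_true(classify_pair(1.5, 1.2)$interior_fraction > 0 &&
                classify_pair(1.5, 1.2)$interior_fraction < 1)
  expect_true(is.na(classify_pair(2, 0.4)$interior_fraction))
})

test_that("critical mortalities are closed-form and bracket the crossing window", {
  p <- worked_pair(alpha_fs = 2, alpha_sf = 0.4)   # product 0.8 < 1
  cm <- critical_mortalities(p)
  expect_equal(cm$delta, c(1/3, 0.375), tolerance = 1e-12)
  expect_identical(cm$coefficient, c("alpha_12", "alpha_21"))
  # in-window classification is coexistence
  expect_identical(classify_pair(effective_params(p, 0.35))$category,
                   "coexistence")

  p2 <- worked_pair(alpha_fs = 2, alpha_sf = 0.8)  # product 1.6 > 1
  cm2 <- critical_mortalities(p2)
  expect_equal(cm2$delta, c(1/6, 1/3), tolerance = 1e-12)
  expect_identical(classify_pair(effective_params(p2, 0.25))$category,
                   "bistability")

  # equal growth rates: coefficients immune to mortality, no crossings
  eq <- community_params(c("a", "b"), c(0.7, 0.7),
                         matrix(c(1, 2, 0.4, 1), 2, 2, byrow = TRUE))
  expect_identical(nrow(critical_mortalities(eq)), 0L)
})

test_that("mortality sweeps traverse the regimes in order", {
  # slow-grower dominance with product < 1: exclusion-by-slow ->
  # coexistence -> exclusion-by-fast
  p <- worked_pair(alpha_fs = 2, alpha_sf = 0.4)
  sw <- mortality_sweep(p, deltas = seq(0, 0.49, length.out = 200))
  cats <- rle(sw$category)$values
  expect_identical(cats, c("species_2_excludes_1", "coexistence",
                           "species_1_excludes_2"))
  # product > 1 analogue crosses bistability instead
  p2 <- worked_pair(alpha_fs = 2, alpha_sf = 0.8)
  sw2 <- mortality_sweep(p2, deltas = seq(0, 0.49, length.out = 200))
  expect_identical(rle(sw2$category)$values,
                   c("species_2_excludes_1", "bistability",
                     "species_1_excludes_2"))
  # fast grower already dominant: no change across the sweep
  p3 <- worked_pair(alpha_fs = 0.3, alpha_sf = 2)
  sw3 <- mortality_sweep(p3, deltas = seq(0, 0.49, length.out = 50))
  expect_identical(unique(sw3$category), "species_1_excludes_2")
  # sweep reports the DF axis consistently
  expect_equal(sw$dilution_factor, delta_to_dilution(sw$delta))
})

test_that("category changes only at the closed-form critical mortalities", {
  set.seed(5)
  for (i in 1:10) {
    p <- community_params(c("s1", "s2"), runif(2, 0.2, 1.5),
                          matrix(c(1, exp(runif(1, log(0.2), log(5))),
                                   exp(runif(1, log(0.2), log(5))), 1),
                                 2, 2, byrow = TRUE))
    cm <- critical_mortalities(p)
    tr <- locate_transitions(p)
    expect_equal(nrow(tr), nrow(cm))
    if (nrow(cm)) expect_equal(tr$delta, cm$delta, tolerance = 1e-6)
  }
})

test_that("the log-coefficient path is a 45-degree line with invariant product", {
  set.seed(17)
  for (i in 1:20) {
    p <- community_params(c("s1", "s2"), runif(2, 0.2, 1.5),
                          matrix(c(1, exp(runif(1, log(0.1), log(10))),
                                   exp(runif(1, log(0.1), log(10))), 1),
                                 2, 2, byrow = TRUE))
    deltas <- seq(0, 0.9 * min(p$growth_rates), length.out = 25)
    la <- t(vapply(deltas, function(d) {
      eff <- effective_params(p, d)
      log(c(eff$alpha_eff[1, 2], eff$alpha_eff[2, 1]))
    }, numeric(2)))
    # product of the two coefficients is mortality-invariant
    expect_equal(rowSums(la), rep(sum(log(p$alpha[1, 2] * p$alpha[2, 1])),
                                  length(deltas)), tolerance = 1e-10)
    # slope of the traced line is exactly -1 (45 degrees)
    if (diff(range(la[, 1])) > 1e-12) {
      slope <- stats::coef(stats::lm(la[, 2] ~ la[, 1]))[2]
      expect_equal(unname(slope), -1, tolerance = 1e-9)
    }
  }
})

test_that("mortality monotonically favors the faster grower", {
  set.seed(23)
  for (i in 1:10) {
    r <- sort(runif(2, 0.2, 1.5), decreasing = TRUE)  # species 1 fast
    p <- community_params(c("f", "s"), r,
                          matrix(c(1, exp(runif(1, log(0.1), log(10))),
                                   exp(runif(1, log(0.1), log(10))), 1),
                                 2, 2, byrow = TRUE))
    deltas <- seq(0, 0.95 * r[2], length.out = 30)
    afs <- vapply(deltas, function(d)
      effective_params(p, d)$alpha_eff[1, 2], numeric(1))
    asf <- vapply(deltas, function(d)
      effective_params(p, d)$alpha_eff[2, 1], numeric(1))
    expect_true(all(diff(afs) < 0))  # inhibition felt by the fast grower falls
    expect_true(all(diff(asf) > 0))  # inhibition felt by the slow grower rises
  }
})

test_that("analytic classification agrees with brute-force simulation", {
  pairs <- sample_margin_pairs(25, seed = 31)
  agree <- vapply(pairs, function(pp) {
    obs <- survivors_to_category(brute_force_outcome(pp$params, pp$delta))
    obs == pp$truth$category
  }, logical(1))
  expect_gte(mean(agree), 0.95)
})
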