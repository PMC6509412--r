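# Minimal experiment table built by hand: one condition, counts per cycle.
counts_table <- function(counts_by_cycle, species, condition_id = "c1",
                         DF = 100, start = "equal", replicate = 1) {
  rows <- lapply(seq_along(counts_by_cycle), function(cy)
    data.frame(condition_id = condition_id, dilution_factor = DF,
               starting_composition = start, replicate = replicate,
               cycle = cy, species = species,
               colony_count = counts_by_cycle[[cy]],
               stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

test_that("endpoint fractions and beta error bars follow the counts", {
  tab <- counts_table(list(c(30, 12), c(25, 17), c(22, 20), c(21, 21)),
                      c("A", "B"))
  ef <- endpoint_fractions(tab)
  expect_equal(ef$fraction, c(0.5, 0.5))
  expect_equal(ef$sd[1], ef$sd[2])  # symmetric counts, symmetric error
  expect_equal(ef$sd[1], beta_sd(21, 21))

  # clean sweep: fraction (1, 0) with the beta SD of a 42-0 plating
  sweep_tab <- counts_table(list(c(40, 2), c(41, 1), c(42, 0), c(42, 0)),
                            c("A", "B"))
  efs <- endpoint_fractions(sweep_tab)
  expect_equal(efs$fraction, c(1, 0))
  expect_equal(efs$sd, beta_sd(c(42, 0), c(0, 42)))

  # trio: per-species error bars use all-other counts as the second shape
  trio <- counts_table(list(c(10, 20, 12)), c("A", "B", "C"))
  eft <- endpoint_fractions(trio, last_k_cycles = 1)
  expect_equal(eft$fraction, c(10, 20, 12) / 42)
  expect_equal(eft$sd, beta_sd(c(10, 20, 12), 42 - c(10, 20, 12)))
  expect_equal(sum(eft$fraction), 1)
})

test_that("convergence and usability flags behave", {
  moving <- counts_table(list(c(40, 2), c(30, 12), c(20, 22), c(10, 32)),
                         c("A", "B"))
  expect_false(endpoint_fractions(moving)$converged[1])
  settled <- counts_table(list(c(40, 2), c(21, 21), c(20, 22), c(21, 21)),
                          c("A", "B"))
  expect_true(endpoint_fractions(settled)$converged[1])
  dead <- counts_table(list(c(5, 1), c(1, 0), c(0, 0)), c("A", "B"))
  efd <- endpoint_fractions(dead)
  expect_false(efd$usable[1])
  expect_true(all(is.na(efd$fraction)))
  expect_error(endpoint_fractions(data.frame(condition_id = 1)),
               "missing columns")
})

test_that("error bars shrink with total colony count", {
  totals <- c(10, 42, 200, 1000)
  sds <- beta_sd(totals %/% 2, totals - totals %/% 2)
  expect_true(all(diff(sds) < 0))
  # roughly 1/sqrt(total) scaling
  expect_equal(sds[4] / sds[2], sqrt(42 / 1000), tolerance = 0.1)
})

# -- pair calls on simulated conditions with known ground truth -------------

simulate_pair_endpoints <- function(alpha_fs, alpha_sf, DF, seed,
                                    mean_colonies = 42) {
  truth <- ground_truth(worked_pair(alpha_fs, alpha_sf))
  design <- design_spec(dilution_factors = DF, mean_colonies = mean_colonies,
                        replicates = 2)
  tab <- simulate_experiment(truth, design, seed = seed,
                             subsets = list(c("fast", "slow")))
  endpoint_fractions(tab)
}

test_that("pair calls recover exclusion, coexistence and bistability", {
  # coexistence window of the worked pair: DF with delta inside (1/3, 0.375)
  DF_co <- round(delta_to_dilution(0.355))
  ends <- simulate_pair_endpoints(2, 0.4, DF_co, seed = 101)
  call <- call_pair_outcome(ends)
  expect_identical(call$category, "coexistence")
  # ground truth for the *fraction* is the noise-free endpoint of the same
  # discrete growth-dilution process (its pre-dilution composition is not
  # the continuous-death interior point; only the outcome type is shared)
  noisefree <- simulate_experiment(
    ground_truth(worked_pair()),
    design_spec(dilution_factors = DF_co, mean_colonies = Inf),
    seed = 1, subsets = list(c("fast", "slow")))
  truth_frac <- mean(noisefree$fraction_true[noisefree$cycle == 7 &
                                               noisefree$species == "fast"])
  expect_equal(call$stable_fraction, truth_frac,
               tolerance = 0.12)  # 42-colony platings scatter at ~7%

  # low DF: slow strong competitor excludes fast grower
  ends_lo <- simulate_pair_endpoints(2, 0.4, 10, seed = 102)
  expect_identical(call_pair_outcome(ends_lo)$category,
                   "species_2_excludes_1")

  # high DF: fast grower takes over
  ends_hi <- simulate_pair_endpoints(2, 0.4, 1e5, seed = 103)
  expect_identical(call_pair_outcome(ends_hi)$category,
                   "species_1_excludes_2")

  # bistable window of the product > 1 pair: starts diverge
  DF_bi <- round(delta_to_dilution(0.25))
  ends_bi <- simulate_pair_endpoints(2, 0.8, DF_bi, seed = 104)
  call_bi <- call_pair_outcome(ends_bi)
  expect_identical(call_bi$category, "bistability")
  expect_gte(length(call_bi$survivor_sets), 2)
})

test_that("a coexistence/exclusion mixture is flagged non-LV, not coerced", {
  ends <- rbind(
    data.frame(condition_id = "c1", dilution_factor = 100,
               starting_composition = "A-dominant", replicate = 1,
               species = c("A", "B"), colony_count = c(25, 17),
               fraction = c(25, 17) / 42, sd = 0.07, converged = TRUE,
               usable = TRUE, stringsAsFactors = FALSE),
    data.frame(condition_id = "c2", dilution_factor = 100,
               starting_composition = "B-dominant", replicate = 1,
               species = c("A", "B"), colony_count = c(0, 42),
               fraction = c(0, 1), sd = 0.02, converged = TRUE,
               usable = TRUE, stringsAsFactors = FALSE))
  call <- call_pair_outcome(ends)
  expect_identical(call$category, "bistability")
  expect_true(call$non_LV)
})

test_that("replicate conflicts within a start raise the ambiguous flag", {
  ends <- do.call(rbind, lapply(1:2, function(i)
    data.frame(condition_id = paste0("c", i), dilution_factor = 100,
               starting_composition = "equal", replicate = i,
               species = c("A", "B"),
               colony_count = if (i == 1) c(42, 0) else c(0, 42),
               fraction = if (i == 1) c(1, 0) else c(0, 1),
               sd = 0.02, converged = TRUE, usable = TRUE,
               stringsAsFactors = FALSE)))
  ends2 <- rbind(ends, transform(ends[1:2, ],
                                 condition_id = "c3",
                                 starting_composition = "A-dominant"))
  call <- call_pair_outcome(ends2)
  expect_true(call$ambiguous)
})

test_that("community state calls separate alternative stable states", {
  # trio engineered so B-C is bistable while A coexists with both:
  # two community states {A, B} and {A, C}
  p <- community_params(c("A", "B", "C"), c(1, 0.9, 0.8),
                        matrix(c(1,   0.5, 0.5,
                                 0.5, 1,   1.6,
                                 0.5, 1.7, 1), 3, 3, byrow = TRUE))
  truth <- ground_truth(p)
  design <- design_spec(dilution_factors = 10, mean_colonies = 200)
  tab <- simulate_experiment(truth, design, seed = 105,
                             subsets = list(c("A", "B", "C")))
  call <- call_community_state(endpoint_fractions(tab))
  keys <- sort(vapply(call$states, paste, character(1), collapse = "+"))
  expect_identical(keys, c("A+B", "A+C"))

  # mutually coexisting triplet: a single all-present state
  p2 <- community_params(c("A", "B", "C"), c(1, 0.9, 0.8),
                         matrix(c(1, 0.4, 0.4,
                                  0.4, 1, 0.4,
                                  0.4, 0.4, 1), 3, 3, byrow = TRUE))
  tab2 <- simulate_experiment(ground_truth(p2), design, seed = 106,
                              subsets = list(c("A", "B", "C")))
  call2 <- call_community_state(endpoint_fractions(tab2))
  expect_length(call2$states, 1)
  expect_identical(call2$states[[1]], c("A", "B", "C"))

  # subway table carries one row per species x DF x state
  sw <- subway_table(list(call))
  expect_identical(nrow(sw), 6L)
  expect_identical(sum(sw$present), 4L)
})
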