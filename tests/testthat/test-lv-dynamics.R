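test_that("derivatives evaluate the model polynomial and respect fixed points", {
  mono <- community_params("a", 1, matrix(1))
  # N* = 1 - delta/r is a fixed point of the monoculture
  expect_equal(unname(lv_derivatives(mono, 0.75, delta = 0.25)), 0)
  # extinction is absorbing
  p <- worked_pair()
  expect_equal(unname(lv_derivatives(p, c(0, 0), delta = 0.3)), c(0, 0))
  # hand evaluation: r=(1,0.5), alpha_12=0.4, alpha_21=2, N=(0.5,0.2)
  q <- community_params(c("x", "y"), c(1, 0.5),
                        matrix(c(1, 0.4, 2, 1), 2, 2, byrow = TRUE))
  expect_equal(unname(lv_derivatives(q, c(0.5, 0.2))),
               c(1 * 0.5 * (1 - 0.5 - 0.4 * 0.2),
                 0.5 * 0.2 * (1 - 2 * 0.5 - 0.2)))
  expect_error(lv_derivatives(p, c(0.1, 0.2, 0.3)), "does not match")
  expect_error(lv_derivatives(p, c(-0.1, 0.2)), "nonnegative")
})

test_that("single-cycle integration reproduces logistic closed forms", {
  mono <- community_params("a", 1, matrix(1))
  expect_equal(unname(integrate_cycle(mono, 1, hours = 24)), 1,
               tolerance = 1e-7)
  expect_equal(unname(integrate_cycle(mono, 0.01, hours = 200)), 1,
               tolerance = 1e-6)
  # with mortality, long-horizon equilibrium is 1 - delta/r
  expect_equal(unname(integrate_cycle(mono, 0.9, hours = 300, delta = 0.25)),
               0.75, tolerance = 1e-6)
  # exact logistic solution at finite horizon
  r <- 0.8; N0 <- 0.02; t <- 6
  expect_equal(unname(integrate_cycle(community_params("a", r, matrix(1)),
                                      N0, hours = t)),
               N0 * exp(r * t) / (1 + N0 * (exp(r * t) - 1)),
               tolerance = 1e-7)
})

test_that("monoculture equilibrium follows max(0, 1 - delta/r)", {
  expect_equal(monoculture_equilibrium(1, 0), 1)
  expect_equal(monoculture_equilibrium(1, 1.5), 0)
  expect_equal(monoculture_equilibrium(0.5, 0.125), 0.75)
  # matches long continuous integration on a random grid
  set.seed(11)
  for (i in 1:5) {
    r <- runif(1, 0.3, 1.5); d <- runif(1, 0, 0.9 * r)
    mono <- community_params("a", r, matrix(1))
    expect_equal(unname(integrate_cycle(mono, 0.5, hours = 400, delta = d)),
                 monoculture_equilibrium(r, d), tolerance = 1e-5)
  }
})

test_that("serial dilution drives slow monocultures extinct and spares DF = 1", {
  mono <- community_params("a", 0.05, matrix(1))  # e^{rT}/DF < 1 at DF = 10
  proto <- lv_protocol("serial-dilution", dilution_factor = 10,
                       n_cycles = 300, extinction_threshold = 1e-8)
  traj <- run_serial_dilution(mono, 0.5, proto)
  expect_equal(unname(traj$densities[nrow(traj$densities), ]), 0)
  expect_lt(traj$cycles_run, 300)

  # DF = 1 is pure growth: composition matches a delta = 0 continuous run
  p <- worked_pair()
  t1 <- run_serial_dilution(p, c(0.02, 0.03),
                            lv_protocol("serial-dilution", dilution_factor = 1,
                                        n_cycles = 15))
  t2 <- run_continuous(p, c(0.02, 0.03),
                       lv_protocol("continuous-death", delta = 0,
                                   n_cycles = 15))
  expect_equal(t1$fractions[15, ], t2$fractions[15, ], tolerance = 1e-6)
})

test_that("high dilution hands the worked pair to the fast grower", {
  p <- worked_pair()  # slow grower dominates at delta = 0
  proto <- lv_protocol("serial-dilution", dilution_factor = 1e5,
                       n_cycles = 100, stop_on_convergence = TRUE)
  traj <- run_serial_dilution(p, c(0.5, 0.5) / 1e5, proto)
  expect_identical(survivor_set(traj), "fast")
  # and at DF ~ 1 the slow strong competitor wins instead
  lo <- run_serial_dilution(p, c(0.5, 0.5) / 2,
                            lv_protocol("serial-dilution", dilution_factor = 2,
                                        n_cycles = 200,
                                        stop_on_convergence = TRUE))
  expect_identical(survivor_set(lo), "slow")
})

test_that("trajectories stay nonnegative and extinction is absorbing", {
  pairs <- sample_margin_pairs(6, seed = 42)
  for (pp in pairs) {
    proto <- lv_protocol("serial-dilution",
                         dilution_factor = delta_to_dilution(pp$delta),
                         n_cycles = 30)
    traj <- run_serial_dilution(pp$params, c(0.4, 0.6) / 100, proto)
    expect_true(all(traj$densities >= 0))
    for (sp in seq_len(2)) {
      dead <- which(traj$densities[, sp] == 0)
      if (length(dead))
        expect_true(all(traj$densities[dead[1]:nrow(traj$densities), sp] == 0))
    }
    tot <- rowSums(traj$densities)
    ok <- tot > 0
    expect_equal(rowSums(traj$fractions[ok, , drop = FALSE]),
                 rep(1, sum(ok)))
  }
})

test_that("pair fixed points match closed forms and stability flags", {
  # symmetric coexistence: alpha = 0.5 both ways -> interior (2/3, 2/3)
  sym <- community_params(c("a", "b"), c(1, 1),
                          matrix(c(1, 0.5, 0.5, 1), 2, 2))
  fp <- pair_fixed_points(sym, delta = 0)
  int <- fp$points[fp$points$type == "interior", ]
  expect_equal(c(int$N_1, int$N_2), c(2/3, 2/3), tolerance = 1e-12)
  expect_true(int$stable)
  expect_false(any(fp$points$stable[fp$points$type != "interior"]))

  # bistability: both alpha > 1 -> interior unstable, boundaries stable
  bis <- community_params(c("a", "b"), c(1, 1),
                          matrix(c(1, 1.5, 1.2, 1), 2, 2, byrow = TRUE))
  fpb <- pair_fixed_points(bis, delta = 0)
  expect_false(fpb$points$stable[fpb$points$type == "interior"])
  expect_true(all(fpb$points$stable[grepl("boundary", fpb$points$type)]))

  # exclusion: alpha_12 > 1 > alpha_21 -> no interior point, winner boundary
  exc <- community_params(c("a", "b"), c(1, 1),
                          matrix(c(1, 2, 0.4, 1), 2, 2, byrow = TRUE))
  fpe <- pair_fixed_points(exc, delta = 0)
  expect_false("interior" %in% fpe$points$type)
  expect_true(fpe$points$stable[fpe$points$type == "boundary_2"])
  expect_false(fpe$points$stable[fpe$points$type == "boundary_1"])

  # degenerate coefficient product signals explicitly
  deg <- community_params(c("a", "b"), c(1, 1),
                          matrix(c(1, 2, 0.5, 1), 2, 2, byrow = TRUE))
  expect_warning(fpd <- pair_fixed_points(deg, delta = 0),
                 class = "lvmort_degenerate")
  expect_true(fpd$degenerate)
})

test_that("stability flags predict the fate of perturbed trajectories", {
  pairs <- sample_margin_pairs(5, seed = 99)
  for (pp in pairs) {
    fp <- pair_fixed_points(pp$params, pp$delta)
    stable_pts <- fp$points[fp$points$stable & fp$points$type != "origin", ]
    proto <- lv_protocol("continuous-death", delta = pp$delta,
                         n_cycles = 300, stop_on_convergence = TRUE)
    for (i in seq_len(nrow(stable_pts))) {
      N0 <- pmax(c(stable_pts$N_1[i], stable_pts$N_2[i]) +
                   c(0.01, -0.01), 1e-4)
      traj <- run_continuous(pp$params, N0, proto)
      expect_equal(unname(traj$densities[nrow(traj$densities), ]),
                   c(stable_pts$N_1[i], stable_pts$N_2[i]),
                   tolerance = 5e-3)
    }
  }
})
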