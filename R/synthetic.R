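#' Experimental design for a synthetic serial-dilution study
#'
#' Captures the layout of the daily-dilution competition experiment the
#' generator emulates: six dilution factors spanning 10 to 10^6, 24-h growth
#' cycles, seven cycles, starting compositions consisting of an even split
#' plus one composition per species in which it starts at 90% with the
#' remainder shared evenly (for pairs this yields starts at 10/50/90%), and
#' colony-count platings averaging 42 colonies per condition.
#'
#' @param dilution_factors Dilution factors (default `10^(1:6)`).
#' @param cycle_hours Growth hours per cycle (default 24).
#' @param n_cycles Number of cycles (default 7).
#' @param replicates Biological replicates per condition (default 1).
#' @param mean_colonies Mean total colonies per plating; the realized total
#'   is Poisson with this mean, reflecting plating variability (default 42).
#' @param dominant_fraction Starting fraction of the focal species in the
#'   single-species-dominant starts (default 0.9).
#' @param od_dilutions Initial dilutions of the equalized stock used for
#'   growth curves (default `10^(-8:-3)`).
#' @param od_stock OD600 of the equalized stock (default 0.5).
#' @return Object of class `design_spec`.
#' @export
design_spec <- function(dilution_factors = 10^(1:6), cycle_hours = 24,
                        n_cycles = 7, replicates = 1, mean_colonies = 42,
                        dominant_fraction = 0.9,
                        od_dilutions = 10^(-8:-3), od_stock = 0.5) {
  if (any(dilution_factors < 1))
    stop("dilution factors must be >= 1", call. = FALSE)
  if (dominant_fraction <= 0 || dominant_fraction >= 1)
    stop("dominant_fraction must lie in (0, 1)", call. = FALSE)
  structure(
    list(dilution_factors = sort(dilution_factors),
         cycle_hours = cycle_hours, n_cycles = n_cycles,
         replicates = replicates, mean_colonies = mean_colonies,
         dominant_fraction = dominant_fraction,
         od_dilutions = od_dilutions, od_stock = od_stock),
    class = "design_spec"
  )
}

#' Starting compositions of the design for a given species subset
#'
#' @param species Character vector of species in the condition.
#' @param design A [design_spec()].
#' @return Named list of compositions: `"equal"` plus one `"<id>-dominant"`
#'   per species (omitted for monocultures).
#' @export
starting_compositions <- function(species, design = design_spec()) {
  n <- length(species)
  comps <- list(equal = stats::setNames(rep(1 / n, n), species))
  if (n > 1) {
    for (sp in species) {
      comp <- stats::setNames(
        rep((1 - design$dominant_fraction) / (n - 1), n), species)
      comp[sp] <- design$dominant_fraction
      comps[[paste0(sp, "-dominant")]] <- comp
    }
  }
  comps
}

#' Assemble a ground-truth community from known parameters
#'
#' Wraps an existing [community_params()] object, per-species absolute
#' carrying capacities and lag times into the `ground_truth` container the
#' simulators consume; [sample_params()] draws one at random instead.
#'
#' @param params A [community_params()] object.
#' @param carrying_capacity Per-species absolute carrying capacity (CFU/ml),
#'   recycled if scalar (default 1e9).
#' @param lag_hours Per-species lag time (hours), recycled if scalar
#'   (default 0).
#' @param seed Optional provenance seed to record.
#' @param settings Optional list of generator settings to record.
#' @return Object of class `ground_truth`.
#' @export
ground_truth <- function(params, carrying_capacity = 1e9, lag_hours = 0,
                         seed = NULL, settings = list()) {
  stopifnot(inherits(params, "community_params"))
  ids <- params$species_ids
  K <- rep_len(carrying_capacity, length(ids))
  lag <- rep_len(lag_hours, length(ids))
  if (any(K <= 0)) stop("carrying capacities must be > 0", call. = FALSE)
  if (any(lag < 0)) stop("lag times must be >= 0", call. = FALSE)
  structure(
    list(params = params,
         carrying_capacity = stats::setNames(K, ids),
         lag_hours = stats::setNames(lag, ids),
         seed = seed, settings = settings),
    class = "ground_truth"
  )
}

#' Sample a ground-truth community with a growth/competition tradeoff
#'
#' Draws growth rates log-uniformly and builds the competition matrix as
#' `alpha[i, j] = exp(log(alpha_geom) + tradeoff * (r_i - r_j) + noise)`.
#' With positive `tradeoff`, faster growers feel stronger inhibition from
#' slower ones than vice versa, so slow growers dominate pairwise at zero
#' mortality -- the regime in which added mortality reverses outcomes.
#' `tradeoff = 0` gives tradeoff-free control communities. Per-species
#' absolute carrying capacities (for converting normalized densities into
#' countable abundances) and lag times are drawn log-uniformly/uniformly.
#'
#' @param n_species Number of species (>= 2).
#' @param tradeoff Tradeoff strength (1/(rate units)); default 4.
#' @param noise SD of the log-normal scatter on the off-diagonal
#'   coefficients; default 0.3.
#' @param seed Optional integer seed; all draws flow from it.
#' @param r_range Range of growth rates (1/h), sampled log-uniformly;
#'   default `c(0.2, 1.5)`.
#' @param alpha_geom Geometric centre of the coefficients for equal rates;
#'   default 0.5 (pairwise product 0.25 < 1, so intermediate-mortality
#'   windows are coexistence unless the noise pushes the product above 1).
#' @param K_range Range of absolute carrying capacities (CFU/ml), sampled
#'   log-uniformly; default `c(5e8, 5e9)`.
#' @param lag_range Range of lag times (hours), uniform; default `c(0, 4)`.
#' @return Object of class `ground_truth`: list with `params`
#'   (a [community_params()]), `carrying_capacity`, `lag_hours`, `seed`, and
#'   `settings`.
#' @export
sample_params <- function(n_species, tradeoff = 4, noise = 0.3, seed = NULL,
                          r_range = c(0.2, 1.5), alpha_geom = 0.5,
                          K_range = c(5e8, 5e9), lag_range = c(0, 4)) {
  if (n_species < 2) stop("n_species must be >= 2", call. = FALSE)
  if (tradeoff < 0) stop("tradeoff must be >= 0", call. = FALSE)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  ids <- sprintf("sp%d", seq_len(n_species))
  r <- exp(stats::runif(n_species, log(r_range[1]), log(r_range[2])))
  eps <- matrix(stats::rnorm(n_species^2, 0, noise), n_species)
  alpha <- exp(log(alpha_geom) + tradeoff * outer(r, r, `-`) + eps)
  diag(alpha) <- 1
  K <- exp(stats::runif(n_species, log(K_range[1]), log(K_range[2])))
  lag <- stats::runif(n_species, lag_range[1], lag_range[2])
  structure(
    list(params = community_params(ids, r, alpha),
         carrying_capacity = stats::setNames(K, ids),
         lag_hours = stats::setNames(lag, ids),
         seed = seed,
         settings = list(tradeoff = tradeoff, noise = noise,
                         r_range = r_range, alpha_geom = alpha_geom,
                         K_range = K_range, lag_range = lag_range)),
    class = "ground_truth"
  )
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("synthetic ground-truth community (seed ",
      if (is.null(x$seed)) "unset" else x$seed, ")\n", sep = "")
  print(x$params)
  invisible(x)
}

#' Simulate the full serial-dilution competition experiment
#'
#' Runs every requested species subset through the dilution design: for each
#' dilution factor x starting composition x replicate, normalized densities
#' are initialized from the starting composition under the day-0 rule (the
#' starting mixture is prediluted by its daily factor, except that the
#' highest factor, 10^6, starts at 10^5 to avoid stochastic day-0
#' extinction), grown and diluted with [run_serial_dilution()], and the
#' per-cycle pre-dilution states converted to observed colony counts: the
#' platable fraction of species i is `K_i N_i / sum_j K_j N_j` (plating
#' counts cells, not carrying-capacity-normalized densities), and the counts
#' are multinomial with a Poisson-distributed total.
#'
#' @param truth A [sample_params()] ground truth.
#' @param design A [design_spec()].
#' @param seed Optional integer seed governing all sampling noise.
#' @param subsets List of species-id vectors to culture; default all pairs
#'   plus (for n > 2) the full community and all monocultures.
#' @param fraction_mode `"abundance"` (weight by carrying capacity; default)
#'   or `"density"` (report normalized-density fractions directly).
#' @return Long-format experiment table (data frame) with columns
#'   `condition_id`, `community`, `dilution_factor`, `starting_composition`,
#'   `replicate`, `cycle`, `species`, `colony_count`, and the noise-free
#'   ground truth columns `fraction_true` and `density`.
#' @export
simulate_experiment <- function(truth, design = design_spec(), seed = NULL,
                                subsets = NULL,
                                fraction_mode = c("abundance", "density")) {
  stopifnot(inherits(truth, "ground_truth"), inherits(design, "design_spec"))
  fraction_mode <- match.arg(fraction_mode)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  ids <- truth$params$species_ids
  if (is.null(subsets)) {
    subsets <- c(utils::combn(ids, 2, simplify = FALSE),
                 if (length(ids) > 2) list(ids),
                 as.list(ids))
  }
  K <- truth$carrying_capacity
  rows <- list()
  for (sub in subsets) {
    sub_params <- subset_community(truth$params, sub)
    comps <- starting_compositions(sub, design)
    for (DF in design$dilution_factors) {
      day0 <- min(DF, 1e5)  # DF 10^6 starts at 10^-5 on day 0
      proto <- lv_protocol("serial-dilution", dilution_factor = DF,
                           cycle_hours = design$cycle_hours,
                           n_cycles = design$n_cycles)
      for (ci in seq_along(comps)) {
        comp <- comps[[ci]]
        N0 <- comp / day0
        traj <- run_serial_dilution(sub_params, N0, proto)
        dens <- traj$densities
        w <- if (fraction_mode == "abundance") K[sub] else rep(1, length(sub))
        for (rep_i in seq_len(design$replicates)) {
          cond <- paste(paste(sub, collapse = "."), DF, names(comps)[ci],
                        rep_i, sep = "_")
          for (cy in seq_len(nrow(dens))) {
            ab <- dens[cy, ] * w
            tot <- sum(ab)
            frac <- if (tot > 0) ab / tot else rep(0, length(sub))
            ncol_tot <- if (is.finite(design$mean_colonies))
              stats::rpois(1, design$mean_colonies) else NA_integer_
            counts <- if (tot == 0) rep(0L, length(sub))
              else if (is.finite(design$mean_colonies))
                as.integer(stats::rmultinom(1, ncol_tot, frac))
              else as.integer(round(frac * 1e6))
            rows[[length(rows) + 1]] <- data.frame(
              condition_id = cond,
              community = paste(sub, collapse = "."),
              dilution_factor = DF,
              starting_composition = names(comps)[ci],
              replicate = rep_i,
              cycle = cy,
              species = sub,
              colony_count = counts,
              fraction_true = unname(frac),
              density = unname(dens[cy, ]),
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

od_curve_values <- function(times, od0, r, lag, od_max) {
  # exponential at rate r from od0 after the lag, then smooth saturation to
  # od_max once half-saturation is reached (rich-media cultures stay
  # effectively exponential well past the measurement threshold)
  od_switch <- od_max / 2
  t1 <- lag + log(od_switch / od0) / r
  ifelse(times < lag, od0,
         ifelse(times < t1, od0 * exp(r * (times - lag)), {
           r2 <- r * od_switch / (od_max - od_switch)  # slope-continuous
           od_max - (od_max - od_switch) * exp(-r2 * (times - t1))
         }))
}

#' Simulate monoculture OD growth curves
#'
#' Produces the growth-curve table the rate estimators consume: for each
#' species and each initial dilution of the equalized stock, OD600 sampled
#' every 15 minutes over ~50 h. Curves are flat at the starting OD for the
#' species' lag, grow exponentially at its true rate, and saturate smoothly
#' to a per-species plateau (carrying capacity / 10^9 OD units per CFU/ml);
#' additive Gaussian read noise is optional.
#'
#' @param truth A [sample_params()] ground truth.
#' @param design A [design_spec()] (supplies `od_dilutions` and `od_stock`).
#' @param noise_sd SD of the additive OD read noise (default 0.002; 0 for
#'   noiseless curves).
#' @param seed Optional integer seed.
#' @param span_hours Duration of the run (default 50).
#' @param step_hours Sampling interval (default 0.25, i.e. 15 min).
#' @param replicates Curves per species x dilution (default 1).
#' @return Data frame with columns `species`, `replicate`,
#'   `initial_dilution`, `time_h`, `od`.
#' @export
simulate_od_curves <- function(truth, design = design_spec(), noise_sd = 0.002,
                               seed = NULL, span_hours = 50,
                               step_hours = 0.25, replicates = 1) {
  stopifnot(inherits(truth, "ground_truth"), inherits(design, "design_spec"))
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  times <- seq(0, span_hours, by = step_hours)
  ids <- truth$params$species_ids
  od_max <- pmax(truth$carrying_capacity / 1e9, 0.3)
  rows <- list()
  for (sp in ids) {
    for (dil in design$od_dilutions) {
      od0 <- design$od_stock * dil
      clean <- od_curve_values(times, od0, truth$params$growth_rates[sp],
                               truth$lag_hours[sp], od_max[sp])
      for (rep_i in seq_len(replicates)) {
        od <- clean + if (noise_sd > 0) stats::rnorm(length(times), 0, noise_sd) else 0
        rows[[length(rows) + 1]] <- data.frame(
          species = sp, replicate = rep_i, initial_dilution = dil,
          time_h = times, od = od, stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
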