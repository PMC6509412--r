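# Shared fixtures: all built in code, no stored data.

# The worked two-species example used throughout: a fast grower (r = 1/h)
# that is a weak competitor and a slow grower (r = 0.5/h) that is a strong
# one (alpha_fs = 2, alpha_sf = 0.4), so the slow grower wins at zero
# mortality and the pair crosses a coexistence window as mortality rises.
worked_pair <- function(alpha_fs = 2, alpha_sf = 0.4) {
  community_params(c("fast", "slow"), c(1, 0.5),
                   matrix(c(1, alpha_fs, alpha_sf, 1), 2, 2, byrow = TRUE))
}

# Draw random pairs with a mortality level whose classification sits well
# away from all boundaries: log-uniform alpha in [0.1, 10], growth rates in
# [0.2, 1.5], dilution factor log-uniform in [10, 1e6], accepted when
# delta <= 0.9 * min(r) and both |log alpha_eff| exceed `margin`.
sample_margin_pairs <- function(n_pairs, seed, margin = 0.15,
                                require_types = NULL) {
  set.seed(seed)
  out <- list()
  while (length(out) < n_pairs) {
    r <- stats::runif(2, 0.2, 1.5)
    a12 <- exp(stats::runif(1, log(0.1), log(10)))
    a21 <- exp(stats::runif(1, log(0.1), log(10)))
    DF <- exp(stats::runif(1, log(10), log(1e6)))
    delta <- dilution_to_delta(DF)
    if (delta > 0.9 * min(r)) next
    p <- community_params(c("s1", "s2"), r,
                          matrix(c(1, a12, a21, 1), 2, 2, byrow = TRUE))
    eff <- effective_params(p, delta)
    la <- abs(log(c(eff$alpha_eff[1, 2], eff$alpha_eff[2, 1])))
    if (min(la) <= margin) next
    cl <- classify_pair(eff)
    if (!is.null(require_types) && !cl$category %in% require_types) next
    out[[length(out) + 1]] <- list(params = p, delta = delta, DF = DF,
                                   truth = cl)
  }
  out
}

# Brute-force survivor sets of a pair from several starting fractions, via
# long continuous-death runs (independent of the analytic classification).
brute_force_outcome <- function(params, delta, starts = c(0.05, 0.5, 0.95),
                                total0 = 0.1, n_blocks = 400) {
  proto <- lv_protocol("continuous-death", delta = delta,
                       cycle_hours = 24, n_cycles = n_blocks,
                       stop_on_convergence = TRUE)
  lapply(starts, function(f1) {
    survivor_set(run_continuous(params, total0 * c(f1, 1 - f1), proto))
  })
}

# Per-start survivor set predicted by the analytic classification. For
# bistable pairs the winner depends on which side of the separatrix the
# start lies; starts within `margin` of the separatrix sit near a basin
# boundary and are excluded (NA), in the same spirit as the parameter-space
# margin on |log alpha_eff|.
predicted_survivors_at_start <- function(cl, start_frac1,
                                         species = c("s1", "s2"),
                                         margin = 0.15) {
  switch(cl$category,
         coexistence = list(sort(species)),
         species_1_excludes_2 = list(species[1]),
         species_2_excludes_1 = list(species[2]),
         bistability = {
           if (abs(start_frac1 - cl$interior_fraction) <= margin) list(NULL)
           else if (start_frac1 > cl$interior_fraction) list(species[1])
           else list(species[2])
         },
         list(NULL))[[1]]
}

# Map a list of per-start survivor sets onto a qualitative category.
survivors_to_category <- function(surv, species = c("s1", "s2")) {
  keys <- vapply(surv, paste, character(1), collapse = "+")
  if (length(unique(keys)) > 1) return("bistability")
  s <- surv[[1]]
  if (length(s) == 2) "coexistence"
  else if (identical(s, species[1])) "species_1_excludes_2"
  else if (identical(s, species[2])) "species_2_excludes_1"
  else "no_survivors"
}

# Survivor set reached from a rare-invader start near one resident's
# monoculture attractor, in either mortality mode. Starting on the attractor
# keeps the comparison away from basin boundaries, whose positions genuinely
# differ between the discrete and continuous processes.
invasion_survivors <- function(params, delta, resident = 1,
                               mode = c("serial-dilution",
                                        "continuous-death"),
                               invader_density = 1e-6, n_cycles = 400) {
  mode <- match.arg(mode)
  r_res <- params$growth_rates[resident]
  N0 <- numeric(2)
  if (mode == "continuous-death") {
    N0[resident] <- monoculture_equilibrium(r_res, delta)
    N0[-resident] <- invader_density
    proto <- lv_protocol("continuous-death", delta = delta,
                         n_cycles = n_cycles, stop_on_convergence = TRUE)
    survivor_set(run_continuous(params, N0, proto))
  } else {
    DF <- delta_to_dilution(delta)
    mono <- subset_community(params, params$species_ids[resident])
    warm <- run_serial_dilution(
      mono, 0.5, lv_protocol("serial-dilution", dilution_factor = DF,
                             n_cycles = 60, stop_on_convergence = TRUE))
    N0[resident] <- warm$densities[nrow(warm$densities), 1] / DF
    N0[-resident] <- invader_density
    proto <- lv_protocol("serial-dilution", dilution_factor = DF,
                         n_cycles = n_cycles, stop_on_convergence = TRUE)
    survivor_set(run_serial_dilution(params, N0, proto))
  }
}

# A hand-built three-species pairwise outcome table at one dilution factor.
make_pair_table <- function(categories, f12s, species = c("A", "B", "C"),
                            DF = 100) {
  combs <- utils::combn(species, 2)
  data.frame(species_1 = combs[1, ], species_2 = combs[2, ],
             dilution_factor = DF, category = categories, f_12 = f12s,
             stringsAsFactors = FALSE)
}
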