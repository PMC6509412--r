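exp_table_cols <- c("condition_id", "dilution_factor", "starting_composition",
                    "replicate", "cycle", "species", "colony_count")

check_experiment_table <- function(table) {
  missing <- setdiff(exp_table_cols, names(table))
  if (length(missing))
    stop("experiment table is missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  cc <- table$colony_count
  if (any(!is.finite(cc)) || any(cc < 0) || any(cc != round(cc)))
    stop("colony counts must be nonnegative integers", call. = FALSE)
  invisible(table)
}

#' Endpoint composition estimates from colony counts
#'
#' For every condition (a single cultured community at one dilution factor,
#' starting composition and replicate) the final-cycle colony counts are
#' turned into composition estimates with beta-distribution error bars
#' ([beta_sd()] with the focal species' count against the summed count of all
#' others), plus a convergence flag: the condition is converged when each
#' species' fraction moved by less than `convergence_tol` over the trailing
#' `last_k_cycles` cycles.
#'
#' @param table Long-format experiment table with columns `condition_id`,
#'   `dilution_factor`, `starting_composition`, `replicate`, `cycle`,
#'   `species`, `colony_count`.
#' @param last_k_cycles Number of trailing cycles for the convergence flag
#'   (default 3).
#' @param convergence_tol Maximum absolute fraction change over the trailing
#'   window (default 0.1, matching the few-percent scatter expected of
#'   ~42-colony platings).
#' @return Data frame with one row per condition x species: counts, endpoint
#'   `fraction`, `sd` (beta SD), `converged`, and `usable` (`FALSE` when the
#'   endpoint plating had zero total colonies -- such conditions are flagged,
#'   never silently dropped).
#' @export
endpoint_fractions <- function(table, last_k_cycles = 3,
                               convergence_tol = 0.1) {
  check_experiment_table(table)
  out <- lapply(split(table, table$condition_id), function(cond) {
    cycles <- sort(unique(cond$cycle))
    last <- max(cycles)
    end <- cond[cond$cycle == last, , drop = FALSE]
    species <- sort(unique(cond$species))
    counts <- stats::setNames(numeric(length(species)), species)
    agg <- tapply(end$colony_count, end$species, sum)
    counts[names(agg)] <- agg
    total <- sum(counts)
    usable <- total > 0
    frac <- if (usable) counts / total else rep(NA_real_, length(counts))
    sds <- if (usable) beta_sd(counts, total - counts) else rep(NA_real_, length(counts))

    # convergence over the trailing window of per-cycle fractions
    win <- cycles[cycles > last - last_k_cycles]
    converged <- FALSE
    if (usable && length(win) >= 2) {
      fr <- vapply(win, function(cy) {
        sl <- cond[cond$cycle == cy, , drop = FALSE]
        cnt <- stats::setNames(numeric(length(species)), species)
        a <- tapply(sl$colony_count, sl$species, sum)
        cnt[names(a)] <- a
        if (sum(cnt) == 0) rep(NA_real_, length(cnt)) else cnt / sum(cnt)
      }, numeric(length(species)))
      fr <- matrix(fr, nrow = length(species))
      converged <- !anyNA(fr) &&
        all(apply(fr, 1, function(x) diff(range(x))) < convergence_tol)
    }
    data.frame(condition_id = cond$condition_id[1],
               dilution_factor = cond$dilution_factor[1],
               starting_composition = cond$starting_composition[1],
               replicate = cond$replicate[1],
               species = species,
               colony_count = unname(counts),
               fraction = unname(frac),
               sd = unname(sds),
               converged = converged,
               usable = usable,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

condition_survivors <- function(end_one_condition, extinction_threshold) {
  with(end_one_condition,
       sort(species[colony_count > 0 & fraction >= extinction_threshold]))
}

set_key <- function(s) paste(s, collapse = "+")

#' Call the qualitative outcome of one pair at one dilution factor
#'
#' Given endpoint estimates (from [endpoint_fractions()]) for the conditions
#' of a single two-species coculture at one dilution factor, across two or
#' more starting fractions, calls the outcome: exclusion when one species is
#' absent from every start, coexistence when all starts converge to interior
#' fractions within `convergence_window` of each other, and bistability when
#' different starts reach different survivor sets. A mixture of an interior
#' (coexistence) state and an exclusion state across starts is not an allowed
#' outcome of the Lotka-Volterra model; it is reported as bistability with
#' `non_LV = TRUE`, never coerced into a model category.
#'
#' @param endpoints Endpoint data frame restricted to one pair and one
#'   dilution factor.
#' @param extinction_threshold A species is called extinct in a condition
#'   when its endpoint count is 0 or its fraction falls below this value
#'   (default 0.005, under one colony at a typical 42-colony plating).
#' @param convergence_window Coexisting starts are deemed to share an
#'   attractor when their endpoint fractions lie within this absolute window
#'   of their mean (default 0.10).
#' @return Object of class `outcome_call`: list with `category`
#'   (`"species_1_excludes_2"`/`"species_2_excludes_1"`/`"coexistence"`/
#'   `"bistability"`/`"no_survivors"`), `survivor_sets` (unique endpoint sets),
#'   `stable_fraction` (mean fraction of the first species across converged
#'   coexisting conditions, with `stable_fraction_sd` from the beta SDs),
#'   `converged`, `ambiguous` (replicate conflict within a start), `non_LV`,
#'   `species`, `dilution_factor`, `n_conditions`.
#' @export
call_pair_outcome <- function(endpoints, extinction_threshold = 0.005,
                              convergence_window = 0.10) {
  species <- sort(unique(endpoints$species))
  if (length(species) != 2)
    stop("call_pair_outcome expects endpoint data for exactly two species",
         call. = FALSE)
  if (length(unique(endpoints$dilution_factor)) != 1)
    stop("call_pair_outcome expects a single dilution factor", call. = FALSE)
  # unusable conditions (zero colonies at endpoint) carry real signal: the
  # culture died out, i.e. an empty survivor set
  starts <- unique(endpoints$starting_composition)
  if (length(starts) < 2)
    stop("need endpoint data from at least two starting fractions",
         call. = FALSE)

  conds <- split(endpoints, endpoints$condition_id)
  surv <- lapply(conds, condition_survivors, extinction_threshold)
  start_of <- vapply(conds, function(d) as.character(d$starting_composition[1]),
                     character(1))
  ambiguous <- any(vapply(split(vapply(surv, set_key, character(1)), start_of),
                          function(k) length(unique(k)) > 1, logical(1)))

  keys <- vapply(surv, set_key, character(1))
  unique_sets <- surv[!duplicated(keys)]
  sizes <- lengths(unique_sets)

  frac1 <- vapply(conds, function(d) d$fraction[d$species == species[1]],
                  numeric(1))
  sd1 <- vapply(conds, function(d) d$sd[d$species == species[1]], numeric(1))
  all_converged <- all(vapply(conds, function(d) d$converged[1], logical(1)))

  stable_fraction <- NA_real_
  stable_fraction_sd <- NA_real_
  non_LV <- FALSE
  converged <- all_converged

  if (length(unique_sets) == 1) {
    s <- unique_sets[[1]]
    if (length(s) == 0) {
      category <- "no_survivors"
    } else if (length(s) == 1) {
      category <- if (s == species[1]) "species_1_excludes_2" else
        "species_2_excludes_1"
    } else {
      same_attractor <- all(abs(frac1 - mean(frac1)) <= convergence_window)
      category <- "coexistence"
      converged <- all_converged && same_attractor
      stable_fraction <- mean(frac1)
      stable_fraction_sd <- sqrt(mean(sd1^2) / length(sd1))
    }
  } else {
    category <- "bistability"
    non_LV <- any(sizes >= 2) && any(sizes <= 1)
    if (any(sizes == 2)) {
      # interior branch present: report its fraction (separatrix-side starts
      # that fell to exclusion are the other branch)
      int_ids <- names(keys)[keys == set_key(species)]
      stable_fraction <- mean(frac1[int_ids])
      stable_fraction_sd <- sqrt(mean(sd1[int_ids]^2) / length(int_ids))
    }
  }
  structure(
    list(category = category, survivor_sets = unname(unique_sets),
         stable_fraction = stable_fraction,
         stable_fraction_sd = stable_fraction_sd,
         converged = converged, ambiguous = ambiguous, non_LV = non_LV,
         species = species,
         dilution_factor = endpoints$dilution_factor[1],
         n_conditions = length(conds)),
    class = "outcome_call"
  )
}

#' @export
print.outcome_call <- function(x, ...) {
  cat("outcome call (", paste(x$species, collapse = ", "), ") at DF ",
      format(x$dilution_factor, big.mark = ","), ": ", x$category, sep = "")
  if (!is.na(x$stable_fraction))
    cat(sprintf(" [fraction of %s = %.3f +/- %.3f]", x$species[1],
                x$stable_fraction, x$stable_fraction_sd))
  if (isTRUE(x$non_LV)) cat(" [non-LV mixture]")
  if (isTRUE(x$ambiguous)) cat(" [ambiguous replicates]")
  cat("\n")
  invisible(x)
}

#' Call the stable state(s) of a multispecies condition set
#'
#' For a trio/quad/quintet cultured at one dilution factor from one or more
#' starting compositions, reports the endpoint survivor set reached from each
#' start. Distinct sets across starts mean multiple stable community states
#' (the multispecies analogue of bistability); the mean endpoint composition
#' over the conditions reaching each state is attached.
#'
#' @inheritParams call_pair_outcome
#' @param endpoints Endpoint data frame for one community and one dilution
#'   factor (any number of species >= 2).
#' @return Object of class `community_state_call`: list with `states` (list
#'   of survivor sets), `compositions` (mean endpoint composition per state,
#'   over the full species list), `state_conditions` (condition ids per
#'   state), `non_converged` (condition ids flagged not converged),
#'   `species`, `dilution_factor`.
#' @export
call_community_state <- function(endpoints, extinction_threshold = 0.005) {
  species <- sort(unique(endpoints$species))
  if (length(unique(endpoints$dilution_factor)) != 1)
    stop("call_community_state expects a single dilution factor", call. = FALSE)
  if (!nrow(endpoints))
    stop("no endpoint conditions", call. = FALSE)
  conds <- split(endpoints, endpoints$condition_id)
  surv <- lapply(conds, condition_survivors, extinction_threshold)
  keys <- vapply(surv, set_key, character(1))
  uk <- unique(keys)
  states <- surv[match(uk, keys)]
  compositions <- lapply(uk, function(k) {
    ids <- names(keys)[keys == k]
    mats <- sapply(ids, function(id) {
      d <- conds[[id]]
      stats::setNames(d$fraction, d$species)[species]
    })
    rowMeans(as.matrix(mats))
  })
  non_converged <- names(conds)[!vapply(conds, function(d) d$converged[1],
                                        logical(1))]
  structure(
    list(states = unname(states), compositions = compositions,
         state_conditions = lapply(uk, function(k) names(keys)[keys == k]),
         non_converged = non_converged, species = species,
         dilution_factor = endpoints$dilution_factor[1]),
    class = "community_state_call"
  )
}

#' @export
print.community_state_call <- function(x, ...) {
  cat("community state call at DF", format(x$dilution_factor, big.mark = ","),
      "-", length(x$states), "state(s)\n")
  for (i in seq_along(x$states)) {
    s <- x$states[[i]]
    cat("  state", i, ":", if (length(s)) paste(s, collapse = " + ")
        else "(all extinct)", "\n")
  }
  invisible(x)
}

#' Subway-map table from community state calls
#'
#' Flattens a set of [call_community_state()] results (one per dilution
#' factor) into the long-format presence/absence table behind a "subway map":
#' one row per species x dilution factor x stable state.
#'
#' @param calls List of `community_state_call` objects.
#' @return Data frame with columns `species`, `dilution_factor`,
#'   `state_index`, `present`.
#' @export
subway_table <- function(calls) {
  rows <- lapply(calls, function(cl) {
    do.call(rbind, lapply(seq_along(cl$states), function(i) {
      data.frame(species = cl$species,
                 dilution_factor = cl$dilution_factor,
                 state_index = i,
                 present = cl$species %in% cl$states[[i]],
                 stringsAsFactors = FALSE)
    }))
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res[order(res$species, res$dilution_factor, res$state_index), ]
}
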