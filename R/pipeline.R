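#' Run configuration for a full synthetic-analysis pipeline
#'
#' Assembles and validates the configuration consumed by [run_pipeline()].
#' Everything needed to reproduce a run lives here; a config plus its seed
#' reproduces the outputs bit for bit.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer root seed; every stochastic stage derives its own
#'   stream from it.
#' @param n_species Community size for the synthetic ground truth.
#' @param tradeoff,noise Generator settings (see [sample_params()]).
#' @param design A [design_spec()].
#' @param extinction_call_threshold,convergence_window Inference thresholds
#'   (see [call_pair_outcome()]).
#' @param stages Which stages to run, in order, among `"synth"`,
#'   `"simulate"`, `"infer"`, `"predict"`, `"score"`.
#' @return Object of class `run_config` (a validated named list).
#' @export
run_config <- function(out_dir, seed = 1, n_species = 3, tradeoff = 4,
                       noise = 0.3, design = design_spec(),
                       extinction_call_threshold = 0.005,
                       convergence_window = 0.10,
                       stages = c("synth", "simulate", "infer", "predict",
                                  "score")) {
  known <- c("synth", "simulate", "infer", "predict", "score")
  bad <- setdiff(stages, known)
  if (length(bad))
    stop("unknown stages: ", paste(bad, collapse = ", "), call. = FALSE)
  if (!is.numeric(seed) || length(seed) != 1 || seed != round(seed))
    stop("seed must be a single integer", call. = FALSE)
  structure(
    list(out_dir = out_dir, seed = as.integer(seed), n_species = n_species,
         tradeoff = tradeoff, noise = noise, design = design,
         extinction_call_threshold = extinction_call_threshold,
         convergence_window = convergence_window,
         stages = known[known %in% stages]),
    class = "run_config"
  )
}

#' Serialize / parse a run configuration
#'
#' @param config A [run_config()] object.
#' @param path YAML file path.
#' @return `write_run_config` returns `path` invisibly; `read_run_config`
#'   returns the reconstructed `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  obj <- unclass(config)
  obj$design <- unclass(obj$design)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  obj <- yaml::read_yaml(path)
  design <- do.call(design_spec, obj$design)
  run_config(out_dir = obj$out_dir, seed = obj$seed,
             n_species = obj$n_species, tradeoff = obj$tradeoff,
             noise = obj$noise, design = design,
             extinction_call_threshold = obj$extinction_call_threshold,
             convergence_window = obj$convergence_window,
             stages = obj$stages)
}

write_csv_ <- function(df, path, digits = 6) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) round(x, digits))
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the synthetic-analysis pipeline end to end
#'
#' Executes the requested stages in order: `synth` samples a ground-truth
#' community and writes its config; `simulate` generates the serial-dilution
#' experiment table and OD curves; `infer` computes endpoint fractions, pair
#' outcome calls and multispecies state calls (with subway-map export);
#' `predict` builds assembly-rule, carrying-capacity and random predictions
#' per dilution factor; `score` compares predictions against the observed
#' multispecies endpoints. A manifest of inputs, settings, seeds, and output
#' checksums is written last. Stage failures abort with a stage-named error;
#' outputs of completed stages are retained.
#'
#' @param config A [run_config()].
#' @return The output directory path, invisibly. Outputs:
#'   `ground_truth.yaml`, `experiment.csv`, `od_curves.csv`,
#'   `endpoints.csv`, `pair_outcomes.csv`, `community_states.csv`,
#'   `subway.csv`, `predictions.csv`, `error_report.csv`, `manifest.json`
#'   (subset according to `stages`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  if (is.null(out) || !nzchar(out))
    stop("config error: out_dir is missing", call. = FALSE)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  design <- config$design
  paths <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  truth <- NULL; exp_tab <- NULL; ends <- NULL; pair_tab <- NULL
  state_calls <- NULL; predictions <- NULL

  if ("synth" %in% config$stages) {
    truth <- stage("synth", {
      tr <- sample_params(config$n_species, tradeoff = config$tradeoff,
                          noise = config$noise, seed = config$seed)
      p <- file.path(out, "ground_truth.yaml")
      write_community_config(tr$params, p, extra = list(
        carrying_capacity = as.list(unname(tr$carrying_capacity)),
        lag_hours = as.list(unname(tr$lag_hours)),
        seed = config$seed))
      paths <- c(paths, p)
      tr
    })
  }
  if ("simulate" %in% config$stages) {
    if (is.null(truth)) stop("config error: 'simulate' requires 'synth'",
                             call. = FALSE)
    exp_tab <- stage("simulate", {
      tab <- simulate_experiment(truth, design, seed = config$seed + 1L)
      paths <- c(paths, write_csv_(tab, file.path(out, "experiment.csv")))
      ods <- simulate_od_curves(truth, design, seed = config$seed + 2L)
      paths <- c(paths, write_csv_(ods, file.path(out, "od_curves.csv")))
      tab
    })
  }
  ids <- if (!is.null(truth)) truth$params$species_ids else NULL
  if ("infer" %in% config$stages) {
    if (is.null(exp_tab)) stop("config error: 'infer' requires 'simulate'",
                               call. = FALSE)
    stage("infer", {
      ends <- endpoint_fractions(exp_tab)
      meta <- unique(exp_tab[, c("condition_id", "community")])
      ends$community <- meta$community[match(ends$condition_id,
                                              meta$condition_id)]
      paths <- c(paths, write_csv_(ends, file.path(out, "endpoints.csv")))
      pairs <- utils::combn(ids, 2, simplify = FALSE)
      calls <- list()
      for (pr in pairs) {
        comm <- paste(pr, collapse = ".")
        for (DF in design$dilution_factors) {
          sel <- ends[ends$community == comm & ends$dilution_factor == DF, ]
          if (!nrow(sel)) next
          calls[[length(calls) + 1]] <- call_pair_outcome(
            sel, config$extinction_call_threshold, config$convergence_window)
        }
      }
      pair_tab <- pair_outcome_table(calls)
      paths <- c(paths, write_csv_(pair_tab,
                                    file.path(out, "pair_outcomes.csv")))
      full <- paste(ids, collapse = ".")
      state_calls <- lapply(design$dilution_factors, function(DF) {
        sel <- ends[ends$community == full & ends$dilution_factor == DF, ]
        call_community_state(sel, config$extinction_call_threshold)
      })
      states_df <- do.call(rbind, lapply(state_calls, function(cl)
        do.call(rbind, lapply(seq_along(cl$states), function(i) data.frame(
          dilution_factor = cl$dilution_factor, state_index = i,
          state = set_key(cl$states[[i]]),
          species = cl$species,
          fraction = unname(cl$compositions[[i]]),
          stringsAsFactors = FALSE)))))
      paths <- c(paths, write_csv_(states_df,
                                    file.path(out, "community_states.csv")))
      paths <- c(paths, write_csv_(subway_table(state_calls),
                                    file.path(out, "subway.csv")))
    })
  }
  if ("predict" %in% config$stages) {
    if (is.null(pair_tab)) stop("config error: 'predict' requires 'infer'",
                                call. = FALSE)
    predictions <- stage("predict", {
      rows <- list()
      for (di in seq_along(design$dilution_factors)) {
        DF <- design$dilution_factors[di]
        mono <- ends[ends$community %in% ids & ends$dilution_factor == DF &
                       ends$species == ends$community, ]
        exp_mono <- exp_tab[exp_tab$condition_id %in% mono$condition_id, ]
        last_cycle <- stats::ave(exp_mono$cycle, exp_mono$condition_id,
                                 FUN = max)
        exp_end <- exp_mono[exp_mono$cycle == last_cycle, ]
        dens <- stats::setNames(
          exp_end$density[match(ids, exp_end$species)] *
            truth$carrying_capacity[ids], ids)
        dens[is.na(dens)] <- 0
        viable <- stats::setNames(dens > 0, ids)
        asm <- tryCatch(
          assembly_prediction(pair_tab, ids, dilution_factor = DF,
                              viable = viable),
          warning = function(w) list(states = list(), compositions = list()))
        add <- function(type, state, comp) {
          rows[[length(rows) + 1]] <<- data.frame(
            dilution_factor = DF, prediction_type = type,
            state = state, species = ids, fraction = unname(comp[ids]),
            stringsAsFactors = FALSE)
        }
        for (i in seq_along(asm$states))
          add("assembly", set_key(asm$states[[i]]), asm$compositions[[i]])
        if (sum(dens) > 0)
          add("carrying_capacity", set_key(ids[dens > 0]),
              carrying_capacity_prediction(dens))
        add("random", "random",
            stats::setNames(random_prediction(length(ids),
                                              seed = config$seed + 100L + di),
                            ids))
      }
      pred_df <- do.call(rbind, rows)
      paths <- c(paths, write_csv_(pred_df,
                                    file.path(out, "predictions.csv")))
      pred_df
    })
  }
  if ("score" %in% config$stages) {
    if (is.null(predictions)) stop("config error: 'score' requires 'predict'",
                                   call. = FALSE)
    stage("score", {
      full <- paste(ids, collapse = ".")
      stratum <- c("2" = "pair", "3" = "trio", "4" = "quad",
                   "5" = "quintet")[as.character(length(ids))]
      cases <- list()
      for (DF in design$dilution_factors) {
        sel <- ends[ends$community == full & ends$dilution_factor == DF &
                      ends$usable, ]
        if (!nrow(sel)) next
        obs <- do.call(rbind, lapply(split(sel, sel$condition_id), function(d)
          stats::setNames(d$fraction, d$species)[ids]))
        colnames(obs) <- ids
        for (type in unique(predictions$prediction_type)) {
          pd <- predictions[predictions$dilution_factor == DF &
                              predictions$prediction_type == type, ]
          preds <- lapply(split(pd, pd$state), function(d)
            stats::setNames(d$fraction, d$species)[ids])
          cases[[length(cases) + 1]] <- list(
            id = paste(full, DF, type, sep = "_"), stratum = stratum,
            type = type, observed = obs, predicted = preds)
        }
      }
      report <- aggregate_errors(cases, config$extinction_call_threshold)
      paths <- c(paths, write_csv_(report$summary,
                                    file.path(out, "error_report.csv")))
      paths <- c(paths, write_csv_(report$per_case,
                                    file.path(out, "error_cases.csv")))
    })
  }
  manifest <- list(
    package = "lvmort",
    version = as.character(utils::packageVersion("lvmort")),
    seed = config$seed,
    stages = config$stages,
    thresholds = list(
      extinction_call = config$extinction_call_threshold,
      convergence_window = config$convergence_window,
      extinction_density = 1e-10),
    outputs = as.list(tools::md5sum(paths))
  )
  names(manifest$outputs) <- basename(paths)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out)
}

#' ASCII rendering of a subway map
#'
#' Draws the presence/absence-by-dilution-factor chart as text: one row per
#' species (fast growers on top when growth rates are supplied), one column
#' per dilution factor, `==` marking presence. Where a dilution factor
#' carries more than one stable state, each species gains extra rows
#' (`"/2"`, ...) showing its presence in the alternative states.
#'
#' @param subway Data frame from [subway_table()] (columns `species`,
#'   `dilution_factor`, `state_index`, `present`).
#' @param growth_rates Optional named rates used to order species fast to
#'   slow.
#' @return Character vector of lines, invisibly; also printed.
#' @export
render_subway <- function(subway, growth_rates = NULL) {
  species <- unique(subway$species)
  if (!is.null(growth_rates))
    species <- species[order(-growth_rates[species])]
  dfs <- sort(unique(subway$dilution_factor))
  n_states <- vapply(dfs, function(DF)
    max(subway$state_index[subway$dilution_factor == DF]), numeric(1))
  width <- 7
  fmt_df <- function(x) formatC(sprintf("1e%d", round(log10(x))),
                                width = width)
  lines <- paste0(formatC("DF:", width = 10, flag = "-"),
                  paste(vapply(dfs, fmt_df, character(1)), collapse = ""))
  for (sp in species) {
    for (st in seq_len(max(n_states))) {
      cells <- vapply(seq_along(dfs), function(i) {
        if (st > n_states[i]) return(formatC("", width = width))
        hit <- subway$present[subway$species == sp &
                                subway$dilution_factor == dfs[i] &
                                subway$state_index == st]
        formatC(if (isTRUE(hit[1])) "==" else "--", width = width)
      }, character(1))
      label <- if (st == 1) sp else paste0(sp, " /", st)
      if (st == 1 || any(grepl("=|-", cells)))
        lines <- c(lines, paste0(formatC(label, width = 10, flag = "-"),
                                 paste(cells, collapse = "")))
    }
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
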