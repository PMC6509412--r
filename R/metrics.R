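#' Normalized quantitative prediction error
#'
#' L2 distance between a predicted and an observed composition, divided by
#' sqrt(2) -- the largest distance two compositions can attain, reached when
#' a species predicted extinct in fact dominates -- so the error always lies
#' in `[0, 1]`.
#'
#' @param predicted,observed Composition vectors over the same species list
#'   (same length and, if named, same names), each summing to 1.
#' @return Normalized error in `[0, 1]`.
#' @export
quantitative_error <- function(predicted, observed) {
  if (length(predicted) != length(observed))
    stop("predicted and observed compositions differ in length", call. = FALSE)
  if (!is.null(names(predicted)) && !is.null(names(observed))) {
    if (!setequal(names(predicted), names(observed)))
      stop("predicted and observed compositions cover different species",
           call. = FALSE)
    observed <- observed[names(predicted)]
  }
  for (v in list(predicted, observed))
    if (abs(sum(v) - 1) > 1e-6 || any(v < -1e-12))
      stop("compositions must be nonnegative and sum to 1", call. = FALSE)
  sqrt(sum((predicted - observed)^2)) / sqrt(2)
}

#' Qualitative (presence/absence) error rate
#'
#' Fraction of species miscalled present or absent. With several allowed
#' predicted states (bistable cases) the best-matching state is scored.
#'
#' @param predicted_sets A survivor set (character vector) or a list of
#'   allowed survivor sets.
#' @param observed_set Observed survivor set.
#' @param species Full species list of the community.
#' @return Miscalled species / total species, in `[0, 1]`.
#' @export
qualitative_error_rate <- function(predicted_sets, observed_set, species) {
  if (!is.list(predicted_sets)) predicted_sets <- list(predicted_sets)
  if (!length(predicted_sets)) return(1)
  errs <- vapply(predicted_sets, function(s) {
    sum((species %in% s) != (species %in% observed_set)) / length(species)
  }, numeric(1))
  min(errs)
}

#' Beta-distribution standard deviation for a colony-count fraction
#'
#' Uncertainty of a composition fraction estimated from colony counts, as
#' the SD of the Beta posterior under a flat (Bayes) prior:
#' `sqrt((a+1)(b+1) / ((a+b+2)^2 (a+b+3)))`, where `a` is the focal species'
#' colony count and `b` the summed count of all other species.
#'
#' @param a,b Nonnegative integer colony counts (vectorized).
#' @return Standard deviation(s) of the estimated fraction.
#' @examples
#' beta_sd(0, 0)   # 1/sqrt(12): a single plating with no colonies at all
#' beta_sd(42, 0)  # a clean sweep of 42 colonies
#' @export
beta_sd <- function(a, b) {
  if (any(a < 0) || any(b < 0) || any(a != round(a)) || any(b != round(b)))
    stop("colony counts must be nonnegative integers", call. = FALSE)
  sqrt((a + 1) * (b + 1) / ((a + b + 2)^2 * (a + b + 3)))
}

#' Aggregate prediction errors over a benchmark of community cases
#'
#' Scores predicted community states against observed endpoints the way the
#' error tables are built: within each case, observed starting conditions are
#' grouped by the survivor set they reached and averaged within each group;
#' each allowed predicted state is scored against the observed group with the
#' matching survivor set (or, failing a match, against its closest group,
#' flagged); cases with several allowed states contribute the smallest of the
#' state errors. Means and standard errors are reported per stratum and
#' prediction type.
#'
#' @param cases List of case descriptions. Each case is a list with:
#'   `observed` -- matrix of endpoint compositions, one row per starting
#'   condition, columns named by species; `predicted` -- a list of predicted
#'   composition vectors (one per allowed state) over the same species;
#'   optional `stratum` (e.g. `"trio"`, `"quad"`) and `type` (e.g.
#'   `"assembly"`, `"carrying_capacity"`, `"random"`) and `id`.
#' @param extinction_threshold Observed fractions below this are treated as
#'   absent when grouping starts by final state (default 0.005).
#' @return List with `per_case` (data frame: id, stratum, type, error,
#'   matched) and `summary` (data frame: stratum x type mean error, SEM, n).
#'   Strata also include an `"overall"` row per type.
#' @export
aggregate_errors <- function(cases, extinction_threshold = 0.005) {
  score_case <- function(case) {
    obs <- as.matrix(case$observed)
    if (is.null(colnames(obs))) stop("observed matrix needs species names",
                                     call. = FALSE)
    keys <- apply(obs >= extinction_threshold, 1, function(p)
      paste(colnames(obs)[p], collapse = "+"))
    groups <- lapply(unique(keys), function(k)
      colMeans(obs[keys == k, , drop = FALSE]))
    gkeys <- unique(keys)
    preds <- case$predicted
    if (!length(preds)) return(c(error = NA_real_, matched = FALSE))
    state_err <- vapply(preds, function(p) {
      p <- p[colnames(obs)]
      pkey <- paste(colnames(obs)[p >= extinction_threshold], collapse = "+")
      hit <- which(gkeys == pkey)
      errs <- vapply(groups, quantitative_error, numeric(1), predicted = p)
      if (length(hit)) errs[hit] else min(errs)
    }, numeric(1))
    matched <- any(vapply(preds, function(p) {
      p <- p[colnames(obs)]
      paste(colnames(obs)[p >= extinction_threshold], collapse = "+") %in% gkeys
    }, logical(1)))
    c(error = min(state_err), matched = matched)
  }
  scored <- t(vapply(cases, score_case, c(error = 0, matched = 0)))
  per_case <- data.frame(
    id = vapply(seq_along(cases), function(i)
      if (!is.null(cases[[i]]$id)) as.character(cases[[i]]$id) else
        as.character(i), character(1)),
    stratum = vapply(cases, function(c)
      if (!is.null(c$stratum)) c$stratum else "all", character(1)),
    type = vapply(cases, function(c)
      if (!is.null(c$type)) c$type else "assembly", character(1)),
    error = scored[, "error"],
    matched = as.logical(scored[, "matched"]),
    stringsAsFactors = FALSE
  )
  summarize <- function(df, stratum) {
    do.call(rbind, lapply(split(df, df$type), function(g) {
      e <- g$error[is.finite(g$error)]
      data.frame(stratum = stratum, type = g$type[1],
                 mean_error = mean(e),
                 sem = if (length(e) > 1) stats::sd(e) / sqrt(length(e)) else NA_real_,
                 n = length(e), stringsAsFactors = FALSE)
    }))
  }
  summ <- do.call(rbind, c(
    lapply(split(per_case, per_case$stratum), function(g)
      summarize(g, g$stratum[1])),
    list(summarize(per_case, "overall"))
  ))
  rownames(summ) <- NULL
  list(per_case = per_case, summary = summ)
}

#' Competitive score of each species across its pairwise cocultures
#'
#' A species' competitive score at one dilution factor is its mean
#' equilibrium fraction over all pairs in which it competed, with replicates
#' of the same pair averaged first. The standard error is a bootstrap over
#' replicate-level pair outcomes: replicates are resampled with replacement
#' within each pair, pair means recomputed, and the species mean taken; the
#' SD of the bootstrap means is reported.
#'
#' @param pair_fractions Data frame with columns `species`, `pair_id`,
#'   `replicate`, `fraction` (the species' endpoint fraction in that pair and
#'   replicate).
#' @param B Number of bootstrap resamples (default 5000).
#' @param seed Optional integer seed for the bootstrap.
#' @return Data frame with columns `species`, `score`, `se`, `n_pairs`.
#' @export
competitive_score <- function(pair_fractions, B = 5000, seed = NULL) {
  need <- c("species", "pair_id", "replicate", "fraction")
  missing <- setdiff(need, names(pair_fractions))
  if (length(missing))
    stop("pair_fractions is missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  out <- lapply(split(pair_fractions, pair_fractions$species), function(d) {
    reps <- split(d$fraction, d$pair_id)
    if (!length(reps)) return(NULL)
    score <- mean(vapply(reps, mean, numeric(1)))
    boots <- vapply(seq_len(B), function(b) {
      mean(vapply(reps, function(x)
        mean(x[sample.int(length(x), replace = TRUE)]), numeric(1)))
    }, numeric(1))
    data.frame(species = d$species[1], score = score,
               se = stats::sd(boots), n_pairs = length(reps),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Regression of competitive score on growth rate
#'
#' Ordinary least squares of score against growth rate across the species at
#' one dilution factor; the slope's sign tracks the growth/competitive-
#' ability tradeoff (negative when slow growers dominate at low mortality,
#' flipping positive at high dilution).
#'
#' @param growth_rates Numeric vector of per-species growth rates (1/h).
#' @param scores Numeric vector of competitive scores, same order.
#' @return List with `slope`, `slope_se`, `intercept`, and the fitted `lm`
#'   object as `fit`.
#' @export
growth_score_regression <- function(growth_rates, scores) {
  if (length(growth_rates) != length(scores))
    stop("growth_rates and scores differ in length", call. = FALSE)
  if (length(scores) < 3)
    stop("need at least three species", call. = FALSE)
  if (stats::sd(growth_rates) == 0)
    stop("growth rates are constant; slope is undefined", call. = FALSE)
  fit <- stats::lm(scores ~ growth_rates)
  cf <- summary(fit)$coefficients
  list(slope = unname(cf["growth_rates", "Estimate"]),
       slope_se = unname(cf["growth_rates", "Std. Error"]),
       intercept = unname(cf["(Intercept)", "Estimate"]),
       fit = fit)
}
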