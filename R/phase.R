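#' Convert a dilution factor to its equivalent continuous mortality rate
#'
#' A fold-dilution `DF` applied every `cycle_hours` removes the same fraction
#' of every population per cycle as a continuous death rate
#' `log(DF)/cycle_hours` acting throughout the cycle, which is the bridge
#' between the batch-transfer protocol and the continuous model.
#'
#' @param dilution_factor Dilution factor (>= 1), vectorized.
#' @param cycle_hours Hours between transfers (default 24).
#' @return Mortality rate in 1/h.
#' @seealso [delta_to_dilution()]
#' @export
dilution_to_delta <- function(dilution_factor, cycle_hours = 24) {
  if (any(dilution_factor < 1)) stop("dilution_factor must be >= 1", call. = FALSE)
  if (cycle_hours <= 0) stop("cycle_hours must be > 0", call. = FALSE)
  log(dilution_factor) / cycle_hours
}

#' Inverse of [dilution_to_delta()]
#'
#' @param delta Mortality rate (per hour, >= 0), vectorized.
#' @param cycle_hours Hours between transfers (default 24).
#' @return Equivalent dilution factor `exp(delta * cycle_hours)`.
#' @export
delta_to_dilution <- function(delta, cycle_hours = 24) {
  if (any(delta < 0)) stop("delta must be >= 0", call. = FALSE)
  exp(delta * cycle_hours)
}

#' Mortality re-parameterization of the competition model
#'
#' With an added death rate the model maps exactly onto the death-free model
#' with rescaled densities and transformed coefficients:
#' `alpha_eff[i, j] = alpha[i, j] * (1 - delta_j/r_j) / (1 - delta_i/r_i)`,
#' effective rates `r_i - delta_i`, and density rescaling
#' `Ntilde_i = N_i / (1 - delta_i/r_i)`. Mortality uniform across species is
#' the usual case (serial dilution kills indiscriminately); a per-species
#' vector is accepted for the species-specific extension, which moves a pair
#' along the same 45-degree line in log-coefficient space but in a direction
#' set by the differing rates.
#'
#' @param params A [community_params()] object.
#' @param delta Mortality rate (per hour): scalar (uniform) or one per
#'   species. Must satisfy `delta_i < r_i` for every species.
#' @return Object of class `effective_params`: list with `delta`,
#'   `alpha_eff`, `r_eff`, `rescale` (the factors `1 - delta_i/r_i`), and
#'   `species_ids`.
#' @export
effective_params <- function(params, delta) {
  stopifnot(inherits(params, "community_params"))
  n <- length(params$species_ids)
  if (!length(delta) %in% c(1L, n))
    stop("delta must be scalar or one rate per species", call. = FALSE)
  delta <- rep_len(as.numeric(delta), n)
  if (any(delta < 0)) stop("delta must be >= 0", call. = FALSE)
  r <- params$growth_rates
  bad <- delta >= r
  if (any(bad))
    stop("mortality exceeds growth rate for species: ",
         paste(params$species_ids[bad], collapse = ", "),
         " (the re-parameterization requires delta < r)", call. = FALSE)
  rescale <- 1 - delta / r
  alpha_eff <- params$alpha * outer(1 / rescale, rescale)
  dimnames(alpha_eff) <- dimnames(params$alpha)
  structure(
    list(delta = stats::setNames(delta, params$species_ids),
         alpha_eff = alpha_eff,
         r_eff = stats::setNames(r - delta, params$species_ids),
         rescale = stats::setNames(rescale, params$species_ids),
         species_ids = params$species_ids),
    class = "effective_params"
  )
}

#' Classify a two-species outcome from its effective coefficients
#'
#' The qualitative outcome depends only on whether each effective coefficient
#' exceeds one: both below one gives stable coexistence, both above one gives
#' bistability (two stable exclusion states separated by an unstable interior
#' point), and exactly one above one gives exclusion by the species with the
#' smaller incoming coefficient.
#'
#' @param alpha_12,alpha_21 Effective competition coefficients (species 1
#'   inhibited by 2, and vice versa). Alternatively pass an
#'   [effective_params()] object for a pair as `alpha_12` and leave
#'   `alpha_21` missing.
#' @param rescale Length-2 factors `1 - delta/r_i` used to express the
#'   interior fraction on the normalized-density scale (default `c(1, 1)`,
#'   i.e. report in rescaled units).
#' @param tie_tol Coefficients within `tie_tol` of 1 (or a coefficient
#'   product within `tie_tol` of 1) give the `"degenerate"` category rather
#'   than an arbitrary side.
#' @return Object of class `pair_outcome`: list with `category` (one of
#'   `"species_1_excludes_2"`, `"species_2_excludes_1"`, `"coexistence"`,
#'   `"bistability"`, `"degenerate"`), `interior_fraction` (fraction of
#'   species 1 at the interior point: the stable coexisting fraction, or the
#'   separatrix for bistable pairs; `NA` otherwise), and the inputs.
#' @export
classify_pair <- function(alpha_12, alpha_21, rescale = c(1, 1),
                          tie_tol = 1e-9) {
  if (inherits(alpha_12, "effective_params")) {
    eff <- alpha_12
    if (length(eff$species_ids) != 2)
      stop("classify_pair needs a two-species effective_params", call. = FALSE)
    rescale <- unname(eff$rescale)
    alpha_21 <- eff$alpha_eff[2, 1]
    alpha_12 <- eff$alpha_eff[1, 2]
  }
  if (!is.finite(alpha_12) || !is.finite(alpha_21) ||
      alpha_12 <= 0 || alpha_21 <= 0)
    stop("effective coefficients must be finite and positive", call. = FALSE)

  near_one <- function(x) abs(x - 1) <= tie_tol
  category <- if (near_one(alpha_12) || near_one(alpha_21)) {
    "degenerate"
  } else if (alpha_12 < 1 && alpha_21 < 1) {
    "coexistence"
  } else if (alpha_12 > 1 && alpha_21 > 1) {
    "bistability"
  } else if (alpha_12 > 1) {
    # species 1 feels super-unit inhibition: species 2 wins
    "species_2_excludes_1"
  } else {
    "species_1_excludes_2"
  }

  interior_fraction <- NA_real_
  if (category %in% c("coexistence", "bistability")) {
    Nt1 <- (1 - alpha_12) / (1 - alpha_12 * alpha_21)
    Nt2 <- (1 - alpha_21) / (1 - alpha_12 * alpha_21)
    N1 <- Nt1 * rescale[1]
    N2 <- Nt2 * rescale[2]
    interior_fraction <- N1 / (N1 + N2)
  }
  structure(
    list(category = category, interior_fraction = interior_fraction,
         alpha_12 = alpha_12, alpha_21 = alpha_21),
    class = "pair_outcome"
  )
}

#' @export
print.pair_outcome <- function(x, ...) {
  cat("pair outcome:", x$category, "\n")
  cat(sprintf("  alpha_eff = (%.4g, %.4g)", x$alpha_12, x$alpha_21))
  if (!is.na(x$interior_fraction))
    cat(sprintf("; interior fraction of species 1 = %.4f", x$interior_fraction))
  cat("\n")
  invisible(x)
}

#' Critical mortality rates of a pair
#'
#' Under uniform mortality each effective coefficient crosses 1 at a
#' closed-form rate: solving `alpha_ij (1 - d/r_j) / (1 - d/r_i) = 1` gives
#' `d* = r_i r_j (1 - alpha_ij) / (r_j - alpha_ij r_i)`. Crossings falling in
#' `(0, min r)` bound the windows of constant qualitative outcome; equal
#' growth rates leave the coefficients mortality-independent (no crossings).
#'
#' @param params A two-species [community_params()].
#' @return Data frame with columns `delta` (ascending), `coefficient`
#'   (`"alpha_12"` or `"alpha_21"`, the coefficient crossing 1), and
#'   `dilution_factor` (the 24-h-cycle equivalent). Zero rows when no
#'   crossing lies in range.
#' @export
critical_mortalities <- function(params) {
  stopifnot(inherits(params, "community_params"))
  if (length(params$species_ids) != 2)
    stop("critical_mortalities requires exactly two species", call. = FALSE)
  r <- unname(params$growth_rates)
  a <- unname(params$alpha)
  if (r[1] == r[2])
    return(data.frame(delta = numeric(0), coefficient = character(0),
                      dilution_factor = numeric(0)))
  cross <- function(i, j) {
    aij <- a[i, j]
    denom <- r[j] - aij * r[i]
    if (denom == 0) return(NA_real_)
    r[i] * r[j] * (1 - aij) / denom
  }
  d <- c(alpha_12 = cross(1, 2), alpha_21 = cross(2, 1))
  keep <- !is.na(d) & d > 0 & d < min(r)
  out <- data.frame(delta = unname(d[keep]),
                    coefficient = names(d)[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(out$delta), , drop = FALSE]
  out$dilution_factor <- delta_to_dilution(out$delta)
  rownames(out) <- NULL
  out
}

#' Sweep mortality and classify the outcome at each level
#'
#' Classifies a pair over a grid of mortality rates (or dilution factors),
#' producing the data behind a bifurcation ("subway map") line: between
#' consecutive critical mortalities the category is constant, and increasing
#' mortality always moves the pair along a 45-degree line in
#' log-effective-coefficient space toward fast-grower dominance.
#'
#' @param params A two-species [community_params()].
#' @param deltas Numeric grid of mortality rates (>= 0). Supply either this
#'   or `dilution_factors`. Grid points at or beyond the smaller growth rate
#'   fall outside the re-parameterization's domain; there the outcome is set
#'   by monoculture viability alone (the slower species cannot persist even
#'   alone) and the effective coefficients are reported as `NA`.
#' @param dilution_factors Numeric grid of dilution factors (converted with
#'   [dilution_to_delta()]).
#' @param cycle_hours Cycle length used for the delta/DF correspondence.
#' @return Data frame with columns `delta`, `dilution_factor`, `category`,
#'   `interior_fraction`, `alpha_eff_12`, `alpha_eff_21`.
#' @export
mortality_sweep <- function(params, deltas = NULL, dilution_factors = NULL,
                            cycle_hours = 24) {
  stopifnot(inherits(params, "community_params"))
  if (length(params$species_ids) != 2)
    stop("mortality_sweep requires exactly two species", call. = FALSE)
  if (is.null(deltas) && is.null(dilution_factors))
    stop("supply deltas or dilution_factors", call. = FALSE)
  if (is.null(deltas)) deltas <- dilution_to_delta(dilution_factors, cycle_hours)
  if (any(deltas < 0))
    stop("mortality grid must be nonnegative", call. = FALSE)
  deltas <- sort(deltas)
  r <- params$growth_rates
  rows <- lapply(deltas, function(d) {
    if (d < min(r)) {
      out <- classify_pair(effective_params(params, d))
      category <- out$category
      interior <- out$interior_fraction
      a12 <- out$alpha_12; a21 <- out$alpha_21
    } else {
      alive <- which(monoculture_equilibrium(r, d) > 0)
      category <- if (!length(alive)) "no_survivors"
        else if (alive == 1L) "species_1_excludes_2" else "species_2_excludes_1"
      interior <- NA_real_; a12 <- NA_real_; a21 <- NA_real_
    }
    data.frame(delta = d,
               dilution_factor = delta_to_dilution(d, cycle_hours),
               category = category,
               interior_fraction = interior,
               alpha_eff_12 = a12,
               alpha_eff_21 = a21,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Numerically locate category transitions along a mortality sweep
#'
#' Scans `[0, upper]` on a fine grid and bisects every category change of
#' [classify_pair()] down to `tol`. This is a purely numerical search on the
#' classification itself, useful as an independent check of the closed-form
#' [critical_mortalities()].
#'
#' @param params A two-species [community_params()].
#' @param upper Upper end of the scan; default just below the smaller growth
#'   rate.
#' @param n_grid Number of initial scan points.
#' @param tol Bisection width at which a transition is reported.
#' @return Data frame with columns `delta` (transition midpoint), `from`,
#'   `to` (categories on either side).
#' @export
locate_transitions <- function(params, upper = NULL, n_grid = 400,
                               tol = 1e-10) {
  stopifnot(inherits(params, "community_params"))
  if (is.null(upper)) upper <- min(params$growth_rates) * (1 - 1e-9)
  grid <- seq(0, upper, length.out = n_grid)
  cat_at <- function(d) classify_pair(effective_params(params, d))$category
  cats <- vapply(grid, cat_at, character(1))
  out <- list()
  for (i in seq_len(length(grid) - 1)) {
    if (cats[i] == cats[i + 1] || cats[i] == "degenerate" ||
        cats[i + 1] == "degenerate") next
    lo <- grid[i]; hi <- grid[i + 1]
    clo <- cats[i]
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      cmid <- cat_at(mid)
      if (cmid == clo) lo <- mid else hi <- mid
    }
    out[[length(out) + 1]] <- data.frame(
      delta = (lo + hi) / 2, from = cats[i], to = cats[i + 1],
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(delta = numeric(0), from = character(0),
                      to = character(0)))
  do.call(rbind, out)
}
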