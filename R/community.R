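#' Community parameter set for the competition model
#'
#' Bundles the ground-truth parameters of an n-species Lotka-Volterra
#' competition community: per-species maximum growth rates and the matrix of
#' competition coefficients. Densities in this model are normalized to each
#' species' own carrying capacity, so self-inhibition is fixed at 1 and
#' `alpha[i, j]` measures how strongly species `j` inhibits species `i`
#' relative to i's self-inhibition.
#'
#' @param species_ids Character vector of unique species labels.
#' @param growth_rates Numeric vector of maximum growth rates r_i (per hour),
#'   all strictly positive, one per species.
#' @param alpha Numeric n x n matrix of competition coefficients, all
#'   nonnegative, with unit diagonal (self-inhibition is absorbed into the
#'   normalization of density by carrying capacity).
#'
#' @return An object of class `community_params`: a list with elements
#'   `species_ids`, `growth_rates` (named), and `alpha` (dimnames set to the
#'   species ids).
#' @examples
#' community_params(c("f", "s"), c(1, 0.5),
#'                  matrix(c(1, 2, 0.4, 1), 2, 2, byrow = TRUE))
#' @export
community_params <- function(species_ids, growth_rates, alpha) {
  species_ids <- as.character(species_ids)
  n <- length(species_ids)
  if (n < 1) stop("at least one species is required", call. = FALSE)
  if (anyDuplicated(species_ids))
    stop("species_ids must be unique", call. = FALSE)
  growth_rates <- as.numeric(growth_rates)
  if (length(growth_rates) != n)
    stop("growth_rates must have one entry per species", call. = FALSE)
  if (!all(is.finite(growth_rates)) || any(growth_rates <= 0))
    stop("all growth rates must be finite and > 0", call. = FALSE)
  alpha <- as.matrix(alpha)
  if (!all(dim(alpha) == c(n, n)))
    stop("alpha must be an n x n matrix matching species_ids", call. = FALSE)
  storage.mode(alpha) <- "double"
  if (!all(is.finite(alpha)) || any(alpha < 0))
    stop("all competition coefficients must be finite and >= 0", call. = FALSE)
  if (!all(diag(alpha) == 1))
    stop("alpha must have unit diagonal (densities are normalized to carrying capacity)",
         call. = FALSE)
  names(growth_rates) <- species_ids
  dimnames(alpha) <- list(species_ids, species_ids)
  structure(
    list(species_ids = species_ids, growth_rates = growth_rates, alpha = alpha),
    class = "community_params"
  )
}

#' @export
print.community_params <- function(x, ...) {
  cat("Lotka-Volterra community:", length(x$species_ids), "species\n")
  cat("growth rates (1/h):\n")
  print(round(x$growth_rates, 4))
  cat("competition matrix alpha[i, j] (j inhibits i):\n")
  print(round(x$alpha, 4))
  invisible(x)
}

#' Restrict a community to a subset of its species
#'
#' @param params A [community_params()] object.
#' @param species Character vector of species ids (or integer indices) to keep.
#' @return A `community_params` object over the requested subset.
#' @export
subset_community <- function(params, species) {
  stopifnot(inherits(params, "community_params"))
  if (is.numeric(species)) species <- params$species_ids[species]
  if (!all(species %in% params$species_ids))
    stop("unknown species: ",
         paste(setdiff(species, params$species_ids), collapse = ", "),
         call. = FALSE)
  community_params(species,
                   params$growth_rates[species],
                   params$alpha[species, species, drop = FALSE])
}

#' Culture protocol for running the competition model
#'
#' Describes how mortality is applied when simulating the model. In
#' `"serial-dilution"` mode the community grows without death for
#' `cycle_hours` and is then diluted by `dilution_factor`, emulating daily
#' batch transfers; in `"continuous-death"` mode a constant per-capita death
#' rate `delta` acts throughout. The two are linked by
#' `delta = log(dilution_factor) / cycle_hours` (equal per-cycle survival).
#'
#' @param mode `"serial-dilution"` or `"continuous-death"`.
#' @param dilution_factor Fold dilution applied at each transfer (>= 1);
#'   serial-dilution mode only.
#' @param delta Continuous mortality rate (per hour, >= 0); continuous mode
#'   only.
#' @param cycle_hours Hours of growth per cycle (default 24).
#' @param n_cycles Number of growth-dilution cycles to run (serial mode), or
#'   the cap on 24-h blocks integrated (continuous mode).
#' @param extinction_threshold Normalized density below which a species is
#'   declared extinct and set to zero. Pure Lotka-Volterra exclusion is only
#'   asymptotic; real populations are finite, so a small positive cutoff makes
#'   exclusion realizable in finitely many cycles. Default `1e-10`.
#' @param convergence_tol Maximum L-infinity change in composition across the
#'   trailing `convergence_window` recorded states for the trajectory to be
#'   flagged converged. Default `1e-4`.
#' @param convergence_window Number of trailing states over which convergence
#'   is assessed. Default 3.
#' @param stop_on_convergence If `TRUE`, stop integrating once the convergence
#'   flag is reached rather than always running `n_cycles` (useful for
#'   equilibrium searches; keep `FALSE` when emulating a fixed-length
#'   experiment).
#'
#' @return An object of class `lv_protocol`.
#' @export
lv_protocol <- function(mode = c("serial-dilution", "continuous-death"),
                        dilution_factor = NULL, delta = NULL,
                        cycle_hours = 24, n_cycles = 7,
                        extinction_threshold = 1e-10,
                        convergence_tol = 1e-4, convergence_window = 3,
                        stop_on_convergence = FALSE) {
  mode <- match.arg(mode)
  if (cycle_hours <= 0) stop("cycle_hours must be > 0", call. = FALSE)
  if (n_cycles < 1) stop("n_cycles must be >= 1", call. = FALSE)
  if (extinction_threshold <= 0 || extinction_threshold >= 1e-2)
    stop("extinction_threshold must be positive and much smaller than 1",
         call. = FALSE)
  if (mode == "serial-dilution") {
    if (is.null(dilution_factor))
      stop("serial-dilution mode requires dilution_factor", call. = FALSE)
    if (dilution_factor < 1)
      stop("dilution_factor must be >= 1", call. = FALSE)
    if (!is.null(delta) && delta != 0)
      stop("in serial-dilution mode mortality enters only through the dilution step; delta must be absent or 0",
           call. = FALSE)
    delta <- 0
  } else {
    if (is.null(delta)) stop("continuous-death mode requires delta", call. = FALSE)
    if (any(delta < 0)) stop("delta must be >= 0", call. = FALSE)
    if (!is.null(dilution_factor))
      stop("dilution_factor is not used in continuous-death mode", call. = FALSE)
  }
  structure(
    list(mode = mode, dilution_factor = dilution_factor, delta = delta,
         cycle_hours = cycle_hours, n_cycles = n_cycles,
         extinction_threshold = extinction_threshold,
         convergence_tol = convergence_tol,
         convergence_window = convergence_window,
         stop_on_convergence = stop_on_convergence),
    class = "lv_protocol"
  )
}

#' Write community parameters to a config file
#'
#' Serializes a [community_params()] object (optionally with extra scalar or
#' vector metadata such as carrying capacities and lag times) to YAML or JSON.
#' The competition matrix is stored row-major as a list of rows.
#'
#' @param params A `community_params` object.
#' @param path Output file; format chosen by extension (`.yml`/`.yaml` or
#'   `.json`).
#' @param extra Named list of additional fields to store alongside the
#'   parameters (e.g. `carrying_capacity`, `lag_hours`, `seed`).
#' @return `path`, invisibly.
#' @seealso [read_community_config()]
#' @export
write_community_config <- function(params, path, extra = list()) {
  stopifnot(inherits(params, "community_params"))
  obj <- c(list(
    species = as.list(params$species_ids),
    growth_rates = as.list(unname(params$growth_rates)),
    alpha = lapply(seq_len(nrow(params$alpha)),
                   function(i) as.list(unname(params$alpha[i, ])))
  ), extra)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(obj, path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  } else {
    stop("unsupported config extension (use .yaml, .yml or .json): ", path,
         call. = FALSE)
  }
  invisible(path)
}

#' Read community parameters from a config file
#'
#' Parses a YAML or JSON community config written by
#' [write_community_config()] (or by hand in the same schema) and validates it
#' strictly: the species list, growth-rate vector and row-major alpha matrix
#' must all be present, consistent in dimension, and satisfy the model's
#' invariants.
#'
#' @param path Config file path.
#' @return A list with `params` (a `community_params` object) and `extra`
#'   (any additional fields found in the file).
#' @export
read_community_config <- function(path) {
  if (!file.exists(path))
    stop("config file not found: ", path, call. = FALSE)
  obj <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    stop("unsupported config extension (use .yaml, .yml or .json): ", path,
         call. = FALSE)
  }
  required <- c("species", "growth_rates", "alpha")
  missing <- setdiff(required, names(obj))
  if (length(missing))
    stop("community config is missing required fields: ",
         paste(missing, collapse = ", "), call. = FALSE)
  species <- vapply(obj$species, as.character, character(1))
  r <- vapply(obj$growth_rates, as.numeric, numeric(1))
  n <- length(species)
  if (length(obj$alpha) != n)
    stop("alpha must have one row per species", call. = FALSE)
  alpha <- do.call(rbind, lapply(obj$alpha, function(row) {
    if (length(row) != n) stop("alpha rows must have n entries", call. = FALSE)
    vapply(row, as.numeric, numeric(1))
  }))
  params <- community_params(species, r, alpha)
  extra <- obj[setdiff(names(obj), required)]
  list(params = params, extra = extra)
}
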