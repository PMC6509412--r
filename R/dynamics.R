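#' Right-hand side of the Lotka-Volterra model with mortality
#'
#' Evaluates dN_i/dt = r_i N_i (1 - sum_j alpha_ij N_j) - delta_i N_i, where
#' the unit diagonal of alpha carries the self-inhibition term. Extinction is
#' absorbing: a species at zero density has zero rate.
#'
#' @param params A [community_params()] object.
#' @param N Nonnegative density vector (normalized to carrying capacity), one
#'   entry per species.
#' @param delta Mortality rate (per hour), a scalar applied to every species
#'   or a per-species vector. Default 0.
#' @return Named numeric vector of per-species density rates.
#' @examples
#' p <- community_params("a", 1, matrix(1))
#' lv_derivatives(p, 0.75, delta = 0.25)  # fixed point: rate 0
#' @export
lv_derivatives <- function(params, N, delta = 0) {
  stopifnot(inherits(params, "community_params"))
  n <- length(params$species_ids)
  if (length(N) != n)
    stop("density vector length ", length(N), " does not match the ", n,
         "-species community", call. = FALSE)
  if (any(N < 0)) stop("densities must be nonnegative", call. = FALSE)
  if (any(delta < 0)) stop("delta must be nonnegative", call. = FALSE)
  if (!length(delta) %in% c(1L, n))
    stop("delta must be scalar or one rate per species", call. = FALSE)
  dN <- params$growth_rates * N * (1 - drop(params$alpha %*% N)) - delta * N
  names(dN) <- params$species_ids
  dN
}

#' Integrate one growth interval of the model
#'
#' Runs the continuous model for a fixed time span with a stiff-capable
#' adaptive integrator ([deSolve::lsoda()]). Tight tolerances are the default
#' because competitive exclusion drives densities to near zero, where sloppy
#' integration oscillates into negative values.
#'
#' @inheritParams lv_derivatives
#' @param N0 Nonnegative starting density vector.
#' @param hours Positive time span to integrate.
#' @param rtol,atol Relative and absolute integrator tolerances.
#' @return Named nonnegative density vector at the end of the interval.
#' @export
integrate_cycle <- function(params, N0, hours, delta = 0,
                            rtol = 1e-8, atol = 1e-12) {
  stopifnot(inherits(params, "community_params"))
  n <- length(params$species_ids)
  if (length(N0) != n)
    stop("N0 length does not match the community", call. = FALSE)
  if (any(N0 < 0)) stop("N0 must be nonnegative", call. = FALSE)
  if (hours <= 0) stop("hours must be > 0", call. = FALSE)
  if (all(N0 == 0)) return(stats::setNames(numeric(n), params$species_ids))

  r <- unname(params$growth_rates)
  A <- unname(params$alpha)
  dfun <- function(t, y, parms) {
    y <- pmax(y, 0)  # guard against tiny negative excursions mid-step
    list(r * y * (1 - drop(A %*% y)) - delta * y)
  }
  out <- deSolve::lsoda(y = unname(N0), times = c(0, hours), func = dfun,
                        parms = NULL, rtol = rtol, atol = atol)
  diagn <- attr(out, "istate")
  if (is.null(diagn) || diagn[1] < 0 || nrow(out) < 2)
    stop("LV integration failed (lsoda istate = ",
         if (is.null(diagn)) "missing" else diagn[1],
         ") for N0 = [", paste(signif(N0, 4), collapse = ", "),
         "], hours = ", hours, ", delta = ",
         paste(signif(delta, 4), collapse = ", "), call. = FALSE)
  Nend <- out[nrow(out), -1]
  if (any(!is.finite(Nend)))
    stop("LV integration produced non-finite densities; N0 = [",
         paste(signif(N0, 4), collapse = ", "), "], hours = ", hours,
         call. = FALSE)
  Nend <- pmax(Nend, 0)
  Nend[N0 == 0] <- 0  # extinction is absorbing
  stats::setNames(as.numeric(Nend), params$species_ids)
}

new_trajectory <- function(times, densities, params, protocol, converged,
                           cycles_run, time_unit) {
  dimnames(densities) <- list(NULL, params$species_ids)
  tot <- rowSums(densities)
  fractions <- densities / ifelse(tot > 0, tot, NA_real_)
  structure(
    list(times = times, densities = densities, fractions = fractions,
         species_ids = params$species_ids, protocol = protocol,
         converged = converged, cycles_run = cycles_run,
         time_unit = time_unit),
    class = "lv_trajectory"
  )
}

#' Survivor set at the end of a trajectory
#'
#' Species still present when the run ended: positive density and a final
#' fraction at or above `fraction_threshold`. The fraction cutoff matters for
#' runs stopped at composition convergence, where an excluded species may
#' still carry a vanishing residual density on its way to the extinction
#' threshold.
#'
#' @param traj An `lv_trajectory`.
#' @param fraction_threshold Minimum final fraction to count as surviving
#'   (default 1e-3).
#' @return Sorted character vector of surviving species ids.
#' @export
survivor_set <- function(traj, fraction_threshold = 1e-3) {
  stopifnot(inherits(traj, "lv_trajectory"))
  final <- traj$densities[nrow(traj$densities), ]
  if (sum(final) == 0) return(character(0))
  frac <- final / sum(final)
  sort(traj$species_ids[final > 0 & frac >= fraction_threshold])
}

#' @export
print.lv_trajectory <- function(x, ...) {
  cat("LV trajectory:", length(x$species_ids), "species,",
      x$cycles_run, if (x$time_unit == "cycles") "cycles" else "blocks",
      "recorded",
      if (isTRUE(x$converged)) "(converged)" else "(not converged)", "\n")
  cat("final state:\n")
  print(signif(x$densities[nrow(x$densities), ], 5))
  invisible(x)
}

#' Long-format data frame view of a trajectory
#'
#' @param x An `lv_trajectory`.
#' @param row.names,optional Ignored (S3 conformance).
#' @param condition_id Optional label stored in a leading column.
#' @param ... Ignored.
#' @return Data frame with columns `condition_id` (if given), `cycle` (or
#'   `time_h` for continuous runs), `species`, `density`, `fraction`.
#' @export
as.data.frame.lv_trajectory <- function(x, row.names = NULL, optional = FALSE,
                                        condition_id = NULL, ...) {
  nt <- length(x$times)
  ns <- length(x$species_ids)
  df <- data.frame(
    time = rep(x$times, each = ns),
    species = rep(x$species_ids, nt),
    density = as.vector(t(x$densities)),
    fraction = as.vector(t(x$fractions)),
    stringsAsFactors = FALSE
  )
  names(df)[1] <- if (x$time_unit == "cycles") "cycle" else "time_h"
  if (!is.null(condition_id)) df <- cbind(condition_id = condition_id, df)
  df
}

traj_converged <- function(states, window, tol) {
  # Composition (L-infinity) settled over the trailing `window` states, and
  # every surviving species' log-density settled too -- otherwise a rare
  # species growing or decaying geometrically from a tiny density would look
  # "converged" long before its fate is decided.
  if (nrow(states) < window) return(FALSE)
  tail_states <- states[(nrow(states) - window + 1):nrow(states), , drop = FALSE]
  tot <- rowSums(tail_states)
  if (all(tot == 0)) return(TRUE)  # everything extinct: trivially settled
  frac <- tail_states / ifelse(tot > 0, tot, 1)
  if (!all(apply(frac, 2, function(col) diff(range(col))) < tol)) return(FALSE)
  for (j in seq_len(ncol(tail_states))) {
    col <- tail_states[, j]
    if (all(col == 0)) next       # extinct and absorbed
    if (any(col == 0)) return(FALSE)  # extinction still in progress
    if (diff(range(log(col))) >= 1e-3) return(FALSE)
  }
  TRUE
}

#' Simulate growth-dilution cycles
#'
#' Emulates the daily batch-transfer protocol: in each cycle the community
#' grows for `cycle_hours` under the mortality-free model, is recorded (the
#' pre-dilution state is what an experimenter plates), and is then diluted by
#' `dilution_factor`, with densities falling below the extinction threshold
#' set to zero.
#'
#' @inheritParams integrate_cycle
#' @param protocol An [lv_protocol()] in `"serial-dilution"` mode.
#' @return An `lv_trajectory` whose `times` are cycle indices 1..k and whose
#'   states are the end-of-growth (pre-dilution) densities.
#' @export
run_serial_dilution <- function(params, N0, protocol,
                                rtol = 1e-8, atol = 1e-12) {
  stopifnot(inherits(params, "community_params"),
            inherits(protocol, "lv_protocol"))
  if (protocol$mode != "serial-dilution")
    stop("protocol must be in serial-dilution mode", call. = FALSE)
  DF <- protocol$dilution_factor
  n <- length(params$species_ids)
  N <- stats::setNames(as.numeric(N0), params$species_ids)
  if (any(N < 0)) stop("N0 must be nonnegative", call. = FALSE)
  states <- matrix(NA_real_, nrow = protocol$n_cycles, ncol = n)
  converged <- FALSE
  k <- 0L
  for (cycle in seq_len(protocol$n_cycles)) {
    N <- integrate_cycle(params, N, protocol$cycle_hours, delta = 0,
                         rtol = rtol, atol = atol)
    k <- cycle
    states[cycle, ] <- N
    converged <- traj_converged(states[seq_len(k), , drop = FALSE],
                                protocol$convergence_window,
                                protocol$convergence_tol)
    if (protocol$stop_on_convergence && converged) break
    N <- N / DF
    N[N < protocol$extinction_threshold] <- 0
    if (all(N == 0) && cycle < protocol$n_cycles) {
      # record the all-extinct state once and stop: nothing can recolonize
      states[cycle + 1L, ] <- 0
      k <- cycle + 1L
      converged <- TRUE
      break
    }
  }
  new_trajectory(times = seq_len(k),
                 densities = states[seq_len(k), , drop = FALSE],
                 params = params, protocol = protocol,
                 converged = converged, cycles_run = k, time_unit = "cycles")
}

#' Simulate the continuous-death model to (near) equilibrium
#'
#' Integrates the model with a constant mortality rate in blocks of
#' `cycle_hours`, recording the state after each block, until the composition
#' settles (see [lv_protocol()]) or `n_cycles` blocks have run. The
#' extinction threshold is applied after each block.
#'
#' @inheritParams run_serial_dilution
#' @param protocol An [lv_protocol()] in `"continuous-death"` mode.
#' @return An `lv_trajectory` with `times` in hours at block boundaries.
#' @export
run_continuous <- function(params, N0, protocol, rtol = 1e-8, atol = 1e-12) {
  stopifnot(inherits(params, "community_params"),
            inherits(protocol, "lv_protocol"))
  if (protocol$mode != "continuous-death")
    stop("protocol must be in continuous-death mode", call. = FALSE)
  n <- length(params$species_ids)
  N <- stats::setNames(as.numeric(N0), params$species_ids)
  if (any(N < 0)) stop("N0 must be nonnegative", call. = FALSE)
  states <- matrix(NA_real_, nrow = protocol$n_cycles, ncol = n)
  converged <- FALSE
  k <- 0L
  for (block in seq_len(protocol$n_cycles)) {
    N <- integrate_cycle(params, N, protocol$cycle_hours,
                         delta = protocol$delta, rtol = rtol, atol = atol)
    N[N < protocol$extinction_threshold] <- 0
    k <- block
    states[block, ] <- N
    converged <- traj_converged(states[seq_len(k), , drop = FALSE],
                                protocol$convergence_window,
                                protocol$convergence_tol)
    if ((protocol$stop_on_convergence && converged) || all(N == 0)) break
  }
  new_trajectory(times = seq_len(k) * protocol$cycle_hours,
                 densities = states[seq_len(k), , drop = FALSE],
                 params = params, protocol = protocol,
                 converged = converged, cycles_run = k, time_unit = "hours")
}

#' Monoculture equilibrium under continuous mortality
#'
#' A single species with growth rate `r` under death rate `delta` settles at
#' normalized density 1 - delta/r, or goes extinct when death outpaces growth.
#'
#' @param r Growth rate (per hour, > 0).
#' @param delta Mortality rate (per hour, >= 0).
#' @return `max(0, 1 - delta/r)`, vectorized over both arguments.
#' @export
monoculture_equilibrium <- function(r, delta) {
  if (any(r <= 0)) stop("r must be > 0", call. = FALSE)
  if (any(delta < 0)) stop("delta must be >= 0", call. = FALSE)
  pmax(0, 1 - delta / r)
}

lv_jacobian <- function(params, N, delta) {
  r <- unname(params$growth_rates)
  A <- unname(params$alpha)
  n <- length(r)
  J <- -r * N * A
  diag(J) <- diag(J) + r * (1 - drop(A %*% N)) - delta
  J
}

#' Fixed points and stability of a two-species community
#'
#' Enumerates the candidate equilibria of the two-species model with uniform
#' mortality: the origin, the two monoculture boundary points, and -- when the
#' re-parameterized coefficients admit one -- the interior point
#' `N_i = Ntilde_i * (1 - delta/r_i)` with
#' `Ntilde_i = (1 - atilde_ij) / (1 - atilde_ij * atilde_ji)`. Each point is
#' flagged stable/unstable by linearization (eigenvalues of the Jacobian).
#'
#' @param params A two-species [community_params()].
#' @param delta Uniform mortality rate (per hour, >= 0).
#' @param tie_tol Tolerance within which `atilde_12 * atilde_21 == 1` is
#'   treated as the degenerate line-of-fixed-points case.
#' @return A list with class `lv_fixed_points`: elements `points` (data frame
#'   with columns `N_1`, `N_2`, `type`, `stable`) and `degenerate` (logical).
#'   The degenerate coefficient product raises a classed condition
#'   (`lvmort_degenerate`) and suppresses the interior point.
#' @export
pair_fixed_points <- function(params, delta = 0, tie_tol = 1e-9) {
  stopifnot(inherits(params, "community_params"))
  if (length(params$species_ids) != 2)
    stop("pair_fixed_points requires exactly two species", call. = FALSE)
  r <- unname(params$growth_rates)
  if (any(delta < 0)) stop("delta must be >= 0", call. = FALSE)

  pts <- list(c(0, 0))
  types <- "origin"
  surv1 <- monoculture_equilibrium(r[1], delta)
  surv2 <- monoculture_equilibrium(r[2], delta)
  if (surv1 > 0) { pts <- c(pts, list(c(surv1, 0))); types <- c(types, "boundary_1") }
  if (surv2 > 0) { pts <- c(pts, list(c(0, surv2))); types <- c(types, "boundary_2") }

  degenerate <- FALSE
  if (delta < min(r)) {
    eff <- effective_params(params, delta)
    a12 <- eff$alpha_eff[1, 2]; a21 <- eff$alpha_eff[2, 1]
    if (abs(a12 * a21 - 1) <= tie_tol) {
      degenerate <- TRUE
      warning(structure(
        class = c("lvmort_degenerate", "warning", "condition"),
        list(message = paste0(
               "degenerate pair: atilde_12 * atilde_21 = 1 within tolerance; ",
               "a line of fixed points exists and no isolated interior point is reported"),
             call = NULL)))
    } else {
      Nt1 <- (1 - a12) / (1 - a12 * a21)
      Nt2 <- (1 - a21) / (1 - a12 * a21)
      if (Nt1 > 0 && Nt2 > 0) {
        pts <- c(pts, list(c(Nt1 * eff$rescale[1], Nt2 * eff$rescale[2])))
        types <- c(types, "interior")
      }
    }
  }

  stable <- vapply(pts, function(N) {
    ev <- eigen(lv_jacobian(params, N, delta), only.values = TRUE)$values
    all(Re(ev) < 0)
  }, logical(1))

  points <- data.frame(
    N_1 = vapply(pts, `[`, numeric(1), 1),
    N_2 = vapply(pts, `[`, numeric(1), 2),
    type = types, stable = stable, stringsAsFactors = FALSE
  )
  structure(list(points = points, degenerate = degenerate, delta = delta,
                 species_ids = params$species_ids),
            class = "lv_fixed_points")
}

#' @export
print.lv_fixed_points <- function(x, ...) {
  cat("fixed points of pair (", paste(x$species_ids, collapse = ", "),
      ") at delta =", signif(x$delta, 5),
      if (x$degenerate) "[degenerate]" else "", "\n")
  print(transform(x$points, N_1 = signif(N_1, 6), N_2 = signif(N_2, 6)))
  invisible(x)
}
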