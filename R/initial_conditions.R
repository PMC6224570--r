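#' Thermal sampling settings
#'
#' Ground-state phase points are harvested from a single long trajectory on
#' the electronic ground state, thermostatted by stochastic velocity
#' rescaling (canonical sampling), discarding an equilibration window and
#' keeping decorrelated snapshots.
#'
#' @param temperature_K bath temperature, kelvin.
#' @param total_time_ps total trajectory length, ps.
#' @param equilibration_ps discarded initial window, ps.
#' @param stride_fs snapshot spacing, fs (>= 10 fs recommended for
#'   decorrelation).
#' @param tau_fs thermostat time constant, fs. The default Langevin friction
#'   time of 5 fs makes kinetic energy decorrelate well within the snapshot
#'   stride; snapshots are exact canonical draws for any friction.
#' @param dt_fs integration timestep, fs.
#' @param seed RNG seed (thermostat noise stream).
#' @param thermostat `"langevin"` (per-dof friction + noise; ergodic even
#'   for quasi-harmonic systems, the default) or `"svr"` (global stochastic
#'   velocity rescaling; kept for comparison - note that with only two
#'   nearly separable modes the global rescaling exchanges energy between
#'   modes very slowly).
#' @return an object of class `thermal_sampling_settings`.
#' @export
thermal_sampling_settings <- function(temperature_K = 300, total_time_ps = 10,
                                      equilibration_ps = 1, stride_fs = 10,
                                      tau_fs = 5, dt_fs = 0.5, seed = 1,
                                      thermostat = c("langevin", "svr")) {
  thermostat <- match.arg(thermostat)
  if (temperature_K <= 0) stop("temperature must be positive")
  if (equilibration_ps >= total_time_ps)
    stop("equilibration must be shorter than the total time")
  if (stride_fs <= 0) stop("stride must be positive")
  structure(list(temperature_K = temperature_K,
                 total_time_ps = total_time_ps,
                 equilibration_ps = equilibration_ps,
                 stride_fs = stride_fs, tau_fs = tau_fs, dt_fs = dt_fs,
                 seed = as.integer(seed), thermostat = thermostat),
            class = "thermal_sampling_settings")
}

#' Sample ground-state phase points at thermal equilibrium
#'
#' Runs ground-electronic-state dynamics (the cavity plays no role on a
#' single surface) with the stochastic velocity-rescaling thermostat and
#' returns snapshots after equilibration at the requested stride.
#'
#' @param model a `polhop_model`.
#' @param settings a [thermal_sampling_settings()].
#' @param n optional number of phase points required; an error is raised if
#'   fewer snapshots are available.
#' @return data frame of phase points (angles in degrees, momenta in au)
#'   with attributes `mean_kinetic` (hartree) and `kinetic` (per-snapshot
#'   kinetic energies).
#' @examples
#' \donttest{
#' s <- thermal_sampling_settings(total_time_ps = 0.2, equilibration_ps = 0.05)
#' pts <- thermal_sample(azo2d_model(), s)
#' }
#' @export
thermal_sample <- function(model, settings, n = NULL) {
  dt <- fs_to_au(settings$dt_fs)
  nsteps <- as.integer(round(settings$total_time_ps * 1000 / settings$dt_fs))
  start <- as.integer(round(settings$equilibration_ps * 1000 /
                              settings$dt_fs)) + 1L
  stride <- max(1L, as.integer(round(settings$stride_fs / settings$dt_fs)))
  kT <- KB_HA * settings$temperature_K
  res <- .thermal_run_cpp(model$id, model$params, model$inertia,
                          model$q_ref, rep(0, model$ncoord), dt, nsteps, kT,
                          fs_to_au(settings$tau_fs),
                          as.double(settings$seed), start, stride,
                          thermostat = if (settings$thermostat == "svr") 1L
                                       else 0L)
  if (!is.null(n) && nrow(res$Q) < n)
    stop("only ", nrow(res$Q), " snapshots available; ", n, " requested ",
         "(lengthen the run or shorten the stride)")
  Q <- res$Q
  Q[, model$angular] <- rad_to_deg(Q[, model$angular])
  df <- data.frame(Q, res$P)
  names(df) <- if (model$name == "azo2d")
    c("theta_deg", "alpha_deg", "p_theta", "p_alpha")
  else c(paste0("q", seq_len(model$ncoord)),
         paste0("p", seq_len(model$ncoord)))
  if (!is.null(n)) df <- df[seq_len(n), , drop = FALSE]
  attr(df, "mean_kinetic") <- res$mean_kinetic
  attr(df, "kinetic") <- res$kinetic
  df
}

#' Vertically excite a phase point to the upper polariton
#'
#' Franck-Condon promotion: nuclear coordinates and momenta are unchanged;
#' the active state becomes the upper polariton |+> (the higher-energy
#' member of the rotating {|S1,0>, |S0,1>} pair, identified by dominant
#' block character with a |S1,0>-dominance tie-break at degeneracy), and the
#' amplitude vector is the unit vector on that state. For the photon-free
#' two-state reference the excitation targets the bare excited state.
#'
#' @param point one row of a [thermal_sample()] data frame, or a list/vector
#'   with coordinates (degrees for angular) and momenta.
#' @param model,cavity model and cavity.
#' @return an initial trajectory state (see [init_trajectory_state()]).
#' @export
vertical_excite <- function(point, model, cavity) {
  v <- as.numeric(unlist(point))
  nc <- model$ncoord
  q <- v[seq_len(nc)]
  q[model$angular] <- deg_to_rad(q[model$angular])
  p <- v[nc + seq_len(nc)]
  st <- init_trajectory_state(model, cavity, q, p, active = 2L)
  n <- cavity$n_states
  act <- upper_polariton_index(st$sol$C, st$sol$energies, n)
  A <- rep(0 + 0i, n)
  A[act] <- 1 + 0i
  st$active <- as.integer(act)
  st$A <- A
  st
}

#' Thermal initial conditions for an excited-state swarm
#'
#' Convenience wrapper: sample `n` ground-state phase points and vertically
#' excite each to the upper polariton.
#'
#' @param model,cavity model and cavity.
#' @param settings a [thermal_sampling_settings()].
#' @param n ensemble size (default 300 trajectories).
#' @return list of initial trajectory states.
#' @export
sample_initial_conditions <- function(model, cavity, settings, n = 300) {
  pts <- thermal_sample(model, settings, n = n)
  lapply(seq_len(n), function(k) vertical_excite(pts[k, ], model, cavity))
}
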