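#' Simulation settings for surface-hopping dynamics
#'
#' @param dt_fs nuclear timestep, fs (one local-diabatization step per
#'   nuclear step).
#' @param t_total_fs total propagation time, fs (`n_steps` overrides).
#' @param n_steps number of steps (derived from `t_total_fs` if missing).
#' @param decoherence apply the energy-based decoherence damping?
#' @param decoherence_alpha the alpha parameter of the decoherence time
#'   `tau_l = (1/|E_l - E_active|) (1 + alpha/E_kin)`, hartree.
#' @param drift_tol_ev total-energy drift beyond which a trajectory is
#'   flagged failed, eV.
#' @param seed master RNG seed; per-trajectory streams are derived from it
#'   by a documented counter scheme (see [child_seed()]).
#' @return an object of class `simulation_settings`.
#' @export
simulation_settings <- function(dt_fs = 0.1, t_total_fs = 300,
                                n_steps = NULL, decoherence = TRUE,
                                decoherence_alpha = 0.1,
                                drift_tol_ev = 0.5, seed = 1) {
  if (dt_fs <= 0) stop("dt must be positive")
  if (decoherence_alpha < 0) stop("decoherence alpha must be >= 0")
  if (is.null(n_steps)) n_steps <- as.integer(round(t_total_fs / dt_fs))
  structure(list(dt_fs = dt_fs, dt_au = fs_to_au(dt_fs),
                 n_steps = as.integer(n_steps), decoherence = decoherence,
                 decoherence_alpha = decoherence_alpha,
                 drift_tol = ev_to_hartree(drift_tol_ev),
                 seed = as.integer(seed)),
            class = "simulation_settings")
}

#' Per-trajectory child seeds
#'
#' Documented counter scheme: stream 0 carries the surface-hopping draws of
#' trajectory `traj`, stream 1 the thermostat noise, stream 2+ are reserved
#' (cavity-loss resampling uses R-side seeds, see [ensemble_losses()]).
#' Deterministic, platform-independent (splitmix64 scramble).
#'
#' @param master master seed (non-negative integer).
#' @param traj trajectory index.
#' @param stream stream id.
#' @return a 53-bit integer-valued double identifying the stream.
#' @export
child_seed <- function(master, traj, stream = 0) {
  .child_seed_cpp(as.double(master), as.double(traj), as.double(stream))
}

# --- single-step operations (reference R implementations) -------------------

# internal: full solve at a geometry (R path; works for R-function models)
solve_at_geometry <- function(model, cavity, q, previous = NULL,
                              elec_prev = NULL) {
  elec <- evaluate(model, q)
  H <- build_hamiltonian(elec, cavity)
  ov <- if (is.null(previous) || is.null(elec_prev)) NULL else {
    d <- elec$mixing_angle - elec_prev$mixing_angle
    matrix(c(cos(d), sin(d), -sin(d), cos(d)), 2, 2)
  }
  sol <- solve_polaritons(H, previous = previous, elec_ov = ov)
  list(elec = elec, sol = sol, elec_ov = ov)
}

#' One velocity-Verlet step on the active polaritonic surface
#'
#' Nuclear coordinates follow Newton's equations with the force from the
#' gradient of the active polaritonic energy; the polaritonic solution at
#' the new geometry is re-solved and sign-fixed against the previous one.
#'
#' @param state list with `q` (coordinates), `p` (momenta), `inertia`,
#'   `active`, `elec`, `sol` (as produced by [init_trajectory_state()]).
#' @param model a `polhop_model`.
#' @param cavity a `cavity_mode`.
#' @param dt timestep, atomic units.
#' @return the updated state (list), including the electronic overlap
#'   `elec_ov` between the two geometries.
#' @export
vv_step <- function(state, model, cavity, dt) {
  grad <- polaritonic_gradient(state$elec, cavity, state$sol, state$active)
  p_half <- state$p - 0.5 * dt * grad
  q_new <- state$q + dt * p_half / state$inertia
  ns <- solve_at_geometry(model, cavity, q_new, previous = state$sol,
                          elec_prev = state$elec)
  grad_new <- polaritonic_gradient(ns$elec, cavity, ns$sol, state$active)
  p_new <- p_half - 0.5 * dt * grad_new
  modifyList(state, list(q = q_new, p = p_new, elec = ns$elec,
                         sol = ns$sol, elec_ov = ns$elec_ov,
                         sol_prev = state$sol, t = state$t + dt))
}

#' Initialize a trajectory state
#'
#' @param model,cavity model and cavity.
#' @param Q a `polhop_geometry` (or coordinate vector, internal units).
#' @param P momentum vector, atomic units.
#' @param active polaritonic state index (sorted order, 1-based).
#' @param A complex amplitude vector (defaults to a unit vector on
#'   `active`).
#' @export
init_trajectory_state <- function(model, cavity, Q, P, active, A = NULL) {
  q <- if (inherits(Q, "polhop_geometry")) Q$coords else as.numeric(Q)
  inertia <- if (inherits(Q, "polhop_geometry")) Q$inertia else model$inertia
  s <- solve_at_geometry(model, cavity, q)
  n <- cavity$n_states
  if (is.null(A)) {
    A <- rep(0 + 0i, n)
    A[active] <- 1 + 0i
  }
  list(q = q, p = as.numeric(P), inertia = inertia, active = as.integer(active),
       A = A, elec = s$elec, sol = s$sol, t = 0)
}

#' Local-diabatization propagation of the electronic amplitudes
#'
#' Builds `T`, the Loewdin orthogonalization of the polaritonic overlap
#' between the solutions at `t` and `t + dt`, and propagates the
#' time-dependent Schroedinger equation in the locally diabatic
#' representation with the averaged Hamiltonian
#' `Z = (E(t) + T E(t+dt) T^T)/2`:
#' `A' = U A` with the unitary `U = T^T exp(-i Z dt)`.
#'
#' @param A complex amplitudes at `t` (adiabatic polaritonic basis).
#' @param sol_t,sol_next sign-fixed `polariton_solution`s at the step ends.
#' @param elec_ov 2x2 electronic overlap between the two geometries.
#' @param dt timestep, atomic units.
#' @return list with the new amplitudes `A` and the propagator `U`.
#' @export
ld_propagate <- function(A, sol_t, sol_next, elec_ov, dt) {
  S <- polaritonic_overlap(sol_t, sol_next, elec_ov)
  T_ <- .loewdin_cpp(S)
  U <- .ld_propagator_cpp(sol_t$energies, sol_next$energies, T_, dt)
  list(A = as.vector(U %*% A), U = U, T = T_)
}

#' Fewest-switches hop decision
#'
#' Hop probability out of the active state k is
#' `max(0, (|A_k|^2 - |A'_k|^2) / |A_k|^2)`, partitioned among target states
#' proportionally to their positive population gain over the step. On an
#' accepted hop the momenta are rescaled isotropically to conserve total
#' energy; insufficient kinetic energy leaves state and momenta unchanged
#' (frustrated hop, no velocity reversal).
#'
#' @param A,A_new amplitudes before/after [ld_propagate()].
#' @param active active state index before the step.
#' @param energies polaritonic energies at the new geometry, hartree.
#' @param p momenta; `inertia` per-coordinate inertias.
#' @param u uniform draw in `[0, 1)` deciding the hop.
#' @return list with `active`, `p`, `hopped`, `frustrated`, `target`,
#'   `p_hop`.
#' @export
fssh_step <- function(A, A_new, active, energies, p, inertia, u) {
  pk_old <- Mod(A[active])^2
  pk_new <- Mod(A_new[active])^2
  p_hop <- if (pk_old < 1e-12) 0 else max(0, (pk_old - pk_new) / pk_old)
  res <- list(active = active, p = p, hopped = FALSE, frustrated = FALSE,
              target = NA_integer_, p_hop = p_hop)
  if (u >= p_hop) return(res)
  w <- pmax(0, Mod(A_new)^2 - Mod(A)^2)
  w[active] <- 0
  if (sum(w) <= 0) return(res)
  r <- (u / p_hop) * sum(w)
  target <- which(cumsum(w) >= r & w > 0)[1]
  if (is.na(target)) target <- max(which(w > 0))
  res$target <- target
  ekin <- sum(0.5 * p^2 / inertia)
  dE <- energies[target] - energies[active]
  if (dE > ekin || ekin <= 0) {
    res$frustrated <- TRUE
    return(res)
  }
  res$p <- p * sqrt((ekin - dE) / ekin)
  res$active <- target
  res$hopped <- TRUE
  res
}

#' Energy-based decoherence damping
#'
#' Each non-active amplitude is damped by `exp(-dt/tau_l)` with
#' `tau_l = (1/|E_l - E_active|) (1 + alpha/E_kin)` (atomic units), after
#' which the active amplitude is rescaled to restore unit norm. No damping
#' is applied when the kinetic energy vanishes (the decoherence time
#' diverges).
#'
#' @param A complex amplitudes.
#' @param active active state index.
#' @param energies polaritonic energies, hartree.
#' @param E_kin nuclear kinetic energy, hartree (>= 0).
#' @param dt timestep, atomic units.
#' @param alpha decoherence parameter, hartree.
#' @return damped, renormalized amplitudes.
#' @export
apply_decoherence <- function(A, active, energies, E_kin, dt, alpha = 0.1) {
  if (E_kin < 0) stop("kinetic energy must be >= 0")
  if (E_kin == 0) return(A)
  n <- length(A)
  for (j in seq_len(n)) {
    if (j == active) next
    dE <- abs(energies[j] - energies[active])
    if (dE > 1e-12) {
      tau <- (1 + alpha / E_kin) / dE
      A[j] <- A[j] * exp(-dt / tau)
    }
  }
  sumoff <- sum(Mod(A[-active])^2)
  pa <- Mod(A[active])^2
  if (pa > 1e-30 && sumoff < 1)
    A[active] <- A[active] * sqrt((1 - sumoff) / pa)
  A
}

# --- full-trajectory drivers ------------------------------------------------

#' Run one surface-hopping trajectory
#'
#' Velocity-Verlet nuclear propagation on the active polaritonic surface,
#' local-diabatization integration of the electronic amplitudes, Tully
#' fewest-switches hops with isotropic momentum rescaling, and energy-based
#' decoherence. The compiled engine (`engine = "cpp"`) is the production
#' path; `engine = "r"` is a readable reference loop built from the
#' single-step operations (identical numerics up to its R RNG for hops) that
#' also accepts R-function models.
#'
#' Uncoupled surfaces with exactly vanishing coupling (g = 0, or planar
#' geometries where mu . lambda = 0) cross without interacting; the active
#' state is re-identified through such trivial crossings by its dominant
#' overlap (diabatic following), logged as a relabel rather than a hop.
#'
#' @param model a `polhop_model`.
#' @param cavity a `cavity_mode`.
#' @param init initial condition from [init_trajectory_state()] or
#'   [vertical_excite()].
#' @param settings a [simulation_settings()].
#' @param traj_index trajectory counter used for the child RNG stream.
#' @param engine `"cpp"` or `"r"`.
#' @return an object of class `polhop_trajectory`: time series of phase
#'   points, active state, energies, active-state composition
#'   |C_i^Gamma|^2 (including the photon-loss weight |C_{S0,1}^Gamma|^2),
#'   amplitude populations, and the hop log.
#' @export
run_trajectory <- function(model, cavity, init, settings, traj_index = 1,
                           engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  n <- cavity$n_states
  if (engine == "cpp") {
    if (!is.null(model$fun))
      stop("the compiled engine requires a shipped analytic model")
    raw <- .run_traj_cpp(model$id, model$params, init$inertia,
                         cavity$omega, cavity$g, cavity$lam, cavity$n_photon,
                         init$q, init$p, init$active, as.complex(init$A),
                         settings$dt_au, settings$n_steps,
                         settings$decoherence_alpha, settings$decoherence,
                         settings$drift_tol,
                         as.double(settings$seed), as.double(traj_index))
  } else {
    raw <- run_traj_r(model, cavity, init, settings, traj_index)
  }
  structure(c(raw, list(dt_au = settings$dt_au, n_states = n,
                        model_name = model$name, seed = settings$seed,
                        traj_index = traj_index, angular = model$angular,
                        inertia = init$inertia)),
            class = "polhop_trajectory")
}

# reference R engine; mirrors the compiled loop
run_traj_r <- function(model, cavity, init, settings, traj_index) {
  set.seed(child_seed(settings$seed, traj_index, 0) %% 2147483647)
  n <- cavity$n_states
  dt <- settings$dt_au
  nst <- settings$n_steps
  st <- init
  if (is.null(st$elec)) st <- init_trajectory_state(model, cavity, init$q,
                                                    init$p, init$active,
                                                    init$A)
  nc <- length(st$q)
  t_ <- numeric(nst + 1); qm <- matrix(NA_real_, nst + 1, nc)
  pm <- qm; Em <- matrix(NA_real_, nst + 1, n); ccol <- Em; apop <- Em
  act <- integer(nst + 1); hopf <- integer(nst + 1); cs01 <- numeric(nst + 1)
  hops <- list()
  rec <- function(i, s, hf) {
    t_[i] <<- s$t; qm[i, ] <<- s$q; pm[i, ] <<- s$p
    Em[i, ] <<- s$sol$energies; act[i] <<- s$active
    ccol[i, ] <<- s$sol$C[, s$active]^2
    apop[i, ] <<- Mod(s$A)^2
    cs01[i] <<- if (n == 4L) s$sol$C[3, s$active]^2 else 0
    hopf[i] <<- hf
  }
  rec(1, st, 0L)
  failed <- FALSE; fail_step <- -1L
  e_ref <- sum(0.5 * st$p^2 / st$inertia) + st$sol$energies[st$active]
  for (k in seq_len(nst)) {
    sol_prev <- st$sol
    A_prev <- st$A
    st2 <- vv_step(st, model, cavity, dt)
    # trivial-crossing relabel by dominant overlap
    S <- st2$sol$overlap
    jbest <- which.max(abs(S[st$active, ]))
    if (jbest != st$active && S[st$active, jbest]^2 > 0.5) {
      # redo the second half-kick on the relabeled surface
      grad_old <- polaritonic_gradient(st$elec, cavity, sol_prev, st$active)
      p_half <- st$p - 0.5 * dt * grad_old
      grad_new <- polaritonic_gradient(st2$elec, cavity, st2$sol, jbest)
      st2$p <- p_half - 0.5 * dt * grad_new
      st2$active <- jbest
    }
    ld <- ld_propagate(A_prev, sol_prev, st2$sol, st2$elec_ov, dt)
    u <- stats::runif(1)
    fs <- fssh_step(A_prev, ld$A, st2$active, st2$sol$energies, st2$p,
                    st2$inertia, u)
    hf <- 0L
    if (!is.na(fs$target)) {
      hops[[length(hops) + 1]] <- data.frame(step = k, from = st2$active,
                                             to = fs$target,
                                             accepted = as.integer(fs$hopped))
      hf <- if (fs$hopped) 1L else -1L
    }
    st2$active <- fs$active
    st2$p <- fs$p
    A <- ld$A
    if (settings$decoherence) {
      ekin <- sum(0.5 * st2$p^2 / st2$inertia)
      A <- apply_decoherence(A, st2$active, st2$sol$energies, ekin, dt,
                             settings$decoherence_alpha)
    }
    st2$A <- A
    st <- st2
    rec(k + 1, st, hf)
    e_now <- sum(0.5 * st$p^2 / st$inertia) + st$sol$energies[st$active]
    if (!is.finite(e_now) || abs(e_now - e_ref) > settings$drift_tol) {
      failed <- TRUE; fail_step <- k
      t_ <- t_[1:(k + 1)]; qm <- qm[1:(k + 1), , drop = FALSE]
      pm <- pm[1:(k + 1), , drop = FALSE]; Em <- Em[1:(k + 1), , drop = FALSE]
      ccol <- ccol[1:(k + 1), , drop = FALSE]
      apop <- apop[1:(k + 1), , drop = FALSE]
      act <- act[1:(k + 1)]; hopf <- hopf[1:(k + 1)]; cs01 <- cs01[1:(k + 1)]
      break
    }
  }
  hops_df <- if (length(hops)) do.call(rbind, hops) else
    data.frame(step = integer(), from = integer(), to = integer(),
               accepted = integer())
  list(t = t_, q = qm, p = pm, active = act, energies = Em,
       c_active_sq = ccol, amp_pop = apop, c_s01_sq = cs01, hop_flag = hopf,
       hops = hops_df, failed = failed, fail_step = fail_step)
}

#' Run an ensemble of independent trajectories
#'
#' The swarm of classical trajectories mimicking the nuclear wavepacket.
#' Each trajectory draws its hop stream from `child_seed(seed, k, 0)`, so
#' results are independent of execution order and reproducible from the
#' master seed alone.
#'
#' @param model,cavity model and cavity.
#' @param inits list of initial conditions (see [vertical_excite()]).
#' @param settings a [simulation_settings()].
#' @param engine `"cpp"` (default) or `"r"`.
#' @return an object of class `polhop_ensemble` with the trajectory list, a
#'   common time grid, and rerun metadata. Failed trajectories are kept,
#'   flagged, and reported with their seeds.
#' @export
run_ensemble <- function(model, cavity, inits, settings,
                         engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  if (length(inits) < 1) stop("at least one initial condition required")
  trajs <- vector("list", length(inits))
  for (k in seq_along(inits)) {
    trajs[[k]] <- run_trajectory(model, cavity, inits[[k]], settings,
                                 traj_index = k, engine = engine)
  }
  failed <- which(vapply(trajs, function(x) isTRUE(x$failed), logical(1)))
  if (length(failed))
    warning("failed trajectories (index/seed): ",
            paste(sprintf("%d/%d", failed, settings$seed), collapse = ", "))
  structure(list(trajectories = trajs,
                 t_au = trajs[[1]]$t,
                 n_states = cavity$n_states,
                 failed = failed,
                 meta = list(model = model$name, cavity = cavity,
                             settings = settings, n_traj = length(inits))),
            class = "polhop_ensemble")
}

#' @export
print.polhop_ensemble <- function(x, ...) {
  cat(sprintf("<polhop_ensemble> %d trajectories, %d states, %.1f fs\n",
              x$meta$n_traj, x$n_states, au_to_fs(max(x$t_au))))
  invisible(x)
}

#' Flatten a trajectory to a data frame
#'
#' Interface units: time fs, angles degrees, energies eV.
#' @param x a `polhop_trajectory`.
#' @param row.names,optional,... standard [as.data.frame()] arguments
#'   (ignored).
#' @export
as.data.frame.polhop_trajectory <- function(x, row.names = NULL,
                                            optional = FALSE, ...) {
  q <- x$q
  ang <- x$angular
  q[, ang] <- rad_to_deg(q[, ang])
  nc <- ncol(q)
  cn <- if (x$model_name == "azo2d") c("theta_deg", "alpha_deg")
        else paste0("q", seq_len(nc))
  pn <- if (x$model_name == "azo2d") c("p_theta", "p_alpha")
        else paste0("p", seq_len(nc))
  df <- data.frame(t_fs = au_to_fs(x$t), q, x$p,
                   active = x$active,
                   hartree_to_ev(x$energies),
                   c_s01_sq = x$c_s01_sq, hop_flag = x$hop_flag)
  names(df) <- c("t_fs", cn, pn, "active",
                 paste0("E", seq_len(x$n_states), "_ev"),
                 "c_s01_sq", "hop_flag")
  df
}
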