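#' Grid wavefunction for exact 1-D polaritonic propagation
#'
#' Four complex component functions on a uniform spatial grid, one per
#' *diabatic* electronic x photon product state (order (d1,0), (d2,0),
#' (d1,1), (d2,1)). The diabatic representation is required for
#' split-operator propagation: there the kinetic operator is diagonal and
#' all electronic and light-matter couplings live in the local potential
#' matrix (in the adiabatic basis the derivative couplings would be lost).
#' The grid must resolve the maximum momentum: `dx < pi / p_max`.
#'
#' @param x uniform spatial grid, bohr.
#' @param psi complex matrix, `length(x)` rows by 4 columns.
#' @param mass particle mass, au.
#' @param dt_au propagation timestep, atomic time units.
#' @param p_max largest momentum the grid is expected to carry (for the
#'   resolution check).
#' @return an object of class `grid_wavefunction`, normalized to 1.
#' @export
grid_wavefunction <- function(x, psi, mass, dt_au, p_max = NULL) {
  dx <- diff(x)
  if (max(abs(dx - dx[1])) > 1e-9 * dx[1]) stop("grid must be uniform")
  dx <- dx[1]
  if (!is.matrix(psi) || nrow(psi) != length(x))
    stop("psi must be a matrix with one row per grid point")
  if (!is.null(p_max) && dx >= pi / p_max)
    stop("grid spacing does not resolve the maximum momentum: need dx < pi/p_max")
  nrm <- sqrt(sum(Mod(psi)^2) * dx)
  if (nrm == 0) stop("zero wavefunction")
  structure(list(x = x, dx = dx, psi = psi / nrm, mass = mass,
                 dt_au = dt_au), class = "grid_wavefunction")
}

#' Gaussian wavepacket helper
#'
#' `exp(-(x - x0)^2 / (4 sigma^2) + i p0 x)`: position uncertainty `sigma`,
#' momentum uncertainty `1/(2 sigma)`.
#'
#' @param x grid; `x0` center; `p0` mean momentum; `sigma` position width.
#' @return complex vector (unnormalized).
#' @export
gaussian_wavepacket <- function(x, x0, p0, sigma) {
  exp(-(x - x0)^2 / (4 * sigma^2) + 1i * p0 * x)
}

# Diabatic-representation potential data at one point:
#  V4    - 4x4 light-molecule potential in the diabatic x photon basis
#  A2D   - block rotation, columns = adiabatic (S0, S1) x photon states
#          expressed over the diabatic basis (so v_adia = t(A2D) %*% v_dia)
#  Q,lam - sorted polaritonic eigenvectors (diabatic basis) and energies
# The diabatic electronic matrix is reconstructed exactly from the model's
# mixing angle: H_dia = U2 diag(E0, E1) U2^T with U2 = [psi0 psi1],
# psi0 = (-sin phi, cos phi), psi1 = (cos phi, sin phi).
diabatic_point <- function(model, cavity, xi) {
  e <- evaluate(model, xi)
  phi <- e$mixing_angle
  U2 <- matrix(c(-sin(phi), cos(phi), cos(phi), sin(phi)), 2, 2)
  Hel <- U2 %*% diag(c(e$E0, e$E1)) %*% t(U2)
  mus <- sum(e$mu_vec * cavity$lam)
  mu_dia <- U2 %*% matrix(c(0, mus, mus, 0), 2, 2) %*% t(U2)
  w <- cavity$omega
  V4 <- rbind(cbind(Hel + diag(2) * w / 2, cavity$g * mu_dia),
              cbind(cavity$g * mu_dia, Hel + diag(2) * 1.5 * w))
  A2D <- rbind(cbind(U2, matrix(0, 2, 2)), cbind(matrix(0, 2, 2), U2))
  es <- eigen(V4, symmetric = TRUE)
  ord <- order(es$values)
  list(V4 = V4, A2D = A2D, Q = es$vectors[, ord, drop = FALSE],
       lam = es$values[ord], elec = e)
}

#' Exact split-operator propagation on 1-D polaritonic surfaces
#'
#' Second-order split-operator scheme alternating kinetic steps (spectral,
#' via FFT) with potential steps (pointwise exponential of the 4x4
#' light-molecule potential in the diabatic x photon representation,
#' diagonalized once per grid point with base R `eigen` - deliberately
#' independent of the engine's Jacobi solver). Returns uncoupled
#' (adiabatic x photon) and polaritonic populations versus time and aborts
#' if the norm drifts beyond 1e-6.
#'
#' @param model a 1-D `polhop_model`.
#' @param cavity a `cavity_mode` (4-state).
#' @param psi0 a [grid_wavefunction()] over the diabatic x photon basis
#'   (see [polariton_wavepacket()] for the standard initial state).
#' @param n_steps number of steps; `record_stride` snapshot spacing.
#' @return list with `t_au`, matrices `pop_unc` and `pop_pol`
#'   (snapshots x states, sorted polaritonic order), `norm`, and the final
#'   wavefunction.
#' @export
split_operator_propagate <- function(model, cavity, psi0, n_steps,
                                     record_stride = 10) {
  if (cavity$n_states != 4L) stop("oracle uses the 4-state basis")
  x <- psi0$x; dx <- psi0$dx; np <- length(x)
  n <- 4L
  dt <- psi0$dt_au
  Vhalf <- array(0+0i, c(n, n, np))
  Qarr <- array(0, c(n, n, np))
  Aarr <- array(0, c(n, n, np))
  for (i in seq_len(np)) {
    d <- diabatic_point(model, cavity, x[i])
    Vhalf[, , i] <- d$Q %*% diag(exp(-1i * d$lam * dt / 2), n) %*% t(d$Q)
    Qarr[, , i] <- d$Q
    Aarr[, , i] <- d$A2D
  }
  k <- 2 * pi * fft_freq(np, dx)
  kin <- exp(-1i * k^2 * dt / (2 * psi0$mass))
  psi <- psi0$psi
  apply_v <- function(psi) {
    out <- psi
    for (a in seq_len(n)) {
      acc <- complex(np)
      for (b in seq_len(n)) acc <- acc + Vhalf[a, b, ] * psi[, b]
      out[, a] <- acc
    }
    out
  }
  nrec <- floor(n_steps / record_stride) + 1
  t_au <- numeric(nrec)
  pop_unc <- matrix(0, nrec, n)
  pop_pol <- matrix(0, nrec, n)
  norms <- numeric(nrec)
  record <- function(r, step, psi) {
    t_au[r] <<- step * dt
    for (g in seq_len(n)) {
      pol <- complex(np); adi <- complex(np)
      for (b in seq_len(n)) {
        pol <- pol + Qarr[b, g, ] * psi[, b]
        adi <- adi + Aarr[b, g, ] * psi[, b]
      }
      pop_pol[r, g] <<- sum(Mod(pol)^2) * dx
      pop_unc[r, g] <<- sum(Mod(adi)^2) * dx
    }
    norms[r] <<- sum(Mod(psi)^2) * dx
  }
  record(1, 0, psi)
  r <- 1
  for (step in seq_len(n_steps)) {
    psi <- apply_v(psi)
    for (a in seq_len(n)) psi[, a] <- stats::fft(kin * stats::fft(psi[, a]),
                                                 inverse = TRUE) / np
    psi <- apply_v(psi)
    if (step %% record_stride == 0) {
      r <- r + 1
      record(r, step, psi)
      if (abs(norms[r] - 1) > 1e-6)
        stop("wavefunction norm drift exceeds 1e-6 at step ", step)
    }
  }
  list(t_au = t_au[1:r], pop_unc = pop_unc[1:r, , drop = FALSE],
       pop_pol = pop_pol[1:r, , drop = FALSE], norm = norms[1:r],
       psi = psi, x = x)
}

# FFT frequencies in cycles per unit length (numpy fftfreq convention)
fft_freq <- function(n, d) {
  c(seq(0, floor((n - 1) / 2)), seq(-floor(n / 2), -1)) / (n * d)
}

#' Gaussian wavepacket on a chosen polaritonic surface
#'
#' Builds the diabatic-basis grid wavefunction `chi(x) v_G(x)` where `chi`
#' is a Gaussian and `v_G(x)` the local polaritonic eigenvector (sorted
#' index `state`, or `"upper"` for the upper polariton identified by
#' rotating-pair character), phase-fixed continuously along the grid.
#'
#' @param model,cavity model and 4-state cavity.
#' @param x grid; `x0`, `p0`, `sigma` packet parameters.
#' @param state sorted polaritonic index or `"upper"`.
#' @param dt_au timestep carried by the wavefunction object.
#' @return a [grid_wavefunction()].
#' @export
polariton_wavepacket <- function(model, cavity, x, x0, p0, sigma, dt_au,
                                 state = "upper") {
  packet <- gaussian_wavepacket(x, x0, p0, sigma)
  psi <- matrix(0+0i, length(x), 4)
  vprev <- NULL
  for (i in seq_along(x)) {
    d <- diabatic_point(model, cavity, x[i])
    g <- if (identical(state, "upper")) {
      # character weights in the adiabatic x photon basis
      W <- t(d$A2D) %*% d$Q
      upper_polariton_index(W, d$lam, 4L)
    } else as.integer(state)
    v <- d$Q[, g]
    if (!is.null(vprev) && sum(v * vprev) < 0) v <- -v
    vprev <- v
    psi[i, ] <- v * packet[i]
  }
  grid_wavefunction(x, psi, model$inertia, dt_au,
                    p_max = abs(p0) + 6 / (2 * sigma))
}

#' Compare surface hopping against the exact wavepacket oracle
#'
#' Runs an FSSH ensemble with initial conditions matched to a Gaussian
#' wavepacket placed on the upper polariton (positions from N(x0, sigma),
#' momenta from the Wigner-conjugate N(p0, 1/(2 sigma))), propagates the
#' same state exactly with the split-operator scheme, and tabulates the
#' per-state polaritonic population differences. The headline scalar is the
#' final lower-polariton population discrepancy.
#'
#' @param model a 1-D `polhop_model`; `cavity` the 4-state mode.
#' @param x0,p0,sigma wavepacket parameters.
#' @param n_traj FSSH ensemble size.
#' @param t_total_fs propagation time; `dt_fs` nuclear/LD timestep.
#' @param xlim,n_grid oracle grid extent and size.
#' @param seed master seed for the FSSH ensemble and sampling.
#' @param settings optional [simulation_settings()] override.
#' @param lower_state sorted index reported as "lower polariton"
#'   (default 2 for the shipped parameter ranges).
#' @return list with the discrepancy `table`, `final_lower_diff`, and both
#'   population records.
#' @export
compare_fssh <- function(model, cavity, x0, p0, sigma, n_traj = 500,
                         t_total_fs = 15, dt_fs = 0.1,
                         xlim = c(-30, 30), n_grid = 1024, seed = 1,
                         settings = NULL, lower_state = 2L) {
  n <- cavity$n_states
  x <- seq(xlim[1], xlim[2], length.out = n_grid + 1)[-(n_grid + 1)]
  dt_au <- fs_to_au(dt_fs)
  psi0 <- polariton_wavepacket(model, cavity, x, x0, p0, sigma, dt_au)
  nst <- as.integer(round(t_total_fs / dt_fs))
  exact <- split_operator_propagate(model, cavity, psi0, nst,
                                    record_stride = 10)
  if (is.null(settings))
    settings <- simulation_settings(dt_fs = dt_fs, t_total_fs = t_total_fs,
                                    decoherence = TRUE, seed = seed)
  set.seed(seed)
  p_spread <- 1 / (2 * sigma)
  xs <- stats::rnorm(n_traj, x0, sigma)
  ps <- stats::rnorm(n_traj, p0, p_spread)
  inits <- lapply(seq_len(n_traj), function(k) {
    st <- init_trajectory_state(model, cavity, xs[k], ps[k], active = 2L)
    up <- upper_polariton_index(st$sol$C, st$sol$energies, n)
    st$active <- up
    A <- rep(0+0i, n); A[up] <- 1+0i
    st$A <- A
    st
  })
  ens <- run_ensemble(model, cavity, inits, settings)
  pops <- population_series(ens)
  rec <- seq(1, nrow(pops), by = 10)
  rec <- rec[seq_len(min(length(rec), length(exact$t_au)))]
  tab <- data.frame(t_fs = pops$t_fs[rec])
  for (g in seq_len(n)) {
    tab[[paste0("dpop_", g)]] <- abs(pops[[paste0("pol_", g)]][rec] -
                                       exact$pop_pol[seq_along(rec), g])
  }
  final_diff <- abs(pops[[paste0("pol_", lower_state)]][rec[length(rec)]] -
                      exact$pop_pol[length(rec), lower_state])
  list(table = tab, final_lower_diff = final_diff,
       fssh = pops, exact = exact)
}

# the higher-energy member of the rotating-pair block; C's rows must be in
# the uncoupled (adiabatic x photon) basis
upper_polariton_index <- function(C, energies, n) {
  if (n == 2L) return(2L)
  wt <- C[2, ]^2 + C[3, ]^2
  pair <- order(wt, decreasing = TRUE)[1:2]
  e <- energies[pair]
  if (abs(diff(e)) < 1e-14) pair[which.max(C[2, pair]^2)]
  else pair[which.max(e)]
}
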