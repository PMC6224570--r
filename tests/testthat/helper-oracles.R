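# Shared fixtures and independent oracles for the test suite.

# Independent closed-form solution of the truncated light-molecule
# Hamiltonian: the rotating block {|S1,0>, |S0,1>} and the counter-rotating
# block {|S0,0>, |S1,1>} never mix, so the 4x4 problem reduces to two 2x2
# eigenproblems solved here in closed form (the implementation under test
# uses a numeric Jacobi solver on the full matrix).
block2_oracle <- function(E0, E1, omega, V) {
  eig2 <- function(a, b, v) {
    m <- (a + b) / 2
    r <- sqrt(((b - a) / 2)^2 + v^2)
    c(m - r, m + r)
  }
  cr <- eig2(E0 + omega / 2, E1 + 1.5 * omega, V)   # counter-rotating block
  ro <- eig2(E1 + omega / 2, E0 + 1.5 * omega, V)   # rotating block
  sort(c(cr, ro))
}

# independent diabatic forms of the 2-D surrogate (duplicated from the
# documented model definition, evaluated directly in R)
azo2d_diabats <- function(theta, alpha, par = list()) {
  p <- modifyList(list(A0 = 1.6, c_cis = 0.6, E_v = 2.8, A1 = 1.4,
                       alpha0 = 115, alpha1 = 130, k0 = 8.73, k1 = 8.73,
                       gamma12 = 0.15), par)
  ev <- 27.211386245988
  a0 <- p$alpha0 * pi / 180; a1 <- p$alpha1 * pi / 180
  H11 <- (p$A0 * sin(theta)^2 + p$c_cis / 2 * (1 + cos(theta)) +
            p$k0 / 2 * (alpha - a0)^2) / ev
  H22 <- (p$E_v - p$A1 * sin(theta)^2 + p$k1 / 2 * (alpha - a1)^2) / ev
  H12 <- p$gamma12 * cos(theta) / ev
  list(H11 = H11, H22 = H22, H12 = H12)
}

# synthetic electronic-structure record (2-state molecule at a notional
# geometry), for Hamiltonian-level tests that need controlled energies
fake_elec <- function(E0, E1, mu_z = 1, grad0 = c(0.01, -0.02),
                      grad1 = c(-0.03, 0.04), dmu_z = c(0.05, 0)) {
  structure(list(E0 = E0, E1 = E1, grad0 = grad0, grad1 = grad1,
                 mu_vec = c(0, 0, mu_z),
                 grad_mu_vec = rbind(0, 0, dmu_z),
                 mixing_angle = 0.3),
            class = "electronic_structure")
}

# deterministic thermal phase points for the 2-D surrogate
thermal_points <- function(n, seed = 1) {
  s <- thermal_sampling_settings(total_time_ps = max(1, ceiling(n * 0.012)),
                                 equilibration_ps = 0.1, seed = seed)
  thermal_sample(azo2d_model(), s, n = n)
}

# minimal hand-built trajectory (for loss/observable accounting tests)
fake_traj <- function(c_s01, dt_au = 1, active = NULL, n_states = 4L,
                      theta = NULL) {
  n <- length(c_s01)
  if (is.null(active)) active <- rep(3L, n)
  q <- cbind(if (is.null(theta)) rep(pi, n) else theta, rep(2, n))
  cc <- matrix(0, n, n_states)
  cc[cbind(seq_len(n), active)] <- 1
  structure(list(t = (seq_len(n) - 1) * dt_au, q = q, p = q * 0,
                 active = active, energies = matrix(0, n, n_states),
                 c_active_sq = cc, amp_pop = cc, c_s01_sq = c_s01,
                 hop_flag = integer(n),
                 hops = data.frame(step = integer(), from = integer(),
                                   to = integer(), accepted = integer()),
                 failed = FALSE, fail_step = -1L, dt_au = dt_au,
                 n_states = n_states, model_name = "azo2d", seed = 1L,
                 traj_index = 1L, angular = c(TRUE, TRUE),
                 inertia = c(1.5e5, 1.25e4)),
            class = "polhop_trajectory")
}

fake_ensemble <- function(trajs) {
  structure(list(trajectories = trajs, t_au = trajs[[1]]$t,
                 n_states = trajs[[1]]$n_states, failed = integer(0),
                 meta = list(model = "azo2d", n_traj = length(trajs))),
            class = "polhop_ensemble")
}

# R-function test models for the reference (R-engine) dynamics path
flat_model <- function(gap = 0.1) {
  m <- list(name = "flat", id = NA, params = NULL, inertia = 2000,
            ncoord = 1L, angular = FALSE, q_ref = 0,
            fun = function(q) list(E0 = 0, E1 = gap, grad0 = 0, grad1 = 0,
                                   mu_vec = c(0, 0, 1),
                                   grad_mu_vec = rbind(0, 0, 0),
                                   mixing_angle = 0))
  class(m) <- "polhop_model"
  m
}

harmonic_model <- function(k = 0.05, x0 = 0, gap = 0.1, mass = 2000) {
  m <- list(name = "harmonic", id = NA, params = NULL, inertia = mass,
            ncoord = 1L, angular = FALSE, q_ref = x0,
            fun = function(q) list(E0 = 0.5 * k * (q - x0)^2,
                                   E1 = 0.5 * k * (q - x0)^2 + gap,
                                   grad0 = k * (q - x0), grad1 = k * (q - x0),
                                   mu_vec = c(0, 0, 1),
                                   grad_mu_vec = rbind(0, 0, 0),
                                   mixing_angle = 0))
  class(m) <- "polhop_model"
  m
}
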