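test_that("velocity Verlet: free motion, harmonic conservation, reversibility", {
  cavb <- cavity_mode(1.3, 0, n_photon = 1)
  dt <- fs_to_au(0.1)
  # flat surface: uniform straight-line motion
  fm <- flat_model()
  st <- init_trajectory_state(fm, cavb, 0.5, 3, active = 1L)
  for (i in 1:50) st <- vv_step(st, fm, cavb, dt)
  expect_equal(st$q, 0.5 + 3 / 2000 * 50 * dt, tolerance = 1e-12)
  expect_equal(st$p, 3)
  # harmonic surface: energy conserved to <= 1e-9 hartree/step at 0.1 fs
  hm <- harmonic_model(k = 0.02, x0 = 0)
  st <- init_trajectory_state(hm, cavb, 0.2, 0, active = 1L)
  e0 <- st$sol$energies[1] + 0.5 * st$p^2 / st$inertia
  nstep <- 200
  for (i in 1:nstep) st <- vv_step(st, hm, cavb, dt)
  e1 <- st$sol$energies[1] + 0.5 * st$p^2 / st$inertia
  expect_lt(abs(e1 - e0), 1e-9 * nstep)
  # time reversal: flip momenta, propagate back, return to start
  st$p <- -st$p
  for (i in 1:nstep) st <- vv_step(st, hm, cavb, dt)
  expect_lt(abs(st$q - 0.2), 1e-8)
})

test_that("LD propagation: adiabatic/diabatic limits, unitarity, substep oracle", {
  # adiabatic limit: identity overlap, constant energies -> pure phases
  E <- c(0.01, 0.05, 0.08, 0.2)
  sol <- list(energies = E, C = diag(4), n = 4L)
  dt <- fs_to_au(0.1)
  A <- c(0.5 + 0.1i, 0.6, 0.2i, 0.3) ; A <- A / sqrt(sum(Mod(A)^2))
  out <- ld_propagate(A, sol, sol, diag(2), dt)
  expect_equal(out$A, A * exp(-1i * E * dt), tolerance = 1e-12)
  # diabatic limit: sudden character swap permutes the populations
  swap <- matrix(c(0, 1, -1, 0), 2, 2) # electronic overlap at a swap
  sol_b <- list(energies = E, C = diag(4), n = 4L)
  out <- ld_propagate(A, sol, sol_b, swap, dt)
  expect_equal(Mod(out$A)^2, (Mod(A)^2)[c(2, 1, 4, 3)], tolerance = 1e-10)
  # unitarity on real trajectory-like steps
  m <- azo2d_model()
  cav <- cavity_mode(1.3, 0.010)
  set.seed(13)
  for (i in 1:20) {
    qa <- c(runif(1, -pi, pi), runif(1, 1.5, 2.7))
    qb <- qa + runif(2, -0.02, 0.02)
    sa <- solve_polaritons(build_hamiltonian(evaluate(m, qa), cav))
    ov <- electronic_overlap(m, qa, qb)
    sb <- solve_polaritons(build_hamiltonian(evaluate(m, qb), cav),
                           previous = sa, elec_ov = ov)
    U <- ld_propagate(A, sa, sb, ov, dt)$U
    expect_lt(max(Mod(Conj(t(U)) %*% U - diag(4))), 1e-10)
  }
  # one coarse LD step against 100 fine substeps along the same path
  # (step size representative of dt = 0.1 fs dynamics)
  qa <- c(2.3, 2.0); qb <- c(2.301, 2.0005)
  sa <- solve_polaritons(build_hamiltonian(evaluate(m, qa), cav))
  ov_ab <- electronic_overlap(m, qa, qb)
  sb <- solve_polaritons(build_hamiltonian(evaluate(m, qb), cav),
                         previous = sa, elec_ov = ov_ab)
  coarse <- ld_propagate(A, sa, sb, ov_ab, dt)$A
  nf <- 100
  Af <- A; sp <- sa; qp <- qa
  for (i in seq_len(nf)) {
    qn <- qa + (qb - qa) * i / nf
    ovn <- electronic_overlap(m, qp, qn)
    sn <- solve_polaritons(build_hamiltonian(evaluate(m, qn), cav),
                           previous = sp, elec_ov = ovn)
    Af <- ld_propagate(Af, sp, sn, ovn, dt / nf)$A
    sp <- sn; qp <- qn
  }
  expect_lt(max(abs(Mod(coarse)^2 - Mod(Af)^2)), 1e-6)
  expect_equal(sum(Mod(coarse)^2), 1, tolerance = 1e-12)
})

test_that("fewest-switches hop decision and momentum rescaling", {
  E <- c(0, 0.05, 0.1, 0.2)
  p <- c(15, 8); inertia <- c(2000, 1000)  # E_kin = 0.088 ha > E[2] - E[1]
  # no population change -> no hop at any draw
  A <- c(1, 0, 0, 0) + 0i
  r <- fssh_step(A, A, 1L, E, p, inertia, u = 1e-12)
  expect_false(r$hopped); expect_equal(r$p_hop, 0)
  # complete one-step transfer -> hop probability 1
  r <- fssh_step(c(1, 0, 0, 0) + 0i, c(0, 1, 0, 0) + 0i, 1L, E, p, inertia,
                 u = 0.999999)
  expect_true(r$hopped); expect_equal(r$p_hop, 1); expect_equal(r$active, 2L)
  # energy conservation under isotropic rescaling
  ek0 <- sum(0.5 * p^2 / inertia)
  ek1 <- sum(0.5 * r$p^2 / inertia)
  expect_equal(ek1 + E[2], ek0 + E[1], tolerance = 1e-12)
  expect_equal(r$p[1] / r$p[2], p[1] / p[2]) # isotropic
  # insufficient kinetic energy -> frustrated, momenta unchanged
  r <- fssh_step(c(1, 0, 0, 0) + 0i, c(0, 0, 0, 1) + 0i, 1L, c(0, 1, 2, 3),
                 c(1, 1), inertia, u = 0.5)
  expect_true(r$frustrated); expect_equal(r$active, 1L)
  expect_equal(r$p, c(1, 1))
  # vanished active population -> defined probability 0
  r <- fssh_step(c(1e-8, 1, 0, 0) + 0i, c(0, 1, 0, 0) + 0i, 1L, E, p,
                 inertia, u = 0.5)
  expect_equal(r$p_hop, 0)
})

test_that("decoherence damping follows the stated energy-based formula", {
  A <- c(0.8, 0.6) * exp(c(0.3i, -1i))
  # tau = (1/|dE|)(1 + alpha/Ekin); dE=0.1, Ekin=0.05, alpha=0.1, dt=1 au
  out <- apply_decoherence(A, 1L, c(0, 0.1), E_kin = 0.05, dt = 1,
                           alpha = 0.1)
  expect_equal(Mod(out[2]), Mod(A[2]) * exp(-1 / 30), tolerance = 1e-12)
  expect_equal(exp(-1 / 30), 0.9672161, tolerance = 1e-7)
  expect_equal(sum(Mod(out)^2), 1, tolerance = 1e-12)
  # alpha = 0 in the high-kinetic-energy limit: tau -> 1/dE
  out <- apply_decoherence(A, 1L, c(0, 0.1), E_kin = 1e12, dt = 1, alpha = 0)
  expect_equal(Mod(out[2]), Mod(A[2]) * exp(-0.1), tolerance = 1e-6)
  # zero kinetic energy: no damping that step
  expect_identical(apply_decoherence(A, 1L, c(0, 0.1), 0, 1, 0.1), A)
})

test_that("trajectory conservation: amplitude norm and total energy", {
  m <- azo2d_model()
  cav <- cavity_mode(1.3, 0.010)
  st <- vertical_excite(c(176, 116, 0.3, 0.1), m, cav)
  set <- simulation_settings(dt_fs = 0.1, t_total_fs = 100,
                             decoherence = FALSE, seed = 2)
  tr <- run_trajectory(m, cav, st, set)
  expect_false(tr$failed)
  norms <- rowSums(tr$amp_pop)
  expect_lt(max(abs(norms - 1)), 1e-8)
  etot <- 0.5 * tr$p[, 1]^2 / m$inertia[1] + 0.5 * tr$p[, 2]^2 / m$inertia[2] +
    tr$energies[cbind(seq_along(tr$active), tr$active)]
  expect_lt(hartree_to_ev(max(abs(etot - etot[1]))), 1e-3)
  # hop bookkeeping: every active-state change is an accepted hop or a
  # trivial-crossing relabel
  ch <- which(diff(tr$active) != 0) + 1
  expect_true(all(tr$hop_flag[ch] %in% c(1L, 2L)))
  expect_equal(sum(tr$hop_flag == 1L), sum(tr$hops$accepted == 1L))
})

test_that("Landau-Zener passage probability on the 1-D model", {
  c1 <- curve1d_model()
  bare <- cavity_mode(hartree_to_ev(0.015), 0, n_photon = 1)
  p0 <- 40
  plz <- exp(-2 * pi * 0.005^2 / ((p0 / 2000) * 2 * 0.01 * 1.6))
  set <- simulation_settings(dt_fs = 0.05, t_total_fs = 10,
                             decoherence = FALSE, seed = 11)
  n <- 600
  fin <- vapply(seq_len(n), function(k) {
    st <- init_trajectory_state(c1, bare, -6, p0, active = 2L)
    tr <- run_trajectory(c1, bare, st, set, traj_index = k)
    tr$active[length(tr$active)]
  }, integer(1))
  # diabatic passage ends on the lower adiabat on the far side
  expect_lt(abs(mean(fin == 1L) - plz), 0.05)
})

test_that("ensembles are deterministic, order-independent, reproducible", {
  m <- azo2d_model()
  cav <- cavity_mode(1.3, 0.010)
  pts <- thermal_points(5, seed = 4)
  inits <- lapply(1:5, function(k) vertical_excite(pts[k, ], m, cav))
  set <- simulation_settings(dt_fs = 0.1, t_total_fs = 30, seed = 17)
  e1 <- run_ensemble(m, cav, inits, set)
  e2 <- run_ensemble(m, cav, inits, set)
  expect_identical(lapply(e1$trajectories, `[[`, "q"),
                   lapply(e2$trajectories, `[[`, "q"))
  # single trajectory rerun with its own index matches the ensemble member
  t3 <- run_trajectory(m, cav, inits[[3]], set, traj_index = 3)
  expect_identical(t3$q, e1$trajectories[[3]]$q)
  expect_identical(t3$hops, e1$trajectories[[3]]$hops)
  # one-trajectory ensemble equals that trajectory
  es <- run_ensemble(m, cav, inits[1], set)
  expect_identical(es$trajectories[[1]]$q,
                   run_trajectory(m, cav, inits[[1]], set, traj_index = 1)$q)
})

test_that("compiled and reference R engines agree on a hop-free segment", {
  c1 <- curve1d_model()
  cav <- cavity_mode(hartree_to_ev(0.015), 0.003)
  st <- init_trajectory_state(c1, cav, -4, 8, active = 1L)
  set <- simulation_settings(dt_fs = 0.1, n_steps = 60, seed = 23)
  tc <- run_trajectory(c1, cav, st, set, engine = "cpp")
  tr <- run_trajectory(c1, cav, st, set, engine = "r")
  expect_equal(nrow(tc$hops), 0L)
  expect_equal(nrow(tr$hops), 0L)
  expect_equal(tc$q, tr$q, tolerance = 1e-10)
  expect_equal(tc$p, tr$p, tolerance = 1e-10)
  expect_equal(tc$amp_pop, tr$amp_pop, tolerance = 1e-8)
  expect_equal(tc$energies, tr$energies, tolerance = 1e-12)
})

test_that("g=0 polaritonic run is bitwise the photon-free two-state run", {
  m <- azo2d_model()
  cav0 <- cavity_mode(1.3, 0)
  bare <- cavity_mode(1.3, 0, n_photon = 1)
  pts <- thermal_points(3, seed = 8)
  set <- simulation_settings(dt_fs = 0.1, t_total_fs = 150, seed = 5)
  for (k in 1:3) {
    t4 <- run_trajectory(m, cav0, vertical_excite(pts[k, ], m, cav0), set,
                         traj_index = k)
    t2 <- run_trajectory(m, bare, vertical_excite(pts[k, ], m, bare), set,
                         traj_index = k)
    expect_identical(t4$q, t2$q)
    expect_identical(t4$p, t2$p)
    e4 <- t4$energies[cbind(seq_along(t4$active), t4$active)]
    e2 <- t2$energies[cbind(seq_along(t2$active), t2$active)]
    expect_identical(e4, e2)
  }
})
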