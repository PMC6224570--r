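test_that("free Gaussian spreading matches the closed form", {
  m0 <- curve1d_model(A = 0, C = 0)       # zero potential
  cav <- cavity_mode(hartree_to_ev(0.015), 0)
  x <- seq(-40, 40, length.out = 1024)[-1024]
  sig <- 1.0; p0 <- 5; mass <- 2000
  psi <- matrix(0 + 0i, length(x), 4)
  psi[, 2] <- gaussian_wavepacket(x, -10, p0, sig)
  wf <- grid_wavefunction(x, psi, mass, fs_to_au(0.2),
                          p_max = p0 + 6 / (2 * sig))
  res <- split_operator_propagate(m0, cav, wf, n_steps = 500,
                                  record_stride = 250)
  tau <- 500 * fs_to_au(0.2)
  sig_exact <- sig * sqrt(1 + (tau / (2 * mass * sig^2))^2)
  dx <- x[2] - x[1]
  d <- Mod(res$psi[, 2])^2; d <- d / (sum(d) * dx)
  xm <- sum(x * d) * dx
  sig_num <- sqrt(sum((x - xm)^2 * d) * dx)
  expect_lt(abs(sig_num - sig_exact), 1e-6)
  expect_lt(max(abs(res$norm - 1)), 1e-10)
})

test_that("harmonic surface shows the analytic revival", {
  k <- 0.05; mass <- 2000
  omega <- sqrt(k / mass)
  hm <- harmonic_model(k = k, x0 = 0, mass = mass)
  cav <- cavity_mode(5, 0)
  x <- seq(-8, 8, length.out = 512)[-512]
  period <- 2 * pi / omega
  nst <- 400
  dt <- period / nst
  sig <- sqrt(1 / (2 * mass * omega))  # coherent-state width
  psi <- matrix(0 + 0i, length(x), 4)
  psi[, 1] <- gaussian_wavepacket(x, 1.0, 0, sig)
  wf <- grid_wavefunction(x, psi, mass, dt, p_max = 2 * mass * omega)
  res <- split_operator_propagate(hm, cav, wf, n_steps = nst,
                                  record_stride = nst)
  dx <- x[2] - x[1]
  auto <- abs(sum(Conj(wf$psi[, 1]) * res$psi[, 1]) * dx)
  expect_gt(auto, 0.999)  # full revival after one period, within one dt
  # half a period later the packet sits on the far side: small overlap
  res2 <- split_operator_propagate(hm, cav, wf, n_steps = nst / 2,
                                   record_stride = nst / 2)
  auto2 <- abs(sum(Conj(wf$psi[, 1]) * res2$psi[, 1]) * dx)
  expect_lt(auto2, 0.2)
})

test_that("wavepacket transmission matches Landau-Zener in its regime", {
  # linear-diabat-conforming parameters: coupling support well inside the
  # linear zone of the tanh diabats; velocity evaluated at the crossing
  c1 <- curve1d_model(A = 0.04, B = 0.25, C = 0.003, D = 0.25)
  cav <- cavity_mode(5, 0)  # photon far off resonance: molecular physics only
  x <- seq(-80, 80, length.out = 4096)[-4096]
  p0 <- 50
  wf <- polariton_wavepacket(c1, cav, x, -15, p0, 1.5, fs_to_au(0.05),
                             state = 2L)
  nst <- round((30 / (p0 / 2000)) / fs_to_au(0.05))
  res <- split_operator_propagate(c1, cav, wf, nst, record_stride = nst)
  pc <- sqrt(p0^2 + 2 * 2000 * (0.04 * tanh(0.25 * 15) - 0.003))
  plz <- exp(-2 * pi * 0.003^2 / ((pc / 2000) * 2 * 0.04 * 0.25))
  expect_lt(abs(res$pop_pol[nrow(res$pop_pol), 1] - plz), 0.02)
})

test_that("oracle self-converges under grid and timestep refinement", {
  c1 <- curve1d_model()
  cav <- cavity_mode(hartree_to_ev(0.015), 0.003)
  run <- function(ng, dt_fs, nst) {
    x <- seq(-30, 30, length.out = ng + 1)[-(ng + 1)]
    wf <- polariton_wavepacket(c1, cav, x, -6, 18, 0.7, fs_to_au(dt_fs))
    split_operator_propagate(c1, cav, wf, nst, record_stride = nst)
  }
  a <- run(1024, 0.1, 250)
  b <- run(2048, 0.05, 500)
  expect_lt(max(abs(a$pop_pol[nrow(a$pop_pol), ] -
                      b$pop_pol[nrow(b$pop_pol), ])), 1e-4)
})

test_that("grid validation catches unresolved momenta and bad grids", {
  x <- seq(-10, 10, length.out = 128)[-128]
  psi <- matrix(0 + 0i, length(x), 4); psi[, 1] <- gaussian_wavepacket(x, 0, 1, 1)
  expect_error(grid_wavefunction(x, psi, 2000, 1, p_max = 1000), "resolve")
  expect_error(grid_wavefunction(c(x[-1], 99), psi[-1, ], 2000, 1), "uniform")
  expect_error(grid_wavefunction(x, 0 * psi, 2000, 1), "zero wavefunction")
})
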