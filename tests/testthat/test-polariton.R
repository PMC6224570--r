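test_that("Hamiltonian structure: diagonal, coupling pattern, selection rule", {
  e <- fake_elec(E0 = 0.01, E1 = 0.12, mu_z = 0.8)
  cav <- cavity_mode(1.3, 0.010)
  w <- cav$omega
  H <- build_hamiltonian(e, cav)
  expect_equal(diag(H), c(0.01 + w / 2, 0.12 + w / 2,
                          0.01 + 1.5 * w, 0.12 + 1.5 * w))
  V <- 0.010 * 0.8
  expect_equal(H[2, 3], V)
  expect_equal(H[1, 4], V)
  # coupling only connects states differing by one photon via the
  # transition dipole: all other off-diagonal entries vanish
  expect_identical(c(H[1, 2], H[1, 3], H[2, 4], H[3, 4]), c(0, 0, 0, 0))
  expect_true(isSymmetric(H))
  # g = 0: diagonal; polaritonic = uncoupled energies
  H0 <- build_hamiltonian(e, cavity_mode(1.3, 0))
  expect_identical(H0[lower.tri(H0)], rep(0, 6))
  s0 <- solve_polaritons(H0)
  expect_equal(s0$energies, sort(diag(H0)))
  expect_true(all(apply(abs(s0$C), 2, max) == 1))
  expect_error(cavity_mode(1.3, 0.01, polarization = c(0, 0, 2)), "unit")
})

test_that("resonant splitting and Lamb shift match the closed-form oracle", {
  # resonance E1 - E0 = omega, mu.lam = 1, g = 0.010 au -> splitting 0.020 au
  w <- ev_to_hartree(1.3)
  e <- fake_elec(E0 = 0, E1 = w, mu_z = 1)
  sol <- solve_polaritons(build_hamiltonian(e, cavity_mode(1.3, 0.010)))
  gap <- sol$energies[3] - sol$energies[2]
  expect_lt(abs(gap - 0.020) / 0.020, 1e-12)
  expect_equal(sol$C[2, 2]^2, 0.5, tolerance = 1e-10)
  expect_equal(sol$C[3, 2]^2, 0.5, tolerance = 1e-10)

  # Lamb-shifted |S0,0>-like state from the counter-rotating coupling
  E0 <- 0; E1 <- 0.1; w <- 0.05; V <- 0.01
  e <- fake_elec(E0, E1, mu_z = 1)
  cav <- cavity_mode(hartree_to_ev(w), V)
  sol <- solve_polaritons(build_hamiltonian(e, cav))
  oracle <- block2_oracle(E0, E1, w, V)
  expect_equal(sol$energies, oracle, tolerance = 1e-13)
  # frozen closed-form value, approximated by second-order perturbation
  # theory -V^2/(E1 - E0 + omega)
  expect_lt(abs(oracle[1] - 0.0243363), 1e-7)
  expect_lt(abs((oracle[1] - (E0 + w / 2)) - (-V^2 / (E1 - E0 + w))), 5e-6)
})

test_that("far-detuned mixing obeys the perturbative bound", {
  set.seed(21)
  for (i in 1:30) {
    E1 <- runif(1, 0.1, 0.2)
    w <- runif(1, 0.01, 0.03)   # far detuned from E1
    V <- runif(1, 1e-4, 1e-3)
    delta <- abs(E1 - w)
    sol <- solve_polaritons(build_hamiltonian(fake_elec(0, E1),
                                              cavity_mode(hartree_to_ev(w), V)))
    offchar <- apply(sol$C^2, 2, function(x) 1 - max(x))
    expect_lt(max(offchar), (V / delta)^2 * (1 + 10 * (V / delta)^2) + 1e-15)
  }
})

test_that("numeric eigensolution equals the closed-form block oracle", {
  set.seed(5)
  for (i in 1:200) {
    E0 <- runif(1, -0.05, 0.05); E1 <- E0 + runif(1, 0.01, 0.2)
    w <- runif(1, 0.01, 0.15); V <- runif(1, -0.02, 0.02)
    H <- matrix(0, 4, 4)
    diag(H) <- c(E0 + w / 2, E1 + w / 2, E0 + 1.5 * w, E1 + 1.5 * w)
    H[2, 3] <- H[3, 2] <- V; H[1, 4] <- H[4, 1] <- V
    sol <- solve_polaritons(H)
    expect_lt(max(abs(sol$energies - block2_oracle(E0, E1, w, V))), 1e-12)
    expect_lt(max(abs(t(sol$C) %*% sol$C - diag(4))), 1e-12)
    # structural block separation: rotating and counter-rotating blocks
    # never mix under the 0/1-photon truncation
    for (j in 1:4) {
      wrot <- sol$C[2, j]^2 + sol$C[3, j]^2
      expect_true(wrot < 1e-20 || wrot > 1 - 1e-12)
    }
  }
})

test_that("polaritonic gradients: limits and finite differences", {
  m <- azo2d_model()
  q <- c(2.3, 2.05)
  e <- evaluate(m, q)
  # g = 0: gradient of the |S1,0>-like state is the bare excited gradient
  cav0 <- cavity_mode(1.3, 0)
  sol0 <- solve_polaritons(build_hamiltonian(e, cav0))
  j <- which(sol0$C[2, ]^2 == 1)
  expect_identical(polaritonic_gradient(e, cav0, sol0, j), e$grad1)
  # resonance with equal mixing: (grad0 + grad1)/2 +- grad V
  w <- e$E1 - e$E0
  cavr <- cavity_mode(hartree_to_ev(w), 0.010)
  solr <- solve_polaritons(build_hamiltonian(e, cavr))
  dV <- 0.010 * as.numeric(c(0, 0, 1) %*% e$grad_mu_vec)
  gm <- polaritonic_gradient(e, cavr, solr, 2)
  gp <- polaritonic_gradient(e, cavr, solr, 3)
  s <- sign(solr$C[2, 3] * solr$C[3, 3])
  expect_equal(gp, (e$grad0 + e$grad1) / 2 + s * dV, tolerance = 1e-9)
  expect_equal(gm, (e$grad0 + e$grad1) / 2 - s * dV, tolerance = 1e-9)
  # finite-difference check of all four eigenvalue gradients
  cav <- cavity_mode(1.3, 0.010)
  h <- 1e-5
  sol <- solve_polaritons(build_hamiltonian(e, cav))
  for (st in 1:4) {
    g <- polaritonic_gradient(e, cav, sol, st)
    for (k in 1:2) {
      dq <- c(0, 0); dq[k] <- h
      Ep <- solve_polaritons(build_hamiltonian(evaluate(m, q + dq), cav))$energies[st]
      Em <- solve_polaritons(build_hamiltonian(evaluate(m, q - dq), cav))$energies[st]
      expect_lt(abs((Ep - Em) / (2 * h) - g[k]) / max(abs(g[k]), 1e-4), 1e-6)
    }
  }
})

test_that("gradient flags exact polaritonic degeneracy", {
  m <- azo2d_model()
  cav <- cavity_mode(2.2, 0.010)
  pci <- locate_pci(m, cav)
  e <- evaluate(m, c(deg_to_rad(pci$theta_deg), deg_to_rad(pci$alpha_deg)))
  sol <- solve_polaritons(build_hamiltonian(e, cav))
  expect_error(polaritonic_gradient(e, cav, sol, 2),
               class = "polhop_degeneracy")
})

test_that("polaritonic overlaps: identity, g=0 separability, orthogonality", {
  m <- azo2d_model()
  cav <- cavity_mode(1.3, 0.010)
  e <- evaluate(m, c(2.4, 2.0))
  sol <- solve_polaritons(build_hamiltonian(e, cav))
  expect_equal(polaritonic_overlap(sol, sol, diag(2)), diag(4),
               tolerance = 1e-12)
  # g = 0 across a step: two copies of the electronic overlap, blocked by
  # photon number (checked entrywise through the state characters)
  cav0 <- cavity_mode(1.3, 0)
  qa <- c(2.4, 2.0); qb <- c(2.41, 2.01)
  ov <- electronic_overlap(m, qa, qb)
  sa <- solve_polaritons(build_hamiltonian(evaluate(m, qa), cav0))
  sb <- solve_polaritons(build_hamiltonian(evaluate(m, qb), cav0))
  S <- polaritonic_overlap(sa, sb, ov)
  elec_of <- c(1, 2, 1, 2); phot_of <- c(0, 0, 1, 1)
  ca <- apply(abs(sa$C), 2, which.max)  # uncoupled character per state
  cb <- apply(abs(sb$C), 2, which.max)
  for (i in 1:4) for (j in 1:4) {
    ref <- if (phot_of[ca[i]] == phot_of[cb[j]])
      ov[elec_of[ca[i]], elec_of[cb[j]]] else 0
    expect_equal(abs(S[i, j]), abs(ref), tolerance = 1e-14)
  }
  set.seed(9)
  for (i in 1:20) {
    qa <- c(runif(1, -pi, pi), runif(1, 1.4, 2.8))
    qb <- qa + runif(2, -0.05, 0.05)
    sa <- solve_polaritons(build_hamiltonian(evaluate(m, qa), cav))
    sb <- solve_polaritons(build_hamiltonian(evaluate(m, qb), cav))
    S <- polaritonic_overlap(sa, sb, electronic_overlap(m, qa, qb))
    expect_lt(max(abs(t(S) %*% S - diag(4))), 1e-12)
  }
})

test_that("sign continuity along a path", {
  m <- azo2d_model()
  cav <- cavity_mode(1.3, 0.010)
  qs <- cbind(seq(pi, 2, length.out = 200), seq(2.0, 2.2, length.out = 200))
  prev <- NULL; eprev <- NULL
  for (i in seq_len(nrow(qs))) {
    e <- evaluate(m, qs[i, ])
    ov <- if (is.null(prev)) NULL else {
      d <- e$mixing_angle - eprev$mixing_angle
      matrix(c(cos(d), sin(d), -sin(d), cos(d)), 2, 2)
    }
    sol <- solve_polaritons(build_hamiltonian(e, cav), previous = prev,
                            elec_ov = ov)
    if (!is.null(prev)) {
      S <- polaritonic_overlap(prev, sol, ov)
      rmax <- apply(abs(S), 2, which.max)
      expect_true(all(abs(S[cbind(rmax, 1:4)]) > 0.9))  # small steps
      expect_true(all(S[cbind(rmax, 1:4)] > 0))         # sign-fixed
    }
    prev <- sol; eprev <- e
  }
})

test_that("PPES scan: lossless seam at g=0, splitting law, PCI", {
  m <- azo2d_model()
  # g = 0: the polaritonic gap vanishes along the whole uncoupled seam
  sc0 <- scan_ppes(m, cavity_mode(1.3, 0), seq(100, 179, 1), seq(90, 170, 1))
  seam <- abs(sc0$table$elec_gap_ev - 1.3) < 0.02
  expect_gt(sum(seam), 10)
  expect_lt(max(sc0$table$gap_pm_ev[seam]), 0.03) # grid-limited closure
  expect_lt(sc0$min_gap$gap_pm_ev, 1e-3)
  # exact splitting on a seam point located by root finding (theta = 120)
  cav <- cavity_mode(1.3, 0.010)
  th <- deg_to_rad(120)
  r <- uniroot(function(al) {
    e <- evaluate(m, c(th, al)); (e$E1 - e$E0) - cav$omega
  }, deg_to_rad(c(115, 179)), tol = 1e-14)
  e <- evaluate(m, c(th, r$root))
  sol <- solve_polaritons(build_hamiltonian(e, cav))
  gap <- sol$energies[3] - sol$energies[2]
  expect_lt(abs(gap - 2 * 0.010 * abs(e$mu_vec[3])) / gap, 1e-10)
  # polaritonic conical intersection at a planar geometry
  pci <- scan_ppes(m, cavity_mode(2.2, 0.010), seq(170, 180, 5),
                   seq(120, 150, 5))$pci
  expect_false(is.null(pci))
  expect_equal(pci$theta_deg, 180)
  expect_lt(pci$gap_ev, 1e-6)
  expect_identical(pci$mu_dot_lam, 0)
  expect_error(scan_ppes(m, cav, numeric(0)), "empty")
})
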