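test_that("surrogate trans reference, planarity and isomer classification", {
  m <- azo2d_model()
  g <- geometry(c(180, 115), m$inertia)
  e <- evaluate(m, g)
  # the diabatic trans reference sits at H11 = 0; the electronic coupling
  # gamma12 depresses the adiabatic E0 by ~gamma12^2/gap (< 0.01 eV)
  expect_lt(abs(hartree_to_ev(e$E0)), 0.01)
  expect_identical(e$mu_vec[3], 0)
  # out-of-plane dipole vanishes exactly at planar geometries, any bend
  for (al in c(80, 100, 115, 140, 170)) {
    expect_identical(evaluate(m, geometry(c(180, al), m$inertia))$mu_vec[3], 0)
    expect_identical(evaluate(m, geometry(c(0, al), m$inertia))$mu_vec[3], 0)
  }
  expect_gt(abs(evaluate(m, geometry(c(90, 115), m$inertia))$mu_vec[3]), 0.99)

  expect_identical(classify_isomer(geometry(c(180, 115), m$inertia)), "trans")
  expect_identical(classify_isomer(geometry(c(10, 115), m$inertia)), "cis")
  expect_identical(classify_isomer(geometry(c(90, 115), m$inertia)), "trans")
})

test_that("adiabatic energies match the independent 2x2 diabatic oracle", {
  m <- azo2d_model()
  set.seed(11)
  for (i in 1:50) {
    th <- runif(1, -pi, pi); al <- runif(1, 1.2, 3)
    d <- azo2d_diabats(th, al)
    mean_ <- (d$H11 + d$H22) / 2
    r <- sqrt(((d$H22 - d$H11) / 2)^2 + d$H12^2)
    e <- evaluate(m, c(th, al))
    expect_lt(abs(e$E0 - (mean_ - r)), 1e-12)
    expect_lt(abs(e$E1 - (mean_ + r)), 1e-12)
  }
})

test_that("electronic conical intersection: unique gap closure on theta=90", {
  m <- azo2d_model()
  # brute-force scan of |H11 - H22| (independent diabats); H12 = 0 at 90 deg
  al <- seq(deg_to_rad(60), deg_to_rad(180), length.out = 20001)
  d <- azo2d_diabats(pi / 2, al)
  dh <- d$H11 - d$H22
  i <- which(diff(sign(dh)) != 0)
  expect_length(i, 1) # exactly one crossing in the physical bend range
  r <- uniroot(function(a) {
    dd <- azo2d_diabats(pi / 2, a); dd$H11 - dd$H22
  }, c(al[i], al[i + 1]), tol = 1e-14)
  e <- evaluate(m, c(pi / 2, r$root))
  expect_lt(e$E1 - e$E0, 1e-8)
  # gap stays open elsewhere on the line
  expect_gt(sort(abs(dh))[2], 0)
})

test_that("gradients agree with central finite differences", {
  h <- 1e-5
  for (model in list(azo2d_model(), curve1d_model())) {
    set.seed(7)
    for (i in 1:50) {
      q <- if (model$ncoord == 2) c(runif(1, -pi, pi), runif(1, 1.3, 2.9))
           else runif(1, -3, 3)
      e <- evaluate(model, q)
      for (k in seq_len(model$ncoord)) {
        dq <- numeric(model$ncoord); dq[k] <- h
        ep <- evaluate(model, q + dq); em <- evaluate(model, q - dq)
        sc <- max(abs(e$grad0[k]), abs(e$grad1[k]), 1e-3)
        expect_lt(abs((ep$E0 - em$E0) / (2 * h) - e$grad0[k]) / sc, 1e-5)
        expect_lt(abs((ep$E1 - em$E1) / (2 * h) - e$grad1[k]) / sc, 1e-5)
        dmu <- (ep$mu_vec[3] - em$mu_vec[3]) / (2 * h)
        expect_lt(abs(dmu - e$grad_mu_vec[3, k]),
                  1e-5 * max(1, abs(e$grad_mu_vec[3, k])))
      }
    }
  }
})

test_that("adiabatic ordering holds on a dense grid", {
  m <- azo2d_model()
  cav <- cavity_mode(1.3, 0) # scan helper exposes the electronic gap
  sc <- scan_ppes(m, cav, seq(-180, 180, length.out = 200),
                  seq(60, 180, length.out = 200))
  expect_true(all(sc$table$elec_gap_ev >= 0))
})

test_that("electronic overlap is the mixing-angle rotation", {
  m <- azo2d_model()
  g1 <- geometry(c(150, 120), m$inertia)
  expect_equal(electronic_overlap(m, g1, g1), diag(2))
  set.seed(3)
  for (i in 1:20) {
    qa <- c(runif(1, -pi, pi), runif(1, 1.3, 2.9))
    qb <- c(runif(1, -pi, pi), runif(1, 1.3, 2.9))
    S <- electronic_overlap(m, qa, qb)
    expect_lt(max(abs(t(S) %*% S - diag(2))), 1e-14)
  }
  # near-unhindered diabatic crossing: character swap, off-diagonal +-1
  c1 <- curve1d_model(C = 1e-9)
  S <- electronic_overlap(c1, -3, 3)
  expect_lt(max(abs(diag(S))), 1e-3)
  expect_equal(abs(S[1, 2]), 1, tolerance = 1e-6)
})

test_that("invalid inputs are rejected", {
  m <- azo2d_model()
  expect_error(geometry(c(NA, 115), m$inertia), "non-finite")
  expect_error(geometry(c(180, 115), c(1, -1)), "strictly positive")
  expect_error(geometry(c(180), m$inertia), "equal length")
  expect_error(evaluate(m, c(Inf, 2)), "non-finite")
  expect_error(evaluate(m, 1), "coordinates")
  # torsion wrapping
  expect_equal(geometry(c(270, 115), m$inertia)$coords[1], deg_to_rad(-90))
})
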