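# Pulse-train representation, propagators, periodic steady state, and
# fingerprint simulation.

test_that("pulse_train validates its invariants and reports indices", {
  expect_error(pulse_train(c(0.1, 4, 0.2, 5), 3e-4), "indices 2, 4")
  expect_error(pulse_train(rep(0.1, 3), c(3e-4, 4e-3, 3e-4)), "indices 2")
  expect_error(pulse_train(rep(0.1, 3), 3e-4, tr = 1, cycle_time = 1),
               "cycle_time")
  tr <- pulse_train(rep(0.3, 10), 2e-4, tr = 3.5e-3, cycle_time = 0.1)
  expect_s3_class(tr, "qmt_train")
  expect_identical(tr$n_pulses, 10L)
  expect_identical(pulses_per_cycle(4, 3.5e-3), 1142)
})

test_that("interval propagator: identity, semigroup, and expm oracle", {
  A <- build_generator(wm_tissue(), wy = 800, wz = 150, r2sl = 5e4)
  expect_equal(interval_propagator(A, 0), diag(6))
  P1 <- interval_propagator(A, 1.3e-3)
  P2 <- interval_propagator(A, 0.9e-3)
  P12 <- interval_propagator(A, 2.2e-3)
  expect_equal(P2 %*% P1, P12, tolerance = 1e-12)
  # independent oracle: Matrix::expm (different algorithm/implementation)
  skip_if_not_installed("Matrix")
  expect_equal(P12, as.matrix(Matrix::expm(A * 2.2e-3)), tolerance = 1e-11)
  expect_error(interval_propagator(A, -1), "dt")
  A[1, 1] <- NaN
  expect_error(interval_propagator(A, 1e-3), "finite")
})

test_that("inversion operator: crusher contract, free-pool flip, semi-solid
           attenuation", {
  t <- wm_tissue()
  P <- inversion_operator(t, trf_inv = 5e-4)
  # post-state has no transverse components, exactly
  expect_identical(P[c(1, 2, 4), ], matrix(0, 3, 6))
  # adiabatic-free limit: T2f >> TRF so zf -> -zf within 1%
  m <- P %*% as.numeric(equilibrium_state(t))
  expect_equal(m[3], -t$m0f, tolerance = 0.01)
  # semi-solid attenuation matches the generalized-Bloch saturation when
  # relaxation/exchange during the pulse are negligible (tiny Rx, R1s --
  # the regime in which the saturation operation is defined)
  t2 <- tissue_pars(0.2, 1e-9, 15, 1e-9, 1e-9, 1e-5)
  P2 <- inversion_operator(t2, trf_inv = 5e-4, r2sl = "exact")
  m2 <- P2 %*% as.numeric(equilibrium_state(t2))
  expect_equal(m2[5] / t2$m0s, saturate_semisolid_pulse(pi, 5e-4, 1e-5),
               tolerance = 1e-6)
})

test_that("cycle propagator: free-evolution limit and sequential oracle", {
  t <- wm_tissue()
  sys <- system_pars()
  # zero flip angles, no inversion: the longitudinal sub-dynamics reduce to
  # the pure two-pool relaxation over cycle_time
  n <- 20
  tr0 <- pulse_train(rep(0, n), 3e-4, tr = 3.5e-3, cycle_time = 0.4,
                     inversion = FALSE)
  M <- cycle_propagator(tr0, t, sys)
  H <- longitudinal_hamiltonian(t)
  skip_if_not_installed("Matrix")
  expect_equal(M[c(3, 5, 6), c(3, 5, 6)],
               as.matrix(Matrix::expm(H * 0.4)), tolerance = 1e-10)
  expect_identical(M[6, ], c(0, 0, 0, 0, 0, 1))
  # constant-alpha train: matches brute-force step-by-step composition with
  # Matrix::expm propagators
  tr1 <- const_train(n = 12, alpha = pi / 8)
  g <- r2sl_grid()
  P <- diag(6)
  Pi <- inversion_operator(t, tr1$trf_inv, r2sl = "grid")
  P <- Pi %*% P
  for (k in seq_len(tr1$n_pulses)) {
    sgn <- if (k %% 2 == 1) 1 else -1
    r2sl <- r2sl_lookup(g, tr1$alpha[k], tr1$trf[k], t$T2s)
    Ap <- build_generator(t, sgn * tr1$alpha[k] / tr1$trf[k], 0, r2sl)
    Af <- build_generator(t, 0, 0, 1 / t$T2s)
    P <- as.matrix(Matrix::expm(Af * (tr1$tr - tr1$trf[k]))) %*%
      as.matrix(Matrix::expm(Ap * tr1$trf[k])) %*% P
  }
  P <- as.matrix(Matrix::expm(
    build_generator(t, 0, 0, 1 / t$T2s) *
      (tr1$cycle_time - tr1$n_pulses * tr1$tr))) %*% P
  expect_equal(cycle_propagator(tr1, t, sys), P, tolerance = 1e-9)
})

test_that("periodic state: equilibrium, fixed point, power iteration", {
  t <- wm_tissue()
  sys <- system_pars()
  # no pulses (alpha = 0), no inversion: thermal equilibrium
  tr0 <- pulse_train(rep(0, 10), 3e-4, tr = 3.5e-3, cycle_time = 1,
                     inversion = FALSE)
  M <- cycle_propagator(tr0, t, sys)
  m <- periodic_state(M)
  expect_equal(as.numeric(m), as.numeric(equilibrium_state(t)),
               tolerance = 1e-9)
  # fixed-point residual and power-iteration oracle on a real train
  tr1 <- test_train(150)
  M <- cycle_propagator(tr1, t, sys)
  m <- periodic_state(M)
  expect_lt(max(abs(M %*% as.numeric(m) - as.numeric(m))), 1e-10)
  y <- as.numeric(equilibrium_state(t))
  for (i in 1:200) y <- as.numeric(M %*% y)
  expect_equal(as.numeric(m), y, tolerance = 1e-8)
})

test_that("fingerprint: M0 linearity, signal bound, phase conventions", {
  t <- wm_tissue()
  tr <- test_train(100)
  s1 <- simulate_fingerprint(tr, t, system_pars(M0 = 1 + 0i))
  s2 <- simulate_fingerprint(tr, t, system_pars(M0 = 2 + 0i))
  expect_equal(as.complex(s2), 2 * as.complex(s1), tolerance = 1e-14)
  sc <- simulate_fingerprint(tr, t, system_pars(M0 = 0.6 - 0.8i))
  expect_equal(as.complex(sc), (0.6 - 0.8i) * as.complex(s1),
               tolerance = 1e-14)
  expect_true(all(Mod(s1) <= t$m0f + 1e-12))
  # a global pi phase shift of the RF (sign flip of every pulse) only flips
  # the sign of the demodulated signal; magnitudes are anchored by the
  # inversion pulse and are NOT invariant under cyclic shifts of the pattern
  tr_shift <- pulse_train(c(tr$alpha[-1], tr$alpha[1]),
                          c(tr$trf[-1], tr$trf[1]), tr = tr$tr,
                          cycle_time = tr$cycle_time, trf_inv = tr$trf_inv)
  s3 <- simulate_fingerprint(tr_shift, t, system_pars())
  expect_gt(max(Mod(as.complex(s3) - as.complex(s1))), 1e-4)
})

test_that("fingerprint vs adaptive ODE integration (reduced train)", {
  t <- wm_tissue()
  sys <- system_pars(wz = 2 * pi * 15, b1 = 1.05, M0 = 1 + 0i)
  tr <- test_train(40, tr = 3.5e-3, cycle_time = 0.145)
  s <- simulate_fingerprint(tr, t, sys)
  m <- periodic_state(cycle_propagator(tr, t, sys))
  s_ode <- ode_fingerprint(tr, t, sys, m, rtol = 1e-11)
  expect_lt(max(Mod(as.complex(s) - s_ode)), 1e-6 * Mod(sys$M0))
})

test_that("fingerprints are smooth in the tissue parameters", {
  # central finite differences are stable under step halving, i.e. the
  # derivative estimate changes by < 1e-4 relative (smoothness of the model
  # through the R2s,l interpolation included)
  t <- wm_tissue(); sys <- system_pars()
  tr <- test_train(60, tr = 3.5e-3, cycle_time = 0.215)
  th0 <- c(m0s = t$m0s, R1f = t$R1f, R2f = t$R2f, Rx = t$Rx, R1s = t$R1s,
           T2s = t$T2s, wz = 0, b1 = 1, M0re = 1, M0im = 0)
  for (p in c("m0s", "R1f", "R2f", "Rx", "R1s", "T2s")) {
    d <- list()
    for (f in c(1, 0.5)) {
      h <- f * 1e-4 * abs(th0[[p]])
      tp <- th0; tp[p] <- tp[p] + h
      tm <- th0; tm[p] <- tm[p] - h
      pp <- qmtr:::theta_to_pars(tp); pm <- qmtr:::theta_to_pars(tm)
      d[[as.character(f)]] <-
        (as.complex(simulate_fingerprint(tr, pp$tissue, pp$sys)) -
         as.complex(simulate_fingerprint(tr, pm$tissue, pm$sys))) / (2 * h)
    }
    rel <- max(Mod(d[["1"]] - d[["0.5"]])) / max(Mod(d[["0.5"]]))
    expect_lt(rel, 1e-4)
  }
})
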