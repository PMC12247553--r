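# Domain types, super-Lorentzian Green's function, generalized-Bloch
# saturation, linearized R2s, and the Bloch-McConnell generator.

test_that("tissue, system, and state types enforce their invariants", {
  t <- wm_tissue()
  expect_identical(t$m0f + t$m0s, 1)
  expect_error(tissue_pars(1, 1, 1, 1, 1, 1e-5), "m0s")
  expect_error(tissue_pars(0.2, -1, 1, 1, 1, 1e-5), "rates")
  expect_error(tissue_pars(0.2, 1, 1, 1, 1, 0), "T2s")
  expect_silent(tissue_pars(0, 1, 1, 1, 1, 1e-5))  # m0s = 0 is allowed
  expect_error(system_pars(b1 = 0), "b1")
  expect_error(system_pars(M0 = 0), "M0")
  st <- equilibrium_state(t)
  expect_identical(unname(st[6]), 1)
  expect_error(spin_state(zf = 1, tissue = t), "m0f")
  expect_error(spin_state(zs = 0.5, tissue = t), "zs")
})

test_that("Green's function: endpoints, monotonicity, quadrature oracle", {
  expect_identical(superlorentzian_green(0, 1e-5), 1)
  T2s <- 1e-5
  expect_lt(superlorentzian_green(2 * T2s, T2s),
            superlorentzian_green(T2s, T2s))
  # frozen from adaptive quadrature (stats::integrate, rel.tol 1e-12)
  expect_equal(superlorentzian_green(T2s, T2s), 0.909705357723634,
               tolerance = 1e-10)
  # fresh quadrature oracle across a range of lags
  x <- c(0.3, 1.7, 5, 20, 80)
  expect_equal(superlorentzian_green(x * T2s, T2s), green_oracle(x),
               tolerance = 1e-9)
  # bounded in (0, 1] and non-increasing over tau in [0, 100 T2s]
  g <- superlorentzian_green(seq(0, 100, length.out = 400) * T2s, T2s)
  expect_true(all(g > 0 & g <= 1))
  expect_true(all(diff(g) <= 1e-15))
  expect_error(superlorentzian_green(-1e-6, T2s), "tau")
  expect_error(superlorentzian_green(1e-6, -1), "T2s")
})

test_that("generalized-Bloch saturation: limits and fine-step oracle", {
  expect_identical(saturate_semisolid_pulse(0, 3e-4, 1e-5), 1)
  # vanishing-lineshape limit: T2s -> 0 at fixed alpha, TRF
  trf <- 3e-4
  expect_equal(saturate_semisolid_pulse(pi / 4, trf, trf / 1e4), 1,
               tolerance = 1e-3)
  # frozen from the >= 1e4-step product-integration oracle in
  # helper-oracles.R (volterra_oracle(pi/2, 300e-6, 1e-5, n = 12800))
  expect_equal(saturate_semisolid_pulse(pi / 2, 300e-6, 1e-5),
               0.675842409603, tolerance = 1e-6)
  expect_error(saturate_semisolid_pulse(pi / 2, -1, 1e-5), "trf")
  expect_error(saturate_semisolid_pulse(pi / 2, 3e-4, 1e-5, n_steps = 8),
               "minimum")
})

test_that("linearized R2s,l: convention, frozen example, self-consistency", {
  expect_identical(linearize_r2s(0, 3e-4, 1e-5), 0)
  # frozen from bisection of the 2x2 closed form (Matrix::expm) against the
  # fine-step Volterra oracle: R2s,l(pi, 500us, 10us) = 16013.651 /s
  expect_equal(linearize_r2s(pi, 500e-6, 1e-5), 16013.6512258,
               tolerance = 1e-6)
  # defining property: re-propagating (xs, zs) with the returned rate
  # reproduces the generalized-Bloch zs at pulse end
  for (case in list(c(pi / 2, 300e-6, 1e-5), c(0.4, 1e-4, 12.5e-6),
                    c(2.5, 8e-4, 2e-5))) {
    a <- case[1]; trf <- case[2]; T2s <- case[3]
    R <- linearize_r2s(a, trf, T2s)
    zs_lin <- lin_zs_end_cpp(a, trf / T2s, R * T2s)
    expect_equal(zs_lin, saturate_semisolid_pulse(a, trf, T2s),
                 tolerance = 1e-8)
  }
})

test_that("R2s,l grid: interpolation accuracy and self-consistency", {
  g <- r2sl_grid()
  expect_true(all(is.finite(g$values)) && all(g$values >= 0))
  # held-out points (off the lattice): bicubic lookup within 1% of direct
  set.seed(11)
  for (i in 1:12) {
    a <- runif(1, 0.15, 3.1)  # direct (exact-root) regime
    r <- exp(runif(1, log(1), log(600)))
    T2s <- 1e-5
    direct <- linearize_r2s(a, r * T2s, T2s)
    interp <- r2sl_lookup(g, a, r * T2s, T2s)
    expect_lt(abs(interp - direct) / direct, 0.01)
  }
  # self-consistency residual across grid nodes: propagating with the grid
  # rate reproduces the generalized-Bloch end value
  ia <- seq(2, length(g$alpha_nodes), by = 6)
  ia <- ia[g$alpha_nodes[ia] <= pi]  # exact-match regime
  il <- seq(1, length(g$logr_nodes), by = 6)
  for (i in ia) for (j in il) {
    a <- g$alpha_nodes[i]; r <- exp(g$logr_nodes[j])
    zs <- volterra_cpp(a, r, green_table(), .qmtr_grid_spec$gdx, 0L, TRUE)
    expect_equal(lin_zs_end_cpp(a, r, g$values[i, j]), zs,
                 tolerance = 1e-8)
  }
})

test_that("grid serialization round-trips (values and axes preserved)", {
  g <- r2sl_grid()
  path <- tempfile(fileext = ".json")
  write_r2sl_grid(g, path)
  g2 <- read_r2sl_grid(path)
  expect_equal(g2$values, g$values, tolerance = 1e-14)
  expect_equal(g2$alpha_nodes, g$alpha_nodes)
  expect_equal(r2sl_lookup(g2, 1.1, 3e-4, 1e-5),
               r2sl_lookup(g, 1.1, 3e-4, 1e-5))
})

test_that("generator layout matches the two-pool Bloch-McConnell equation", {
  t <- wm_tissue()
  A <- build_generator(t, wy = 2000, wz = 300, r2sl = 1e4)
  expect_identical(A[6, ], rep(0, 6))  # bottom row: homogeneous coordinate
  # longitudinal sub-matrix at wy = 0 equals the 3x3 longitudinal
  # Hamiltonian exactly
  A0 <- build_generator(t, wy = 0, wz = 0, r2sl = 1e4)
  expect_identical(A0[c(3, 5, 6), c(3, 5, 6)], longitudinal_hamiltonian(t))
  # antisymmetric rotation couplings
  expect_identical(A[1, 3], -A[3, 1])
  expect_identical(A[4, 5], -A[5, 4])
  expect_identical(A[1, 2], -A[2, 1])
  # exchange and drive terms
  expect_equal(A[3, 5], t$Rx * t$m0f)
  expect_equal(A[5, 3], t$Rx * t$m0s)
  expect_equal(A[3, 6], t$m0f * t$R1f)
  expect_equal(A[5, 6], t$m0s * t$R1s)
  # compiled core assembles the identical matrix
  expect_equal(generator_cpp(t$m0s, t$R1f, t$R2f, t$Rx, t$R1s, t$T2s,
                             2000, 300, 1e4), A)
})

test_that("generator dynamics: closed-form and ODE oracles", {
  t <- wm_tissue()
  # with wy = 0 and Rx = 0, zf relaxes mono-exponentially to m0f with R1f
  t0 <- tissue_pars(t$m0s, t$R1f, t$R2f, 1e-12, t$R1s, t$T2s)
  A <- build_generator(t0, 0, 0, 1e4)
  y <- as.numeric(equilibrium_state(t0)); y[3] <- -t0$m0f
  for (dt in c(0.1, 0.5, 2)) {
    yt <- expm_cpp(A * dt) %*% y
    expect_equal(yt[3], t0$m0f * (1 - 2 * exp(-t0$R1f * dt)),
                 tolerance = 1e-10)
  }
  # expm propagation over 1 ms agrees with adaptive ODE integration
  A <- build_generator(t, wy = 1500, wz = 200, r2sl = 8e4)
  y0 <- as.numeric(equilibrium_state(t))
  y0[1] <- 0.3; y0[3] <- 0.5; y0[5] <- 0.15
  y_expm <- as.numeric(expm_cpp(A * 1e-3) %*% y0)
  y_ode <- rk45_lin(A, y0, 1e-3, rtol = 1e-11, atol = 1e-14)
  expect_equal(y_expm, y_ode, tolerance = 1e-9)
  # homogeneous coordinate preserved exactly
  expect_identical(y_expm[6], 1)
})
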