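# Dictionaries, subspaces, voxel fitting, and mono-exponential recovery.

test_that("dictionary: single atom, determinism, element-wise oracle", {
  tr <- test_train(50, tr = 3.5e-3, cycle_time = 0.18)
  d1 <- build_dictionary(list(m0s = 0.2), tr)
  th <- qmtr:::.qmt_default_start; th["m0s"] <- 0.2
  pr <- qmtr:::theta_to_pars(th)
  expect_equal(d1$fingerprints[, 1],
               as.complex(simulate_fingerprint(tr, pr$tissue, pr$sys)))
  # deterministic across rebuilds
  spec <- list(m0s = c(0.1, 0.2, 0.3), R1f = c(0.4, 0.6, 0.9))
  da <- build_dictionary(spec, tr)
  db <- build_dictionary(spec, tr)
  expect_identical(da$fingerprints, db$fingerprints)
  expect_identical(nrow(da$atoms), 9L)
  # each atom equals an individually simulated fingerprint
  for (i in c(1, 5, 9)) {
    th <- qmtr:::.qmt_default_start
    th["m0s"] <- da$atoms$m0s[i]; th["R1f"] <- da$atoms$R1f[i]
    pr <- qmtr:::theta_to_pars(th)
    expect_equal(da$fingerprints[, i],
                 as.complex(simulate_fingerprint(tr, pr$tissue, pr$sys)))
  }
  expect_error(build_dictionary(list(), tr), "empty")
  expect_error(build_dictionary(list(m0s = c(0.3, 0.1)), tr), "increasing")
})

test_that("subspace: orthonormality, exact reconstruction, compression", {
  tr <- test_train(30, tr = 3.5e-3, cycle_time = 0.11)
  spec <- list(m0s = seq(0.05, 0.35, length.out = 5),
               R1f = c(0.35, 0.55, 0.8), T2s = c(8e-6, 12.5e-6, 18e-6))
  dict <- build_dictionary(spec, tr)
  sub <- fingerprint_subspace(dict, rank = 15)
  G <- Conj(t(sub$basis)) %*% sub$basis
  expect_lt(max(Mod(G - diag(15))), 1e-10)
  expect_lt(sub$max_projection_error, 1e-3)  # smooth manifold, rank 15
  # rank = n_pulses: zero projection error
  subf <- fingerprint_subspace(dict, rank = 30)
  expect_lt(subf$max_projection_error, 1e-9)
  expect_error(fingerprint_subspace(dict, rank = 100), "rank")
  # compress: basis columns map to unit vectors; in-subspace norms preserved
  cf <- compress_fingerprint(sub$basis[, 3], sub)
  expect_equal(Mod(cf), c(0, 0, 1, rep(0, 12)), tolerance = 1e-10)
  s <- dict$fingerprints[, 7]
  cf <- compress_fingerprint(s, sub)
  expect_equal(sqrt(sum(Mod(cf)^2)), sqrt(sum(Mod(s)^2)),
               tolerance = sub$max_projection_error * 2)
  # normalized coefficients are invariant to a global complex scale
  c1 <- compress_fingerprint(s, sub, normalize = TRUE)
  c2 <- compress_fingerprint((0.3 - 1.2i) * s, sub, normalize = TRUE)
  expect_equal(c1, c2, tolerance = 1e-10)
  expect_error(compress_fingerprint(s[1:7], sub), "dimension")
})

test_that("fit_voxel: exact recovery and truth-start zero residual", {
  t <- wm_tissue()
  sys <- system_pars(wz = 2 * pi * 8, b1 = 1.04, M0 = 0.8 + 0.4i)
  tr <- test_train(150)
  s <- as.complex(simulate_fingerprint(tr, t, sys))
  truth <- qmtr:::pars_to_theta(t, sys)
  # init at ground truth on noiseless data: zero residual immediately
  f0 <- fit_voxel(s, tr, init = truth)
  expect_lt(f0$cost, 1e-18)
  expect_true(f0$converged)
  # perturbed init (+-20%): all six tissue parameters recovered to 0.1%
  set.seed(3)
  init <- truth
  init[1:8] <- truth[1:8] * runif(8, 0.8, 1.2)
  f <- fit_voxel(s, tr, init = init, maxit = 80)
  rel <- abs(f$estimates - truth)[1:6] / abs(truth[1:6])
  expect_lt(max(rel), 1e-3)
  expect_error(fit_voxel(rep(0 + 0i, length(s)), tr), "all-zero")
})

test_that("constraining R1s := R1f biases the pool size downward", {
  # inversion-recovery data generated with R1s > R1f, fitted with the
  # constrained model R1s := R1f: the apparent-parameter theory predicts
  # the fitted pool size undershoots the generating one and the fitted
  # free-pool rate overshoots (T1f under-estimated)
  gen <- tissue_pars(0.2, 0.5, 15, 15, 3, 1.25e-5)
  ti <- seq(0.02, 6, by = 0.05)
  zf_of <- function(tissue) {
    H <- longitudinal_hamiltonian(tissue)
    # affine dynamics via eigen-decomposition of the homogeneous 3x3
    E <- eigen(H)
    y0 <- c(-tissue$m0f, tissue$m0s, 1)  # T2-selective inversion
    c0 <- solve(E$vectors, y0)
    vapply(ti, function(tp)
      Re((E$vectors %*% (exp(E$values * tp) * c0))[1]), numeric(1))
  }
  zf <- zf_of(gen)
  cfit <- function(p) {
    if (p[1] <= 0.01 || p[1] >= 0.9 || p[2] <= 0 || p[3] <= 0) return(1e6)
    sum((zf_of(tissue_pars(p[1], p[2], 15, p[3], p[2], 1.25e-5)) - zf)^2)
  }
  o <- optim(c(0.2, 0.5, 15), cfit, control = list(maxit = 2000,
                                                   reltol = 1e-12))
  # the time-domain least-squares fit weights the eigenmodes differently
  # than the pure eigenvector matching behind the Taylor expansion, so only
  # the direction of the bias is asserted, not its Taylor magnitude
  expect_lt(o$par[1], gen$m0s)   # m0s under-estimated
  expect_gt(o$par[2], gen$R1f)   # R1f over-estimated (shorter apparent T1f)
})

test_that("subspace fitting and first-coefficient normalization", {
  t <- wm_tissue(); sys <- system_pars(M0 = 1.5 + 0i)
  tr <- test_train(100)
  spec <- list(m0s = seq(0.08, 0.32, length.out = 4),
               R1f = c(0.35, 0.55, 0.8), R1s = c(2, 3, 4.5))
  dict <- build_dictionary(spec, tr)
  sub <- fingerprint_subspace(dict, rank = 15)
  s <- as.complex(simulate_fingerprint(tr, t, sys))
  truth <- qmtr:::pars_to_theta(t, sys)
  init <- truth
  init[1:6] <- truth[1:6] * 1.1
  f_full <- fit_voxel(s, tr, init = init, maxit = 60)
  f_sub <- fit_voxel(s, tr, subspace = sub, init = init, maxit = 60)
  # subspace estimates deviate by no more than the projection error allows
  rel <- abs(f_sub$estimates[1:6] - f_full$estimates[1:6]) / truth[1:6]
  expect_lt(max(rel), 10 * sub$max_projection_error + 1e-6)
  # normalization removes M0 from the unknown set but not the tissue fit
  f_norm <- fit_voxel(s, tr, subspace = sub, normalize = TRUE,
                      init = init, maxit = 60)
  expect_false("M0re" %in% f_norm$free)
  rel <- abs(f_norm$estimates[1:6] - truth[1:6]) / truth[1:6]
  expect_lt(max(rel), 1e-2)
})

test_that("fit_map matches scalar fits and respects the mask", {
  wm <- wm_tissue(); gm <- gm_tissue()
  tr <- test_train(100)
  sys <- system_pars()
  img <- array(0 + 0i, c(2, 1, 1, tr$n_pulses))
  img[1, 1, 1, ] <- as.complex(simulate_fingerprint(tr, wm, sys))
  img[2, 1, 1, ] <- as.complex(simulate_fingerprint(tr, gm, sys))
  mask <- array(c(TRUE, FALSE), c(2, 1, 1))
  init <- qmtr:::pars_to_theta(wm, sys)
  maps <- fit_map(img, mask, tr, init = init, maxit = 50)
  f1 <- fit_voxel(img[1, 1, 1, ], tr, init = init, maxit = 50)
  expect_equal(maps$m0s[1, 1, 1], f1$estimates[["m0s"]], tolerance = 1e-10)
  expect_equal(maps$R1f[1, 1, 1], f1$estimates[["R1f"]], tolerance = 1e-10)
  # masked voxels untouched
  expect_true(is.na(maps$m0s[2, 1, 1]))
  expect_identical(attr(maps, "n_failed"), 0L)
  expect_error(fit_map(img, array(TRUE, c(3, 1, 1)), tr), "mismatch")
})

test_that("mono-exponential recovery fitting", {
  # exact single exponential: rate recovered to 1e-8
  tt <- seq(0, 6, by = 0.25)
  y <- 1 - 2 * exp(-0.5435 * tt)
  R <- fit_monoexp(tt, y)
  expect_equal(as.numeric(R), 0.5435, tolerance = 1e-8)
  # constant signal: zero rate
  expect_lt(abs(as.numeric(fit_monoexp(tt, rep(2, length(tt))))), 1e-6)
  expect_error(fit_monoexp(c(0, 1), c(1, 2)), "3")
  # bi-exponential two-pool recovery with both pools equally inverted,
  # sampled late (TI >> 1/Rx_a): rate within 1% of the exact eigenvalue
  t <- wm_tissue()
  H <- longitudinal_hamiltonian(t)
  rates <- exact_apparent_rates(t)
  skip_if_not_installed("Matrix")
  ti <- seq(0.3, 6, by = 0.15)  # 0.3 s >> 1/Rx_a ~ 0.06 s
  y0 <- c(-t$m0f, -t$m0s, 1)
  zf <- vapply(ti, function(tp)
    (as.matrix(Matrix::expm(H * tp)) %*% y0)[1], numeric(1))
  R <- fit_monoexp(ti, zf)
  expect_equal(as.numeric(R), unname(rates["R1f_a"]), tolerance = 0.01)
})
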