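# Digital phantom, noise injection, and Monte-Carlo experiments.

#' Default tissue classes for the digital phantom
#'
#' Healthy-control ROI means for white matter and cortical gray matter
#' (converted to rates from the characteristic times: WM m0s 0.212,
#' T1f 1.84 s, T2f 76.9 ms, Rx 13.6/s, T1s 0.34 s, T2s 12.5 us; cortical GM
#' analogously), plus a CSF-like class with a near-vanishing semi-solid
#' pool. Standard deviations (same source, delta-method-converted to rate
#' units) drive the optional per-voxel jitter.
#'
#' @return `data.frame` with one row per class (`label`, parameter columns,
#'   `sd_*` columns).
#' @export
qmt_default_classes <- function() {
  data.frame(
    name = c("WM", "GM", "CSF"),
    label = c(1L, 2L, 3L),
    m0s = c(0.212, 0.098, 0.005),
    R1f = c(1 / 1.84, 1 / 2.46, 0.25),
    R2f = c(1 / 0.0769, 1 / 0.083, 0.5),
    Rx = c(13.6, 14.0, 13.6),
    R1s = c(1 / 0.34, 1 / 0.42, 2.0),
    T2s = c(12.5e-6, 14.4e-6, 12.0e-6),
    sd_m0s = c(0.022, 0.026, 0),
    sd_R1f = c(0.17 / 1.84^2, 0.56 / 2.46^2, 0),
    sd_R2f = c(0.0083 / 0.0769^2, 0.015 / 0.083^2, 0),
    sd_Rx = c(1.1, 3.1, 0),
    sd_R1s = c(0.10 / 0.34^2, 0.40 / 0.42^2, 0),
    sd_T2s = c(1.8e-6, 3.9e-6, 0),
    stringsAsFactors = FALSE)
}

#' Digital phantom: concentric ellipsoids with smooth field maps
#'
#' Builds a deterministic (seeded) 3-D phantom of nested ellipsoids -- a
#' CSF-like core, a gray-matter shell, and a white-matter bulk -- with
#' per-class ground-truth tissue parameters, smooth low-order polynomial
#' off-resonance (`wz`) and transmit (`b1`) field maps, and optional
#' per-voxel Gaussian jitter of the tissue values.
#'
#' @param shape Integer vector of 3 dimensions, each >= 8.
#' @param classes Class table as from [qmt_default_classes()].
#' @param wz_range Off-resonance range, rad/s (smooth map spans it).
#' @param b1_range Transmit-scale range.
#' @param jitter Add per-voxel Gaussian variation with the class `sd_*`
#'   columns (truncated to valid parameter ranges).
#' @param seed Integer seed; rebuilds are bit-identical for a fixed seed.
#' @return Object of class `qmt_phantom`: `label` array, `truth` (named
#'   list of parameter arrays incl. `wz`, `b1`), the class table and seed.
#' @export
make_phantom <- function(shape = c(16, 16, 16),
                         classes = qmt_default_classes(),
                         wz_range = 2 * pi * c(-30, 30),
                         b1_range = c(0.9, 1.1),
                         jitter = FALSE, seed = 1) {
  if (length(shape) != 3 || any(shape < 8))
    stop("make_phantom: shape must be 3-D with each dimension >= 8")
  if (!nrow(classes)) stop("make_phantom: empty class table")
  for (i in seq_len(nrow(classes)))  # validates invariants
    tissue_pars(classes$m0s[i], classes$R1f[i], classes$R2f[i],
                classes$Rx[i], classes$R1s[i], classes$T2s[i])
  set.seed(seed)
  u <- lapply(shape, function(n) seq(-1, 1, length.out = n))
  X <- array(rep(u[[1]], times = shape[2] * shape[3]), shape)
  Y <- array(rep(rep(u[[2]], each = shape[1]), times = shape[3]), shape)
  Z <- array(rep(u[[3]], each = shape[1] * shape[2]), shape)
  rho <- sqrt((X / 0.90)^2 + (Y / 0.85)^2 + (Z / 0.88)^2)
  label <- array(0L, shape)
  label[rho < 1.00] <- classes$label[1]           # WM bulk
  if (nrow(classes) > 1) label[rho < 0.55] <- classes$label[2]  # GM shell
  if (nrow(classes) > 2) label[rho < 0.25] <- classes$label[3]  # CSF core
  # smooth second-order polynomial field maps, rescaled to the stated ranges
  span <- function(f, range) {
    f <- f - min(f)
    if (max(f) > 0) f <- f / max(f)
    range[1] + f * (range[2] - range[1])
  }
  wz <- span(0.3 * X + 0.5 * Y - 0.2 * Z + 0.6 * X * Y + 0.4 * Z^2, wz_range)
  b1 <- span(1 - 0.5 * (X^2 + 0.8 * Y^2 + 1.2 * Z^2), b1_range)
  pars <- c("m0s", "R1f", "R2f", "Rx", "R1s", "T2s")
  truth <- lapply(pars, function(p) array(NA_real_, shape))
  names(truth) <- pars
  lo <- c(m0s = 0, R1f = 1e-3, R2f = 1e-3, Rx = 1e-3, R1s = 1e-3, T2s = 1e-7)
  for (i in seq_len(nrow(classes))) {
    vox <- which(label == classes$label[i])
    for (p in pars) {
      val <- rep(classes[[p]][i], length(vox))
      if (jitter && classes[[paste0("sd_", p)]][i] > 0)
        val <- pmax(val + rnorm(length(vox),
                                sd = classes[[paste0("sd_", p)]][i]),
                    lo[[p]])
      if (p == "m0s") val <- pmin(val, 0.999)
      truth[[p]][vox] <- val
    }
  }
  truth$wz <- wz; truth$b1 <- b1
  structure(list(label = label, truth = truth, classes = classes,
                 shape = shape, seed = seed,
                 wz_range = wz_range, b1_range = b1_range,
                 jitter = jitter),
            class = "qmt_phantom")
}

#' Simulate the 4-D fingerprint image of a phantom
#'
#' One fingerprint per labeled voxel (background voxels stay zero).
#'
#' @param phantom A `qmt_phantom`.
#' @param train A `qmt_train`.
#' @param M0 Complex scale applied to every voxel.
#' @return 4-D complex array `shape x n_pulses`.
#' @export
phantom_image <- function(phantom, train, M0 = 1 + 0i) {
  d <- c(phantom$shape, train$n_pulses)
  img <- array(0 + 0i, d)
  idx <- which(phantom$label > 0, arr.ind = TRUE)
  tr <- phantom$truth
  for (v in seq_len(nrow(idx))) {
    i <- idx[v, 1]; j <- idx[v, 2]; k <- idx[v, 3]
    tis <- tissue_pars(tr$m0s[i, j, k], tr$R1f[i, j, k], tr$R2f[i, j, k],
                       tr$Rx[i, j, k], tr$R1s[i, j, k], tr$T2s[i, j, k])
    sys <- system_pars(tr$wz[i, j, k], tr$b1[i, j, k], M0)
    img[i, j, k, ] <- as.complex(simulate_fingerprint(train, tis, sys))
  }
  img
}

#' Add complex white Gaussian noise
#'
#' i.i.d. Gaussian noise of standard deviation `sigma` added independently
#' to the real and imaginary channel of every sample -- the noise model
#' under which the package's CRB computations apply.
#'
#' @param x Complex vector/array of signals.
#' @param sigma Per-channel noise standard deviation, `>= 0`.
#' @param seed Optional seed for reproducible draws (restores the caller's
#'   RNG state afterwards).
#' @return `x` plus noise, same shape.
#' @export
add_noise <- function(x, sigma, seed = NULL) {
  if (sigma < 0) stop("add_noise: sigma must be >= 0")
  if (sigma == 0) return(x)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  n <- length(x)
  x + array(complex(real = rnorm(n, 0, sigma),
                    imaginary = rnorm(n, 0, sigma)),
            dim = dim(x) %||% n)
}

#' Noise level for a target SNR
#'
#' SNR is referenced to the signal magnitude at the largest-|signal| time
#' point of the fingerprint: `sigma = max_n |s_n| / SNR` per channel.
#'
#' @param fingerprint Complex fingerprint (as simulated for the voxel).
#' @param snr Target SNR.
#' @return Per-channel noise standard deviation.
#' @export
snr_sigma <- function(fingerprint, snr) {
  max(Mod(as.complex(fingerprint))) / snr
}

#' Monte-Carlo consistency of estimator noise with the CRB
#'
#' Repeats simulate -> add noise -> fit and tabulates, per unknown, the
#' estimator bias, the standard deviation, and its ratio to the CRB
#' prediction `sqrt(CRB)`. Fits start at the ground truth (the standard
#' setting for checking CRB attainment, i.e. estimator efficiency rather
#' than global convergence).
#'
#' @param tissue,sys Ground-truth parameter point.
#' @param train A `qmt_train`.
#' @param sigma Per-channel noise standard deviation.
#' @param n_reps Number of noise draws (>= 50).
#' @param seed Seed; results are deterministic given it.
#' @param unknowns Unknowns fitted and tabulated.
#' @param maxit Iteration cap per fit.
#' @return `data.frame` per unknown: `truth`, `bias`, `std`, `sqrt_crb`,
#'   `ratio`; failed-fit count in attribute `n_failed` (flagged via warning
#'   above 20%).
#' @export
monte_carlo <- function(tissue, sys, train, sigma, n_reps = 200, seed = 1,
                        unknowns = QMT_UNKNOWNS, maxit = 80) {
  if (n_reps < 50) stop("monte_carlo: n_reps must be >= 50")
  fp <- as.complex(simulate_fingerprint(train, tissue, sys))
  J <- fingerprint_jacobian(train, tissue, sys, unknowns)
  crb <- crb_values(fisher_information(J, sigma^2))
  truth <- pars_to_theta(tissue, sys)
  est <- matrix(NA_real_, n_reps, length(unknowns),
                dimnames = list(NULL, unknowns))
  n_failed <- 0L
  for (r in seq_len(n_reps)) {
    obs <- add_noise(fp, sigma, seed = seed + r)
    res <- tryCatch(
      fit_voxel(obs, train, init = truth[QMT_UNKNOWNS], free = unknowns,
                maxit = maxit),
      error = function(e) NULL)
    if (is.null(res) || !res$converged) { n_failed <- n_failed + 1L; next }
    est[r, ] <- res$estimates[unknowns]
  }
  if (n_failed > 0.2 * n_reps)
    warning(sprintf("monte_carlo: %d/%d fits failed", n_failed, n_reps))
  ok <- stats::complete.cases(est)
  out <- data.frame(
    unknown = unknowns,
    truth = unname(truth[unknowns]),
    bias = colMeans(est[ok, , drop = FALSE]) - truth[unknowns],
    std = apply(est[ok, , drop = FALSE], 2, stats::sd),
    sqrt_crb = sqrt(unname(crb)),
    row.names = NULL, stringsAsFactors = FALSE)
  out$ratio <- out$std / out$sqrt_crb
  attr(out, "n_failed") <- n_failed
  attr(out, "sigma") <- sigma
  out
}
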