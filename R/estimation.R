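# Dictionaries, SVD subspaces, voxel-wise NLLS fitting, and
# mono-exponential recovery fitting.

#' Default fit bounds for the voxel model
#'
#' Box bounds enclosing the physiologic ranges (white/gray matter and the
#' CRB reference values) with margin: `m0s` in [0, 0.5], `R1f` in [0.1, 5]/s,
#' `R2f` in [1, 50]/s, `Rx` in [1, 100]/s, `R1s` in [0.1, 20]/s, `T2s` in
#' [1, 30] us, `wz` within +/- 2 pi 200 rad/s, `b1` in [0.5, 1.5].
#'
#' @return List with named vectors `lower` and `upper` over [QMT_UNKNOWNS].
#' @export
qmt_default_bounds <- function() {
  list(lower = c(m0s = 1e-4, R1f = 0.1, R2f = 1, Rx = 1, R1s = 0.1,
                 T2s = 1e-6, wz = -2 * pi * 200, b1 = 0.5,
                 M0re = -1e3, M0im = -1e3),
       upper = c(m0s = 0.5, R1f = 5, R2f = 50, Rx = 100, R1s = 20,
                 T2s = 30e-6, wz = 2 * pi * 200, b1 = 1.5,
                 M0re = 1e3, M0im = 1e3))
}

# generic default start (fixed physiologic values, mid-range)
.qmt_default_start <- c(m0s = 0.2, R1f = 0.6, R2f = 14, Rx = 15, R1s = 3,
                        T2s = 1.2e-5, wz = 0, b1 = 1, M0re = 1, M0im = 0)

#' Build a fingerprint dictionary over a parameter grid
#'
#' Simulates one fingerprint per atom of the Cartesian product of the given
#' parameter values. Unlisted parameters are held at the defaults in
#' `base_theta`.
#'
#' @param grid_spec Named list of numeric vectors (names from
#'   [QMT_UNKNOWNS], excluding `M0re`/`M0im`: dictionaries are built at
#'   `M0 = 1`), each strictly increasing.
#' @param train A `qmt_train`.
#' @param base_theta Named base values for parameters not in `grid_spec`.
#' @return Object of class `qmt_dictionary`: complex matrix `fingerprints`
#'   (`n_pulses x n_atoms`), the atom parameter table `atoms`, and the grid
#'   axes.
#' @export
build_dictionary <- function(grid_spec, train,
                             base_theta = .qmt_default_start) {
  if (!length(grid_spec)) stop("build_dictionary: empty grid")
  stopifnot(all(names(grid_spec) %in% setdiff(QMT_UNKNOWNS,
                                              c("M0re", "M0im"))))
  for (v in grid_spec)
    if (is.unsorted(v, strictly = TRUE))
      stop("build_dictionary: grid axes must be strictly increasing")
  atoms <- expand.grid(grid_spec, KEEP.OUT.ATTRS = FALSE)
  n_atoms <- nrow(atoms)
  Fp <- matrix(0 + 0i, train$n_pulses, n_atoms)
  for (i in seq_len(n_atoms)) {
    th <- base_theta
    th[names(grid_spec)] <- as.numeric(atoms[i, , drop = TRUE])
    pr <- theta_to_pars(th)
    Fp[, i] <- as.complex(simulate_fingerprint(train, pr$tissue, pr$sys))
  }
  structure(list(fingerprints = Fp, atoms = atoms, axes = grid_spec,
                 base_theta = base_theta,
                 train_hash = digest_train(train)),
            class = "qmt_dictionary")
}

# cheap content hash so dictionaries record which train generated them
digest_train <- function(train) {
  v <- c(train$alpha, train$trf, train$tr, train$cycle_time, train$trf_inv)
  sprintf("%d-%.8e", train$n_pulses, sum(v * seq_along(v)))
}

#' SVD subspace of a dictionary
#'
#' The top left singular vectors of the dictionary matrix span a
#' low-dimensional subspace that captures the fingerprints of all atoms;
#' reconstruction and fitting can be carried out on the `rank` subspace
#' coefficients instead of the full time series.
#'
#' @param dictionary A `qmt_dictionary`.
#' @param rank Subspace dimension (default 15).
#' @return Object of class `qmt_subspace`: orthonormal complex `basis`
#'   (`n_pulses x rank`), singular values, and the worst relative
#'   projection error over the dictionary atoms.
#' @export
fingerprint_subspace <- function(dictionary, rank = 15) {
  Fp <- dictionary$fingerprints
  if (rank > min(dim(Fp)))
    stop("fingerprint_subspace: rank exceeds dictionary rank")
  sv <- svd(Fp, nu = rank, nv = 0)
  B <- sv$u[, seq_len(rank), drop = FALSE]
  proj <- B %*% (Conj(t(B)) %*% Fp)
  relerr <- sqrt(colSums(Mod(Fp - proj)^2) / colSums(Mod(Fp)^2))
  structure(list(basis = B, d = sv$d, rank = rank,
                 max_projection_error = max(relerr)),
            class = "qmt_subspace")
}

#' Compress a fingerprint into subspace coefficients
#'
#' `coef = basis^H fingerprint`; with `normalize = TRUE` the complex
#' coefficients are divided by the first coefficient, which removes the
#' global complex scale `M0` (and any global phase) from the representation.
#'
#' @param fingerprint Complex vector (length `n_pulses`) or an
#'   already-compressed coefficient vector (length `rank`).
#' @param subspace A `qmt_subspace`.
#' @param normalize Divide by the first coefficient.
#' @return Complex coefficient vector of length `rank`.
#' @export
compress_fingerprint <- function(fingerprint, subspace, normalize = FALSE) {
  fingerprint <- as.complex(fingerprint)
  cf <- if (length(fingerprint) == nrow(subspace$basis)) {
    as.vector(Conj(t(subspace$basis)) %*% fingerprint)
  } else if (length(fingerprint) == subspace$rank) {
    fingerprint
  } else stop("compress_fingerprint: dimension mismatch")
  if (normalize) {
    if (Mod(cf[1]) == 0)
      stop("compress_fingerprint: zero first coefficient, cannot normalize")
    cf <- cf / cf[1]
  }
  cf
}

# internal model: parameters -> processed observation-space vector (stacked
# Re/Im of the fingerprint, its subspace coefficients, or the normalized
# coefficients)
qmt_model_fn <- function(train, subspace = NULL, normalize = FALSE) {
  force(train); force(subspace); force(normalize)
  function(theta) {
    pr <- theta_to_pars(theta)
    s <- as.complex(simulate_fingerprint(train, pr$tissue, pr$sys))
    if (!is.null(subspace)) s <- compress_fingerprint(s, subspace)
    if (normalize) s <- s / s[1]
    c(Re(s), Im(s))
  }
}

#' Fit the voxel model to one observation
#'
#' Bounded Levenberg-Marquardt least squares over the ten real unknowns
#' (six biophysical parameters plus `wz`, `b1`, and complex `M0`), with the
#' model evaluated through the full simulation (optionally compressed into a
#' subspace). With `normalize = TRUE` observation and model are divided by
#' their first subspace coefficient, which removes `M0` from the effective
#' unknown set (it is then held fixed). Real and imaginary parts are fitted
#' jointly; the global phase is absorbed into `M0`.
#'
#' Multiple starts are used when available: the caller-supplied `init`, the
#' fixed physiologic default, and (if a dictionary is given) the
#' best-matching atom; the best converged fit wins.
#'
#' @param obs Complex observation: a fingerprint (length `n_pulses`) or
#'   coefficient vector (length `rank`).
#' @param train A `qmt_train`.
#' @param subspace Optional `qmt_subspace`.
#' @param init Optional named start vector over [QMT_UNKNOWNS].
#' @param dictionary Optional `qmt_dictionary` for a nearest-atom start.
#' @param normalize First-coefficient normalization (requires `subspace`
#'   or a fingerprint observation; drops `M0` from the unknowns).
#' @param free Character vector of unknowns to fit (others held at `init`).
#' @param lower,upper Bounds; default [qmt_default_bounds()].
#' @param maxit Iteration cap per start.
#' @param starts Which starting points to use, a subset of
#'   `c("init", "default", "dictionary")`.
#' @return Object of class `qmt_fit`: `estimates` (full named vector),
#'   `residual`, `cost`, `converged`, `iterations`, `start_used`.
#' @export
fit_voxel <- function(obs, train, subspace = NULL, init = NULL,
                      dictionary = NULL, normalize = FALSE,
                      free = NULL, lower = NULL, upper = NULL, maxit = 60,
                      starts = c("init", "default", "dictionary")) {
  obs <- as.complex(obs)
  if (all(Mod(obs) == 0)) stop("fit_voxel: all-zero observation")
  b <- qmt_default_bounds()
  lower <- if (is.null(lower)) b$lower else replace(b$lower, names(lower), lower)
  upper <- if (is.null(upper)) b$upper else replace(b$upper, names(upper), upper)
  if (is.null(free))
    free <- if (normalize) setdiff(QMT_UNKNOWNS, c("M0re", "M0im")) else
      QMT_UNKNOWNS

  if (!is.null(subspace) && length(obs) == nrow(subspace$basis))
    obs <- compress_fingerprint(obs, subspace)
  if (normalize) {
    if (Mod(obs[1]) == 0) stop("fit_voxel: degenerate voxel (zero first coefficient)")
    obs <- obs / obs[1]
  }
  yobs <- c(Re(obs), Im(obs))
  model <- qmt_model_fn(train, subspace, normalize)

  use <- match.arg(starts, several.ok = TRUE)
  starts <- list()
  if (!is.null(init) && "init" %in% use) {
    th <- .qmt_default_start
    th[names(init)] <- init
    starts$init <- th
  }
  if ("default" %in% use) starts$default <- .qmt_default_start
  if (!length(starts)) starts$default <- .qmt_default_start
  if (!is.null(dictionary) && "dictionary" %in% use) {
    D <- dictionary$fingerprints
    dc <- if (!is.null(subspace)) Conj(t(subspace$basis)) %*% D else D
    if (normalize) dc <- sweep(dc, 2, dc[1, ], "/")
    sc <- Mod(Conj(t(dc)) %*% obs) / sqrt(colSums(Mod(dc)^2))
    k <- which.max(sc)
    th <- dictionary$base_theta
    th[names(dictionary$axes)] <- as.numeric(dictionary$atoms[k, ,
                                                              drop = TRUE])
    starts$dictionary <- th
  }

  fit_one <- function(theta0) {
    theta0[free] <- pmin(pmax(theta0[free], lower[free]), upper[free])
    # data-driven M0 start: linear LS on the current model shape
    if (!normalize && all(c("M0re", "M0im") %in% free)) {
      th1 <- theta0; th1["M0re"] <- 1; th1["M0im"] <- 0
      m <- model(th1)
      mc <- complex(real = m[seq_along(obs)],
                    imaginary = m[-seq_along(obs)])
      a <- sum(Conj(mc) * obs) / max(sum(Mod(mc)^2), 1e-300)
      theta0["M0re"] <- Re(a); theta0["M0im"] <- Im(a)
      theta0[free] <- pmin(pmax(theta0[free], lower[free]), upper[free])
    }
    resid_fn <- function(p) {
      th <- theta0; th[free] <- p
      model(th) - yobs
    }
    lm_bounded(theta0[free], resid_fn, lower[free], upper[free],
               scales = .qmt_scales[free], maxit = maxit)
  }

  best <- NULL; used <- NA_character_
  for (nm in names(starts)) {
    res <- tryCatch(fit_one(starts[[nm]]), error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(best) || res$cost < best$cost) { best <- res; used <- nm }
  }
  if (is.null(best)) stop("fit_voxel: all starts failed")
  est <- starts[[used]]
  est[free] <- best$par
  structure(list(estimates = est, residual = best$residual,
                 cost = best$cost, converged = best$converged,
                 iterations = best$iterations, start_used = used,
                 free = free),
            class = "qmt_fit")
}

#' @export
print.qmt_fit <- function(x, ...) {
  cat("qMT voxel fit (", if (x$converged) "converged" else "NOT converged",
      ", ", x$iterations, " iterations, residual ",
      format(x$residual, digits = 4), ")\n", sep = "")
  print(signif(x$estimates, 5))
  invisible(x)
}

#' Voxel-wise parameter mapping
#'
#' Applies [fit_voxel()] independently to every voxel inside the mask of a
#' 4-D complex image (x, y, z, time-or-coefficient). Voxel order does not
#' influence any result (fits are independent); failed voxels are set to
#' `NA` and counted.
#'
#' @param img 4-D complex array.
#' @param mask 3-D logical array (or `NULL` for all voxels).
#' @param train A `qmt_train`.
#' @param subspace Optional `qmt_subspace` (required if the 4th dimension is
#'   coefficients).
#' @param ... Passed to [fit_voxel()] (`init`, `dictionary`, `normalize`,
#'   ...).
#' @return List of 3-D parameter maps (one per unknown) plus `residual`,
#'   `converged`, and the failure count as attribute `n_failed`.
#' @export
fit_map <- function(img, mask = NULL, train, subspace = NULL, ...) {
  d <- dim(img)
  if (length(d) != 4) stop("fit_map: img must be 4-D")
  if (is.null(mask)) mask <- array(TRUE, d[1:3])
  if (!identical(dim(mask), d[1:3])) stop("fit_map: mask/image mismatch")
  maps <- lapply(QMT_UNKNOWNS, function(u) array(NA_real_, d[1:3]))
  names(maps) <- QMT_UNKNOWNS
  maps$residual <- array(NA_real_, d[1:3])
  maps$converged <- array(NA, d[1:3])
  n_failed <- 0L
  idx <- which(mask, arr.ind = TRUE)
  for (v in seq_len(nrow(idx))) {
    i <- idx[v, 1]; j <- idx[v, 2]; k <- idx[v, 3]
    obs <- img[i, j, k, ]
    res <- tryCatch(fit_voxel(obs, train, subspace = subspace, ...),
                    error = function(e) NULL)
    if (is.null(res)) { n_failed <- n_failed + 1L; next }
    for (u in QMT_UNKNOWNS) maps[[u]][i, j, k] <- res$estimates[[u]]
    maps$residual[i, j, k] <- res$residual
    maps$converged[i, j, k] <- res$converged
  }
  attr(maps, "n_failed") <- n_failed
  maps
}

#' Mono-exponential recovery fit
#'
#' Least-squares fit of `y(t) = a + b exp(-R t)`; the workhorse for
#' extracting an apparent longitudinal relaxation rate from (possibly
#' bi-exponential) inversion-recovery data.
#'
#' @param times Sample times, s (at least 3).
#' @param signal Longitudinal signal at `times`.
#' @param r_range Search interval for the rate (1/s).
#' @return The fitted rate `R` (1/s), with `a`, `b` and the residual norm as
#'   attributes.
#' @export
fit_monoexp <- function(times, signal, r_range = c(0, 100)) {
  if (length(times) < 3 || length(signal) != length(times))
    stop("fit_monoexp: need >= 3 matching time points")
  if (stats::sd(signal) == 0)  # constant signal: no decay
    return(structure(0, a = signal[1], b = 0, residual = 0))
  sse <- function(R) {
    X <- cbind(1, exp(-R * times))
    f <- stats::lm.fit(X, signal)
    sum(f$residuals^2)
  }
  # profile the linear coefficients; 1-D search over the rate, then polish
  Rg <- seq(r_range[1], r_range[2], length.out = 200)
  R0 <- Rg[which.min(vapply(Rg, sse, numeric(1)))]
  w <- diff(r_range) / 199
  R1 <- optimize(sse, c(max(r_range[1], R0 - 2 * w),
                        min(r_range[2], R0 + 2 * w)), tol = 1e-12)$minimum
  X <- cbind(1, exp(-R1 * times))
  cf <- stats::lm.fit(X, signal)$coefficients
  fit <- tryCatch(
    nls(signal ~ a + b * exp(-R * times),
        start = list(a = cf[[1]], b = cf[[2]], R = R1),
        control = nls.control(maxiter = 100, tol = 1e-10,
                              scaleOffset = 1, warnOnly = TRUE)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    cfs <- coef(fit)
    R1 <- cfs[["R"]]; a <- cfs[["a"]]; b <- cfs[["b"]]
    rn <- sqrt(sum(stats::resid(fit)^2))
  } else {
    a <- cf[[1]]; b <- cf[[2]]
    rn <- sqrt(sse(R1))
  }
  structure(R1, a = a, b = b, residual = rn)
}
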