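# Cramer-Rao bound machinery: signal derivatives, Fisher information,
# variance bounds, normalized CRB, and CRB-driven pulse-train optimization.

#' Unknown-parameter labels of the full signal model
#'
#' The ten real unknowns of the voxel model: the six biophysical parameters
#' of the unconstrained MT model plus the nuisance parameters off-resonance
#' `wz`, transmit scale `b1`, and the complex scale `M0` (split into real
#' and imaginary parts).
#' @export
QMT_UNKNOWNS <- c("m0s", "R1f", "R2f", "Rx", "R1s", "T2s", "wz", "b1",
                  "M0re", "M0im")

# characteristic scales used for relative finite-difference steps (and as
# fallbacks when a reference value is zero, e.g. wz = 0)
.qmt_scales <- c(m0s = 0.1, R1f = 1, R2f = 10, Rx = 10, R1s = 1, T2s = 1e-5,
                 wz = 2 * pi, b1 = 1, M0re = 1, M0im = 1)

pars_to_theta <- function(tissue, sys) {
  c(m0s = tissue$m0s, R1f = tissue$R1f, R2f = tissue$R2f, Rx = tissue$Rx,
    R1s = tissue$R1s, T2s = tissue$T2s, wz = sys$wz, b1 = sys$b1,
    M0re = Re(sys$M0), M0im = Im(sys$M0))
}

theta_to_pars <- function(theta) {
  list(tissue = tissue_pars(theta[["m0s"]], theta[["R1f"]], theta[["R2f"]],
                            theta[["Rx"]], theta[["R1s"]], theta[["T2s"]]),
       sys = system_pars(theta[["wz"]], theta[["b1"]],
                         complex(real = theta[["M0re"]],
                                 imaginary = theta[["M0im"]])))
}

#' Jacobian of the fingerprint with respect to the model unknowns
#'
#' Computes `ds_n / d theta_k` at the reference point, either by central
#' finite differences with relative steps (default) or by complex-step
#' differentiation propagated through the complexified simulation (a
#' cancellation-free implementation of augmented propagation: the
#' first-order term in `h` of `exp(dt A(theta + i h))` is exactly the
#' Frechet-derivative block of the augmented generator
#' `[[A, dA], [0, A]]`). Derivatives with respect to `Re M0` and `Im M0`
#' are analytic (`s / M0` and `i s / M0`).
#'
#' @param train A `qmt_train`.
#' @param tissue,sys Reference parameter point.
#' @param unknowns Character vector of labels from [QMT_UNKNOWNS].
#' @param method `"fd"` (central finite differences) or `"cstep"`
#'   (complex-step / augmented propagation).
#' @param rel_step Relative step for `"fd"`.
#' @return Complex matrix `n_pulses x length(unknowns)` with column names.
#' @export
fingerprint_jacobian <- function(train, tissue, sys = system_pars(),
                                 unknowns = QMT_UNKNOWNS,
                                 method = c("fd", "cstep"),
                                 rel_step = 1e-4) {
  method <- match.arg(method)
  stopifnot(all(unknowns %in% QMT_UNKNOWNS), !anyDuplicated(unknowns))
  theta0 <- pars_to_theta(tissue, sys)
  g <- r2sl_grid()
  M0 <- sys$M0
  n <- train$n_pulses
  J <- matrix(0 + 0i, n, length(unknowns),
              dimnames = list(NULL, unknowns))
  s0 <- NULL
  for (k in seq_along(unknowns)) {
    u <- unknowns[k]
    if (u %in% c("M0re", "M0im")) {
      if (is.null(s0)) s0 <- as.complex(simulate_fingerprint(train, tissue, sys))
      w <- s0 / M0
      J[, k] <- if (u == "M0re") w else 1i * w
      next
    }
    if (method == "cstep") {
      out <- simulate_cstep_cpp(pars_clist(tissue, sys), train_clist(train),
                                g$values, g$a0, g$da, g$l0, g$dl, u, 1e-200)
      ds <- complex(real = Im(out$xf) / 1e-200,
                    imaginary = Im(out$yf) / 1e-200)
      J[, k] <- M0 * ds
    } else {
      h <- rel_step * max(abs(theta0[[u]]), .qmt_scales[[u]])
      tp <- theta0; tp[u] <- tp[u] + h
      tm <- theta0; tm[u] <- tm[u] - h
      pp <- theta_to_pars(tp); pm <- theta_to_pars(tm)
      sp <- as.complex(simulate_fingerprint(train, pp$tissue, pp$sys))
      sm <- as.complex(simulate_fingerprint(train, pm$tissue, pm$sys))
      J[, k] <- (sp - sm) / (2 * h)
    }
    if (!all(is.finite(Re(J[, k])) & is.finite(Im(J[, k]))))
      stop("fingerprint_jacobian: non-finite derivative for parameter ", u)
  }
  J
}

#' Fisher information for complex Gaussian noise
#'
#' For i.i.d. complex Gaussian noise with per-channel variance `sigma2`,
#' the Fisher information of the real parameterization is
#' `F = Re(J^H J) / sigma2`.
#'
#' @param J Complex Jacobian (`n x p`).
#' @param sigma2 Noise variance per real/imaginary channel; `> 0`.
#' @return Real symmetric positive semi-definite `p x p` matrix.
#' @export
fisher_information <- function(J, sigma2 = 1) {
  if (sigma2 <= 0) stop("fisher_information: sigma2 must be > 0")
  if (!all(is.finite(Re(J)) & is.finite(Im(J))))
    stop("fisher_information: non-finite Jacobian")
  Fm <- Re(Conj(t(J)) %*% J) / sigma2
  (Fm + t(Fm)) / 2
}

#' Cramer-Rao variance bounds
#'
#' Diagonal of the inverse Fisher matrix, in unknown order. With a single
#' unknown this reduces to `sigma2 / ||ds/dtheta||^2`; with several, each
#' bound is the inverse squared norm of the *orthogonalized* derivative
#' (the component orthogonal to all other columns), which is why
#' disentangling the derivatives is the key to a stable fit.
#'
#' @param F Fisher matrix from [fisher_information()].
#' @param cond_limit Condition-number limit beyond which the Fisher matrix
#'   is treated as singular; the error message names the most collinear
#'   pair of unknowns.
#' @return Named numeric vector of variance bounds.
#' @export
crb_values <- function(F, cond_limit = 1e12) {
  D <- sqrt(diag(F))
  if (any(D <= 0)) stop("crb_values: zero diagonal in the Fisher matrix")
  # conditioning is assessed on the unit-diagonal (correlation-like) scaling,
  # so it reflects collinearity of the derivatives, not parameter units
  C <- F / outer(D, D)
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0 || max(ev) / min(ev) > cond_limit) {
    Coff <- C
    diag(Coff) <- 0
    ij <- which(abs(Coff) == max(abs(Coff)), arr.ind = TRUE)[1, ]
    nm <- colnames(F) %||% as.character(seq_len(ncol(F)))
    stop("crb_values: Fisher matrix singular or ill-conditioned ",
         sprintf("(cond ~ %.3g); most collinear pair: %s, %s",
                 max(ev) / max(min(ev), .Machine$double.xmin),
                 nm[ij[1]], nm[ij[2]]))
  }
  crb <- diag(solve(C)) / D^2
  names(crb) <- colnames(F)
  crb
}

#' Normalized Cramer-Rao bound
#'
#' `nCRB = CRB * T_cycle / theta^2`, i.e. the variance bound normalized by
#' the squared parameter value (to resemble an inverse squared SNR) and
#' referenced to unit-variance noise per unit time, which gives it units of
#' seconds. Any fixed convention preserves rankings; this one is used both
#' for reporting and as the optimization objective.
#'
#' @param crb Variance bound(s) computed at `sigma2 = 1`.
#' @param theta Reference parameter value(s), nonzero.
#' @param t_cycle Cycle (observation) time, s.
#' @return Normalized CRB(s), seconds.
#' @export
normalized_crb <- function(crb, theta, t_cycle) {
  if (any(theta == 0)) stop("normalized_crb: theta must be nonzero")
  crb * t_cycle / theta^2
}

#' Reference parameters used for sequence evaluation and optimization
#'
#' The fixed simulation point for CRB calculations:
#' `m0s = 0.25, R1f = 0.5/s, R2f = 15.4/s, Rx = 20/s, R1s = 2/s,
#' T2s = 10 us, wz = 0, B1+ = 1`.
#' @return List with elements `tissue` and `sys`.
#' @export
crb_reference_pars <- function() {
  list(tissue = tissue_pars(0.25, 0.5, 15.4, 20, 2, 1e-5),
       sys = system_pars(wz = 0, b1 = 1, M0 = 1 + 0i))
}

#' CRB report for a pulse train
#'
#' Convenience wrapper: Jacobian, Fisher matrix, CRB and normalized CRB for
#' a set of unknowns at a reference point.
#'
#' @inheritParams fingerprint_jacobian
#' @param sigma2 Noise variance per channel.
#' @return A `data.frame` with one row per unknown (`unknown`, `value`,
#'   `crb`, `ncrb`), with the Fisher matrix attached as attribute
#'   `"fisher"`.
#' @export
crb_report <- function(train, tissue, sys = system_pars(),
                       unknowns = QMT_UNKNOWNS, sigma2 = 1,
                       method = "fd") {
  J <- fingerprint_jacobian(train, tissue, sys, unknowns, method = method)
  Fm <- fisher_information(J, sigma2)
  crb <- crb_values(Fm)
  theta <- pars_to_theta(tissue, sys)[unknowns]
  ncrb <- ifelse(theta != 0, crb * train$cycle_time / theta^2, NA_real_)
  out <- data.frame(unknown = unknowns, value = unname(theta),
                    crb = unname(crb), ncrb = unname(ncrb),
                    stringsAsFactors = FALSE)
  attr(out, "fisher") <- Fm
  attr(out, "sigma2") <- sigma2
  out
}

#' CRB-driven optimization of the pulse train
#'
#' Parameterizes the flip-angle and pulse-duration patterns by smooth
#' natural cubic splines over `n_control` control points and minimizes the
#' weighted sum of normalized CRBs of the biophysical parameters (with
#' `wz`, `b1` and complex `M0` always carried as additional unknowns in the
#' Fisher matrix) with bounded quasi-Newton (L-BFGS-B) and seeded random
#' restarts.
#'
#' @param init A `qmt_train` used as starting pattern (and to define
#'   `n_pulses`, TR, cycle time).
#' @param weights Named weights on the normalized CRBs summed in the
#'   objective; default weight 1 on the six biophysical parameters.
#' @param alpha_bounds,trf_bounds Bounds for flip angles (rad) and pulse
#'   durations (s).
#' @param n_control Number of spline control points per pattern.
#' @param maxiter L-BFGS-B iteration cap per restart; `maxiter = 0` returns
#'   `init` unchanged.
#' @param restarts Number of seeded starts (first = `init` pattern).
#' @param seed Integer seed; the optimization is deterministic given it.
#' @param unknowns Unknown set for the Fisher matrix.
#' @param reference Reference point, as from [crb_reference_pars()].
#' @return The optimized `qmt_train` with attributes `objective`,
#'   `objective_init`, and a `log` data.frame (one row per restart).
#' @export
optimize_train <- function(init, weights = NULL,
                           alpha_bounds = c(1e-3, pi),
                           trf_bounds = c(1e-4, 1e-3),
                           n_control = 8, maxiter = 50, restarts = 3,
                           seed = 1, unknowns = QMT_UNKNOWNS,
                           reference = crb_reference_pars()) {
  stopifnot(inherits(init, "qmt_train"))
  if (alpha_bounds[1] >= alpha_bounds[2] || trf_bounds[1] >= trf_bounds[2])
    stop("optimize_train: infeasible bounds")
  if (trf_bounds[2] >= init$tr)
    stop("optimize_train: trf upper bound must stay below TR")
  bio <- c("m0s", "R1f", "R2f", "Rx", "R1s", "T2s")
  if (is.null(weights)) weights <- setNames(rep(1, 6), bio)
  stopifnot(all(names(weights) %in% unknowns))
  tissue <- reference$tissue; sys <- reference$sys
  theta <- pars_to_theta(tissue, sys)
  n <- init$n_pulses

  ctl_idx <- seq(1, n, length.out = n_control)
  make_train <- function(x) {
    train_from_controls(x[seq_len(n_control)],
                        x[n_control + seq_len(n_control)],
                        n, init$tr, init$cycle_time, init$trf_inv,
                        alpha_bounds, trf_bounds)
  }
  objective_train <- function(tr) {
    val <- tryCatch({
      rep_ <- crb_report(tr, tissue, sys, unknowns, sigma2 = 1,
                         method = "cstep")
      sum(weights * rep_$ncrb[match(names(weights), rep_$unknown)])
    }, error = function(e) NA_real_)
    if (!is.finite(val)) 1e12 else val
  }
  objective <- function(x) objective_train(make_train(x))

  if (maxiter == 0) {
    out <- init
    f0i <- objective_train(init)
    attr(out, "objective") <- f0i
    attr(out, "objective_init") <- f0i
    return(out)
  }
  x0 <- c(pmin(pmax(init$alpha[round(ctl_idx)], alpha_bounds[1]),
               alpha_bounds[2]),
          pmin(pmax(init$trf[round(ctl_idx)], trf_bounds[1]), trf_bounds[2]))
  lower <- c(rep(alpha_bounds[1], n_control), rep(trf_bounds[1], n_control))
  upper <- c(rep(alpha_bounds[2], n_control), rep(trf_bounds[2], n_control))
  f0 <- objective(x0)

  set.seed(seed)
  best <- list(par = x0, value = f0)
  log <- data.frame(restart = integer(), value = numeric(),
                    convergence = integer())
  for (r in seq_len(restarts)) {
    xs <- if (r == 1) x0 else pmin(pmax(
      x0 * (1 + 0.3 * rnorm(length(x0))), lower), upper)
    fit <- tryCatch(
      optim(xs, objective, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = maxiter,
                           parscale = c(rep(1, n_control),
                                        rep(1e-4, n_control)))),
      error = function(e) list(par = xs, value = objective(xs),
                               convergence = 99L))
    log <- rbind(log, data.frame(restart = r, value = fit$value,
                                 convergence = fit$convergence))
    if (fit$value < best$value) best <- fit
  }
  if (best$value >= f0)
    warning("optimize_train: no improvement over the initial pattern")
  out <- make_train(best$par)
  attr(out, "objective") <- min(best$value, f0)
  attr(out, "objective_init") <- f0
  attr(out, "log") <- log
  attr(out, "controls") <- list(alpha_ctrl = best$par[seq_len(n_control)],
                                trf_ctrl = best$par[n_control +
                                                      seq_len(n_control)])
  out
}
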