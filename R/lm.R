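# Compact bounded Levenberg-Marquardt for nonlinear least squares.
# Residual function returns a numeric vector; Jacobian by forward
# differences with per-parameter characteristic scales. Box bounds are
# enforced by clipping trial steps; lambda is adapted multiplicatively.

lm_bounded <- function(par, resid_fn, lower, upper, scales = NULL,
                       maxit = 60, ftol = 1e-12, ptol = 1e-11) {
  p <- length(par)
  if (is.null(scales)) scales <- pmax(abs(par), 1e-8)
  par <- pmin(pmax(par, lower), upper)
  r <- resid_fn(par)
  cost <- sum(r^2)
  lambda <- 1e-3
  it <- 0L
  converged <- FALSE
  repeat {
    it <- it + 1L
    # forward-difference Jacobian
    J <- matrix(0, length(r), p)
    for (k in seq_len(p)) {
      h <- 1e-6 * max(abs(par[k]), scales[k])
      if (par[k] + h > upper[k]) h <- -h
      pk <- par; pk[k] <- pk[k] + h
      J[, k] <- (resid_fn(pk) - r) / h
    }
    g <- crossprod(J, r)
    H <- crossprod(J)
    dH <- pmax(diag(H), 1e-12 * max(diag(H), 1e-300))
    improved <- FALSE
    for (trial in 1:12) {
      step <- tryCatch(
        solve(H + lambda * diag(dH, p), -g),
        error = function(e) NULL)
      if (is.null(step)) { lambda <- lambda * 10; next }
      cand <- pmin(pmax(par + as.numeric(step), lower), upper)
      rc <- resid_fn(cand)
      cc <- sum(rc^2)
      if (is.finite(cc) && cc < cost) {
        dp <- max(abs(cand - par) / pmax(abs(par), scales))
        dc <- (cost - cc) / max(cost, .Machine$double.xmin)
        par <- cand; r <- rc; cost <- cc
        lambda <- max(lambda / 9, 1e-12)
        improved <- TRUE
        if (dc < ftol || dp < ptol) converged <- TRUE
        break
      }
      lambda <- lambda * 10
      if (lambda > 1e12) break
    }
    if (!improved) { converged <- TRUE; break }  # stalled at a minimum
    if (converged || it >= maxit) break
  }
  list(par = par, cost = cost, residual = sqrt(cost),
       converged = converged, iterations = it)
}
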