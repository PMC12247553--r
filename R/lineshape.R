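# Super-Lorentzian lineshape, generalized-Bloch saturation, and the
# linearized semi-solid relaxation rate R2s,l.

#' Super-Lorentzian Green's function
#'
#' Attenuation of semi-solid magnetization after a free-evolution lag
#' `tau` under super-Lorentzian decay characteristics:
#' `G(tau) = int_0^1 exp(-(tau/T2s)^2 (3 zeta^2 - 1)^2 / 8) d zeta`.
#' `G` is 1 at `tau = 0` and decays monotonically (slowly, ~1/tau for large
#' lags, which is what makes the decay non-exponential).
#'
#' @param tau Lag time(s), s; `tau >= 0`. Vectorized.
#' @param T2s Semi-solid transverse relaxation time, s; `> 0`.
#' @param tol Quadrature tolerance.
#' @return Attenuation value(s) in (0, 1].
#' @export
superlorentzian_green <- function(tau, T2s, tol = 1e-12) {
  if (any(tau < 0)) stop("superlorentzian_green: tau must be >= 0")
  if (!is.numeric(T2s) || T2s <= 0)
    stop("superlorentzian_green: T2s must be > 0")
  vapply(tau / T2s, green_superlorentzian_cpp, numeric(1), tol = tol)
}

# Cached Green's-function lookup table in normalized time x = tau/T2s.
green_table <- function() {
  if (is.null(.qmtr$gtab)) {
    .qmtr$gtab <- green_table_cpp(.qmtr_grid_spec$rmax + 5,
                                  .qmtr_grid_spec$gdx, 1e-11)
  }
  .qmtr$gtab
}

# grid layout shared by the cache builder and serialization
.qmtr_grid_spec <- list(
  alpha_max = 4.8,    # rad; covers b1 <= 1.5 times a pi pulse
  dalpha = 0.1,
  rmin = 0.5,         # TRF / T2s
  rmax = 1100,
  n_logr = 48,
  gdx = 0.004         # Green's table spacing in tau/T2s
)

#' Semi-solid saturation by a rectangular RF pulse (generalized Bloch)
#'
#' Solves the Volterra integro-differential equation
#' `dz/dt = -omega_y^2 int_0^t G(t - tau) z(tau) dtau` for the longitudinal
#' semi-solid magnetization during a rectangular pulse of constant Rabi
#' frequency `omega_y = alpha / TRF`, by step-wise product integration
#' (trapezoidal weights, implicit in the newest point, Richardson
#' extrapolated). Longitudinal relaxation and exchange are neglected during
#' the pulse (pulse durations are far below 1/R1s and 1/Rx).
#'
#' @param alpha Flip angle, rad.
#' @param trf Pulse duration, s; `> 0`.
#' @param T2s Semi-solid transverse relaxation time, s.
#' @param n_steps Number of product-integration steps; `NULL` selects a
#'   resolution based on `trf/T2s` (minimum 64).
#' @param richardson Apply Richardson extrapolation of the O(h^2) scheme.
#' @return The attenuation `zs(TRF) / zs(0)` in [-1, 1].
#' @export
saturate_semisolid_pulse <- function(alpha, trf, T2s, n_steps = NULL,
                                     richardson = TRUE) {
  if (trf <= 0) stop("saturate_semisolid_pulse: trf must be > 0")
  if (T2s <= 0) stop("saturate_semisolid_pulse: T2s must be > 0")
  if (alpha == 0) return(1)
  n <- if (is.null(n_steps)) 0L else as.integer(n_steps)
  if (!is.null(n_steps) && n < 64L)
    stop("saturate_semisolid_pulse: n_steps below the minimum of 64")
  volterra_cpp(abs(alpha), trf / T2s, green_table(), .qmtr_grid_spec$gdx,
               n, richardson)
}

#' Linearized semi-solid relaxation rate R2s,l
#'
#' The non-exponential super-Lorentzian decay cannot be captured by the
#' original Bloch equations, but an effective exponential rate can be chosen
#' such that a Bloch-type 2x2 rotation-with-decay propagation of `(xs, zs)`
#' over the pulse reproduces the generalized-Bloch `zs` at the end of the
#' pulse. That rate, `R2s,l(R2s, alpha, TRF)`, is what enters the
#' Bloch-McConnell generator.
#'
#' @inheritParams saturate_semisolid_pulse
#' @param tol Root-finding tolerance on the normalized rate.
#' @return `R2s,l` in 1/s. By convention `linearize_r2s(0, ...) = 0`: without
#'   irradiation no saturation occurs and the rate is unobservable.
#' @export
linearize_r2s <- function(alpha, trf, T2s, tol = 1e-12) {
  if (alpha == 0) return(0)
  if (trf <= 0) stop("linearize_r2s: trf must be > 0")
  if (T2s <= 0) stop("linearize_r2s: T2s must be > 0")
  r <- trf / T2s
  zs <- saturate_semisolid_pulse(alpha, trf, T2s)
  linearize_rho_cpp(abs(alpha), r, zs, tol) / T2s
}

#' Precomputed grid of the linearized rate R2s,l
#'
#' `R2s,l * T2s` is a dimensionless function of the flip angle and of the
#' ratio `TRF / T2s` alone, so a single grid serves all tissues. The grid is
#' computed lazily once per session (a few seconds), cached, and interpolated
#' bicubically inside all simulations. Note the grid column at `alpha = 0`
#' stores the small-angle *limit* of the matching rate so the interpolant
#' stays smooth; the `alpha = 0` convention of [linearize_r2s()] applies only
#' to direct evaluation.
#'
#' @param force Rebuild even if a cached grid exists.
#' @return An object of class `qmt_r2sl_grid` with the axes, the value
#'   matrix (`alpha` by `log(TRF/T2s)`), and generation metadata.
#' @export
r2sl_grid <- function(force = FALSE) {
  if (force || is.null(.qmtr$grid)) {
    sp <- .qmtr_grid_spec
    alpha_nodes <- seq(0, sp$alpha_max, by = sp$dalpha)
    logr_nodes <- seq(log(sp$rmin), log(sp$rmax), length.out = sp$n_logr)
    V <- r2sl_grid_cpp(alpha_nodes, logr_nodes, green_table(), sp$gdx)
    .qmtr$grid <- structure(
      list(alpha_nodes = alpha_nodes, logr_nodes = logr_nodes, values = V,
           a0 = alpha_nodes[1], da = sp$dalpha, l0 = logr_nodes[1],
           dl = diff(logr_nodes)[1],
           meta = list(gdx = sp$gdx, volterra = "trapezoidal product
integration, adaptive steps (24 per unit TRF/T2s, 512..2048), Richardson
extrapolated", root_tol = 1e-12, interpolation = "bicubic (Keys)")),
      class = "qmt_r2sl_grid")
  }
  .qmtr$grid
}

#' Interpolated linearized rate from the precomputed grid
#'
#' @param grid A `qmt_r2sl_grid` from [r2sl_grid()].
#' @param alpha Flip angle(s), rad (effective, i.e. after B1+ scaling).
#' @param trf Pulse duration(s), s.
#' @param T2s Semi-solid T2, s.
#' @return `R2s,l` in 1/s (vectorized over `alpha`/`trf`).
#' @export
r2sl_lookup <- function(grid, alpha, trf, T2s) {
  n <- max(length(alpha), length(trf))
  alpha <- rep_len(abs(alpha), n)
  trf <- rep_len(trf, n)
  vapply(seq_len(n), function(i) {
    if (alpha[i] == 0) return(0)
    grid_lookup_cpp(grid$values, grid$a0, grid$da, grid$l0, grid$dl,
                    alpha[i], log(trf[i] / T2s)) / T2s
  }, numeric(1))
}

#' Serialize / restore the linearized-rate grid
#'
#' Text (JSON) serialization of the grid with axes, values, and generation
#' metadata, so a grid can be shipped or compared across machines.
#'
#' @param grid A `qmt_r2sl_grid`.
#' @param path File path.
#' @return `read_r2sl_grid` returns a `qmt_r2sl_grid`.
#' @export
write_r2sl_grid <- function(grid, path) {
  stopifnot(inherits(grid, "qmt_r2sl_grid"))
  obj <- list(alpha_nodes = grid$alpha_nodes, logr_nodes = grid$logr_nodes,
              values = grid$values, meta = grid$meta)
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_r2sl_grid
#' @export
read_r2sl_grid <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  alpha_nodes <- obj$alpha_nodes
  logr_nodes <- obj$logr_nodes
  V <- matrix(obj$values, nrow = length(alpha_nodes), byrow = FALSE)
  if (is.matrix(obj$values)) V <- obj$values
  structure(list(alpha_nodes = alpha_nodes, logr_nodes = logr_nodes,
                 values = V, a0 = alpha_nodes[1],
                 da = diff(alpha_nodes)[1], l0 = logr_nodes[1],
                 dl = diff(logr_nodes)[1], meta = obj$meta),
            class = "qmt_r2sl_grid")
}
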