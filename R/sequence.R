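# Hybrid-state pulse trains: representation, propagators, periodic steady
# state, and fingerprint simulation.

#' Hybrid-state pulse train
#'
#' A balanced inversion-recovery pulse train: a rectangular pi inversion
#' pulse flanked by crusher gradients, followed by `n_pulses` rectangular RF
#' pulses with per-pulse flip angles and durations, separated by a fixed
#' `TR`. The RF phase is incremented by pi between consecutive pulses
#' (implemented as a sign alternation of the Rabi frequency with matching
#' demodulation of the signal). After one `cycle_time` the remaining
#' magnetization is inverted again and the train repeats, which defines the
#' periodic boundary condition of the spin dynamics.
#'
#' @param alpha Flip angles, rad, in `[0, pi]`; length `n_pulses`.
#' @param trf Pulse durations, s, each in `(0, TR)`; recycled to match.
#' @param tr Repetition time, s. Default 3.5 ms.
#' @param cycle_time Cycle duration, s. Default 4 s (1142 pulses at the
#'   default TR).
#' @param trf_inv Inversion-pulse duration, s. Default 500 us.
#' @param inversion Include the inversion pulse (default `TRUE`; disabling
#'   it turns the sequence into a plain periodic pulse train, useful for
#'   steady-state limits).
#' @return An object of class `qmt_train`.
#' @export
pulse_train <- function(alpha, trf, tr = 3.5e-3, cycle_time = 4,
                        trf_inv = 500e-6, inversion = TRUE) {
  n <- length(alpha)
  trf <- rep_len(trf, n)
  bad <- which(alpha < 0 | alpha > pi)
  if (length(bad))
    stop("pulse_train: flip angles outside [0, pi] at indices ",
         paste(utils::head(bad, 10), collapse = ", "))
  bad <- which(trf <= 0 | trf >= tr)
  if (length(bad))
    stop("pulse_train: pulse durations outside (0, TR) at indices ",
         paste(utils::head(bad, 10), collapse = ", "))
  if (trf_inv <= 0) stop("pulse_train: trf_inv must be > 0")
  if (n * tr > cycle_time + tr)
    stop("pulse_train: n_pulses * TR exceeds cycle_time + TR")
  structure(list(alpha = as.numeric(alpha), trf = as.numeric(trf),
                 tr = tr, cycle_time = cycle_time, trf_inv = trf_inv,
                 inversion = isTRUE(inversion), n_pulses = n),
            class = "qmt_train")
}

#' @export
print.qmt_train <- function(x, ...) {
  cat(sprintf(
    "Hybrid-state pulse train: %d pulses, TR = %.4g ms, cycle = %.4g s\n",
    x$n_pulses, 1e3 * x$tr, x$cycle_time))
  cat(sprintf("  alpha in [%.3g, %.3g] rad, TRF in [%.3g, %.3g] us, inversion TRF = %.3g us\n",
              min(x$alpha), max(x$alpha), 1e6 * min(x$trf), 1e6 * max(x$trf),
              1e6 * x$trf_inv))
  invisible(x)
}

# internal: list layout handed to the C++ core
train_clist <- function(train) {
  list(alpha = train$alpha, trf = train$trf, tr = train$tr,
       trf_inv = train$trf_inv, cycle_time = train$cycle_time,
       inversion = train$inversion %||% TRUE)
}

pars_clist <- function(tissue, sys) {
  list(m0s = tissue$m0s, R1f = tissue$R1f, R2f = tissue$R2f, Rx = tissue$Rx,
       R1s = tissue$R1s, T2s = tissue$T2s, wz = sys$wz, b1 = sys$b1)
}

#' Number of RF pulses fitting in one cycle
#' @param cycle_time Cycle duration, s.
#' @param tr Repetition time, s.
#' @return `floor(cycle_time / tr)`.
#' @export
pulses_per_cycle <- function(cycle_time = 4, tr = 3.5e-3) {
  floor(cycle_time / tr)
}

#' Default shipped pulse train
#'
#' A smooth, spline-parameterized flip-angle/pulse-duration pattern produced
#' by the package's CRB optimizer ([optimize_train()]) for the joint
#' normalized CRB of all six biophysical parameters; regenerable with
#' `scripts` in the repository. Control points are stored as plain text under
#' `inst/extdata` and interpolated to the requested number of pulses.
#'
#' @param n_pulses Number of pulses (default 1142, i.e. a 4 s cycle at
#'   TR = 3.5 ms).
#' @param tr Repetition time, s.
#' @param cycle_time Cycle time, s.
#' @return A `qmt_train`.
#' @export
default_train <- function(n_pulses = 1142, tr = 3.5e-3, cycle_time = 4) {
  path <- system.file("extdata", "default_train.json", package = "qmtr")
  ctl <- jsonlite::read_json(path, simplifyVector = TRUE)
  train_from_controls(ctl$alpha_ctrl, ctl$trf_ctrl, n_pulses, tr, cycle_time,
                      trf_inv = ctl$trf_inv,
                      alpha_bounds = c(0, pi),
                      trf_bounds = c(ctl$trf_min, ctl$trf_max))
}

# spline-interpolate control points to per-pulse values, clamped to bounds
train_from_controls <- function(alpha_ctrl, trf_ctrl, n_pulses, tr,
                                cycle_time, trf_inv = 500e-6,
                                alpha_bounds = c(0, pi),
                                trf_bounds = c(1e-4, 1e-3)) {
  xc <- seq(1, n_pulses, length.out = length(alpha_ctrl))
  a <- spline(xc, alpha_ctrl, xout = seq_len(n_pulses), method = "natural")$y
  xc <- seq(1, n_pulses, length.out = length(trf_ctrl))
  d <- spline(xc, trf_ctrl, xout = seq_len(n_pulses), method = "natural")$y
  a <- pmin(pmax(a, alpha_bounds[1]), alpha_bounds[2])
  d <- pmin(pmax(d, trf_bounds[1]), min(trf_bounds[2], tr * 0.999))
  pulse_train(a, d, tr = tr, cycle_time = cycle_time, trf_inv = trf_inv)
}

#' Interval propagator (matrix exponential of the generator)
#'
#' Exact evolution operator `exp(dt * A)` for piecewise-constant
#' coefficients. The zero bottom row of the generator guarantees the
#' homogeneous coordinate is preserved.
#'
#' @param generator 6x6 generator from [build_generator()].
#' @param dt Interval duration, s; `>= 0`.
#' @return A 6x6 propagator matrix.
#' @export
interval_propagator <- function(generator, dt) {
  if (dt < 0) stop("interval_propagator: dt must be >= 0")
  if (!all(is.finite(generator)))
    stop("interval_propagator: non-finite generator entries")
  expm_cpp(generator * dt)
}

#' T2-selective inversion operator
#'
#' Full-pulse propagation of a rectangular pi pulse (Rabi frequency
#' `b1 * pi / trf_inv`) followed by the crusher contract: the transverse
#' components `xf, yf, xs` are zeroed. Because the pulse is long compared to
#' T2s but short compared to T2f, it inverts the free pool while mostly
#' saturating rather than inverting the semi-solid pool.
#'
#' @param tissue A `qmt_tissue`.
#' @param trf_inv Inversion-pulse duration, s.
#' @param b1 Transmit scale (nominal flip angle pi is scaled by `b1`).
#' @param wz Off-resonance, rad/s.
#' @param r2sl How to obtain the linearized semi-solid rate: `"exact"`
#'   (direct generalized-Bloch solve + root matching) or `"grid"`
#'   (bicubic interpolation; the path used inside fast simulations).
#' @return A 6x6 propagator.
#' @export
inversion_operator <- function(tissue, trf_inv = 500e-6, b1 = 1, wz = 0,
                               r2sl = c("exact", "grid")) {
  r2sl <- match.arg(r2sl)
  if (trf_inv <= 0) stop("inversion_operator: trf_inv must be > 0")
  aeff <- b1 * pi
  rate <- if (r2sl == "exact") {
    linearize_r2s(aeff, trf_inv, tissue$T2s)
  } else {
    r2sl_lookup(r2sl_grid(), aeff, trf_inv, tissue$T2s)
  }
  A <- build_generator(tissue, wy = aeff / trf_inv, wz = wz, r2sl = rate)
  P <- expm_cpp(A * trf_inv)
  P[c(1, 2, 4), ] <- 0  # crushers spoil xf, yf, xs
  P
}

#' Full-cycle propagator
#'
#' Composition of the inversion operator and, for each pulse `n`, the pulse
#' propagator (Rabi frequency with alternating sign, per-pulse `R2s,l`)
#' followed by the free interval `TR - TRF_n`, plus any trailing free
#' interval up to `cycle_time`.
#'
#' @param train A `qmt_train`.
#' @param tissue A `qmt_tissue`.
#' @param sys A `qmt_system` (M0 does not enter the propagator).
#' @return A 6x6 matrix mapping the state just before one inversion to the
#'   state just before the next.
#' @export
cycle_propagator <- function(train, tissue, sys = system_pars()) {
  g <- r2sl_grid()
  out <- simulate_cpp(pars_clist(tissue, sys), train_clist(train),
                      g$values, g$a0, g$da, g$l0, g$dl)
  out$cycle
}

#' Periodic steady state of the cycle
#'
#' The hybrid-state sequence repeats identically every cycle, so the spin
#' state is the unique fixed point `m` of the affine cycle map:
#' `(I - A5) m = b`, with `A5`/`b` the linear/affine parts of the 6x6 cycle
#' propagator. Requires the spectral radius of `A5` to be below 1, which
#' holds for any positive relaxation rates.
#'
#' @param cycle 6x6 cycle propagator from [cycle_propagator()].
#' @return A `qmt_state` (the state just before the inversion pulse).
#' @export
periodic_state <- function(cycle) {
  A5 <- cycle[1:5, 1:5, drop = FALSE]
  b5 <- cycle[1:5, 6]
  sr <- max(Mod(eigen(A5, only.values = TRUE)$values))
  if (sr >= 1)
    stop("periodic_state: cycle dynamics not contracting (spectral radius ",
         format(sr), ")")
  M <- diag(5) - A5
  if (rcond(M) < 1e-14)
    stop("periodic_state: degenerate cycle dynamics, (I - A) singular")
  m5 <- solve(M, b5)
  spin_state(m5[1], m5[2], m5[3], m5[4], m5[5])
}

#' Simulate the hybrid-state fingerprint
#'
#' Starting from the periodic steady state, applies the inversion and the
#' pulse train, recording the complex signal
#' `s_n = M0 (xf + i yf)` at the echo time TR/2 after each pulse center
#' (gradient moments are balanced each TR, making the mid-TR echo the
#' canonical observation point), demodulated for the pi phase increment.
#'
#' @inheritParams cycle_propagator
#' @return Complex vector of length `n_pulses` with class `qmt_fingerprint`;
#'   attributes record the sampling and demodulation conventions.
#' @export
simulate_fingerprint <- function(train, tissue, sys = system_pars()) {
  g <- r2sl_grid()
  out <- simulate_cpp(pars_clist(tissue, sys), train_clist(train),
                      g$values, g$a0, g$da, g$l0, g$dl)
  s <- sys$M0 * complex(real = out$xf, imaginary = out$yf)
  structure(s, class = "qmt_fingerprint", sampling = "echo (TR/2 after pulse center)",
            demodulation = "pi phase increment (per-pulse sign alternation)")
}
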