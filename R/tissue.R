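#' Tissue parameters of the unconstrained two-pool MT model
#'
#' Bundles the six biophysical unknowns of the unconstrained
#' magnetization-transfer model. The thermal-equilibrium magnetization is
#' normalized to `m0f + m0s = 1`, so `m0s` is the fractional size of the
#' semi-solid pool and `m0f = 1 - m0s` is derived.
#'
#' @param m0s Fractional semi-solid pool size, `0 <= m0s < 1`.
#' @param R1f Longitudinal relaxation rate of the free pool (1/s).
#' @param R2f Transverse relaxation rate of the free pool (1/s).
#' @param Rx Exchange rate between the pools (1/s).
#' @param R1s Longitudinal relaxation rate of the semi-solid pool (1/s).
#' @param T2s Transverse relaxation time of the semi-solid pool (s),
#'   typically ~10 us.
#' @return An object of class `qmt_tissue`: a named list with the six
#'   parameters plus the derived `m0f`.
#' @examples
#' wm <- tissue_pars(m0s = 0.212, R1f = 1 / 1.84, R2f = 1 / 0.0769,
#'                   Rx = 13.6, R1s = 1 / 0.34, T2s = 12.5e-6)
#' @export
tissue_pars <- function(m0s, R1f, R2f, Rx, R1s, T2s) {
  x <- list(m0s = m0s, R1f = R1f, R2f = R2f, Rx = Rx, R1s = R1s, T2s = T2s)
  if (!all(vapply(x, function(v) is.numeric(v) && length(v) == 1L &&
                  is.finite(v), logical(1))))
    stop("tissue_pars: all parameters must be finite scalars")
  if (m0s < 0 || m0s >= 1)
    stop("tissue_pars: m0s must satisfy 0 <= m0s < 1")
  if (R1f <= 0 || R2f <= 0 || Rx <= 0 || R1s <= 0)
    stop("tissue_pars: all rates must be > 0")
  if (T2s <= 0) stop("tissue_pars: T2s must be > 0")
  x$m0f <- 1 - m0s
  class(x) <- "qmt_tissue"
  x
}

#' @export
print.qmt_tissue <- function(x, ...) {
  cat("Two-pool MT tissue parameters:\n")
  cat(sprintf("  m0s = %.4g (m0f = %.4g)\n", x$m0s, x$m0f))
  cat(sprintf("  R1f = %.4g /s   R2f = %.4g /s\n", x$R1f, x$R2f))
  cat(sprintf("  Rx  = %.4g /s   R1s = %.4g /s   T2s = %.4g us\n",
              x$Rx, x$R1s, 1e6 * x$T2s))
  invisible(x)
}

#' System (nuisance) parameters: off-resonance, B1+ scale, and M0
#'
#' @param wz Off-resonance frequency (rad/s).
#' @param b1 Dimensionless transmit-field scale: the actual Rabi frequency is
#'   `b1` times the nominal one. Must be > 0.
#' @param M0 Complex scale jointly describing spin density and receive-coil
#'   sensitivity; `|M0| > 0`.
#' @return An object of class `qmt_system`.
#' @export
system_pars <- function(wz = 0, b1 = 1, M0 = 1 + 0i) {
  if (!is.numeric(wz) || !is.finite(wz)) stop("system_pars: wz must be finite")
  if (!is.numeric(b1) || b1 <= 0) stop("system_pars: b1 must be > 0")
  M0 <- as.complex(M0)
  if (!is.finite(Mod(M0)) || Mod(M0) == 0)
    stop("system_pars: |M0| must be > 0 and finite")
  structure(list(wz = wz, b1 = b1, M0 = M0), class = "qmt_system")
}

#' Spin state in homogeneous coordinates
#'
#' The 6-vector `(xf, yf, zf, xs, zs, 1)`: transverse and longitudinal
#' magnetization of the free pool, transverse and longitudinal magnetization
#' of the semi-solid pool, and the constant homogeneous coordinate that
#' carries the thermal-equilibrium drive.
#'
#' @param xf,yf,zf Free-pool magnetization components.
#' @param xs,zs Semi-solid pool magnetization components.
#' @param tissue Optional `qmt_tissue`; if given, pool-size bounds are checked.
#' @param tol Tolerance for the bound checks.
#' @return A numeric 6-vector of class `qmt_state`.
#' @export
spin_state <- function(xf = 0, yf = 0, zf = 0, xs = 0, zs = 0,
                       tissue = NULL, tol = 1e-9) {
  m <- c(xf = xf, yf = yf, zf = zf, xs = xs, zs = zs, h = 1)
  if (!all(is.finite(m))) stop("spin_state: components must be finite")
  if (!is.null(tissue)) {
    if (sqrt(xf^2 + yf^2 + zf^2) > tissue$m0f + tol)
      stop("spin_state: free-pool magnitude exceeds m0f")
    if (abs(zs) > tissue$m0s + tol)
      stop("spin_state: |zs| exceeds m0s")
  }
  structure(m, class = "qmt_state")
}

#' Thermal-equilibrium spin state of a tissue
#' @param tissue A `qmt_tissue`.
#' @return The state `(0, 0, m0f, 0, m0s, 1)`.
#' @export
equilibrium_state <- function(tissue) {
  spin_state(zf = tissue$m0f, zs = tissue$m0s, tissue = tissue)
}
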