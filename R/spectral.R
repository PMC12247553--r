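# Apparent-parameter theory: what an observer assuming R1s = R1f would
# infer from the longitudinal two-pool dynamics.

#' Longitudinal two-pool Hamiltonian
#'
#' In the absence of RF irradiation the longitudinal components decouple
#' from the transverse ones; their dynamics are governed by the 3x3
#' homogeneous-coordinate generator acting on `(zf, zs, 1)`.
#'
#' @param tissue A `qmt_tissue`.
#' @return A 3x3 matrix; the last row is identically zero.
#' @export
longitudinal_hamiltonian <- function(tissue) {
  m0s <- tissue$m0s; m0f <- tissue$m0f
  matrix(c(-tissue$R1f - tissue$Rx * m0s,  tissue$Rx * m0f, m0f * tissue$R1f,
           tissue$Rx * m0s, -tissue$R1s - tissue$Rx * m0f, m0s * tissue$R1s,
           0, 0, 0),
         nrow = 3, byrow = TRUE)
}

#' Exact apparent relaxation and exchange rates
#'
#' Eigendecomposition of the longitudinal Hamiltonian: one eigenvalue is
#' zero (thermal equilibrium); the magnitude of the smaller remaining
#' eigenvalue is the apparent free-pool relaxation rate `R1f_a` (the rate a
#' mono-exponential observer sees at late inversion times), and the larger
#' one is the apparent exchange rate `Rx_a`.
#'
#' @param tissue A `qmt_tissue` with `0 < m0s < 1`.
#' @param degenerate_tol Relative tolerance below which the two nonzero
#'   eigenvalues are flagged as degenerate (attribute `degenerate`).
#' @return Named vector `c(R1f_a, Rx_a)` (1/s).
#' @export
exact_apparent_rates <- function(tissue, degenerate_tol = 1e-8) {
  if (tissue$m0s <= 0 || tissue$m0s >= 1)
    stop("exact_apparent_rates: requires 0 < m0s < 1")
  H <- longitudinal_hamiltonian(tissue)
  lam <- eigen(H[1:2, 1:2], only.values = TRUE)$values
  lam <- sort(abs(lam))
  out <- c(R1f_a = lam[1], Rx_a = lam[2])
  if (abs(lam[2] - lam[1]) <= degenerate_tol * lam[2]) {
    warning("exact_apparent_rates: near-degenerate eigenvalues")
    attr(out, "degenerate") <- TRUE
  }
  out
}

#' Taylor-expanded apparent free-pool relaxation rate
#'
#' Second-order Taylor expansion of the exact eigenvalue around
#' `R1s = R1f`:
#' `R1f_a ~ R1f + m0s (R1s - R1f) - m0f m0s (R1s - R1f)^2 / Rx`.
#' The linear term shows that magnetization transfer contributes directly to
#' the observed longitudinal relaxation whenever `m0s (R1s - R1f)` is not
#' negligible against `R1f`.
#'
#' @param tissue A `qmt_tissue`.
#' @param order 1 returns only `R1f` plus the linear correction; 2 (default)
#'   adds the quadratic term (requires `Rx > 0`).
#' @return `R1f_a` in 1/s.
#' @export
taylor_r1f_a <- function(tissue, order = 2) {
  d <- tissue$R1s - tissue$R1f
  lin <- tissue$R1f + tissue$m0s * d
  if (order == 1) return(lin)
  if (tissue$Rx == 0) stop("taylor_r1f_a: quadratic term requires Rx > 0")
  lin - tissue$m0f * tissue$m0s * d^2 / tissue$Rx
}

#' Taylor-expanded apparent exchange rate
#'
#' `Rx_a ~ (Rx + R1f) + m0f (R1s - R1f) + m0f m0s (R1s - R1f)^2 / Rx`;
#' dominated by the exchange rate for most tissues, hence interpreted as a
#' cross-relaxation rate.
#'
#' @param tissue A `qmt_tissue` with `Rx > 0`.
#' @return `Rx_a` in 1/s.
#' @export
taylor_rx_a <- function(tissue) {
  if (tissue$Rx == 0) stop("taylor_rx_a: requires Rx > 0")
  d <- tissue$R1s - tissue$R1f
  (tissue$Rx + tissue$R1f) + tissue$m0f * d +
    tissue$m0f * tissue$m0s * d^2 / tissue$Rx
}

#' Taylor-expanded apparent semi-solid pool size
#'
#' `m0s_a ~ m0s (1 - 2 m0f (R1s - R1f) / Rx)`: when `R1s > R1f`, an
#' analysis constraining `R1s = R1f` under-estimates the semi-solid pool
#' size.
#'
#' @param tissue A `qmt_tissue` with `Rx > 0`.
#' @return Apparent pool size (dimensionless).
#' @export
taylor_m0s_a <- function(tissue) {
  if (tissue$Rx == 0) stop("taylor_m0s_a: requires Rx > 0")
  d <- tissue$R1s - tissue$R1f
  tissue$m0s * (1 - 2 * tissue$m0f * d / tissue$Rx)
}

#' Convert between semi-solid pool-size normalizations
#'
#' Two conventions coexist in the MT literature: normalizing the total pool
#' to one (`m0f + m0s = 1`, used throughout this package) or normalizing the
#' free pool to one (`m0f = 1`, pool size written `m0s_tilde`). The bijection
#' is `m0s = m0s_tilde / (1 + m0s_tilde)` and
#' `m0s_tilde = m0s / (1 - m0s)`.
#'
#' @param value Pool size(s) to convert.
#' @param direction `"tilde_to_frac"` maps `m0s_tilde -> m0s`;
#'   `"frac_to_tilde"` maps `m0s -> m0s_tilde`.
#' @return Converted value(s).
#' @export
convert_pool_size <- function(value,
                              direction = c("tilde_to_frac",
                                            "frac_to_tilde")) {
  direction <- match.arg(direction)
  if (direction == "tilde_to_frac") {
    if (any(value < 0)) stop("convert_pool_size: m0s_tilde must be >= 0")
    value / (1 + value)
  } else {
    if (any(value < 0 | value >= 1))
      stop("convert_pool_size: m0s must be in [0, 1)")
    value / (1 - value)
  }
}

#' Voxel-wise apparent-parameter maps
#'
#' Applies the Taylor (or exact) apparent-parameter formulas voxel-by-voxel
#' to co-registered parameter maps. Voxels outside the mask, with any
#' non-finite input, or with `m0s` below `min_m0s` (semi-solid
#' characteristics are unreliable at vanishing pool size, e.g. CSF and
#' partial-volume voxels) are set to `NA`.
#'
#' @param m0s,R1f,R1s,Rx Numeric arrays of identical dimension.
#' @param mask Logical array of the same dimension, or `NULL` for all
#'   voxels.
#' @param method `"taylor"` (default; the formula set used for map display)
#'   or `"exact"` (eigendecomposition per voxel).
#' @param min_m0s Exclusion threshold on `m0s` (default 0.01).
#' @return Named list of arrays `R1f_a`, `Rx_a`, `m0s_a`, plus the method
#'   tag as attribute.
#' @export
apparent_maps <- function(m0s, R1f, R1s, Rx, mask = NULL,
                          method = c("taylor", "exact"), min_m0s = 0.01) {
  method <- match.arg(method)
  dm <- dim(m0s) %||% length(m0s)
  same <- function(x) identical(dim(x) %||% length(x), dm)
  if (!same(R1f) || !same(R1s) || !same(Rx))
    stop("apparent_maps: map dimensions differ")
  if (is.null(mask)) mask <- array(TRUE, dim = if (is.null(dim(m0s)))
    length(m0s) else dim(m0s))
  if (!same(mask)) stop("apparent_maps: mask dimension differs")
  ok <- mask & is.finite(m0s) & is.finite(R1f) & is.finite(R1s) &
    is.finite(Rx) & m0s >= min_m0s & m0s < 1 & Rx > 0
  mk <- function() { x <- m0s; x[] <- NA_real_; x }
  r1fa <- mk(); rxa <- mk(); m0sa <- mk()
  idx <- which(ok)
  if (method == "taylor") {
    d <- R1s[idx] - R1f[idx]
    m0f <- 1 - m0s[idx]
    r1fa[idx] <- R1f[idx] + m0s[idx] * d - m0f * m0s[idx] * d^2 / Rx[idx]
    rxa[idx] <- (Rx[idx] + R1f[idx]) + m0f * d + m0f * m0s[idx] * d^2 / Rx[idx]
    m0sa[idx] <- m0s[idx] * (1 - 2 * m0f * d / Rx[idx])
  } else {
    for (i in idx) {
      tis <- tissue_pars(m0s[i], R1f[i], 1, Rx[i], R1s[i], 1e-5)
      ex <- exact_apparent_rates(tis)
      r1fa[i] <- ex["R1f_a"]; rxa[i] <- ex["Rx_a"]
      m0sa[i] <- taylor_m0s_a(tis)
    }
  }
  structure(list(R1f_a = r1fa, Rx_a = rxa, m0s_a = m0sa), method = method)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
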