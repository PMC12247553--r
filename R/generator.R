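#' Bloch-McConnell generator of the two-pool MT model
#'
#' Assembles the 6x6 generator of the homogeneous-coordinate spin state
#' `(xf, yf, zf, xs, zs, 1)`:
#' free-pool rotation/relaxation block (`R2f`, off-resonance `wz`, Rabi
#' frequency `wy` coupling `xf <-> zf`), the semi-solid block with the
#' linearized transverse rate `-R2s,l` and `wy` coupling `xs <-> zs`,
#' exchange terms `+/- Rx m0s`, `+/- Rx m0f` between `zf` and `zs`, and the
#' thermal-equilibrium drive column (`m0f R1f`, `m0s R1s`). The last row is
#' identically zero so that the 6th state component stays 1 under
#' propagation.
#'
#' @param tissue A `qmt_tissue`.
#' @param wy Rabi frequency of the RF field, rad/s (0 during free evolution).
#' @param wz Off-resonance frequency, rad/s.
#' @param r2sl Linearized semi-solid transverse rate, 1/s (see
#'   [linearize_r2s()]).
#' @return A 6x6 numeric matrix.
#' @export
build_generator <- function(tissue, wy, wz, r2sl) {
  stopifnot(inherits(tissue, "qmt_tissue"))
  if (!all(is.finite(c(wy, wz, r2sl))))
    stop("build_generator: wy, wz, r2sl must be finite")
  m0s <- tissue$m0s; m0f <- tissue$m0f
  A <- matrix(0, 6, 6)
  A[1, 1] <- -tissue$R2f; A[1, 2] <- -wz; A[1, 3] <- wy
  A[2, 1] <- wz;          A[2, 2] <- -tissue$R2f
  A[3, 1] <- -wy
  A[3, 3] <- -(tissue$R1f + tissue$Rx * m0s)
  A[3, 5] <- tissue$Rx * m0f
  A[3, 6] <- m0f * tissue$R1f
  A[4, 4] <- -r2sl; A[4, 5] <- wy
  A[5, 3] <- tissue$Rx * m0s
  A[5, 4] <- -wy
  A[5, 5] <- -(tissue$R1s + tissue$Rx * m0f)
  A[5, 6] <- m0s * tissue$R1s
  A
}
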