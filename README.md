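# qmtr — unconstrained quantitative magnetization transfer imaging

`qmtr` is an R toolkit for **unconstrained two-pool quantitative
magnetization transfer (qMT)** imaging: simulating hybrid-state pulse
sequences for the coupled free/semi-solid spin system, evaluating and
optimizing their encoding power via the Cramér-Rao bound (CRB), fitting the
full model voxel-by-voxel, and relating unconstrained parameters to the
"apparent" parameters that conventional, constrained analyses report.

## The model

Magnetization transfer couples two proton pools: a *free* pool (liquid
water, observable, transverse relaxation rate `R2f`) and a *semi-solid*
pool (macromolecular protons, `T2s ≈ 10 µs`, invisible to direct imaging)
of fractional size `m0s` (normalized so `m0f + m0s = 1`), exchanging
longitudinal magnetization at rate `Rx`. The spin state
`(xf, yf, zf, xs, zs, 1)` evolves under a Bloch-McConnell generator whose
semi-solid block uses the **generalized Bloch model**: the super-Lorentzian
lineshape's non-exponential decay is solved as a Volterra equation during
each RF pulse and replaced, pulse-by-pulse, by a *linearized* rate
`R2s,l(R2s, α, TRF)` that reproduces the same end-of-pulse magnetization.

Most qMT methods constrain `R1s = R1f` because the two longitudinal rates
are hard to disentangle. Removing the constraint changes what the other
parameters mean. Eigen-analysis of the longitudinal dynamics gives the
**apparent** parameters a constrained observer would infer, with Taylor
expansions around `R1s = R1f`:

    R1f,a ≈ R1f + m0s (R1s − R1f) − m0f m0s (R1s − R1f)² / Rx
    Rx,a  ≈ (Rx + R1f) + m0f (R1s − R1f) + m0f m0s (R1s − R1f)² / Rx
    m0s,a ≈ m0s (1 − 2 m0f (R1s − R1f) / Rx)

With `R1f = 0.5 /s`, `R1s = 3 /s`, `m0s = 0.2`, the linear MT correction to
`R1f,a` is `0.5 /s` — as large as `R1f` itself — and with `Rx = 15 /s` the
apparent pool size drops to `≈ 0.15`: magnetization transfer is itself a
driver of observed longitudinal relaxation, and constrained fits
under-estimate both `T1f` differences and the pool size.

The sequence model is a hybrid-state train: a rectangular, T2-selective π
inversion pulse (crusher gradients spoil all transverse magnetization),
then 1142 rectangular pulses with varying flip angle `α_n ∈ [0, π]` and
duration `TRF,n`, π phase increment, `TR = 3.5 ms`, repeating every 4 s
cycle. Flip angles steer free-pool relaxation and exchange; pulse durations
steer semi-solid saturation — the two handles the CRB optimizer plays with.

## Worked example

```r
library(qmtr)

# healthy white-matter ROI means
wm <- tissue_pars(m0s = 0.212, R1f = 1/1.84, R2f = 1/0.0769,
                  Rx = 13.6, R1s = 1/0.34, T2s = 12.5e-6)

exact_apparent_rates(wm)
#>   R1f_a    Rx_a
#>  0.9880 16.0967
round(taylor_m0s_a(wm), 4)
#> [1] 0.1531
```

Although `T1f = 1.84 s` and `T1s = 0.34 s` differ by a factor of five, a
constrained observer sees `T1f,a = 1/0.988 ≈ 1.01 s` — and a pool size of
0.153 instead of 0.212.

```r
tr <- default_train()            # shipped CRB-optimized pattern
s  <- simulate_fingerprint(tr, wm, system_pars())
length(s); max(Mod(s))
#> [1] 1142
#> [1] 0.1712

crb_report(tr, crb_reference_pars()$tissue, method = "cstep")[1:6, c(1, 2, 4)]
#>   unknown    value ncrb
#> 1     m0s  0.25000  266
#> 2     R1f  0.50000  320
#> 3     R2f 15.40000  103
#> 4      Rx 20.00000  787
#> 5     R1s  2.00000 2985
#> 6     T2s  0.00001  912
```

The normalized CRB (`CRB · T_cycle / θ²`, seconds; an inverse squared
SNR-efficiency per unit time) shows the familiar ordering: `m0s`, `R1f`,
`R2f` are well-encoded, while `Rx`, `R1s`, `T2s` carry the largest bounds —
the parameters whose maps are noisiest in practice.

Voxel-wise estimation (`fit_voxel`, `fit_map`) is bounded
Levenberg-Marquardt over all ten real unknowns (`m0s, R1f, R2f, Rx, R1s,
T2s`, off-resonance `ωz`, transmit scale `B1+`, complex `M0`), optionally
in a rank-15 SVD subspace of a fingerprint dictionary
(`build_dictionary`, `fingerprint_subspace`, `compress_fingerprint`).
`make_phantom` + `monte_carlo` provide a fully synthetic test bed; at
SNR 100 the estimator standard deviations sit within a few percent of
`sqrt(CRB)`.

A command-line interface wraps the same operations:

```sh
Rscript inst/cli/qmt.R phantom --out ph --train train.json --shape 16,16,16 --seed 1
Rscript inst/cli/qmt.R fit     --data ph --train train.json --out maps
Rscript inst/cli/qmt.R apparent --maps maps --out apparent
```

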