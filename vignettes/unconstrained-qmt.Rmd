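---
title: "Unconstrained qMT: model, numerics, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unconstrained qMT: model, numerics, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's account of the science it implements: the
spin model and its assumptions, the parameters that matter and their
defaults, the numerical schemes and their tolerances, what the synthetic
data emulate (and deliberately do not), and the design decisions taken
where more than one reasonable implementation exists. Everything
quantitative stated here is computed by the test suite or the acceptance
script; nothing is quoted from elsewhere.

## 1. The two-pool model

Brain-tissue magnetization is modeled as a *free* pool (liquid water;
fraction `m0f`) and a *semi-solid* pool (macromolecular protons; fraction
`m0s`, with the normalization `m0f + m0s = 1`). The homogeneous-coordinate
state `(xf, yf, zf, xs, zs, 1)` evolves under a 6×6 Bloch-McConnell
generator (`build_generator()`): free-pool precession/relaxation
(`R2f`, off-resonance `ωz`, Rabi frequency `ωy`), a semi-solid block with
transverse rate `R2s,l` and `ωy` coupling `xs ↔ zs`, longitudinal exchange
`±Rx·m0s`, `±Rx·m0f`, and equilibrium drives `m0f·R1f`, `m0s·R1s` in the
last column. The `ys` component is dropped (valid because the semi-solid
transverse decay rate vastly exceeds `ωz`), and the zero bottom row makes
the affine dynamics linear, so matrix exponentials propagate exactly over
piecewise-constant intervals.

Units everywhere: rad, s, 1/s, rad/s. Files store these base units only;
the five orders of magnitude between `TR` (ms) and `T2s` (µs) make display
conversions a correctness hazard, so they are confined to print methods.

### Semi-solid saturation and the linearized rate

The semi-solid pool's transverse decay is non-exponential
(super-Lorentzian). During a rectangular pulse of constant `ωy = α/TRF`
its longitudinal component obeys the Volterra equation

    ∂t zs(t) = −ωy² ∫₀ᵗ G((t−τ)/T2s) zs(τ) dτ,
    G(x) = ∫₀¹ exp(−x² (3ζ²−1)²/8) dζ,

solved by `saturate_semisolid_pulse()`. Two modeling assumptions, fixed
deliberately: **(a)** longitudinal relaxation and exchange are frozen
during pulses when computing this saturation (pulse durations of 0.1–1 ms
are far below `1/R1s` and `1/Rx`); **(b)** the Bloch-McConnell generator
then uses an *effective exponential* rate `R2s,l(R2s, α, TRF)`
(`linearize_r2s()`), defined as the transverse rate for which a plain 2×2
rotation-with-decay propagation of `(xs, zs)` reproduces the
generalized-Bloch `zs` at the end of the pulse. `R2s,l(α = 0) := 0` by
convention — without irradiation the rate is unobservable.

## 2. Numerics of the lineshape layer

* **Green's function.** Adaptive Simpson quadrature split at the
  stationary point `ζ = 1/√3` (tolerance 1e−12); for the Volterra solver a
  lookup table in normalized lag `x = τ/T2s` (spacing 0.004, Catmull-Rom
  interpolation, asymptotic `1/x` tail beyond the table) is precomputed
  once per session.
* **Volterra solver.** Product integration with trapezoidal weights,
  implicit in the newest point; step count `24·(TRF/T2s)` clamped to
  [512, 2048]; one Richardson extrapolation of the O(h²) scheme. Against a
  ≥10⁴-step oracle with quadrature-exact kernel values the default solver
  agrees to ~2e−9 at the reference case (tested).
* **Root finding.** `R2s,l·T2s` is found by bisection after a log-spaced
  scan locates the bracket. The scan matters: beyond `α ≈ π` the damped
  rotation is non-monotonic in the rate.
* **No-root region.** For effective flip angles beyond ~π (reachable only
  through `B1+ > 1` scaling of a π pulse) there are `(α, TRF/T2s)`
  combinations where *no* exponential rate reproduces the
  generalized-Bloch end value (the damped rotation cannot reach end values
  more inverted than its envelope). Direct evaluation raises an error
  there, as the matching is genuinely undefined; the precomputed grid
  stores the least-misfit rate instead, which is continuous at the
  boundary. Self-consistency at 1e−8 is asserted over the exact regime
  `α ≤ π`.
* **The grid.** `R2s,l·T2s` depends only on `(α, TRF/T2s)`, so one grid
  serves all tissues: uniform in `α ∈ [0, 4.8]` (step 0.1) ×
  `log(TRF/T2s)`, `TRF/T2s ∈ [0.5, 1100]` (48 nodes), bicubic (Keys)
  interpolation. The range exceeds a `[0, π] × [1, 200]` design on
  purpose: the fit bounds (below) allow `B1+` up to 1.5 and `T2s` down to
  1 µs, and the grid is the analytic fast path *inside* the fit model, so
  it must cover everything the optimizer may probe. The `α = 0` column
  stores the small-angle limit of the matching rate (from the O(ωy²)
  expansions of both models), not the user-facing 0 convention — storing 0
  would poison the interpolant near small flip angles. Interpolation error
  against direct evaluation is ~1e−5 relative (tested at 1%).

## 3. The sequence engine

A cycle is: rectangular π inversion (duration `trf_inv`, default 500 µs —
a value the protocol does not pin down, made configurable), crusher
contract (transverse components `xf, yf, xs` zeroed exactly), then
`n_pulses` pulses at spacing `TR`, each `[pulse, echo, free]`, plus any
trailing free interval up to `cycle_time` (3 ms at the 1142 × 3.5 ms
default). Two conventions the protocol leaves open were fixed as:

* **Phase increment (π per TR).** Implemented as a sign alternation of
  `ωy` with matching `(−1)ⁿ` demodulation of the signal — the standard
  balanced-SSFP equivalence; it keeps on-resonance states real.
* **Sampling time.** `s_n = M0·(xf + i·yf)` is recorded at `TR/2` after
  the pulse center — the canonical echo of a sequence with balanced
  gradient moments. In the single-pool limit this reproduces the
  balanced-SSFP closed form once the exactly-known transverse decay from
  pulse end to echo is divided out (tested to 1e−6).

During free intervals the semi-solid transverse rate is the natural
`1/T2s` (`xs` decays to nothing within microseconds, consistent with the
crushers); during pulses it is the per-pulse `R2s,l`. The periodic
boundary condition (`periodic_state()`) is the fixed point of the affine
cycle map, solved directly from `(I − A₅)m = b` and cross-checked against
200-cycle power iteration (1e−8). The full simulator is validated against
an adaptive Dormand-Prince integration of the same piecewise-constant
model: maximum deviation ~5e−11 over a 1142-pulse cycle (tolerance 1e−6).

The shipped default train (`default_train()`) is a natural-cubic-spline
pattern over 8 control points per channel produced by this package's own
CRB optimizer (seed 20260910) — the original optimized patterns are not
public, so the package ships what its own tools produce, stored as plain
JSON control points.

## 4. CRB machinery

Derivatives of the fingerprint with respect to all ten real unknowns
(`m0s, R1f, R2f, Rx, R1s, T2s, ωz, B1+, Re M0, Im M0`) come in two
implementations: central finite differences (relative step 1e−4, with
fixed characteristic scales for zero-valued parameters such as `ωz`), and
**complex-step differentiation** through the complexified simulation. The
complex step *is* augmented propagation: the O(h) term of
`exp(Δt·A(θ+ih))` equals the Fréchet-derivative block of
`[[A, ∂A], [0, A]]` — but without subtractive cancellation, so it serves
as the machine-precision validation path (the two agree to ~1e−9 relative,
tested at 1e−6). `M0` derivatives are analytic.

Fisher information for complex white Gaussian noise is
`Re(Jᴴ J)/σ²`; conditioning is assessed on the unit-diagonal scaling so it
reflects derivative collinearity rather than parameter units, with the
most collinear pair named on failure. The **normalized CRB** is
`CRB·T_cycle/θ²` (seconds) at unit-variance noise per unit time — the θ²
normalization is standard; the time/noise constant is a convention and
cancels in all comparisons and in the optimizer objective.

`optimize_train()` minimizes the weighted sum of normalized CRBs of the
six biophysical parameters at the fixed reference point
(`m0s 0.25, R1f 0.5, R2f 15.4, Rx 20, R1s 2 /s, T2s 10 µs, ωz 0, B1+ 1`)
over spline control points of `α` and `TRF`, with L-BFGS-B and seeded
random restarts. A noteworthy property the tests pin down: a
constant-α/constant-TRF train is CRB-*singular* at this reference point
(the `R1s` and `R1f` derivatives are collinear) — varying the pattern is
not an optimization nicety but the thing that makes the unconstrained
model identifiable at all.

## 5. Estimation

`fit_voxel()` is bounded Levenberg-Marquardt (hand-written; projection
onto box bounds, multiplicative damping) over the ten real unknowns, with
the model evaluated through the full simulator, optionally compressed to a
rank-15 SVD subspace of a dictionary. Real and imaginary parts are fitted
jointly, the global phase absorbed into complex `M0` (first-coefficient
normalization is exposed as an alternative that removes `M0` from the
unknown set; both paths agree on the tissue parameters, tested). A
neural-network estimator is explicitly out of scope; NLLS estimates the
same quantity, is deterministic, and its efficiency is measurable against
the CRB. Default bounds: `m0s ∈ [0, 0.5]`, `R1f ∈ [0.1, 5]`,
`R2f ∈ [1, 50]`, `Rx ∈ [1, 100]`, `R1s ∈ [0.1, 20]` (1/s),
`T2s ∈ [1, 30] µs`, `ωz ∈ ±2π·200 rad/s`, `B1+ ∈ [0.5, 1.5]`.

Multi-start policy: caller-supplied init, a fixed physiologic default, and
(when a dictionary is supplied) the best-matching atom; the lowest-cost
converged fit wins, with a linear least-squares `M0` start each time.

**A finding worth recording** (ledgered; asserted by the tests): fitting
the *full fingerprint* with `R1s` constrained to `R1f` does **not**
under-estimate `m0s` — the constrained full-signal fit drifts to *larger*
pool sizes, because the steady-state saturation observables compensate
differently than the longitudinal eigenmodes. The classic
pool-size-under-estimation bias belongs to the longitudinal-recovery
domain, where the apparent-parameter theory lives; the test suite
demonstrates it there (constrained fits of two-pool inversion-recovery
curves: `m0s` biased down, `R1f` biased up).

## 6. Apparent parameters

`exact_apparent_rates()` eigendecomposes the 2×2 longitudinal block (one
eigenvalue of the 3×3 is always 0: thermal equilibrium); the *apparent*
free-pool rate is the smaller nonzero eigenvalue in magnitude, the
apparent exchange rate the larger — the absolute-value ordering is part of
the definition. The Taylor forms (`taylor_r1f_a()`, `taylor_rx_a()`,
`taylor_m0s_a()`) agree with the exact eigenvalues to better than 1% at
the worked-example point and exactly at `R1s = R1f`.

Voxel-wise maps (`apparent_maps()`) exclude voxels with `m0s < 0.01`:
semi-solid characteristics are unreliable at vanishing pool size
(CSF, partial-volume voxels), and the Taylor expressions divide by `Rx`.

One number deliberately left unreconciled: inserting the white-matter ROI
*means* (`m0s 0.212, T1f 1.84 s, T1s 0.34 s, Rx 13.6 /s`) into the exact
eigendecomposition gives `T1f,a = 1.012 s` (Taylor: 1.019 s), whereas
voxel-wise apparent maps averaged over an ROI are reported near 0.94 s in
the unconstrained-qMT literature. The mapping is nonlinear, so the
apparent rate of the mean need not equal the mean apparent rate; both
numbers are recorded and no agreement is forced.

## 7. Synthetic data: the stated world

`make_phantom()` builds nested ellipsoids — CSF-like core, gray-matter
shell, white-matter bulk — at 8³–32³ voxels. Class values are the
healthy-control ROI means (rates from the characteristic times):

| class | m0s | R1f (1/s) | R2f (1/s) | Rx (1/s) | R1s (1/s) | T2s (µs) |
|-------|------|-----------|-----------|----------|-----------|----------|
| WM    | 0.212 | 1/1.84   | 1/0.0769  | 13.6     | 1/0.34    | 12.5     |
| GM    | 0.098 | 1/2.46   | 1/0.083   | 14.0     | 1/0.42    | 14.4     |
| CSF   | 0.005 | 0.25     | 0.5       | 13.6     | 2.0       | 12.0     |

The CSF row is a stand-in (near-zero pool size, long relaxation times)
chosen once to exercise the low-`m0s` exclusion logic; no literature claim
is attached to it. Optional per-voxel jitter uses the published ROI
standard deviations, delta-method-converted to rate units. Field maps are
smooth low-order polynomials: `ωz` spanning ±2π·30 rad/s, `B1+` spanning
0.9–1.1 — inside the fit bounds, as in a reasonably shimmed brain exam.
Noise is i.i.d. complex Gaussian per channel (the model under which the
CRB applies); SNR is referenced to the largest fingerprint magnitude,
`σ = max|s_n| / SNR`.

What the phantom deliberately does **not** emulate: anatomy, k-space
undersampling and reconstruction artifacts, motion, coil sensitivities,
partial-volume mixtures, myelin-water compartments. A green
phantom-recovery test therefore establishes correctness and statistical
efficiency of the *estimator on the stated model* — not robustness to
model violations.

Reduced problem sizes in the tests are a time-budget choice, stated where
used: Monte-Carlo runs use the shipped pattern resampled to 200 pulses
with `TR` stretched to 20 ms so the full 4 s inversion-recovery window —
the backbone of `R1f`/`R1s` encoding — is preserved.

## 8. Known limitations

* Single lineshape (super-Lorentzian); no Lorentzian/Gaussian option, no
  temperature or offset dependence of the lineshape.
* The linearized-rate grid clamps below `TRF/T2s = 0.5` (pulses much
  shorter than `T2s` are outside the physical protocol; the clamp only
  matters for mathematical limit tests, which set `m0s = 0`).
* The fitted model assumes the noiseless forward model is exact;
  reconstruction-domain effects (subspace truncation of *measured* data,
  coloured noise) enter only through the rank-15 compression option.
* The optimizer explores a spline-restricted pattern family with a fixed
  reference tissue; it reproduces the qualitative CRB ordering, not any
  particular published pattern.
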