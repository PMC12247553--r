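# Shared fixtures: tissue parameter sets and small pulse trains.
# All fixtures are built in code; nothing is read from disk.

# healthy-control ROI means (entire white matter / cortical gray matter)
wm_tissue <- function() {
  tissue_pars(m0s = 0.212, R1f = 1 / 1.84, R2f = 1 / 0.0769,
              Rx = 13.6, R1s = 1 / 0.34, T2s = 12.5e-6)
}

gm_tissue <- function() {
  tissue_pars(m0s = 0.098, R1f = 1 / 2.46, R2f = 1 / 0.083,
              Rx = 14.0, R1s = 1 / 0.42, T2s = 14.4e-6)
}

# worked-example parameters of the apparent-parameter theory
example_tissue <- function(Rx = 15) {
  tissue_pars(m0s = 0.2, R1f = 0.5, R2f = 15, Rx = Rx, R1s = 3, T2s = 1e-5)
}

# reduced train used throughout the tests: the shipped (optimized) pattern
# resampled to n pulses; TR stretched so one cycle still covers the full 4 s
# inversion-recovery window
test_train <- function(n = 200, tr = 4 / n, cycle_time = 4) {
  default_train(n, tr = tr, cycle_time = cycle_time)
}

# small constant train (fast, deliberately unoptimized)
const_train <- function(n = 50, alpha = pi / 8, trf = 3e-4, tr = 3.5e-3,
                        cycle_time = n * tr + 1e-3, ...) {
  pulse_train(rep(alpha, n), rep(trf, n), tr = tr, cycle_time = cycle_time,
              ...)
}
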