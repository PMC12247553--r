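# Independent oracles used by the tests. These deliberately avoid the code
# paths they validate: quadrature via stats::integrate, matrix exponentials
# via Matrix::expm, ODE integration via a hand-coded adaptive
# Dormand-Prince(4,5), and the Volterra equation via a fine-step R
# implementation with quadrature-evaluated kernel values.

# Green's function by adaptive quadrature (stats::integrate)
green_oracle <- function(x, rel.tol = 1e-12) {
  vapply(x, function(xi)
    integrate(function(z) exp(-xi^2 * (3 * z^2 - 1)^2 / 8), 0, 1,
              rel.tol = rel.tol, subdivisions = 2000L)$value,
    numeric(1))
}

# fine-step product integration of the generalized-Bloch Volterra equation
# (trapezoidal weights, implicit newest point), kernel via green_oracle
volterra_oracle <- function(alpha, trf, T2s, n = 12800) {
  r <- trf / T2s
  h <- r / n
  kap <- alpha / r
  G <- green_oracle((0:n) * h, rel.tol = 1e-10)
  z <- numeric(n + 1); z[1] <- 1
  f <- numeric(n + 1)
  den <- 1 + 0.25 * h^2 * kap^2 * G[1]
  for (k in 0:(n - 1)) {
    jj <- seq_len(k)
    s <- 0.5 * G[k + 2] + (if (k > 0) sum(G[k + 2 - jj] * z[jj + 1]) else 0)
    Ip <- h * s
    zn <- (z[k + 1] + 0.5 * h * (f[k + 1] - kap^2 * Ip)) / den
    z[k + 2] <- zn
    f[k + 2] <- -kap^2 * (Ip + 0.5 * h * G[1] * zn)
  }
  z[n + 1]
}

# adaptive Dormand-Prince(4,5) for the linear system y' = A y
rk45_lin <- function(A, y0, t_end, rtol = 1e-10, atol = 1e-13) {
  if (t_end == 0) return(y0)
  a <- list(c(1/5),
            c(3/40, 9/40),
            c(44/45, -56/15, 32/9),
            c(19372/6561, -25360/2187, 64448/6561, -212/729),
            c(9017/3168, -355/33, 46732/5247, 49/176, -5103/18656),
            c(35/384, 0, 500/1113, 125/192, -2187/6784, 11/84))
  b4 <- c(5179/57600, 0, 7571/16695, 393/640, -92097/339200, 187/2100, 1/40)
  b5 <- c(35/384, 0, 500/1113, 125/192, -2187/6784, 11/84, 0)
  y <- y0
  t <- 0
  # conservative first step from the spectral scale of A
  h <- min(t_end, 0.1 / max(abs(A), 1e-12))
  K <- matrix(0, length(y0), 7)
  while (t < t_end) {
    h <- min(h, t_end - t)
    K[, 1] <- A %*% y
    for (s in 1:5)
      K[, s + 1] <- A %*% (y + h * (K[, 1:s, drop = FALSE] %*% a[[s]]))
    y5 <- y + h * (K[, 1:6] %*% b5[1:6])
    K[, 7] <- A %*% y5
    y4 <- y + h * (K %*% b4)
    sc <- atol + rtol * pmax(abs(y), abs(y5))
    err <- sqrt(mean(((y5 - y4) / sc)^2))
    if (err <= 1 || h < 1e-12 * t_end) {
      t <- t + h
      y <- as.numeric(y5)
    }
    h <- h * min(5, max(0.2, 0.9 * (1 / max(err, 1e-16))^(1/5)))
  }
  y
}

# ODE-integrated fingerprint through the full cycle, starting from `state`.
# Uses the same per-pulse R2s,l values as the production simulator (the
# linearization is part of the model; this checks the propagation). During
# free intervals xs decouples (wy = 0) and is advanced analytically to keep
# the explicit integrator out of the stiff 1/T2s mode.
ode_fingerprint <- function(train, tissue, sys, state, rtol = 1e-10) {
  g <- r2sl_grid()
  n <- train$n_pulses
  y <- as.numeric(state)
  free_step <- function(y, dt) {
    Af <- build_generator(tissue, 0, sys$wz, 0)
    xs0 <- y[4]
    Af[4, ] <- 0
    y <- rk45_lin(Af, y, dt, rtol = rtol)
    y[4] <- xs0 * exp(-dt / tissue$T2s)
    y
  }
  if (train$inversion) {
    aeff <- sys$b1 * pi
    r2sl <- r2sl_lookup(g, aeff, train$trf_inv, tissue$T2s)
    Ai <- build_generator(tissue, aeff / train$trf_inv, sys$wz, r2sl)
    y <- rk45_lin(Ai, y, train$trf_inv, rtol = rtol)
    y[c(1, 2, 4)] <- 0
  }
  s <- complex(n)
  for (k in seq_len(n)) {
    aeff <- sys$b1 * train$alpha[k]
    sgn <- if (k %% 2 == 1) 1 else -1
    r2sl <- r2sl_lookup(g, aeff, train$trf[k], tissue$T2s)
    Ap <- build_generator(tissue, sgn * aeff / train$trf[k], sys$wz, r2sl)
    y <- rk45_lin(Ap, y, train$trf[k], rtol = rtol)
    y <- free_step(y, (train$tr - train$trf[k]) / 2)
    s[k] <- sgn * sys$M0 * complex(real = y[1], imaginary = y[2])
    y <- free_step(y, (train$tr - train$trf[k]) / 2)
  }
  s
}

# single-pool balanced-SSFP magnitude steady state (instantaneous pulses,
# sampled immediately after the pulse)
bssfp_closed_form <- function(M0, alpha, tr, R1, R2) {
  E1 <- exp(-tr * R1); E2 <- exp(-tr * R2)
  Mod(M0) * sin(alpha) * (1 - E1) / (1 - (E1 - E2) * cos(alpha) - E1 * E2)
}
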