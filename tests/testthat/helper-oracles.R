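# Independent numerical oracles kept outside the implementation paths.

# Complex moduli by numerical Fourier transformation of the time-domain
# creep compliance: J*(w) = J(0+) + int_0^inf J'(t) exp(-i w t) dt, with the
# terminal flow slope split off analytically so the remaining integrand
# decays; G*(w) = 1 / J*(w). Uses only sampled J(t) values.
moduli_from_creep_numeric <- function(omega, params, t_max = 200,
                                      n = 20001) {
  t <- seq(0, t_max, length.out = n)
  J <- creep_compliance(t, params)
  s_inf <- (J[n] - J[n - 1]) / (t[n] - t[n - 1])     # long-time slope
  dJ <- diff(J) / diff(t)                            # midpoint derivative
  tm <- (t[-1] + t[-n]) / 2
  g <- dJ - s_inf
  dt <- t[2] - t[1]
  vapply(omega, function(w) {
    Jstar <- sum(g * exp(-1i * w * tm)) * dt + s_inf / (1i * w)
    Gs <- 1 / Jstar
    c(Re(Gs), Im(Gs))
  }, numeric(2))
}

# Complex-arithmetic inversion of the model compliance (independent of the
# closed-form G'/G'' expressions).
moduli_by_complex_inversion <- function(omega, params) {
  Jstar <- 1 / complex(real = params$E, imaginary = omega * params$eta2) +
    1 / complex(real = 0, imaginary = omega * params$eta1)
  Gs <- 1 / Jstar
  c(Re(Gs), Im(Gs))
}

# Brute-force grid search of the truncated power-law log-likelihood.
powerlaw_grid_mle <- function(volumes, v_min, v_max,
                              grid = seq(-3, 0, by = 1e-4)) {
  logv <- log(volumes)
  n <- length(volumes)
  ll <- vapply(grid, function(a) {
    a1 <- a + 1
    lC <- if (abs(a1) < 1e-12) -log(log(v_max / v_min))
          else log(abs(a1)) - log(abs(v_max^a1 - v_min^a1))
    n * lC + a * sum(logv)
  }, numeric(1))
  grid[which.max(ll)]
}

# Rodrigues rotation of points about a unit axis (brute-force oracle for
# the gravity-axis alignment).
rodrigues_rotate <- function(points, axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  t(apply(points, 1, function(p) {
    p * cos(angle) +
      c(axis[2] * p[3] - axis[3] * p[2],
        axis[3] * p[1] - axis[1] * p[3],
        axis[1] * p[2] - axis[2] * p[1]) * sin(angle) +
      axis * sum(axis * p) * (1 - cos(angle))
  }))
}

# Reference parameter sets (printed fit values)
creep_ref_params <- function() viscoelastic_params(0.14, 0.15, 1.7)
osc_ref_params <- function() viscoelastic_params(0.10, 0.05, 0.9)

random_rotation <- function(seed) {
  set.seed(seed)
  qr_r <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_r)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}
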