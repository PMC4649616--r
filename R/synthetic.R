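# Seeded synthetic-data generators. Every generator embeds its ground truth
# in the output metadata so estimator roundtrips can be checked exactly.
#
# Defaults follow the experimental conditions: oscillatory forcing at
# 0.02-1 Hz and 0.2-1.75 pN on 1.4-um beads; nuclei ~400 um across with a
# downward body asymmetry of tens of um; body volumes power-law with
# exponent -1.5; centrifugation at 10/100/1000 g.

#' Synthetic oscillatory bead trajectory
#'
#' Generates the steady-state response of a bead in an extended
#' Kelvin-Voigt medium to a sinusoidal force F(t) = F0 sin(w t):
#' x(t) = x0 sin(w t - delta) with amplitude x0 = F0 / (6 pi R |G*|) and
#' phase lag delta = atan2(G'', G'), plus additive Gaussian noise.
#'
#' @param params a [viscoelastic_params()] ground truth.
#' @param frequency_hz drive frequency, Hz (default 0.1, inside the
#'   0.02-1 Hz experimental band).
#' @param F0 force amplitude, pN (default 1, inside 0.2-1.75 pN).
#' @param bead_radius bead radius, um.
#' @param n_periods periods sampled (>= 4).
#' @param points_per_period samples per period (>= 20).
#' @param noise_sd additive noise as a fraction of x0.
#' @param seed RNG seed.
#' @return a [bead_trajectory()]; `meta$truth` holds the generating
#'   parameters and the analytic `x0` (um) and `delta` (rad).
#' @export
synth_oscillatory_trajectory <- function(params, frequency_hz = 0.1,
                                         F0 = 1, bead_radius = 1.4,
                                         n_periods = 6,
                                         points_per_period = 40,
                                         noise_sd = 0, seed = 1) {
  stopifnot(inherits(params, "viscoelastic_params"),
            frequency_hz > 0, F0 > 0, n_periods >= 4,
            points_per_period >= 20, noise_sd >= 0)
  omega <- 2 * pi * frequency_hz
  m <- complex_moduli(omega, params)
  Gmag <- sqrt(m$G_storage^2 + m$G_loss^2)
  x0 <- F0 / (6 * pi * bead_radius * Gmag)
  delta <- atan2(m$G_loss, m$G_storage)
  times <- seq(0, n_periods / frequency_hz,
               length.out = n_periods * points_per_period + 1)
  set.seed(seed)
  x <- x0 * sin(omega * times - delta) +
    stats::rnorm(length(times), 0, noise_sd * x0)
  bead_trajectory(times, x, F0 * sin(omega * times), bead_radius,
                  meta = list(truth = list(params = params, x0 = x0,
                                           delta = delta, omega = omega,
                                           F0 = F0),
                              noise_sd = noise_sd, seed = seed))
}

#' Synthetic step-force creep trajectory
#'
#' Bead displacement under a constant force, x(t) = F0 J(t) / (6 pi R) with
#' J the model creep compliance; the sampled window covers at least five
#' retardation times plus a linear-flow tail.
#'
#' @inheritParams synth_oscillatory_trajectory
#' @param F0 step force, pN (default 1.4, a typical applied step).
#' @param t_end window length, s; default
#'   `max(5 * eta2/E, 3 * eta1/E)` to cover retardation and flow.
#' @param dt sampling interval, s.
#' @param noise_sd additive noise as a fraction of the final displacement.
#' @return a [bead_trajectory()] with constant force trace; `meta$truth`
#'   holds the generating parameters.
#' @export
synth_creep_trajectory <- function(params, F0 = 1.4, bead_radius = 1.4,
                                   t_end = NULL, dt = 0.1, noise_sd = 0,
                                   seed = 1) {
  stopifnot(inherits(params, "viscoelastic_params"), F0 > 0, noise_sd >= 0)
  tau <- params$eta2 / params$E
  if (is.null(t_end)) t_end <- max(5 * tau, 3 * params$eta1 / params$E)
  times <- seq(0, t_end, by = dt)
  if (length(times) < 10L) stop("window too short; lower dt or raise t_end")
  x_clean <- F0 * creep_compliance(times, params) / (6 * pi * bead_radius)
  set.seed(seed)
  x <- x_clean + stats::rnorm(length(times), 0, noise_sd * max(x_clean))
  bead_trajectory(times, x, rep(F0, length(times)), bead_radius,
                  meta = list(truth = list(params = params, F0 = F0),
                              noise_sd = noise_sd, seed = seed))
}

#' Synthetic moduli spectrum
#'
#' Noise-free or multiplicatively noisy storage/loss moduli evaluated from
#' the closed-form model at log-spaced frequencies.
#'
#' @inheritParams synth_oscillatory_trajectory
#' @param frequencies_hz frequency grid, Hz; default 10 log-spaced points
#'   spanning 0.02-1 Hz.
#' @param noise_frac multiplicative Gaussian noise fraction.
#' @return a [moduli_spectrum()].
#' @export
synth_moduli_spectrum <- function(params,
                                  frequencies_hz =
                                    exp(seq(log(0.02), log(1),
                                            length.out = 10)),
                                  noise_frac = 0, seed = 1) {
  stopifnot(inherits(params, "viscoelastic_params"))
  m <- complex_moduli(2 * pi * frequencies_hz, params)
  set.seed(seed)
  k <- length(frequencies_hz)
  gs <- m$G_storage * pmax(1 + stats::rnorm(k, 0, noise_frac), 0)
  gl <- m$G_loss * pmax(1 + stats::rnorm(k, 0, noise_frac), 0)
  moduli_spectrum(frequencies_hz, gs, gl)
}

# expected centered z (in [-c, c]) under tilt density A(z) exp(-(z + c)/lambda);
# trapezoid quadrature on a fine grid (stats::integrate loses the sharply
# peaked integrand at small lambda)
.tilt_mean_z <- function(lambda, c_axis) {
  z <- seq(-c_axis, c_axis, length.out = 20001)
  logw <- log1p(-(z / c_axis)^2) - (z + c_axis) / lambda
  w <- exp(logw - max(logw[is.finite(logw)]))
  w[!is.finite(w)] <- 0
  sum(z * w) / sum(w)
}

# solve the tilt length-scale lambda so that E[z] = -target (centered coords)
.solve_tilt_lambda <- function(target, c_axis) {
  if (target <= 1e-9) return(Inf)
  f <- function(loglam) .tilt_mean_z(exp(loglam), c_axis) + target
  stats::uniroot(f, lower = log(c_axis * 1e-3), upper = log(c_axis * 1e4),
                 tol = 1e-12)$root |> exp()
}

#' Synthetic nuclear-body cloud in an ellipsoidal nucleus
#'
#' Samples body positions inside an axis-aligned ellipsoid from a
#' vertically tilted density p(z) proportional to A(z) exp(-z / lambda)
#' (A(z) the cross-section area), with lambda calibrated by numerical
#' integration so that the expected asymmetry distance measured after
#' sphere normalization equals `target_z0`. Horizontal coordinates are
#' uniform within each cross-section. Body radii come from the truncated
#' power law. Per-plane nucleus geometry is synthesized by slicing the
#' ellipsoid at `plane_step` intervals.
#'
#' @param n_bodies number of bodies.
#' @param semi_axes ellipsoid semi-axes (a, b, c), um; default
#'   (220, 200, 180) for a ~400-um nucleus.
#' @param target_z0 target asymmetry distance z0, um (in the
#'   sphere-normalized frame where z0 is measured); must not exceed half
#'   the vertical semi-axis.
#' @param exponent,v_min,v_max volume power law (see
#'   [sample_powerlaw_volumes()]).
#' @param center raw-frame nucleus center (x, y, z), um.
#' @param plane_step geometry slicing interval, um (default 2, the imaging
#'   z-step).
#' @param seed RNG seed.
#' @return list with `cloud` (raw-frame [nucleolus_cloud()], ground truth
#'   in `meta$truth`) and `geometry` (per-plane [nucleus_geometry()]).
#' @export
synth_nucleolus_cloud <- function(n_bodies = 500,
                                  semi_axes = c(220, 200, 180),
                                  target_z0 = 50, exponent = -1.5,
                                  v_min = 0.5, v_max = 4000,
                                  center = c(0, 0, 0), plane_step = 2,
                                  seed = 1) {
  stopifnot(length(semi_axes) == 3, all(semi_axes > 0), n_bodies >= 1,
            target_z0 >= 0)
  a <- semi_axes[1]; b <- semi_axes[2]; cc <- semi_axes[3]
  if (target_z0 > cc / 2)
    stop("target_z0 exceeds half the vertical semi-axis; infeasible tilt")
  s <- prod(semi_axes)^(1 / 3)
  # z0 is measured after normalization (z scaled by s/c); calibrate the
  # raw-frame offset accordingly
  raw_target <- target_z0 * cc / s
  lambda <- .solve_tilt_lambda(raw_target, cc)
  set.seed(seed)
  # inverse-CDF sampling of centered z on a fine grid
  zg <- seq(-cc, cc, length.out = 4001)
  w <- (1 - (zg / cc)^2) * if (is.finite(lambda))
    exp(-(zg + cc) / lambda) else 1
  cdf <- cumsum(w); cdf <- cdf / cdf[length(cdf)]
  keep <- c(TRUE, diff(cdf) > 0)
  z <- stats::approx(cdf[keep], zg[keep], xout = stats::runif(n_bodies),
                     rule = 2)$y
  # uniform in the cross-section ellipse at each z
  shrink <- sqrt(pmax(1 - (z / cc)^2, 0))
  rr <- sqrt(stats::runif(n_bodies))
  th <- stats::runif(n_bodies, 0, 2 * pi)
  x <- a * shrink * rr * cos(th)
  y <- b * shrink * rr * sin(th)
  vols <- sample_powerlaw_volumes(n_bodies, exponent, v_min, v_max)
  pos <- cbind(x + center[1], y + center[2], z + center[3])
  cloud <- nucleolus_cloud(pos, radius_from_volume(vols), frame = "raw",
                           meta = list(truth = list(
                             target_z0 = target_z0, lambda = lambda,
                             semi_axes = semi_axes, exponent = exponent,
                             v_min = v_min, v_max = v_max, center = center),
                             seed = seed))
  zp <- seq(-cc + plane_step, cc - plane_step, by = plane_step)
  sh <- sqrt(1 - (zp / cc)^2)
  geom <- nucleus_geometry(
    plane_z = zp + center[3],
    plane_center = cbind(rep(center[1], length(zp)),
                         rep(center[2], length(zp))),
    plane_area = pi * a * b * sh^2,
    plane_rx = a * sh, plane_ry = b * sh)
  list(cloud = cloud, geometry = geom)
}

#' Synthetic centrifugation cohort
#'
#' Emulates the centrifugation design: for each effective gravity the mean
#' sedimentation displacement follows Stokes creep
#' Delta-z = (2/9) delta_rho g0 g R_med^2 t / eta, with optional Gaussian
#' per-time scatter. The default (g, t) grid matches the experimental
#' schedule: 10 g at 20 min/3 h/8 h/14 h, 100 g at 10-100 min, 1000 g at
#' 2-20 min. Displacements are capped at `max_dz` (bodies piling up at the
#' nuclear envelope).
#'
#' @param g_multiples effective gravities.
#' @param times_s list of time grids, s, one per gravity.
#' @param eta long-time viscosity ground truth, Pa.s.
#' @param r_median median body radius, um; default the analytic median of
#'   the default volume power law.
#' @param delta_rho density difference, kg/m^3.
#' @param noise_sd additive scatter on each displacement, um.
#' @param max_dz displacement cap, um (nucleus diameter scale).
#' @param seed RNG seed.
#' @return list of [sedimentation_series()]; ground truth in
#'   `attr(, "truth")`.
#' @export
synth_cohort <- function(g_multiples = c(10, 100, 1000),
                         times_s = list(c(1200, 10800, 28800, 50400),
                                        c(600, 1200, 1800, 3000, 6000),
                                        c(120, 300, 600, 1200)),
                         eta = 1.7, r_median = NULL, delta_rho = 50,
                         noise_sd = 0, max_dz = 380, seed = 1) {
  stopifnot(length(g_multiples) == length(times_s), eta > 0, noise_sd >= 0)
  if (is.null(r_median)) {
    v_med <- (0.5^(-0.5) + 0.5 * (4000^(-0.5) - 0.5^(-0.5)))^(-2)
    r_median <- radius_from_volume(v_med)
  }
  set.seed(seed)
  out <- Map(function(g, tt) {
    dz <- force_time_variable(g, tt, r_median, delta_rho) / eta
    if (noise_sd > 0) dz <- dz + stats::rnorm(length(tt), 0, noise_sd)
    sedimentation_series(g, tt, pmin(pmax(dz, 0), max_dz), r_median,
                         delta_rho)
  }, g_multiples, times_s)
  attr(out, "truth") <- list(eta = eta, r_median = r_median,
                             delta_rho = delta_rho, seed = seed)
  out
}

#' Synthetic 1-D intensity profile of a body
#'
#' A Gaussian intensity profile whose FWHM/2 equals the body radius
#' (sigma = radius / sqrt(2 ln 2)), plus additive noise — the input of the
#' Gaussian sizing step.
#'
#' @param radius body radius, um.
#' @param noise_sd additive noise as a fraction of the amplitude.
#' @param seed RNG seed.
#' @param amplitude,baseline profile scale, arbitrary units.
#' @param half_extent half-width of the sampled window, um.
#' @param n number of samples.
#' @return data.frame with `position_um` and `intensity`.
#' @export
synth_intensity_profile <- function(radius, noise_sd = 0, seed = 1,
                                    amplitude = 1, baseline = 0,
                                    half_extent = 4 * radius, n = 201) {
  stopifnot(radius > 0, noise_sd >= 0)
  sigma <- radius / sqrt(2 * log(2))
  pos <- seq(-half_extent, half_extent, length.out = n)
  set.seed(seed)
  data.frame(position_um = pos,
             intensity = amplitude * exp(-pos^2 / (2 * sigma^2)) + baseline +
               stats::rnorm(n, 0, noise_sd * amplitude))
}
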