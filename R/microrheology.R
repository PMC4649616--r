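# Estimation of viscoelastic properties from magnetic-bead trajectories.

#' Bead radius presets
#'
#' The superparamagnetic probe beads are nominally 2.8 um in diameter
#' (radius 1.4 um); some imaging-based estimates give 1.5 um. Both are kept
#' as named presets; `"nominal"` (1.4 um) is the package default.
#' @export
BEAD_RADIUS_PRESETS <- c(nominal = 1.4, imaging = 1.5)

#' Bead trajectory container
#'
#' A timestamped bead displacement record together with the applied force
#' protocol and the bead radius.
#'
#' @param times sample times, s, strictly increasing, length >= 10.
#' @param displacement bead displacement along the force axis, um.
#' @param force applied force at each time, pN.
#' @param bead_radius bead radius, um.
#' @param meta optional named list of metadata (e.g. generator ground truth).
#' @return an object of class `bead_trajectory`.
#' @export
bead_trajectory <- function(times, displacement, force, bead_radius = 1.4,
                            meta = list()) {
  if (length(times) < 10L)
    stop("a trajectory needs at least 10 samples")
  if (length(displacement) != length(times) || length(force) != length(times))
    stop("'times', 'displacement' and 'force' must have equal length")
  if (any(!is.finite(times)) || any(diff(times) <= 0))
    stop("'times' must be finite and strictly increasing")
  if (any(!is.finite(displacement)) || any(!is.finite(force)))
    stop("displacement and force must be finite")
  if (!is.numeric(bead_radius) || bead_radius <= 0)
    stop("'bead_radius' must be positive")
  structure(list(times = as.numeric(times),
                 displacement = as.numeric(displacement),
                 force = as.numeric(force),
                 bead_radius = bead_radius, meta = meta),
            class = "bead_trajectory")
}

#' @export
print.bead_trajectory <- function(x, ...) {
  cat(sprintf("Bead trajectory: %d samples over %.3g s, bead radius %.3g um\n",
              length(x$times), diff(range(x$times)), x$bead_radius))
  invisible(x)
}

# least-squares sinusoid at known frequency: y ~ a sin(wt) + b cos(wt) [+ c + d t]
.sin_basis_fit <- function(t, y, omega, drift) {
  X <- cbind(sin(omega * t), cos(omega * t), 1)
  if (drift) X <- cbind(X, t)
  fit <- stats::lm.fit(X, y)
  cf <- fit$coefficients
  list(amplitude = sqrt(cf[1]^2 + cf[2]^2),
       phase = atan2(cf[2], cf[1]),   # y = A sin(wt + phase)
       offset = cf[3],
       drift = if (drift) cf[4] else 0,
       residuals = fit$residuals)
}

#' Fit a sinusoid to an oscillatory bead response
#'
#' Fits the displacement record to
#' x(t) = offset + drift t + x0 sin(w t + phi_x) by linear least squares in
#' the (sin, cos) basis at the known drive frequency, and the force record to
#' F(t) = F0 sin(w t + phi_F) likewise. The phase lag of the bead behind the
#' force is delta = phi_F - phi_x, wrapped to [0, pi); delta = 0 is a purely
#' elastic response and delta = pi/2 purely viscous.
#'
#' @param traj a [bead_trajectory()].
#' @param omega drive angular frequency, rad/s (known from the protocol).
#' @param drift include a linear drift term (default TRUE; magnetic-bead
#'   recordings commonly drift).
#' @return an object of class `oscillatory_fit` with fields `omega`,
#'   `amplitude_x0` (um), `phase_delta` (rad), `force_amplitude_F0` (pN),
#'   `offset` (um), `drift` (um/s) and `residual_sd`.
#' @export
fit_sinusoid <- function(traj, omega, drift = TRUE) {
  stopifnot(inherits(traj, "bead_trajectory"))
  if (!is.numeric(omega) || omega <= 0) stop("'omega' must be positive")
  span <- diff(range(traj$times))
  if (span < 2 * (2 * pi / omega))
    stop("trajectory must span at least 2 full periods at this frequency")
  fx <- .sin_basis_fit(traj$times, traj$displacement, omega, drift)
  ff <- .sin_basis_fit(traj$times, traj$force, omega, drift = FALSE)
  if (fx$amplitude <= 0 || !is.finite(fx$amplitude))
    stop("sinusoid fit did not converge to a positive amplitude")
  delta <- (ff$phase - fx$phase) %% pi
  structure(list(omega = omega,
                 amplitude_x0 = unname(fx$amplitude),
                 phase_delta = unname(delta),
                 force_amplitude_F0 = unname(ff$amplitude),
                 offset = unname(fx$offset),
                 drift = unname(fx$drift),
                 residual_sd = stats::sd(fx$residuals)),
            class = "oscillatory_fit")
}

#' Storage and loss moduli from an oscillatory fit
#'
#' G'(w) = F0 cos(delta) / (6 pi R x0) and G''(w) = F0 sin(delta) /
#' (6 pi R x0): the in-phase and out-of-phase parts of the bead's response
#' amplitude converted to a modulus through the Stokes geometric factor.
#'
#' @param fit an `oscillatory_fit` (from [fit_sinusoid()]).
#' @param bead_radius bead radius, um.
#' @return list with `G_storage` and `G_loss`, Pa.
#' @export
moduli_from_oscillation <- function(fit, bead_radius = 1.4) {
  stopifnot(inherits(fit, "oscillatory_fit"))
  if (fit$amplitude_x0 <= 0)
    stop("degenerate response: zero displacement amplitude")
  scale <- fit$force_amplitude_F0 / (6 * pi * bead_radius * fit$amplitude_x0)
  list(G_storage = scale * cos(fit$phase_delta),
       G_loss = scale * sin(fit$phase_delta))
}

#' Creep compliance from a step-force trajectory
#'
#' Under a constant force F0 the bead compliance is
#' J(t) = 6 pi R x(t) / F0, with displacement zeroed at force onset.
#'
#' @param traj a [bead_trajectory()] whose force trace is constant at `F0`
#'   over the analyzed window.
#' @param F0 step force magnitude, pN.
#' @param bead_radius bead radius, um.
#' @param force_tol relative tolerance on force constancy within the window.
#' @return an object of class `creep_curve`: list with `times` (s since
#'   onset) and `compliance` (1/Pa).
#' @export
compliance_from_step <- function(traj, F0, bead_radius = 1.4,
                                 force_tol = 1e-6) {
  stopifnot(inherits(traj, "bead_trajectory"))
  if (!is.numeric(F0) || F0 <= 0) stop("'F0' must be positive")
  if (any(abs(traj$force - F0) > force_tol * max(F0, 1)))
    stop("force trace is not constant at F0 over the analyzed window")
  t0 <- traj$times[1]
  x0 <- traj$displacement[1]
  creep_curve(traj$times - t0,
              6 * pi * bead_radius * (traj$displacement - x0) / F0)
}

#' Creep-compliance curve container
#'
#' @param times s since force onset, non-negative, increasing.
#' @param compliance 1/Pa.
#' @return object of class `creep_curve`.
#' @export
creep_curve <- function(times, compliance) {
  if (length(times) != length(compliance))
    stop("'times' and 'compliance' must have equal length")
  if (any(diff(times) <= 0)) stop("'times' must be strictly increasing")
  structure(list(times = as.numeric(times),
                 compliance = as.numeric(compliance)),
            class = "creep_curve")
}

#' Moduli spectrum container
#'
#' @param frequencies Hz, strictly increasing.
#' @param G_storage,G_loss moduli, Pa, non-negative.
#' @param uncertainties optional per-point standard errors, Pa (recycled
#'   across G' and G'').
#' @return object of class `moduli_spectrum`.
#' @export
moduli_spectrum <- function(frequencies, G_storage, G_loss,
                            uncertainties = NULL) {
  n <- length(frequencies)
  if (length(G_storage) != n || length(G_loss) != n)
    stop("moduli must match the length of 'frequencies'")
  if (any(diff(frequencies) <= 0))
    stop("'frequencies' must be strictly increasing")
  if (any(G_storage < 0) || any(G_loss < 0))
    stop("moduli must be non-negative")
  if (!is.null(uncertainties)) {
    if (length(uncertainties) != n || any(uncertainties <= 0))
      stop("'uncertainties' must be positive and match 'frequencies'")
  }
  structure(list(frequencies = as.numeric(frequencies),
                 G_storage = as.numeric(G_storage),
                 G_loss = as.numeric(G_loss),
                 uncertainties = uncertainties),
            class = "moduli_spectrum")
}

# weighted residual vector for a spectrum under params (log-parameterized)
.spectrum_resid <- function(logp, spec, w) {
  p <- viscoelastic_params(exp(logp[1]), exp(logp[2]), exp(logp[3]))
  m <- complex_moduli(2 * pi * spec$frequencies, p)
  c(w * (m$G_storage - spec$G_storage), w * (m$G_loss - spec$G_loss))
}

.fit_spectrum_once <- function(spec, w, logp0) {
  obj <- function(lp) sum(.spectrum_resid(lp, spec, w)^2)
  best <- stats::optim(logp0, obj, method = "Nelder-Mead",
                       control = list(maxit = 5000, reltol = 1e-14))
  best <- stats::optim(best$par, obj, method = "BFGS",
                       control = list(maxit = 1000, reltol = 1e-14))
  best
}

# data-driven initialization: E from G' plateau, eta1 from low-f G''/w,
# eta2 from high-f G''/w with the series correction removed
.spectrum_init <- function(spec) {
  w <- 2 * pi * spec$frequencies
  E0 <- max(spec$G_storage)
  eta1 <- spec$G_loss[1] / w[1]
  nh <- length(w)
  eta_hi <- spec$G_loss[nh] / w[nh]          # ~ eta1 eta2/(eta1+eta2)
  eta2 <- if (eta_hi < eta1) eta_hi * eta1 / (eta1 - eta_hi) else eta_hi
  pmax(c(E0, eta2, eta1), 1e-8)
}

#' Fit the extended Kelvin-Voigt model to a moduli spectrum
#'
#' Fits G'(w) and G''(w) simultaneously by minimizing the weighted sum of
#' squared residuals over (E, eta2, eta1), parameterized on the log scale to
#' enforce positivity. Weights are inverse-variance when per-point
#' uncertainties are supplied, otherwise inverse-magnitude (uniform weights
#' on relative residuals). Initialization is data-driven (G' plateau for E,
#' terminal G''/w for eta1, high-frequency G''/w for eta2) plus random
#' restarts; 95% parameter intervals come from a seeded parametric
#' bootstrap.
#'
#' @param spectrum a [moduli_spectrum()] with >= 3 frequencies.
#' @param n_boot bootstrap replicates for the 95% CIs (0 disables).
#' @param noise_frac multiplicative noise fraction used when bootstrapping a
#'   spectrum without supplied uncertainties.
#' @param n_restarts random restarts in addition to the data-driven start.
#' @param seed RNG seed for the bootstrap and restarts.
#' @return an object of class `model_fit` with fields `params`
#'   ([viscoelastic_params()]), `ci95` (3 x 2 matrix or NULL),
#'   `residual_norm`, `method = "oscillatory"`, `convergence`.
#' @export
fit_model_to_moduli <- function(spectrum, n_boot = 200, noise_frac = 0.1,
                                n_restarts = 3, seed = 1) {
  stopifnot(inherits(spectrum, "moduli_spectrum"))
  if (length(spectrum$frequencies) < 3L)
    stop("need at least 3 frequencies to constrain 3 parameters")
  w <- if (!is.null(spectrum$uncertainties)) {
    1 / rep(spectrum$uncertainties, 1)
  } else {
    1 / pmax(c(spectrum$G_storage + spectrum$G_loss) / 2, 1e-12)
  }
  set.seed(seed)
  starts <- list(log(.spectrum_init(spectrum)))
  for (i in seq_len(n_restarts))
    starts[[i + 1L]] <- starts[[1L]] + stats::rnorm(3, sd = 1)
  fits <- lapply(starts, function(s) .fit_spectrum_once(spectrum, w, s))
  vals <- vapply(fits, `[[`, numeric(1), "value")
  if (all(!is.finite(vals)))
    stop("simultaneous moduli fit failed to converge from ",
         length(starts), " initializations")
  best <- fits[[which.min(vals)]]
  p_hat <- viscoelastic_params(exp(best$par[1]), exp(best$par[2]),
                               exp(best$par[3]))
  ci <- NULL
  if (n_boot > 0) {
    m_hat <- complex_moduli(2 * pi * spectrum$frequencies, p_hat)
    sd_s <- if (!is.null(spectrum$uncertainties)) spectrum$uncertainties
            else noise_frac * m_hat$G_storage
    sd_l <- if (!is.null(spectrum$uncertainties)) spectrum$uncertainties
            else noise_frac * m_hat$G_loss
    boot <- matrix(NA_real_, n_boot, 3)
    for (b in seq_len(n_boot)) {
      sp_b <- moduli_spectrum(
        spectrum$frequencies,
        pmax(m_hat$G_storage + stats::rnorm(length(sd_s), 0, sd_s), 0),
        pmax(m_hat$G_loss + stats::rnorm(length(sd_l), 0, sd_l), 0),
        spectrum$uncertainties)
      fb <- try(.fit_spectrum_once(sp_b, w, best$par), silent = TRUE)
      if (!inherits(fb, "try-error")) boot[b, ] <- exp(fb$par)
    }
    ci <- t(apply(boot, 2, stats::quantile, probs = c(0.025, 0.975),
                  na.rm = TRUE))
    rownames(ci) <- c("E", "eta2", "eta1")
  }
  structure(list(params = p_hat, ci95 = ci,
                 residual_norm = sqrt(best$value),
                 method = "oscillatory",
                 convergence = best$convergence,
                 degenerate = FALSE),
            class = "model_fit")
}

#' Fit the extended Kelvin-Voigt model to a creep-compliance curve
#'
#' Least-squares fit of J(t) = (1/E)(1 - exp(-t E/eta2)) + t/eta1 to a
#' measured compliance curve. The long-time viscosity eta1 is identified by
#' the terminal slope; E and eta2 by the initial retardation. A window too
#' short to constrain eta1 (shorter than ~3 retardation times) sets a
#' warning flag, and an essentially pure-fluid curve (no measurable
#' elastic plateau) is flagged degenerate.
#'
#' @param curve a [creep_curve()] covering both the retardation and the
#'   linear-flow regime.
#' @param n_boot bootstrap replicates for 95% CIs (0 disables).
#' @param noise_sd absolute noise sd used for the parametric bootstrap; if
#'   NULL it is taken from the fit residuals.
#' @param seed RNG seed.
#' @return a `model_fit` (see [fit_model_to_moduli()]) with
#'   `method = "creep"` and logical flags `short_window`, `degenerate`.
#' @export
fit_model_to_creep <- function(curve, n_boot = 200, noise_sd = NULL,
                               seed = 1) {
  stopifnot(inherits(curve, "creep_curve"))
  t <- curve$times; J <- curve$compliance
  keep <- t > 0
  if (sum(keep) < 4L) stop("creep curve too short to fit 3 parameters")
  obj <- function(lp) {
    p <- viscoelastic_params(exp(lp[1]), exp(lp[2]), exp(lp[3]))
    sum((creep_compliance(t, p) - J)^2)
  }
  # neutral data-driven start: terminal slope -> eta1, intercept -> 1/E,
  # quarter-rise time -> eta2
  n <- length(t)
  tail_i <- which(t >= stats::quantile(t, 0.5))
  slope <- stats::coef(stats::lm(J[tail_i] ~ t[tail_i]))[2]
  slope <- max(slope, 1e-12)
  icept <- max(stats::coef(stats::lm(J[tail_i] ~ t[tail_i]))[1], 1e-8)
  E0 <- 1 / icept
  eta2_0 <- max(E0 * t[n] / 20, 1e-8)
  st <- log(c(E0, eta2_0, 1 / slope))
  set.seed(seed)
  starts <- list(st, st + c(1, 1, 0), st + c(-1, -1, 0), st + stats::rnorm(3))
  fits <- lapply(starts, function(s) {
    f <- stats::optim(s, obj, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-15))
    stats::optim(f$par, obj, method = "BFGS",
                 control = list(maxit = 1000, reltol = 1e-15))
  })
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  p_hat <- viscoelastic_params(exp(best$par[1]), exp(best$par[2]),
                               exp(best$par[3]))
  tau <- p_hat$eta2 / p_hat$E
  short_window <- max(t) < 3 * tau
  # degenerate pure fluid: elastic plateau 1/E below curve resolution
  degenerate <- (1 / p_hat$E) < 1e-6 * max(abs(J))
  ci <- NULL
  if (n_boot > 0) {
    J_hat <- creep_compliance(t, p_hat)
    sdv <- if (is.null(noise_sd)) stats::sd(J - J_hat) else noise_sd
    sdv <- max(sdv, 1e-12)
    boot <- matrix(NA_real_, n_boot, 3)
    for (b in seq_len(n_boot)) {
      Jb <- J_hat + stats::rnorm(n, 0, sdv)
      ob <- function(lp) {
        p <- viscoelastic_params(exp(lp[1]), exp(lp[2]), exp(lp[3]))
        sum((creep_compliance(t, p) - Jb)^2)
      }
      fb <- try(stats::optim(best$par, ob, method = "BFGS",
                             control = list(maxit = 500)), silent = TRUE)
      if (!inherits(fb, "try-error")) boot[b, ] <- exp(fb$par)
    }
    ci <- t(apply(boot, 2, stats::quantile, probs = c(0.025, 0.975),
                  na.rm = TRUE))
    rownames(ci) <- c("E", "eta2", "eta1")
  }
  structure(list(params = p_hat, ci95 = ci,
                 residual_norm = sqrt(best$value),
                 method = "creep", convergence = best$convergence,
                 short_window = short_window, degenerate = degenerate),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("Extended Kelvin-Voigt fit (%s data):\n", x$method))
  cat(sprintf("  E    = %.4g Pa\n  eta2 = %.4g Pa.s\n  eta1 = %.4g Pa.s\n",
              x$params$E, x$params$eta2, x$params$eta1))
  if (!is.null(x$ci95)) {
    cat("  95% CI:\n")
    print(signif(x$ci95, 3))
  }
  if (isTRUE(x$degenerate)) cat("  [flag] degenerate (pure-fluid-like)\n")
  if (isTRUE(x$short_window)) cat("  [flag] window short for eta1\n")
  invisible(x)
}

#' Force from a Stokes-law bead calibration
#'
#' In a calibration fluid of known viscosity a bead dragged at steady
#' terminal velocity v experiences F = 6 pi eta R v; this converts measured
#' velocities into the applied force of the magnetic tweezers.
#'
#' @param velocity terminal bead velocity, um/s.
#' @param viscosity_cal calibration-fluid viscosity, Pa.s.
#' @param bead_radius bead radius, um.
#' @return force, pN.
#' @export
calibrate_force <- function(velocity, viscosity_cal, bead_radius = 1.4) {
  if (any(velocity < 0)) stop("'velocity' must be non-negative")
  stokes_drag(bead_radius, viscosity_cal) * velocity
}

#' Lissajous ellipse of a force-displacement loop
#'
#' Under sinusoidal forcing a linear viscoelastic material traces an ellipse
#' in the force-displacement plane; its enclosed area pi F0 x0 sin(delta) is
#' the energy dissipated per cycle. Fits the general conic
#' a x^2 + b x y + c y^2 + d x + e y + f = 0 by direct least squares with
#' the ellipse constraint (Fitzgibbon), then extracts center, semi-axes,
#' tilt and area.
#'
#' @param force applied force samples, pN (>= 1 full cycle).
#' @param displacement paired displacement samples, um.
#' @return list with `center` (x, F), `semi_axes` (major, minor), `tilt`
#'   (rad), `enclosed_area` (pN.um) and logical `degenerate` (TRUE when the
#'   loop collapses to a line, area 0).
#' @export
lissajous_ellipse <- function(force, displacement) {
  if (length(force) != length(displacement))
    stop("'force' and 'displacement' must be paired")
  if (length(force) < 8L) stop("need at least one full sampled cycle")
  x <- displacement; y <- force
  # scale-normalize for conditioning
  mx <- mean(x); my <- mean(y)
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0 || sy == 0)
    return(list(center = c(mx, my), semi_axes = c(0, 0), tilt = 0,
                enclosed_area = 0, degenerate = TRUE))
  u <- (x - mx) / sx; v <- (y - my) / sy
  # collinear loop -> degenerate line descriptor
  if (abs(stats::cor(u, v)) > 1 - 1e-10) {
    return(list(center = c(mx, my), semi_axes = c(0, 0),
                tilt = atan2(stats::sd(y), stats::sd(x)),
                enclosed_area = 0, degenerate = TRUE))
  }
  D1 <- cbind(u^2, u * v, v^2)
  D2 <- cbind(u, v, 1)
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  Tm <- -solve(S3, t(S2))
  M <- S1 + S2 %*% Tm
  C1inv <- matrix(c(0, 0, 0.5, 0, -1, 0, 0.5, 0, 0), 3, 3)
  eg <- eigen(C1inv %*% M)
  cand <- Re(eg$vectors)
  cond <- 4 * cand[1, ] * cand[3, ] - cand[2, ]^2
  a1 <- cand[, which(cond > 0)[1]]
  if (length(a1) == 0 || all(is.na(a1)))
    stop("ellipse fit degenerate: no elliptical solution")
  coef6 <- c(a1, Tm %*% a1)   # A B C D E F in normalized coords
  A <- coef6[1]; B <- coef6[2]; C <- coef6[3]
  D <- coef6[4]; E <- coef6[5]; Ff <- coef6[6]
  # center in normalized coords
  den <- 4 * A * C - B^2
  uc <- (B * E - 2 * C * D) / den
  vc <- (B * D - 2 * A * E) / den
  # constant at center
  Fc <- Ff + A * uc^2 + B * uc * vc + C * vc^2 + D * uc + E * vc
  M2 <- matrix(c(A, B / 2, B / 2, C), 2, 2)
  ev <- eigen(M2, symmetric = TRUE)
  ax_n <- sqrt(pmax(-Fc / ev$values, 0))       # normalized semi-axes
  # area is invariant under the diagonal unscaling up to sx*sy
  area <- pi * prod(ax_n) * sx * sy
  # map axes/tilt back to data units for reporting (approximate for tilt)
  vecs <- ev$vectors
  ax1 <- c(ax_n[1] * vecs[1, 1] * sx, ax_n[1] * vecs[2, 1] * sy)
  ax2 <- c(ax_n[2] * vecs[1, 2] * sx, ax_n[2] * vecs[2, 2] * sy)
  semi <- sort(c(sqrt(sum(ax1^2)), sqrt(sum(ax2^2))), decreasing = TRUE)
  tilt <- atan2(ax1[2], ax1[1])
  list(center = c(mx + uc * sx, my + vc * sy),
       semi_axes = semi, tilt = tilt,
       enclosed_area = abs(area), degenerate = FALSE)
}
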