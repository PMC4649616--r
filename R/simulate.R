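# Brownian-dynamics simulation of nuclear bodies creeping under effective
# gravity in a viscous medium, with fusion on contact.
#
# Dynamics are 2D (x, z) as in the source model: per particle i with radius
# R_i = (3 V_i / 4 pi)^(1/3), drag zeta_i = 6 pi eta1 R_i and weight
# F_i = V_i delta_rho g, each step updates
#   x <- x + xi_x,   z <- z - (F_i / zeta_i) dt + xi_z
# with xi ~ N(0, 2 (kB T / zeta_i) dt) per axis, reflecting walls on the
# particle centers at the wall-clearance planes, then fusion of overlapping
# pairs (combined volume, volume-weighted centroid).

#' Simulation configuration
#'
#' @param box_side side of the square simulation box, um (nucleus diameter
#'   scale; default 400).
#' @param n_particles initial particle count (default 1000).
#' @param eta1 long-time medium viscosity, Pa.s (the measured long-time
#'   network viscosity; only the viscous response enters the simulation).
#' @param delta_rho body-medium density difference, kg/m^3 (default 50;
#'   the disruption timescale scales as 1/delta_rho).
#' @param g_multiple effective gravity as a multiple of standard gravity.
#' @param temperature absolute temperature, K.
#' @param dt integration step, s; `NULL` resolves it via
#'   [recommended_timestep()].
#' @param t_end total simulated time, s.
#' @param v_min,v_max bounds of the initial volume distribution, um^3.
#' @param exponent initial power-law volume exponent.
#' @param fusion merge colliding particles (default TRUE; FALSE gives
#'   non-interacting particles for diffusion/drift checks).
#' @param seed RNG seed; every run is deterministic given (config, seed).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(box_side = 400, n_particles = 1000, eta1 = 1.7,
                       delta_rho = 50, g_multiple = 1, temperature = 298,
                       dt = NULL, t_end = 3600, v_min = 0.5, v_max = 4000,
                       exponent = -1.5, fusion = TRUE, seed = 1) {
  stopifnot(box_side > 0, n_particles >= 1, eta1 > 0, g_multiple >= 0,
            temperature >= 0, t_end > 0, v_min > 0, v_max > v_min)
  if (!is.null(dt) && dt <= 0) stop("'dt' must be positive")
  structure(list(box_side = box_side, n_particles = n_particles,
                 eta1 = eta1, delta_rho = delta_rho,
                 g_multiple = g_multiple, temperature = temperature,
                 dt = dt, t_end = t_end, v_min = v_min, v_max = v_max,
                 exponent = exponent, fusion = isTRUE(fusion), seed = seed),
            class = "sim_config")
}

.sim_radii <- function(volumes) (3 * volumes / (4 * pi))^(1 / 3)

.sim_drift_speed <- function(volumes, config) {
  # downward drift speed, um/s: F / zeta
  gravitational_force(volumes, config$delta_rho, config$g_multiple) /
    stokes_drag(.sim_radii(volumes), config$eta1)
}

#' Recommended integration timestep
#'
#' Chooses dt so that a particle's displacement in one step (deterministic
#' drift plus three standard deviations of the Brownian step) stays below
#' its own diameter, checked at both volume bounds (drift binds for the
#' largest particles, diffusion for the smallest), then halved as a safety
#' factor and capped at `t_end`.
#'
#' @param config a [sim_config()].
#' @return timestep, s.
#' @export
recommended_timestep <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  kt <- thermal_energy(max(config$temperature, 1e-12))
  if (config$temperature == 0) kt <- 0
  solve_dt <- function(V) {
    R <- .sim_radii(V)
    a <- .sim_drift_speed(V, config)              # drift, um/s
    D <- kt / stokes_drag(R, config$eta1)         # diffusion, um^2/s
    b <- 3 * sqrt(2 * D)                          # 3 sd per sqrt(dt)
    d <- 2 * R
    if (a == 0 && b == 0) return(Inf)
    if (a == 0) return((d / b)^2)
    s <- (-b + sqrt(b^2 + 4 * a * d)) / (2 * a)   # sqrt(dt) root
    s^2
  }
  dt <- 0.5 * min(solve_dt(config$v_min), solve_dt(config$v_max))
  min(dt, config$t_end)
}

.sim_state <- function(positions, volumes, time) {
  structure(list(positions = positions, volumes = volumes, time = time),
            class = "sim_state")
}

#' Initialize the simulation state
#'
#' Draws initial volumes from the truncated power law, places particles
#' uniformly at random in the box (respecting wall clearance per particle),
#' and resolves any initial overlaps by immediate fusion. Randomness comes
#' from the current RNG stream; [run_sedimentation()] seeds it from the
#' config.
#'
#' @param config a [sim_config()].
#' @return object of class `sim_state` with `positions` (n x 2 matrix,
#'   columns x and z), `volumes` (um^3) and `time = 0`.
#' @export
init_state <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  L <- config$box_side
  vols <- sample_powerlaw_volumes(config$n_particles, config$exponent,
                                  config$v_min, config$v_max)
  radii <- .sim_radii(vols)
  if (2 * max(radii) >= L)
    stop("largest particle does not fit in the box")
  if (sum(pi * radii^2) > 2 * L^2)
    stop("initialization infeasible: particle area exceeds the box")
  pos <- cbind(stats::runif(config$n_particles, radii, L - radii),
               stats::runif(config$n_particles, radii, L - radii))
  colnames(pos) <- c("x", "z")
  st <- .sim_state(pos, vols, 0)
  if (config$fusion) st <- resolve_fusions(st, L) else st
}

#' Resolve all particle overlaps by fusion
#'
#' Two bodies whose center distance is below the sum of their radii fuse
#' into one body carrying the combined volume, placed at the
#' volume-weighted centroid (re-clamped to the wall-clearance planes).
#' Overlapping pairs are merged in ascending order of surface gap and the
#' scan is iterated to a fixpoint, so chains of mutually overlapping bodies
#' collapse into one. Total volume is conserved exactly.
#'
#' @param state a `sim_state`.
#' @param box_side box side, um, for re-clamping merged centers.
#' @return the state with no remaining overlapping pair.
#' @export
resolve_fusions <- function(state, box_side) {
  pos <- state$positions; vol <- state$volumes
  repeat {
    n <- nrow(pos)
    if (n < 2L) break
    r <- .sim_radii(vol)
    d <- as.matrix(stats::dist(pos))
    gap <- d - outer(r, r, `+`)
    diag(gap) <- Inf
    ov <- which(gap < 0 & upper.tri(gap), arr.ind = TRUE)
    if (nrow(ov) == 0L) break
    ov <- ov[order(gap[ov]), , drop = FALSE]
    taken <- logical(n)
    drop <- integer(0)
    for (k in seq_len(nrow(ov))) {
      i <- ov[k, 1]; j <- ov[k, 2]
      if (taken[i] || taken[j]) next
      taken[i] <- taken[j] <- TRUE
      w <- vol[c(i, j)] / sum(vol[c(i, j)])
      newpos <- w[1] * pos[i, ] + w[2] * pos[j, ]
      vol[i] <- vol[i] + vol[j]
      rr <- .sim_radii(vol[i])
      pos[i, ] <- pmin(pmax(newpos, rr), box_side - rr)
      drop <- c(drop, j)
    }
    if (length(drop)) {
      pos <- pos[-drop, , drop = FALSE]
      vol <- vol[-drop]
    }
  }
  .sim_state(pos, vol, state$time)
}

# reflect centers into [lo, hi] (single fold is enough given the dt bound,
# but loop for safety)
.reflect <- function(x, lo, hi) {
  bad <- which(x < lo | x > hi)
  for (i in bad) {
    xi <- x[i]
    while (xi < lo[i] || xi > hi[i]) {
      if (xi < lo[i]) xi <- 2 * lo[i] - xi
      if (xi > hi[i]) xi <- 2 * hi[i] - xi
    }
    x[i] <- xi
  }
  x
}

#' Advance the simulation one timestep
#'
#' Applies the discrete Langevin update (deterministic Stokes drift down,
#' Gaussian Brownian kicks on both axes), reflects particle centers at the
#' wall-clearance planes, then resolves fusions (if enabled).
#'
#' @param state a `sim_state`.
#' @param config a [sim_config()] whose `dt` has been resolved.
#' @param dt timestep, s (defaults to `config$dt`).
#' @return the advanced `sim_state`.
#' @export
sim_step <- function(state, config, dt = config$dt) {
  stopifnot(inherits(state, "sim_state"), inherits(config, "sim_config"))
  if (is.null(dt)) stop("timestep not resolved; set config$dt or pass dt")
  n <- nrow(state$positions)
  r <- .sim_radii(state$volumes)
  zeta <- stokes_drag(r, config$eta1)
  kt <- if (config$temperature > 0) thermal_energy(config$temperature) else 0
  sd_step <- sqrt(2 * (kt / zeta) * dt)
  drift <- .sim_drift_speed(state$volumes, config) * dt
  pos <- state$positions
  pos[, 1] <- pos[, 1] + stats::rnorm(n, 0, sd_step)
  pos[, 2] <- pos[, 2] - drift + stats::rnorm(n, 0, sd_step)
  if (any(!is.finite(pos))) stop("non-finite position in simulation step")
  L <- config$box_side
  pos[, 1] <- .reflect(pos[, 1], r, L - r)
  pos[, 2] <- .reflect(pos[, 2], r, L - r)
  st <- .sim_state(pos, state$volumes, state$time + dt)
  if (config$fusion) resolve_fusions(st, L) else st
}

#' Run a sedimentation-coalescence simulation
#'
#' Integrates the Brownian dynamics from a fresh initial state to `t_end`,
#' recording the sedimentation displacement Delta-z (downward shift of the
#' mean body height relative to t = 0), the median body radius and the
#' particle count at the requested sample times. Deterministic given
#' (config, seed).
#'
#' @param config a [sim_config()].
#' @param n_samples number of equally spaced sample times.
#' @param keep_snapshots record full position/volume snapshots at sample
#'   times (memory permitting).
#' @return object of class `sedimentation_summary`: data.frame `series`
#'   (time_s, delta_z_um, r_median_um, count), `config`, `dt`, and
#'   optionally `snapshots`.
#' @export
run_sedimentation <- function(config, n_samples = 50,
                              keep_snapshots = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  dt <- if (is.null(config$dt)) recommended_timestep(config) else config$dt
  n_steps <- max(1L, ceiling(config$t_end / dt))
  dt <- config$t_end / n_steps
  state <- init_state(config)
  z0_mean <- mean(state$positions[, 2])
  sample_steps <- unique(round(seq(0, n_steps, length.out = n_samples + 1)))
  rec <- function(st) data.frame(
    time_s = st$time,
    delta_z_um = z0_mean - mean(st$positions[, 2]),
    r_median_um = stats::median(.sim_radii(st$volumes)),
    count = nrow(st$positions))
  out <- vector("list", length(sample_steps))
  snaps <- if (keep_snapshots) vector("list", length(sample_steps)) else NULL
  k <- 1L
  if (sample_steps[1] == 0L) {
    out[[k]] <- rec(state)
    if (keep_snapshots) snaps[[k]] <- state
    k <- k + 1L
  }
  for (s in seq_len(n_steps)) {
    state <- sim_step(state, config, dt)
    if (k <= length(sample_steps) && s == sample_steps[k]) {
      out[[k]] <- rec(state)
      if (keep_snapshots) snaps[[k]] <- state
      k <- k + 1L
    }
  }
  structure(list(series = do.call(rbind, out), config = config, dt = dt,
                 snapshots = snaps),
            class = "sedimentation_summary")
}

#' @export
print.sedimentation_summary <- function(x, ...) {
  s <- x$series
  cat(sprintf(
    "Sedimentation run: %.3g s at %.3g g, dt = %.3g s\n  final Delta-z = %.3g um, count %d -> %d, median radius %.3g -> %.3g um\n",
    max(s$time_s), x$config$g_multiple, x$dt, s$delta_z_um[nrow(s)],
    s$count[1], s$count[nrow(s)], s$r_median_um[1], s$r_median_um[nrow(s)]))
  invisible(x)
}

#' First time the sedimentation displacement crosses a threshold
#'
#' Linear interpolation between recorded samples; the default 200-um
#' threshold is the nucleus radius, the displacement at which nuclear
#' organization is considered severely disrupted.
#'
#' @param summary a `sedimentation_summary` (or its `series` data.frame).
#' @param threshold displacement threshold, um.
#' @return crossing time tau-star, s, or `NA` if never crossed.
#' @export
time_to_displacement <- function(summary, threshold = 200) {
  s <- if (inherits(summary, "sedimentation_summary")) summary$series
       else summary
  dz <- s$delta_z_um; tt <- s$time_s
  above <- which(dz >= threshold)
  if (length(above) == 0L) return(NA_real_)
  i <- above[1]
  if (i == 1L) return(tt[1])
  stats::approx(dz[(i - 1):i], tt[(i - 1):i], xout = threshold)$y
}
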