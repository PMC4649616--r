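# Nucleus-geometry normalization and nuclear-body spatial statistics.
#
# Coordinate convention: gravity acts along -z; after alignment, z = 0 is the
# bottom of the nucleus. All lengths in um.

#' Nuclear-body point cloud
#'
#' 3D positions and radii of the nuclear bodies detected in one nucleus,
#' plus the coordinate frame the positions live in: `"raw"` (microscope
#' frame), `"sphere"` (after ellipsoid-to-sphere normalization) or
#' `"gravity"` (after rotation onto the gravitational axis, z = 0 at the
#' nucleus bottom).
#'
#' @param positions n x 3 numeric matrix of (x, y, z), um.
#' @param radii body radii, um, length n.
#' @param frame one of `"raw"`, `"sphere"`, `"gravity"`.
#' @param meta named list of metadata (nucleus id, cohort condition,
#'   generator truth, sphere radius after normalization, ...).
#' @return object of class `nucleolus_cloud`.
#' @export
nucleolus_cloud <- function(positions, radii,
                            frame = c("raw", "sphere", "gravity"),
                            meta = list()) {
  frame <- match.arg(frame)
  positions <- as.matrix(positions)
  if (ncol(positions) != 3L) stop("'positions' must be an n x 3 matrix")
  if (nrow(positions) < 1L) stop("a cloud needs at least one body")
  if (length(radii) != nrow(positions))
    stop("'radii' must have one entry per body")
  if (any(!is.finite(positions))) stop("positions must be finite")
  if (any(!is.finite(radii)) || any(radii <= 0))
    stop("radii must be positive and finite")
  dimnames(positions) <- list(NULL, c("x", "y", "z"))
  structure(list(positions = positions, radii = as.numeric(radii),
                 frame = frame, meta = meta),
            class = "nucleolus_cloud")
}

#' @export
print.nucleolus_cloud <- function(x, ...) {
  cat(sprintf("Nuclear-body cloud: %d bodies, frame '%s'\n",
              nrow(x$positions), x$frame))
  invisible(x)
}

#' Per-plane nucleus geometry
#'
#' The per-z-plane segmentation summary of one nucleus: plane heights,
#' cross-section centers and areas, and optionally the half-extents of the
#' cross-section along x and y (needed to resolve the two horizontal
#' semi-axes separately; from areas alone only their product is
#' identifiable).
#'
#' @param plane_z plane heights, um, sorted increasing.
#' @param plane_center n x 2 matrix of cross-section centers (x, y), um.
#' @param plane_area cross-section areas, um^2, positive.
#' @param plane_rx,plane_ry optional half-extents of each cross-section, um.
#' @param ellipsoid optional fitted ellipsoid (from [fit_ellipsoid()]).
#' @return object of class `nucleus_geometry`.
#' @export
nucleus_geometry <- function(plane_z, plane_center, plane_area,
                             plane_rx = NULL, plane_ry = NULL,
                             ellipsoid = NULL) {
  plane_center <- as.matrix(plane_center)
  n <- length(plane_z)
  if (is.unsorted(plane_z, strictly = TRUE)) stop("planes must be sorted by z")
  if (nrow(plane_center) != n || ncol(plane_center) != 2L)
    stop("'plane_center' must be n x 2")
  if (length(plane_area) != n || any(plane_area <= 0))
    stop("'plane_area' must be positive, one per plane")
  structure(list(plane_z = as.numeric(plane_z), plane_center = plane_center,
                 plane_area = as.numeric(plane_area),
                 plane_rx = plane_rx, plane_ry = plane_ry,
                 ellipsoid = ellipsoid),
            class = "nucleus_geometry")
}

#' Fit an axis-aligned ellipsoid to per-plane nucleus data
#'
#' The stack of segmented cross-sections of an ellipsoid with vertical
#' semi-axis c satisfies A(z) = pi a b (1 - ((z - zc)/c)^2): a quadratic in
#' z. Fitting that quadratic by least squares yields the center height zc,
#' the vertical semi-axis c and the product a*b; when per-plane x/y
#' half-extents are available, a and b are resolved separately the same way
#' (rx(z)^2 and ry(z)^2 are quadratics in z), otherwise both horizontal
#' semi-axes are reported as sqrt(a*b). The horizontal center is the
#' area-weighted mean of the plane centers.
#'
#' @param geom a [nucleus_geometry()] with >= 5 planes.
#' @return `geom` with the `ellipsoid` field set: a list with `center`
#'   (x, y, z um), `semi_axes` (a, b, c um) and `orientation` (3 x 3
#'   rotation, identity for the axis-aligned fit).
#' @export
fit_ellipsoid <- function(geom) {
  stopifnot(inherits(geom, "nucleus_geometry"))
  z <- geom$plane_z
  if (length(z) < 5L)
    stop("need at least 5 planes with positive areas to fit an ellipsoid")
  # quadratic fit q(z) = p0 + p1 z + p2 z^2 to a profile; returns (zc, half
  # height c, peak value)
  quad_profile <- function(y) {
    cf <- stats::coef(stats::lm(y ~ z + I(z^2)))
    if (!is.finite(cf[3]) || cf[3] >= 0)
      stop("plane profile is not concave; cannot fit an ellipsoid")
    zc <- -cf[2] / (2 * cf[3])
    peak <- cf[1] + cf[2] * zc + cf[3] * zc^2
    c_half <- sqrt(max(-peak / cf[3], 0))
    c(zc = unname(zc), c = unname(c_half), peak = unname(peak))
  }
  pa <- quad_profile(geom$plane_area)
  ab <- pa["peak"] / pi
  if (!is.null(geom$plane_rx) && !is.null(geom$plane_ry)) {
    px <- quad_profile(geom$plane_rx^2)
    py <- quad_profile(geom$plane_ry^2)
    a <- sqrt(px["peak"]); b <- sqrt(py["peak"])
  } else {
    a <- b <- sqrt(ab)
  }
  w <- geom$plane_area / sum(geom$plane_area)
  center_xy <- colSums(geom$plane_center * w)
  geom$ellipsoid <- list(center = c(center_xy, pa["zc"]),
                         semi_axes = unname(c(a, b, pa["c"])),
                         orientation = diag(3))
  names(geom$ellipsoid$center) <- c("x", "y", "z")
  geom
}

#' @export
print.nucleus_geometry <- function(x, ...) {
  cat(sprintf("Nucleus geometry: %d planes", length(x$plane_z)))
  if (!is.null(x$ellipsoid))
    cat(sprintf("; ellipsoid semi-axes (%.1f, %.1f, %.1f) um",
                x$ellipsoid$semi_axes[1], x$ellipsoid$semi_axes[2],
                x$ellipsoid$semi_axes[3]))
  cat("\n")
  invisible(x)
}

#' Normalize a cloud to a spherical nucleus
#'
#' Applies the linear map that carries the fitted ellipsoid onto a sphere of
#' radius equal to the geometric mean of the semi-axes (volume-preserving)
#' to every body position. Body radii are unchanged; only the coordinate
#' frame is remapped.
#'
#' @param cloud a `nucleolus_cloud` in the `"raw"` frame.
#' @param geom a `nucleus_geometry` with a fitted ellipsoid.
#' @return the cloud in the `"sphere"` frame, centered on the nucleus
#'   center, with `meta$sphere_radius` set.
#' @export
normalize_to_sphere <- function(cloud, geom) {
  stopifnot(inherits(cloud, "nucleolus_cloud"),
            inherits(geom, "nucleus_geometry"))
  if (cloud$frame != "raw")
    stop("cloud must be in the 'raw' frame (got '", cloud$frame, "')")
  if (is.null(geom$ellipsoid)) stop("fit the ellipsoid first")
  el <- geom$ellipsoid
  s <- prod(el$semi_axes)^(1 / 3)
  Q <- el$orientation
  centered <- sweep(cloud$positions, 2, el$center) %*% Q
  scaled <- sweep(centered, 2, s / el$semi_axes, `*`) %*% t(Q)
  meta <- cloud$meta
  meta$sphere_radius <- s
  nucleolus_cloud(scaled, cloud$radii, frame = "sphere", meta = meta)
}

# rotation taking unit vector a onto unit vector b (Rodrigues)
.rotation_between <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- c(a[2] * b[3] - a[3] * b[2],
         a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  cth <- sum(a * b)
  if (cth > 1 - 1e-14) return(diag(3))
  if (cth < -1 + 1e-14) {
    # 180 degrees: rotate about any axis orthogonal to a
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- p - sum(p * a) * a; ax <- ax / sqrt(sum(ax^2))
    K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
    return(diag(3) + 2 * K %*% K)
  }
  K <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + K + K %*% K / (1 + cth)
}

#' Rotate a cloud onto the gravitational axis
#'
#' The apparent gravitational axis of a nucleus is the direction from its
#' centroid to the mean body position (bodies sediment downwards, so the
#' mean is displaced along gravity). This rotation (det +1) carries that
#' direction onto -z, then shifts the origin so z = 0 is the bottom of the
#' spherical nucleus.
#'
#' @param cloud a `nucleolus_cloud` in the `"sphere"` frame (centered on
#'   the nucleus center).
#' @param tol if the mean body position is within `tol` um of the centroid
#'   the axis is undefined; the identity rotation is used and
#'   `meta$degenerate_axis` is set.
#' @return the cloud in the `"gravity"` frame, with
#'   `meta$nucleus_center_z = sphere_radius` (the nucleus center height).
#' @export
align_gravity_axis <- function(cloud, tol = 1e-9) {
  stopifnot(inherits(cloud, "nucleolus_cloud"))
  if (cloud$frame != "sphere")
    stop("cloud must be sphere-normalized before alignment")
  s <- cloud$meta$sphere_radius
  if (is.null(s)) stop("cloud metadata lacks 'sphere_radius'")
  m <- colMeans(cloud$positions)
  meta <- cloud$meta
  if (sqrt(sum(m^2)) < tol) {
    R <- diag(3)
    meta$degenerate_axis <- TRUE
  } else {
    R <- .rotation_between(m, c(0, 0, -1))
    meta$degenerate_axis <- FALSE
  }
  rotated <- cloud$positions %*% t(R)
  rotated[, 3] <- rotated[, 3] + s   # z = 0 at nucleus bottom
  meta$nucleus_center_z <- s
  nucleolus_cloud(rotated, cloud$radii, frame = "gravity", meta = meta)
}

#' Asymmetry distance z0
#'
#' The distance along the gravitational axis between the mean nuclear-body
#' position and the nucleus center; z0 = 0 for a symmetric distribution and
#' grows as bodies sediment. Reported as an absolute distance; the signed
#' offset (negative when bodies lie below center) is kept alongside for
#' displacement arithmetic.
#'
#' @param cloud a gravity-aligned `nucleolus_cloud`.
#' @return list with `z0` (um, >= 0), `signed` (mean body z minus center z)
#'   and `mean_z` (um above the nucleus bottom).
#' @export
asymmetry_z0 <- function(cloud) {
  stopifnot(inherits(cloud, "nucleolus_cloud"))
  if (cloud$frame != "gravity")
    stop("cloud must be gravity-aligned")
  mz <- mean(cloud$positions[, 3])
  cz <- cloud$meta$nucleus_center_z
  if (is.null(cz)) stop("cloud metadata lacks 'nucleus_center_z'")
  list(z0 = abs(mz - cz), signed = mz - cz, mean_z = mz)
}

#' Vertical number-density profile
#'
#' Normalized histogram of body heights in fixed-width bins from the
#' nucleus bottom (z = 0) upward.
#'
#' @param cloud a gravity-aligned `nucleolus_cloud`.
#' @param bin_width bin width, um (default 20).
#' @return object of class `density_profile`: list with `bin_edges` (um)
#'   and `normalized_counts` (sums to 1).
#' @export
density_profile <- function(cloud, bin_width = 20) {
  stopifnot(inherits(cloud, "nucleolus_cloud"))
  if (cloud$frame != "gravity")
    stop("cloud must be gravity-aligned")
  z <- cloud$positions[, 3]
  top <- max(z, cloud$meta$nucleus_center_z * 2, na.rm = TRUE)
  edges <- seq(0, bin_width * ceiling(top / bin_width + 1e-9), by = bin_width)
  idx <- findInterval(pmax(z, 0), edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
  counts <- tabulate(idx, nbins = length(edges) - 1L)
  structure(list(bin_edges = edges,
                 normalized_counts = counts / sum(counts)),
            class = "density_profile")
}

#' Relative sedimentation displacement Delta-z
#'
#' The downward shift of the mean body height in a (centrifuged or aged)
#' cohort of nuclei relative to the native reference:
#' Delta-z = reference mean z - cohort mean z, positive when the cohort has
#' sedimented. Computed per nucleus, then summarized as mean +/- s.e.m.
#'
#' @param reference_mean_z mean body height of the native reference, um.
#' @param cohort a list of gravity-aligned `nucleolus_cloud` objects.
#' @return list with `per_nucleus` (um), `mean`, `sem`, `n`.
#' @export
delta_z <- function(reference_mean_z, cohort) {
  if (inherits(cohort, "nucleolus_cloud")) cohort <- list(cohort)
  if (length(cohort) == 0L) stop("empty cohort")
  dz <- vapply(cohort, function(cl) {
    stopifnot(inherits(cl, "nucleolus_cloud"))
    if (cl$frame != "gravity") stop("cohort clouds must be gravity-aligned")
    reference_mean_z - mean(cl$positions[, 3])
  }, numeric(1))
  list(per_nucleus = dz, mean = mean(dz),
       sem = if (length(dz) > 1) stats::sd(dz) / sqrt(length(dz)) else NA_real_,
       n = length(dz))
}

#' Sedimentation time series container
#'
#' Mean sedimentation displacement versus time for one centrifugation
#' condition, with the metadata needed for force-time scaling.
#'
#' @param g_multiple effective gravity multiple.
#' @param times centrifugation times, s, increasing.
#' @param delta_z_um displacement at each time, um.
#' @param r_median median body radius, um.
#' @param delta_rho body-medium density difference, kg/m^3.
#' @param sem optional per-time s.e.m., um.
#' @return object of class `sedimentation_series`.
#' @export
sedimentation_series <- function(g_multiple, times, delta_z_um,
                                 r_median, delta_rho = 50, sem = NULL) {
  if (length(times) != length(delta_z_um))
    stop("'times' and 'delta_z_um' must be paired")
  if (any(diff(times) <= 0)) stop("'times' must be increasing")
  stopifnot(g_multiple >= 0, r_median > 0)
  structure(list(g_multiple = g_multiple, times = as.numeric(times),
                 delta_z = as.numeric(delta_z_um), r_median = r_median,
                 delta_rho = delta_rho, sem = sem),
            class = "sedimentation_series")
}

#' Creep velocity of a sedimentation series
#'
#' Slope of Delta-z versus time by least squares through the origin
#' (Delta-z is zero at t = 0 by definition), with a 95% CI from the
#' regression.
#'
#' @param series a [sedimentation_series()] with >= 3 time points.
#' @return list with `velocity` (um/s), `ci95`, `se`.
#' @export
creep_velocity <- function(series) {
  stopifnot(inherits(series, "sedimentation_series"))
  if (length(series$times) < 3L)
    stop("need at least 3 time points to estimate a creep velocity")
  fit <- stats::lm(series$delta_z ~ 0 + series$times)
  ci <- stats::confint(fit, level = 0.95)
  list(velocity = unname(stats::coef(fit)[1]),
       ci95 = unname(ci[1, ]),
       se = unname(summary(fit)$coefficients[1, 2]))
}

#' Force-time collapse and long-time viscosity
#'
#' Rescales each series' time axis into the Stokes force-time variable
#' u = (2/9) delta_rho g0 g R_med^2 t (see [force_time_variable()]); for
#' Stokes creep all conditions fall on the single master line
#' Delta-z = u / eta. The pooled regression through the origin gives the
#' apparent long-time viscosity eta (inverse slope); per-condition
#' viscosities diagnose departures from collapse.
#'
#' @param series_set list of [sedimentation_series()].
#' @return list with `eta` (Pa.s), `eta_per_series` (named by g-multiple),
#'   `collapse` (data.frame u, delta_z, g_multiple).
#' @export
force_time_collapse <- function(series_set) {
  if (inherits(series_set, "sedimentation_series"))
    series_set <- list(series_set)
  if (length(series_set) == 0L) stop("empty series set")
  rows <- lapply(series_set, function(s) {
    stopifnot(inherits(s, "sedimentation_series"))
    data.frame(u = force_time_variable(s$g_multiple, s$times, s$r_median,
                                       s$delta_rho),
               delta_z = s$delta_z, g_multiple = s$g_multiple)
  })
  df <- do.call(rbind, rows)
  slope_of <- function(d) {
    if (all(d$u == 0)) return(NA_real_)
    unname(stats::coef(stats::lm(delta_z ~ 0 + u, data = d))[1])
  }
  pooled <- slope_of(df)
  per <- vapply(split(df, df$g_multiple), slope_of, numeric(1))
  list(eta = 1 / pooled, eta_per_series = 1 / per, collapse = df)
}

#' Body radius from a Gaussian intensity profile
#'
#' Fits a Gaussian A exp(-(x - mu)^2 / (2 sigma^2)) + baseline to a 1-D
#' intensity profile through a body's brightest plane; the body radius is
#' half the full width at half maximum, FWHM/2 = sigma sqrt(2 ln 2).
#'
#' @param position sample positions, um.
#' @param intensity intensities at each position (arbitrary units).
#' @return list with `radius` (um), `sigma`, `mu`, `amplitude`, `baseline`.
#' @export
radius_from_profile <- function(position, intensity) {
  if (length(position) != length(intensity))
    stop("'position' and 'intensity' must be paired")
  i_max <- which.max(intensity)
  mu0 <- position[i_max]
  base0 <- min(intensity)
  amp0 <- intensity[i_max] - base0
  above <- intensity - base0 > amp0 / 2
  sig0 <- max(diff(range(position[above])) / 2.355, diff(range(position)) / 50)
  fit <- try(stats::nls(
    intensity ~ A * exp(-(position - mu)^2 / (2 * sigma^2)) + b,
    start = list(A = amp0, mu = mu0, sigma = sig0, b = base0),
    # scaleOffset lets nls converge on noise-free (zero-residual) profiles
    control = stats::nls.control(maxiter = 200, warnOnly = FALSE,
                                 scaleOffset = 1)),
    silent = TRUE)
  if (!inherits(fit, "try-error")) {
    cf <- stats::coef(fit)
  } else {
    # fall back to direct least squares when the nls gradient degenerates
    obj <- function(p) sum((p[1] * exp(-(position - p[2])^2 / (2 * p[3]^2)) +
                              p[4] - intensity)^2)
    op <- stats::optim(c(amp0, mu0, sig0, base0), obj, method = "BFGS",
                       control = list(maxit = 1000, reltol = 1e-14))
    op <- stats::optim(op$par, obj, method = "Nelder-Mead",
                       control = list(maxit = 2000, reltol = 1e-14))
    if (!is.finite(op$value)) stop("Gaussian sizing fit did not converge")
    cf <- c(A = op$par[1], mu = op$par[2], sigma = op$par[3], b = op$par[4])
  }
  sigma <- abs(unname(cf["sigma"]))
  if (!is.finite(sigma) || sigma <= 0)
    stop("Gaussian sizing fit did not converge")
  list(radius = sigma * sqrt(2 * log(2)), sigma = sigma,
       mu = unname(cf["mu"]), amplitude = unname(cf["A"]),
       baseline = unname(cf["b"]))
}

#' Pearson correlation with Fisher-z 95% confidence interval
#'
#' `correlation_with_ci` computes the sample Pearson r of paired data and
#' its Fisher-z interval; `correlation_ci` applies the interval formula
#' tanh(atanh(r) +/- 1.96 / sqrt(n - 3)) to an already-computed coefficient.
#'
#' @param x,y paired numeric vectors, n >= 4.
#' @return object of class `correlation_result`: `r`, `n`, `ci95`
#'   (low, high), logical `degenerate` (|r| = 1, zero-width sampling
#'   distribution).
#' @export
correlation_with_ci <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must be paired")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) stop("need at least 4 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined")
  correlation_ci(stats::cor(x, y), n)
}

#' @rdname correlation_with_ci
#' @param r Pearson correlation coefficient in [-1, 1].
#' @param n sample size (>= 4).
#' @export
correlation_ci <- function(r, n) {
  if (n < 4L) stop("need n >= 4 for a Fisher-z interval")
  if (abs(r) > 1) stop("'r' must lie in [-1, 1]")
  degenerate <- abs(r) >= 1 - 1e-15
  ci <- if (degenerate) c(r, r)
        else tanh(atanh(r) + c(-1, 1) * 1.96 / sqrt(n - 3))
  structure(list(r = r, n = n, ci95 = ci, degenerate = degenerate),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson r = %.3f (n = %d), 95%% CI [%.2f, %.2f]%s\n",
              x$r, x$n, x$ci95[1], x$ci95[2],
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}
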