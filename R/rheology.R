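# Extended Kelvin-Voigt model and Stokes-law utilities.
#
# Internal unit convention: lengths in um, time in s, force in pN,
# moduli/viscosity in Pa (= pN/um^2) and Pa.s.  Densities stay in SI
# (kg/m^3) and are converted where they meet the micron-scale quantities.

#' Standard gravity
#'
#' Acceleration of standard gravity, m/s^2. Effective gravity elsewhere in
#' the package is always expressed as a dimensionless multiple of this.
#' @export
G_STANDARD <- 9.81

#' Thermal energy at temperature T
#'
#' Boltzmann constant times temperature, in pN.um (1 J = 1e18 pN.um).
#' At the default 298 K this is about 4.11e-3 pN.um.
#'
#' @param temperature absolute temperature, K.
#' @return thermal energy kB*T in pN.um.
#' @export
thermal_energy <- function(temperature = 298) {
  stopifnot(is.numeric(temperature), temperature > 0)
  1.380649e-5 * temperature
}

#' Extended Kelvin-Voigt parameter set
#'
#' The three-parameter viscoelastic material description used throughout the
#' package: a spring of modulus `E` in parallel with a dashpot of viscosity
#' `eta2` (the Kelvin-Voigt body, setting the retarded elastic response),
#' in series with a dashpot of viscosity `eta1` (long-time flow).
#'
#' @param E elastic modulus of the spring, Pa.
#' @param eta2 viscosity of the Kelvin-Voigt dashpot, Pa.s.
#' @param eta1 long-time (series) dashpot viscosity, Pa.s.
#' @return an object of class `viscoelastic_params`.
#' @examples
#' viscoelastic_params(E = 0.14, eta2 = 0.15, eta1 = 1.7)
#' @export
viscoelastic_params <- function(E, eta2, eta1) {
  for (nm in c("E", "eta2", "eta1")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("'%s' must be a single positive finite number", nm))
  }
  structure(list(E = E, eta2 = eta2, eta1 = eta1),
            class = "viscoelastic_params")
}

#' @export
print.viscoelastic_params <- function(x, ...) {
  cat(sprintf(
    "Extended Kelvin-Voigt parameters:\n  E    = %.4g Pa\n  eta2 = %.4g Pa.s\n  eta1 = %.4g Pa.s\n  retardation time eta2/E = %.4g s\n",
    x$E, x$eta2, x$eta1, x$eta2 / x$E))
  invisible(x)
}

#' Serialize / deserialize viscoelastic parameters as JSON
#'
#' @param params a `viscoelastic_params` object.
#' @param path file path; for `read_viscoelastic_json` the file to read.
#' @return `write_viscoelastic_json` returns `path` invisibly;
#'   `read_viscoelastic_json` returns a `viscoelastic_params` object.
#' @export
write_viscoelastic_json <- function(params, path) {
  stopifnot(inherits(params, "viscoelastic_params"))
  jsonlite::write_json(
    list(E_Pa = params$E, eta2_Pas = params$eta2, eta1_Pas = params$eta1),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_viscoelastic_json
#' @export
read_viscoelastic_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("E_Pa", "eta2_Pas", "eta1_Pas")
  if (!all(need %in% names(x)))
    stop("parameter JSON must contain fields: ", paste(need, collapse = ", "))
  viscoelastic_params(x$E_Pa, x$eta2_Pas, x$eta1_Pas)
}

#' Creep compliance of the extended Kelvin-Voigt model
#'
#' J(t) = (1/E) (1 - exp(-t E / eta2)) + t / eta1.  The first term is the
#' retarded elastic response of the Kelvin-Voigt body; the second is
#' long-time viscous flow.
#'
#' @param t time since force onset, s (vectorized, all >= 0).
#' @param params a [viscoelastic_params()] object.
#' @return compliance in 1/Pa, same length as `t`.
#' @examples
#' p <- viscoelastic_params(0.14, 0.15, 1.7)
#' creep_compliance(c(0, 1, 10), p)
#' @export
creep_compliance <- function(t, params) {
  stopifnot(inherits(params, "viscoelastic_params"))
  if (!is.numeric(t) || any(!is.finite(t)))
    stop("'t' must be finite numeric")
  if (any(t < 0)) stop("'t' must be non-negative")
  (1 / params$E) * (1 - exp(-t * params$E / params$eta2)) + t / params$eta1
}

#' Complex moduli of the extended Kelvin-Voigt model
#'
#' Closed-form storage and loss moduli obtained by Fourier transformation of
#' the model: the complex compliance is
#' J*(w) = 1/(E + i w eta2) + 1/(i w eta1) and G*(w) = 1/J*(w), giving
#' \deqn{G'(w) = E w^2 eta1^2 / (E^2 + w^2 (eta1+eta2)^2)}
#' \deqn{G''(w) = (w eta1 E^2 + w^3 eta1 eta2 (eta1+eta2)) /
#'               (E^2 + w^2 (eta1+eta2)^2)}
#'
#' @param omega angular frequency, rad/s (vectorized, all > 0).
#' @inheritParams creep_compliance
#' @return a list with components `G_storage` and `G_loss`, Pa.
#' @examples
#' p <- viscoelastic_params(0.10, 0.05, 0.9)
#' complex_moduli(2 * pi * 0.1, p)
#' @export
complex_moduli <- function(omega, params) {
  stopifnot(inherits(params, "viscoelastic_params"))
  if (!is.numeric(omega) || any(!is.finite(omega)) || any(omega <= 0))
    stop("'omega' must be positive finite numeric")
  E <- params$E; e1 <- params$eta1; e2 <- params$eta2
  den <- E^2 + omega^2 * (e1 + e2)^2
  list(G_storage = E * omega^2 * e1^2 / den,
       G_loss = (omega * e1 * E^2 + omega^3 * e1 * e2 * (e1 + e2)) / den)
}

#' Stokes drag coefficient
#'
#' zeta = 6 pi eta R, returned in pN.s/um (1 Pa = 1 pN/um^2, so Pa.s times
#' um gives pN.s/um directly).
#'
#' @param radius particle radius, um.
#' @param viscosity medium viscosity, Pa.s.
#' @return drag coefficient, pN.s/um.
#' @export
stokes_drag <- function(radius, viscosity) {
  if (any(!is.finite(radius)) || any(radius <= 0))
    stop("'radius' must be positive")
  if (any(!is.finite(viscosity)) || any(viscosity <= 0))
    stop("'viscosity' must be positive")
  6 * pi * viscosity * radius
}

#' Stokes settling context
#'
#' Bundles the quantities entering the gravitational Stokes velocity of a
#' dense particle in a viscous medium.
#'
#' @param radius particle radius, um.
#' @param delta_rho particle-medium density difference, kg/m^3.
#' @param g_multiple effective gravity as a multiple of standard gravity
#'   (dimensionless, >= 0); centrifugation at "100 g" is `g_multiple = 100`.
#' @param viscosity medium viscosity, Pa.s.
#' @return an object of class `stokes_context`.
#' @export
stokes_context <- function(radius, delta_rho = 50, g_multiple = 1,
                           viscosity = 1.7) {
  stopifnot(is.numeric(radius), radius > 0,
            is.numeric(delta_rho), is.finite(delta_rho),
            is.numeric(g_multiple), g_multiple >= 0,
            is.numeric(viscosity), viscosity > 0)
  structure(list(radius = radius, delta_rho = delta_rho,
                 g_multiple = g_multiple, viscosity = viscosity),
            class = "stokes_context")
}

#' Gravitational Stokes settling velocity
#'
#' v = F / (6 pi eta R) with buoyancy-corrected weight
#' F = (4/3) pi R^3 delta_rho g, which reduces to
#' v = (2/9) delta_rho g R^2 / eta.  Unit bookkeeping: R in um, delta_rho in
#' kg/m^3, g in m/s^2, eta in Pa.s yields v in um/s after a 1e-6 factor.
#'
#' @param ctx a [stokes_context()].
#' @return settling speed, um/s (non-negative, linear in `g_multiple`).
#' @examples
#' stokes_velocity(stokes_context(radius = 4, delta_rho = 50,
#'                                g_multiple = 1, viscosity = 1.7))
#' @export
stokes_velocity <- function(ctx) {
  stopifnot(inherits(ctx, "stokes_context"))
  2 / 9 * ctx$delta_rho * G_STANDARD * ctx$g_multiple * ctx$radius^2 *
    1e-6 / ctx$viscosity
}

#' Buoyancy-corrected particle weight
#'
#' F = V delta_rho g, in pN, for a particle of volume V um^3 under effective
#' gravity `g_multiple` times standard gravity.
#'
#' @param volume particle volume, um^3.
#' @param delta_rho density difference, kg/m^3.
#' @param g_multiple effective gravity multiple.
#' @return force, pN.
#' @export
gravitational_force <- function(volume, delta_rho, g_multiple) {
  volume * delta_rho * G_STANDARD * g_multiple * 1e-6
}

#' Scaled force-time variable for sedimentation collapse
#'
#' u = (2/9) delta_rho g0 g_multiple R_med^2 t, in um.Pa.s units such that
#' the sedimentation displacement of a Stokes-settling particle is
#' Delta-z = u / eta.  Plotting Delta-z against u collapses data taken at
#' different effective gravities onto one master line whose inverse slope is
#' the long-time viscosity.
#'
#' @param g_multiple effective gravity multiple.
#' @param time_s elapsed time, s.
#' @param r_median median particle radius, um.
#' @param delta_rho density difference, kg/m^3.
#' @return scaled variable u, um.Pa.s (so that u / eta is um).
#' @export
force_time_variable <- function(g_multiple, time_s, r_median, delta_rho = 50) {
  2 / 9 * delta_rho * G_STANDARD * g_multiple * r_median^2 * time_s * 1e-6
}

#' Radius of a sphere of given volume
#'
#' @param volume volume, um^3.
#' @return radius (3V / 4 pi)^(1/3), um.
#' @export
radius_from_volume <- function(volume) (3 * volume / (4 * pi))^(1 / 3)

#' @rdname radius_from_volume
#' @param radius radius, um.
#' @export
volume_from_radius <- function(radius) 4 / 3 * pi * radius^3
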