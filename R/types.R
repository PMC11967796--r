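#' Rectangular microchannel geometry
#'
#' Describes one straight-through rectangular nozzle channel. All lengths are
#' in metres. Width and height are interchangeable physically (the hydraulic
#' formulas are symmetric under exchange); `length` is the streamwise extent
#' of the channel.
#'
#' @param width Channel width w (m), strictly positive.
#' @param height Channel height h (m), strictly positive.
#' @param length Channel length l (m); must exceed `max(width, height)`.
#' @param max_cross_section Sanity bound on w and h (m); microchannels are
#'   expected below 1 mm by default.
#' @return An object of class `channel_geometry`.
#' @examples
#' channel_geometry(20e-6, 20e-6, 5e-3)
#' @export
channel_geometry <- function(width, height, length, max_cross_section = 1e-3) {
  .check_num(width, "width", positive = TRUE)
  .check_num(height, "height", positive = TRUE)
  .check_num(length, "length", positive = TRUE)
  if (width > max_cross_section || height > max_cross_section) {
    stop("channel cross-section exceeds the microchannel sanity bound (",
         format(max_cross_section), " m); raise `max_cross_section` if intended",
         call. = FALSE)
  }
  if (length <= max(width, height)) {
    stop("channel `length` must exceed both cross-section dimensions", call. = FALSE)
  }
  structure(list(width = width, height = height, length = length),
            class = "channel_geometry")
}

#' Aqueous/oil fluid system
#'
#' The liquid parameters entering the hydraulics: aqueous density and
#' viscosity, aqueous/oil interfacial tension, and the contact angle of the
#' (typically hydrophobically treated) channel walls.
#'
#' @param density Aqueous density (kg m^-3), > 0.
#' @param viscosity Aqueous dynamic viscosity (Pa s), > 0.
#' @param surface_tension Interfacial tension (N m^-1), > 0.
#' @param contact_angle Wall contact angle (radians), in \[0, pi\]. Angles
#'   above pi/2 (hydrophobic walls) give a negative capillary pressure that
#'   opposes channel filling.
#' @return An object of class `fluid_system`.
#' @examples
#' fluid_system(1000, 1e-3, 5e-3, deg_to_rad(120))
#' @export
fluid_system <- function(density, viscosity, surface_tension, contact_angle) {
  .check_num(density, "density", positive = TRUE)
  .check_num(viscosity, "viscosity", positive = TRUE)
  .check_num(surface_tension, "surface_tension", positive = TRUE)
  .check_num(contact_angle, "contact_angle")
  if (contact_angle < 0 || contact_angle > pi) {
    stop("`contact_angle` must lie in [0, pi] radians", call. = FALSE)
  }
  structure(list(density = density, viscosity = viscosity,
                 surface_tension = surface_tension,
                 contact_angle = contact_angle),
            class = "fluid_system")
}

#' Rotor configuration of the centrifugal platform
#'
#' @param omega Angular velocity (rad s^-1), >= 0. Use [rpm_to_rad_s()] for
#'   rpm settings.
#' @param r1 Distance from the rotational centre to the free surface of the
#'   aqueous phase (m), >= 0.
#' @param r2 Distance from the aqueous free surface to the nozzles (m), > 0;
#'   the radial extent of the liquid column.
#' @return An object of class `rotor_config`.
#' @examples
#' rotor_config(rpm_to_rad_s(5000), 18e-3, 6e-3)
#' @export
rotor_config <- function(omega, r1, r2) {
  .check_num(omega, "omega")
  .check_num(r1, "r1")
  .check_num(r2, "r2", positive = TRUE)
  if (omega < 0) stop("`omega` must be non-negative", call. = FALSE)
  if (r1 < 0) stop("`r1` must be non-negative", call. = FALSE)
  structure(list(omega = omega, r1 = r1, r2 = r2), class = "rotor_config")
}

.check_num <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop("`", name, "` must be a single finite number", call. = FALSE)
  }
  if (positive && x <= 0) {
    stop("`", name, "` must be strictly positive", call. = FALSE)
  }
  invisible(x)
}

#' @export
print.channel_geometry <- function(x, ...) {
  cat(sprintf("Rectangular microchannel: %g x %g um cross-section, %g mm long\n",
              x$width / .UM, x$height / .UM, x$length / .MM))
  invisible(x)
}

#' @export
print.rotor_config <- function(x, ...) {
  cat(sprintf("Rotor: omega = %g rad/s (%.0f rpm), R1 = %g mm, R2 = %g mm\n",
              x$omega, rad_s_to_rpm(x$omega), x$r1 / .MM, x$r2 / .MM))
  invisible(x)
}
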