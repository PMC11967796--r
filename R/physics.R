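#' Centrifugal acceleration at the nozzles
#'
#' Acceleration experienced by the liquid at the nozzle radius,
#' `a = omega^2 * (R1 + R2)`. At a settled rotational speed this is the
#' acceleration that, together with the channel dimension and the inlet flow
#' rate, dominates droplet size.
#'
#' @param rotor A [rotor_config()].
#' @return Acceleration in m s^-2; zero iff `omega = 0`.
#' @examples
#' centrifugal_acceleration(rotor_config(523.599, 18e-3, 6e-3)) # 6579.7
#' @export
centrifugal_acceleration <- function(rotor) {
  stopifnot(inherits(rotor, "rotor_config"))
  rotor$omega^2 * (rotor$r1 + rotor$r2)
}

#' Centrifugal driving pressure of the aqueous column
#'
#' Pressure at the nozzles from the rotating liquid column,
#' `P_aqu = 1/2 rho omega^2 ((R1+R2)^2 - R1^2)`, i.e. the integral of
#' `rho omega^2 r` over the column from the free surface (radius R1) to the
#' nozzles (radius R1+R2). Non-negative; zero when the rotor is at rest or
#' the column has vanished.
#'
#' @param rotor A [rotor_config()].
#' @param fluids A [fluid_system()].
#' @return Driving pressure in Pa.
#' @export
driving_pressure <- function(rotor, fluids) {
  stopifnot(inherits(rotor, "rotor_config"), inherits(fluids, "fluid_system"))
  0.5 * fluids$density * rotor$omega^2 * ((rotor$r1 + rotor$r2)^2 - rotor$r1^2)
}

#' Capillary pressure of a rectangular microchannel
#'
#' Young-Laplace pressure of the advancing meniscus,
#' `P_cap = 2 gamma cos(theta) (1/w + 1/h)`. Negative for contact angles
#' above 90 degrees: hydrophobic walls oppose filling and must be overcome
#' by the driving pressure.
#'
#' @inheritParams driving_pressure
#' @param channel A [channel_geometry()].
#' @return Capillary pressure in Pa (signed).
#' @export
capillary_pressure <- function(channel, fluids) {
  stopifnot(inherits(channel, "channel_geometry"), inherits(fluids, "fluid_system"))
  2 * fluids$surface_tension * cos(fluids$contact_angle) *
    (1 / channel$width + 1 / channel$height)
}

#' Shape factor of a rectangular duct
#'
#' The bracketed series factor in the laminar hydraulic resistance of a
#' rectangular duct,
#' `1 - (192 h / (pi^5 w)) * sum_{i odd} tanh(i pi w / (2 h)) / i^5`,
#' evaluated with the smaller cross-section dimension in the role of `h`
#' (the series converges to the physical value only in that convention, and
#' the resistance is symmetric under w <-> h exchange). For a square duct the
#' factor is 0.42173; in the parallel-plate limit (w >> h) it tends to 1.
#'
#' @param width,height Cross-section dimensions (m).
#' @param tol Relative series truncation tolerance in (0, 1e-3]; terms are
#'   added until a term contributes less than `tol` of the running sum.
#' @return Dimensionless factor in (0, 1).
#' @examples
#' duct_shape_factor(20e-6, 20e-6) # 0.4217
#' @export
duct_shape_factor <- function(width, height, tol = 1e-12) {
  if (width <= 0 || height <= 0) {
    stop("degenerate cross-section: `width` and `height` must be positive",
         call. = FALSE)
  }
  if (tol <= 0 || tol > 1e-3) stop("`tol` must lie in (0, 1e-3]", call. = FALSE)
  wmax <- max(width, height)
  hmin <- min(width, height)
  s <- 0
  i <- 1
  repeat {
    term <- tanh(i * pi * wmax / (2 * hmin)) / i^5
    s <- s + term
    if (term < tol * s || i >= 999) break
    i <- i + 2
  }
  1 - (192 * hmin / (pi^5 * wmax)) * s
}

#' Hydraulic resistance of a rectangular microchannel
#'
#' Laminar flow resistance
#' `R_hyd = 12 mu l / (w h^3 * F(w, h))`, with `F` the rectangular-duct
#' series factor of [duct_shape_factor()] and the smaller cross-section
#' dimension taken as `h`. For a square 20 um channel of 5 mm length in
#' water this is 8.89e14 Pa s m^-3.
#'
#' @inheritParams capillary_pressure
#' @param tol Series truncation tolerance, see [duct_shape_factor()].
#' @return Resistance in Pa s m^-3; doubles when the length doubles.
#' @export
hydraulic_resistance <- function(channel, fluids, tol = 1e-12) {
  stopifnot(inherits(channel, "channel_geometry"), inherits(fluids, "fluid_system"))
  wmax <- max(channel$width, channel$height)
  hmin <- min(channel$width, channel$height)
  f <- duct_shape_factor(wmax, hmin, tol)
  12 * fluids$viscosity * channel$length / (wmax * hmin^3 * f)
}

#' Mean inlet velocity of the aqueous phase in a microchannel
#'
#' Combines driving pressure, capillary pressure and hydraulic resistance:
#' `V_in = (P_aqu + P_cap) / (R_hyd * w * h)`. When the total pressure is
#' non-positive (e.g. a hydrophobic channel whose capillary pressure the
#' depleted column can no longer overcome) the channel does not flow; the
#' velocity is reported as 0 with attribute `no_flow = TRUE` rather than as
#' an error, since this state occurs legitimately at the end of reservoir
#' depletion.
#'
#' @inheritParams capillary_pressure
#' @inheritParams driving_pressure
#' @return Velocity in m s^-1 with a logical attribute `no_flow`.
#' @export
inlet_velocity <- function(channel, fluids, rotor) {
  p <- driving_pressure(rotor, fluids) + capillary_pressure(channel, fluids)
  if (p <= 0) {
    return(structure(0, no_flow = TRUE))
  }
  r <- hydraulic_resistance(channel, fluids)
  structure(p / (r * channel$width * channel$height), no_flow = FALSE)
}

#' Weber number at the nozzle
#'
#' `We = rho V_in^2 D_h / gamma` with hydraulic diameter
#' `D_h = 2 w h / (w + h)`; the ratio of inertial to capillary stresses that
#' separates the monodisperse periodic dripping regime from the polydisperse
#' dripping-faucet regime.
#'
#' @param velocity Mean channel velocity V_in (m s^-1).
#' @inheritParams capillary_pressure
#' @return Dimensionless Weber number, >= 0.
#' @export
weber_number <- function(velocity, channel, fluids) {
  stopifnot(inherits(channel, "channel_geometry"), inherits(fluids, "fluid_system"))
  dh <- 2 * channel$width * channel$height / (channel$width + channel$height)
  fluids$density * as.numeric(velocity)^2 * dh / fluids$surface_tension
}

#' Classify the droplet-generation regime
#'
#' Low Weber numbers give periodic dripping (regular neck collapse by
#' Rayleigh-Plateau instability, monodisperse droplets); high Weber numbers
#' give a dripping faucet (quasi-continuous jet, polydisperse droplets). The
#' crossover is order one; no sharp experimental boundary exists, so the
#' threshold defaults to 1 and is configurable. A Weber number exactly at
#' the threshold is classified as `dripping_faucet`.
#'
#' @param we Weber number (dimensionless), >= 0.
#' @param threshold Regime boundary, default 1 (heuristic).
#' @return `"periodic_dripping"` or `"dripping_faucet"`.
#' @export
classify_regime <- function(we, threshold = 1) {
  stopifnot(is.numeric(we), all(we >= 0))
  ifelse(we < threshold, "periodic_dripping", "dripping_faucet")
}

#' Full flow state of an emulsification condition
#'
#' Evaluates the hydraulics chain for one channel/fluids/rotor combination:
#' driving pressure, capillary pressure, hydraulic resistance, inlet
#' velocity, Weber number and regime label.
#'
#' @inheritParams capillary_pressure
#' @inheritParams driving_pressure
#' @param we_threshold Weber-number regime boundary passed to
#'   [classify_regime()].
#' @return An object of class `flow_state`: a list with elements
#'   `p_drive`, `p_cap`, `r_hyd`, `v_in`, `no_flow`, `we`, `regime`.
#' @export
flow_state <- function(channel, fluids, rotor, we_threshold = 1) {
  v <- inlet_velocity(channel, fluids, rotor)
  we <- weber_number(v, channel, fluids)
  structure(list(
    p_drive = driving_pressure(rotor, fluids),
    p_cap = capillary_pressure(channel, fluids),
    r_hyd = hydraulic_resistance(channel, fluids),
    v_in = as.numeric(v),
    no_flow = isTRUE(attr(v, "no_flow")),
    we = we,
    regime = classify_regime(we, we_threshold)
  ), class = "flow_state")
}

#' An emulsification condition
#'
#' Bundles geometry, fluids and rotor settings with the derived hydraulics
#' (acceleration, inlet velocity, Weber number, regime). This is the unit of
#' the experimental dataset: one condition maps to one measured droplet
#' diameter distribution, and only conditions in the periodic dripping
#' regime are eligible for the predictive model.
#'
#' @inheritParams flow_state
#' @return An object of class `emul_condition`.
#' @examples
#' ch <- channel_geometry(20e-6, 20e-6, 5e-3)
#' fl <- fluid_system(1000, 1e-3, 5e-3, deg_to_rad(120))
#' ro <- rotor_config(rpm_to_rad_s(5000), 18e-3, 6e-3)
#' emul_condition(ch, fl, ro)
#' @export
emul_condition <- function(channel, fluids, rotor, we_threshold = 1) {
  st <- flow_state(channel, fluids, rotor, we_threshold)
  structure(c(list(channel = channel, fluids = fluids, rotor = rotor,
                   acceleration = centrifugal_acceleration(rotor)),
              unclass(st)),
            class = "emul_condition")
}

#' @export
print.emul_condition <- function(x, ...) {
  cat(sprintf(
    "Emulsification condition: %g x %g um channel, a = %.1f m/s^2\n  V_in = %.4g m/s, We = %.3g, regime = %s%s\n",
    x$channel$width / .UM, x$channel$height / .UM, x$acceleration,
    x$v_in, x$we, x$regime, if (x$no_flow) " (no flow)" else ""))
  invisible(x)
}

#' @export
print.flow_state <- function(x, ...) {
  cat(sprintf(
    "Flow state: P_drive = %.4g Pa, P_cap = %.4g Pa, R_hyd = %.4g Pa s/m^3\n  V_in = %.4g m/s, We = %.3g, regime = %s%s\n",
    x$p_drive, x$p_cap, x$r_hyd, x$v_in, x$we, x$regime,
    if (x$no_flow) " (no flow)" else ""))
  invisible(x)
}
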