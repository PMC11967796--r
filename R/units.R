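# Internal SI scale factors for the tabular interchange format
# (columns are named with their units: w_um, l_mm, omega_rpm, ...).
.UM <- 1e-6     # micrometre -> metre
.MM <- 1e-3     # millimetre -> metre
.UL <- 1e-9     # microlitre -> cubic metre
.MPA_S <- 1e-3  # millipascal-second -> pascal-second
.MN_M <- 1e-3   # millinewton per metre -> newton per metre

#' Rotational-speed and angle conversions
#'
#' The package works in SI units internally (m, s, kg, Pa, rad). Bench
#' settings are usually quoted in rpm and degrees; these helpers convert on
#' ingest.
#'
#' @param rpm Rotational speed in revolutions per minute.
#' @param omega Angular velocity in rad s^-1.
#' @param deg Angle in degrees.
#' @return A numeric vector in the target unit.
#' @examples
#' rpm_to_rad_s(5000) # 523.6 rad/s
#' deg_to_rad(120)
#' @export
rpm_to_rad_s <- function(rpm) rpm * pi / 30

#' @rdname rpm_to_rad_s
#' @export
rad_s_to_rpm <- function(omega) omega * 30 / pi

#' @rdname rpm_to_rad_s
#' @export
deg_to_rad <- function(deg) deg * pi / 180
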