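#' Tiling constraints for droplet pre-design
#'
#' The design inputs for choosing a droplet size before generation: the
#' reservoir area available for monolayer tiling, the sample volume to be
#' emulsified, the minimum droplet count needed for the assay's dynamic
#' range, and an optional fraction of the reservoir held back as tiling
#' headroom (to allow rapid tiling without stacking).
#'
#' @param reservoir_area Droplet reservoir area (m^2), > 0.
#' @param sample_volume Sample volume to emulsify (m^3), > 0.
#' @param min_count Minimum droplet count, >= 1.
#' @param reserve_fraction Fraction of the reservoir reserved as headroom,
#'   in \[0, 1).
#' @return An object of class `tiling_constraints`.
#' @export
tiling_constraints <- function(reservoir_area, sample_volume, min_count,
                               reserve_fraction = 0) {
  .check_num(reservoir_area, "reservoir_area", positive = TRUE)
  .check_num(sample_volume, "sample_volume", positive = TRUE)
  .check_num(min_count, "min_count", positive = TRUE)
  if (min_count < 1) stop("`min_count` must be at least 1", call. = FALSE)
  .check_num(reserve_fraction, "reserve_fraction")
  if (reserve_fraction < 0 || reserve_fraction >= 1) {
    stop("`reserve_fraction` must lie in [0, 1)", call. = FALSE)
  }
  structure(list(reservoir_area = reservoir_area,
                 sample_volume = sample_volume,
                 min_count = min_count,
                 reserve_fraction = reserve_fraction),
            class = "tiling_constraints")
}

#' Accumulated circle-area budget of a droplet reservoir
#'
#' In a monolayer each droplet of diameter D occupies a D-by-D square
#' footprint of which only the inscribed circle (a pi/4 share) is droplet
#' area; the square-minus-circle remainder is the inter-droplet spacing.
#' The accumulated circle-area budget is therefore
#' `A_reservoir (1 - reserve) pi / 4`. With no headroom a 350 mm^2
#' reservoir yields 275 mm^2 of droplet area.
#'
#' @param reservoir_area Reservoir area (m^2), > 0.
#' @param reserve_fraction Headroom fraction in \[0, 1).
#' @return Area budget in m^2.
#' @examples
#' area_budget(350e-6) * 1e6 # 274.9 mm^2
#' @export
area_budget <- function(reservoir_area, reserve_fraction = 0) {
  .check_num(reservoir_area, "reservoir_area", positive = TRUE)
  .check_num(reserve_fraction, "reserve_fraction")
  if (reserve_fraction < 0 || reserve_fraction >= 1) {
    stop("`reserve_fraction` must lie in [0, 1)", call. = FALSE)
  }
  reservoir_area * (1 - reserve_fraction) * pi / 4
}

#' Droplet count from a sample volume
#'
#' Under no-dead-volume emulsification the whole sample becomes droplets,
#' so `N = 6 V / (pi D^3)`. The unrounded real value is returned; round for
#' display as appropriate.
#'
#' @param sample_volume Sample volume (m^3), > 0.
#' @param diameter Droplet diameter (m), > 0; may be a vector.
#' @return Real-valued droplet count.
#' @examples
#' droplet_count(20e-9, 145e-6) # ~12500 droplets
#' @export
droplet_count <- function(sample_volume, diameter) {
  stopifnot(sample_volume > 0, all(diameter > 0))
  6 * sample_volume / (pi * diameter^3)
}

#' Mean occupancy of entities per droplet
#'
#' Expected number of entities (copies, cells, bacteria) per droplet at a
#' bulk concentration: `lambda = c * pi D^3 / 6`. This is the Poisson mean
#' underlying digital quantification.
#'
#' @param concentration_per_ml Bulk concentration in entities per mL.
#' @param diameter Droplet diameter (m), > 0.
#' @return Expected entities per droplet (dimensionless).
#' @examples
#' mean_occupancy(1e6, 380e-6) # ~30 cells per 380 um microsphere
#' @export
mean_occupancy <- function(concentration_per_ml, diameter) {
  stopifnot(concentration_per_ml >= 0, all(diameter > 0))
  concentration_per_ml * 1e6 * pi * diameter^3 / 6
}

#' Admissible droplet diameter window under tiling constraints
#'
#' Two constraints bound the diameter. The monolayer accumulated circle
#' area of N droplets is `A(D) = N pi D^2 / 4 = 1.5 V / D` (using
#' `N = 6V/(pi D^3)`), which decreases with D, so the area budget binds from
#' below: `D_min = 1.5 V / A_budget`. The droplet count
#' `N(D) = 6V/(pi D^3)` also decreases with D, so the minimum-count
#' requirement binds from above: `D_max = (6 V / (pi N_min))^(1/3)`. The
#' window is infeasible when `D_min > D_max`.
#'
#' @param sample_volume Sample volume V (m^3), > 0; alternatively a
#'   [tiling_constraints()] object, from which the volume, count and budget
#'   are all derived.
#' @param min_count Minimum droplet count N_min, >= 1.
#' @param budget Accumulated circle-area budget (m^2), > 0; from
#'   [area_budget()] or supplied directly as an override (designs sometimes
#'   quote a rounded budget).
#' @return An object of class `diameter_window`: a list with `d_min`,
#'   `d_max` (m), `binding` (labels for each bound) and `feasible`.
#' @examples
#' # 20 uL, 208 mm^2 budget, at least 10 000 droplets -> 144-156 um
#' diameter_window(20e-9, 1e4, 208e-6)
#' diameter_window(tiling_constraints(350e-6, 20e-9, 1e4, 0.25))
#' @export
diameter_window <- function(sample_volume, min_count, budget) {
  if (inherits(sample_volume, "tiling_constraints")) {
    tc <- sample_volume
    if (missing(budget)) {
      budget <- area_budget(tc$reservoir_area, tc$reserve_fraction)
    }
    min_count <- tc$min_count
    sample_volume <- tc$sample_volume
  }
  .check_num(sample_volume, "sample_volume", positive = TRUE)
  .check_num(min_count, "min_count", positive = TRUE)
  if (!is.numeric(budget) || length(budget) != 1L || !is.finite(budget) ||
      budget <= 0) {
    stop("`budget` must be a single positive area in m^2", call. = FALSE)
  }
  d_min <- 1.5 * sample_volume / budget
  d_max <- (6 * sample_volume / (pi * min_count))^(1 / 3)
  structure(list(d_min = d_min, d_max = d_max,
                 binding = c(lower = "area_budget", upper = "droplet_count"),
                 feasible = d_min <= d_max),
            class = "diameter_window")
}

#' @export
print.diameter_window <- function(x, ...) {
  if (x$feasible) {
    cat(sprintf("Admissible diameter window: %.1f to %.1f um\n",
                x$d_min / .UM, x$d_max / .UM))
    cat(sprintf("  lower bound set by %s, upper bound by %s\n",
                x$binding[["lower"]], x$binding[["upper"]]))
  } else {
    cat(sprintf("INFEASIBLE window: area budget demands D >= %.1f um but the droplet count demands D <= %.1f um\n",
                x$d_min / .UM, x$d_max / .UM))
  }
  invisible(x)
}

#' Reverse-engineer generation conditions for a target diameter window
#'
#' Grid search over a channel catalogue and a rotational-speed grid: each
#' (channel, omega) pair is evaluated through the hydraulics chain and the
#' predictive model, and pairs whose predicted diameter falls inside the
#' window while remaining in the periodic dripping regime are returned as
#' design candidates, sorted by distance of the predicted diameter from the
#' window midpoint. Rejected pairs are kept with per-condition reasons.
#'
#' @param model A `droplet_model`.
#' @param window A [diameter_window()]; must be feasible.
#' @param channels A list of [channel_geometry()] objects (the catalogue).
#' @param omega_grid Angular velocities to scan (rad s^-1). The default
#'   spans 500-6000 rpm in 100 rpm steps, the range of a lab centrifuge.
#' @param rotor_template A [rotor_config()] providing R1 and R2 (its omega
#'   is ignored).
#' @param fluids A [fluid_system()].
#' @param we_threshold Weber regime boundary.
#' @param interpolate Allow interpolation between fitted accelerations
#'   (default `TRUE`; candidates are flagged).
#' @return An object of class `design_search`: a list with `candidates`
#'   (data frame: `w_um, h_um, omega_rpm, acceleration, v_in, d_um, f_hz,
#'   interpolated`) and `rejections` (data frame: condition descriptor and
#'   `reason`).
#' @export
reverse_engineer <- function(model, window, channels,
                             omega_grid = rpm_to_rad_s(seq(500, 6000, by = 100)),
                             rotor_template, fluids, we_threshold = 1,
                             interpolate = TRUE) {
  stopifnot(inherits(model, "droplet_model"), inherits(window, "diameter_window"),
            inherits(rotor_template, "rotor_config"), inherits(fluids, "fluid_system"))
  if (!window$feasible) {
    stop("cannot search an infeasible diameter window", call. = FALSE)
  }
  mid <- (window$d_min + window$d_max) / 2
  cand <- list()
  rej <- list()
  for (ch in channels) {
    for (om in omega_grid) {
      rotor <- rotor_config(om, rotor_template$r1, rotor_template$r2)
      cond <- emul_condition(ch, fluids, rotor, we_threshold)
      desc <- list(w_um = ch$width / .UM, h_um = ch$height / .UM,
                   omega_rpm = rad_s_to_rpm(om),
                   acceleration = cond$acceleration)
      dh <- 2 * ch$width * ch$height / (ch$width + ch$height)
      if (window$d_max <= dh) {
        # predicted diameters always exceed the hydraulic diameter, so a
        # window capped below it can never be met by this channel
        rej[[length(rej) + 1L]] <- c(desc, reason = "below model support")
        next
      }
      if (cond$no_flow) {
        rej[[length(rej) + 1L]] <- c(desc, reason = "no flow")
        next
      }
      if (!identical(cond$regime, "periodic_dripping")) {
        rej[[length(rej) + 1L]] <- c(desc, reason = "dripping_faucet")
        next
      }
      D <- tryCatch(predict_diameter(cond, model, interpolate = interpolate),
                    error = function(e) e)
      if (inherits(D, "error")) {
        reason <- if (grepl("outside model range", conditionMessage(D))) {
          "below model support"
        } else {
          conditionMessage(D)
        }
        rej[[length(rej) + 1L]] <- c(desc, reason = reason)
        next
      }
      if (D < window$d_min || D > window$d_max) {
        rej[[length(rej) + 1L]] <- c(desc, reason = "outside diameter window")
        next
      }
      cand[[length(cand) + 1L]] <- data.frame(
        w_um = desc$w_um, h_um = desc$h_um, omega_rpm = desc$omega_rpm,
        acceleration = desc$acceleration, v_in = cond$v_in,
        d_um = as.numeric(D) / .UM,
        f_hz = predict_frequency(cond, as.numeric(D)),
        interpolated = isTRUE(attr(D, "interpolated"))
      )
    }
  }
  candidates <- if (length(cand) > 0L) {
    df <- do.call(rbind, cand)
    df[order(abs(df$d_um * .UM - mid)), , drop = FALSE]
  } else {
    data.frame(w_um = numeric(0), h_um = numeric(0), omega_rpm = numeric(0),
               acceleration = numeric(0), v_in = numeric(0), d_um = numeric(0),
               f_hz = numeric(0), interpolated = logical(0))
  }
  rejections <- if (length(rej) > 0L) {
    do.call(rbind, lapply(rej, function(r) {
      data.frame(w_um = r$w_um, h_um = r$h_um, omega_rpm = r$omega_rpm,
                 acceleration = r$acceleration, reason = r$reason)
    }))
  } else {
    data.frame(w_um = numeric(0), h_um = numeric(0), omega_rpm = numeric(0),
               acceleration = numeric(0), reason = character(0))
  }
  rownames(candidates) <- NULL
  rownames(rejections) <- NULL
  structure(list(candidates = candidates, rejections = rejections,
                 window = window),
            class = "design_search")
}

#' @export
print.design_search <- function(x, ...) {
  cat(sprintf("Design search: %d candidate(s), %d rejection(s) for window %.1f-%.1f um\n",
              nrow(x$candidates), nrow(x$rejections),
              x$window$d_min / .UM, x$window$d_max / .UM))
  if (nrow(x$candidates) > 0L) {
    print(utils::head(x$candidates, 5), row.names = FALSE)
  }
  invisible(x)
}
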