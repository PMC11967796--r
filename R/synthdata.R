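#' Ground truth for synthetic emulsification datasets
#'
#' Defines the synthetic exponential laws and noise model used by the data
#' generators. The defaults are chosen so that the default 60-condition grid
#' (see [generate_condition_grid()]) produces droplet diameters spanning the
#' 80-400 um envelope typical of centrifugal step emulsifiers: `ln alpha`
#' falls linearly with acceleration and `beta` carries a mild linear trend.
#' These coefficients are synthetic calibration values, not fitted
#' experimental constants.
#'
#' @param lnalpha_intercept,lnalpha_slope Coefficients of
#'   `ln alpha(a) = intercept + slope * a` (alpha in Pa s m^-1, a in m s^-2).
#' @param beta_ref Beta at the reference acceleration (m^-1).
#' @param beta_slope Linear trend of beta with acceleration (m^-1 per
#'   m s^-2).
#' @param beta_ref_accel Reference acceleration for the beta trend (m s^-2).
#' @param diameter_cv_pct Diameter coefficient of variation in percent
#'   (default 1; experimental monodispersity reaches CVs below 1 percent).
#' @param seed Integer seed; identical seed and spec give identical outputs.
#' @return An object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(lnalpha_intercept = 16.0, lnalpha_slope = -6.0e-4,
                            beta_ref = 2.0e4, beta_slope = 0.15,
                            beta_ref_accel = 4500, diameter_cv_pct = 1,
                            seed = 1L) {
  structure(list(lnalpha_intercept = lnalpha_intercept,
                 lnalpha_slope = lnalpha_slope,
                 beta_ref = beta_ref, beta_slope = beta_slope,
                 beta_ref_accel = beta_ref_accel,
                 diameter_cv_pct = diameter_cv_pct,
                 seed = as.integer(seed)),
            class = "synthetic_truth")
}

#' @rdname synthetic_truth
#' @param truth A `synthetic_truth`.
#' @param acceleration Centrifugal acceleration(s) (m s^-2).
#' @export
truth_alpha <- function(truth, acceleration) {
  exp(truth$lnalpha_intercept + truth$lnalpha_slope * acceleration)
}

#' @rdname synthetic_truth
#' @export
truth_beta <- function(truth, acceleration) {
  truth$beta_ref + truth$beta_slope * (acceleration - truth$beta_ref_accel)
}

#' Generate a synthetic grid of emulsification conditions
#'
#' Builds the default study grid: three square channel cross-sections (20,
#' 30, 40 um) crossed with 20 rotor settings (five centrifugal
#' accelerations, each realised by four rotor geometries differing in R1,
#' with omega chosen as `sqrt(a / (R1 + R2))`), i.e. 60 conditions in
#' total. Each condition carries the computed inlet velocity, Weber number
#' and regime label; high-acceleration large-channel conditions legitimately
#' fall in the dripping-faucet regime and are flagged as such.
#'
#' @param accelerations Centrifugal accelerations at the nozzle (m s^-2).
#' @param r1_mm Rotor R1 variants (mm).
#' @param r2_mm Rotor R2 (mm).
#' @param channel_um Square channel cross-sections (um).
#' @param channel_length_mm Channel length (mm).
#' @param fluids A [fluid_system()]; the default is a plausible synthetic
#'   aqueous/oil system (water-like aqueous phase, 5 mN/m interfacial
#'   tension, 120 degree hydrophobic contact angle), not a measured one.
#' @param we_threshold Weber regime boundary.
#' @return A data frame in the tabular interchange convention (`w_um, h_um,
#'   l_mm, rho_kg_m3, mu_mPa_s, gamma_mN_m, theta_deg, omega_rpm, R1_mm,
#'   R2_mm`) plus derived columns `a_m_s2`, `vin_m_s`, `we`, `regime`.
#' @export
generate_condition_grid <- function(accelerations = c(1500, 3000, 4500, 6579.7, 8000),
                                    r1_mm = c(12, 15, 18, 21), r2_mm = 6,
                                    channel_um = c(20, 30, 40),
                                    channel_length_mm = 5,
                                    fluids = fluid_system(1000, 1e-3, 5e-3,
                                                          deg_to_rad(120)),
                                    we_threshold = 1) {
  stopifnot(inherits(fluids, "fluid_system"))
  grid <- expand.grid(w = channel_um, r1 = r1_mm, a = accelerations,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    w <- grid$w[i]
    r1 <- grid$r1[i] * .MM
    r2 <- r2_mm * .MM
    omega <- sqrt(grid$a[i] / (r1 + r2))
    ch <- channel_geometry(w * .UM, w * .UM, channel_length_mm * .MM)
    cond <- emul_condition(ch, fluids, rotor_config(omega, r1, r2),
                           we_threshold)
    data.frame(
      w_um = w, h_um = w, l_mm = channel_length_mm,
      rho_kg_m3 = fluids$density, mu_mPa_s = fluids$viscosity / .MPA_S,
      gamma_mN_m = fluids$surface_tension / .MN_M,
      theta_deg = fluids$contact_angle * 180 / pi,
      omega_rpm = rad_s_to_rpm(omega), R1_mm = grid$r1[i], R2_mm = r2_mm,
      a_m_s2 = cond$acceleration, vin_m_s = cond$v_in, we = cond$we,
      regime = cond$regime
    )
  })
  out <- do.call(rbind, rows)
  if (!any(out$regime == "periodic_dripping")) {
    stop("grid specification yields no periodic-dripping conditions",
         call. = FALSE)
  }
  out
}

#' Generate synthetic droplet observations from a condition grid
#'
#' For every periodic-dripping condition in the grid, solves the diameter
#' equation under the truth law for the exact diameter D*, then applies the
#' configured CV at two levels: a condition-level multiplicative lognormal
#' perturbation of the mean diameter (emulating model mismatch and
#' assembly-to-assembly variability, the component that limits prediction
#' accuracy) and droplet-level polydispersity in the `n_droplets` individual
#' diameters drawn around that mean (setting the emitted empirical CV).
#' Conditions outside the dripping regime or outside the truth law's
#' support are skipped and listed in the `skipped` attribute.
#'
#' @param grid A condition grid from [generate_condition_grid()].
#' @param truth A [synthetic_truth()].
#' @param n_droplets Droplets drawn per condition (default 1000).
#' @param seed Seed for the noise draws (default `truth$seed`).
#' @return A data frame of observations (grid columns plus `D_um`,
#'   `cv_pct`, `n_droplets`) with attribute `skipped` (integer row indices
#'   of the grid that were skipped).
#' @export
generate_observations <- function(grid, truth, n_droplets = 1000,
                                  seed = truth$seed) {
  stopifnot(inherits(truth, "synthetic_truth"))
  set.seed(seed)
  cv <- truth$diameter_cv_pct / 100
  sdlog <- sqrt(log(1 + cv^2))
  rows <- list()
  skipped <- integer(0)
  for (i in seq_len(nrow(grid))) {
    if (grid$regime[i] != "periodic_dripping" || grid$vin_m_s[i] <= 0) {
      skipped <- c(skipped, i)
      next
    }
    a <- grid$a_m_s2[i]
    w <- grid$w_um[i] * .UM
    h <- grid$h_um[i] * .UM
    gam <- grid$gamma_mN_m[i] * .MN_M
    dstar <- tryCatch(
      .solve_diameter(gam, w, h, grid$vin_m_s[i],
                      truth_alpha(truth, a), truth_beta(truth, a)),
      error = function(e) NA_real_)
    if (is.na(dstar)) {
      skipped <- c(skipped, i)
      next
    }
    centre <- if (cv > 0) dstar * stats::rlnorm(1, -sdlog^2 / 2, sdlog)
              else dstar
    d_i <- if (cv > 0) centre * stats::rlnorm(n_droplets, -sdlog^2 / 2, sdlog)
           else rep(centre, n_droplets)
    row <- grid[i, setdiff(names(grid), c("a_m_s2", "vin_m_s", "we", "regime")),
                drop = FALSE]
    row$D_um <- mean(d_i) / .UM
    row$cv_pct <- 100 * stats::sd(d_i) / mean(d_i)
    row$n_droplets <- n_droplets
    rows[[length(rows) + 1L]] <- row
  }
  if (length(rows) == 0L) {
    stop("no condition in the grid is inside the truth law's support",
         call. = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Generate a synthetic droplet fluorescence population
#'
#' Emulates a scanned droplet array: analyte occupancy is Poisson with mean
#' `lambda = C * V`; intensity is a negative baseline plus a sinusoidal
#' stitching drift, Gaussian noise, and a fixed positive shift for occupied
#' droplets. True labels are retained for classifier evaluation.
#'
#' @param concentration Analyte concentration in copies (or CFU) per uL.
#' @param diameter Droplet diameter (m).
#' @param n Number of droplets, >= 1.
#' @param baseline Negative baseline intensity (a.u.).
#' @param noise_sd Gaussian intensity noise SD (a.u.).
#' @param drift_amplitude Stitching drift amplitude (a.u.); the default is
#'   10 percent of the positive-negative separation.
#' @param drift_period Drift period in droplets (default 500, i.e. much
#'   shorter than a full array scan).
#' @param positive_shift Intensity shift of occupied droplets (a.u.).
#' @param seed Integer seed.
#' @return A [droplet_population()] with `truth` labels; the droplet volume
#'   (uL) is derived from `diameter`.
#' @export
generate_droplet_population <- function(concentration, diameter, n,
                                        baseline = 100, noise_sd = 2,
                                        drift_amplitude = 10,
                                        drift_period = 500,
                                        positive_shift = 100, seed = 1L) {
  stopifnot(concentration >= 0, diameter > 0, n >= 1)
  set.seed(seed)
  volume_ul <- pi * diameter^3 / 6 / .UL
  lambda <- concentration * volume_ul
  occupancy <- stats::rpois(n, lambda)
  idx <- seq_len(n)
  intensity <- baseline +
    drift_amplitude * sin(2 * pi * idx / drift_period) +
    stats::rnorm(n, 0, noise_sd) +
    positive_shift * (occupancy >= 1)
  droplet_population(intensity, idx, volume_ul, truth = occupancy >= 1)
}
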