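test_that("resistance factor matches hand evaluation and rises with D", {
  # gamma = 5 mN/m, 20 um square channel, V_in = 0.05 m/s, D = 150 um
  cond <- ref_condition()
  cond$v_in <- 0.05
  expect_equal(resistance_factor(cond, 150e-6), 1.733e4, tolerance = 1e-3)
  # vanishes at the hydraulic diameter (bracket root)
  dh <- 2 * 20e-6 * 20e-6 / (40e-6)
  expect_equal(resistance_factor(cond, dh), 0)
  # strictly increasing in D
  rfs <- resistance_factor(cond, c(100, 150, 200, 300) * 1e-6)
  expect_true(all(diff(rfs) > 0))
  cond$v_in <- 0
  cond$no_flow <- TRUE
  expect_error(resistance_factor(cond, 150e-6), "no flow")
})

test_that("exponential-law fit recovers known coefficients exactly on clean data", {
  alpha <- 1e6
  beta <- 2e4
  D <- seq(100e-6, 300e-6, length.out = 10)
  law <- fit_exp_law(D, law_rf(D, alpha, beta), acceleration = 4500)
  expect_equal(law$alpha, alpha, tolerance = 1e-8)
  expect_equal(law$beta, beta, tolerance = 1e-8)
  expect_equal(law$r_squared, 1, tolerance = 1e-12)
})

test_that("beta survives 1% diameter noise within 5%", {
  set.seed(42)
  alpha <- 1e6
  beta <- 2e4
  D_true <- seq(100e-6, 300e-6, length.out = 20)
  rf <- law_rf(D_true, alpha, beta)
  D_noisy <- D_true * exp(rnorm(20, 0, 0.01))
  law <- fit_exp_law(D_noisy, rf)
  expect_equal(law$beta, beta, tolerance = 0.05)
})

test_that("observations from different channel sizes fall on one per-acceleration line", {
  # Noise-free synthetic conditions at one acceleration, two channel
  # dimensions: resistance factors from both must collapse onto a single
  # exponential in D.
  fl <- ref_fluids()
  alpha <- 2e5
  beta <- 2e4
  rows <- list()
  for (w in c(20e-6, 30e-6)) {
    for (r1 in c(12, 15, 18, 21) * 1e-3) {
      omega <- sqrt(6579.7 / (r1 + 6e-3))
      cond <- emul_condition(channel_geometry(w, w, 5e-3), fl,
                             rotor_config(omega, r1, 6e-3))
      D <- stepemul:::.solve_diameter(fl$surface_tension, w, w, cond$v_in,
                                      alpha, beta)
      rows[[length(rows) + 1L]] <- c(D = D, rf = resistance_factor(cond, D))
    }
  }
  m <- do.call(rbind, rows)
  law <- fit_exp_law(m[, "D"], m[, "rf"], acceleration = 6579.7)
  expect_gt(law$r_squared, 0.99)
  expect_equal(law$alpha, alpha, tolerance = 1e-6)
})

test_that("fit rejects degenerate inputs with diagnostics", {
  expect_error(fit_exp_law(c(1e-4, 2e-4), c(1, 2)), "at least 3")
  expect_error(fit_exp_law(c(1e-4, 2e-4, 3e-4), c(1, -2, 3)), "positive")
})

test_that("diameter prediction is self-consistent and agrees with a grid scan", {
  fl <- ref_fluids()
  model <- structure(list(
    laws = data.frame(acceleration = 6579.7, alpha = 2e5, beta = 2e4,
                      r_squared = 1, n = 10),
    group_rtol = 0.01), class = "droplet_model")
  cond <- ref_condition()
  D <- predict_diameter(cond, model)
  # round trip: the returned D satisfies the diameter equation
  lhs <- resistance_factor(cond, as.numeric(D))
  rhs <- 2e5 * exp(-2e4 * as.numeric(D))
  expect_equal(lhs, rhs, tolerance = 1e-9)
  # brute-force oracle: densest |LHS - RHS| point on a 1e4-point grid
  dh <- 2 * cond$channel$width * cond$channel$height /
    (cond$channel$width + cond$channel$height)
  grid <- seq(dh * (1 + 1e-6), 1e-3, length.out = 1e4)
  mis <- abs(resistance_factor(cond, grid) - 2e5 * exp(-2e4 * grid))
  d_grid <- grid[which.min(mis)]
  expect_lt(abs(as.numeric(D) - d_grid), diff(grid[1:2]))
})

test_that("predicted diameter exceeds the hydraulic diameter and grows with V_in", {
  model <- structure(list(
    laws = data.frame(acceleration = 6579.7, alpha = 2e5, beta = 2e4,
                      r_squared = 1, n = 10),
    group_rtol = 0.01), class = "droplet_model")
  dh <- 2 * 20e-6 * 20e-6 / 40e-6
  ds <- sapply(c(0.05, 0.08, 0.12, 0.2), function(v) {
    cond <- ref_condition()
    cond$v_in <- v
    as.numeric(predict_diameter(cond, model))
  })
  expect_true(all(ds > dh))
  expect_true(all(diff(ds) > 0))
})

test_that("untrained accelerations error unless interpolation is enabled", {
  model <- structure(list(
    laws = data.frame(acceleration = c(3000, 6000), alpha = c(4e5, 2e5),
                      beta = c(1.9e4, 2.1e4), r_squared = c(1, 1), n = c(5, 5)),
    group_rtol = 0.01), class = "droplet_model")
  cond <- emul_condition(ref_channel(), ref_fluids(),
                         rotor_config(sqrt(4500 / 24e-3), 18e-3, 6e-3))
  expect_error(predict_diameter(cond, model), "untrained acceleration")
  D <- predict_diameter(cond, model, interpolate = TRUE)
  expect_true(attr(D, "interpolated"))
  # interpolated coefficients are geometric/arithmetic midpoints at a = 4500
  expect_equal(stepemul:::.match_law(model, 4500, TRUE)$alpha,
               sqrt(4e5 * 2e5), tolerance = 1e-10)
})

test_that("generation frequency conserves the volumetric rate", {
  cond <- ref_condition()
  cond$v_in <- 0.1
  f <- predict_frequency(cond, 145e-6)
  expect_equal(f, 25.1, tolerance = 5e-3)
  # f * droplet volume = w h V_in exactly
  expect_equal(f * pi * (145e-6)^3 / 6, 20e-6 * 20e-6 * 0.1)
  # halving D multiplies f by 8
  expect_equal(predict_frequency(cond, 72.5e-6) / f, 8)
})

test_that("train/validate evaluation recovers a model-generated dataset", {
  grid <- generate_condition_grid()
  truth <- synthetic_truth(diameter_cv_pct = 0)
  obs <- generate_observations(grid, truth, seed = 7)
  ev <- evaluate_model(obs, seed = 11)
  expect_lt(ev$error_pct, 0.1)
  expect_equal(ev$n_train + ev$n_validation, nrow(obs))
})

test_that("evaluation error is invariant to the unit ingest path", {
  # resistance factors computed from a um-convention table row equal those
  # from directly constructed SI objects
  grid <- generate_condition_grid()
  cond_tab <- conditions_from_table(grid[1, ])[[1]]
  cond_si <- emul_condition(
    channel_geometry(grid$w_um[1] * 1e-6, grid$h_um[1] * 1e-6,
                     grid$l_mm[1] * 1e-3),
    fluid_system(grid$rho_kg_m3[1], grid$mu_mPa_s[1] * 1e-3,
                 grid$gamma_mN_m[1] * 1e-3, deg_to_rad(grid$theta_deg[1])),
    rotor_config(rpm_to_rad_s(grid$omega_rpm[1]), grid$R1_mm[1] * 1e-3,
                 grid$R2_mm[1] * 1e-3))
  expect_equal(resistance_factor(cond_tab, 150e-6),
               resistance_factor(cond_si, 150e-6))
  expect_equal(cond_tab$v_in, cond_si$v_in)
})

test_that("evaluation reports deficient strata instead of fitting them", {
  grid <- generate_condition_grid()
  truth <- synthetic_truth(diameter_cv_pct = 0)
  obs <- generate_observations(grid, truth, seed = 7)
  # keep only 3 points in one acceleration group: 2/3 split leaves 2 to train
  a <- grid$a_m_s2[match(interaction(obs$omega_rpm, obs$w_um),
                         interaction(grid$omega_rpm, grid$w_um))]
  keep <- c(which(abs(a - 1500) < 20)[1:3], which(abs(a - 1500) >= 20))
  expect_error(evaluate_model(obs[keep, ], seed = 1), "fewer than 3")
})
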