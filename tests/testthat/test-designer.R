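test_that("area budget follows the square-footprint pi/4 rule", {
  # 350 mm^2 reservoir, no headroom -> 275 mm^2 of droplet area
  expect_equal(area_budget(350e-6) * 1e6, 274.89, tolerance = 1e-4)
  # one quarter reserved for rapid tiling
  expect_equal(area_budget(350e-6, 0.25) * 1e6, 206.17, tolerance = 1e-4)
  # full reservation drives the budget to zero
  expect_lt(area_budget(350e-6, 1 - 1e-9), 1e-12)
  expect_error(area_budget(350e-6, 1), "reserve_fraction")
})

test_that("droplet counts reproduce the worked design cases", {
  expect_equal(droplet_count(20e-9, 145e-6), 12529.3, tolerance = 1e-4)
  expect_equal(droplet_count(20e-9, 108e-6), 30322.4, tolerance = 1e-4)
  expect_equal(droplet_count(50e-9, 380e-6), 1740, tolerance = 1e-3)
  # no-dead-volume: count times droplet volume is the sample volume, exactly
  D <- 145e-6
  expect_equal(droplet_count(20e-9, D) * pi * D^3 / 6, 20e-9)
})

test_that("mean occupancy is linear in concentration", {
  expect_equal(mean_occupancy(0, 380e-6), 0)
  # 10^6 cells/mL in 380 um gel microspheres -> ~30 cells each
  expect_equal(mean_occupancy(1e6, 380e-6), 28.73, tolerance = 1e-3)
  expect_equal(mean_occupancy(2e6, 380e-6), 2 * mean_occupancy(1e6, 380e-6))
})

test_that("diameter windows reproduce the two assay designs", {
  # 20 uL, 208 mm^2 budget, >= 10 000 droplets -> 144-156 um
  w1 <- diameter_window(20e-9, 1e4, 208e-6)
  expect_equal(w1$d_min * 1e6, 144.2, tolerance = 1e-3)
  expect_equal(w1$d_max * 1e6, 156.3, tolerance = 1e-3)
  expect_true(w1$feasible)
  # 20 uL, full 275 mm^2 budget -> 109-156 um (printed as 110-156)
  w2 <- diameter_window(20e-9, 1e4, area_budget(350e-6))
  expect_equal(w2$d_min * 1e6, 109.1, tolerance = 1e-3)
  expect_equal(w2$d_max * 1e6, 156.3, tolerance = 1e-3)
  # single-droplet limit: a vast budget frees the lower bound
  w3 <- diameter_window(20e-9, 1, 1e6)
  expect_lt(w3$d_min, 1e-12)
  expect_equal(w3$d_max, (6 * 20e-9 / pi)^(1 / 3))
  # the bundled-constraints path derives its own budget from the rule
  w4 <- diameter_window(tiling_constraints(350e-6, 20e-9, 1e4, 0.25))
  expect_equal(w4$d_min, 1.5 * 20e-9 / area_budget(350e-6, 0.25))
  expect_equal(w4$d_max, w2$d_max)
})

test_that("window bounds invert their defining constraints exactly", {
  w <- diameter_window(20e-9, 1e4, 208e-6)
  # accumulated circle area at D_min equals the budget
  n_min <- droplet_count(20e-9, w$d_min)
  expect_equal(n_min * pi * w$d_min^2 / 4, 208e-6, tolerance = 1e-9)
  # droplet count at D_max equals the minimum count
  expect_equal(droplet_count(20e-9, w$d_max), 1e4, tolerance = 1e-9)
  expect_identical(unname(w$binding["lower"]), "area_budget")
  expect_identical(unname(w$binding["upper"]), "droplet_count")
})

test_that("infeasible windows are flagged, not silently clipped", {
  # tiny budget forces D_min above the count-limited D_max
  w <- diameter_window(20e-9, 1e4, 1e-7)
  expect_false(w$feasible)
  expect_gt(w$d_min, w$d_max)
  expect_error(
    reverse_engineer(structure(list(laws = data.frame(), group_rtol = 0.01),
                               class = "droplet_model"),
                     w, list(ref_channel()), rpm_to_rad_s(1000),
                     ref_rotor(), ref_fluids()),
    "infeasible")
})

test_that("reverse engineering equals exhaustive per-condition prediction", {
  grid <- generate_condition_grid()
  truth <- synthetic_truth(diameter_cv_pct = 0)
  obs <- generate_observations(grid, truth, seed = 3)
  model <- fit_droplet_model(obs)
  window <- diameter_window(20e-9, 1e4, 208e-6)
  channels <- lapply(c(20, 30, 40) * 1e-6, function(w) {
    channel_geometry(w, w, 5e-3)
  })
  omega_grid <- rpm_to_rad_s(seq(1000, 6000, by = 250))
  fl <- ref_fluids()
  des <- reverse_engineer(model, window, channels, omega_grid,
                          ref_rotor(), fl)
  # brute force over the full grid with direct prediction calls
  brute <- list()
  for (ch in channels) {
    for (om in omega_grid) {
      cond <- emul_condition(ch, fl, rotor_config(om, 18e-3, 6e-3))
      if (cond$no_flow || cond$regime != "periodic_dripping") next
      D <- tryCatch(
        as.numeric(predict_diameter(cond, model, interpolate = TRUE)),
        error = function(e) NA_real_)
      if (is.na(D) || D < window$d_min || D > window$d_max) next
      brute[[length(brute) + 1L]] <- c(ch$width * 1e6, rad_s_to_rpm(om))
    }
  }
  brute <- do.call(rbind, brute)
  found <- des$candidates[, c("w_um", "omega_rpm")]
  expect_equal(nrow(found), nrow(brute))
  key <- function(m) sort(paste(round(m[, 1]), round(m[, 2])))
  expect_identical(key(as.matrix(found)), key(brute))
  # every condition is accounted for
  expect_equal(nrow(des$candidates) + nrow(des$rejections),
               length(channels) * length(omega_grid))
  # candidates are sorted by distance from the window midpoint
  mid <- (window$d_min + window$d_max) / 2 * 1e6
  expect_true(!is.unsorted(abs(des$candidates$d_um - mid)))
})

test_that("a window below the bracket support rejects every channel", {
  model <- structure(list(
    laws = data.frame(acceleration = 6579.7, alpha = 2e5, beta = 2e4,
                      r_squared = 1, n = 10),
    group_rtol = 0.01), class = "droplet_model")
  # admissible window sits below 2wh/(w+h) for a 20 um channel
  w <- structure(list(d_min = 1e-6, d_max = 15e-6,
                      binding = c(lower = "area_budget", upper = "droplet_count"),
                      feasible = TRUE), class = "diameter_window")
  des <- reverse_engineer(model, w, list(ref_channel()),
                          rpm_to_rad_s(c(4000, 5000)), ref_rotor(),
                          ref_fluids())
  expect_equal(nrow(des$candidates), 0)
  expect_true(all(des$rejections$reason == "below model support"))
})
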