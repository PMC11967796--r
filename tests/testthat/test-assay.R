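test_that("global threshold is mean + 3 SD of the negative control", {
  expect_equal(global_threshold(c(100, 100, 100)), 100)
  expect_equal(global_threshold(c(90, 100, 110)), 130)
  # order invariance
  expect_equal(global_threshold(c(110, 90, 100)), 130)
  expect_error(global_threshold(100), "at least 2")
})

test_that("local classification handles flat and extreme populations", {
  pop <- droplet_population(rep(100, 50), volume = 1e-3)
  res <- local_classify(pop)
  expect_equal(res$p, 0)
  expect_false(any(res$positive))
  # one droplet at 1e6 among flat negatives: exactly one positive
  pop2 <- droplet_population(c(rep(100, 50), 1e6), volume = 1e-3)
  res2 <- local_classify(pop2)
  expect_equal(sum(res2$positive), 1)
  expect_true(res2$positive[51])
})

test_that("positive fraction is invariant to affine intensity rescaling", {
  pop <- generate_droplet_population(500, 145e-6, 2000, seed = 5)
  ctrl <- generate_droplet_population(0, 145e-6, 500, seed = 6)
  r1 <- local_classify(pop, controls = ctrl$intensity)
  scaled <- droplet_population(3.7 * pop$intensity + 42, pop$position,
                               pop$volume)
  r2 <- local_classify(scaled, controls = 3.7 * ctrl$intensity + 42)
  expect_equal(r1$p, r2$p)
  expect_identical(r1$positive, r2$positive)
})

test_that("too few provisional negatives falls back to global thresholding", {
  # nearly all droplets sit above the control-derived threshold
  pop <- droplet_population(c(rep(500, 30), 100, 100), volume = 1e-3)
  expect_warning(res <- local_classify(pop, controls = c(99, 100, 101)),
                 "falling back")
  expect_true(res$fallback)
})

test_that("local rule absorbs stitching drift that breaks the global rule", {
  # Sinusoidal baseline drift with amplitude 10% of the positive shift;
  # threshold trained on a drift-free negative control.
  pop <- generate_droplet_population(300, 145e-6, 5000, seed = 2)
  set.seed(101)
  ctrl_int <- 100 + rnorm(500, 0, 2)
  thr0 <- global_threshold(ctrl_int)
  global_labels <- pop$intensity > thr0
  res <- local_classify(pop, controls = ctrl_int)
  global_acc <- mean(global_labels == pop$truth)
  local_acc <- mean(res$positive == pop$truth)
  # drift peaks push negatives over the global threshold...
  expect_lt(global_acc, 0.95)
  # ...but the local neighbourhood rule recovers essentially all labels
  expect_gte(local_acc, 0.99)
})

test_that("with no drift, global and local classifications agree", {
  # noise-free population: the two rules are label-for-label identical
  set.seed(77)
  int <- c(rep(100, 200), rep(200, 20))[sample.int(220)]
  flat <- droplet_population(int, volume = 1.596e-3)
  ctrl_flat <- c(99, 100, 101)
  res_flat <- local_classify(flat, controls = ctrl_flat)
  expect_identical(res_flat$positive, int > global_threshold(ctrl_flat))
  # with Gaussian noise the 5-SD local rule and 3-SD global rule can only
  # differ on ~0.1% upper-tail negatives; the local rule matches the truth
  pop <- generate_droplet_population(300, 145e-6, 3000, drift_amplitude = 0,
                                     seed = 9)
  ctrl <- generate_droplet_population(0, 145e-6, 500, drift_amplitude = 0,
                                      seed = 10)
  res <- local_classify(pop, controls = ctrl$intensity)
  global_labels <- pop$intensity > global_threshold(ctrl$intensity)
  expect_gt(mean(res$positive == pop$truth), 0.999)
  expect_lt(mean(res$positive != global_labels), 0.005)
})

test_that("Poisson quantification inverts the occupancy map", {
  expect_equal(poisson_concentration(0, 1e-3)$concentration, 0)
  # p = 1 - 1/e in 1 nL droplets is exactly 1000 copies/uL
  expect_equal(poisson_concentration(1 - exp(-1), 1e-3)$concentration, 1000)
  # 145 um droplet (1.596e-3 uL) at p = 0.05
  expect_equal(poisson_concentration(0.05, 1.596e-3)$concentration, 32.1,
               tolerance = 5e-3)
  expect_error(poisson_concentration(1, 1e-3), "saturated")
  # forward/backward closure to 1e-12 relative
  for (C in c(10, 500, 3000)) {
    V <- 1.596e-3
    p <- 1 - exp(-C * V)
    expect_equal(poisson_concentration(p, V)$concentration, C,
                 tolerance = 1e-12)
  }
})

test_that("Wilson interval brackets the point estimate", {
  est <- poisson_concentration(0.05, 1.596e-3, n = 12500)
  expect_lt(est$conf_low, est$concentration)
  expect_gt(est$conf_high, est$concentration)
})

test_that("dilution linearity recovers exact and offset series", {
  theo <- c(10, 100, 1000, 10000)
  fit <- dilution_linearity(theo, theo)
  expect_equal(fit$slope, 1)
  expect_equal(fit$intercept, 0)
  expect_equal(fit$r_squared, 1)
  fit2 <- dilution_linearity(2 * theo, theo)
  expect_equal(fit2$slope, 1)
  expect_equal(fit2$intercept, log10(2))
  expect_error(dilution_linearity(c(-1, 1, 2), c(1, 2, 3)), "positive")
})

test_that("noisy four-decade dilution series stays linear", {
  set.seed(13)
  theo <- 2.85 * 10^(1:4)
  measured <- theo * exp(rnorm(4 * 3, 0, 0.1))
  fit <- dilution_linearity(measured, rep(theo, 3))
  expect_gt(fit$r_squared, 0.99)
  expect_equal(fit$slope, 1, tolerance = 0.1)
})

test_that("LOD is the lowest all-replicates-positive concentration", {
  calls <- list(`10` = c(FALSE, FALSE, TRUE),
                `28.5` = c(TRUE, TRUE, TRUE),
                `285` = c(TRUE, TRUE, TRUE))
  expect_equal(lod(calls)$lod, 28.5)
  expect_false(lod(list(`10` = c(FALSE, FALSE)))$reached)
  # adding a higher all-positive concentration never raises the LOD
  calls2 <- c(calls, list(`2850` = c(TRUE, TRUE, TRUE)))
  expect_lte(lod(calls2)$lod, lod(calls)$lod)
})

test_that("MIC is read at the survival cutoff", {
  curve <- data.frame(concentration = c(0, 0.5, 1, 2),
                      survival_pct = c(100, 60, 8, 1))
  expect_equal(mic(curve)$mic, 1)
  high <- data.frame(concentration = c(0, 1, 2), survival_pct = c(99, 60, 30))
  expect_false(mic(high)$reached)
  # a 100% cutoff is met by the lowest tested concentration
  expect_equal(mic(curve, cutoff = 100)$mic, 0)
  expect_error(mic(data.frame(concentration = c(1, 1),
                              survival_pct = c(50, 40))),
               "strictly increasing")
})
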