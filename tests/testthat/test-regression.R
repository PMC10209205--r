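test_that("stepping fit recovers a noiseless controller exactly", {
  feats <- noiseless_features()
  truth <- noiseless_sim()$truth
  fit <- fit_stepping(feats, "ap")
  expect_s3_class(fit, "stepping_fit")
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_equal(unname(fit$gains), unname(truth$stepping_gains["ap", ]),
               tolerance = 1e-6)
  td <- tidy(fit)
  expect_identical(td$term, state_names())
  expect_identical(nrow(glance(fit)), 1L)
})

test_that("stepping fit is scale-equivariant in its predictors", {
  feats <- noisy_features()
  base <- fit_stepping(feats, "ml")
  scaled <- feats
  scaled$vel_y <- scaled$vel_y * 10
  fit2 <- fit_stepping(scaled, "ml")
  expect_equal(fit2$gains[["vel_y"]], base$gains[["vel_y"]] / 10,
               tolerance = 1e-9)
  others <- setdiff(state_names(), "vel_y")
  expect_equal(fit2$gains[others], base$gains[others], tolerance = 1e-9)
  expect_equal(fit2$r_squared, base$r_squared, tolerance = 1e-12)
})

test_that("nondimensionalization leaves the stepping R2 unchanged", {
  feats <- noisy_features()
  nf <- nondimensionalize_features(feats)
  expect_equal(fit_stepping(nf, "ap")$r_squared,
               fit_stepping(feats, "ap")$r_squared, tolerance = 1e-12)
})

test_that("rank-deficient predictors are reported by name", {
  feats <- noisy_features()
  feats$acc_z <- feats$acc_y
  expect_error(fit_stepping(feats, "ap"), "acc_[yz]")
})

test_that("too few strides and missing columns are rejected", {
  feats <- noisy_features()
  expect_error(fit_stepping(feats[1:10, ], "ap"), "at least 30")
  expect_error(fit_stepping(feats[, 1:4], "ap"), "missing column")
})

test_that("foot-placement error is the signed OLS residual with zero mean", {
  feats <- noisy_features()
  fit <- fit_stepping(feats, "ml")
  err <- compute_fp_error(fit, feats)
  expect_identical(nrow(err), nrow(feats))
  expect_lt(abs(mean(err$fp_error)), 1e-12)
  expect_equal(err$fp_error, -fit$residuals, tolerance = 1e-15)
  expect_error(compute_fp_error(fit, feats[1:5, ]), "strides")
})

test_that("foot-placement error variance matches the configured noise", {
  sim <- cached("n500", simulate_walker(sim_config(n_strides = 500,
                                                   seed = 900)))
  feats <- cached("n500_feats",
                  gait_features(sim$kin, sim$insole, clock_offset = 0))
  fit <- fit_stepping(feats, "ml")
  err <- compute_fp_error(fit)
  ratio <- var(err$fp_error) / sim$truth$config$fp_noise_sd^2
  expect_gt(ratio, 0.85)
  expect_lt(ratio, 1.15)
})

test_that("compensation fit recovers a noise-free strategy split exactly", {
  feats <- comp_exact_features()
  truth <- comp_exact_sim()$truth
  fit <- fit_stepping(feats, "ml")
  err <- compute_fp_error(fit)
  comp <- fit_compensation(err$fp_error, feats$cop_bar, feats$trunk_bar)
  expect_equal(comp$r_squared, 1, tolerance = 1e-9)
  expect_equal(comp$ankle_gain, truth$ankle_gain, tolerance = 1e-6)
  expect_equal(comp$trunk_gain, truth$trunk_gain, tolerance = 1e-6)
  expect_identical(nrow(tidy(comp)), 2L)
})

test_that("swapping the compensation predictors swaps the fitted gains", {
  feats <- comp_exact_features()
  err <- compute_fp_error(fit_stepping(feats, "ml"))
  a <- fit_compensation(err$fp_error, feats$cop_bar, feats$trunk_bar)
  b <- fit_compensation(err$fp_error, feats$trunk_bar, feats$cop_bar)
  expect_equal(a$ankle_gain, b$trunk_gain, tolerance = 1e-12)
  expect_equal(a$trunk_gain, b$ankle_gain, tolerance = 1e-12)
})

test_that("constant compensation predictors are rejected", {
  feats <- comp_exact_features()
  err <- compute_fp_error(fit_stepping(feats, "ml"))
  expect_error(
    fit_compensation(err$fp_error, rep(0.01, nrow(feats)),
                     feats$trunk_bar),
    "constant")
})

test_that("midstance state accessor returns the nine components", {
  feats <- noisy_features()
  s <- extract_midstance_state(feats, 5)
  expect_identical(names(s), state_names())
  expect_error(extract_midstance_state(feats, 1e5), "not found")
})
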