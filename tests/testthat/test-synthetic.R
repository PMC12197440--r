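# Ground-truthed synthetic plate renderer.

test_that("rendering is byte-identical under a fixed seed", {
  spec <- synthetic_plate_spec(
    lanes = list(synthetic_lane(320, 0.6, 0.4)), seed = 77)
  r1 <- render_plate(spec)
  r2 <- render_plate(spec)
  expect_identical(r1$plate$pixels, r2$plate$pixels)
  expect_identical(r1$manifest, r2$manifest)
  r3 <- render_plate(synthetic_plate_spec(
    lanes = list(synthetic_lane(320, 0.6, 0.4)), seed = 78))
  expect_false(identical(r1$plate$pixels, r3$plate$pixels))
})

test_that("rendering does not disturb the caller's RNG stream", {
  set.seed(123)
  a <- runif(1)
  set.seed(123)
  invisible(render_plate(synthetic_plate_spec(seed = 5)))
  expect_identical(runif(1), a)
})

test_that("a background-only plate yields no spots", {
  rp <- render_plate(synthetic_plate_spec(seed = 9))
  pr <- suppressWarnings(run_pipeline(rp$plate))
  expect_length(pr$spots, 0)
  expect_equal(nrow(rp$manifest), 0)
})

test_that("manifest analytic AUC matches dense numeric integration", {
  for (s in c(3, 5, 8, 12)) {
    spec <- synthetic_plate_spec(
      lanes = list(synthetic_lane(320, 0.55, 0.4, sigma_px = s)),
      noise_sd = 0, seed = 1)
    rp <- render_plate(spec)
    integral <- sum(spec$background_green - rp$noiseless_green)
    expect_equal(rp$manifest$auc_raw, 2 * pi * 0.4 * s^2, tolerance = 1e-9)
    expect_equal(integral, rp$manifest$auc_raw, tolerance = 0.02)
  }
})

test_that("spec invariants are enforced", {
  expect_error(synthetic_plate_spec(background_green = 0),
               class = "tlc_spec_error")
  expect_error(synthetic_plate_spec(noise_sd = -0.1),
               class = "tlc_spec_error")
  expect_error(synthetic_plate_spec(
    lanes = list(synthetic_lane(100, 1.2, 0.4))), class = "tlc_spec_error")
  expect_error(synthetic_plate_spec(
    lanes = list(synthetic_lane(100, 0.5, 0.9))), class = "tlc_spec_error")
  expect_error(synthetic_plate_spec(
    lanes = list(synthetic_lane(100, 0.5, 0.4, sigma_px = 0))),
    class = "tlc_spec_error")
  expect_error(render_plate(synthetic_plate_spec(
    lanes = list(synthetic_lane(9999, 0.5, 0.4)))),
    class = "tlc_spec_error")
})

test_that("quench quantization happens before the pipeline sees pixels", {
  rp <- make_uniform_plate(0.4, seed = 11, n_lanes = 1)
  expect_true(is.integer(rp$plate$pixels))
  expect_true(all(rp$plate$pixels >= 0L & rp$plate$pixels <= 255L))
})

test_that("calibration-set amplitudes follow the requested gain", {
  set <- render_calibration_set(ladder_levels, gain = ladder_gain)
  expect_length(set$plates, 1)
  expect_equal(set$truth$auc_raw, ladder_gain * ladder_levels)
  expect_equal(nrow(set$truth), length(ladder_levels))
  # detected AUC correlates with amplitude across the ladder
  cal <- calibrate_image(set$plates[[1]]$plate, ladder_levels)
  expect_gt(cal$model$r_squared, 0.99)
  expect_true(all(diff(cal$auc) > 0))
})

test_that("empty level lists and clipping gains are handled", {
  empty <- render_calibration_set(numeric(0))
  expect_length(empty$plates, 0)
  expect_error(render_calibration_set(c(1, 100), gain = 60),
               class = "tlc_spec_error")
  expect_error(render_calibration_set(c(-1, 2)), class = "tlc_spec_error")
})

test_that("noisy replicate plates keep the recovered slope near truth", {
  set <- render_calibration_set(ladder_levels, gain = ladder_gain,
                                n_plates = 5)
  slopes <- vapply(set$plates, function(p)
    calibrate_image(p$plate, ladder_levels)$model$slope, numeric(1))
  truth <- coef(lm(auc_norm ~ level,
                   data = set$truth[set$truth$plate == 1, ]))[["level"]]
  # plate-to-plate scatter is small; the systematic offset (the
  # threshold-dependent footprint baseline) stays bounded
  expect_lt(sd(slopes) / mean(slopes), 0.03)
  expect_lt(abs(mean(slopes) / truth - 1), 0.25)
})

test_that("plates and manifests are written to disk as text + png", {
  rp <- make_uniform_plate(0.4, seed = 13, n_lanes = 2)
  d <- tempfile()
  paths <- write_synthetic_plate(rp, d, "demo")
  expect_true(all(file.exists(file.path(d, c("demo.png",
                                             "demo_manifest.csv",
                                             "demo_manifest.json")))))
  back <- read_plate(file.path(d, "demo.png"),
                     origin_row = rp$plate$origin_row,
                     front_row = rp$plate$front_row)
  expect_identical(back$pixels, rp$plate$pixels)
})
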