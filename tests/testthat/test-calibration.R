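# Calibration fitting, LoD/LoQ, inverse prediction and model IO.

test_that("noiseless points on a line are fitted exactly", {
  conc <- c(0.5, 1, 2, 3, 4)
  cal <- tlc_calibration(conc, 10701 * conc + 7502)
  expect_equal(cal$slope, 10701)
  expect_equal(cal$intercept, 7502)
  expect_equal(cal$sy, 0)
  expect_equal(cal$r_squared, 1)
  expect_equal(cal$linear_range, c(0.5, 4))
  expect_equal(unname(coef(cal)), c(7502, 10701))
})

test_that("duplicated two-point designs interpolate with zero residual sd", {
  cal <- tlc_calibration(c(1, 1, 3, 3), c(10, 10, 30, 30))
  expect_equal(cal$slope, 10)
  expect_equal(cal$sy, 0)
})

test_that("degenerate calibrations raise classed errors", {
  expect_error(tlc_calibration(c(1, 2), c(1, 2)),
               class = "tlc_insufficient_data_error")
  expect_error(tlc_calibration(c(2, 2, 2), c(1, 2, 3)),
               class = "tlc_singular_fit_error")
  expect_error(tlc_calibration(1:3, 1:4), class = "tlc_format_error")
})

test_that("LoD and LoQ follow the 3.3 and 10 sy/S formulas", {
  cal <- tlc_calibration(c(1, 2, 3), c(10, 20, 30))
  expect_equal(unname(lod_loq(cal)), c(0, 0))

  m <- list(slope = 1000, sy = 250)
  ll <- lod_loq(m)
  expect_equal(ll[["lod"]], 3.3 * 250 / 1000)
  expect_equal(ll[["loq"]], 10 * 250 / 1000)
  expect_equal(ll[["loq"]] / ll[["lod"]], 10 / 3.3)
  expect_lt(ll[["lod"]], ll[["loq"]])
  expect_error(lod_loq(list(slope = -1, sy = 1)),
               class = "tlc_invalid_model_error")
})

test_that("back-solved residual sd reproduces the reference LoD scale", {
  # a slope-10701 calibration whose LoD is 1.45 mg/mL implies
  # sy = 1.45 * 10701 / 3.3
  sy <- 1.45 * 10701 / 3.3
  expect_equal(sy, 4701.95, tolerance = 1e-4)
  m <- list(slope = 10701, sy = sy)
  expect_equal(unname(lod_loq(m)[["lod"]]), 1.45, tolerance = 1e-12)
})

test_that("LoD/LoQ scale linearly in sy and inversely in slope", {
  base <- lod_loq(list(slope = 500, sy = 100))
  expect_equal(unname(lod_loq(list(slope = 500, sy = 200))),
               unname(2 * base))
  expect_equal(unname(lod_loq(list(slope = 1000, sy = 100))),
               unname(base / 2))
})

test_that("inverse prediction is exact on noiseless calibrations", {
  set.seed(42)
  for (i in 1:10) {
    S <- runif(1, 100, 20000); b <- runif(1, -500, 9000)
    conc <- sort(runif(5, 0.2, 5))
    cal <- tlc_calibration(conc, S * conc + b)
    c0 <- runif(1, min(conc), max(conc))
    expect_equal(predict_conc(cal, S * c0 + b), c0, tolerance = 1e-8)
  }
})

test_that("prediction handles anchor points, clamping and extrapolation", {
  conc <- c(0.5, 1, 2, 3, 4)
  cal <- tlc_calibration(conc, 10701 * conc + 7502)
  expect_warning(p0 <- predict_conc(cal, 7502),
                 class = "tlc_extrapolation_warning")
  expect_equal(p0, 0)
  expect_equal(predict_conc(cal, 10701 * 4 + 7502), 4)
  expect_warning(predict_conc(cal, 10701 * 5 + 7502),
                 class = "tlc_extrapolation_warning")
  expect_true(is.na(suppressWarnings(
    predict_conc(cal, 10701 * 5 + 7502, extrapolation_policy = "reject"))))
  # the predict() method routes through inverse prediction
  expect_equal(predict(cal, auc = 10701 * 2 + 7502), 2)
})

test_that("slope estimation is unbiased on noisy synthetic calibrations", {
  conc <- c(0.5, 1, 2, 3, 4, 4.5)
  S <- 10701; b <- 7502; noise_sd <- 400
  set.seed(99)
  slopes <- replicate(200, {
    tlc_calibration(conc, S * conc + b + rnorm(6, 0, noise_sd))$slope
  })
  expect_lt(abs(mean(slopes) / S - 1), 0.02)
  # bias shrinks as replicates accumulate
  expect_lt(abs(mean(slopes) / S - 1), abs(slopes[1] / S - 1) + 0.02)
})

test_that("models and tables round-trip through their file formats", {
  conc <- c(0.5, 1, 2, 3, 4)
  cal <- tlc_calibration(conc, 10701 * conc + 7502 + c(1, -2, 0, 2, -1))
  f <- tempfile(fileext = ".yaml")
  write_calibration_model(cal, f)
  back <- read_calibration_model(f)
  expect_equal(back$slope, cal$slope)
  expect_equal(back$intercept, cal$intercept)
  expect_equal(back$sy, cal$sy)
  expect_equal(back$linear_range, as.numeric(cal$linear_range))
  expect_equal(predict_conc(back, 30000), predict_conc(cal, 30000))

  tab <- data.frame(conc_mg_ml = conc, auc = 10701 * conc + 7502)
  tf <- tempfile(fileext = ".csv")
  write_calibration_table(tab, tf)
  expect_equal(read_calibration_table(tf), tab)
  expect_error(read_calibration_model("nope.yaml"),
               class = "tlc_config_error")
})

test_that("calibrating from a ladder image recovers the generator gain", {
  lv <- ladder_levels
  set0 <- render_calibration_set(lv, gain = ladder_gain,
                                 template = synthetic_plate_spec(noise_sd = 0))
  cal <- calibrate_image(set0$plates[[1]]$plate, lv)
  truth_slope <- coef(lm(auc_norm ~ level, data = set0$truth))[["level"]]
  expect_lt(abs(cal$model$slope / truth_slope - 1), 0.02)
  expect_gt(cal$model$r_squared, 0.99)
  expect_error(calibrate_image(set0$plates[[1]]$plate, c(1, 2)),
               class = "tlc_insufficient_data_error")
})
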