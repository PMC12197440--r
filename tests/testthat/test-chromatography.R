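# Retention factors, lane assignment, principal-spot selection and the
# Rf identity rule.

test_that("retention factor is 0 at the origin and 1 at the front", {
  expect_equal(compute_rf(380, origin_row = 380, front_row = 20)$rf, 0)
  expect_equal(compute_rf(20, origin_row = 380, front_row = 20)$rf, 1)
  r <- compute_rf(380 - 0.604 * 360, origin_row = 380, front_row = 20)
  expect_equal(r$rf, 0.604)
  expect_equal(r$distance_spot / r$distance_front, r$rf)
})

test_that("centroids outside the development region are rejected", {
  expect_error(compute_rf(390, origin_row = 380, front_row = 20),
               class = "tlc_geometry_error")
  expect_error(compute_rf(10, origin_row = 380, front_row = 20),
               class = "tlc_geometry_error")
  expect_error(compute_rf(100, origin_row = 20, front_row = 380),
               class = "tlc_geometry_error")
})

test_that("a rendered spot at 60.4% of the development distance reads 0.604", {
  rp <- make_uniform_plate(0.4, noise_sd = 0, seed = 2, n_lanes = 1,
                           rf = 0.604)
  pr <- run_pipeline(rp$plate)
  expect_length(pr$spots, 1)
  r <- compute_rf(pr$spots[[1]], pr$plate$origin_row, pr$plate$front_row)
  expect_equal(round(r$rf, 2), 0.60)
  expect_lt(abs(r$rf - 0.604), 0.01)
})

test_that("Rf is invariant under vertical rescaling of the crop", {
  rp <- make_uniform_plate(0.4, noise_sd = 0, seed = 2, n_lanes = 1,
                           rf = 0.604)
  for (height in c(200L, 400L, 600L)) {
    cfg <- pipeline_config(standard_height = height)
    pr <- run_pipeline(rp$plate, cfg)
    r <- compute_rf(pr$spots[[1]], pr$plate$origin_row, pr$plate$front_row)
    span <- pr$plate$origin_row - pr$plate$front_row
    expect_lt(abs(r$rf - 0.604), 1 / span + 0.005)
  }
})

test_that("lane assignment is single-linkage clustering on columns", {
  spots <- lapply(c(50, 52, 150, 250), fake_spot)
  lm1 <- assign_lanes(spots, gap_threshold = 40)
  expect_length(lm1$lane_centers, 3)
  expect_equal(lm1$assignment, c(1L, 1L, 2L, 3L))
  expect_equal(lm1$lane_centers, c(51, 150, 250))
  expect_equal(lm1$lane_centers, sort(lm1$lane_centers))

  lm2 <- assign_lanes(spots, gap_threshold = 300)
  expect_length(lm2$lane_centers, 1)
  expect_true(all(lm2$assignment == 1L))

  expect_length(assign_lanes(list(fake_spot(10)), gap_threshold = 5)$lane_centers, 1)
  expect_error(assign_lanes(list(), gap_threshold = 5),
               class = "tlc_lookup_error")
  expect_error(assign_lanes(spots), class = "tlc_config_error")
})

test_that("lane recovery matches the synthetic manifest", {
  for (n_lanes in c(3, 5, 6)) {
    rp <- make_uniform_plate(0.4, seed = 30 + n_lanes, n_lanes = n_lanes)
    pr <- run_pipeline(rp$plate)
    lanes <- assign_lanes(pr$spots, crop_width = ncol(pr$signal),
                          expected_lanes = n_lanes)
    expect_length(lanes$lane_centers, n_lanes)
  }
})

test_that("principal spot has maximal AUC with documented tie-breaks", {
  s1 <- fake_spot(10, auc = 120); s2 <- fake_spot(12, auc = 300)
  expect_identical(select_principal(list(s1, s2)), s2)
  expect_identical(select_principal(list(s1)), s1)
  # AUC tie -> larger area; area tie -> lower row
  a <- fake_spot(10, auc = 100, area = 50)
  b <- fake_spot(10, auc = 100, area = 80)
  expect_identical(select_principal(list(a, b)), b)
  c1 <- fake_spot(10, row = 40, auc = 100, area = 80)
  expect_identical(select_principal(list(b, c1)), c1)
  expect_error(select_principal(list()), class = "tlc_lookup_error")
})

test_that("faint satellites do not displace the principal spot", {
  centers <- round(640 * 0.5)
  lanes <- list(list(column_center = centers, spots = list(
    list(rf_true = 0.604, amplitude = 0.5, sigma_px = 8),
    list(rf_true = 0.30, amplitude = 0.1, sigma_px = 8))))
  rp <- render_plate(synthetic_plate_spec(lanes = lanes, seed = 5))
  pr <- run_pipeline(rp$plate,
                     pipeline_config(threshold_method = "background"))
  expect_gte(length(pr$spots), 2)
  principal <- select_principal(pr$spots)
  r <- compute_rf(principal, pr$plate$origin_row, pr$plate$front_row)
  expect_lt(abs(r$rf - 0.604), 0.02)
})

test_that("Rf identity uses inclusive relative deviation", {
  expect_true(rf_match(0.58, 0.604))            # 4.0% deviation
  expect_false(rf_match(0.54, 0.604))           # 10.6% deviation
  expect_true(rf_match(0.604, 0.604))
  # boundary: exactly 10% relative deviation passes
  expect_true(rf_match(0.604 * 1.10, 0.604))
  expect_true(rf_match(0.604 * 0.90, 0.604))
  expect_false(rf_match(0.604 * 1.1001, 0.604))
  expect_error(rf_match(0.5, 0), class = "tlc_config_error")
  expect_error(rf_match(0.5, 0.6, tolerance_frac = 0),
               class = "tlc_config_error")
})

test_that("rf_match is symmetric around the standard and monotone in
           tolerance", {
  std <- 0.6
  for (d in c(0.01, 0.05, 0.059)) {
    expect_equal(rf_match(std + d, std), rf_match(std - d, std))
  }
  dev <- 0.08
  tols <- c(0.05, 0.1, 0.2, 0.3)
  ok <- vapply(tols, function(t) rf_match(std * (1 + dev), std, t),
               logical(1))
  expect_true(all(diff(ok) >= 0))   # once true, stays true
})

test_that("standards registry validates reference Rf values", {
  p <- system.file("extdata", "standards.yaml", package = "tlcscreen")
  reg <- read_standards(p)
  expect_equal(reg$metformin$standard_rf, 0.604)
  expect_equal(reg$metformin$label_claim_mg, 500)
  bad <- tempfile(fileext = ".yaml")
  writeLines("drug:\n  standard_rf: 1.5", bad)
  expect_error(read_standards(bad), class = "tlc_config_error")
  expect_error(read_standards("no/such/file.yaml"),
               class = "tlc_config_error")
})
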