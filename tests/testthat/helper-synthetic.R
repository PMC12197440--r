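# Shared synthetic-plate builders. Conditions (geometry, background, spot
# sigma, noise) mirror the package defaults; the ladder spans the 0.5-4
# mg/mL linear range with analytic gain 60 raw-AUC units per mg/mL.

ladder_levels <- c(0.5, 1, 2, 3, 4)
ladder_gain <- 60
spot_sigma <- 8

# amplitude of a lane at `level` mg/mL under the analytic gain
level_amplitude <- function(level, gain = ladder_gain, sigma = spot_sigma) {
  gain * level / (2 * pi * sigma^2)
}

# plate with the 5-level ladder plus one sample lane (lane 6)
make_ladder_sample_plate <- function(sample_level, sample_rf = 0.604,
                                     seed = 1, noise_sd = 0.01) {
  lv <- c(ladder_levels, sample_level)
  centers <- round(seq(0.5, 5.5) / 6 * 640)
  lanes <- lapply(seq_along(lv), function(i)
    synthetic_lane(centers[i],
                   rf_true = if (i == 6) sample_rf else 0.604,
                   amplitude = level_amplitude(lv[i]),
                   sigma_px = spot_sigma))
  render_plate(synthetic_plate_spec(lanes = lanes, noise_sd = noise_sd,
                                    seed = seed))
}

# plate with n equal-amplitude lanes (single spot each)
make_uniform_plate <- function(amplitude, noise_sd = 0.01, seed = 1,
                               n_lanes = 6, rf = 0.604) {
  centers <- round(seq(0.5, n_lanes - 0.5) / n_lanes * 640)
  lanes <- lapply(centers, function(cc)
    synthetic_lane(cc, rf, amplitude, spot_sigma))
  render_plate(synthetic_plate_spec(lanes = lanes, noise_sd = noise_sd,
                                    seed = seed))
}

# fit a calibration from the ladder lanes of a ladder+sample plate and
# return list(model, pipeline result, lane map)
self_calibrate <- function(rendered,
                           pcfg = pipeline_config(
                             threshold_method = "background")) {
  pr <- run_pipeline(rendered$plate, pcfg)
  lanes <- assign_lanes(pr$spots, crop_width = ncol(pr$signal),
                        expected_lanes = 6)
  auc <- vapply(seq_along(lanes$lane_centers), function(k)
    select_principal(pr$spots[lanes$assignment == k])$auc, numeric(1))
  list(model = tlc_calibration(ladder_levels, auc[seq_along(ladder_levels)]),
       pipeline = pr, lanes = lanes, auc = auc)
}

# minimal stand-in spot for lane/selection tests
fake_spot <- function(col, row = 100, auc = 1, area = 100) {
  structure(list(centroid = c(row = row, col = col), auc = auc,
                 area_px = area, bbox = NULL, contour = NULL),
            class = "spot")
}
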