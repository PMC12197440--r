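#' Specify a synthetic TLC plate
#'
#' Describes a ground-truthed synthetic plate image emulating an F254
#' silica plate under short-wave UV: a bright green fluorescent background
#' on which UV-absorbing analyte spots appear as dark Gaussian quench
#' profiles, optionally with a linear illumination gradient and Gaussian
#' pixel noise. Rendering is fully deterministic given the seed.
#'
#' @param width,height raster size in pixels (defaults 640 x 400, the
#'   pipeline's standard crop height).
#' @param lanes list of lane specs, each
#'   `list(column_center =, spots = list(list(rf_true =, amplitude =,
#'   sigma_px =), ...))`; see [synthetic_lane()].
#' @param background_green base green level in `(0, 1]` (default 0.70).
#' @param gradient `c(per_row, per_col)` linear illumination slope across
#'   the full image extent (default none).
#' @param noise_sd Gaussian pixel noise standard deviation on the `[0, 1]`
#'   green scale (default 0.01, typical of 8-bit smartphone frames).
#' @param origin_row,front_row reference rows (defaults 20 px inside the
#'   bottom and top edges).
#' @param seed RNG seed for the noise field.
#' @return A list of class `synthetic_plate_spec`.
#' @export
synthetic_plate_spec <- function(width = 640L, height = 400L,
                                 lanes = list(),
                                 background_green = 0.70,
                                 gradient = c(0, 0), noise_sd = 0.01,
                                 origin_row = height - 20L,
                                 front_row = 20L, seed = 1L) {
  if (background_green <= 0 || background_green > 1)
    tlc_abort("background_green must be in (0, 1]", "tlc_spec_error")
  if (noise_sd < 0)
    tlc_abort("noise_sd must be >= 0", "tlc_spec_error")
  if (!(front_row < origin_row))
    tlc_abort("front_row must be above origin_row", "tlc_spec_error")
  for (ln in lanes) {
    for (sp in ln$spots) {
      if (sp$rf_true < 0 || sp$rf_true > 1)
        tlc_abort("spot rf_true must be in [0, 1]", "tlc_spec_error")
      if (sp$amplitude <= 0 || sp$amplitude > background_green)
        tlc_abort("spot amplitude must be in (0, background_green]",
                  "tlc_spec_error")
      if (sp$sigma_px <= 0)
        tlc_abort("spot sigma_px must be positive", "tlc_spec_error")
    }
  }
  structure(list(width = as.integer(width), height = as.integer(height),
                 lanes = lanes, background_green = background_green,
                 gradient = gradient, noise_sd = noise_sd,
                 origin_row = origin_row, front_row = front_row,
                 seed = as.integer(seed)),
            class = "synthetic_plate_spec")
}

#' Describe one synthetic lane
#'
#' @param column_center lane centre column (pixels).
#' @param rf_true retention factor(s) of the lane's spot(s), in `[0, 1]`.
#' @param amplitude quench depth(s) on the `[0, 1]` green scale.
#' @param sigma_px spatial standard deviation(s) of the Gaussian spot.
#' @return A lane spec for [synthetic_plate_spec()].
#' @export
synthetic_lane <- function(column_center, rf_true, amplitude,
                           sigma_px = 8) {
  n <- max(length(rf_true), length(amplitude))
  rf_true <- rep_len(rf_true, n)
  amplitude <- rep_len(amplitude, n)
  sigma_px <- rep_len(sigma_px, n)
  list(column_center = column_center,
       spots = lapply(seq_len(n), function(i)
         list(rf_true = rf_true[i], amplitude = amplitude[i],
              sigma_px = sigma_px[i])))
}

#' Render a synthetic plate and its ground-truth manifest
#'
#' The green channel is `background + gradient - sum(Gaussian quench
#' spots) + noise`, clipped to `[0, 1]` and quantized to 8 bits before the
#' pipeline ever sees it, so tests run in the same precision regime as
#' real photographs. Red and blue channels are low constants. The manifest
#' records, per spot, the true centroid, retention factor, amplitude and
#' the analytic quench AUC `2 * pi * amplitude * sigma^2` both in raw
#' green units (`auc_raw`) and divided by the noiseless min-max range of
#' the plate (`auc_norm`, the convention of the inverted-normalized signal
#' the pipeline integrates).
#'
#' @param spec a [synthetic_plate_spec].
#' @return A list of class `synthetic_plate`: `plate` (a [plate_image]),
#'   `manifest` (data frame), `scale` (noiseless min-max range) and
#'   `noiseless_green` (float matrix, for oracle integrations).
#' @export
render_plate <- function(spec) {
  stopifnot(inherits(spec, "synthetic_plate_spec"))
  h <- spec$height; w <- spec$width
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  g <- spec$background_green +
    spec$gradient[1] * (rows - 1) / (h - 1) +
    spec$gradient[2] * (cols - 1) / (w - 1)
  manifest <- list()
  dev_span <- spec$origin_row - spec$front_row
  for (li in seq_along(spec$lanes)) {
    ln <- spec$lanes[[li]]
    for (si in seq_along(ln$spots)) {
      sp <- ln$spots[[si]]
      r0 <- spec$origin_row - sp$rf_true * dev_span
      c0 <- ln$column_center
      if (c0 < 1 || c0 > w)
        tlc_abort("lane centre outside the image", "tlc_spec_error")
      g <- g - sp$amplitude *
        exp(-((rows - r0)^2 + (cols - c0)^2) / (2 * sp$sigma_px^2))
      manifest[[length(manifest) + 1L]] <- data.frame(
        lane = li, spot = si, row_true = r0, col_true = c0,
        rf_true = sp$rf_true, amplitude = sp$amplitude,
        sigma_px = sp$sigma_px,
        auc_raw = 2 * pi * sp$amplitude * sp$sigma_px^2)
    }
  }
  noiseless <- pmin(1, pmax(0, g))
  scale <- max(noiseless) - min(noiseless)
  if (spec$noise_sd > 0) {
    g <- g + with_seed(spec$seed, matrix(rnorm(h * w, 0, spec$noise_sd), h, w))
  }
  g8 <- as.integer(round(pmin(1, pmax(0, g)) * 255))
  px <- array(0L, dim = c(h, w, 3L))
  px[, , 1] <- 20L
  px[, , 2] <- g8
  px[, , 3] <- 26L
  manifest <- if (length(manifest)) do.call(rbind, manifest) else
    data.frame(lane = integer(), spot = integer(), row_true = numeric(),
               col_true = numeric(), rf_true = numeric(),
               amplitude = numeric(), sigma_px = numeric(),
               auc_raw = numeric())
  manifest$auc_norm <- if (scale > 0) manifest$auc_raw / scale
                       else rep(NA_real_, nrow(manifest))
  structure(list(
    plate = plate_image(px, origin_row = spec$origin_row,
                        front_row = spec$front_row),
    manifest = manifest, scale = scale, noiseless_green = noiseless,
    seed = spec$seed),
    class = "synthetic_plate")
}

#' @export
print.synthetic_plate <- function(x, ...) {
  cat(sprintf("<synthetic_plate> %d spot(s), seed %d, min-max scale %.3f\n",
              nrow(x$manifest), x$seed, x$scale))
  invisible(x)
}

#' Render a synthetic calibration set
#'
#' Lays one lane per concentration level on each plate, choosing the spot
#' quench amplitude so that the analytic raw AUC follows
#' `gain * level + baseline`; the emitted truth table carries the analytic
#' AUC in both raw and plate-normalized conventions, so a calibration
#' fitted to detected AUCs can be compared against the normalized truth
#' slope.
#'
#' @param levels concentrations (mg/mL), all positive; an empty vector
#'   yields an empty set.
#' @param gain analytic raw-AUC units per mg/mL (default 60).
#' @param baseline analytic raw-AUC offset (default 0).
#' @param sigma_px spot spatial sigma (default 8).
#' @param template a [synthetic_plate_spec] supplying geometry, background,
#'   gradient and noise (its `lanes` are replaced).
#' @param n_plates number of replicate plates (default 1); plate `k` uses
#'   seed `template$seed + k - 1`.
#' @return A list of class `calibration_set`: `plates` (list of
#'   [render_plate()] results), `truth` (data frame: plate, lane, level,
#'   amplitude, auc_raw, auc_norm), `levels`, `gain`.
#' @export
render_calibration_set <- function(levels, gain = 60, baseline = 0,
                                   sigma_px = 8,
                                   template = synthetic_plate_spec(),
                                   n_plates = 1L) {
  if (length(levels) == 0L)
    return(structure(list(plates = list(), truth = data.frame(),
                          levels = levels, gain = gain),
                     class = "calibration_set"))
  if (any(levels <= 0))
    tlc_abort("calibration levels must be positive", "tlc_spec_error")
  amp <- (gain * levels + baseline) / (2 * pi * sigma_px^2)
  if (any(amp > template$background_green))
    tlc_abort(paste("requested gain implies quench amplitude above the",
                    "background level; clipping would corrupt linearity"),
              "tlc_spec_error")
  n <- length(levels)
  centers <- round(seq(0.5, n - 0.5) / n * template$width)
  plates <- vector("list", n_plates)
  truth <- list()
  for (k in seq_len(n_plates)) {
    spec <- template
    spec$seed <- template$seed + k - 1L
    spec$lanes <- lapply(seq_len(n), function(i)
      synthetic_lane(centers[i], rf_true = 0.604, amplitude = amp[i],
                     sigma_px = sigma_px))
    class(spec) <- "synthetic_plate_spec"
    plates[[k]] <- render_plate(spec)
    truth[[k]] <- data.frame(plate = k, lane = seq_len(n), level = levels,
                             amplitude = amp,
                             auc_raw = 2 * pi * amp * sigma_px^2,
                             auc_norm = plates[[k]]$manifest$auc_norm)
  }
  structure(list(plates = plates, truth = do.call(rbind, truth),
                 levels = levels, gain = gain),
            class = "calibration_set")
}

#' Write a synthetic plate's image and manifest to disk
#'
#' @param sp a `synthetic_plate` from [render_plate()].
#' @param dir output directory (created if needed).
#' @param stem file stem (default "plate").
#' @return Invisibly, the paths written (PNG image, CSV and JSON manifest).
#' @export
write_synthetic_plate <- function(sp, dir, stem = "plate") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  png_path <- file.path(dir, paste0(stem, ".png"))
  csv_path <- file.path(dir, paste0(stem, "_manifest.csv"))
  json_path <- file.path(dir, paste0(stem, "_manifest.json"))
  write_plate(sp$plate, png_path)
  write.csv(sp$manifest, csv_path, row.names = FALSE)
  jsonlite::write_json(list(origin_row = sp$plate$origin_row,
                            front_row = sp$plate$front_row,
                            seed = sp$seed, scale = sp$scale,
                            spots = sp$manifest),
                       json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(png_path, csv_path, json_path))
}
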