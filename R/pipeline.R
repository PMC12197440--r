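#' Pixel-pipeline configuration
#'
#' Parameters of the spot-detection chain: green-channel extraction,
#' min-max inversion, Gaussian smoothing, grayscale dilation, thresholding
#' and contour detection.
#'
#' @param blur_kernel odd Gaussian kernel width in pixels (default 5).
#' @param sigma Gaussian sigma; `0` derives it from the kernel width as
#'   `0.3 * ((k - 1)/2 - 1) + 0.8` (so 1.1 for the default 5-tap kernel).
#' @param dilation_kernel side of the square structuring element for the
#'   moving-window maximum (default 16).
#' @param threshold_method `"otsu"` (default), `"fixed"`, or
#'   `"background"`. Otsu's criterion separates spots from background well
#'   when spot intensities are comparable, but on crops whose spots span a
#'   wide dynamic range (e.g. a 0.5-4 mg/mL calibration ladder) it drops
#'   the faintest spots; the `"background"` method thresholds at the
#'   background floor — the median of the (background-dominated) image —
#'   plus `background_offset`, which retains faint spots.
#' @param fixed_threshold threshold in `[0, 1]`; required when
#'   `threshold_method = "fixed"`.
#' @param background_offset margin above the image median used by the
#'   `"background"` method (default 0.05).
#' @param max_foreground_frac sparsity guard: quench spots cover a small
#'   fraction of a plate crop, so a threshold that marks more than this
#'   fraction of pixels as foreground (as data-driven thresholds do on
#'   featureless noise-only crops, where any split is spurious) yields an
#'   empty mask with a warning instead (default 0.25).
#' @param min_spot_area minimum filled-contour area in pixels at the
#'   reference crop height; components smaller than
#'   `min_spot_area * (H / standard_height)^2` are discarded as noise.
#' @param standard_height crop height (rows) to which plates are resampled
#'   before processing (default 400).
#' @param dilate_before_threshold the chain dilates the smoothed image and
#'   thresholds the result; set `FALSE` to threshold first and dilate the
#'   mask instead (experimentation switch).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(blur_kernel = 5L, sigma = 0,
                            dilation_kernel = 16L,
                            threshold_method = c("otsu", "fixed",
                                                 "background"),
                            fixed_threshold = NULL,
                            background_offset = 0.05,
                            max_foreground_frac = 0.25,
                            min_spot_area = 50L,
                            standard_height = 400L,
                            dilate_before_threshold = TRUE) {
  threshold_method <- match.arg(threshold_method)
  if (blur_kernel < 3L || blur_kernel %% 2L == 0L)
    tlc_abort("blur_kernel must be an odd integer >= 3", "tlc_config_error")
  if (sigma < 0)
    tlc_abort("sigma must be >= 0", "tlc_config_error")
  if (dilation_kernel < 1L)
    tlc_abort("dilation_kernel must be >= 1", "tlc_config_error")
  if (threshold_method == "fixed") {
    if (is.null(fixed_threshold) || fixed_threshold < 0 ||
        fixed_threshold > 1)
      tlc_abort("fixed_threshold in [0,1] is required for method 'fixed'",
                "tlc_config_error")
  } else if (!is.null(fixed_threshold)) {
    tlc_abort("fixed_threshold is only meaningful with method 'fixed'",
              "tlc_config_error")
  }
  if (background_offset < 0 || background_offset > 1)
    tlc_abort("background_offset must be in [0, 1]", "tlc_config_error")
  structure(list(blur_kernel = as.integer(blur_kernel), sigma = sigma,
                 dilation_kernel = as.integer(dilation_kernel),
                 threshold_method = threshold_method,
                 fixed_threshold = fixed_threshold,
                 background_offset = background_offset,
                 max_foreground_frac = max_foreground_frac,
                 min_spot_area = min_spot_area,
                 standard_height = as.integer(standard_height),
                 dilate_before_threshold = isTRUE(dilate_before_threshold)),
            class = "pipeline_config")
}

signal_image <- function(values, provenance) {
  attr(values, "provenance") <- provenance
  values
}

#' Extract the green channel of a plate image
#'
#' Under short-wave UV the fluorescent indicator of an F254 plate emits
#' green light and UV-absorbing analytes quench it, so the green channel
#' carries the densitometric signal.
#'
#' @param img a [plate_image].
#' @return An `H x W` matrix in `[0, 1]` (green value / 255).
#' @export
extract_green <- function(img) {
  if (!inherits(img, "plate_image"))
    tlc_abort("extract_green expects a plate_image", "tlc_format_error")
  signal_image(img$pixels[, , 2] / 255, "green")
}

#' Invert and min-max normalize a signal image
#'
#' Maps `v` to `(max - v) / (max - min)` so that dark quench spots become
#' high signal on a `[0, 1]` scale with at least one 0 and one 1. A
#' constant (flat) image would divide by zero; it is returned as all zeros
#' with a warning instead.
#'
#' @param sig an `H x W` matrix in `[0, 1]`.
#' @return The inverted, normalized matrix.
#' @export
invert_normalize <- function(sig) {
  mx <- max(sig); mn <- min(sig)
  if (mx <= mn) {
    tlc_warn("flat image: min-max normalization undefined, returning zeros",
             "tlc_flat_image_warning")
    return(signal_image(array(0, dim(sig)), "inverted_normalized"))
  }
  signal_image((mx - sig) / (mx - mn), "inverted_normalized")
}

# 1-D normalized Gaussian kernel; sigma = 0 derives sigma from the kernel
# width (the convention of the imaging toolkit the pipeline mirrors).
gaussian_kernel <- function(k, sigma = 0) {
  if (k < 1L || k %% 2L == 0L)
    tlc_abort("Gaussian kernel width must be odd", "tlc_config_error")
  if (sigma <= 0) sigma <- 0.3 * ((k - 1) / 2 - 1) + 0.8
  x <- seq_len(k) - (k + 1) / 2
  w <- exp(-x^2 / (2 * sigma^2))
  w / sum(w)
}

# reflect-101 padded index vector (mirror about the edge pixel)
reflect_idx <- function(n, p) {
  c(rev(seq_len(p)) + 1L, seq_len(n), n - seq_len(p))
}

#' Gaussian smoothing
#'
#' Separable 2-D Gaussian convolution with reflected borders; kernel
#' weights sum to 1 so flat regions are preserved exactly.
#'
#' @param sig an `H x W` signal matrix.
#' @param cfg a [pipeline_config] supplying `blur_kernel` and `sigma`.
#' @return The smoothed matrix.
#' @export
gaussian_smooth <- function(sig, cfg = pipeline_config()) {
  w <- gaussian_kernel(cfg$blur_kernel, cfg$sigma)
  k <- length(w); p <- (k - 1L) %/% 2L
  n <- nrow(sig); m <- ncol(sig)
  # rows
  padded <- sig[reflect_idx(n, p), , drop = FALSE]
  out <- matrix(0, n, m)
  for (j in seq_len(k)) out <- out + w[j] * padded[j:(j + n - 1L), , drop = FALSE]
  # columns
  padded <- out[, reflect_idx(m, p), drop = FALSE]
  res <- matrix(0, n, m)
  for (j in seq_len(k)) res <- res + w[j] * padded[, j:(j + m - 1L), drop = FALSE]
  signal_image(pmin(pmax(res, 0), 1), "smoothed")
}

#' Grayscale dilation (moving-window maximum)
#'
#' Replaces every pixel by the maximum over a square window, enlarging
#' bright regions. For an even kernel width `K` the window spans offsets
#' `-K/2 .. K/2 - 1` around the anchor (rows and columns); borders are
#' replicated. The output dominates the input pointwise.
#'
#' @param sig an `H x W` signal matrix.
#' @param cfg a [pipeline_config] supplying `dilation_kernel`.
#' @return The dilated matrix.
#' @export
dilate <- function(sig, cfg = pipeline_config()) {
  k <- cfg$dilation_kernel
  if (k < 1L) tlc_abort("dilation_kernel must be >= 1", "tlc_config_error")
  lo <- -(k %/% 2L); hi <- k - 1L + lo
  n <- nrow(sig); m <- ncol(sig)
  out <- matrix(-Inf, n, m)
  for (d in lo:hi) {                       # rows
    idx <- pmin(pmax(seq_len(n) + d, 1L), n)
    out <- pmax(out, sig[idx, , drop = FALSE])
  }
  res <- matrix(-Inf, n, m)
  for (d in lo:hi) {                       # columns
    idx <- pmin(pmax(seq_len(m) + d, 1L), m)
    res <- pmax(res, out[, idx, drop = FALSE])
  }
  signal_image(res, "dilated")
}

#' Otsu threshold of a signal image
#'
#' Histogram-based threshold selection over 256 uniform bins on `[0, 1]`:
#' the returned threshold `t = k/255` maximizes the between-class variance
#' of the split `v < t` versus `v >= t` (smallest such `k` on ties). On a
#' flat image the criterion is undefined; `1.0` is returned with a warning
#' so the downstream mask is empty for any signal below full scale.
#'
#' @param sig an `H x W` matrix in `[0, 1]`.
#' @return Threshold in `[0, 1]`.
#' @export
otsu_threshold <- function(sig) {
  bins <- pmin(floor(as.numeric(sig) * 255), 255)
  counts <- tabulate(bins + 1L, 256L)
  total <- sum(counts)
  if (sum(counts > 0L) < 2L) {
    tlc_warn("flat image: Otsu threshold undefined, falling back to 1.0",
             "tlc_flat_image_warning")
    return(1.0)
  }
  lev <- 0:255
  # cumulative count / intensity sum below each candidate k (bins < k)
  cw <- cumsum(counts)          # bins <= k
  cs <- cumsum(counts * lev)
  w0 <- c(0, cw[-256L])         # weight of class {bin < k}, k = 0..255
  s0 <- c(0, cs[-256L])
  w1 <- total - w0
  mu0 <- ifelse(w0 > 0, s0 / w0, 0)
  mu1 <- ifelse(w1 > 0, (cs[256L] - s0) / w1, 0)
  bcv <- w0 * w1 * (mu0 - mu1)^2
  k <- which.max(bcv) - 1L      # smallest argmax
  k / 255
}

#' Binarize a signal image
#'
#' Pixels whose value is greater than or equal to the threshold become 1,
#' all others 0. The threshold comes from Otsu's criterion on the supplied
#' image (default), from `cfg$fixed_threshold`, or from the background
#' floor (image median plus `cfg$background_offset`).
#'
#' @param sig an `H x W` matrix in `[0, 1]`.
#' @param cfg a [pipeline_config].
#' @return A list of class `binary_mask` with elements `values` (0/1
#'   integer matrix), `threshold_used` and `method`.
#' @export
binarize <- function(sig, cfg = pipeline_config()) {
  t <- switch(cfg$threshold_method,
              fixed = cfg$fixed_threshold,
              background = min(1, stats::median(sig) + cfg$background_offset),
              otsu = otsu_threshold(sig))
  mask <- matrix(0L, nrow(sig), ncol(sig))
  mask[sig >= t] <- 1L
  guard <- cfg$max_foreground_frac %||% 1
  if (cfg$threshold_method != "fixed" && mean(mask) > guard) {
    tlc_warn(sprintf(
      "threshold marks %.0f%% of the crop as foreground; no spots assumed",
      100 * mean(mask)), "tlc_featureless_warning")
    mask[] <- 0L
  }
  structure(list(values = mask, threshold_used = t,
                 method = cfg$threshold_method),
            class = "binary_mask")
}

# Run-based 8-connected component labeling. Returns a list of components,
# each a list(pixels = 2-col matrix (row, col), area, centroid, bbox).
label_components <- function(mask) {
  n <- nrow(mask); m <- ncol(mask)
  # run-length encode each row's foreground
  runs_row <- integer(0); runs_c1 <- integer(0); runs_c2 <- integer(0)
  for (r in seq_len(n)) {
    v <- mask[r, ]
    if (!any(v == 1L)) next
    d <- diff(c(0L, v, 0L))
    starts <- which(d == 1L); ends <- which(d == -1L) - 1L
    runs_row <- c(runs_row, rep.int(r, length(starts)))
    runs_c1 <- c(runs_c1, starts); runs_c2 <- c(runs_c2, ends)
  }
  nr <- length(runs_row)
  if (nr == 0L) return(list())
  parent <- seq_len(nr)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[rj] <<- ri }
  # union runs in adjacent rows whose column spans touch (8-connectivity:
  # spans within one column of each other)
  prev_idx <- integer(0); prev_row <- -1L
  row_order <- order(runs_row, runs_c1)
  i <- 1L
  while (i <= nr) {
    r <- runs_row[row_order[i]]
    cur_idx <- row_order[which(runs_row[row_order] == r)]
    # indices i..j with this row (row_order sorted by row)
    j <- i
    while (j < nr && runs_row[row_order[j + 1L]] == r) j <- j + 1L
    cur_idx <- row_order[i:j]
    if (r == prev_row + 1L) {
      for (a in cur_idx) for (b in prev_idx) {
        if (runs_c1[b] <= runs_c2[a] + 1L && runs_c2[b] >= runs_c1[a] - 1L)
          union(a, b)
      }
    }
    prev_idx <- cur_idx; prev_row <- r
    i <- j + 1L
  }
  roots <- vapply(seq_len(nr), find, integer(1))
  comp_of <- match(roots, unique(roots))
  lapply(seq_len(max(comp_of)), function(ci) {
    idx <- which(comp_of == ci)
    len <- runs_c2[idx] - runs_c1[idx] + 1L
    area <- sum(len)
    sum_col <- sum((runs_c1[idx] + runs_c2[idx]) * len / 2)
    sum_row <- sum(runs_row[idx] * len)
    px <- do.call(rbind, lapply(idx, function(k)
      cbind(runs_row[k], runs_c1[k]:runs_c2[k])))
    list(pixels = px, area = area,
         centroid = c(row = sum_row / area, col = sum_col / area),
         bbox = c(row1 = min(runs_row[idx]), row2 = max(runs_row[idx]),
                  col1 = min(runs_c1[idx]), col2 = max(runs_c2[idx])))
  })
}

# Moore-neighbour boundary tracing of one component; `pixels` is the
# component's (row, col) matrix. Returns the ordered closed contour.
trace_contour <- function(pixels) {
  off_r <- min(pixels[, 1]) - 2L; off_c <- min(pixels[, 2]) - 2L
  h <- max(pixels[, 1]) - off_r + 2L; w <- max(pixels[, 2]) - off_c + 2L
  m <- matrix(FALSE, h, w)   # 1-px pad all around
  m[cbind(pixels[, 1] - off_r, pixels[, 2] - off_c)] <- TRUE
  start <- unname(pixels[order(pixels[, 1], pixels[, 2])[1], ]) -
    c(off_r, off_c)
  if (nrow(pixels) == 1L)
    return(matrix(start + c(off_r, off_c), 1,
                  dimnames = list(NULL, c("row", "col"))))
  # 8 directions, clockwise when rows grow downward: E, SE, S, SW, W, NW, N, NE
  moves <- rbind(c(0, 1), c(1, 1), c(1, 0), c(1, -1),
                 c(0, -1), c(-1, -1), c(-1, 0), c(-1, 1))
  contour <- matrix(0L, nrow(pixels) * 4L, 2L)
  contour[1L, ] <- start
  np <- 1L
  cur <- start
  prev_dir <- 5L  # direction from cur to the (empty) cell we came from: W
  repeat {
    found <- FALSE
    for (s in 1:8) {
      d <- ((prev_dir + s - 1L) %% 8L) + 1L   # clockwise sweep after prev
      cand <- cur + moves[d, ]
      if (m[cand[1], cand[2]]) {
        prev_dir <- ((d + 4L - 1L) %% 8L) + 1L  # from cand back to cur
        cur <- cand
        found <- TRUE
        break
      }
    }
    if (!found || all(cur == start)) break
    np <- np + 1L
    if (np > nrow(contour))
      contour <- rbind(contour, matrix(0L, nrow(contour), 2L))
    contour[np, ] <- cur
  }
  contour <- contour[seq_len(np), , drop = FALSE]
  contour[, 1] <- contour[, 1] + off_r
  contour[, 2] <- contour[, 2] + off_c
  dimnames(contour) <- list(NULL, c("row", "col"))
  contour
}

#' Sum a signal over a pixel region (spot AUC)
#'
#' The densitometric area-under-the-curve of a spot: the sum of the
#' inverted-normalized green signal over every pixel of the filled contour.
#' No background subtraction is applied; the calibration intercept absorbs
#' the baseline.
#'
#' @param signal an `H x W` signal matrix.
#' @param region 2-column matrix of (row, col) pixel coordinates.
#' @return Non-negative scalar.
#' @export
spot_auc <- function(signal, region) {
  region <- as.matrix(region)
  if (nrow(region) == 0L)
    tlc_abort("empty region", "tlc_geometry_error")
  if (min(region) < 1L || max(region[, 1]) > nrow(signal) ||
      max(region[, 2]) > ncol(signal))
    tlc_abort("region extends outside the image", "tlc_geometry_error")
  sum(signal[region])
}

#' Detect spots in a binary mask
#'
#' Finds external contours of 8-connected foreground components, discards
#' components smaller than the (height-scaled) minimum spot area, and
#' quantifies each remaining spot on the supplied signal image — by
#' convention the pre-blur inverted-normalized green image, so AUC grows
#' with analyte amount.
#'
#' @param mask a `binary_mask` (or 0/1 matrix).
#' @param signal the inverted-normalized green image, same shape.
#' @param cfg a [pipeline_config].
#' @return A list of `spot` objects (contour, centroid, bbox, area_px,
#'   auc, rf = NA, lane = NA), sorted by centroid column then row.
#' @export
detect_spots <- function(mask, signal, cfg = pipeline_config()) {
  values <- if (inherits(mask, "binary_mask")) mask$values else mask
  if (!all(dim(values) == dim(signal)))
    tlc_abort("mask and signal shapes differ", "tlc_format_error")
  comps <- label_components(values)
  min_area <- cfg$min_spot_area * (nrow(values) / cfg$standard_height)^2
  comps <- Filter(function(co) co$area >= min_area, comps)
  spots <- lapply(comps, function(co) {
    structure(list(contour = trace_contour(co$pixels),
                   centroid = co$centroid,
                   bbox = co$bbox,
                   area_px = co$area,
                   auc = spot_auc(signal, co$pixels),
                   pixels = co$pixels,
                   rf = NA_real_, lane = NA_integer_),
              class = "spot")
  })
  ord <- order(vapply(spots, function(s) s$centroid["col"], numeric(1)),
               vapply(spots, function(s) s$centroid["row"], numeric(1)))
  spots[ord]
}

#' @export
print.spot <- function(x, ...) {
  cat(sprintf(
    "<spot> centroid (%.1f, %.1f), area %d px, auc %.2f, rf %s, lane %s\n",
    x$centroid["row"], x$centroid["col"], x$area_px, x$auc,
    ifelse(is.na(x$rf), "-", sprintf("%.2f", x$rf)),
    ifelse(is.na(x$lane), "-", x$lane)))
  invisible(x)
}

#' Run the full pixel pipeline on a plate image
#'
#' Chains green-channel extraction, min-max inversion, Gaussian smoothing,
#' grayscale dilation, thresholding and spot detection. The plate is first
#' resampled to `cfg$standard_height` rows so AUC units are comparable
#' across photographs. Spot AUC is measured on the pre-blur
#' inverted-normalized green image.
#'
#' @param img a [plate_image].
#' @param cfg a [pipeline_config].
#' @param debug_dir if non-`NULL`, per-stage diagnostic PNGs are written
#'   into this directory.
#' @return A list with `spots`, `threshold`, `plate` (the resampled
#'   [plate_image]) and `signal` (the inverted-normalized green image).
#' @export
run_pipeline <- function(img, cfg = pipeline_config(), debug_dir = NULL) {
  img <- resample_plate(img, cfg$standard_height)
  green <- extract_green(img)
  inv <- invert_normalize(green)
  smoothed <- gaussian_smooth(inv, cfg)
  if (cfg$dilate_before_threshold) {
    dil <- dilate(smoothed, cfg)
    mask <- binarize(dil, cfg)
  } else {
    mask <- binarize(smoothed, cfg)
    dil_mask <- dilate(mask$values + 0, cfg)
    mask$values <- matrix(as.integer(dil_mask >= 0.5), nrow(dil_mask))
    dil <- dil_mask
  }
  if (!is.null(debug_dir)) {
    dir.create(debug_dir, showWarnings = FALSE, recursive = TRUE)
    stages <- list(green = green, inverted = inv, smoothed = smoothed,
                   dilated = dil, mask = mask$values + 0)
    for (nm in names(stages)) {
      EBImage::writeImage(EBImage::Image(t(stages[[nm]])),
                          file.path(debug_dir, paste0(nm, ".png")))
    }
  }
  spots <- detect_spots(mask, inv, cfg)
  list(spots = spots, threshold = mask$threshold_used, plate = img,
       signal = inv)
}
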