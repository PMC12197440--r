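#' Retention factor of a spot
#'
#' The retention factor is the ratio of the distance travelled by the spot
#' to the distance travelled by the solvent front, both measured from the
#' origin line. Distances are in pixel rows of the (resampled) crop; the
#' spot position is its moment centroid row.
#'
#' @param spot a `spot` (or anything with `$centroid["row"]`), or a bare
#'   centroid row number.
#' @param origin_row,front_row reference rows; `front_row < origin_row`.
#' @return A list of class `rf_result`: `rf`, `distance_spot`,
#'   `distance_front`.
#' @export
compute_rf <- function(spot, origin_row, front_row) {
  row <- if (is.numeric(spot)) spot[1] else unname(spot$centroid["row"])
  if (!(front_row < origin_row))
    tlc_abort("front_row must be above origin_row", "tlc_geometry_error")
  if (row > origin_row || row < front_row)
    tlc_abort("spot centroid lies outside the development region",
              "tlc_geometry_error")
  d_spot <- origin_row - row
  d_front <- origin_row - front_row
  structure(list(rf = d_spot / d_front, distance_spot = d_spot,
                 distance_front = d_front),
            class = "rf_result")
}

#' @export
print.rf_result <- function(x, ...) {
  cat(sprintf("Rf = %.2f (spot %g px / front %g px)\n",
              x$rf, x$distance_spot, x$distance_front))
  invisible(x)
}

#' Assign spots to lanes by centroid column
#'
#' One-dimensional single-linkage clustering of spot centroid columns: the
#' sorted columns are split wherever the gap to the previous centroid
#' exceeds `gap_threshold`.
#'
#' @param spots list of `spot` objects.
#' @param gap_threshold column gap (pixels) that starts a new lane. The
#'   default `crop_width / (2 * expected_lanes)` needs `crop_width`.
#' @param crop_width,expected_lanes used only for the default gap.
#' @return A list of class `lane_map`: `lane_centers` (increasing),
#'   `assignment` (spot index -> lane), `gap_threshold`.
#' @export
assign_lanes <- function(spots, gap_threshold = NULL, crop_width = NULL,
                         expected_lanes = 6) {
  if (length(spots) == 0L)
    tlc_abort("cannot assign lanes with no spots", "tlc_lookup_error")
  if (is.null(gap_threshold)) {
    if (is.null(crop_width))
      tlc_abort("gap_threshold or crop_width must be given",
                "tlc_config_error")
    gap_threshold <- crop_width / (2 * expected_lanes)
  }
  cols <- vapply(spots, function(s) unname(s$centroid["col"]), numeric(1))
  ord <- order(cols)
  lane_sorted <- cumsum(c(1, diff(cols[ord]) > gap_threshold))
  assignment <- integer(length(cols))
  assignment[ord] <- lane_sorted
  centers <- vapply(split(cols, assignment), mean, numeric(1))
  structure(list(lane_centers = unname(centers), assignment = assignment,
                 gap_threshold = gap_threshold),
            class = "lane_map")
}

#' Principal spot of a lane
#'
#' The principal spot — the one attributed to the active ingredient — is
#' the spot with the largest AUC; ties go to the larger area, then to the
#' spot nearer the solvent front (lower row).
#'
#' @param lane_spots non-empty list of `spot` objects in one lane.
#' @return The selected `spot`.
#' @export
select_principal <- function(lane_spots) {
  if (length(lane_spots) == 0L)
    tlc_abort("empty lane has no principal spot", "tlc_lookup_error")
  auc <- vapply(lane_spots, function(s) s$auc, numeric(1))
  area <- vapply(lane_spots, function(s) as.numeric(s$area_px), numeric(1))
  row <- vapply(lane_spots, function(s) unname(s$centroid["row"]), numeric(1))
  lane_spots[[order(-auc, -area, row)[1]]]
}

#' Test a sample retention factor against a standard
#'
#' A sample is identified as the reference compound when its retention
#' factor deviates from the standard's by at most `tolerance_frac`
#' (relative deviation, boundary inclusive).
#'
#' @param sample_rf,standard_rf retention factors in `[0, 1]`.
#' @param tolerance_frac maximum relative deviation (default 0.10).
#' @return `TRUE` when the identity check passes.
#' @export
rf_match <- function(sample_rf, standard_rf, tolerance_frac = 0.10) {
  if (standard_rf == 0)
    tlc_abort("relative deviation undefined for standard Rf = 0",
              "tlc_config_error")
  if (tolerance_frac <= 0)
    tlc_abort("tolerance_frac must be positive", "tlc_config_error")
  # tiny slack keeps the inclusive boundary inclusive under floating-point
  # rounding (e.g. a sample at exactly 110% of the standard)
  abs(sample_rf - standard_rf) / standard_rf <= tolerance_frac + 1e-9
}

#' Read a standards registry
#'
#' A YAML mapping of drug name to reference values:
#' `standard_rf`, `label_claim_mg`, `tolerance_frac`.
#'
#' @param path YAML file.
#' @return Named list of standards.
#' @export
read_standards <- function(path) {
  if (!file.exists(path))
    tlc_abort(sprintf("standards registry not found: %s", path),
              "tlc_config_error")
  reg <- yaml::read_yaml(path)
  for (nm in names(reg)) {
    s <- reg[[nm]]
    if (is.null(s$standard_rf) || s$standard_rf <= 0 || s$standard_rf > 1)
      tlc_abort(sprintf("standard '%s': standard_rf must be in (0, 1]", nm),
                "tlc_config_error")
  }
  reg
}
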