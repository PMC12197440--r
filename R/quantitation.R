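#' Quantitation configuration
#'
#' Converts working-solution concentration to per-tablet active-ingredient
#' content and encodes the pharmacopeial acceptance band. The default
#' dilution factor of 125 mL reflects the reference sample preparation:
#' one tablet dissolved in 25 mL, then diluted 5-fold to the 4 mg/mL
#' working solution, so `mg/tablet = conc_mg_ml * 125`.
#'
#' @param dilution_factor_ml effective volume (mL) mapping working-solution
#'   concentration to mg per tablet (default 125).
#' @param label_claim_mg labelled tablet content (default 500 mg).
#' @param content_tolerance_frac pharmacopeial tolerance around the label
#'   claim (default 0.10, i.e. 450-550 mg for a 500 mg claim).
#' @param extrapolation_policy forwarded to [predict_conc()].
#' @return A list of class `quant_config`.
#' @export
quant_config <- function(dilution_factor_ml = 125, label_claim_mg = 500,
                         content_tolerance_frac = 0.10,
                         extrapolation_policy = c("warn", "reject")) {
  extrapolation_policy <- match.arg(extrapolation_policy)
  if (dilution_factor_ml <= 0 || label_claim_mg <= 0)
    tlc_abort("dilution factor and label claim must be positive",
              "tlc_config_error")
  if (content_tolerance_frac <= 0 || content_tolerance_frac >= 1)
    tlc_abort("content_tolerance_frac must be in (0, 1)",
              "tlc_config_error")
  structure(list(dilution_factor_ml = dilution_factor_ml,
                 label_claim_mg = label_claim_mg,
                 content_tolerance_frac = content_tolerance_frac,
                 extrapolation_policy = extrapolation_policy),
            class = "quant_config")
}

#' Working-solution concentration to per-tablet content
#'
#' @param conc_mg_ml concentration of the working solution (mg/mL).
#' @param cfg a [quant_config].
#' @return mg of active ingredient per tablet.
#' @export
to_api_content <- function(conc_mg_ml, cfg = quant_config()) {
  if (any(conc_mg_ml < 0, na.rm = TRUE))
    tlc_abort("concentration must be non-negative", "tlc_format_error")
  conc_mg_ml * cfg$dilution_factor_ml
}

#' Pharmacopeial content verdict
#'
#' `TRUE` when the measured content lies within the acceptance band
#' `label_claim * (1 +/- tolerance)`, boundaries inclusive (a 500 mg claim
#' with 10% tolerance accepts exactly 450 and exactly 550 mg).
#'
#' @param api_mg measured content (mg per tablet).
#' @param cfg a [quant_config].
#' @return Logical.
#' @export
content_verdict <- function(api_mg, cfg = quant_config()) {
  lo <- cfg$label_claim_mg * (1 - cfg$content_tolerance_frac)
  hi <- cfg$label_claim_mg * (1 + cfg$content_tolerance_frac)
  !is.na(api_mg) & api_mg >= lo & api_mg <= hi
}

new_sample_result <- function(sample_id, rf = NA_real_, rf_ok = FALSE,
                              conc = NA_real_, api = NA_real_,
                              content_ok = FALSE, verdict, auc = NA_real_,
                              lane = NA_integer_) {
  structure(list(sample_id = sample_id, rf = rf, rf_ok = rf_ok,
                 conc_mg_ml = conc, api_mg_per_tablet = api,
                 content_ok = content_ok, verdict = verdict, auc = auc,
                 lane = lane),
            class = "sample_result")
}

#' @export
print.sample_result <- function(x, ...) {
  cat(sprintf("<sample %s> Rf %.2f [%s]  %s mg/tablet [%s]  -> %s\n",
              x$sample_id,
              ifelse(is.na(x$rf), NaN, x$rf),
              ifelse(x$rf_ok, "id ok", "id FAIL"),
              ifelse(is.na(x$api_mg_per_tablet), "-",
                     sprintf("%.2f", x$api_mg_per_tablet)),
              ifelse(x$content_ok, "content ok", "content FAIL"),
              x$verdict))
  invisible(x)
}

#' @export
as.data.frame.sample_result <- function(x, ...) {
  data.frame(sample_id = x$sample_id, lane = x$lane,
             rf = round(x$rf, 2), rf_ok = x$rf_ok, auc = x$auc,
             conc_mg_ml = round(x$conc_mg_ml, 2),
             api_mg_per_tablet = round(x$api_mg_per_tablet, 2),
             content_ok = x$content_ok, verdict = x$verdict)
}

# verdict per the identity-then-content decision rule
decide_verdict <- function(rf_ok, content_ok, out_of_calibration = FALSE) {
  if (!rf_ok) return("identity_fail")
  if (out_of_calibration) return("out_of_calibration")
  if (!content_ok) return("substandard_content")
  "pass"
}

#' Analyze a plate image end to end
#'
#' Runs the pixel pipeline, groups spots into lanes, selects each lane's
#' principal spot, computes retention factors, checks the identity of each
#' lane against the standard's retention factor, converts the principal
#' spot AUC to concentration and per-tablet content through the calibration
#' model, and renders the pharmacopeial verdict.
#'
#' @param img a [plate_image].
#' @param model a [tlc_calibration] (fitted or read from file).
#' @param standard_rf reference retention factor of the drug standard.
#' @param qcfg a [quant_config].
#' @param pcfg a [pipeline_config].
#' @param sample_ids optional character vector naming the lanes
#'   (recycled/padded as `lane<k>`).
#' @param rf_tolerance_frac identity tolerance (default 0.10).
#' @param expected_lanes used for the default lane gap threshold.
#' @param gap_threshold explicit lane gap in pixels (overrides default).
#' @return List of class `plate_result`: `samples` (list of
#'   `sample_result`), `spots`, `lanes`, `threshold`.
#' @export
analyze_plate <- function(img, model, standard_rf,
                          qcfg = quant_config(), pcfg = pipeline_config(),
                          sample_ids = NULL, rf_tolerance_frac = 0.10,
                          expected_lanes = 6, gap_threshold = NULL) {
  pr <- run_pipeline(img, pcfg)
  if (length(pr$spots) == 0L) {
    res <- new_sample_result(
      sample_id = if (is.null(sample_ids)) "sample1" else sample_ids[1],
      verdict = "identity_fail")
    return(structure(list(samples = list(res), spots = list(),
                          lanes = NULL, threshold = pr$threshold),
                     class = "plate_result"))
  }
  lanes <- assign_lanes(pr$spots, gap_threshold = gap_threshold,
                        crop_width = ncol(pr$signal),
                        expected_lanes = expected_lanes)
  n_lanes <- length(lanes$lane_centers)
  ids <- if (is.null(sample_ids)) paste0("lane", seq_len(n_lanes))
         else c(sample_ids, paste0("lane", seq_len(n_lanes)))[seq_len(n_lanes)]
  samples <- vector("list", n_lanes)
  for (k in seq_len(n_lanes)) {
    lane_spots <- pr$spots[lanes$assignment == k]
    principal <- select_principal(lane_spots)
    rfres <- compute_rf(principal, pr$plate$origin_row, pr$plate$front_row)
    rf_ok <- rf_match(rfres$rf, standard_rf, rf_tolerance_frac)
    conc <- suppressWarnings(
      predict_conc(model, principal$auc,
                   extrapolation_policy = qcfg$extrapolation_policy))
    ooc <- is.na(conc)
    api <- if (ooc) NA_real_ else to_api_content(conc, qcfg)
    c_ok <- !ooc && content_verdict(api, qcfg)
    samples[[k]] <- new_sample_result(
      sample_id = ids[k], rf = rfres$rf, rf_ok = rf_ok, conc = conc,
      api = api, content_ok = c_ok,
      verdict = decide_verdict(rf_ok, c_ok, ooc),
      auc = principal$auc, lane = k)
  }
  structure(list(samples = samples, spots = pr$spots, lanes = lanes,
                 threshold = pr$threshold),
            class = "plate_result")
}

#' @export
print.plate_result <- function(x, ...) {
  cat(sprintf("<plate_result> %d spot(s), %d lane(s), threshold %.3f\n",
              length(x$spots),
              if (is.null(x$lanes)) 0L else length(x$lanes$lane_centers),
              x$threshold))
  for (s in x$samples) print(s)
  invisible(x)
}

#' @export
as.data.frame.plate_result <- function(x, ...) {
  do.call(rbind, lapply(x$samples, as.data.frame))
}

#' Analyze a single-sample plate
#'
#' Convenience wrapper around [analyze_plate()] for an image holding one
#' sample lane; returns that lane's `sample_result`.
#'
#' @inheritParams analyze_plate
#' @param sample_id identifier for the sample.
#' @return A `sample_result`.
#' @export
analyze_sample <- function(img, model, standard_rf, qcfg = quant_config(),
                           pcfg = pipeline_config(), sample_id = "sample1",
                           rf_tolerance_frac = 0.10) {
  res <- analyze_plate(img, model, standard_rf, qcfg, pcfg,
                       sample_ids = sample_id,
                       rf_tolerance_frac = rf_tolerance_frac,
                       expected_lanes = 1)
  if (length(res$samples) > 1L) {
    # multiple lanes detected on a single-sample plate: keep the strongest
    auc <- vapply(res$samples, function(s)
      ifelse(is.na(s$auc), -Inf, s$auc), numeric(1))
    res$samples[[which.max(auc)]]
  } else res$samples[[1]]
}
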