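#' Fit a linear TLC calibration model
#'
#' Ordinary least squares of spot AUC on analyte concentration,
#' `AUC = S * conc + b`. Beyond the slope `S`, intercept and R-squared, the
#' fit reports the residual standard deviation of the calibration
#' `sy = sqrt(SSE / (n - 2))` and the derived limits of detection and
#' quantification, `LoD = 3.3 * sy / S` and `LoQ = 10 * sy / S`. The linear
#' range is the span of the fitted concentrations.
#'
#' @param conc concentrations (mg/mL), at least 3 points, not all equal.
#' @param auc matching spot AUC values.
#' @return An object of class `tlc_calibration` with components `slope`,
#'   `intercept`, `r_squared`, `sy`, `n_points`, `linear_range`, `lod`,
#'   `loq` and the underlying `lm` fit.
#' @seealso [predict_conc()], [lod_loq()]
#' @examples
#' cal <- tlc_calibration(c(0.5, 1, 2, 3, 4),
#'                        10701 * c(0.5, 1, 2, 3, 4) + 7502)
#' coef(cal)
#' predict(cal, auc = 10701 * 2 + 7502)
#' @export
tlc_calibration <- function(conc, auc) {
  if (length(conc) != length(auc))
    tlc_abort("conc and auc lengths differ", "tlc_format_error")
  if (length(conc) < 3L)
    tlc_abort("calibration needs at least 3 points",
              "tlc_insufficient_data_error")
  if (length(unique(conc)) < 2L)
    tlc_abort("calibration concentrations are all equal",
              "tlc_singular_fit_error")
  fit <- lm(auc ~ conc)
  n <- length(conc)
  sse <- sum(residuals(fit)^2)
  sst <- sum((auc - mean(auc))^2)
  obj <- structure(list(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r_squared = if (sst > 0) 1 - sse / sst else 1,
    sy = sqrt(sse / (n - 2)),
    n_points = n,
    linear_range = range(conc),
    fit = fit), class = "tlc_calibration")
  ll <- lod_loq(obj)
  obj$lod <- ll[["lod"]]; obj$loq <- ll[["loq"]]
  obj
}

#' Limits of detection and quantification of a calibration
#'
#' `LoD = 3.3 * sy / S`, `LoQ = 10 * sy / S`, where `sy` is the residual
#' standard deviation of the calibration curve and `S` its slope; their
#' ratio is 10/3.3 by construction.
#'
#' @param model a [tlc_calibration] (or list with `slope` and `sy`).
#' @return Named numeric vector `c(lod, loq)` in mg/mL.
#' @export
lod_loq <- function(model) {
  if (is.null(model$slope) || !is.finite(model$slope) || model$slope <= 0)
    tlc_abort("calibration slope must be positive for LoD/LoQ",
              "tlc_invalid_model_error")
  c(lod = 3.3 * model$sy / model$slope,
    loq = 10 * model$sy / model$slope)
}

#' @export
print.tlc_calibration <- function(x, digits = 4, ...) {
  cat("TLC calibration (AUC = S * conc + b)\n")
  cat(sprintf("  slope S    : %s AUC/(mg/mL)\n", format(x$slope, digits = digits)))
  cat(sprintf("  intercept  : %s AUC\n", format(x$intercept, digits = digits)))
  cat(sprintf("  R-squared  : %s   sy: %s   n: %d\n",
              format(x$r_squared, digits = digits),
              format(x$sy, digits = digits), x$n_points))
  cat(sprintf("  linear range: %g-%g mg/mL   LoD: %s   LoQ: %s mg/mL\n",
              x$linear_range[1], x$linear_range[2],
              format(x$lod, digits = digits), format(x$loq, digits = digits)))
  invisible(x)
}

#' @export
summary.tlc_calibration <- function(object, ...) {
  print(object)
  cat("\nUnderlying least-squares fit:\n")
  print(summary(object$fit))
  invisible(object)
}

#' @export
coef.tlc_calibration <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
residuals.tlc_calibration <- function(object, ...) residuals(object$fit)

#' Inverse prediction from a calibration model
#'
#' @param object a [tlc_calibration].
#' @param auc spot AUC values to convert to concentration.
#' @param ... passed to [predict_conc()].
#' @return Concentrations in mg/mL.
#' @export
predict.tlc_calibration <- function(object, auc, ...) {
  predict_conc(object, auc, ...)
}

#' @export
plot.tlc_calibration <- function(x, ...) {
  d <- x$fit$model
  plot(d$conc, d$auc, xlab = "concentration (mg/mL)", ylab = "spot AUC",
       main = "TLC calibration", ...)
  abline(x$intercept, x$slope, col = "steelblue")
  invisible(x)
}

#' Predict concentration from spot AUC (inverse calibration)
#'
#' `conc = (auc - intercept) / slope`. Predictions below zero are clamped
#' to 0 with a warning; predictions outside the calibrated linear range
#' trigger the extrapolation policy: `"warn"` keeps the value, `"reject"`
#' returns `NA` (flagged upstream as out-of-calibration).
#'
#' @param model a [tlc_calibration].
#' @param auc numeric AUC values.
#' @param extrapolation_policy `"warn"` (default) or `"reject"`.
#' @return Concentrations in mg/mL (NA where rejected).
#' @export
predict_conc <- function(model, auc,
                         extrapolation_policy = c("warn", "reject")) {
  extrapolation_policy <- match.arg(extrapolation_policy)
  if (is.null(model$slope) || !is.finite(model$slope) || model$slope <= 0)
    tlc_abort("invalid calibration model", "tlc_invalid_model_error")
  x <- (auc - model$intercept) / model$slope
  out_of_range <- !is.null(model$linear_range) &
    (x < model$linear_range[1] | x > model$linear_range[2])
  if (any(out_of_range)) {
    if (extrapolation_policy == "reject") {
      x[out_of_range] <- NA_real_
    } else {
      tlc_warn(sprintf("%d prediction(s) outside the calibrated range %g-%g mg/mL",
                       sum(out_of_range), model$linear_range[1],
                       model$linear_range[2]),
               "tlc_extrapolation_warning")
    }
  }
  neg <- !is.na(x) & x < 0
  if (any(neg)) {
    tlc_warn("negative predicted concentration clamped to 0",
             "tlc_extrapolation_warning")
    x[neg] <- 0
  }
  x
}

#' Fit a calibration from a multi-lane plate image
#'
#' Runs the pixel pipeline on a plate carrying one lane per concentration
#' level (lanes ordered left to right by increasing or given level order),
#' takes each lane's principal-spot AUC and fits [tlc_calibration()].
#' Because a calibration ladder spans a wide dynamic range, the
#' `"background"` threshold method is the default here.
#'
#' @param img a [plate_image].
#' @param levels concentrations (mg/mL) of the lanes, left to right.
#' @param pcfg a [pipeline_config].
#' @return A list: `model` (the [tlc_calibration]), `auc` (per-lane
#'   detected AUC), `levels`.
#' @export
calibrate_image <- function(img, levels,
                            pcfg = pipeline_config(
                              threshold_method = "background")) {
  if (length(levels) < 3L)
    tlc_abort("calibration needs at least 3 levels",
              "tlc_insufficient_data_error")
  pr <- run_pipeline(img, pcfg)
  if (length(pr$spots) == 0L)
    tlc_abort("no spots detected on the calibration plate",
              "tlc_insufficient_data_error")
  lanes <- assign_lanes(pr$spots, crop_width = ncol(pr$signal),
                        expected_lanes = length(levels))
  if (length(lanes$lane_centers) != length(levels))
    tlc_abort(sprintf("detected %d lanes for %d levels",
                      length(lanes$lane_centers), length(levels)),
              "tlc_insufficient_data_error")
  auc <- vapply(seq_along(levels), function(k)
    select_principal(pr$spots[lanes$assignment == k])$auc, numeric(1))
  list(model = tlc_calibration(levels, auc), auc = auc, levels = levels)
}

#' Read/write calibration tables and model files
#'
#' Calibration tables are CSV with columns `conc_mg_ml`, `auc`; fitted
#' models round-trip through a YAML file holding slope, intercept, sy,
#' r_squared, n_points and linear range.
#'
#' @param path file path.
#' @return `read_calibration_table`: a data frame; `read_calibration_model`:
#'   a [tlc_calibration]-like model usable by [predict_conc()].
#' @name calibration-io
NULL

#' @rdname calibration-io
#' @export
read_calibration_table <- function(path) {
  if (!file.exists(path))
    tlc_abort(sprintf("calibration table not found: %s", path),
              "tlc_config_error")
  d <- read.csv(path)
  if (!all(c("conc_mg_ml", "auc") %in% names(d)))
    tlc_abort("calibration CSV needs columns conc_mg_ml, auc",
              "tlc_format_error")
  d
}

#' @rdname calibration-io
#' @param table data frame with `conc_mg_ml` and `auc`.
#' @export
write_calibration_table <- function(table, path) {
  write.csv(table[, c("conc_mg_ml", "auc")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname calibration-io
#' @param model a [tlc_calibration].
#' @export
write_calibration_model <- function(model, path) {
  yaml::write_yaml(list(
    slope = model$slope, intercept = model$intercept, sy = model$sy,
    r_squared = model$r_squared, n_points = model$n_points,
    linear_range = as.numeric(model$linear_range),
    lod = model$lod, loq = model$loq), path)
  invisible(path)
}

#' @rdname calibration-io
#' @export
read_calibration_model <- function(path) {
  if (!file.exists(path))
    tlc_abort(sprintf("model file not found: %s", path), "tlc_config_error")
  m <- yaml::read_yaml(path)
  if (is.null(m$slope) || is.null(m$intercept))
    tlc_abort("model file lacks slope/intercept", "tlc_format_error")
  m$linear_range <- as.numeric(unlist(m$linear_range))
  class(m) <- "tlc_calibration"
  m
}
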