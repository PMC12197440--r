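#' Coefficient of variation (percent)
#'
#' `CV = 100 * sd / mean`. Either raw values (sample standard deviation,
#' n - 1 denominator) or a precomputed mean/sd pair can be supplied.
#'
#' @param values numeric vector (n >= 2), or `NULL` when `mean`/`sd` given.
#' @param mean,sd precomputed summary statistics.
#' @return CV in percent.
#' @export
cv <- function(values = NULL, mean = NULL, sd = NULL) {
  if (!is.null(values)) {
    if (length(values) < 2L)
      tlc_abort("cv from raw values needs n >= 2",
                "tlc_insufficient_data_error")
    mean <- base::mean(values)
    sd <- stats::sd(values)
  } else if (is.null(mean) || is.null(sd)) {
    tlc_abort("supply either values or both mean and sd",
              "tlc_config_error")
  }
  if (mean == 0)
    tlc_abort("CV undefined for zero mean", "tlc_undefined_cv_error")
  100 * sd / mean
}

#' Spike-recovery summary
#'
#' Per-replicate percent recovery `100 * measured / spiked`, summarized as
#' mean and sample standard deviation.
#'
#' @param measured measured concentrations (mg/mL), one per replicate.
#' @param spiked spiked (true) concentration, > 0.
#' @return A list of class `recovery_record`: `spiked`, `measured`,
#'   `recovery_percent` (per replicate), `mean`, `sd`.
#' @export
recovery <- function(measured, spiked) {
  if (spiked <= 0)
    tlc_abort("spiked concentration must be positive", "tlc_config_error")
  rec <- 100 * measured / spiked
  structure(list(spiked = spiked, measured = measured,
                 recovery_percent = rec, mean = mean(rec),
                 sd = if (length(rec) > 1L) stats::sd(rec) else NA_real_),
            class = "recovery_record")
}

#' @export
print.recovery_record <- function(x, ...) {
  cat(sprintf("recovery at %g mg/mL: %.2f%% +/- %s (n = %d)\n",
              x$spiked, x$mean,
              ifelse(is.na(x$sd), "-", sprintf("%.2f%%", x$sd)),
              length(x$recovery_percent)))
  invisible(x)
}

#' One-way ANOVA agreement between two methods
#'
#' Fixed-effects one-way analysis of variance across the two groups
#' (equivalent to a pooled two-sample t-test); used to ask whether two
#' measurement methods give systematically different results. When both
#' groups are constant with equal means the F statistic is defined as 0.
#'
#' @param group_a,group_b numeric vectors, each n >= 2.
#' @return Named vector `c(F, p)`.
#' @export
method_agreement <- function(group_a, group_b) {
  if (length(group_a) < 2L || length(group_b) < 2L)
    tlc_abort("method_agreement needs n >= 2 per group",
              "tlc_insufficient_data_error")
  y <- c(group_a, group_b)
  g <- factor(rep(c("a", "b"), c(length(group_a), length(group_b))))
  within_ss <- sum((group_a - mean(group_a))^2) +
    sum((group_b - mean(group_b))^2)
  if (within_ss == 0) {
    if (mean(group_a) == mean(group_b)) return(c(F = 0, p = 1))
    return(c(F = Inf, p = 0))
  }
  tab <- anova(aov(y ~ g))
  c(F = tab[["F value"]][1], p = tab[["Pr(>F)"]][1])
}
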