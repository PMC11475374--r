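# Bland-Altman agreement between calibrated DWI and EM axonal volume
# fractions: per-point differences delta = fA(DWI) - fA(EM) against means
# m = (fA(DWI) + fA(EM))/2; bias = <delta>; error = 1.96 * population SD of
# delta; relative versions divide by the EM dynamic range
# max(fA_EM) - min(fA_EM) and are reported in percent.

#' Bland-Altman agreement analysis
#'
#' @param fA_DWI_cal calibrated DWI axonal volume fractions.
#' @param fA_EM EM reference of equal length (n >= 2).
#' @param population use population (divide-by-n) moments for the SD in the
#'   error, matching the plain-average definition (default `TRUE`); set
#'   `FALSE` for the sample SD.
#' @return list of class `accuracy_report`: `per_point` (data frame with
#'   `delta`, `m`), `bias`, `error`, and `NA` placeholders for the relative
#'   fields until [relative_metrics()] fills them.
#' @export
#' @examples
#' bland_altman(c(0.4, 0.6), c(0.5, 0.5))
bland_altman <- function(fA_DWI_cal, fA_EM, population = TRUE) {
  if (length(fA_DWI_cal) != length(fA_EM)) {
    stop("length mismatch", call. = FALSE)
  }
  n <- length(fA_EM)
  if (n < 2L) stop("Bland-Altman needs at least 2 points", call. = FALSE)
  delta <- fA_DWI_cal - fA_EM
  m <- (fA_DWI_cal + fA_EM) / 2
  bias <- mean(delta)
  sd_pop <- sqrt(max(mean(delta^2) - mean(delta)^2, 0))
  sdv <- if (population) sd_pop else stats::sd(delta)
  structure(list(per_point = data.frame(delta = delta, m = m),
                 bias = bias, error = 1.96 * sdv,
                 rel_bias = NA_real_, rel_error = NA_real_,
                 em_range = NA_real_, population = population),
            class = "accuracy_report")
}

#' Dynamic-range-relative bias and error
#'
#' Divides bias and error by the EM dynamic range
#' `max(fA_EM) - min(fA_EM)` and expresses them in percent.
#'
#' @param report an `accuracy_report` from [bland_altman()].
#' @param fA_EM the EM reference vector defining the dynamic range (all
#'   observations entering the comparison).
#' @return the report with `rel_bias`, `rel_error` (in %) and `em_range`
#'   filled in.
#' @export
relative_metrics <- function(report, fA_EM) {
  stopifnot(inherits(report, "accuracy_report"))
  rng <- max(fA_EM) - min(fA_EM)
  if (rng <= 0) {
    stop("EM dynamic range is zero; relative metrics undefined", call. = FALSE)
  }
  report$em_range <- rng
  report$rel_bias <- 100 * report$bias / rng
  report$rel_error <- 100 * report$error / rng
  report
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("bias %.2f (%s%%)  error %.2f (%s%%)  [EM range %.3f, n = %d]\n",
              x$bias,
              if (is.na(x$rel_bias)) "?" else sprintf("%.0f", x$rel_bias),
              x$error,
              if (is.na(x$rel_error)) "?" else sprintf("%.0f", x$rel_error),
              x$em_range, nrow(x$per_point)))
  invisible(x)
}

#' Accuracy table across models and calibration variants
#'
#' For each DWI model, reports bias (relative bias, %) and error (relative
#' error, %) of the baseline, the best data-driven combination, and (when
#' supplied) the hybrid fit — one row per (model, variant), rendered like
#' "-0.17 (-39)".
#'
#' @param cohort an `axon_cohort` with groups assigned.
#' @param calibrations named list (per model) of lists of
#'   `calibration_result` variants; names inside each list label the variant
#'   (e.g. `baseline`, `best`, `hybrid`).
#' @return data frame with numeric columns `bias`, `rel_bias`, `error`,
#'   `rel_error` and rendered columns `bias_rendered`, `error_rendered`.
#' @export
accuracy_table <- function(cohort, calibrations) {
  rows <- list()
  for (model in names(calibrations)) {
    for (variant in names(calibrations[[model]])) {
      res <- calibrations[[model]][[variant]]
      U <- ifelse(cohort$group == 1L, res$U1, res$U2)
      cal <- apply_calibration(cohort[[paste0("fAW_", model)]],
                               cohort$fM_EM, s = res$s, U = U)
      rep <- relative_metrics(bland_altman(cal, cohort$fA_EM), cohort$fA_EM)
      rows[[length(rows) + 1L]] <- data.frame(
        model = model, variant = variant, combo = res$combo$name,
        bias = rep$bias, rel_bias = rep$rel_bias,
        error = rep$error, rel_error = rep$rel_error,
        bias_rendered = sprintf("%.2f (%.0f)", rep$bias, rep$rel_bias),
        error_rendered = sprintf("%.2f (%.0f)", rep$error, rep$rel_error),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Scatter and Bland-Altman panels for a calibrated model
#'
#' Optional ggplot2 figure: EM-vs-DWI scatter with the unity line, and the
#' Bland-Altman panel with bias and bias +/- error band.
#'
#' @param cohort an `axon_cohort` with groups assigned.
#' @param model DWI-model name.
#' @param result a `calibration_result` for that model.
#' @return a patchable list of two ggplot objects (requires ggplot2).
#' @export
plot_agreement <- function(cohort, model, result) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_agreement requires the ggplot2 package", call. = FALSE)
  }
  U <- ifelse(cohort$group == 1L, result$U1, result$U2)
  cal <- apply_calibration(cohort[[paste0("fAW_", model)]], cohort$fM_EM,
                           s = result$s, U = U)
  rep <- relative_metrics(bland_altman(cal, cohort$fA_EM), cohort$fA_EM)
  df <- data.frame(fA_EM = cohort$fA_EM, fA_DWI = cal,
                   group = factor(cohort$group),
                   delta = rep$per_point$delta, m = rep$per_point$m)
  p1 <- ggplot2::ggplot(df, ggplot2::aes(x = fA_EM, y = fA_DWI,
                                         colour = group)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_point() +
    ggplot2::labs(title = paste0(model, " ", result$combo$name),
                  x = "fA (EM)", y = "fA (DWI), calibrated")
  p2 <- ggplot2::ggplot(df, ggplot2::aes(x = m, y = delta, colour = group)) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                      ymin = rep$bias - rep$error, ymax = rep$bias + rep$error,
                      alpha = 0.15) +
    ggplot2::geom_hline(yintercept = rep$bias, linetype = 2) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "mean of DWI and EM", y = "difference DWI - EM")
  list(scatter = p1, bland_altman = p2)
}
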