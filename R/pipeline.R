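# End-to-end orchestration of the three analysis stages:
# (1) group selection from the EM metric, (2) calibration-combination
# fitting and BIC ranking (plus hybrid fits with a fixed predicted
# scaling), (3) Bland-Altman accuracy relative to the EM dynamic range.

result_record <- function(res, loo_sd = NULL) {
  if (inherits(res, "calibration_error")) {
    return(list(combo = res$combo$name, error = res$error))
  }
  list(combo = res$combo$name, free_params = res$combo$free,
       estimates = list(U1 = res$U1, U2 = res$U2, s = res$s),
       fixed_s = res$combo$fixed_s,
       RSS = res$RSS, k = res$k, n = res$n,
       BIC = res$BIC, delta_BIC = res$delta_BIC %||% NA_real_,
       converged = res$converged, n_starts = res$n_starts,
       perfect_fit = isTRUE(res$perfect_fit),
       loo_sd = loo_sd)
}

#' Run the full calibration pipeline
#'
#' Group selection, all-combination calibration with BIC ranking,
#' leave-one-out stability of the best combination, optional hybrid
#' calibration with a fixed (predicted) scaling, and the accuracy table.
#'
#' @param input an `axon_cohort`, a CSV path, or a [synthetic_config()]
#'   (which is generated with its own seed).
#' @param models DWI-model names to analyse (default: all in the cohort).
#' @param combos combination list including the baseline
#'   (default [all_combos()]).
#' @param alpha significance level for genotype pooling.
#' @param override optional genotype -> group mapping when pooling is
#'   ambiguous.
#' @param fixed_s scaling for the hybrid stage: a number, or a list
#'   `list(sf =, t2 =, TE =)` evaluated via [predicted_scaling()]; `NULL`
#'   skips the hybrid stage.
#' @param hybrid_free offsets fitted in the hybrid stage (default `"U2"`).
#' @param constraint_form passed to [fit_combo()].
#' @param loo run the leave-one-out analysis on each best combination.
#' @return list of class `run_report`: `groups`, `anova`, per-model
#'   `calibration` rankings, `accuracy` table, `config` echo, `version`.
#' @export
run_pipeline <- function(input, models = NULL, combos = all_combos(),
                         alpha = 0.05, override = NULL, fixed_s = NULL,
                         hybrid_free = "U2",
                         constraint_form = "elementwise", loo = TRUE) {
  cohort <- if (inherits(input, "axon_cohort")) {
    input
  } else if (inherits(input, "synthetic_config")) {
    generate_cohort(input)
  } else if (is.character(input)) {
    read_cohort(input)
  } else {
    stop("input must be a cohort, a CSV path, or a synthetic_config",
         call. = FALSE)
  }
  if (!"group" %in% names(cohort)) {
    cohort <- assign_groups(cohort, alpha = alpha, override = override)
  }
  if (is.null(models)) models <- dwi_models(cohort)

  s_hybrid <- if (is.null(fixed_s)) NULL else resolve_s_true(fixed_s)

  per_model <- list()
  calibrations <- list()
  any_flagged <- FALSE
  for (model in models) {
    ranked <- select_best(cohort, model, combos,
                          constraint_form = constraint_form)
    ranked_ok <- Filter(function(r) !inherits(r, "calibration_error"), ranked)
    best <- ranked_ok[[1]]
    if (best$combo$name == "{}" && length(ranked_ok) > 1) {
      # the accuracy table still reports a distinct best data-driven row
      best_nonbase <- ranked_ok[[2]]
    } else {
      best_nonbase <- best
    }
    loo_sd <- NULL
    if (loo && length(best_nonbase$combo$free) > 0) {
      loo_res <- leave_one_out(cohort, model, best_nonbase$combo,
                               constraint_form = constraint_form)
      loo_sd <- as.list(loo_res$sd)
    }
    variants <- list(baseline = ranked_ok[[which(vapply(ranked_ok, function(r)
      r$combo$name, "") == "{}")]])
    if (best_nonbase$combo$name != "{}") variants$best <- best_nonbase
    hybrid <- NULL
    if (!is.null(s_hybrid)) {
      hybrid <- tryCatch(
        hybrid_fit(cohort, model, free = hybrid_free, fixed_s = s_hybrid,
                   constraint_form = constraint_form),
        error = function(e) NULL)
      if (!is.null(hybrid)) {
        hybrid$delta_BIC <- delta_bic(hybrid, variants$baseline)
        variants$hybrid <- hybrid
      }
    }
    any_flagged <- any_flagged ||
      any(!vapply(ranked_ok, `[[`, TRUE, "converged"))
    per_model[[model]] <- list(
      ranking = lapply(ranked, result_record),
      best_combo = best$combo$name,
      loo_sd = loo_sd,
      hybrid = if (!is.null(hybrid)) result_record(hybrid))
    calibrations[[model]] <- variants
  }

  ga <- attr(cohort, "group_assignment")
  structure(list(
    groups = list(mapping = if (!is.null(ga)) as.list(ga$mapping),
                  sizes = as.list(group_sizes(cohort)),
                  alpha = alpha),
    anova = attr(cohort, "anova"),
    calibration = per_model,
    accuracy = accuracy_table(cohort, calibrations),
    fixed_s = s_hybrid,
    config = provenance(cohort),
    n_observations = nrow(cohort),
    flagged_nonconvergence = any_flagged,
    version = as.character(utils::packageVersion("axocal"))),
    class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("axocal run report\n")
  cat(sprintf("  observations: %d (N1 = %d, N2 = %d)\n", x$n_observations,
              x$groups$sizes$N1, x$groups$sizes$N2))
  for (m in names(x$calibration)) {
    cat(sprintf("  %s: best combo %s\n", m, x$calibration[[m]]$best_combo))
  }
  cat("accuracy:\n")
  print(x$accuracy[, c("model", "variant", "combo",
                       "bias_rendered", "error_rendered")])
  invisible(x)
}

#' Write a run report to JSON (and the accuracy table to CSV)
#'
#' @param report a `run_report`.
#' @param path output JSON path; the accuracy table goes to
#'   `<path without .json>_accuracy.csv`.
#' @return `path`, invisibly.
#' @export
write_run_report <- function(report, path) {
  stopifnot(inherits(report, "run_report"))
  out <- unclass(report)
  out$accuracy <- report$accuracy[, c("model", "variant", "combo", "bias",
                                      "rel_bias", "error", "rel_error")]
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", force = TRUE)
  csv <- sub("\\.json$", "", path)
  utils::write.csv(report$accuracy, paste0(csv, "_accuracy.csv"),
                   row.names = FALSE)
  invisible(path)
}
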