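# Seeded synthetic cohort generator.
#
# Emulates the study design the calibration assumes: 15 mice (6 Controls,
# 3 Pten, 3 Rictor, 3 Tsc2) x 4 ROIs, a group-specific unmyelinated-axon
# fraction (the latent counterpart of the offset U), a global T2-driven
# scaling on the observed axonal water fraction (the latent counterpart of
# s), voxel-level Gaussian noise with outlier/NaN injection exercising the
# validity filter, and Gaussian EM measurement noise. The forward model
# composes the volume-fraction algebra with the inverse of the scaling:
#   fAW_observed = fAW_true / s_true + noise,
# so that calibrating with s = s_true and U = fA_U recovers fA_M exactly in
# the noiseless regime.

#' Synthetic cohort configuration
#'
#' Defaults describe the "paper-like" regime: equal myelinated-axon means
#' (0.35) for Control/Pten/Rictor and a severely reduced mean (0.10) for
#' Tsc2; an unmyelinated fraction visible to DWI of 0 in group 1 and 0.20
#' in group 2; a global scaling `s_true = 0.75`; 6-12 voxels per ROI with
#' SD-0.03 voxel noise and small outlier/NaN rates; SD-0.02 EM noise.
#'
#' @param mice_per_genotype named integer vector of mice per genotype.
#' @param rois ROI names (4 by default).
#' @param fA_M_mean,fM_mean named per-genotype means of the myelinated-axon
#'   and myelin volume fractions.
#' @param roi_sd_fA_M,roi_sd_fM between-ROI (and between-mouse) SD of the
#'   latent fractions.
#' @param fA_U_mode `"constant-per-group"` (use `fA_U_group`) or
#'   `"derived-from-total"` (`fA_U = max(fA_total - fA_M, 0)`).
#' @param fA_U_group unmyelinated fraction per group `c(g1, g2)`.
#' @param fA_total total axonal volume fraction for the derived mode.
#' @param dwi_sees_unmyelinated weight in \[0,1\] of the unmyelinated
#'   fraction inside the DWI-visible axonal volume (1 = impermeable sticks).
#' @param s_true global scaling applied in inverse to the observed fAW;
#'   alternatively a list `list(sf =, t2 =, TE =)` routed through
#'   [predicted_scaling()].
#' @param models named list of per-DWI-model channels, each a list with
#'   optional `s_true` and `extra_noise_sd`; default a single `"WMTI"`
#'   channel inheriting the global `s_true`.
#' @param voxel_count_range integer pair, voxels per ROI (default 6-12).
#' @param voxel_noise_sd Gaussian SD of voxelwise fAW noise.
#' @param outlier_rates named rates `c(neg =, gt1 =, nan =)` of injected
#'   invalid voxels.
#' @param em_noise_sd Gaussian SD of the EM observations.
#' @param min_valid ROI flagging threshold passed to [roi_mean()].
#' @param seed default RNG seed used by [generate_cohort()].
#' @param preset free-text label stored in the provenance.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(
    mice_per_genotype = c(Control = 6L, Pten = 3L, Rictor = 3L, Tsc2 = 3L),
    rois = ROIS,
    fA_M_mean = c(Control = 0.35, Pten = 0.35, Rictor = 0.35, Tsc2 = 0.10),
    fM_mean = c(Control = 0.30, Pten = 0.37, Rictor = 0.24, Tsc2 = 0.10),
    roi_sd_fA_M = 0.03,
    roi_sd_fM = 0.03,
    fA_U_mode = c("constant-per-group", "derived-from-total"),
    fA_U_group = c(0, 0.20),
    fA_total = 0.5,
    dwi_sees_unmyelinated = 1,
    s_true = 0.75,
    models = list(WMTI = list()),
    voxel_count_range = c(6L, 12L),
    voxel_noise_sd = 0.03,
    outlier_rates = c(neg = 0.02, gt1 = 0.02, nan = 0.01),
    em_noise_sd = 0.02,
    min_valid = 3L,
    seed = 1L,
    preset = "paper-like") {
  fA_U_mode <- match.arg(fA_U_mode)
  stopifnot(all(names(mice_per_genotype) %in% GENOTYPES),
            length(voxel_count_range) == 2L,
            voxel_count_range[1] >= 1L,
            all(outlier_rates >= 0), sum(outlier_rates) < 1,
            dwi_sees_unmyelinated >= 0, dwi_sees_unmyelinated <= 1)
  structure(list(
    mice_per_genotype = mice_per_genotype, rois = rois,
    fA_M_mean = fA_M_mean, fM_mean = fM_mean,
    roi_sd_fA_M = roi_sd_fA_M, roi_sd_fM = roi_sd_fM,
    fA_U_mode = fA_U_mode, fA_U_group = fA_U_group, fA_total = fA_total,
    dwi_sees_unmyelinated = dwi_sees_unmyelinated,
    s_true = s_true, models = models,
    voxel_count_range = as.integer(voxel_count_range),
    voxel_noise_sd = voxel_noise_sd, outlier_rates = outlier_rates,
    em_noise_sd = em_noise_sd, min_valid = min_valid,
    seed = seed, preset = preset), class = "synthetic_config")
}

#' The paper-like preset
#'
#' The default [synthetic_config()]: two statistically distinct groups in
#' the EM metric, a group-2 offset of 0.20, a global scaling of 0.75, and
#' moderate voxel/EM noise. Under it, genotype pooling yields the 48/12
#' two-group split and `{U2,s}` is the expected best combination.
#'
#' @return a `synthetic_config`.
#' @export
paper_like_preset <- function() synthetic_config()

#' The zero-effect preset
#'
#' No offset (`fA_U = 0` in both groups) and no scaling (`s_true = 1`):
#' the regime in which the uncalibrated baseline should win model selection.
#'
#' @return a `synthetic_config`.
#' @export
zero_effect_preset <- function() {
  synthetic_config(fA_U_group = c(0, 0), s_true = 1, preset = "zero-effect")
}

#' Noiseless variant of a configuration
#'
#' Zero noise SDs and outlier rates, unmyelinated fraction constant within
#' each group: the identifiable regime in which `{U2,s}` fitting recovers
#' the generator parameters exactly.
#'
#' @param config a `synthetic_config`.
#' @return the modified `synthetic_config`.
#' @export
noiseless_variant <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  config$voxel_noise_sd <- 0
  config$em_noise_sd <- 0
  config$outlier_rates <- c(neg = 0, gt1 = 0, nan = 0)
  config$fA_U_mode <- "constant-per-group"
  config$preset <- paste0(config$preset, "-noiseless")
  config
}

resolve_s_true <- function(s_true) {
  if (is.numeric(s_true)) return(s_true)
  if (is.list(s_true)) {
    return(predicted_scaling(s_true$sf, s_true$t2, s_true$TE))
  }
  stop("s_true must be numeric or a list(sf, t2, TE)", call. = FALSE)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

GROUP_OF_GENOTYPE <- c(Control = 1L, Pten = 1L, Rictor = 1L, Tsc2 = 2L)

#' Generate a synthetic cohort
#'
#' Draws latent tissue fractions per mouse x ROI, simulates voxelwise
#' observed axonal water fractions (`fAW_true / s_true` + noise, with
#' injected invalid voxels), applies [filter_voxels()] and [roi_mean()],
#' and adds Gaussian noise to the EM observations. Fully determined by
#' `(config, seed)`.
#'
#' @param config a [synthetic_config()].
#' @param seed RNG seed (default `config$seed`).
#' @return an `axon_cohort` with attributes `truth` (data frame of every
#'   latent value per observation, plus per-ROI voxel rejection counts) and
#'   the usual provenance.
#' @export
generate_cohort <- function(config = synthetic_config(), seed = config$seed) {
  stopifnot(inherits(config, "synthetic_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  s_global <- resolve_s_true(config$s_true)
  model_names <- names(config$models)
  if (is.null(model_names) || any(!nzchar(model_names))) {
    stop("config$models must be a named list", call. = FALSE)
  }

  rows <- list()
  truth <- list()
  for (gt in names(config$mice_per_genotype)) {
    grp <- GROUP_OF_GENOTYPE[[gt]]
    for (i in seq_len(config$mice_per_genotype[[gt]])) {
      mouse <- sprintf("%s_%d", gt, i)
      for (roi in config$rois) {
        fA_M <- clamp01(stats::rnorm(1, config$fA_M_mean[[gt]], config$roi_sd_fA_M))
        fM <- clamp01(stats::rnorm(1, config$fM_mean[[gt]], config$roi_sd_fM))
        fA_U <- switch(config$fA_U_mode,
          "constant-per-group" = config$fA_U_group[[grp]],
          "derived-from-total" = max(config$fA_total - fA_M, 0))
        fE <- 1 - fA_M - fA_U - fM
        if (fE <= 0) {
          stop(sprintf(
            "config implies non-positive extracellular fraction (%.3f) for genotype %s",
            fE, gt), call. = FALSE)
        }
        tf <- tissue_fractions(fA_M, fA_U, fM, fE)
        w <- config$dwi_sees_unmyelinated
        fAW_true <- (fA_M + w * fA_U) / (fA_M + fA_U + fE)

        faw_obs <- numeric(length(model_names))
        names(faw_obs) <- model_names
        rej <- c(neg = 0L, gt1 = 0L, nan = 0L)
        n_valid <- integer(0)
        for (mn in model_names) {
          mcfg <- config$models[[mn]]
          s_m <- if (!is.null(mcfg$s_true)) resolve_s_true(mcfg$s_true) else s_global
          extra <- mcfg$extra_noise_sd %||% 0
          nvox <- sample(seq(config$voxel_count_range[1],
                             config$voxel_count_range[2]), 1L)
          vox <- fAW_true / s_m +
            stats::rnorm(nvox, 0, sqrt(config$voxel_noise_sd^2 + extra^2))
          u <- stats::runif(nvox)
          r <- config$outlier_rates
          vox[u < r[["neg"]]] <- -stats::runif(sum(u < r[["neg"]]), 0.01, 0.2)
          sel <- u >= r[["neg"]] & u < r[["neg"]] + r[["gt1"]]
          vox[sel] <- 1 + stats::runif(sum(sel), 0.01, 0.2)
          sel <- u >= r[["neg"]] + r[["gt1"]] &
            u < r[["neg"]] + r[["gt1"]] + r[["nan"]]
          vox[sel] <- NaN
          flt <- filter_voxels(vox)
          rej <- rej + flt$rejected
          if (length(flt$values) == 0L) {
            # degenerate draw: fall back to the noiseless voxel value
            flt$values <- fAW_true / s_m
          }
          rm <- suppressWarnings(roi_mean(flt$values, config$min_valid))
          faw_obs[mn] <- clamp01(as.numeric(rm))
          n_valid <- c(n_valid, attr(rm, "n_valid"))
        }

        fA_EM <- clamp01(fA_M + stats::rnorm(1, 0, config$em_noise_sd))
        fM_EM <- clamp01(fM + stats::rnorm(1, 0, config$em_noise_sd))
        if (fA_EM + fM_EM > 1) {
          sc <- 1 / (fA_EM + fM_EM)
          fA_EM <- fA_EM * sc
          fM_EM <- fM_EM * sc
        }

        row <- data.frame(mouse_id = mouse, genotype = gt, roi = roi,
                          fA_EM = fA_EM, fM_EM = fM_EM,
                          stringsAsFactors = FALSE)
        for (mn in model_names) row[[paste0("fAW_", mn)]] <- faw_obs[[mn]]
        rows[[length(rows) + 1L]] <- row
        truth[[length(truth) + 1L]] <- data.frame(
          mouse_id = mouse, genotype = gt, roi = roi, group = grp,
          fA_M = fA_M, fA_U = fA_U, fM = fM, fE = fE,
          fAW_true = fAW_true, s_true = s_global,
          rejected_neg = rej[["neg"]], rejected_gt1 = rej[["gt1"]],
          rejected_nan = rej[["nan"]], n_valid_min = min(n_valid),
          stringsAsFactors = FALSE)
      }
    }
  }
  df <- do.call(rbind, rows)
  cohort <- as_cohort(df, provenance = list(
    generator = "axocal::generate_cohort", preset = config$preset,
    seed = seed, s_true = s_global))
  attr(cohort, "truth") <- do.call(rbind, truth)
  attr(cohort, "config") <- config
  cohort
}

#' Ground-truth sidecar of a synthetic cohort
#' @param cohort a cohort from [generate_cohort()].
#' @return data frame of latent values, one row per observation.
#' @export
cohort_truth <- function(cohort) attr(cohort, "truth")
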