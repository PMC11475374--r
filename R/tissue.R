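# Three-compartment white-matter tissue model:
#   fA + fM + fE = 1, with fA = fA_M (myelinated) + fA_U (unmyelinated).
# DWI is blind to myelin water, so DWI models estimate the axonal water
# fraction fAW = fA / (fA + fE); EM measures fA_M and fM directly.

#' Tissue volume fractions
#'
#' @param fA_M myelinated-axon volume fraction.
#' @param fA_U unmyelinated-axon volume fraction.
#' @param fM myelin volume fraction.
#' @param fE extracellular volume fraction; default closes the sum to 1.
#' @return list of class `tissue_fractions`.
#' @export
#' @examples
#' tissue_fractions(fA_M = 0.35, fA_U = 0, fM = 0.30)
tissue_fractions <- function(fA_M, fA_U, fM, fE = 1 - fA_M - fA_U - fM) {
  t <- list(fA_M = fA_M, fA_U = fA_U, fM = fM, fE = fE)
  vals <- unlist(t)
  if (any(!is.finite(vals)) || any(vals < -1e-12) || any(vals > 1 + 1e-12)) {
    stop("tissue fractions must lie in [0,1]; got ",
         paste(sprintf("%s=%g", names(t), vals), collapse = ", "), call. = FALSE)
  }
  if (abs(sum(vals) - 1) > 1e-12) {
    stop(sprintf("tissue fractions must sum to 1 (got %.15g)", sum(vals)),
         call. = FALSE)
  }
  structure(t, class = "tissue_fractions")
}

#' Axonal water fraction of a tissue composition
#'
#' The axonal share of the MR-visible (non-myelin) water,
#' `fAW = fA / (fA + fE)` with `fA = fA_M + fA_U`.
#'
#' @param t a [tissue_fractions()] object.
#' @return fraction in \[0,1\].
#' @export
axonal_water_fraction <- function(t) {
  stopifnot(inherits(t, "tissue_fractions"))
  fA <- t$fA_M + t$fA_U
  den <- fA + t$fE
  if (den <= 0) {
    stop("axonal water fraction undefined: fA + fE = 0", call. = FALSE)
  }
  fA / den
}

#' Uncalibrated DWI-based axonal volume fraction
#'
#' Rescales an axonal water fraction into a volume fraction using the EM
#' myelin reference: `fA(DWI) = (1 - fM_EM) * fAW_DWI`.
#'
#' @param fAW_DWI axonal water fraction(s) in \[0,1\] (vectorized).
#' @param fM_EM EM myelin volume fraction(s) in \[0,1\].
#' @return numeric vector of axonal volume fractions.
#' @export
dwi_axonal_volume <- function(fAW_DWI, fM_EM) {
  stopifnot(all(fAW_DWI >= 0 & fAW_DWI <= 1), all(fM_EM >= 0 & fM_EM <= 1))
  (1 - fM_EM) * fAW_DWI
}

#' Discard invalid voxel values
#'
#' Voxels with `fAW < 0`, `fAW > 1` or `NaN`/`NA` are discarded before ROI
#' averaging; the boundary values 0 and 1 are retained (the discard rule is
#' strict). Order is preserved and per-category rejection counts are kept so
#' that outlier rates can be reported.
#'
#' @param values numeric vector of voxelwise axonal water fractions.
#' @return list with `values` (the valid sublist) and `rejected`, a named
#'   integer vector with counts `neg`, `gt1`, `nan`.
#' @export
#' @examples
#' filter_voxels(c(0.5, -0.1, 1.2, NaN, 0.6))
filter_voxels <- function(values) {
  stopifnot(is.numeric(values))
  nan <- !is.finite(values)
  neg <- !nan & values < 0
  gt1 <- !nan & values > 1
  keep <- !(nan | neg | gt1)
  list(values = values[keep],
       rejected = c(neg = sum(neg), gt1 = sum(gt1), nan = sum(nan)))
}

#' ROI mean of valid voxel values
#'
#' @param values numeric vector of already-filtered voxel values.
#' @param min_valid smallest voxel count considered reliable; ROIs below it
#'   are kept but flagged (attribute `flagged` and a warning). Default 3.
#' @return the arithmetic mean, with attribute `n_valid` and logical
#'   attribute `flagged`.
#' @export
roi_mean <- function(values, min_valid = 3L) {
  stopifnot(is.numeric(values))
  if (length(values) == 0L) {
    stop("no valid voxels left in ROI", call. = FALSE)
  }
  flagged <- length(values) < min_valid
  if (flagged) {
    warning(sprintf("ROI retained with only %d valid voxel(s) (min_valid = %d)",
                    length(values), min_valid), call. = FALSE)
  }
  structure(mean(values), n_valid = length(values), flagged = flagged)
}

#' Total axonal volume fraction under the constant-total assumption
#'
#' Given the myelinated-axon volume fraction and the literature percentage of
#' axons that are unmyelinated, the total axonal volume fraction is
#' `fA_M / (1 - unmyelinated_pct)`; e.g. 0.35 and 33% give about 0.52.
#'
#' @param fA_M myelinated-axon volume fraction.
#' @param unmyelinated_pct fraction (of all axons) that are unmyelinated, in
#'   \[0,1).
#' @return total axonal volume fraction.
#' @export
#' @examples
#' unmyelinated_fraction_estimate(0.35, 0.33)
unmyelinated_fraction_estimate <- function(fA_M, unmyelinated_pct) {
  stopifnot(fA_M >= 0, fA_M <= 1)
  if (any(unmyelinated_pct < 0 | unmyelinated_pct >= 1)) {
    stop("unmyelinated_pct must lie in [0,1)", call. = FALSE)
  }
  fA_M / (1 - unmyelinated_pct)
}

#' Unmyelinated-axon volume fraction under the constant-total assumption
#'
#' Companion to [unmyelinated_fraction_estimate()]: the part of the total
#' axonal volume not accounted for by myelinated axons.
#'
#' @inheritParams unmyelinated_fraction_estimate
#' @return `fA_U = fA_M / (1 - unmyelinated_pct) - fA_M`.
#' @export
unmyelinated_volume <- function(fA_M, unmyelinated_pct) {
  unmyelinated_fraction_estimate(fA_M, unmyelinated_pct) - fA_M
}
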