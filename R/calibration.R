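# Core calibration machinery.
#
# Model (stacked over the N1 + N2 observations, sorted by group):
#   fA(DWI) = (1 - fM(EM)) * s * fAW(DWI) - U,   U = (U1 e1^T, U2 e2^T)^T
# fitted to the EM reference fA(EM) by minimising the residual sum of
# squares subject to U1, U2 in [0,1], s in [0,2] and the volume-fraction
# constraint fA(DWI) + fM(EM) <= 1 (elementwise by default).
#
# The objective is a convex quadratic in (U1, U2, s), so the box-constrained
# optimum is found exactly by enumerating the <= 3^k bound-activity patterns
# and solving the reduced least-squares problem for each; the volume
# constraint is checked on the winner and, in the rare case it binds, the
# fit falls back to log-barrier optimisation (constrOptim) from a
# deterministic multi-start set.

PARAM_ORDER <- c("U1", "U2", "s")

#' Define a calibration-parameter combination
#'
#' The eight data-driven combinations free any subset of
#' \{U1, U2, s\} (including the empty baseline); in hybrid mode `s` is not
#' free but fixed to a supplied value (typically [predicted_scaling()]).
#'
#' @param free character subset of `c("U1", "U2", "s")`; `character(0)` is
#'   the baseline.
#' @param fixed_s optional positive scaling used instead of the default 1
#'   when `s` is not free (hybrid calibration); must lie in (0, 2].
#' @return list of class `calibration_combo` with `free`, `fixed_s`, `name`.
#' @export
#' @examples
#' calibration_combo(c("U2", "s"))
#' calibration_combo("U2", fixed_s = 0.89) # hybrid
calibration_combo <- function(free = character(), fixed_s = NULL) {
  free <- as.character(free)
  if (!all(free %in% PARAM_ORDER) || anyDuplicated(free)) {
    stop("free must be a subset of {U1, U2, s}", call. = FALSE)
  }
  free <- PARAM_ORDER[PARAM_ORDER %in% free]
  if (!is.null(fixed_s)) {
    if ("s" %in% free) stop("s cannot be both free and fixed", call. = FALSE)
    if (fixed_s <= 0 || fixed_s > 2) stop("fixed_s must lie in (0, 2]", call. = FALSE)
  }
  nm <- paste0("{", paste(free, collapse = ","), "}")
  if (!is.null(fixed_s)) {
    nm <- paste0("{", paste(c(free, "s_pred"), collapse = ","), "}")
  }
  structure(list(free = free, fixed_s = fixed_s, name = nm),
            class = "calibration_combo")
}

#' All eight data-driven calibration combinations
#'
#' The baseline `{}` plus the seven combinations `{U1}`, `{U2}`, `{s}`,
#' `{U1,U2}`, `{U1,s}`, `{U2,s}`, `{U1,U2,s}`.
#'
#' @return named list of [calibration_combo()] objects.
#' @export
all_combos <- function() {
  sets <- list(character(0), "U1", "U2", "s", c("U1", "U2"), c("U1", "s"),
               c("U2", "s"), c("U1", "U2", "s"))
  combos <- lapply(sets, calibration_combo)
  names(combos) <- vapply(combos, `[[`, "", "name")
  combos
}

#' Apply the linear calibration
#'
#' `fA(DWI) = (1 - fM_EM) * s * fAW_DWI - U`. May be negative before the
#' fitter's constraints are applied; no clipping happens here.
#'
#' @param fAW_DWI axonal water fraction(s).
#' @param fM_EM EM myelin volume fraction(s).
#' @param s scaling calibration in \[0,2\].
#' @param U offset calibration in \[0,1\] (scalar or per-observation).
#' @return calibrated axonal volume fraction(s).
#' @export
apply_calibration <- function(fAW_DWI, fM_EM, s = 1, U = 0) {
  stopifnot(all(fAW_DWI >= 0 & fAW_DWI <= 1), all(fM_EM >= 0 & fM_EM <= 1),
            all(s >= 0 & s <= 2), all(U >= 0 & U <= 1))
  (1 - fM_EM) * s * fAW_DWI - U
}

#' Residual sum of squares
#'
#' @param fA_EM EM reference vector.
#' @param fA_DWI_cal calibrated DWI vector of equal length.
#' @return `sum((fA_EM - fA_DWI_cal)^2)`.
#' @export
rss <- function(fA_EM, fA_DWI_cal) {
  if (length(fA_EM) != length(fA_DWI_cal)) {
    stop("length mismatch between EM and DWI vectors", call. = FALSE)
  }
  sum((fA_EM - fA_DWI_cal)^2)
}

#' Bayesian information criterion for an RSS fit
#'
#' `BIC = k ln(n) + n ln(RSS/n)`. A perfect fit (`RSS = 0`) has no finite
#' BIC; it is reported as `-Inf` so that it ranks first, with a
#' `perfect_fit` attribute set.
#'
#' @param k number of free parameters (0 for the baseline).
#' @param n number of data points.
#' @param RSS residual sum of squares, >= 0.
#' @return BIC value (`-Inf` flagged when `RSS == 0`).
#' @export
bic <- function(k, n, RSS) {
  stopifnot(n > 0, k >= 0, RSS >= 0)
  if (RSS == 0) {
    return(structure(-Inf, perfect_fit = TRUE))
  }
  k * log(n) + n * log(RSS / n)
}

#' BIC difference against the uncalibrated baseline
#'
#' @param result a `calibration_result`.
#' @param baseline the baseline `{}` result on the same data.
#' @return `BIC - BIC_baseline` (0 for the baseline itself).
#' @export
delta_bic <- function(result, baseline) {
  if (result$n != baseline$n) stop("n mismatch between result and baseline",
                                   call. = FALSE)
  d <- result$BIC - baseline$BIC
  # -Inf - -Inf: two perfect fits tie at 0
  if (is.nan(d)) d <- 0
  d
}

# ---- fitting internals ----------------------------------------------------

# design pieces for one model column; observations in cohort row order
fit_design <- function(cohort, model) {
  col <- paste0("fAW_", model)
  if (!col %in% names(cohort)) {
    stop(sprintf("cohort has no column '%s'", col), call. = FALSE)
  }
  if (!"group" %in% names(cohort)) {
    stop("cohort has no group column; run assign_groups() first", call. = FALSE)
  }
  list(y = cohort$fA_EM,
       a = (1 - cohort$fM_EM) * cohort[[col]],
       fM = cohort$fM_EM,
       e1 = as.numeric(cohort$group == 1L),
       e2 = as.numeric(cohort$group == 2L))
}

# predictions for full parameter vector c(U1, U2, s)
predict_cal <- function(d, theta) {
  d$a * theta[["s"]] - theta[["U1"]] * d$e1 - theta[["U2"]] * d$e2
}

full_theta <- function(free_theta, combo) {
  theta <- c(U1 = 0, U2 = 0, s = if (is.null(combo$fixed_s)) 1 else combo$fixed_s)
  theta[combo$free] <- free_theta
  theta
}

param_bounds <- function() {
  list(lb = c(U1 = 0, U2 = 0, s = 0), ub = c(U1 = 1, U2 = 1, s = 2))
}

# max_i (pred_i + fM_i - 1); <= tol means the volume constraint holds
volume_violation <- function(d, theta, form = "elementwise") {
  g <- predict_cal(d, theta) + d$fM - 1
  if (form == "elementwise") max(g) else min(g)
}

# exact box-constrained QP by bound-activity enumeration
solve_box_qp <- function(d, combo) {
  free <- combo$free
  k <- length(free)
  b <- param_bounds()
  if (k == 0L) {
    return(list(theta = full_theta(numeric(0), combo), n_starts = 0L,
                converged = TRUE))
  }
  # columns of the free design: d(pred)/d(theta_p)
  cols <- list(U1 = -d$e1, U2 = -d$e2, s = d$a)
  X <- do.call(cbind, cols[free])
  # residual target: y_eff = y - prediction with all free params at 0
  theta0 <- full_theta(stats::setNames(rep(0, k), free), combo)
  y_eff <- d$y - predict_cal(d, theta0)

  states <- expand.grid(rep(list(c("lb", "ub", "free")), k),
                        stringsAsFactors = FALSE)
  best <- NULL
  n_cand <- 0L
  for (r in seq_len(nrow(states))) {
    st <- unlist(states[r, ], use.names = FALSE)
    th <- stats::setNames(numeric(k), free)
    fixed_mask <- st != "free"
    th[st == "lb"] <- b$lb[free][st == "lb"]
    th[st == "ub"] <- b$ub[free][st == "ub"]
    if (any(!fixed_mask)) {
      Xf <- X[, !fixed_mask, drop = FALSE]
      resid_target <- y_eff - X[, fixed_mask, drop = FALSE] %*% th[fixed_mask]
      sol <- tryCatch(qr.solve(crossprod(Xf), crossprod(Xf, resid_target)),
                      error = function(e) NULL)
      if (is.null(sol)) next
      th[!fixed_mask] <- as.numeric(sol)
      # free coordinates must respect the box
      if (any(th[!fixed_mask] < b$lb[free][!fixed_mask] - 1e-12) ||
          any(th[!fixed_mask] > b$ub[free][!fixed_mask] + 1e-12)) next
      th[!fixed_mask] <- pmin(pmax(th[!fixed_mask], b$lb[free][!fixed_mask]),
                              b$ub[free][!fixed_mask])
    }
    n_cand <- n_cand + 1L
    val <- sum((y_eff - X %*% th)^2)
    if (is.null(best) || val < best$val) best <- list(theta = th, val = val)
  }
  if (is.null(best)) return(NULL)
  list(theta = full_theta(best$theta, combo), n_starts = n_cand,
       converged = TRUE)
}

# log-barrier fallback honouring the elementwise volume constraint
solve_barrier <- function(d, combo, constraint_form) {
  free <- combo$free
  k <- length(free)
  b <- param_bounds()
  cols <- list(U1 = -d$e1, U2 = -d$e2, s = d$a)
  X <- do.call(cbind, cols[free])
  theta0 <- full_theta(stats::setNames(rep(0, k), free), combo)
  y_eff <- d$y - predict_cal(d, theta0)

  fn <- function(th) sum((y_eff - X %*% th)^2)
  gr <- function(th) as.numeric(-2 * crossprod(X, y_eff - X %*% th))

  # linear constraints ui %*% th >= ci: box rows + volume rows
  ui <- rbind(diag(k), -diag(k))
  ci <- c(b$lb[free], -b$ub[free])
  if (constraint_form == "elementwise") {
    pred_fixed <- predict_cal(d, theta0)
    ui <- rbind(ui, -X)
    ci <- c(ci, pred_fixed + d$fM - 1)
  }

  grid <- list(U1 = c(0.05, 0.5, 0.9), U2 = c(0.05, 0.5, 0.9),
               s = c(0.1, 0.75, 1.4))
  starts <- expand.grid(grid[free])
  starts <- rbind(starts, stats::setNames(
    as.data.frame(as.list(c(U1 = 0.001, U2 = 0.001, s = 1)[free])), free))
  feasible <- apply(starts, 1, function(th) all(ui %*% th - ci > 1e-8))
  starts <- starts[feasible, , drop = FALSE]
  if (nrow(starts) == 0L) return(NULL)

  best <- NULL
  for (r in seq_len(nrow(starts))) {
    th0 <- as.numeric(starts[r, ])
    fit <- tryCatch(
      stats::constrOptim(th0, fn, gr, ui = ui, ci = ci, mu = 1e-08,
                         outer.eps = 1e-10, method = "BFGS",
                         control = list(reltol = 1e-14, maxit = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) {
      best <- fit
    }
  }
  if (is.null(best)) return(NULL)
  th <- stats::setNames(pmin(pmax(best$par, b$lb[free]), b$ub[free]), free)
  list(theta = full_theta(th, combo), n_starts = nrow(starts),
       converged = best$convergence == 0)
}

#' Fit one calibration combination
#'
#' Minimises the residual sum of squares of the calibrated DWI axonal
#' volume fraction against the EM reference over the combination's free
#' parameters, with `U1, U2` in \[0,1\], `s` in \[0,2\] and the
#' volume-fraction constraint `fA(DWI) + fM(EM) <= 1`. Parameters not freed
#' stay at `U = 0`, `s = 1` (or `s = fixed_s` in hybrid mode). The baseline
#' `{}` performs no optimisation.
#'
#' @param cohort an `axon_cohort` with a `group` column
#'   (see [assign_groups()]).
#' @param model DWI-model name (the `<MODEL>` in `fAW_<MODEL>`).
#' @param combo a [calibration_combo()].
#' @param constraint_form `"elementwise"` (default; the constraint holds for
#'   every observation) or `"min"` (the literal scalar form
#'   `min(fA(DWI) + fM(EM) - 1) < 0`, binding only the smallest value).
#' @return list of class `calibration_result`: `combo`, `model`, `U1`, `U2`,
#'   `s`, `RSS`, `k`, `n`, `BIC`, `converged`, `n_starts`.
#' @export
fit_combo <- function(cohort, model, combo,
                      constraint_form = c("elementwise", "min")) {
  constraint_form <- match.arg(constraint_form)
  stopifnot(inherits(combo, "calibration_combo"))
  d <- fit_design(cohort, model)
  if (length(combo$free) > 0) {
    if ("U2" %in% combo$free && sum(d$e2) == 0) {
      stop("cannot fit U2: no group-2 observations", call. = FALSE)
    }
    if ("U1" %in% combo$free && sum(d$e1) == 0) {
      stop("cannot fit U1: no group-1 observations", call. = FALSE)
    }
  }

  sol <- solve_box_qp(d, combo)
  used_fallback <- FALSE
  if (!is.null(sol) && length(combo$free) > 0 &&
      constraint_form == "elementwise" &&
      volume_violation(d, sol$theta, "elementwise") > 1e-9) {
    sol <- solve_barrier(d, combo, constraint_form)
    used_fallback <- TRUE
  }
  if (is.null(sol)) {
    stop(sprintf("fit of combo %s did not converge from any start", combo$name),
         call. = FALSE)
  }
  theta <- sol$theta
  n <- length(d$y)
  RSS <- sum((d$y - predict_cal(d, theta))^2)
  k <- length(combo$free)
  structure(list(combo = combo, model = model,
                 U1 = unname(theta[["U1"]]), U2 = unname(theta[["U2"]]),
                 s = unname(theta[["s"]]),
                 RSS = RSS, k = k, n = n, BIC = as.numeric(bic(k, n, RSS)),
                 perfect_fit = RSS == 0,
                 constraint_form = constraint_form,
                 converged = sol$converged,
                 n_starts = sol$n_starts,
                 barrier_fallback = used_fallback),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("%s [%s]: U1=%.4f U2=%.4f s=%.4f RSS=%.6g BIC=%.2f (k=%d, n=%d)%s\n",
              x$combo$name, x$model, x$U1, x$U2, x$s, x$RSS, x$BIC, x$k, x$n,
              if (!x$converged) " [NOT CONVERGED]" else ""))
  invisible(x)
}

#' Fit and rank all calibration combinations
#'
#' Fits each combination on all data and ranks by BIC difference against the
#' baseline (ascending); ties break by fewer free parameters, then by name.
#'
#' @inheritParams fit_combo
#' @param combos list of [calibration_combo()]; must include the baseline
#'   (default [all_combos()]).
#' @return list of `calibration_result` in rank order, each with a
#'   `delta_BIC` field; failed fits are kept as error records at the end.
#' @export
select_best <- function(cohort, model, combos = all_combos(),
                        constraint_form = "elementwise") {
  names(combos) <- vapply(combos, `[[`, "", "name")
  if (!"{}" %in% names(combos)) {
    stop("combos must include the baseline {}", call. = FALSE)
  }
  fits <- lapply(combos, function(cb) {
    tryCatch(fit_combo(cohort, model, cb, constraint_form = constraint_form),
             error = function(e) structure(list(combo = cb, error = conditionMessage(e)),
                                           class = "calibration_error"))
  })
  ok <- !vapply(fits, inherits, TRUE, "calibration_error")
  baseline <- fits[["{}"]]
  for (nm in names(fits)[ok]) fits[[nm]]$delta_BIC <- delta_bic(fits[[nm]], baseline)
  good <- fits[ok]
  dbic <- vapply(good, `[[`, 0, "delta_BIC")
  kk <- vapply(good, `[[`, 0L, "k")
  ord <- order(dbic, kk, names(good))
  c(good[ord], fits[!ok])
}

#' Leave-one-out stability of a calibration fit
#'
#' Refits the combination with each mouse (all of its ROIs) removed in turn
#' and reports the spread of the estimates across folds.
#'
#' @inheritParams fit_combo
#' @return list with `per_fold` (one `calibration_result` per left-out
#'   mouse, `NULL` where the fold failed), `estimates` (folds x free-params
#'   matrix) and `sd` (named per-parameter sample standard deviation across
#'   successful folds).
#' @export
leave_one_out <- function(cohort, model, combo,
                          constraint_form = "elementwise") {
  mice <- unique(cohort$mouse_id)
  if (length(mice) < 3L) stop("leave_one_out needs >= 3 mice", call. = FALSE)
  ga <- attr(cohort, "group_assignment")
  folds <- lapply(mice, function(m) {
    sub <- cohort[cohort$mouse_id != m, , drop = FALSE]
    class(sub) <- c("axon_cohort", "data.frame")
    attr(sub, "group_assignment") <- ga
    tryCatch(fit_combo(sub, model, combo, constraint_form = constraint_form),
             error = function(e) NULL)
  })
  names(folds) <- mice
  failed <- vapply(folds, is.null, TRUE)
  if (any(failed)) {
    warning(sprintf("%d leave-one-out fold(s) failed (%s); SD over the rest",
                    sum(failed), paste(mice[failed], collapse = ", ")),
            call. = FALSE)
  }
  pars <- combo$free
  est <- t(vapply(folds[!failed],
                  function(f) unlist(f[pars]),
                  stats::setNames(numeric(length(pars)), pars)))
  sds <- if (length(pars) > 0 && nrow(est) > 1) apply(est, 2, stats::sd)
         else stats::setNames(numeric(length(pars)), pars)
  list(per_fold = folds, estimates = est, sd = sds)
}

#' Hybrid calibration: fixed predicted scaling, fitted offsets
#'
#' Identical to [fit_combo()] with the scaling clamped to `fixed_s` (for
#' example [predicted_scaling()]); only the offsets in `free` are estimated
#' and `k` counts only those.
#'
#' @inheritParams fit_combo
#' @param free offset subset of `c("U1", "U2")` to estimate.
#' @param fixed_s the fixed scaling, in (0, 2].
#' @return a `calibration_result`.
#' @export
hybrid_fit <- function(cohort, model, free = "U2", fixed_s,
                       constraint_form = "elementwise") {
  if ("s" %in% free) stop("s is fixed in hybrid calibration", call. = FALSE)
  fit_combo(cohort, model, calibration_combo(free, fixed_s = fixed_s),
            constraint_form = constraint_form)
}

#' Convert an external slope/offset regression into this calibration
#'
#' Studies that regress EM fractions on DWI axonal *water* fractions report
#' a slope and offset; those map onto this package's parameters as
#' `s_equiv = (1 - fM_EM)/slope` and
#' `U_equiv = offset * (1 - fM_EM)/slope - fA_U`.
#'
#' @param slope,offset external regression coefficients (`slope != 0`).
#' @param fM_EM myelin volume fraction of the compared tissue.
#' @param fA_U unmyelinated-axon volume fraction assumed for it.
#' @return list with `s_equiv` and `U_equiv`.
#' @export
convert_external_slope_offset <- function(slope, offset, fM_EM, fA_U) {
  if (slope == 0) stop("slope must be nonzero", call. = FALSE)
  s_equiv <- (1 - fM_EM) / slope
  list(s_equiv = s_equiv, U_equiv = offset * s_equiv - fA_U)
}
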