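# TE-dependent signal-fraction model at b = 0.
#
# With compartmental T2 relaxation the coefficient of the axonal signal in
# the four-compartment (ex vivo NODDI) model becomes echo-time dependent:
#   fAW(TE) = (1-nu_dot)(1-nu_iso) nu exp(-TE/T2a) / S0hat(TE),
# so a model blind to relaxation needs a scaling s(TE) to recover the true
# axonal water fraction. s_pred is that scaling in closed form; it depends
# on the compartmental T2 values only through the differences
# Delta_x = 1/(1/T2x - 1/T2a).

#' Compartmental signal fractions
#'
#' @param nu axonal signal fraction, `fA/(fA+fE)`.
#' @param nu_iso isotropic (CSF) signal fraction; 0 for two-compartment
#'   models.
#' @param nu_dot dot-compartment signal fraction (fixed ex vivo tissue); 0
#'   in vivo.
#' @return list of class `signal_fractions`.
#' @export
signal_fractions <- function(nu, nu_iso = 0, nu_dot = 0) {
  v <- c(nu = nu, nu_iso = nu_iso, nu_dot = nu_dot)
  if (any(!is.finite(v)) || any(v < 0) || any(v > 1)) {
    stop("signal fractions must lie in [0,1]", call. = FALSE)
  }
  structure(as.list(v), class = "signal_fractions")
}

#' Compartmental T2 profile
#'
#' @param T2_a axonal T2 (ms, > 0).
#' @param T2_e extracellular T2 (ms, > 0).
#' @param T2_iso isotropic-compartment T2 (ms); required only when
#'   `nu_iso > 0`.
#' @param T2_dot dot-compartment T2 (ms); required only when `nu_dot > 0`.
#' @return list of class `t2_profile`.
#' @export
t2_profile <- function(T2_a, T2_e, T2_iso = NA_real_, T2_dot = NA_real_) {
  for (x in list(T2_a, T2_e)) {
    if (!is.finite(x) || x <= 0) stop("T2_a and T2_e must be positive", call. = FALSE)
  }
  for (x in list(T2_iso, T2_dot)) {
    if (!is.na(x) && x <= 0) stop("optional T2 values must be positive", call. = FALSE)
  }
  structure(list(T2_a = T2_a, T2_e = T2_e, T2_iso = T2_iso, T2_dot = T2_dot),
            class = "t2_profile")
}

check_t2 <- function(sf, t2) {
  if (sf$nu_iso > 0 && is.na(t2$T2_iso)) {
    stop("nu_iso > 0 requires T2_iso in the T2 profile", call. = FALSE)
  }
  if (sf$nu_dot > 0 && is.na(t2$T2_dot)) {
    stop("nu_dot > 0 requires T2_dot in the T2 profile", call. = FALSE)
  }
}

# exp(-TE/T2) treating an absent compartment (weight 0, T2 NA) as factor 0-safe
decay <- function(TE, T2) if (is.na(T2)) 0 else exp(-TE / T2)

#' Normalized b=0 signal with compartmental relaxation
#'
#' `S0hat(TE) = (1-nu_dot)[(1-nu_iso)(nu e^{-TE/T2a} + (1-nu) e^{-TE/T2e})
#'  + nu_iso e^{-TE/T2iso}] + nu_dot e^{-TE/T2dot}`; equals 1 at `TE = 0`.
#'
#' @param sf a [signal_fractions()] object.
#' @param t2 a [t2_profile()] object.
#' @param TE echo time in ms, >= 0.
#' @return value in (0, 1].
#' @export
s0_hat <- function(sf, t2, TE) {
  stopifnot(inherits(sf, "signal_fractions"), inherits(t2, "t2_profile"), TE >= 0)
  check_t2(sf, t2)
  (1 - sf$nu_dot) * ((1 - sf$nu_iso) *
    (sf$nu * decay(TE, t2$T2_a) + (1 - sf$nu) * decay(TE, t2$T2_e)) +
    sf$nu_iso * decay(TE, t2$T2_iso)) +
    sf$nu_dot * decay(TE, t2$T2_dot)
}

#' TE-biased axonal signal-fraction coefficient
#'
#' What a relaxation-blind DWI model reports as the axonal water fraction at
#' echo time `TE`:
#' `fAW(TE) = (1-nu_dot)(1-nu_iso) nu e^{-TE/T2a} / S0hat(TE)`.
#' At `TE = 0` this reduces to `(1-nu_dot)(1-nu_iso) nu`, the unbiased
#' axonal water fraction.
#'
#' @inheritParams s0_hat
#' @return fraction in \[0,1\].
#' @export
fAW_at_TE <- function(sf, t2, TE) {
  stopifnot(inherits(sf, "signal_fractions"), inherits(t2, "t2_profile"), TE >= 0)
  check_t2(sf, t2)
  (1 - sf$nu_dot) * (1 - sf$nu_iso) * sf$nu * decay(TE, t2$T2_a) / s0_hat(sf, t2, TE)
}

# relaxation-difference time constant; equal T2s -> Inf (decay factor 1)
delta_time <- function(T2_x, T2_a) {
  if (is.na(T2_x)) return(NA_real_)
  d <- 1 / T2_x - 1 / T2_a
  if (d == 0) Inf else 1 / d
}

#' Theoretically predicted scaling calibration factor
#'
#' `s_pred = S0hat(TE) / e^{-TE/T2a}
#'         = (1-nu_dot)[(1-nu_iso)(nu + (1-nu) e^{-TE/De})
#'           + nu_iso e^{-TE/Diso}] + nu_dot e^{-TE/Ddot}`,
#' with `Dx = 1/(1/T2x - 1/T2a)`. It satisfies the defining identity
#' `s_pred * fAW(TE) = (1-nu_dot)(1-nu_iso) nu` and equals 1 at `TE = 0` or
#' when all compartmental T2 values coincide.
#'
#' @inheritParams s0_hat
#' @return positive scaling factor.
#' @export
#' @examples
#' sf <- signal_fractions(nu = 0.475)
#' predicted_scaling(sf, t2_profile(T2_a = 50, T2_e = 30), TE = 19)
predicted_scaling <- function(sf, t2, TE) {
  stopifnot(inherits(sf, "signal_fractions"), inherits(t2, "t2_profile"), TE >= 0)
  check_t2(sf, t2)
  de <- delta_time(t2$T2_e, t2$T2_a)
  diso <- delta_time(t2$T2_iso, t2$T2_a)
  ddot <- delta_time(t2$T2_dot, t2$T2_a)
  dfac <- function(d) if (is.na(d)) 0 else if (is.infinite(d)) 1 else exp(-TE / d)
  (1 - sf$nu_dot) * ((1 - sf$nu_iso) * (sf$nu + (1 - sf$nu) * dfac(de)) +
                       sf$nu_iso * dfac(diso)) +
    sf$nu_dot * dfac(ddot)
}

#' Invert the two-compartment scaling for the relaxation time constant
#'
#' Solves `s_pred(Delta_e) = s_target` for the two-compartment case
#' (`nu_iso = nu_dot = 0`), where
#' `s_pred = nu + (1-nu) e^{-TE/Delta_e}`. Used to build configurations
#' consistent with a stated scaling when the underlying compartmental T2
#' values are not available. Feasible only for `s_target` in `(nu, 1)`
#' (s_pred -> nu as Delta_e -> 0+, -> 1 as Delta_e -> Inf).
#'
#' @param sf two-compartment [signal_fractions()] (`nu_iso = nu_dot = 0`).
#' @param TE echo time in ms, > 0.
#' @param s_target desired scaling in `(nu, 1)`.
#' @param cap upper bound on the returned time constant (ms); targets whose
#'   solution exceeds it are reported infeasible.
#' @return `Delta_e` in ms such that `predicted_scaling` reproduces
#'   `s_target` to 1e-10.
#' @export
solve_delta_e <- function(sf, TE, s_target, cap = 1e6) {
  stopifnot(inherits(sf, "signal_fractions"), TE > 0)
  if (sf$nu_iso != 0 || sf$nu_dot != 0) {
    stop("solve_delta_e applies to the two-compartment case only", call. = FALSE)
  }
  if (s_target <= sf$nu || s_target >= 1) {
    stop(sprintf("s_target must lie strictly in (nu, 1) = (%g, 1)", sf$nu),
         call. = FALSE)
  }
  # nu + (1-nu) exp(-TE/De) = s  =>  De = TE / log((1-nu)/(s-nu))
  de <- TE / log((1 - sf$nu) / (s_target - sf$nu))
  if (!is.finite(de) || de <= 0 || de > cap) {
    stop(sprintf("s_target %g infeasible: implied Delta_e %g outside (0, %g]",
                 s_target, de, cap), call. = FALSE)
  }
  de
}

#' Synthetic two-compartment T2 profile consistent with a target scaling
#'
#' The compartmental T2 values behind a published scaling are often not
#' available; this helper constructs a *synthetic* profile (anchored at a
#' chosen axonal T2) whose [predicted_scaling()] reproduces `s_target` at
#' the given `TE`. It is a fixture-building device, not an estimate of real
#' relaxation times.
#'
#' @inheritParams solve_delta_e
#' @param T2_a anchor axonal T2 in ms (default 50).
#' @return a [t2_profile()].
#' @export
synthetic_t2_profile <- function(sf, TE, s_target, T2_a = 50) {
  de <- solve_delta_e(sf, TE, s_target)
  # De = 1/(1/T2e - 1/T2a)  =>  T2e = 1/(1/De + 1/T2a)
  t2_profile(T2_a = T2_a, T2_e = 1 / (1 / de + 1 / T2_a))
}
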