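#' Time-varying elastance waveform
#'
#' Rise-plateau-fall activation: elastance rises from `E_min` along a
#' half-cosine over the first 40% of systole, holds at exactly `E_max`
#' until 75% of systole, relaxes along a half-cosine over the remaining
#' 25%, and stays at `E_min` through diastole.  The waveform is periodic with period `T`, has a
#' continuous first derivative, and its peak value is independent of the
#' cardiac period (systole duration adapts through the diastole-duration
#' relation, the amplitude does not).
#'
#' @param t Time (s), vectorised; any non-negative value.
#' @param T Cardiac period (s).
#' @param E_max,E_min Maximum and minimum chamber elastance (mmHg/mL).
#' @param t_sys Systole duration (s); defaults to `T - diastole_duration(T)`.
#' @param coef Length-2 diastole-duration coefficients used when `t_sys` is
#'   not given (see [diastole_duration()]).
#' @return Elastance values (mmHg/mL), same length as `t`.
#' @export
#' @examples
#' elastance_waveform(0, T = 0.8, E_max = 2.6, E_min = 0.08)  # E_min
elastance_waveform <- function(t, T, E_max, E_min, t_sys = NULL,
                               coef = c(0.8, -0.19)) {
  if (!is.finite(T) || T <= 0) stop("T must be > 0", call. = FALSE)
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  if (E_max <= E_min) stop("E_max must exceed E_min", call. = FALSE)
  if (is.null(t_sys)) t_sys <- T - diastole_duration(T, coef)
  tb <- t %% T
  tr <- 0.4 * t_sys
  th <- 0.75 * t_sys
  tf <- t_sys - th
  phi <- ifelse(tb < tr, 0.5 * (1 - cos(pi * tb / tr)),
         ifelse(tb < th, 1,
         ifelse(tb < t_sys, 0.5 * (1 + cos(pi * (tb - th) / tf)), 0)))
  E_min + (E_max - E_min) * phi
}

#' Diastole duration as a function of cardiac period
#'
#' Affine relation `T_dia = a * T + b` between cardiac period and diastole
#' duration.  The shipped coefficients are placeholders calibrated to give
#' a diastolic time fraction near 0.56 at a 0.8 s period and increasing
#' with the period, matching the physiological pattern that diastole
#' absorbs most of a lengthening beat; they are plain configuration values
#' and should be overridden when a fitted relation is available.
#'
#' @param T Cardiac period (s), in `[0.4, 1.5]`.
#' @param coef Numeric length-2 vector `c(slope, intercept_s)`.
#' @return Diastole duration `T_dia` (s), guaranteed in `(0, T)`.
#' @export
#' @examples
#' diastole_duration(0.8)        # 0.45
#' diastole_duration(0.8) / 0.8  # diastolic time fraction
diastole_duration <- function(T, coef = c(0.8, -0.19)) {
  if (any(!is.finite(T)) || any(T < 0.4) || any(T > 1.5)) {
    stop("T must be within [0.4, 1.5] s", call. = FALSE)
  }
  td <- coef[1] * T + coef[2]
  if (any(td <= 0) || any(td >= T)) {
    stop("diastole-duration coefficients give T_dia outside (0, T)",
         call. = FALSE)
  }
  td
}

#' Volume-dependent intramyocardial layer resistance
#'
#' Inverse-square law `R = R0 * (V0 / V)^2`: as a layer's vascular volume
#' is compressed below its reference volume the resistance rises steeply,
#' which is what transmits the systolic intramyocardial squeeze into the
#' flow waveform.
#'
#' @param V Current layer vascular volume (mL), > 0.
#' @param R0 Reference resistance at `V = V0` (mmHg.s/mL).
#' @param V0 Reference volume (mL), > 0.
#' @return Resistance (mmHg.s/mL).
#' @export
#' @examples
#' layer_resistance(1, R0 = 1, V0 = 2)  # 4
layer_resistance <- function(V, R0, V0) {
  if (any(!is.finite(V)) || any(V <= 0)) {
    stop("V must be > 0 (collapsed vessel outside model validity)",
         call. = FALSE)
  }
  if (V0 <= 0) stop("V0 must be > 0", call. = FALSE)
  if (R0 < 0) stop("R0 must be >= 0", call. = FALSE)
  R0 * (V0 / V)^2
}

#' Intramyocardial pressure at a given wall depth
#'
#' The contraction-generated tissue pressure is taken to increase linearly
#' with depth in the myocardial wall, from zero at the epicardial surface
#' to the full left-ventricular pressure at the endocardium.
#'
#' @param p_lv Left ventricular pressure (mmHg), vectorised.
#' @param depth_fraction Relative wall depth in `[0, 1]` (0 = epicardium).
#' @return Intramyocardial pressure (mmHg).
#' @export
#' @examples
#' intramyocardial_pressure(100, 0.5)  # 50
intramyocardial_pressure <- function(p_lv, depth_fraction) {
  if (any(depth_fraction < 0) || any(depth_fraction > 1)) {
    stop("depth_fraction must lie in [0, 1]", call. = FALSE)
  }
  depth_fraction * p_lv
}
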