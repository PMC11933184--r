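# Young-Tsai empirical stenosis element.  Geometry and coefficients are
# kept in CGS (cm, g, s, dyn) as the correlation was fitted in those
# units; pressure drops are converted to mmHg at the interface.

MMHG_PER_DYN_CM2 <- 1 / 1333.22

#' Stenosis geometry from a percentage diameter reduction
#'
#' Derives the cross-sectional areas and vena-contracta diameter of a
#' stenosis from its percentage diameter reduction.  By default the vena
#' contracta equals the stenosed lumen diameter,
#' `D_s = D0 * (1 - pct_s/100)`, so the area ratio is
#' `A_s / A0 = (1 - pct_s/100)^2`.  Full occlusion (`pct_s >= 100`) is not
#' representable by this element and must be handled by removing the
#' branch.
#'
#' @param pct_s Percentage diameter reduction, `0 <= pct_s < 100`.
#' @param D0 Unstenosed vessel diameter (cm).
#' @param l_s Effective stenosis length (cm).
#' @param D_s Vena-contracta diameter (cm); defaults to the stenosed lumen
#'   diameter.
#' @param K_t,K_u Turbulent and inertial loss constants (shape-independent
#'   defaults 1.52 and 1.2).
#' @return An object of class `stenosis_geometry` with fields `pct_s`,
#'   `D0`, `l_s`, `D_s`, `A0`, `A_s`, `K_t`, `K_u` (areas in cm^2).
#' @export
#' @examples
#' g <- stenosis_geometry(50, D0 = 0.28, l_s = 0.3)
#' g$A0 / g$A_s  # 4
stenosis_geometry <- function(pct_s, D0, l_s, D_s = NULL,
                              K_t = 1.52, K_u = 1.2) {
  if (!is.finite(pct_s) || pct_s < 0 || pct_s >= 100) {
    stop("pct_s must be in [0, 100); full occlusion is handled by branch ",
         "removal, not by the stenosis element", call. = FALSE)
  }
  if (D0 <= 0 || l_s <= 0) stop("D0 and l_s must be > 0", call. = FALSE)
  if (is.null(D_s)) D_s <- D0 * (1 - pct_s / 100)
  if (D_s > D0) stop("D_s cannot exceed D0", call. = FALSE)
  geom <- list(pct_s = pct_s, D0 = D0, l_s = l_s, D_s = D_s,
               A0 = pi * D0^2 / 4, A_s = pi * D0^2 / 4 * (1 - pct_s / 100)^2,
               K_t = K_t, K_u = K_u)
  class(geom) <- "stenosis_geometry"
  geom
}

#' @export
print.stenosis_geometry <- function(x, ...) {
  cat(sprintf("<stenosis_geometry> %.1f%% diameter (%.1f%% area) reduction\n",
              x$pct_s, 100 * (1 - x$A_s / x$A0)))
  cat(sprintf("  D0 = %.3g cm, l_s = %.3g cm, D_s = %.3g cm, K_v = %.4g\n",
              x$D0, x$l_s, x$D_s, kv_coefficient(x)))
  invisible(x)
}

#' Geometry-dependent viscous loss coefficient
#'
#' `K_v = 32 * (0.83 * l_s + 1.64 * D_s) / D0 * (A0 / A_s)^2`, the
#' empirical viscous coefficient of the stenosis pressure-drop model.
#'
#' @param geom A [stenosis_geometry()] object.
#' @return Dimensionless viscous coefficient.
#' @export
kv_coefficient <- function(geom) {
  stopifnot(inherits(geom, "stenosis_geometry"))
  32 * (0.83 * geom$l_s + 1.64 * geom$D_s) / geom$D0 * (geom$A0 / geom$A_s)^2
}

#' Stenosis pressure drop (viscous + turbulent + inertial)
#'
#' Empirical pressure drop across a stenosis:
#' \deqn{\Delta p = \frac{4 K_v \mu}{\pi D_0^3} Q
#'   + \frac{\rho K_t}{2 A_0^2}\left(\frac{A_0}{A_s}-1\right)^2 Q |Q|
#'   + \frac{\rho K_u l_s}{A_0} \frac{dQ}{dt}}
#' evaluated in CGS units and converted to mmHg.  The turbulent term uses
#' `Q|Q|` (odd extension of the original forward-flow `Q^2` form) so that
#' the element is antisymmetric: `dp(-Q, -dQdt) = -dp(Q, dQdt)`, which is
#' required for transiently reversing graft flow.
#'
#' @param Q_s Flow through the stenosis (mL/s), vectorised.
#' @param dQdt Flow time-derivative (mL/s^2), vectorised.
#' @param geom A [stenosis_geometry()] object.
#' @param mu Blood viscosity (poise).
#' @param rho Blood density (g/mL).
#' @return Pressure drop (mmHg).
#' @export
#' @examples
#' g <- stenosis_geometry(50, D0 = 0.2, l_s = 0.3)
#' stenosis_pressure_drop(1, 0, g, mu = 0.035, rho = 1.06)
stenosis_pressure_drop <- function(Q_s, dQdt, geom, mu, rho) {
  stopifnot(inherits(geom, "stenosis_geometry"))
  if (any(!is.finite(Q_s)) || any(!is.finite(dQdt))) {
    stop("Q_s and dQdt must be finite", call. = FALSE)
  }
  co <- stenosis_coefficients(geom, mu, rho)
  co$R_v * Q_s + co$K_turb * Q_s * abs(Q_s) + co$L_u * dQdt
}

#' Lumped coefficients of the stenosis element
#'
#' Collapses the stenosis pressure-drop model into three lumped
#' coefficients in clinical units, ready for insertion into the graft
#' branch of the 0D network: a linear resistance `R_v` (mmHg.s/mL), a
#' turbulent coefficient `K_turb` (mmHg.s^2/mL^2, multiplying `Q|Q|`),
#' and an inertance `L_u` (mmHg.s^2/mL).
#'
#' @inheritParams stenosis_pressure_drop
#' @return List with `R_v`, `K_turb`, `L_u`.
#' @export
stenosis_coefficients <- function(geom, mu, rho) {
  stopifnot(inherits(geom, "stenosis_geometry"))
  if (mu <= 0 || rho <= 0) stop("mu and rho must be > 0", call. = FALSE)
  K_v <- kv_coefficient(geom)
  list(
    R_v    = 4 * K_v * mu / (pi * geom$D0^3) * MMHG_PER_DYN_CM2,
    K_turb = rho * geom$K_t / (2 * geom$A0^2) *
             (geom$A0 / geom$A_s - 1)^2 * MMHG_PER_DYN_CM2,
    L_u    = rho * geom$K_u * geom$l_s / geom$A0 * MMHG_PER_DYN_CM2
  )
}

#' Diameter reduction equivalent to a given area reduction
#'
#' Converts a percentage area reduction into the equivalent percentage
#' diameter reduction under a circular lumen,
#' `pct_d = 100 * (1 - sqrt(1 - pct_area/100))`.
#'
#' @param pct_area Percentage area reduction in `[0, 100)`.
#' @return Percentage diameter reduction.
#' @export
#' @examples
#' diameter_from_area_reduction(90)  # ~68
diameter_from_area_reduction <- function(pct_area) {
  if (any(pct_area < 0) || any(pct_area >= 100)) {
    stop("pct_area must be in [0, 100)", call. = FALSE)
  }
  100 * (1 - sqrt(1 - pct_area / 100))
}
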