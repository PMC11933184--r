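#' Parameter registry for the 0D circulation model
#'
#' Returns the registry of the 39 tunable model constants (the stenosis
#' percentage included), with default values, units, and the probability
#' distribution attached to each parameter for sensitivity screening.
#' Distribution families are `"tnorm"` (normal truncated to mean +/- 2 sd)
#' or `"uniform"`; where no literature standard deviation is recorded the
#' `sd` column is `NA` and a default of 25% of the mean is applied when the
#' distributions are materialised (see [morris_distributions()]).
#'
#' The defaults are literature-guided values for a resting adult and are
#' validated only against broad sanity bands (aortic pressure near 120/80
#' mmHg, cardiac output 4-6 L/min at a 0.8 s cardiac period); the per-layer
#' intramyocardial constants follow the intramyocardial-pump family of
#' models with volume-dependent layer resistances.
#'
#' @return A data.frame with columns `name`, `default`, `units`, `family`,
#'   `sd`, `lower`, `upper`, `group`, `description`; 39 rows.
#' @export
#' @examples
#' reg <- param_registry()
#' nrow(reg)  # 39
param_registry <- function() {
  row <- function(name, default, units, group, description,
                  family = "tnorm", sd = NA_real_,
                  lower = NA_real_, upper = NA_real_) {
    data.frame(name = name, default = default, units = units,
               family = family, sd = sd, lower = lower, upper = upper,
               group = group, description = description,
               stringsAsFactors = FALSE)
  }
  reg <- rbind(
    row("T",          0.8,   "s",         "heart", "cardiac period",
        sd = 0.12),
    row("E_max_lv",   2.6,   "mmHg/mL",   "heart", "LV maximum elastance"),
    row("E_min_lv",   0.10,  "mmHg/mL",   "heart", "LV minimum elastance"),
    row("E_max_rv",   0.65,  "mmHg/mL",   "heart", "RV maximum elastance"),
    row("E_min_rv",   0.045, "mmHg/mL",   "heart", "RV minimum elastance"),
    row("V0_lv",      10,    "mL",        "heart", "LV unstressed volume"),
    row("V0_rv",      10,    "mL",        "heart", "RV unstressed volume"),
    row("R_mv",       0.006, "mmHg.s/mL", "valves", "mitral valve resistance"),
    row("R_av",       0.060, "mmHg.s/mL", "valves",
        "aortic valve / systemic characteristic resistance"),
    row("R_tv",       0.006, "mmHg.s/mL", "valves",
        "tricuspid inflow resistance (atrium lumped)"),
    row("R_pv",       0.008, "mmHg.s/mL", "valves", "pulmonary valve resistance"),
    row("C_sa",       1.4,   "mL/mmHg",   "systemic", "systemic arterial compliance"),
    row("L_sa",       1.0e-3,"mmHg.s2/mL","systemic", "systemic arterial inertance"),
    row("R0_svb",     1.05,  "mmHg.s/mL", "systemic",
        "systemic vascular bed reference resistance"),
    row("C_sv",       45,    "mL/mmHg",   "systemic", "systemic venous compliance"),
    row("C_pa",       4.5,   "mL/mmHg",   "pulmonary", "pulmonary arterial compliance"),
    row("L_pa",       8.0e-4,"mmHg.s2/mL","pulmonary", "pulmonary arterial inertance"),
    row("R_pvb",      0.08,  "mmHg.s/mL", "pulmonary",
        "pulmonary vascular bed resistance"),
    row("C_pv",       15,    "mL/mmHg",   "pulmonary", "pulmonary venous compliance"),
    row("R_graft",    9.0,   "mmHg.s/mL", "graft", "graft lumped resistance"),
    row("L_graft",    0.25,  "mmHg.s2/mL","graft", "graft lumped inertance"),
    row("pct_s",      0,     "%",         "stenosis",
        "stenosis percentage diameter reduction",
        family = "uniform", lower = 0, upper = 75),
    row("D0_g",       0.17,  "cm",        "stenosis", "unstenosed graft diameter"),
    row("l_s",        0.3,   "cm",        "stenosis", "effective stenosis length"),
    row("mu",         0.035, "poise",     "blood", "blood dynamic viscosity",
        sd = 0.005),
    row("rho",        1.06,  "g/mL",      "blood", "blood density", sd = 0.03),
    row("C1",         0.012, "mL/mmHg",   "intramyocardial",
        "arterial-side intramyocardial compliance (all layers)"),
    row("V0_1",       4.0,   "mL",        "intramyocardial",
        "arterial-side intramyocardial reference volume (all layers)"),
    row("C2",         0.08,  "mL/mmHg",   "intramyocardial",
        "venous-side intramyocardial compliance (all layers)"),
    row("V0_2",       8.0,   "mL",        "intramyocardial",
        "venous-side intramyocardial reference volume (all layers)"),
    row("R0_a",       45,    "mmHg.s/mL", "intramyocardial",
        "arterial-side reference resistance (parallel equivalent)"),
    row("R0_m",       40,    "mmHg.s/mL", "intramyocardial",
        "middle reference resistance (parallel equivalent)"),
    row("R0_v",       16,    "mmHg.s/mL", "intramyocardial",
        "venous outlet resistance (parallel equivalent)"),
    row("endo_epi_vratio", 1.25, "-",     "intramyocardial",
        "subendocardial/subepicardial reference-volume ratio",
        family = "uniform", lower = 0.8, upper = 1.6),
    row("tdia_slope",     0.8, "-",      "timing",
        "diastole-duration relation slope (T_dia = a*T + b)", sd = 0.05),
    row("tdia_intercept", -0.19, "s",    "timing",
        "diastole-duration relation intercept", sd = 0.02),
    row("V_total",    5050,  "mL",        "blood", "total blood volume",
        sd = 400),
    row("K_t",        1.52,  "-",         "stenosis",
        "turbulent-loss stenosis constant", sd = 0.15),
    row("K_u",        1.2,   "-",         "stenosis",
        "inertial stenosis constant", sd = 0.12)
  )
  rownames(reg) <- NULL
  reg
}

#' Build a complete model parameter set
#'
#' Populates every entry of the parameter registry with its default and
#' applies named overrides, either from an in-memory list or a YAML/JSON
#' parameter file with flat `name: value` keys.  The stenosis element is
#' controlled separately through `stenosis_enabled`: a disabled element
#' contributes no pressure drop at all, which differs from an enabled
#' element at 0% (the viscous term of the stenosis model remains).
#'
#' @param overrides Named list (or NULL) of registry parameter values.
#' @param file Optional path to a YAML or JSON file of overrides; entries
#'   in `overrides` take precedence over the file.
#' @param stenosis_enabled Logical; insert the stenosis element into the
#'   graft branch.
#' @return An object of class `graft_params`: a named list with the 39
#'   registry values plus `stenosis_enabled`.
#' @export
#' @examples
#' p <- default_parameters(list(T = 1.0))
#' p$T
default_parameters <- function(overrides = list(), file = NULL,
                               stenosis_enabled = TRUE) {
  reg <- param_registry()
  vals <- as.list(stats::setNames(reg$default, reg$name))
  if (!is.null(file)) {
    ext <- tolower(tools::file_ext(file))
    from_file <- if (ext == "json") jsonlite::read_json(file, simplifyVector = TRUE)
                 else yaml::read_yaml(file)
    if (!is.null(from_file$stenosis_enabled)) {
      stenosis_enabled <- isTRUE(from_file$stenosis_enabled)
      from_file$stenosis_enabled <- NULL
    }
    vals <- apply_overrides(vals, from_file, reg$name)
  }
  vals <- apply_overrides(vals, overrides, reg$name)
  vals$stenosis_enabled <- isTRUE(stenosis_enabled)
  class(vals) <- "graft_params"
  validate_parameters(vals)
  vals
}

apply_overrides <- function(vals, overrides, known) {
  if (length(overrides) == 0) return(vals)
  nm <- names(overrides)
  if (is.null(nm) || any(nm == "")) {
    stop("parameter overrides must be a named list", call. = FALSE)
  }
  unknown <- setdiff(nm, known)
  if (length(unknown) > 0) {
    stop("unknown parameter name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (n in nm) vals[[n]] <- as.numeric(overrides[[n]])
  vals
}

#' Validate a model parameter set
#'
#' Checks the physical invariants of the parameter set (positive period,
#' non-negative resistances and compliances, elastance ordering, stenosis
#' percentage below total occlusion, positive viscosity and density) and
#' raises an error naming the offending field.
#'
#' @param params A `graft_params` object.
#' @return `params`, invisibly, if valid.
#' @export
validate_parameters <- function(params) {
  chk <- function(cond, field, msg) {
    if (!cond) stop("invalid parameter '", field, "': ", msg, call. = FALSE)
  }
  p <- params
  chk(is.finite(p$T) && p$T > 0, "T", "cardiac period must be > 0")
  for (f in c("R_mv", "R_av", "R_tv", "R_pv", "R0_svb", "R_pvb",
              "R_graft", "R0_a", "R0_m", "R0_v")) {
    chk(is.finite(p[[f]]) && p[[f]] >= 0, f, "resistance must be >= 0")
  }
  for (f in c("C_sa", "C_sv", "C_pa", "C_pv", "C1", "C2")) {
    chk(is.finite(p[[f]]) && p[[f]] > 0, f, "compliance must be > 0")
  }
  for (f in c("L_sa", "L_pa", "L_graft")) {
    chk(is.finite(p[[f]]) && p[[f]] > 0, f, "inertance must be > 0")
  }
  chk(p$E_max_lv > p$E_min_lv && p$E_min_lv > 0, "E_max_lv",
      "must satisfy E_max > E_min > 0")
  chk(p$E_max_rv > p$E_min_rv && p$E_min_rv > 0, "E_max_rv",
      "must satisfy E_max > E_min > 0")
  chk(p$pct_s >= 0 && p$pct_s < 100, "pct_s",
      "stenosis percentage must be in [0, 100)")
  chk(p$D0_g > 0, "D0_g", "diameter must be > 0")
  chk(p$l_s > 0, "l_s", "stenosis length must be > 0")
  chk(p$mu > 0, "mu", "viscosity must be > 0")
  chk(p$rho > 0, "rho", "density must be > 0")
  chk(p$V0_1 > 0 && p$V0_2 > 0, "V0_1", "reference volumes must be > 0")
  chk(p$V_total > 0, "V_total", "total blood volume must be > 0")
  chk(p$endo_epi_vratio > 0, "endo_epi_vratio", "volume ratio must be > 0")
  # diastole-duration relation must yield 0 < T_dia < T at this period
  td <- p$tdia_slope * p$T + p$tdia_intercept
  chk(td > 0 && td < p$T, "tdia_slope",
      "diastole-duration relation gives T_dia outside (0, T)")
  invisible(params)
}

#' @export
print.graft_params <- function(x, ...) {
  cat("<graft_params> 0D circulation parameter set\n")
  cat(sprintf("  T = %.3g s, E_max_lv = %.3g mmHg/mL, R0_svb = %.3g mmHg.s/mL\n",
              x$T, x$E_max_lv, x$R0_svb))
  cat(sprintf("  stenosis: %s, pct_s = %.3g%%\n",
              if (x$stenosis_enabled) "enabled" else "disabled", x$pct_s))
  invisible(x)
}
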