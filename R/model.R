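# Assembly of the 0D network and its integration.  The network topology:
# LV -> aortic valve -> systemic arterial compliance -> {systemic vascular
# bed (R0_svb, L_sa) -> systemic venous compliance} and in parallel the
# graft branch {R_graft, L_graft, optional stenosis} -> three-layer
# intramyocardial bed -> systemic venous compliance -> tricuspid ->
# RV -> pulmonary valve -> pulmonary arterial compliance -> pulmonary bed
# -> pulmonary venous compliance -> mitral -> LV.

# names of the 17 state variables, in integrator order
STATE_NAMES <- c("V_lv", "V_rv", "V_sa", "V_sv", "V_pa", "V_pu",
                 "Q_sa", "Q_pa", "Q_g", "V_gp", "V_cor",
                 "V1_epi", "V1_mid", "V1_endo",
                 "V2_epi", "V2_mid", "V2_endo")

SIGNAL_NAMES <- c("p_ao", "p_lv", "p_rv", "p_sv", "p_pa", "p_pu", "p_probe",
                  "q_av", "q_mv", "q_graft", "q_epi", "q_mid", "q_endo",
                  "V_lv", "V_rv", "V_tot", "q_sten")

# mid-depths of three equal-thickness wall layers (epi, mid, endo)
LAYER_DEPTHS <- c(1, 3, 5) / 6

# unstressed compartment volumes (mL) and reference layer pressures (mmHg);
# fixed network constants, not part of the 39-parameter registry
VU_SA <- 500; VU_SV <- 3200; VU_PA <- 100; VU_PU <- 400
P1_REF <- 60; P2_REF <- 15
VALVE_W <- 0.1   # valve smoothing width (mmHg)
# graft-branch storage: a proximal compliance at the probe site (the
# graft's own wall storage upstream of the stenosis) and a distal
# epicardial node feeding the intramyocardial layers
C_GP <- 0.002    # mL/mmHg, proximal graft compliance
V0_GP <- 1.0     # mL at the reference pressure
C_COR <- 0.001   # mL/mmHg, distal epicardial node compliance
V0_COR <- 1.0    # mL at the reference pressure
P_COR_REF <- 75  # mmHg

#' Per-layer split of the intramyocardial constants
#'
#' Distributes the bed-level intramyocardial constants over the three wall
#' layers.  Reference volumes and compliances are split in proportion to
#' layer shares derived from the subendocardial/subepicardial volume ratio
#' (mid-wall takes the mean share, total reference volume is conserved);
#' reference resistances scale inversely with the share so the registry
#' values remain the parallel-equivalent resistances of the whole bed.
#'
#' @param params A `graft_params` object.
#' @return List of per-layer vectors (epi, mid, endo): `share`, `C1`, `C2`,
#'   `V0_1`, `V0_2`, `R0_a`, `R0_m`, `R_v`, `depth`.
#' @export
layer_constants <- function(params) {
  r <- params$endo_epi_vratio
  w <- c(1, (1 + r) / 2, r)
  share <- w / sum(w)
  list(share = share,
       C1 = params$C1 * share, C2 = params$C2 * share,
       V0_1 = params$V0_1 * share, V0_2 = params$V0_2 * share,
       R0_a = params$R0_a / share, R0_m = params$R0_m / share,
       R_v = params$R0_v / share,
       depth = LAYER_DEPTHS)
}

# Pack parameters + derived constants into the numeric context vector the
# compiled right-hand side consumes.
build_sim_context <- function(params) {
  validate_parameters(params)
  p <- params
  t_dia <- diastole_duration(p$T, c(p$tdia_slope, p$tdia_intercept))
  t_sys <- p$T - t_dia

  if (p$stenosis_enabled) {
    geom <- stenosis_geometry(p$pct_s, D0 = p$D0_g, l_s = p$l_s,
                              K_t = p$K_t, K_u = p$K_u)
    st <- stenosis_coefficients(geom, p$mu, p$rho)
  } else {
    st <- list(R_v = 0, K_turb = 0, L_u = 0)
  }

  lay <- layer_constants(p)
  vu1 <- lay$V0_1 - lay$C1 * P1_REF
  vu2 <- lay$V0_2 - lay$C2 * P2_REF

  ctx <- c(p$T, t_sys, p$E_max_lv, p$E_min_lv, p$E_max_rv, p$E_min_rv,
           p$V0_lv, p$V0_rv,
           p$R_mv, p$R_av, p$R_tv, p$R_pv,
           p$C_sa, p$L_sa, p$R0_svb, p$C_sv,
           p$C_pa, p$L_pa, p$R_pvb, p$C_pv,
           p$R_graft, p$L_graft + st$L_u, st$R_v, st$K_turb,
           VU_SA, VU_SV, VU_PA, VU_PU, VALVE_W,
           C_COR, V0_COR - C_COR * P_COR_REF,
           C_GP, V0_GP - C_GP * P_COR_REF,
           as.numeric(p$stenosis_enabled),
           lay$depth, lay$C1, lay$C2, lay$V0_1, lay$V0_2,
           lay$R0_a, lay$R0_m, lay$R_v, vu1, vu2)
  stopifnot(length(ctx) == 64)
  ctx
}

#' Initial state of the 0D model
#'
#' Builds a physiologically plausible starting state: compartments are set
#' to nominal resting pressures and the intramyocardial layers to their
#' reference volumes; the systemic venous compartment absorbs whatever
#' volume remains of `V_total`, so total blood volume is exactly
#' `params$V_total`.
#'
#' @param params A `graft_params` object.
#' @return Named numeric state vector (17 entries; volumes in mL, inertial
#'   flows in mL/s).
#' @export
initial_state <- function(params) {
  p <- params
  lay <- layer_constants(p)
  vu1 <- lay$V0_1 - lay$C1 * P1_REF
  vu2 <- lay$V0_2 - lay$C2 * P2_REF
  # start the graft flow near its resistive steady value so severe
  # stenoses do not see a violent initial transient
  r_sten <- if (p$stenosis_enabled) {
    geom <- stenosis_geometry(p$pct_s, D0 = p$D0_g, l_s = p$l_s,
                              K_t = p$K_t, K_u = p$K_u)
    stenosis_coefficients(geom, p$mu, p$rho)$R_v
  } else 0
  q_g0 <- min(0.8, 85 / (p$R_graft + r_sten + 100))
  y <- c(V_lv = 130, V_rv = 140,
         V_sa = VU_SA + p$C_sa * 85,
         V_sv = 0,
         V_pa = VU_PA + p$C_pa * 16,
         V_pu = VU_PU + p$C_pv * 8,
         Q_sa = 70, Q_pa = 70, Q_g = q_g0, V_gp = V0_GP, V_cor = V0_COR,
         V1_epi = lay$V0_1[1], V1_mid = lay$V0_1[2], V1_endo = lay$V0_1[3],
         V2_epi = lay$V0_2[1], V2_mid = lay$V0_2[2], V2_endo = lay$V0_2[3])
  vol_idx <- setdiff(STATE_NAMES, c("Q_sa", "Q_pa", "Q_g"))
  y["V_sv"] <- p$V_total - sum(y[setdiff(vol_idx, "V_sv")])
  if (y["V_sv"] <= 0) {
    stop("V_total too small to fill the circulation", call. = FALSE)
  }
  y[STATE_NAMES]
}

#' Time derivative of the model state
#'
#' Evaluates the network right-hand side at one instant: chamber elastances
#' from the activation waveform, pressure-gated valve flows, the graft
#' branch with its optional stenosis element, and the three intramyocardial
#' layers with volume-dependent resistances and depth-scaled
#' intramyocardial pressure.  Volume rates sum to zero exactly (closed
#' loop).
#'
#' @param state Named numeric state vector as from [initial_state()].
#' @param t Time (s).
#' @param params A `graft_params` object.
#' @return Named numeric vector of rates, same layout as `state`.
#' @export
state_derivative <- function(state, t, params) {
  ctx <- build_sim_context(params)
  dy <- rhs0d_cpp(as.numeric(state[STATE_NAMES]), t, ctx)
  if (any(!is.finite(dy))) {
    bad <- STATE_NAMES[!is.finite(dy)]
    stop("non-finite state derivative in compartment(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  stats::setNames(dy, STATE_NAMES)
}

#' Simulate the closed-loop 0D model
#'
#' Integrates the model over `n_beats` cardiac periods with the fixed-step
#' classical Runge-Kutta scheme.  Signals are recorded on a uniform grid;
#' aortic valve open/close events are extracted per beat; convergence to a
#' periodic steady state is flagged when the last two beats agree to a
#' relative L2 residual below `tol` on both aortic pressure and graft
#' flow.
#'
#' @param params A `graft_params` object (see [default_parameters()]).
#' @param n_beats Number of cardiac periods to integrate (>= 2, default 10).
#' @param dt Integration step (s); default `min(T/2000, 4e-4)`.  Must
#'   resolve the beat (`dt <= T/500`).
#' @param store_dt Output sampling interval (s); default `T/1000` (rounded
#'   to a multiple of `dt`).
#' @param y0 Optional initial state (defaults to [initial_state()]).
#' @param tol Beat-periodicity residual threshold for the convergence flag.
#' @return Object of class `graft_sim`: list with `time` (s), `signals`
#'   (data.frame of named waveforms), `events` (aortic valve open/close per
#'   beat), `n_beats`, `dt`, `converged`, `residuals` (beat-to-beat L2
#'   residual per beat), `volume_drift` (relative total-volume span), and
#'   `params`.
#' @export
#' @examples
#' \donttest{
#' sim <- simulate_graftflow(default_parameters(), n_beats = 6)
#' sim$converged
#' }
simulate_graftflow <- function(params, n_beats = 10, dt = NULL,
                               store_dt = NULL, y0 = NULL, tol = 1e-3) {
  if (n_beats < 2) stop("n_beats must be >= 2", call. = FALSE)
  ctx <- build_sim_context(params)
  T <- params$T
  if (is.null(dt)) {
    dt <- min(T / 2000, 4e-4)
    if (params$stenosis_enabled) {
      # the algebraic stenosis resistor couples the two graft-branch
      # compliances; keep the explicit scheme inside the stability
      # region of that fastest mode (ctx[23] is the viscous stenosis
      # resistance in mmHg.s/mL)
      c_ser <- C_GP * C_COR / (C_GP + C_COR)
      dt <- min(dt, 1.2 * c_ser * ctx[23])
    }
  }
  if (dt > T / 500) stop("dt must resolve the beat (dt <= T/500)",
                         call. = FALSE)
  # make the beat an exact number of steps so beats align on the grid
  steps_per_beat <- ceiling(T / dt)
  dt <- T / steps_per_beat
  if (is.null(store_dt)) store_dt <- T / 1000
  stride <- max(1L, round(store_dt / dt))
  # stride must divide the beat so stored samples align beat-to-beat
  while (steps_per_beat %% stride != 0) stride <- stride - 1L
  n_steps <- steps_per_beat * n_beats

  if (is.null(y0)) y0 <- initial_state(params)
  res <- sim0d_cpp(as.numeric(y0[STATE_NAMES]), ctx, dt, n_steps, stride)
  if (!res$ok) {
    stop(sprintf("integration diverged at t = %.4f s (non-finite state or ",
                 res$fail_step * dt),
         "collapsed intramyocardial volume)", call. = FALSE)
  }
  sig <- as.data.frame(res$signals)
  names(sig) <- c("time_s", SIGNAL_NAMES)

  per_beat <- steps_per_beat %/% stride
  residuals <- beat_residuals(sig, per_beat, n_beats)
  drift <- diff(range(sig$V_tot)) / sig$V_tot[1]
  events <- valve_events(sig$time_s, sig$q_av, T, n_beats)

  out <- list(time = sig$time_s, signals = sig, events = events,
              n_beats = n_beats, dt = dt,
              converged = is.finite(residuals[length(residuals)]) &&
                          residuals[length(residuals)] < tol,
              residuals = residuals, volume_drift = drift,
              y_final = stats::setNames(as.numeric(res$y_final), STATE_NAMES),
              params = params)
  class(out) <- "graft_sim"
  out
}

# Beat-to-beat relative L2 residual on aortic pressure and graft flow;
# residual k compares beat k with beat k-1 (k = 2..n_beats).
beat_residuals <- function(sig, per_beat, n_beats) {
  resid <- numeric(n_beats - 1)
  for (k in 2:n_beats) {
    i1 <- ((k - 2) * per_beat + 1):((k - 1) * per_beat)
    i2 <- ((k - 1) * per_beat + 1):(k * per_beat)
    r_p <- sqrt(sum((sig$p_ao[i2] - sig$p_ao[i1])^2) / sum(sig$p_ao[i2]^2))
    qs <- sum(sig$q_graft[i2]^2)
    r_q <- if (qs > 0) sqrt(sum((sig$q_graft[i2] - sig$q_graft[i1])^2) / qs)
           else sqrt(sum((sig$q_graft[i2] - sig$q_graft[i1])^2))
    resid[k - 1] <- max(r_p, r_q)
  }
  resid
}

# Aortic valve open/close times per beat from the q_av waveform.
valve_events <- function(time, q_av, T, n_beats) {
  thr <- max(q_av) * 0.02
  ev <- data.frame(beat = integer(0), t_open = numeric(0),
                   t_close = numeric(0))
  for (k in seq_len(n_beats)) {
    in_beat <- time >= (k - 1) * T & time < k * T
    tt <- time[in_beat]; qq <- q_av[in_beat]
    above <- which(qq > thr)
    if (length(above) < 2) next
    ev <- rbind(ev, data.frame(beat = k, t_open = tt[above[1]],
                               t_close = tt[above[length(above)]]))
  }
  ev
}

#' @export
print.graft_sim <- function(x, ...) {
  cat(sprintf("<graft_sim> %d beats @ T = %.3g s (dt = %.2g ms)\n",
              x$n_beats, x$params$T, 1000 * x$dt))
  lb <- last_beat_window(x)
  i <- x$time >= lb[1] & x$time < lb[2]
  cat(sprintf("  aortic pressure %.0f/%.0f mmHg, graft Q_mean %.1f mL/min\n",
              max(x$signals$p_ao[i]), min(x$signals$p_ao[i]),
              60 * mean(x$signals$q_graft[i])))
  cat(sprintf("  converged: %s (residual %.2e), volume drift %.2e\n",
              x$converged, x$residuals[length(x$residuals)],
              x$volume_drift))
  invisible(x)
}

# time window [start, end) of the last complete beat
last_beat_window <- function(sim) {
  T <- sim$params$T
  c((sim$n_beats - 1) * T, sim$n_beats * T)
}

#' Subendocardial-to-subepicardial flow ratio
#'
#' Ratio of beat-averaged subendocardial to subepicardial layer flow over
#' the last `n_avg` complete beats; the canonical marker of transmural
#' perfusion distribution.
#'
#' @param sim A `graft_sim` object.
#' @param n_avg Number of trailing beats to average (default 3).
#' @return Dimensionless flow ratio.
#' @export
endo_epi_flow_ratio <- function(sim, n_avg = 3) {
  stopifnot(inherits(sim, "graft_sim"))
  T <- sim$params$T
  t0 <- (sim$n_beats - n_avg) * T
  t1 <- sim$n_beats * T
  epi <- phase_integral(sim$time, sim$signals$q_epi, t0, t1)
  if (abs(epi) < .Machine$double.eps * 100) {
    stop("subepicardial mean flow is zero; ratio undefined", call. = FALSE)
  }
  phase_integral(sim$time, sim$signals$q_endo, t0, t1) / epi
}

#' Write simulation waveforms to CSV
#'
#' Writes the recorded signals as a CSV with a header row, `time_s` first
#' and the named signals in a fixed, deterministic order, plus a JSON
#' sidecar with run metadata (parameter hash, step size, beat count,
#' convergence flag).
#'
#' @param sim A `graft_sim` object.
#' @param path Output CSV path; metadata goes to `paste0(path, ".json")`.
#' @param signals Which signal columns to write (default: all).
#' @return `path`, invisibly.
#' @export
write_waveforms <- function(sim, path, signals = SIGNAL_NAMES) {
  stopifnot(inherits(sim, "graft_sim"))
  df <- sim$signals[, c("time_s", signals)]
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(params_hash = config_hash(sim$params),
               dt = sim$dt, n_beats = sim$n_beats,
               converged = sim$converged)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
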