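# Shared fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

# default 10-beat simulation, cached
default_sim <- function() {
  if (is.null(.fixture_env$sim)) {
    .fixture_env$sim <- simulate_graftflow(default_parameters(),
                                           n_beats = 10)
  }
  .fixture_env$sim
}

# 75%-stenosis simulation, cached
stenosed_sim <- function() {
  if (is.null(.fixture_env$sim75)) {
    .fixture_env$sim75 <- simulate_graftflow(
      default_parameters(list(pct_s = 75)), n_beats = 10)
  }
  .fixture_env$sim75
}

# synthetic clinical-style record: tiled analytic waveforms + markers
synthetic_record <- function(n_beats = 5, T = 0.8, t_sys = 0.3,
                             dt = 0.002) {
  time <- seq(0, n_beats * T, by = dt)
  tb <- time %% T
  # smooth, exactly T-periodic waveforms (continuous across beats)
  flow <- 0.8 + 0.3 * sin(2 * pi * tb / T) + 0.2 * sin(4 * pi * tb / T)
  pressure <- 95 + 25 * sin(2 * pi * (tb - 0.1) / T)
  markers <- data.frame(beat_start_s = (0:(n_beats - 1)) * T,
                        systole_end_s = (0:(n_beats - 1)) * T + t_sys)
  list(time = time, flow = flow, pressure = pressure, markers = markers,
       T = T, t_sys = t_sys)
}

# equilibrium state with every network pressure equal to P (diastole)
equilibrium_state <- function(params, P = 8) {
  lay <- layer_constants(params)
  vu1 <- lay$V0_1 - lay$C1 * 60
  vu2 <- lay$V0_2 - lay$C2 * 15
  depth <- lay$depth
  st <- initial_state(params)
  st["V_lv"] <- params$V0_lv + P / params$E_min_lv
  st["V_rv"] <- params$V0_rv + P / params$E_min_rv
  st["V_sa"] <- 500 + params$C_sa * P
  st["V_sv"] <- 3200 + params$C_sv * P
  st["V_pa"] <- 100 + params$C_pa * P
  st["V_pu"] <- 400 + params$C_pv * P
  st[c("Q_sa", "Q_pa", "Q_g")] <- 0
  st["V_gp"] <- (1.0 - 0.002 * 75) + 0.002 * P
  st["V_cor"] <- (1.0 - 0.001 * 75) + 0.001 * P
  for (j in 1:3) {
    st[paste0("V1_", c("epi", "mid", "endo"))[j]] <-
      vu1[j] + lay$C1[j] * P * (1 - depth[j])
    st[paste0("V2_", c("epi", "mid", "endo"))[j]] <-
      vu2[j] + lay$C2[j] * P * (1 - depth[j])
  }
  st
}
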