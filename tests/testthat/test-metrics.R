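test_that("marker-based segmentation does the beat arithmetic", {
  mk <- data.frame(beat_start_s = c(0, 0.8, 1.6),
                   systole_end_s = c(0.3, 1.1, 1.9))
  seg <- segment_beats(mk, t_end = 2.4)
  expect_equal(nrow(seg), 3)
  expect_equal(seg$T, rep(0.8, 3))
  expect_equal(seg$T_sys, rep(0.3, 3))
  expect_equal(seg$T_dia, rep(0.5, 3))
  expect_equal(seg$T_sys + seg$T_dia, seg$T)

  expect_error(segment_beats(data.frame(beat_start_s = c(1, 0.5),
                                        systole_end_s = c(1.2, 0.7))),
               "increasing")
  expect_error(segment_beats(mk[1, , drop = FALSE], t_end = 0.8),
               "beats")
})

test_that("valve-event segmentation marks systole as the open interval", {
  sim <- default_sim()
  seg <- segment_beats(sim)
  expect_equal(attr(seg, "source"), "valve-events")
  expect_equal(nrow(seg), sim$n_beats - 1)
  expect_equal(seg$t_start, sim$events$t_open[-nrow(sim$events)])
  expect_equal(seg$t_sys_end, sim$events$t_close[-nrow(sim$events)])
  expect_true(all(seg$T_sys > 0 & seg$T_dia > 0))
})

test_that("mean flow integrates the beat and reports mL/min", {
  r <- synthetic_record()
  seg <- segment_beats(r$markers, t_end = max(r$time))
  b <- seg[2, ]

  # constant flow: 50 mL/min in = 50 mL/min out
  expect_equal(q_mean(r$time, rep(50 / 60, length(r$time)), b), 50)

  # zero-mean sinusoid rides on the mean
  qs <- (60 + 40 * sin(2 * pi * r$time / 0.8)) / 60
  expect_equal(q_mean(r$time, qs, b), 60, tolerance = 1e-6)

  # refinement oracle: trapezoid on a 10x finer grid agrees to 0.1%
  tt <- seq(0, 4, by = 0.002)
  qq <- 1 + 0.5 * sin(2 * pi * tt / 0.8) + 0.2 * cos(6 * pi * tt / 0.8)
  tf <- seq(0, 4, by = 2e-4)
  qf <- 1 + 0.5 * sin(2 * pi * tf / 0.8) + 0.2 * cos(6 * pi * tf / 0.8)
  bb <- data.frame(t_start = 0.8, t_sys_end = 1.1, t_end = 1.6)
  expect_equal(q_mean(tt, qq, bb), q_mean(tf, qf, bb), tolerance = 1e-3)

  # gappy sampling is refused
  tg <- tt[-(600:900)]
  expect_error(q_mean(tg, qq[-(600:900)], bb), "gap")
})

test_that("pulsatility index is the normalized flow excursion", {
  r <- synthetic_record()
  seg <- segment_beats(r$markers, t_end = max(r$time))
  b <- seg[2, ]

  expect_equal(pulsatility_index(r$time, rep(2, length(r$time)), b), 0)

  # Q_max 100, Q_min 20, Q_mean 60 -> PI = 4/3
  qs <- 60 + 40 * sin(2 * pi * (r$time - 0.8) / 0.8)
  expect_equal(pulsatility_index(r$time, qs, b), 4 / 3, tolerance = 1e-4)

  # invariant under positive rescaling
  expect_equal(pulsatility_index(r$time, 7.3 * qs, b),
               pulsatility_index(r$time, qs, b), tolerance = 1e-12)

  expect_error(pulsatility_index(r$time, sin(2 * pi * r$time / 0.8), b),
               "Q_mean")
})

test_that("D/S-ratio and DF% come from absolute delivered volumes", {
  # equal |Q| in both phases and T_sys = T_dia -> DS = 1, DF = 50
  tt <- seq(0, 2.4, by = 0.001)
  mk <- data.frame(beat_start_s = c(0, 0.8, 1.6),
                   systole_end_s = c(0.4, 1.2, 2.0))
  seg <- segment_beats(mk, t_end = 2.4)
  out <- ds_ratio_and_df(tt, rep(1.5, length(tt)), seg[2, ])
  expect_equal(out$DS_ratio, 1, tolerance = 1e-9)
  expect_equal(out$DF_pct, 50, tolerance = 1e-9)

  # flow negative in diastole still delivers volume (absolute value)
  q <- ifelse(tt %% 0.8 < 0.4, 1, -1)
  out2 <- ds_ratio_and_df(tt, q, seg[2, ])
  expect_gt(out2$DS_ratio, 0.99)

  expect_error(ds_ratio_and_df(tt, ifelse(tt %% 0.8 < 0.4, 0, 1),
                               seg[2, ]), "systolic")
})

test_that("DRI follows the phase-quotient arithmetic", {
  tt <- seq(0, 2.4, by = 5e-4)
  mk <- data.frame(beat_start_s = c(0, 0.8, 1.6),
                   systole_end_s = c(0.3, 1.1, 1.9))
  seg <- segment_beats(mk, t_end = 2.4)
  b <- seg[2, ]
  in_sys <- (tt %% 0.8) < 0.3
  p <- ifelse(in_sys, 100, 80)
  q <- ifelse(in_sys, 25, 40)
  # (80/40) / (100/25) = 0.5
  expect_equal(dri(tt, q, p, b), 0.5, tolerance = 5e-3)

  # equal phase pressures, equal durations, DS = 1 -> DRI = 1
  mk2 <- data.frame(beat_start_s = c(0, 0.8, 1.6),
                    systole_end_s = c(0.4, 1.2, 2.0))
  b2 <- segment_beats(mk2, t_end = 2.4)[2, ]
  expect_equal(dri(tt, rep(3, length(tt)), rep(90, length(tt)), b2), 1,
               tolerance = 1e-9)

  expect_error(dri(tt, rep(0, length(tt)), p, b), "phase-mean")
})

test_that("metric identities hold on every computed beat", {
  for (sim in list(default_sim(), stenosed_sim())) {
    pm <- sim_metrics(sim)
    pb <- pm$per_beat
    expect_equal(pb$DF_pct, 100 * pb$DS_ratio / (1 + pb$DS_ratio),
                 tolerance = 1e-9)
    # DRI = (p_dia/p_sys) (T_dia/T_sys) / DS on each beat
    seg <- segment_beats(sim)
    for (k in seq_len(nrow(seg))) {
      b <- seg[k, ]
      p_s <- graftflow:::phase_mean(sim$time, sim$signals$p_probe,
                                    b$t_start, b$t_sys_end)
      p_d <- graftflow:::phase_mean(sim$time, sim$signals$p_probe,
                                    b$t_sys_end, b$t_end)
      rhs <- (p_d / p_s) * (b$T_dia / b$T_sys) / pb$DS_ratio[k]
      expect_equal(pb$DRI[k], rhs, tolerance = 1e-9)
    }
  }
})

test_that("metrics are invariant to time shift and scale as claimed", {
  r <- synthetic_record()
  seg <- segment_beats(r$markers, t_end = max(r$time))
  pm <- patency_metrics(r$time, r$flow, seg, pressure = r$pressure)

  shift <- 12.5
  mk2 <- r$markers + shift
  names(mk2) <- names(r$markers)
  seg2 <- segment_beats(mk2, t_end = max(r$time) + shift)
  pm2 <- patency_metrics(r$time + shift, r$flow, seg2,
                         pressure = r$pressure)
  expect_equal(pm$median, pm2$median, tolerance = 1e-9)

  pm3 <- patency_metrics(r$time, 3 * r$flow, seg, pressure = r$pressure)
  expect_equal(pm3$median[["Q_mean"]], 3 * pm$median[["Q_mean"]])
  expect_equal(pm3$median[["PI"]], pm$median[["PI"]], tolerance = 1e-12)
  expect_equal(pm3$median[["DS_ratio"]], pm$median[["DS_ratio"]],
               tolerance = 1e-12)
})

test_that("periodic records give identical per-beat values and medians", {
  r <- synthetic_record(n_beats = 6)
  seg <- segment_beats(r$markers, t_end = max(r$time))
  pm <- patency_metrics(r$time, r$flow, seg, pressure = r$pressure)
  for (m in c("Q_mean", "PI", "DS_ratio", "DF_pct", "DRI")) {
    expect_lt(diff(range(pm$per_beat[[m]])), 1e-6)
    expect_equal(pm$median[[m]], pm$per_beat[[m]][1], tolerance = 1e-6)
  }
})

test_that("missing pressure downgrades gracefully to a DRI-less report", {
  r <- synthetic_record()
  seg <- segment_beats(r$markers, t_end = max(r$time))
  expect_warning(pm <- patency_metrics(r$time, r$flow, seg), "DRI")
  expect_true(is.na(pm$median[["DRI"]]))
  expect_false(anyNA(pm$median[c("Q_mean", "PI", "DS_ratio", "DF_pct")]))
})

test_that("file-based records reproduce the in-memory computation", {
  dir <- withr::local_tempdir()
  r <- synthetic_record()
  wf <- file.path(dir, "wave.csv"); mk <- file.path(dir, "markers.csv")
  write.csv(data.frame(time_s = r$time, flow_mls = r$flow,
                       pressure_mmHg = r$pressure), wf, row.names = FALSE)
  write.csv(r$markers, mk, row.names = FALSE)
  pm_file <- record_metrics(wf, mk)
  seg <- segment_beats(r$markers, t_end = max(r$time))
  pm_mem <- patency_metrics(r$time, r$flow, seg, pressure = r$pressure)
  expect_equal(pm_file$median, pm_mem$median, tolerance = 1e-9)

  tidy <- file.path(dir, "tidy.csv")
  write_metrics(pm_file, tidy)
  td <- read.csv(tidy)
  expect_setequal(unique(td$metric),
                  c("Q_mean", "PI", "DS_ratio", "DF_pct", "DRI"))
})
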