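test_that("cohort generation respects counts, classes and the seed", {
  cohort <- generate_cohort(n_patients = 2, grafts_per_patient = 2,
                            seed = 7, n_beats = 8)
  expect_length(cohort, 4)
  expect_equal(41 * 3, 123)  # the default study shape

  cls <- graftflow:::PATENCY_CLASSES
  for (r in cohort) {
    row <- cls[cls$class == r$class, ]
    expect_gte(r$pct_true, row$lower)
    expect_lte(r$pct_true, row$upper)
    expect_gte(nrow(r$markers), 4)
  }

  cohort2 <- generate_cohort(n_patients = 2, grafts_per_patient = 2,
                             seed = 7, n_beats = 8)
  expect_identical(cohort[[3]]$flow_mlmin, cohort2[[3]]$flow_mlmin)
  expect_identical(cohort[[3]]$markers, cohort2[[3]]$markers)

  expect_error(generate_cohort(2, 2, class_mix = c(patent = 0.5,
                                                   questionable = 0.5,
                                                   failed = 0.5)),
               "sum to 1")
})

test_that("noise-free records reproduce the simulator-side metrics", {
  cohort <- generate_cohort(n_patients = 1, grafts_per_patient = 1,
                            class_mix = c(patent = 1, questionable = 0,
                                          failed = 0),
                            seed = 3, noise_sd_mlmin = 0, jitter_sd_ms = 0)
  r <- cohort[[1]]
  # with noise and jitter off, the record waveform with its markers must
  # yield exactly the metrics of the underlying flow samples
  seg <- segment_beats(r$markers, t_end = max(r$time))
  pm <- suppressWarnings(
    patency_metrics(r$time, r$flow_mlmin / 60, seg))
  # the flow-only metrics agree with the simulator's own valve-event
  # metrics to within beat-segmentation differences
  expect_equal(pm$median[["Q_mean"]], r$sim_metrics[["Q_mean"]],
               tolerance = 0.02)
  expect_equal(pm$median[["DS_ratio"]], r$sim_metrics[["DS_ratio"]],
               tolerance = 0.05)
})

test_that("central-pressure estimation matches closed forms", {
  T <- 0.8
  tt <- seq(0, 4 * T, by = 0.001)

  expect_equal(estimate_central_pressure(tt, rep(90, length(tt)), T),
               c(SBP_est = 90, DBP_est = 90))

  # sinusoid: the moving average of width w attenuates the peak by
  # sin(pi w / T) / (pi w / T)
  M <- 100; A <- 20
  p <- M + A * sin(2 * pi * tt / T)
  est <- estimate_central_pressure(tt, p, T, window_fraction = 0.25)
  expect_equal(est[["SBP_est"]], M + A * sin(pi / 4) / (pi / 4),
               tolerance = 1e-3)
  expect_equal(est[["DBP_est"]], M - A, tolerance = 1e-6)

  # vanishing window recovers the raw maximum
  est0 <- estimate_central_pressure(tt, p, T, window_fraction = 0.003)
  expect_equal(est0[["SBP_est"]], M + A, tolerance = 1e-3)

  expect_error(estimate_central_pressure(tt, p, T, window_fraction = 0.7),
               "window_fraction")
  expect_error(estimate_central_pressure(tt[tt < 0.5], p[tt < 0.5], T),
               "full beat")

  # bounds property on arbitrary waveforms
  set.seed(11)
  for (k in 1:5) {
    pw <- 80 + cumsum(stats::rnorm(length(tt), 0, 0.5))
    e <- estimate_central_pressure(tt, pw, T, window_fraction = 0.3)
    expect_lte(e[["SBP_est"]], max(pw))
    expect_gte(e[["SBP_est"]], mean(pw) - 1e-9)
  }
})

test_that("relative MAD behaves as a robust scale-free dispersion", {
  expect_equal(mad_over_median(rep(3, 5)), 0)
  expect_equal(mad_over_median(c(1, 2, 3, 4, 5)), 1 / 3)
  x <- c(2.3, 5.1, 4.4, 8, 3.3)
  expect_equal(mad_over_median(17 * x), mad_over_median(x))
  expect_error(mad_over_median(c(-1, 0, 1)), "median")
  expect_error(mad_over_median(3), "2 finite")
})

test_that("rank tests agree with exact enumeration and detect shifts", {
  set.seed(21)
  a <- c(1.2, 2.1, 2.8, 3.9, 5.1)
  b <- c(2.0, 3.1, 3.4, 4.8, 6.0, 6.5)

  # brute-force rank-sum enumeration oracle (two-sided)
  pooled <- c(a, b)
  ranks <- rank(pooled)
  w_obs <- sum(ranks[seq_along(a)]) - length(a) * (length(a) + 1) / 2
  combos <- utils::combn(length(pooled), length(a))
  w_all <- apply(combos, 2, function(i) {
    sum(ranks[i]) - length(a) * (length(a) + 1) / 2
  })
  mu <- mean(w_all)
  p_exact <- mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-12)

  p_norm <- compare_groups(a, b, method = "normal")$p_value
  expect_lt(abs(p_norm - p_exact), 0.02)

  # identical groups sit at the null
  same <- compare_groups(c(1, 2, 3, 4), c(1, 2, 3, 4),
                         method = "normal")
  expect_gt(same$p_value, 0.9)

  # a large planted shift at n = 20/20 is overwhelming evidence
  g1 <- stats::rnorm(20, 0, 1)
  g2 <- stats::rnorm(20, 4, 1)
  expect_lt(compare_groups(g1, g2)$p_value, 0.001)

  # paired path and its degenerate guard
  expect_error(compare_groups(c(1, 2), c(1, 2), paired = TRUE),
               "tied")
  pr <- compare_groups(g1, g1 + 2 + stats::rnorm(20, 0, 0.1),
                       paired = TRUE)
  expect_lt(pr$p_value, 0.001)
  expect_error(compare_groups(1:3, 1:4, paired = TRUE), "equal lengths")
})

test_that("class summaries report medians, variability, tests, trends", {
  set.seed(5)
  mk_rows <- function(cls, n, q_shift) {
    data.frame(patient_id = seq_len(n), graft_id = 1, class = cls,
               pct_true = 10,
               Q_mean = stats::rnorm(n, 40 - q_shift, 1),
               PI = stats::rnorm(n, 2 + q_shift / 20, 0.1),
               DS_ratio = stats::rnorm(n, 3 - q_shift / 10, 0.05),
               DF_pct = 70, DRI = stats::rnorm(n, 0.5 + q_shift / 30, 0.02),
               SAP = stats::rnorm(n, 120, 5), DAP = stats::rnorm(n, 78, 4),
               MAP = stats::rnorm(n, 93, 4), PP = stats::rnorm(n, 42, 4),
               T = stats::rnorm(n, 0.8, 0.05),
               DTF = stats::rnorm(n, 0.55, 0.02))
  }
  df <- rbind(mk_rows("patent", 12, 0), mk_rows("questionable", 10, 10),
              mk_rows("failed", 8, 25))
  s <- summarize_by_class(df)
  expect_equal(s$trend$direction[s$trend$metric == "Q_mean"], "decreasing")
  expect_equal(s$trend$direction[s$trend$metric == "DS_ratio"],
               "decreasing")
  cs <- s$class_summary
  expect_true(all(cs$q1 <= cs$median & cs$median <= cs$q3))
  expect_true(all(s$variability$mad_over_median >= 0))
  expect_equal(nrow(s$tests), 2 * 5)
  # planted Q_mean separation is detected between successive classes
  pq <- s$tests$p_value[s$tests$metric == "Q_mean"]
  expect_true(all(pq < 0.01))

  expect_message(s1 <- summarize_by_class(mk_rows("patent", 6, 0)),
                 "single-class")
  expect_null(s1$tests)
  expect_error(summarize_by_class(df[c(1, 13), ]), "fewer than")
})

test_that("cohort metrics and on-disk layout fit the record contract", {
  cohort <- generate_cohort(n_patients = 2, grafts_per_patient = 2,
                            seed = 13, n_beats = 8)
  met <- cohort_metrics(cohort)
  expect_equal(nrow(met), 4)
  expect_true(all(c("Q_mean", "DS_ratio", "DRI", "SAP", "DAP", "MAP",
                    "PP", "T", "DTF") %in% names(met)))
  expect_true(all(met$SAP > met$DAP))
  expect_true(all(met$T > 0.3 & met$T < 1.5))

  dir <- withr::local_tempdir()
  manifest <- write_cohort(cohort, dir)
  mf <- read.csv(manifest)
  expect_equal(nrow(mf), 4)
  expect_true(all(file.exists(file.path(dir, mf$waveform))))
  expect_true(all(file.exists(file.path(dir, mf$markers))))
  wf <- read.csv(file.path(dir, mf$waveform[1]))
  expect_identical(names(wf), c("time_s", "flow_mls", "pressure_mmHg"))
})
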