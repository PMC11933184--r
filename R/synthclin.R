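# Synthetic clinical-cohort generator and comparison statistics.  Each
# record mimics an intraoperative TTFM measurement: a graft flow waveform
# (mL/min), a peripheral (radial-like) pressure waveform derived from the
# simulated central pressure by a resonant low-pass transform with
# systolic amplification and delay, ECG-like beat markers with jitter,
# and a patency-class label tied to the hidden true stenosis percentage.

# patency-class convention on true diameter reduction; configurable
PATENCY_CLASSES <- data.frame(
  class = c("patent", "questionable", "failed"),
  lower = c(0, 50, 75),
  upper = c(49, 74, 90)
)

#' Generate a synthetic clinical cohort
#'
#' Per patient, a physiology is drawn from the screening distribution
#' registry (cardiac period, peripheral resistance, elastance, arterial
#' compliance, blood volume); per graft, a patency class is drawn from
#' `class_mix` and a true stenosis percentage from that class's range,
#' the 0D model is run, the central pressure is transformed to a
#' peripheral waveform, and seeded measurement noise and marker jitter
#' are added.  Failed simulations are resampled with bounded retries.
#'
#' @param n_patients Number of patients (default 41).
#' @param grafts_per_patient Grafts per patient (default 3).
#' @param class_mix Named probabilities over `patent`, `questionable`,
#'   `failed`; must sum to 1.
#' @param seed Integer RNG seed; the cohort is fully reproducible.
#' @param noise_sd_mlmin Additive Gaussian flow noise sd (mL/min,
#'   default 2).
#' @param jitter_sd_ms Beat-marker jitter sd (ms, default 10).
#' @param classes Patency-class table (`class`, `lower`, `upper` in true
#'   diameter-reduction %).
#' @param n_beats,dt Simulation settings per record.
#' @param max_retries Resampling budget per graft on simulation failure.
#' @return List of `clinical_record` objects, each a list with `time`
#'   (s), `flow_mlmin`, `pressure_mmHg` (peripheral), `markers`
#'   (data.frame `beat_start_s`, `systole_end_s`), `class`, `pct_true`,
#'   `patient_id`, `graft_id`, and `sim_metrics` (noise-free
#'   simulator-side metrics, for round-trip checks).
#' @export
#' @examples
#' \donttest{
#' cohort <- generate_cohort(n_patients = 2, grafts_per_patient = 2,
#'                           seed = 7)
#' length(cohort)  # 4
#' }
generate_cohort <- function(n_patients = 41, grafts_per_patient = 3,
                            class_mix = c(patent = 0.5,
                                          questionable = 0.3,
                                          failed = 0.2),
                            seed = 1, noise_sd_mlmin = 2,
                            jitter_sd_ms = 10,
                            classes = PATENCY_CLASSES,
                            n_beats = 10, dt = NULL, max_retries = 5) {
  if (abs(sum(class_mix) - 1) > 1e-8) {
    stop("class_mix must sum to 1 over the three classes", call. = FALSE)
  }
  set.seed(seed)
  dists <- morris_distributions()
  phys_names <- c("T", "R0_svb", "E_max_lv", "C_sa", "V_total")
  records <- vector("list", n_patients * grafts_per_patient)
  rec_i <- 0
  retry_log <- integer(0)
  for (pat in seq_len(n_patients)) {
    phys <- draw_physiology(dists, phys_names)
    for (gr in seq_len(grafts_per_patient)) {
      cls <- sample(classes$class, 1, prob = class_mix[classes$class])
      row <- classes[classes$class == cls, ]
      pct <- stats::runif(1, row$lower, row$upper)
      sim <- NULL
      for (try in 0:max_retries) {
        pars <- tryCatch(
          default_parameters(c(phys, list(pct_s = pct))),
          error = function(e) NULL)
        sim <- if (is.null(pars)) NULL else tryCatch(
          simulate_graftflow(pars, n_beats = n_beats, dt = dt),
          error = function(e) NULL)
        if (!is.null(sim)) break
        retry_log <- c(retry_log, pat)
        phys <- draw_physiology(dists, phys_names)
      }
      if (is.null(sim)) {
        stop("simulation kept failing after ", max_retries,
             " resamples (patient ", pat, ")", call. = FALSE)
      }
      rec_i <- rec_i + 1
      records[[rec_i]] <- make_record(sim, cls, pct, pat, gr,
                                      noise_sd_mlmin, jitter_sd_ms)
    }
  }
  attr(records, "n_resampled") <- length(retry_log)
  records
}

draw_physiology <- function(dists, names) {
  u <- stats::runif(length(names))
  d <- dists[match(names, dists$name), ]
  vals <- vapply(seq_along(names), function(j) {
    map_to_physical(matrix(u[j], 1, 1), d[j, , drop = FALSE])[1, 1]
  }, numeric(1))
  stats::setNames(as.list(vals), names)
}

make_record <- function(sim, cls, pct, patient_id, graft_id,
                        noise_sd_mlmin, jitter_sd_ms) {
  # drop the initial transient: keep from the 3rd beat on
  T <- sim$params$T
  keep <- sim$time >= 2 * T
  time <- sim$time[keep] - 2 * T
  flow <- 60 * sim$signals$q_graft[keep]            # mL/min
  central <- sim$signals$p_ao[keep]
  periph <- peripheral_transform(time, central, T)
  flow <- flow + stats::rnorm(length(flow), 0, noise_sd_mlmin)

  ev <- sim$events[sim$events$t_open >= 2 * T, ]
  jit <- function(n) stats::rnorm(n, 0, jitter_sd_ms / 1000)
  markers <- data.frame(
    beat_start_s = ev$t_open - 2 * T + jit(nrow(ev)),
    systole_end_s = ev$t_close - 2 * T + jit(nrow(ev)))
  markers <- markers[order(markers$beat_start_s), ]

  rec <- list(time = time, flow_mlmin = flow, pressure_mmHg = periph,
              markers = markers, class = cls, pct_true = pct,
              patient_id = patient_id, graft_id = graft_id,
              sim_metrics = sim_metrics(sim)$median)
  class(rec) <- "clinical_record"
  rec
}

#' Central-to-peripheral pressure transform
#'
#' Fixture machinery for the cohort generator: a second-order resonant
#' low-pass (natural frequency `f_n`, damping `zeta`) applied to the
#' central waveform plus a pure delay, which reproduces the systolic
#' amplification and rounding seen in radial recordings (about +10 mmHg
#' systolic at the defaults).  Only its inverse direction (central
#' pressure estimation by moving average) is methodologically specified;
#' the forward map is a documented modelling convenience.
#'
#' @param time Sample times (s), uniform grid.
#' @param pressure Central pressure (mmHg).
#' @param T Cardiac period (s) (unused by the filter; kept for
#'   signature symmetry).
#' @param f_n Resonance frequency (Hz, default 5.5).
#' @param zeta Damping ratio (default 0.25).
#' @param delay_s Transmission delay (s, default 0.06).
#' @return Peripheral pressure waveform (mmHg).
#' @export
peripheral_transform <- function(time, pressure, T, f_n = 5.5,
                                 zeta = 0.25, delay_s = 0.06) {
  dtt <- time[2] - time[1]
  wn <- 2 * pi * f_n
  # explicit integration of y'' + 2 zeta wn y' + wn^2 y = wn^2 x
  n <- length(pressure)
  y <- numeric(n); v <- 0
  y[1] <- pressure[1]
  for (i in 2:n) {
    a <- wn^2 * (pressure[i - 1] - y[i - 1]) - 2 * zeta * wn * v
    v <- v + a * dtt
    y[i] <- y[i - 1] + v * dtt
  }
  shift <- round(delay_s / dtt)
  if (shift > 0) y <- c(rep(y[1], shift), y[seq_len(n - shift)])
  y
}

#' Estimate central pressures from a peripheral waveform
#'
#' N-point moving-average estimator: the systolic central pressure is the
#' maximum of the moving average of the peripheral waveform with a window
#' of `window_fraction * T` seconds; the diastolic estimate is the
#' waveform minimum over the record.
#'
#' @param time Sample times (s), uniform grid covering >= 1 full beat.
#' @param pressure Peripheral pressure (mmHg).
#' @param T Cardiac period (s).
#' @param window_fraction Window length as a fraction of `T`, in
#'   `(0, 0.5]` (default 0.25).
#' @return Named vector `c(SBP_est, DBP_est)` (mmHg).
#' @export
estimate_central_pressure <- function(time, pressure, T,
                                      window_fraction = 0.25) {
  if (window_fraction <= 0 || window_fraction > 0.5) {
    stop("window_fraction must be in (0, 0.5]", call. = FALSE)
  }
  dtt <- stats::median(diff(time))
  span <- max(time) - min(time)
  if (span < T) stop("need at least one full beat", call. = FALSE)
  win <- window_fraction * T
  if (win >= span) stop("window longer than the record", call. = FALSE)
  N <- max(1L, round(win / dtt))
  ma <- stats::filter(pressure, rep(1 / N, N), sides = 2)
  c(SBP_est = max(ma, na.rm = TRUE), DBP_est = min(pressure))
}

#' Median absolute deviation relative to the median
#'
#' Robust relative-variability measure `median(|x - median(x)|) /
#' median(x)`; scale invariant for positive rescaling.
#'
#' @param values Numeric vector (>= 2 finite values, nonzero median).
#' @return Dimensionless variability.
#' @export
#' @examples
#' mad_over_median(c(1, 2, 3, 4, 5))  # 1/3
mad_over_median <- function(values) {
  v <- values[is.finite(values)]
  if (length(v) < 2) stop("need at least 2 finite values", call. = FALSE)
  m <- stats::median(v)
  if (m == 0) stop("median is zero; relative MAD undefined", call. = FALSE)
  stats::median(abs(v - m)) / m
}

#' Nonparametric two-group comparison
#'
#' Wilcoxon rank-sum test for independent groups or signed-rank test for
#' paired samples.  `method = "normal"` forces the normal approximation
#' (with continuity correction); `"exact"` forces exact computation;
#' `"auto"` lets the sample size decide.
#'
#' @param a,b Numeric vectors; equal length required when `paired`.
#' @param paired Logical.
#' @param method One of `"auto"`, `"exact"`, `"normal"`.
#' @return List with `statistic`, `p_value`, `method`, `n`.
#' @export
compare_groups <- function(a, b, paired = FALSE,
                           method = c("auto", "exact", "normal")) {
  method <- match.arg(method)
  if (paired) {
    if (length(a) != length(b)) {
      stop("paired comparison needs equal lengths", call. = FALSE)
    }
    if (all(a == b)) {
      stop("all paired differences tied; test degenerate", call. = FALSE)
    }
  }
  exact <- switch(method, auto = NULL, exact = TRUE, normal = FALSE)
  wt <- stats::wilcox.test(a, b, paired = paired, exact = exact,
                           correct = TRUE)
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       method = wt$method, n = c(length(a), length(b)))
}

#' Patency metrics of every record in a cohort
#'
#' Marker-based segmentation on each record's flow (converted to mL/s)
#' and peripheral pressure; returns one row of across-beat medians per
#' record, plus the record's hemodynamic summary parameters (estimated
#' systolic/diastolic/mean arterial pressure, pulse pressure, cardiac
#' period, diastolic time fraction).
#'
#' @param records List of `clinical_record` objects.
#' @param window_fraction Central-pressure estimator window (see
#'   [estimate_central_pressure()]).
#' @return data.frame, one row per record.
#' @export
cohort_metrics <- function(records, window_fraction = 0.25) {
  rows <- lapply(records, function(r) {
    seg <- segment_beats(r$markers, t_end = max(r$time))
    pm <- suppressWarnings(
      patency_metrics(r$time, r$flow_mlmin / 60, seg,
                      pressure = r$pressure_mmHg))
    T_med <- stats::median(seg$T)
    cp <- estimate_central_pressure(r$time, r$pressure_mmHg, T_med,
                                    window_fraction)
    data.frame(patient_id = r$patient_id, graft_id = r$graft_id,
               class = r$class, pct_true = r$pct_true,
               Q_mean = pm$median[["Q_mean"]], PI = pm$median[["PI"]],
               DS_ratio = pm$median[["DS_ratio"]],
               DF_pct = pm$median[["DF_pct"]], DRI = pm$median[["DRI"]],
               SAP = cp[["SBP_est"]], DAP = cp[["DBP_est"]],
               MAP = mean(r$pressure_mmHg),
               PP = cp[["SBP_est"]] - cp[["DBP_est"]],
               T = T_med, DTF = stats::median(seg$T_dia / seg$T))
  })
  do.call(rbind, rows)
}

#' Summarise a cohort by patency class
#'
#' Median and IQR of each patency metric per class, MAD/median
#' variability of the hemodynamic parameters, rank-sum tests between
#' successive severity classes, and the monotone-trend direction of the
#' class medians per metric.  Single-class cohorts skip the between-class
#' tests with a notice.
#'
#' @param metrics_df Output of [cohort_metrics()].
#' @param min_per_class Minimum records required per represented class.
#' @return Object of class `cohort_summary`: list with `class_summary`,
#'   `variability`, `tests` (or NULL), `trend`.
#' @export
summarize_by_class <- function(metrics_df, min_per_class = 2) {
  cls_order <- PATENCY_CLASSES$class
  present <- cls_order[cls_order %in% metrics_df$class]
  counts <- table(metrics_df$class)[present]
  if (any(counts < min_per_class)) {
    stop("class(es) with fewer than ", min_per_class, " records: ",
         paste(names(counts)[counts < min_per_class], collapse = ", "),
         call. = FALSE)
  }
  metric_names <- c("Q_mean", "PI", "DS_ratio", "DF_pct", "DRI")
  hemo_names <- c("SAP", "DAP", "MAP", "PP", "T", "DTF")

  cs <- do.call(rbind, lapply(present, function(cl) {
    sub <- metrics_df[metrics_df$class == cl, ]
    do.call(rbind, lapply(metric_names, function(m) {
      q <- stats::quantile(sub[[m]], c(0.25, 0.5, 0.75), na.rm = TRUE)
      data.frame(class = cl, metric = m, q1 = q[[1]], median = q[[2]],
                 q3 = q[[3]], n = nrow(sub))
    }))
  }))
  variability <- data.frame(
    parameter = hemo_names,
    mad_over_median = vapply(hemo_names, function(h) {
      mad_over_median(metrics_df[[h]])
    }, numeric(1)))

  tests <- NULL
  if (length(present) >= 2) {
    tests <- do.call(rbind, lapply(seq_len(length(present) - 1),
                                   function(i) {
      a_cl <- present[i]; b_cl <- present[i + 1]
      do.call(rbind, lapply(metric_names, function(m) {
        a <- metrics_df[[m]][metrics_df$class == a_cl]
        b <- metrics_df[[m]][metrics_df$class == b_cl]
        ok <- sum(is.finite(a)) >= 2 && sum(is.finite(b)) >= 2
        p <- if (ok) suppressWarnings(
          compare_groups(a[is.finite(a)], b[is.finite(b)])$p_value)
          else NA_real_
        data.frame(metric = m, class_a = a_cl, class_b = b_cl,
                   p_value = p)
      }))
    }))
  } else {
    message("single-class cohort: between-class tests skipped")
  }

  trend <- do.call(rbind, lapply(metric_names, function(m) {
    med <- vapply(present, function(cl) {
      stats::median(metrics_df[[m]][metrics_df$class == cl], na.rm = TRUE)
    }, numeric(1))
    dir <- if (length(med) < 2) "n/a"
      else if (all(diff(med) < 0)) "decreasing"
      else if (all(diff(med) > 0)) "increasing"
      else "non-monotone"
    data.frame(metric = m, direction = dir)
  }))

  out <- list(class_summary = cs, variability = variability,
              tests = tests, trend = trend)
  class(out) <- "cohort_summary"
  out
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("<cohort_summary>\n  class medians:\n")
  med <- stats::reshape(
    x$class_summary[, c("class", "metric", "median")],
    direction = "wide", idvar = "metric", timevar = "class")
  print(med, row.names = FALSE, digits = 3)
  cat("  trend directions:",
      paste(x$trend$metric, x$trend$direction, sep = "=",
            collapse = ", "), "\n")
  invisible(x)
}

#' Write a cohort to disk
#'
#' One waveform CSV (`time_s`, `flow_mls`, `pressure_mmHg`) and one
#' marker CSV per record, plus a cohort manifest CSV with ids, class and
#' true stenosis percentage.
#'
#' @param records List of `clinical_record` objects.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(records, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- do.call(rbind, lapply(records, function(r) {
    stem <- sprintf("p%03d_g%02d", r$patient_id, r$graft_id)
    utils::write.csv(data.frame(time_s = r$time,
                                flow_mls = r$flow_mlmin / 60,
                                pressure_mmHg = r$pressure_mmHg),
                     file.path(dir, paste0(stem, "_waveform.csv")),
                     row.names = FALSE)
    utils::write.csv(r$markers,
                     file.path(dir, paste0(stem, "_markers.csv")),
                     row.names = FALSE)
    data.frame(patient_id = r$patient_id, graft_id = r$graft_id,
               class = r$class, pct_true = r$pct_true,
               waveform = paste0(stem, "_waveform.csv"),
               markers = paste0(stem, "_markers.csv"))
  }))
  path <- file.path(dir, "cohort_manifest.csv")
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}
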