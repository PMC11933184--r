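# Beat segmentation and the five TTFM patency metrics.  Phase integrals
# use the trapezoid rule on the native sampling grid with linear
# interpolation at phase boundaries; across-beat summaries are medians.

#' Segment a record into beats with systole/diastole intervals
#'
#' Two segmentation sources are supported.  For a simulation
#' (`graft_sim`), systole is the aortic-valve open interval of each beat
#' and diastole the remainder, mirroring how a model exposes its own valve
#' events.  For clinical-style records, beat-start (R-peak-like) and
#' systole-end marker times are supplied directly, as produced by
#' ECG-based systole/diastole detection.  Incomplete edge beats are
#' discarded.
#'
#' @param x A `graft_sim` object, or a data.frame of markers with columns
#'   `beat_start_s` and `systole_end_s`.
#' @param t_end For marker input: end time of the record (s), used to close
#'   the final beat; defaults to the last beat start (dropping it).
#' @return Object of class `beat_segmentation`: data.frame with one row
#'   per complete beat and columns `beat`, `t_start`, `t_sys_end`, `t_end`,
#'   `T`, `T_sys`, `T_dia`, plus attribute `source`.
#' @export
segment_beats <- function(x, t_end = NULL) {
  if (inherits(x, "graft_sim")) {
    ev <- x$events
    if (nrow(ev) < 2) stop("need at least 2 complete beats", call. = FALSE)
    # beat spans valve-open to next valve-open; last open has no successor
    n <- nrow(ev) - 1
    seg <- data.frame(beat = seq_len(n),
                      t_start = ev$t_open[seq_len(n)],
                      t_sys_end = ev$t_close[seq_len(n)],
                      t_end = ev$t_open[seq_len(n) + 1])
    src <- "valve-events"
  } else {
    mk <- as.data.frame(x)
    if (!all(c("beat_start_s", "systole_end_s") %in% names(mk))) {
      stop("markers need columns beat_start_s and systole_end_s",
           call. = FALSE)
    }
    if (is.unsorted(mk$beat_start_s, strictly = TRUE)) {
      stop("beat marker times must be strictly increasing", call. = FALSE)
    }
    if (any(mk$systole_end_s <= mk$beat_start_s)) {
      stop("systole_end_s must follow its beat_start_s", call. = FALSE)
    }
    starts <- mk$beat_start_s
    ends <- c(starts[-1], t_end)
    keep <- !is.na(ends) & ends > starts
    if (sum(keep) < 2) stop("need at least 2 complete beats", call. = FALSE)
    seg <- data.frame(beat = seq_len(sum(keep)),
                      t_start = starts[keep],
                      t_sys_end = mk$systole_end_s[keep],
                      t_end = ends[keep])
    if (any(seg$t_sys_end >= seg$t_end)) {
      stop("systole_end_s must precede the next beat start", call. = FALSE)
    }
    src <- "ECG-markers"
  }
  seg$T <- seg$t_end - seg$t_start
  seg$T_sys <- seg$t_sys_end - seg$t_start
  seg$T_dia <- seg$T - seg$T_sys
  attr(seg, "source") <- src
  class(seg) <- c("beat_segmentation", "data.frame")
  seg
}

# trapezoid integral of y over [t0, t1] with interpolated endpoints
phase_integral <- function(time, y, t0, t1) {
  if (t1 <= t0) stop("empty integration interval", call. = FALSE)
  inside <- time > t0 & time < t1
  d <- diff(time[time >= t0 - (t1 - t0) & time <= t1 + (t1 - t0)])
  if (length(d) == 0 || max(d) > 5 * stats::median(d)) {
    stop("gap in waveform samples inside the beat", call. = FALSE)
  }
  y0 <- stats::approx(time, y, xout = t0, rule = 2)$y
  y1 <- stats::approx(time, y, xout = t1, rule = 2)$y
  tt <- c(t0, time[inside], t1)
  yy <- c(y0, y[inside], y1)
  sum(diff(tt) * (utils::head(yy, -1) + utils::tail(yy, -1)) / 2)
}

phase_mean <- function(time, y, t0, t1) phase_integral(time, y, t0, t1) / (t1 - t0)

#' Mean flow rate of one beat
#'
#' `(1/T) * integral of Q dt` over the beat (trapezoid rule), converted to
#' mL/min (the clinical TTFM display convention).
#'
#' @param time Sample times (s).
#' @param flow Flow samples (mL/s).
#' @param beat One row of a [segment_beats()] segmentation.
#' @return Mean flow (mL/min).
#' @export
q_mean <- function(time, flow, beat) {
  60 * phase_mean(time, flow, beat$t_start, beat$t_end)
}

#' Pulsatility index of one beat
#'
#' `(Q_max - Q_min) / Q_mean` over the beat; dimensionless and invariant
#' to positive rescaling of the flow.
#'
#' @inheritParams q_mean
#' @return Pulsatility index.
#' @export
pulsatility_index <- function(time, flow, beat) {
  qm <- phase_mean(time, flow, beat$t_start, beat$t_end)
  if (abs(qm) < .Machine$double.eps * 100) {
    stop("pulsatility index undefined: Q_mean is zero", call. = FALSE)
  }
  i <- time >= beat$t_start & time <= beat$t_end
  (max(flow[i]) - min(flow[i])) / qm
}

#' Diastolic/systolic volume ratio and diastolic filling percentage
#'
#' Delivered volumes are computed from the absolute flow rate:
#' `V_dia = integral of |Q| over diastole`, `V_sys` likewise over systole;
#' then `DS = V_dia / V_sys` and `DF% = 100 * V_dia / (V_dia + V_sys)`,
#' which makes `DF% = 100 * DS / (1 + DS)` an exact identity.
#'
#' @inheritParams q_mean
#' @return Named list `DS_ratio`, `DF_pct`.
#' @export
ds_ratio_and_df <- function(time, flow, beat) {
  v_sys <- phase_integral(time, abs(flow), beat$t_start, beat$t_sys_end)
  v_dia <- phase_integral(time, abs(flow), beat$t_sys_end, beat$t_end)
  if (v_sys <= 0) {
    stop("D/S-ratio undefined: zero systolic delivered volume",
         call. = FALSE)
  }
  list(DS_ratio = v_dia / v_sys, DF_pct = 100 * v_dia / (v_dia + v_sys))
}

#' Diastolic resistance index of one beat
#'
#' `DRI = (p_dia / |Q|_dia) / (p_sys / |Q|_sys)` with phase means of the
#' pressure and of the absolute flow rate: the ratio of the apparent
#' diastolic to systolic pressure-to-flow quotients.  Diastolic dominance
#' of a patent graft yields DRI below 1; stenosis pushes it up.
#'
#' @inheritParams q_mean
#' @param pressure Pressure samples (mmHg), time-aligned with `flow`.
#' @return Diastolic resistance index (dimensionless).
#' @export
dri <- function(time, flow, pressure, beat) {
  p_sys <- phase_mean(time, pressure, beat$t_start, beat$t_sys_end)
  p_dia <- phase_mean(time, pressure, beat$t_sys_end, beat$t_end)
  q_sys <- phase_mean(time, abs(flow), beat$t_start, beat$t_sys_end)
  q_dia <- phase_mean(time, abs(flow), beat$t_sys_end, beat$t_end)
  if (q_sys <= 0 || q_dia <= 0) {
    stop("DRI undefined: zero phase-mean flow", call. = FALSE)
  }
  (p_dia / q_dia) / (p_sys / q_sys)
}

#' All patency metrics of a record
#'
#' Computes Q_mean, PI, D/S-ratio, DF% and (when a pressure waveform is
#' available) DRI for every complete beat, plus the across-beat median of
#' each metric.  Beats on which a metric is undefined are recorded in the
#' `failed` field and excluded from the medians.
#'
#' @param time Sample times (s).
#' @param flow Flow samples (mL/s).
#' @param seg A [segment_beats()] segmentation.
#' @param pressure Optional pressure samples (mmHg); without it DRI is
#'   omitted with a warning.
#' @return Object of class `patency_metrics`: list with `per_beat`
#'   (data.frame), `median` (named vector), `failed` (data.frame of beat /
#'   metric / message).
#' @export
patency_metrics <- function(time, flow, seg, pressure = NULL) {
  stopifnot(inherits(seg, "beat_segmentation"))
  has_p <- !is.null(pressure)
  if (!has_p) warning("no pressure waveform: DRI unavailable", call. = FALSE)
  rows <- vector("list", nrow(seg))
  failed <- data.frame(beat = integer(0), metric = character(0),
                       message = character(0))
  for (k in seq_len(nrow(seg))) {
    b <- seg[k, ]
    val <- c(Q_mean = NA_real_, PI = NA_real_, DS_ratio = NA_real_,
             DF_pct = NA_real_, DRI = NA_real_)
    grab <- function(metric, expr) {
      tryCatch(expr, error = function(e) {
        failed <<- rbind(failed, data.frame(beat = k, metric = metric,
                                            message = conditionMessage(e)))
        NA_real_
      })
    }
    val["Q_mean"] <- grab("Q_mean", q_mean(time, flow, b))
    val["PI"] <- grab("PI", pulsatility_index(time, flow, b))
    dsdf <- grab("DS_ratio", unlist(ds_ratio_and_df(time, flow, b)))
    if (length(dsdf) == 2) {
      val["DS_ratio"] <- dsdf[1]; val["DF_pct"] <- dsdf[2]
    }
    if (has_p) val["DRI"] <- grab("DRI", dri(time, flow, pressure, b))
    rows[[k]] <- c(beat = k, val)
  }
  per_beat <- as.data.frame(do.call(rbind, rows))
  med <- apply(per_beat[, -1, drop = FALSE], 2, stats::median, na.rm = TRUE)
  if (!has_p) med["DRI"] <- NA_real_
  out <- list(per_beat = per_beat, median = med, failed = failed)
  class(out) <- "patency_metrics"
  out
}

#' @export
print.patency_metrics <- function(x, ...) {
  cat("<patency_metrics> across-beat medians over",
      nrow(x$per_beat), "beats\n")
  m <- x$median
  cat(sprintf("  Q_mean %.1f mL/min | PI %.2f | D/S %.2f | DF%% %.1f | DRI %s\n",
              m["Q_mean"], m["PI"], m["DS_ratio"], m["DF_pct"],
              if (is.na(m["DRI"])) "n/a" else sprintf("%.2f", m["DRI"])))
  invisible(x)
}

#' Patency metrics of a simulation run
#'
#' Convenience wrapper: segments a `graft_sim` by its aortic-valve events
#' and computes the metrics on graft flow and graft probe pressure.
#'
#' @param sim A `graft_sim` object.
#' @return A `patency_metrics` object.
#' @export
sim_metrics <- function(sim) {
  seg <- segment_beats(sim)
  patency_metrics(sim$time, sim$signals$q_graft, seg,
                  pressure = sim$signals$p_probe)
}

#' Read a waveform + marker record and compute its metrics
#'
#' File-based entry point matching the module's external interface: a
#' waveform CSV (`time_s`, `flow_mls`, optional `pressure_mmHg`) and a
#' marker CSV (`beat_start_s`, `systole_end_s`).
#'
#' @param waveform_csv,marker_csv Input file paths.
#' @return A `patency_metrics` object.
#' @export
record_metrics <- function(waveform_csv, marker_csv) {
  wf <- utils::read.csv(waveform_csv)
  mk <- utils::read.csv(marker_csv)
  seg <- segment_beats(mk, t_end = max(wf$time_s))
  p <- if ("pressure_mmHg" %in% names(wf)) wf$pressure_mmHg else NULL
  patency_metrics(wf$time_s, wf$flow_mls, seg, pressure = p)
}

#' Write per-beat metrics as tidy CSV and JSON
#'
#' @param metrics A `patency_metrics` object.
#' @param csv_path Tidy CSV output (one row per beat per metric).
#' @param json_path Optional JSON output with per-beat values and medians.
#' @return `csv_path`, invisibly.
#' @export
write_metrics <- function(metrics, csv_path, json_path = NULL) {
  pb <- metrics$per_beat
  tidy <- do.call(rbind, lapply(setdiff(names(pb), "beat"), function(m) {
    data.frame(beat = pb$beat, metric = m, value = pb[[m]])
  }))
  utils::write.csv(tidy, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(list(per_beat = pb,
                              median = as.list(metrics$median)),
                         json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(csv_path)
}
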