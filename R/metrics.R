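#' Basal localization level of one trace
#'
#' Mean localization index over the pre-shift time points (t < 0), the basal
#' reference level drawn as the black horizontal line in the group figures.
#'
#' @param time,index Time (min) and localization-index vectors.
#' @return Mean pre-shift index, or `NA` if the trace has no pre-shift
#'   points (downstream pulse heights then fall back to the analysis-window
#'   baseline).
#' @export
compute_basal <- function(time, index) {
  pre <- time < 0 & !is.na(index)
  if (!any(pre)) return(NA_real_)
  mean(index[pre])
}

#' Short-term response metrics (initial nuclear accumulation)
#'
#' Maximum localization index in the window directly after the shift, the
#' time of that maximum (first occurrence for ties / monotone traces), and
#' the window mean.
#'
#' @param time,index Trace vectors.
#' @param window Window in minutes, default `c(0, 60)`.
#' @param min_points Minimum in-window points required (default 3).
#' @return List `max_short`, `t_max_short`, `mean_short` (all `NA` when too
#'   few points).
#' @export
short_term_metrics <- function(time, index, window = c(0, 60),
                               min_points = 3) {
  inw <- time >= window[1] & time <= window[2] & !is.na(index)
  if (sum(inw) < min_points)
    return(list(max_short = NA_real_, t_max_short = NA_real_,
                mean_short = NA_real_))
  tw <- time[inw]; xw <- index[inw]
  i <- which.max(xw)
  list(max_short = xw[i], t_max_short = tw[i], mean_short = mean(xw))
}

#' Long-term (adapted-phase) mean localization
#'
#' Mean localization index over the adapted-cell window, missing points
#' skipped; reported as missing when fewer than `min_coverage` of the
#' window's scheduled frames carry a valid measurement.
#'
#' @param time,index Trace vectors (`time` should contain the scheduled
#'   frame times; missing measurements are `NA` in `index`).
#' @param window Window in minutes, default `c(240, 480)`.
#' @param min_coverage Minimum fraction of window frames present.
#' @return Window mean or `NA`.
#' @export
long_term_mean <- function(time, index, window = c(240, 480),
                           min_coverage = 0.5) {
  inw <- time >= window[1] & time <= window[2]
  if (!any(inw)) return(NA_real_)
  ok <- inw & !is.na(index)
  if (sum(ok) / sum(inw) < min_coverage) return(NA_real_)
  mean(index[ok])
}

# Local maxima of x: strictly-lower immediate neighbours; a plateau (run of
# equal values) counts once, at its centre index. Endpoints are not peaks.
.find_peaks <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  k <- length(r$values)
  if (k < 3) return(integer(0))
  mid <- 2:(k - 1)
  is_pk <- r$values[mid] > r$values[mid - 1] & r$values[mid] > r$values[mid + 1]
  runs <- mid[is_pk]
  as.integer(floor((starts[runs] + ends[runs]) / 2))
}

# Topographic prominence of peaks at indices `peaks` in x: walk out from the
# peak to the nearest strictly higher sample on each side (or the series
# end); the base on that side is the minimum en route; prominence is peak
# height minus the higher of the two bases.
.peak_prominence <- function(x, peaks) {
  vapply(peaks, function(i) {
    h <- x[i]
    left <- x[seq_len(i - 1)]
    hi_l <- which(left > h)
    base_l <- if (length(hi_l)) min(x[(max(hi_l)):i]) else min(x[1:i])
    right <- x[(i + 1):length(x)]
    hi_r <- which(right > h)
    base_r <- if (length(hi_r)) min(x[i:(i + min(hi_r))]) else min(x[i:length(x)])
    h - max(base_l, base_r)
  }, numeric(1))
}

# Width at half prominence by linear interpolation around peak i.
.peak_width <- function(time, x, i, prom) {
  half <- x[i] - prom / 2
  tl <- time[1]
  if (i > 1) for (j in (i - 1):1) {
    if (x[j] <= half) {
      tl <- time[j] + (time[j + 1] - time[j]) * (half - x[j]) / (x[j + 1] - x[j])
      break
    }
    tl <- time[j]
  }
  tr <- time[length(x)]
  if (i < length(x)) for (j in (i + 1):length(x)) {
    if (x[j] <= half) {
      tr <- time[j] - (time[j] - time[j - 1]) * (half - x[j]) / (x[j - 1] - x[j])
      break
    }
    tr <- time[j]
  }
  tr - tl
}

#' Estimate per-trace measurement noise
#'
#' Robust noise SD from the median absolute successive difference:
#' `mad(diff(x)) / sqrt(2)`, insensitive to the slow localization signal.
#'
#' @param x Index series (NAs dropped).
#' @return Estimated noise SD.
#' @export
estimate_noise_sd <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 3) return(NA_real_)
  stats::mad(diff(x)) / sqrt(2)
}

#' Detect nucleocytoplasmic shuttling pulses
#'
#' Finds local maxima of the localization trace within the analysis window
#' whose topographic prominence (height above the highest saddle separating
#' the peak from any higher point) reaches `min_prominence`, then enforces a
#' minimum pairwise separation by keeping peaks in order of decreasing
#' prominence. Pulses during the initial response (before the window start,
#' 60 min by default) are excluded because the biphasic response is analysed
#' per phase. Pulse height is measured above the basal (pre-shift) level;
#' when no basal is available the window median is used instead. Gaps of up
#' to `max_gap` frames are linearly interpolated before detection.
#'
#' @param time,index Trace vectors on the scheduled frame grid.
#' @param window Analysis window in minutes, default `c(60, 480)`.
#' @param min_prominence Prominence threshold (index units); default
#'   `max(0.1, 3 * estimate_noise_sd(index))`.
#' @param min_separation Minimum peak separation in minutes (default 15).
#' @param basal Basal level; default computed via [compute_basal()].
#' @param baseline `"basal"` (default, the figure convention) or `"trough"`
#'   to measure height above the lower of the two adjacent prominence bases.
#' @param max_gap Maximum run of missing frames to interpolate.
#' @return Data frame of class `mig_pulses`: `time`, `peak_value`, `height`,
#'   `prominence`, `width` (min, at half prominence). Zero rows for flat or
#'   pulse-free traces.
#' @export
detect_pulses <- function(time, index, window = c(60, 480),
                          min_prominence = NULL, min_separation = 15,
                          basal = NULL, baseline = c("basal", "trough"),
                          max_gap = 1) {
  baseline <- match.arg(baseline)
  if (is.null(basal)) basal <- compute_basal(time, index)
  if (is.null(min_prominence)) {
    # estimate noise from the signal-free pre-shift segment when possible:
    # successive differences inside the window are dominated by pulse flanks
    pre <- index[time < 0]
    s <- if (sum(!is.na(pre)) >= 5) estimate_noise_sd(pre) else
      estimate_noise_sd(index)
    min_prominence <- max(0.1, if (is.na(s)) 0 else 3 * s)
  }

  inw <- time >= window[1] & time <= window[2]
  tw <- time[inw]; xw <- index[inw]
  if (length(xw) >= 3 && anyNA(xw)) {
    xw <- as.numeric(zoo::na.approx(zoo::zoo(xw, tw), maxgap = max_gap,
                                    na.rm = FALSE))
  }
  empty <- data.frame(time = numeric(0), peak_value = numeric(0),
                      height = numeric(0), prominence = numeric(0),
                      width = numeric(0))
  class(empty) <- c("mig_pulses", "data.frame")
  ok <- !is.na(xw)
  if (sum(ok) < 3) return(empty)
  # remaining NAs (gaps beyond max_gap) split the window into segments
  seg_id <- cumsum(!ok)[ok]
  tw <- tw[ok]; xw <- xw[ok]

  found <- list()
  for (sid in unique(seg_id)) {
    sel <- seg_id == sid
    ts <- tw[sel]; xs <- xw[sel]
    pk <- .find_peaks(xs)
    if (!length(pk)) next
    prom <- .peak_prominence(xs, pk)
    keep <- prom >= min_prominence
    pk <- pk[keep]; prom <- prom[keep]
    if (!length(pk)) next
    base_ref <- if (!is.na(basal)) basal else stats::median(xs)
    found[[length(found) + 1]] <- data.frame(
      time = ts[pk], peak_value = xs[pk],
      height = if (baseline == "basal") xs[pk] - base_ref else prom,
      prominence = prom,
      width = vapply(seq_along(pk),
                     function(k) .peak_width(ts, xs, pk[k], prom[k]),
                     numeric(1)))
  }
  if (!length(found)) return(empty)
  out <- do.call(rbind, found)

  # enforce separation: decreasing prominence, earlier peak wins ties
  ord <- order(-out$prominence, out$time)
  kept <- integer(0)
  for (k in ord) {
    if (!length(kept) || all(abs(out$time[kept] - out$time[k]) >= min_separation))
      kept <- c(kept, k)
  }
  out <- out[sort(kept), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("mig_pulses", "data.frame")
  out
}

#' Mean pulse height
#' @param pulses A `mig_pulses` data frame.
#' @return Arithmetic mean of pulse heights, `NA` if there are none.
#' @export
mean_pulse_height <- function(pulses) {
  if (is.null(pulses) || nrow(pulses) == 0) return(NA_real_)
  mean(pulses$height)
}

#' Reporter-expression metrics of one trace
#'
#' The time-averaged reporter signal over the adapted window, and the
#' expression onset: the first time the reporter exceeds the pre-shift mean
#' plus `onset_threshold_sd` pre-shift SDs for at least `min_run`
#' consecutive frames (`NA` if never). Because the fluorophore matures
#' slowly, the detected onset lags true promoter derepression by roughly
#' the maturation delay.
#'
#' @param time,reporter Trace vectors.
#' @param window Averaging window (min), default `c(240, 480)`.
#' @param onset_threshold_sd Threshold in pre-shift SDs (default 3).
#' @param min_run Consecutive frames required above threshold.
#' @return List `expr_mean_long`, `expr_onset` (min or `NA`).
#' @export
expression_metrics <- function(time, reporter, window = c(240, 480),
                               onset_threshold_sd = 3, min_run = 3) {
  ok <- !is.na(reporter)
  inw <- time >= window[1] & time <= window[2] & ok
  expr_mean <- if (any(inw)) mean(reporter[inw]) else NA_real_

  pre <- time < 0 & ok
  onset <- NA_real_
  if (any(pre)) {
    thr <- mean(reporter[pre]) +
      onset_threshold_sd * max(stats::sd(reporter[pre]), 0, na.rm = TRUE)
    post <- which(time >= 0 & ok)
    above <- reporter[post] > thr
    if (any(above)) {
      r <- rle(above)
      ends <- cumsum(r$lengths)
      hit <- which(r$values & r$lengths >= min_run)
      if (length(hit)) {
        first <- ends[hit[1]] - r$lengths[hit[1]] + 1
        onset <- time[post[first]]
      }
    }
  }
  list(expr_mean_long = expr_mean, expr_onset = onset)
}

#' Per-cell summary metrics for a set of traces
#'
#' Applies the per-trace metric operations to every cell of a `mig_traces`
#' table: basal level, short-term maximum/mean and peak time (0-60 min),
#' adapted-phase mean (240-480 min), shuttling pulses (60-480 min) with
#' mean pulse height, reporter expression metrics, the expression-marker
#' level (mean over its sparse frames) and a death flag (cell not alive at
#' the last frame).
#'
#' @param traces A `mig_traces` data frame.
#' @param short_window,long_window,pulse_window Analysis windows (min).
#' @param min_prominence,min_separation Pulse-detector settings
#'   (see [detect_pulses()]).
#' @param onset_threshold_sd Reporter onset threshold (pre-shift SDs).
#' @return List with `metrics` (one row per cell: class `mig_metrics`) and
#'   `pulses` (all pulse events with `cell_id`).
#' @export
compute_trace_metrics <- function(traces,
                                  short_window = c(0, 60),
                                  long_window = c(240, 480),
                                  pulse_window = c(60, 480),
                                  min_prominence = NULL,
                                  min_separation = 15,
                                  onset_threshold_sd = 3) {
  stopifnot(is.data.frame(traces))
  ids <- unique(traces$cell_id)
  rows <- vector("list", length(ids))
  pulse_rows <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    tr <- traces[traces$cell_id == ids[k], ]
    tr <- tr[order(tr$time_min), ]
    basal <- compute_basal(tr$time_min, tr$loc_index)
    st <- short_term_metrics(tr$time_min, tr$loc_index, short_window)
    ml <- long_term_mean(tr$time_min, tr$loc_index, long_window)
    pl <- detect_pulses(tr$time_min, tr$loc_index, pulse_window,
                        min_prominence = min_prominence,
                        min_separation = min_separation, basal = basal)
    ex <- expression_metrics(tr$time_min, tr$reporter, long_window,
                             onset_threshold_sd = onset_threshold_sd)
    expr_level <- if (all(is.na(tr$expr_marker))) NA_real_ else
      mean(tr$expr_marker, na.rm = TRUE)
    dead <- if ("alive" %in% names(tr)) !tr$alive[nrow(tr)] else FALSE
    hours <- diff(pulse_window) / 60
    rows[[k]] <- data.frame(
      cell_id = ids[k],
      strain = tr$strain[1], hexose = tr$hexose[1],
      basal = basal,
      max_short = st$max_short, t_max_short = st$t_max_short,
      mean_short = st$mean_short,
      mean_long = ml,
      n_pulses = nrow(pl),
      pulse_rate = nrow(pl) / hours,
      mean_pulse_height = mean_pulse_height(pl),
      expr_mean_long = ex$expr_mean_long,
      expr_onset = ex$expr_onset,
      expr_marker_level = expr_level,
      dead = dead,
      stringsAsFactors = FALSE)
    if (nrow(pl))
      pulse_rows[[k]] <- cbind(data.frame(cell_id = ids[k]), pl)
  }
  metrics <- do.call(rbind, rows)
  class(metrics) <- c("mig_metrics", "data.frame")
  pulses <- do.call(rbind, pulse_rows[!vapply(pulse_rows, is.null, logical(1))])
  if (is.null(pulses))
    pulses <- data.frame(cell_id = integer(0), time = numeric(0),
                         peak_value = numeric(0), height = numeric(0),
                         prominence = numeric(0), width = numeric(0))
  list(metrics = metrics, pulses = pulses)
}
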