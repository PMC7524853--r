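#' Acquisition schedule for a media-shift time-lapse experiment
#'
#' Builds the frame-time grid used throughout the package: sparse imaging
#' before the media shift (t <= 0), dense imaging afterwards (t >= 0), with
#' one fluorescence channel (the expression-level marker) acquired only on
#' every `sparse_period`-th post-shift frame to limit photodamage.
#'
#' The default protocol images every 30 min from -240 to 0 min and every
#' 5 min from 0 to 720 min; t = 0 (the shift itself) is counted once.
#'
#' @param pre_interval Minutes between frames before the shift (> 0).
#' @param post_interval Minutes between frames after the shift (> 0).
#' @param t_min First frame time in minutes (< 0).
#' @param t_max Last frame time in minutes (> 0).
#' @param sparse_period Acquire the expression-marker channel on every
#'   `sparse_period`-th post-shift frame (>= 1, counted from t = 0).
#'
#' @return An object of class `mig_schedule`: a list with `times` (all frame
#'   times, strictly increasing), `pre_shift_times` (t <= 0),
#'   `post_shift_times` (t >= 0), `shift_index` (index of t = 0 in `times`),
#'   `sparse_period`, and `sparse_frames` (indices into `times` on which the
#'   sparse channel is acquired).
#' @examples
#' sched <- make_schedule()
#' length(sched$pre_shift_times)   # 9
#' length(sched$post_shift_times)  # 145
#' @export
make_schedule <- function(pre_interval = 30, post_interval = 5,
                          t_min = -240, t_max = 720, sparse_period = 4) {
  if (pre_interval <= 0 || post_interval <= 0)
    stop("acquisition intervals must be positive")
  if (!(t_min < 0 && t_max > 0))
    stop("t_min must be negative and t_max positive (shift at t = 0)")
  if (sparse_period < 1) stop("sparse_period must be >= 1")

  pre <- rev(seq(0, t_min, by = -pre_interval))
  post <- seq(0, t_max, by = post_interval)
  times <- sort(unique(c(pre, post)))
  shift_index <- match(0, times)
  if (is.na(shift_index)) {
    # grids never skip 0 by construction (both sequences anchor there)
    shift_index <- which.min(abs(times))
  }
  post_idx <- which(times >= 0)
  sparse_frames <- post_idx[seq(1, length(post_idx), by = sparse_period)]

  structure(
    list(times = times,
         pre_shift_times = times[times <= 0],
         post_shift_times = times[times >= 0],
         shift_index = shift_index,
         sparse_period = sparse_period,
         sparse_frames = sparse_frames),
    class = "mig_schedule"
  )
}

#' @export
print.mig_schedule <- function(x, ...) {
  cat("Acquisition schedule:", length(x$times), "frames,",
      sprintf("%g to %g min;", min(x$times), max(x$times)),
      length(x$pre_shift_times), "pre-shift /",
      length(x$post_shift_times), "post-shift (t = 0 once);",
      length(x$sparse_frames), "sparse-channel frames\n")
  invisible(x)
}

#' Number of frames in a schedule
#' @param schedule A `mig_schedule`.
#' @return Integer frame count.
#' @export
n_frames <- function(schedule) length(schedule$times)
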