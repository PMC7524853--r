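#' Initial-response kernel
#'
#' Gamma-shaped rise-and-decay kernel for the initial nuclear-accumulation
#' phase, normalized so its mode at `t_peak` has value 1:
#' `k(t) = (t/t_peak)^(t_peak/tau) * exp((t_peak - t)/tau)` for `t >= 0`,
#' 0 before the shift. Smooth, two-parameter, rises to a maximum near
#' `t_peak` (~30 min in the default presets) and decays with time constant
#' `tau` over the following hours.
#'
#' @param t Times in minutes (vector).
#' @param t_peak Mode of the kernel (min, > 0).
#' @param tau Decay time constant (min, > 0).
#' @return Kernel values in `[0, 1]`.
#' @export
response_kernel <- function(t, t_peak = 30, tau = 80) {
  k <- numeric(length(t))
  pos <- t > 0
  tp <- t[pos]
  k[pos] <- (tp / t_peak)^(t_peak / tau) * exp((t_peak - tp) / tau)
  k
}

# Log-normal multiplicative jitter with mean exactly 1.
.jitter <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, -sdlog^2 / 2, sdlog))
}

# Pulse arrival times on (t_start, t_end]: renewal process with gap
# = refractory + Exp(mean 1/rate - refractory), so consecutive pulses stay
# resolvable while the long-run event rate equals `rate` (rates in
# events/min). Saturates to a regular gap of `refractory` when
# 1/rate <= refractory.
.pulse_arrivals <- function(rate, refractory, t_start, t_end) {
  if (rate <= 0) return(numeric(0))
  mean_gap <- 1 / rate
  exp_mean <- max(mean_gap - refractory, 0)
  out <- numeric(0)
  t <- t_start
  repeat {
    gap <- refractory + if (exp_mean > 0) stats::rexp(1, 1 / exp_mean) else 0
    t <- t + gap
    if (t > t_end) break
    out <- c(out, t)
  }
  out
}

#' Closed-form destabilized-reporter fluorescence series
#'
#' Solves the delayed-production model
#' `dF/dt = rate(t - maturation_delay) - degradation_rate * F` exactly for a
#' piecewise-constant production rate that steps from `repressed_rate` to
#' `derepressed_rate` at `derepression_onset`, with the pre-shift repressed
#' steady state `repressed_rate / degradation_rate` as initial condition.
#' Fluorescence therefore cannot change before
#' `derepression_onset + maturation_delay` and approaches the derepressed
#' steady state `derepressed_rate / degradation_rate`.
#'
#' @param params A [reporter_params()] object.
#' @param times Sample times in minutes.
#' @param scale Multiplicative cell-to-cell factor applied to both rates.
#' @return Fluorescence series (AU) at `times`.
#' @export
reporter_series <- function(params, times, scale = 1) {
  k <- params$degradation_rate
  r0 <- params$repressed_rate * scale
  f0 <- r0 / k
  if (identical(params$derepression_onset, "never")) {
    return(rep(f0, length(times)))
  }
  t1 <- params$derepression_onset + params$maturation_delay
  r1 <- params$derepressed_rate * scale
  f1 <- r1 / k
  out <- rep(f0, length(times))
  late <- times > t1
  out[late] <- f1 + (f0 - f1) * exp(-k * (times[late] - t1))
  out
}

#' Simulate the reporter channel for one ground-truth trace
#'
#' Convenience wrapper sampling [reporter_series()] on a schedule.
#'
#' @param params A [reporter_params()] object.
#' @param schedule A [make_schedule()] object.
#' @param scale Per-cell production scale factor.
#' @return AU series on `schedule$times`.
#' @export
simulate_reporter <- function(params, schedule, scale = 1) {
  reporter_series(params, schedule$times, scale = scale)
}

#' Simulate ground-truth single-cell localization traces
#'
#' Draws per-cell parameters (log-normal cell-to-cell jitter on the initial
#' amplitude, pulse rate, pulse heights and reporter production), generates
#' the noise-free localization index
#' `b + A_i * kernel(t) + (L_i - b) * ramp(t) + sum of pulse bumps` for
#' `t >= 0` (constant `b` before the shift), draws shuttling pulses as a
#' refractory point process starting after the initial phase (t >= 60 min),
#' adds Gaussian measurement noise, and computes the reporter channel and
#' per-cell constitutive expression-marker level. For presets with
#' `death_fraction > 0`, the cells with the highest expression-marker level
#' die at t = 60 min: their traces freeze at the death-time value and they
#' stop pulsing.
#'
#' @param config A [sim_config()] or [preset()] object.
#' @param schedule A [make_schedule()] object.
#' @return An object of class `mig_truth`: list with `times`, matrices
#'   `index` (observed, cells x frames), `index_clean` (noise-free),
#'   `reporter` (noise-free), `alive` (logical), vector `expr_marker`,
#'   data.frame `pulses` (cell, time, amplitude, height -- height is the
#'   noise-free trace at the pulse apex minus the basal level, the quantity
#'   the metrics module measures), per-cell parameter table `cells`, the
#'   `config` and `schedule`, and `death_threshold` (expression-marker level
#'   above which cells die, `NA` when `death_fraction = 0`).
#' @export
simulate_traces <- function(config, schedule = make_schedule()) {
  stopifnot(inherits(config, "mig_sim_config"))
  set.seed(config$seed)
  n <- config$n_cells
  times <- schedule$times
  Tn <- length(times)
  b <- config$basal_level
  sw <- config$pulse_width / (2 * sqrt(2 * log(2)))  # FWHM -> sigma

  # expression-marker level (log-normal with the configured mean/sd)
  m <- config$expression_marker_mean
  s <- config$expression_marker_sd
  sdlog <- sqrt(log(1 + (s / m)^2))
  meanlog <- log(m) - sdlog^2 / 2
  expr_marker <- stats::rlnorm(n, meanlog, sdlog)

  death_threshold <- NA_real_
  dead <- rep(FALSE, n)
  if (config$death_fraction > 0) {
    death_threshold <- stats::qlnorm(1 - config$death_fraction, meanlog, sdlog)
    dead <- expr_marker > death_threshold
  }
  death_time <- 60  # arrest shortly after the shift

  A_i <- config$initial_amplitude * .jitter(n, config$cell_cv)
  lam_i <- config$pulse_rate * .jitter(n, config$cell_cv) / 60  # per min
  h_i <- config$pulse_height_mean * .jitter(n, config$cell_cv)
  rep_scale <- .jitter(n, config$cell_cv)
  responder <- stats::runif(n) < config$responder_fraction
  lam_i[!responder] <- 0
  plateau_i <- rep(config$plateau_level - b, n)

  if (!is.null(config$dose_response)) {
    K <- config$dose_response$K
    h_exp <- config$dose_response$hill
    f <- expr_marker^h_exp / (K^h_exp + expr_marker^h_exp)
    lam_i <- lam_i * f
    plateau_i <- plateau_i * f
  }

  kernel_t <- response_kernel(times, config$peak_time, config$decay_tau)
  ramp_t <- ifelse(times > 0, 1 - exp(-pmax(times, 0) / 120), 0)
  post <- times >= 0

  index_clean <- matrix(b, n, Tn)
  alive <- matrix(TRUE, n, Tn)
  pulses <- vector("list", n)

  clean_at <- function(tt, i, ptimes, pamps) {
    # noise-free trace value at arbitrary (continuous) times tt
    v <- b + A_i[i] * response_kernel(tt, config$peak_time, config$decay_tau) +
      plateau_i[i] * ifelse(tt > 0, 1 - exp(-pmax(tt, 0) / 120), 0)
    for (j in seq_along(ptimes))
      v <- v + pamps[j] * exp(-(tt - ptimes[j])^2 / (2 * sw^2))
    v
  }

  for (i in seq_len(n)) {
    t_stop <- if (dead[i]) death_time else max(times)
    pt <- .pulse_arrivals(lam_i[i], config$pulse_refractory, 60, t_stop)
    pa <- if (length(pt)) {
      pmax(stats::rnorm(length(pt), h_i[i], config$pulse_height_sd), 0.02)
    } else numeric(0)

    v <- b + A_i[i] * kernel_t + plateau_i[i] * ramp_t
    for (j in seq_along(pt)) {
      win <- abs(times - pt[j]) < 4 * sw
      v[win] <- v[win] + pa[j] * exp(-(times[win] - pt[j])^2 / (2 * sw^2))
    }
    if (dead[i]) {
      frz <- times >= death_time
      v[frz] <- v[which(frz)[1]]
      alive[i, frz] <- FALSE
    }
    index_clean[i, ] <- v
    if (length(pt)) {
      pulses[[i]] <- data.frame(
        cell = i, time = pt, amplitude = pa,
        height = clean_at(pt, i, pt, pa) - b)
    }
  }

  index <- index_clean +
    matrix(stats::rnorm(n * Tn, 0, config$noise_sd), n, Tn)

  reporter <- matrix(0, n, Tn)
  for (i in seq_len(n)) {
    r <- reporter_series(config$reporter, times, scale = rep_scale[i])
    if (dead[i]) {
      frz <- times >= death_time
      r[frz] <- r[which(frz)[1]]
    }
    reporter[i, ] <- r
  }

  pulses <- if (any(!vapply(pulses, is.null, logical(1)))) {
    do.call(rbind, pulses)
  } else {
    data.frame(cell = integer(0), time = numeric(0),
               amplitude = numeric(0), height = numeric(0))
  }

  structure(
    list(times = times, index = index, index_clean = index_clean,
         reporter = reporter, alive = alive, expr_marker = expr_marker,
         pulses = pulses,
         cells = data.frame(cell = seq_len(n), A = A_i,
                            pulse_rate = lam_i * 60, pulse_height = h_i,
                            reporter_scale = rep_scale, dead = dead),
         config = config, schedule = schedule,
         death_threshold = death_threshold),
    class = "mig_truth"
  )
}

#' @export
print.mig_truth <- function(x, ...) {
  cat(sprintf("Ground truth: %d cells x %d frames (%s / %s), %d pulses, %d dead\n",
              nrow(x$index), ncol(x$index), x$config$strain, x$config$hexose,
              nrow(x$pulses), sum(x$cells$dead)))
  invisible(x)
}

#' Tidy single-cell traces from simulated ground truth (trace-only mode)
#'
#' Converts a `mig_truth` object into the tidy per-cell trace table the
#' metrics module consumes, bypassing rendering, segmentation and tracking.
#' The localization index carries the configured measurement noise; the
#' reporter gets `reporter_noise_sd` Gaussian noise; the expression marker
#' is observed only on the schedule's sparse frames.
#'
#' @param truth A [simulate_traces()] result.
#' @return A data.frame of class `mig_traces` with columns `cell_id`,
#'   `time_min`, `loc_index`, `reporter`, `expr_marker`, `alive`, `strain`,
#'   `hexose`.
#' @export
traces_from_truth <- function(truth) {
  stopifnot(inherits(truth, "mig_truth"))
  set.seed(truth$config$seed + 500000L)  # independent of the generator stream
  n <- nrow(truth$index); Tn <- ncol(truth$index)
  rep_obs <- truth$reporter +
    matrix(stats::rnorm(n * Tn, 0, truth$config$reporter_noise_sd), n, Tn)
  expr <- matrix(NA_real_, n, Tn)
  expr[, truth$schedule$sparse_frames] <- truth$expr_marker
  out <- data.frame(
    cell_id = rep(seq_len(n), each = Tn),
    time_min = rep(truth$times, n),
    loc_index = as.vector(t(truth$index)),
    reporter = as.vector(t(rep_obs)),
    expr_marker = as.vector(t(expr)),
    alive = as.vector(t(truth$alive)),
    strain = truth$config$strain,
    hexose = truth$config$hexose,
    stringsAsFactors = FALSE
  )
  class(out) <- c("mig_traces", "data.frame")
  out
}
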