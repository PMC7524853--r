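#' @keywords internal
"_PACKAGE"

STRAINS <- c("wt", "hxk1d", "hxk2d", "hxk1d_hxk2d",
             "oeHXK1", "oeHXK2", "oeGLK1")
HEXOSES <- c("glucose", "fructose", "mannose")

# Accept the Greek-delta spellings used in figure legends.
normalize_strain <- function(strain) {
  s <- gsub("Δ|∆", "d", strain)
  s <- gsub("^\\+", "oe", s)
  s <- sub("hxk1dhxk2d", "hxk1d_hxk2d", s, fixed = TRUE)
  if (!s %in% STRAINS)
    stop("unknown strain '", strain, "'; expected one of: ",
         paste(STRAINS, collapse = ", "))
  s
}

#' Reporter (destabilized fluorescent protein) kinetic parameters
#'
#' Parameters of the promoter-reporter model: a destabilized fluorescent
#' protein expressed from a catabolite-repressed promoter (SUC2- or
#' HXK1-type). Production switches from `repressed_rate` to
#' `derepressed_rate` at `derepression_onset`; fluorescence lags production
#' by the chromophore `maturation_delay`; the fluorescent pool turns over
#' with first-order `degradation_rate` (the protein is destabilized, so its
#' level tracks ongoing promoter activity).
#'
#' @param repressed_rate Production rate under repression (AU/min, >= 0).
#' @param derepressed_rate Production rate after derepression (AU/min, >= 0).
#' @param maturation_delay Chromophore maturation lag (min, >= 0).
#' @param degradation_rate First-order decay of the fluorescent pool
#'   (1/min, > 0).
#' @param derepression_onset Time of derepression in minutes (>= 0), or
#'   `"never"` for conditions that stay repressed.
#' @return A list of class `mig_reporter_params`.
#' @export
reporter_params <- function(repressed_rate = 0.1,
                            derepressed_rate = 0.1,
                            maturation_delay = 30,
                            degradation_rate = 0.025,
                            derepression_onset = "never") {
  stopifnot(repressed_rate >= 0, derepressed_rate >= 0,
            maturation_delay >= 0, degradation_rate > 0)
  if (!identical(derepression_onset, "never")) {
    stopifnot(is.numeric(derepression_onset), derepression_onset >= 0)
  }
  structure(list(repressed_rate = repressed_rate,
                 derepressed_rate = derepressed_rate,
                 maturation_delay = maturation_delay,
                 degradation_rate = degradation_rate,
                 derepression_onset = derepression_onset),
            class = "mig_reporter_params")
}

#' Simulation configuration for one strain-by-hexose condition
#'
#' Describes the ground-truth single-cell dynamics to simulate: the biphasic
#' localization response (an initial nuclear peak of amplitude `A` with mode
#' at `t_peak` decaying with time constant `decay_tau`, an adapted-phase
#' plateau at `plateau_level`, and pulsatile nucleocytoplasmic shuttling as a
#' rate-`pulse_rate` point process of Gaussian bumps), cell-to-cell
#' variability, measurement noise, reporter kinetics, and (for the
#' mannose-toxicity overexpression presets) cell death above an expression
#' threshold.
#'
#' @param strain,hexose Condition labels (see [preset()] for valid values).
#' @param n_cells Number of cells.
#' @param seed RNG seed for this condition.
#' @param initial_amplitude Peak amplitude `A` of the initial nuclear
#'   response (localization-index units, >= 0).
#' @param peak_time Mode of the initial response kernel (min).
#' @param decay_tau Decay time constant of the initial response (min, > 0).
#' @param plateau_level Adapted-phase deterministic level `L` (index units);
#'   equals `basal_level` when there is no sustained nuclear presence.
#' @param pulse_rate Shuttling pulse rate (pulses/hour, >= 0).
#' @param pulse_height_mean,pulse_height_sd Pulse bump amplitude
#'   distribution (index units).
#' @param pulse_width Pulse full width at half maximum (min).
#' @param pulse_refractory Minimum gap between consecutive pulses (min);
#'   defaults to the pulse detector's separation floor so generated pulse
#'   trains are resolvable at the 5-min sampling interval.
#' @param basal_level Pre-shift basal localization index `b`.
#' @param noise_sd Gaussian measurement noise on the index (index units).
#' @param cell_cv Log-normal cell-to-cell coefficient of variation applied
#'   multiplicatively to amplitude, pulse rate, pulse height and reporter
#'   production.
#' @param responder_fraction Fraction of cells that shuttle at all.
#' @param reporter A [reporter_params()] object.
#' @param reporter_noise_sd Gaussian noise on the sampled reporter (AU).
#' @param death_fraction Fraction of cells that die after the shift
#'   (hexokinase-overexpression-in-mannose presets); death strikes the cells
#'   with the highest expression-marker level.
#' @param expression_marker_mean,expression_marker_sd Mean and SD of the
#'   per-cell constitutive expression-marker level (AU, log-normal).
#' @param dose_response Optional list `list(K=, hill=)`: scale shuttling
#'   (pulse rate and plateau elevation) by the Hill function
#'   `x^h / (K^h + x^h)` of the cell's expression-marker level, for
#'   kinase-overexpression rescue presets. `NULL` for no coupling.
#' @return A list of class `mig_sim_config`.
#' @export
sim_config <- function(strain = "wt", hexose = "glucose",
                       n_cells = 50, seed = 1L,
                       initial_amplitude = 0.8, peak_time = 30,
                       decay_tau = 80, plateau_level = 0.15,
                       pulse_rate = 2, pulse_height_mean = 0.4,
                       pulse_height_sd = 0.12, pulse_width = 10,
                       pulse_refractory = 15,
                       basal_level = 0.05, noise_sd = 0.03,
                       cell_cv = 0.3, responder_fraction = 1,
                       reporter = reporter_params(),
                       reporter_noise_sd = 0.5,
                       death_fraction = 0,
                       expression_marker_mean = 200,
                       expression_marker_sd = 50,
                       dose_response = NULL) {
  stopifnot(initial_amplitude >= 0, decay_tau > 0, pulse_rate >= 0,
            pulse_width > 0, noise_sd >= 0, n_cells >= 1,
            responder_fraction >= 0, responder_fraction <= 1,
            death_fraction >= 0, death_fraction <= 1,
            inherits(reporter, "mig_reporter_params"))
  structure(
    list(strain = strain, hexose = hexose, n_cells = as.integer(n_cells),
         seed = as.integer(seed),
         initial_amplitude = initial_amplitude, peak_time = peak_time,
         decay_tau = decay_tau, plateau_level = plateau_level,
         pulse_rate = pulse_rate, pulse_height_mean = pulse_height_mean,
         pulse_height_sd = pulse_height_sd, pulse_width = pulse_width,
         pulse_refractory = pulse_refractory,
         basal_level = basal_level, noise_sd = noise_sd,
         cell_cv = cell_cv, responder_fraction = responder_fraction,
         reporter = reporter, reporter_noise_sd = reporter_noise_sd,
         death_fraction = death_fraction,
         expression_marker_mean = expression_marker_mean,
         expression_marker_sd = expression_marker_sd,
         dose_response = dose_response),
    class = "mig_sim_config"
  )
}

#' @export
print.mig_sim_config <- function(x, ...) {
  cat(sprintf("Condition %s / %s: %d cells, A=%.2g, lambda=%.2g/h, L=%.2g, b=%.2g\n",
              x$strain, x$hexose, x$n_cells, x$initial_amplitude,
              x$pulse_rate, x$plateau_level, x$basal_level))
  invisible(x)
}

# Reporter production rate (AU/min) that yields approximately the requested
# fold change of the 240-480 min window mean over the repressed steady state,
# given onset, maturation 30 min and degradation 0.025/min. Rounded values
# fixed at design time.
.derep_rate_for_fold <- list(`7.5` = 0.76, `4` = 0.41, `3` = 0.31,
                             `2` = 0.20, `1.5` = 0.15)

#' Strain-by-hexose simulation presets
#'
#' Returns the [sim_config()] encoding a given condition's qualitative
#' behaviour: whether the initial nuclear response occurs (it requires any
#' hexose-phosphorylating activity, so it is absent only when the strain
#' cannot phosphorylate the supplied hexose), whether adapted-phase
#' nucleocytoplasmic shuttling occurs (requires Hxk2 in glucose/mannose,
#' Hxk1 or Hxk2 in fructose; Glk1 never confers it), reporter derepression
#' (with fold changes of ~7.5x in glucose, ~1.5x in fructose and 2-4x in
#' mannose for the derepressed mutants), and the toxicity of hexokinase
#' overexpression in mannose (death above an expression-marker threshold).
#' Absolute magnitudes are package design choices; only orderings and
#' presence/absence encode reported biology.
#'
#' @param strain One of `wt`, `hxk1d`, `hxk2d`, `hxk1d_hxk2d`, `oeHXK1`,
#'   `oeHXK2`, `oeGLK1` (Greek-delta and `+HXK1`-style spellings accepted).
#' @param hexose One of `glucose`, `fructose`, `mannose`.
#' @param n_cells,seed Passed to [sim_config()]; the default seed is derived
#'   from the condition's position in the preset grid.
#' @return A `mig_sim_config`.
#' @examples
#' preset("hxk1d_hxk2d", "fructose")$initial_amplitude  # 0: cannot phosphorylate
#' preset("wt", "glucose")$pulse_rate                   # > 0: shuttling
#' @export
preset <- function(strain, hexose, n_cells = 50, seed = NULL) {
  strain <- normalize_strain(strain)
  if (!hexose %in% HEXOSES)
    stop("unknown hexose '", hexose, "'; expected one of: ",
         paste(HEXOSES, collapse = ", "))
  if (is.null(seed)) {
    seed <- 1000L + match(strain, STRAINS) * 10L + match(hexose, HEXOSES)
  }

  cfg <- sim_config(strain = strain, hexose = hexose,
                    n_cells = n_cells, seed = seed)
  A <- 0.8; lam <- 2; L <- 0.15; tau <- 80
  rep_par <- reporter_params()  # repressed, never derepressed
  death <- 0; dr <- NULL
  expr_mean <- 200; expr_sd <- 50

  derep <- function(fold, onset) {
    reporter_params(derepressed_rate = .derep_rate_for_fold[[as.character(fold)]],
                    derepression_onset = onset)
  }

  if (strain == "wt") {
    A <- switch(hexose, glucose = 0.8, fructose = 1.0, mannose = 0.8)
  } else if (strain == "hxk1d") {
    A <- switch(hexose, glucose = 0.8, fructose = 0.9, mannose = 0.8)
    if (hexose == "mannose") rep_par <- derep(2, 120)
  } else if (strain == "hxk2d") {
    A <- switch(hexose, glucose = 1.0, fructose = 1.0, mannose = 0.9)
    if (hexose != "fructose") { lam <- 0; L <- cfg$basal_level }
    rep_par <- switch(hexose,
                      glucose = derep(7.5, 90),
                      fructose = derep(1.5, 90),
                      mannose = derep(4, 90))
  } else if (strain == "hxk1d_hxk2d") {
    lam <- 0; L <- cfg$basal_level
    if (hexose == "fructose") {
      A <- 0
      rep_par <- derep(1.5, 10)
    } else {
      A <- 0.3; tau <- 40  # Glk1 only: reduced, short-lived peak
      rep_par <- if (hexose == "glucose") derep(7.5, 10) else derep(3, 10)
    }
  } else if (strain %in% c("oeHXK1", "oeHXK2")) {
    A <- 1.0
    expr_mean <- 900; expr_sd <- 600
    dr <- list(K = if (hexose == "mannose") 300 else 700, hill = 2)
    if (hexose == "mannose")
      death <- if (strain == "oeHXK2") 0.32 else 0.13
  } else if (strain == "oeGLK1") {
    lam <- 0; L <- cfg$basal_level
    A <- if (hexose == "fructose") 0 else 0.6  # Glk1 cannot use fructose
    expr_mean <- 900; expr_sd <- 600
    rep_par <- switch(hexose,
                      glucose = derep(7.5, 90),
                      fructose = derep(1.5, 90),
                      mannose = derep(3, 90))
    if (hexose == "fructose" && A == 0) rep_par <- derep(1.5, 10)
  }

  cfg$initial_amplitude <- A
  cfg$pulse_rate <- lam
  cfg$plateau_level <- L
  cfg$decay_tau <- tau
  cfg$reporter <- rep_par
  cfg$death_fraction <- death
  cfg$dose_response <- dr
  cfg$expression_marker_mean <- expr_mean
  cfg$expression_marker_sd <- expr_sd
  cfg
}

#' The full preset grid
#' @param n_cells Cells per condition.
#' @return A list of `mig_sim_config`, one per strain-by-hexose combination.
#' @export
preset_grid <- function(n_cells = 50) {
  out <- list()
  for (s in STRAINS) for (h in HEXOSES) {
    out[[paste(s, h, sep = ":")]] <- preset(s, h, n_cells = n_cells)
  }
  out
}
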