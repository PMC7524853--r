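#' Summarize one group of per-cell metric values
#'
#' Mean, SD (n-1 denominator) and t-based 95% confidence interval of a
#' per-cell metric, with an optional test against a reference group (wild
#' type in the figures). The original figures cite a paired t test against
#' the wild-type condition, but different strains are different cells, so
#' pairing is not defined; the default here is Welch's two-sample
#' unequal-variance t test, with a permutation test on the difference of
#' means as an option. Significance is called at p < 0.05.
#'
#' @param values Per-cell metric values (NAs dropped).
#' @param reference_values Reference group values, or `NULL` (no test).
#' @param conf_level Confidence level (default 0.95).
#' @param test `"welch"` (default) or `"permutation"`.
#' @param n_perm Permutation count for the permutation test.
#' @return One-row data.frame: `n`, `mean`, `sd`, `ci_low`, `ci_high`,
#'   `p_vs_reference`, `significant`. CI is `NA` for n < 2; p is `NA`
#'   without a reference.
#' @examples
#' s <- summarize_group(c(1, 2, 3))
#' c(s$ci_low, s$ci_high)  # 2 -/+ 4.303 * sd/sqrt(3)
#' @export
summarize_group <- function(values, reference_values = NULL,
                            conf_level = 0.95,
                            test = c("welch", "permutation"),
                            n_perm = 2000) {
  test <- match.arg(test)
  values <- values[!is.na(values)]
  n <- length(values)
  m <- if (n) mean(values) else NA_real_
  s <- if (n >= 2) stats::sd(values) else NA_real_
  if (n >= 2) {
    half <- stats::qt(1 - (1 - conf_level) / 2, df = n - 1) * s / sqrt(n)
    ci <- c(m - half, m + half)
  } else ci <- c(NA_real_, NA_real_)

  p <- NA_real_
  if (!is.null(reference_values)) {
    ref <- reference_values[!is.na(reference_values)]
    if (n >= 2 && length(ref) >= 2) {
      if (stats::sd(values) == 0 && stats::sd(ref) == 0) {
        p <- if (isTRUE(all.equal(mean(values), mean(ref)))) 1 else 0
      } else if (test == "welch") {
        p <- stats::t.test(values, ref, var.equal = FALSE)$p.value
      } else {
        obs <- abs(mean(values) - mean(ref))
        pool <- c(values, ref)
        hits <- 0L
        for (i in seq_len(n_perm)) {
          idx <- sample.int(length(pool), n)
          if (abs(mean(pool[idx]) - mean(pool[-idx])) >= obs) hits <- hits + 1L
        }
        p <- (hits + 1) / (n_perm + 1)
      }
    }
  }
  data.frame(n = n, mean = m, sd = s, ci_low = ci[1], ci_high = ci[2],
             p_vs_reference = p,
             significant = !is.na(p) & p < 0.05)
}

#' Fold change of group mean expression over a reference
#'
#' Simple ratio of group means (the convention behind the reported 7-8 fold
#' SUC2 derepression). A non-positive reference makes the ratio undefined;
#' the absolute difference is then reported instead.
#'
#' @param group_mean,reference_mean Group mean expression levels (AU).
#' @return List `fold` (ratio or `NA`), `difference`, `group_mean`,
#'   `reference_mean`.
#' @export
fold_change <- function(group_mean, reference_mean) {
  if (is.na(reference_mean) || reference_mean <= 0) {
    return(list(fold = NA_real_, difference = group_mean - reference_mean,
                group_mean = group_mean, reference_mean = reference_mean))
  }
  list(fold = group_mean / reference_mean,
       difference = group_mean - reference_mean,
       group_mean = group_mean, reference_mean = reference_mean)
}

#' Dose-response of adapted-phase localization vs kinase expression level
#'
#' Bins cells by expression-marker level (quantile bins) and reports the
#' mean adapted-phase localization per bin, plus the Spearman rank
#' correlation between expression level and localization across cells --
#' the analysis behind the dose-responsive restoration of shuttling by
#' hexokinase expression.
#'
#' @param expr_level Per-cell expression-marker levels (AU).
#' @param mean_long Per-cell adapted-phase mean localization.
#' @param n_bins Number of quantile bins.
#' @param min_bin_n Minimum cells per bin; bins below it are dropped. If
#'   fewer than 2 bins survive, only the correlation is returned.
#' @return List `bins` (data.frame `expr_level`, `mean_long`, `n`, possibly
#'   empty), `rho` (Spearman), `p_value`.
#' @export
dose_response <- function(expr_level, mean_long, n_bins = 5, min_bin_n = 10) {
  ok <- !is.na(expr_level) & !is.na(mean_long)
  x <- expr_level[ok]; y <- mean_long[ok]
  if (length(x) < 3)
    return(list(bins = data.frame(expr_level = numeric(0),
                                  mean_long = numeric(0), n = integer(0)),
                rho = NA_real_, p_value = NA_real_))
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  qs <- unique(stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1)))
  bins <- data.frame(expr_level = numeric(0), mean_long = numeric(0),
                     n = integer(0))
  if (length(qs) >= 3) {
    bin <- cut(x, qs, include.lowest = TRUE)
    bins <- data.frame(
      expr_level = as.numeric(tapply(x, bin, mean)),
      mean_long = as.numeric(tapply(y, bin, mean)),
      n = as.integer(table(bin)))
    bins <- bins[!is.na(bins$expr_level) & bins$n >= min_bin_n, ]
    rownames(bins) <- NULL
  }
  if (nrow(bins) < 2)
    bins <- bins[0, ]
  list(bins = bins, rho = unname(ct$estimate), p_value = ct$p.value)
}

#' Filter dead cells in toxicity conditions
#'
#' Hexokinase overexpression is toxic in mannose above a kinase expression
#' threshold: dying cells arrest and freeze. This filter excludes cells
#' flagged dead by the metrics (frozen tracks) and estimates the
#' expression-marker level separating viable from dead cells as the
#' midpoint between the two groups' mean levels.
#'
#' @param metrics A `mig_metrics` table (needs `dead` and
#'   `expr_marker_level`).
#' @return List `viable` (filtered metrics), `n_excluded`,
#'   `expr_threshold` (`NA` when nothing was excluded). All-dead input
#'   returns zero rows with a warning.
#' @export
viability_filter <- function(metrics) {
  dead <- metrics$dead %in% TRUE
  thr <- NA_real_
  if (any(dead) && any(!dead)) {
    thr <- (mean(metrics$expr_marker_level[dead], na.rm = TRUE) +
            mean(metrics$expr_marker_level[!dead], na.rm = TRUE)) / 2
  }
  if (all(dead) && length(dead)) warning("all cells are dead in this condition")
  list(viable = metrics[!dead, , drop = FALSE],
       n_excluded = sum(dead), expr_threshold = thr)
}

#' Expected qualitative behaviour matrix
#'
#' The reported strain-by-hexose matrix of (short-term response present,
#' long-term shuttling present, reporter derepressed): the initial response
#' requires any hexose-phosphorylating activity (absent only where the
#' strain cannot phosphorylate the hexose: the hxk1/hxk2 double deletion
#' and the Glk1-rescued strain in fructose); adapted-phase shuttling
#' requires Hxk2 in glucose and mannose, Hxk1 or Hxk2 in fructose, and is
#' restored by overexpressing either hexokinase but never by Glk1; reporter
#' derepression occurs in glucose for hxk2 and hxk1 hxk2 deletions, in
#' fructose (weakly) for the same, and in mannose additionally for the hxk1
#' deletion, with the Glk1-rescued strain derepressed and hexokinase-rescued
#' strains repressed.
#'
#' @return Data frame: `strain`, `hexose`, `short_term`, `shuttling`,
#'   `derepressed` (logical).
#' @export
expected_matrix <- function() {
  g <- expand.grid(strain = STRAINS, hexose = HEXOSES,
                   stringsAsFactors = FALSE)
  g$short_term <- !((g$strain == "hxk1d_hxk2d" & g$hexose == "fructose") |
                    (g$strain == "oeGLK1" & g$hexose == "fructose"))
  g$shuttling <-
    (g$strain %in% c("wt", "hxk1d", "oeHXK1", "oeHXK2")) |
    (g$strain == "hxk2d" & g$hexose == "fructose")
  g$derepressed <-
    (g$strain %in% c("hxk2d", "hxk1d_hxk2d", "oeGLK1")) |
    (g$strain == "hxk1d" & g$hexose == "mannose")
  g
}

#' Decide the qualitative behaviour of one measured condition
#'
#' Turns measured per-cell metrics into the three qualitative calls, using
#' only pipeline outputs: short-term response present when the group mean
#' short-window maximum exceeds the group mean basal by
#' `short_margin`; shuttling present when the group mean detected pulse
#' rate exceeds `min_rate` pulses/hour; reporter derepressed when the
#' adapted-window reporter signal is significantly above the reference
#' condition (one-sided Welch test at 0.05, the figure-star convention)
#' with at least a `derep_fold` fold change of the group means as an
#' effect-size floor.
#'
#' @param metrics `mig_metrics` for one condition (dead cells should be
#'   filtered first).
#' @param reference_metrics `mig_metrics` of the repressed reference
#'   condition (matching wild type), or `NULL`.
#' @param short_margin Index-units margin over basal (default 0.1).
#' @param min_rate Pulses/hour threshold (default 0.5).
#' @param derep_fold Minimum fold change of group means (default 1.2).
#' @return List of logicals `short_term`, `shuttling`, `derepressed`.
#' @export
classify_condition <- function(metrics, reference_metrics = NULL,
                               short_margin = 0.1, min_rate = 0.5,
                               derep_fold = 1.2) {
  derep <- FALSE
  if (!is.null(reference_metrics)) {
    v <- metrics$expr_mean_long[!is.na(metrics$expr_mean_long)]
    r <- reference_metrics$expr_mean_long[!is.na(reference_metrics$expr_mean_long)]
    if (length(v) >= 2 && length(r) >= 2 && mean(r) > 0) {
      same <- length(v) == length(r) && isTRUE(all.equal(v, r))
      p <- if (same) 1 else
        stats::t.test(v, r, alternative = "greater", var.equal = FALSE)$p.value
      derep <- p < 0.05 && mean(v) / mean(r) >= derep_fold
    }
  }
  list(
    short_term = mean(metrics$max_short, na.rm = TRUE) >
      mean(metrics$basal, na.rm = TRUE) + short_margin,
    shuttling = mean(metrics$pulse_rate, na.rm = TRUE) > min_rate,
    derepressed = derep
  )
}

#' Group-level report across conditions
#'
#' Aggregates per-cell metrics from several conditions into the group
#' comparison tables: per-condition mean/SD/95% CI and Welch test against
#' the reference condition for each headline metric, reporter fold changes
#' over the reference, and the measured qualitative matrix compared against
#' [expected_matrix()]. Dead cells are excluded via [viability_filter()]
#' before aggregation.
#'
#' @param metrics_list Named list of `mig_metrics` tables, names
#'   `"strain:hexose"` (as from [preset_grid()] keys).
#' @param reference Name of the reference condition (default
#'   `"wt:glucose"`); each hexose is compared against the wild type in the
#'   same hexose when available.
#' @param metrics_to_compare Metric columns to summarize.
#' @return List of class `mig_report`: `summary` (tidy data.frame of group
#'   summaries), `fold_changes`, `matrix` (measured qualitative calls with
#'   expected values and `agree` flags), `excluded` (dead-cell counts).
#' @export
build_report <- function(metrics_list, reference = "wt:glucose",
                         metrics_to_compare = c("max_short", "mean_long",
                                                "mean_pulse_height",
                                                "expr_mean_long")) {
  if (!length(metrics_list)) {
    warning("no conditions to report")
    return(structure(list(summary = data.frame(), fold_changes = data.frame(),
                          matrix = data.frame(), excluded = data.frame()),
                     class = "mig_report"))
  }
  viable <- list(); excluded <- list()
  for (nm in names(metrics_list)) {
    vf <- viability_filter(metrics_list[[nm]])
    viable[[nm]] <- vf$viable
    excluded[[nm]] <- data.frame(condition = nm, n_excluded = vf$n_excluded,
                                 expr_threshold = vf$expr_threshold)
  }

  ref_for <- function(nm) {
    hex <- sub("^.*:", "", nm)
    cand <- paste0("wt:", hex)
    if (cand %in% names(viable)) cand else
      if (reference %in% names(viable)) reference else NA_character_
  }

  rows <- list(); folds <- list(); mats <- list()
  exp_mat <- expected_matrix()
  for (nm in names(viable)) {
    mt <- viable[[nm]]
    if (!nrow(mt)) next
    rn <- ref_for(nm)
    ref_mt <- if (!is.na(rn)) viable[[rn]] else NULL
    for (metric in metrics_to_compare) {
      vals <- mt[[metric]]
      refv <- if (!is.null(ref_mt) && !identical(rn, nm)) ref_mt[[metric]] else NULL
      s <- summarize_group(vals, refv)
      rows[[length(rows) + 1]] <- cbind(
        data.frame(condition = nm, strain = mt$strain[1],
                   hexose = mt$hexose[1], metric = metric), s)
    }
    if (!is.null(ref_mt)) {
      fc <- fold_change(mean(mt$expr_mean_long, na.rm = TRUE),
                        mean(ref_mt$expr_mean_long, na.rm = TRUE))
      folds[[length(folds) + 1]] <- data.frame(
        condition = nm, reference = rn, fold = fc$fold,
        group_mean = fc$group_mean, reference_mean = fc$reference_mean)
      cls <- classify_condition(mt, ref_mt)
      em <- exp_mat[exp_mat$strain == mt$strain[1] &
                    exp_mat$hexose == mt$hexose[1], ]
      mats[[length(mats) + 1]] <- data.frame(
        condition = nm, strain = mt$strain[1], hexose = mt$hexose[1],
        short_term = cls$short_term, shuttling = cls$shuttling,
        derepressed = cls$derepressed,
        expected_short_term = if (nrow(em)) em$short_term else NA,
        expected_shuttling = if (nrow(em)) em$shuttling else NA,
        expected_derepressed = if (nrow(em)) em$derepressed else NA)
    }
  }
  summary <- do.call(rbind, rows)
  fold_changes <- if (length(folds)) do.call(rbind, folds) else data.frame()
  matrix_df <- if (length(mats)) do.call(rbind, mats) else data.frame()
  if (nrow(matrix_df)) {
    matrix_df$agree <- with(matrix_df,
      short_term == expected_short_term &
      shuttling == expected_shuttling &
      (is.na(expected_derepressed) | derepressed == expected_derepressed))
  }
  structure(list(summary = summary, fold_changes = fold_changes,
                 matrix = matrix_df,
                 excluded = do.call(rbind, excluded)),
            class = "mig_report")
}

#' @export
print.mig_report <- function(x, ...) {
  cat("Group report:", length(unique(x$summary$condition)), "conditions\n")
  if (nrow(x$matrix))
    cat("Qualitative matrix agreement:",
        sum(x$matrix$agree), "/", nrow(x$matrix), "conditions\n")
  invisible(x)
}

#' Strip plot of a per-cell metric by condition (Fig. 2d-style)
#'
#' Jittered per-cell points with the group mean, 95% CI and one-SD band,
#' and a horizontal basal reference line.
#'
#' @param metrics_list Named list of `mig_metrics`.
#' @param metric Column to plot.
#' @param basal_line Basal reference level (`NA` to omit).
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the summary table used.
#' @export
plot_metric_strip <- function(metrics_list, metric = "mean_long",
                              basal_line = NA, ...) {
  k <- length(metrics_list)
  vals <- lapply(metrics_list, function(m) m[[metric]][!is.na(m[[metric]])])
  ylim <- range(unlist(vals), na.rm = TRUE)
  graphics::plot(NA, xlim = c(0.5, k + 0.5), ylim = ylim, xaxt = "n",
                 xlab = "", ylab = metric, ...)
  graphics::axis(1, at = seq_len(k), labels = names(metrics_list), las = 2,
                 cex.axis = 0.7)
  out <- list()
  for (i in seq_len(k)) {
    v <- vals[[i]]
    if (!length(v)) next
    s <- summarize_group(v)
    graphics::rect(i - 0.3, s$mean - s$sd, i + 0.3, s$mean + s$sd,
                   col = grDevices::adjustcolor("steelblue", 0.15), border = NA)
    if (!is.na(s$ci_low))
      graphics::rect(i - 0.3, s$ci_low, i + 0.3, s$ci_high,
                     col = grDevices::adjustcolor("steelblue", 0.3), border = NA)
    graphics::points(jitter(rep(i, length(v)), amount = 0.18), v,
                     pch = 16, cex = 0.4,
                     col = grDevices::adjustcolor("grey30", 0.5))
    graphics::segments(i - 0.35, s$mean, i + 0.35, s$mean,
                       col = "steelblue4", lwd = 2)
    out[[i]] <- s
  }
  if (!is.na(basal_line)) graphics::abline(h = basal_line, col = "black")
  invisible(do.call(rbind, out))
}

#' Heatmap of localization traces (cells x time)
#'
#' @param traces A `mig_traces` table for one condition.
#' @param ... Passed to [graphics::image()].
#' @return Invisibly, the cells-by-time matrix drawn.
#' @export
plot_trace_heatmap <- function(traces, ...) {
  ids <- unique(traces$cell_id)
  times <- sort(unique(traces$time_min))
  m <- matrix(NA_real_, length(ids), length(times))
  for (i in seq_along(ids)) {
    tr <- traces[traces$cell_id == ids[i], ]
    m[i, match(tr$time_min, times)] <- tr$loc_index
  }
  graphics::image(x = times, y = seq_along(ids), z = t(m),
                  xlab = "time (min)", ylab = "cell",
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(m)
}
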