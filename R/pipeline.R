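#' Default run configuration
#'
#' Describes a full seeded run: the acquisition schedule, the condition list
#' (strain, hexose, cells, seed), scene geometry (ignored in trace-only
#' mode), analysis parameters and output directory. Trace-only mode feeds
#' ground-truth traces directly to the metrics stage so statistical runs do
#' not pay the imaging cost; it is a first-class path, not a shortcut.
#'
#' @param conditions Data frame with columns `strain`, `hexose`, `n_cells`,
#'   `seed` (every condition carries an explicit seed).
#' @param trace_only Skip rendering/segmentation/tracking.
#' @param out_dir Output directory.
#' @param schedule A [make_schedule()] object.
#' @param geometry A [scene_geometry()] object.
#' @param reference Reference condition name for the report.
#' @param analysis Named list of analysis overrides (`max_displacement`,
#'   `max_gap`, `min_prominence`, `min_separation`, `fallback_fraction`,
#'   `require_span`).
#' @return A list of class `mig_run_config`.
#' @export
run_config <- function(conditions = data.frame(
                         strain = c("wt", "hxk2d", "hxk1d_hxk2d"),
                         hexose = "glucose",
                         n_cells = 50,
                         seed = c(11L, 12L, 13L)),
                       trace_only = TRUE,
                       out_dir = tempfile("migshuttle_run_"),
                       schedule = make_schedule(),
                       geometry = scene_geometry(),
                       reference = "wt:glucose",
                       analysis = list()) {
  stopifnot(all(c("strain", "hexose", "n_cells", "seed") %in%
                names(conditions)))
  structure(list(conditions = conditions, trace_only = trace_only,
                 out_dir = out_dir, schedule = schedule,
                 geometry = geometry, reference = reference,
                 analysis = analysis),
            class = "mig_run_config")
}

#' Analyze one movie into per-cell traces
#'
#' The imaging arm of the pipeline: per-frame measurement
#' (division, segmentation, nucleus, index), tracking, trace assembly.
#'
#' @param movie A `mig_movie`.
#' @param strain,hexose Condition labels.
#' @param max_displacement,max_gap,require_span Tracking settings
#'   (see [build_tracks()]).
#' @param seg_params Segmentation parameters.
#' @param use_truth_masks Bypass segmentation with ground-truth masks.
#' @return List `traces` (a `mig_traces`), `measurements`, `tracks`.
#' @export
analyze_movie <- function(movie, strain = NA, hexose = NA,
                          max_displacement = 10, max_gap = 1,
                          require_span = NULL,
                          seg_params = segmentation_params(),
                          use_truth_masks = FALSE) {
  meas <- measure_stack(movie, params = seg_params,
                        use_truth_masks = use_truth_masks)
  tracks <- build_tracks(meas, max_displacement = max_displacement,
                         max_gap = max_gap, require_span = require_span)
  traces <- assemble_traces(tracks, meas, strain = strain, hexose = hexose)
  list(traces = traces, measurements = meas, tracks = tracks)
}

#' Run the full pipeline end to end
#'
#' For every condition: simulate ground truth (seeded), obtain per-cell
#' traces (trace-only or render + measure + track), compute per-cell
#' metrics, and finally build the cross-condition group report. All outputs
#' are CSV (plus PNG figures) under `config$out_dir`; a JSON manifest
#' records the config, seeds and file checksums, so two identical runs
#' produce byte-identical metric tables. A failing condition is logged and
#' skipped; the run fails only if every condition fails.
#'
#' @param config A [run_config()].
#' @return The `mig_report`, invisibly; side effect: the output directory.
#' @export
run_end_to_end <- function(config = run_config()) {
  stopifnot(inherits(config, "mig_run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  an <- config$analysis
  metrics_list <- list(); traces_list <- list(); failures <- character(0)

  for (i in seq_len(nrow(config$conditions))) {
    cond <- config$conditions[i, ]
    nm <- paste(cond$strain, cond$hexose, sep = ":")
    res <- tryCatch({
      cfg <- preset(cond$strain, cond$hexose,
                    n_cells = cond$n_cells, seed = cond$seed)
      truth <- simulate_traces(cfg, config$schedule)
      traces <- if (config$trace_only) {
        traces_from_truth(truth)
      } else {
        geom <- config$geometry
        geom$n_cells <- cfg$n_cells
        movie <- render_movie(truth, geom)
        analyze_movie(movie, strain = cfg$strain, hexose = cfg$hexose,
                      max_displacement = an$max_displacement %||% 10,
                      max_gap = an$max_gap %||% 1,
                      require_span = an$require_span)$traces
      }
      mt <- compute_trace_metrics(
        traces,
        min_prominence = an$min_prominence,
        min_separation = an$min_separation %||% 15)
      # dead-cell flags come from the generator in trace-only mode
      cond_dir <- file.path(config$out_dir, gsub(":", "_", nm))
      write_table_csv(traces, file.path(cond_dir, "traces.csv"))
      write_table_csv(mt$metrics, file.path(cond_dir, "metrics.csv"))
      write_table_csv(mt$pulses, file.path(cond_dir, "pulses.csv"))
      list(metrics = mt$metrics, traces = traces)
    }, error = function(e) {
      message("condition ", nm, " failed: ", conditionMessage(e))
      NULL
    })
    if (is.null(res)) failures <- c(failures, nm) else {
      metrics_list[[nm]] <- res$metrics
      traces_list[[nm]] <- res$traces
    }
  }
  if (!length(metrics_list))
    stop("all conditions failed: ", paste(failures, collapse = ", "))

  report <- build_report(metrics_list, reference = config$reference)
  write_table_csv(report$summary, file.path(config$out_dir, "summary.csv"))
  if (nrow(report$fold_changes))
    write_table_csv(report$fold_changes,
                    file.path(config$out_dir, "fold_changes.csv"))
  if (nrow(report$matrix))
    write_table_csv(report$matrix,
                    file.path(config$out_dir, "qualitative_matrix.csv"))

  grDevices::png(file.path(config$out_dir, "mean_long_strip.png"),
                 width = 900, height = 500)
  try(plot_metric_strip(metrics_list, "mean_long",
                        basal_line = 0.05), silent = TRUE)
  grDevices::dev.off()

  manifest <- list(
    conditions = config$conditions,
    trace_only = config$trace_only,
    reference = config$reference,
    failures = failures,
    files = as.list(tools::md5sum(list.files(config$out_dir, "\\.csv$",
                                             recursive = TRUE,
                                             full.names = TRUE))))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate test fixtures
#'
#' `tiny`: 5-cell, 30-frame trace-only fixtures plus one 128 x 128 px
#' rendered movie on a shortened schedule; `default`: the 3-condition
#' trace-only demo grid. All outputs are deterministic and checksummed.
#'
#' @param size `"tiny"` or `"default"`.
#' @param dir Output directory.
#' @return Named md5 checksum vector of the written files, invisibly.
#' @export
make_fixtures <- function(size = c("tiny", "default"),
                          dir = tempfile("migshuttle_fixtures_")) {
  size <- match.arg(size)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (size == "tiny") {
    sched <- make_schedule(30, 10, -60, 230, 4)  # 30 frames
    cfg <- preset("wt", "glucose", n_cells = 5, seed = 42L)
    truth <- simulate_traces(cfg, sched)
    write_truth(truth, file.path(dir, "traces_tiny"))
    geom <- scene_geometry(image_size = c(128, 128), n_cells = 5,
                           cell_radius_mean = 10, seed = 42L)
    movie <- render_movie(truth, geom)
    write_movie(movie, file.path(dir, "movie_tiny"))
  } else {
    cfg <- run_config(out_dir = file.path(dir, "demo_grid"))
    run_end_to_end(cfg)
  }
  files <- list.files(dir, recursive = TRUE, full.names = TRUE)
  sums <- tools::md5sum(files)
  utils::write.csv(data.frame(file = basename(names(sums)), md5 = sums),
                   file.path(dir, "checksums.csv"), row.names = FALSE)
  invisible(sums)
}
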