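#' Write a rendered movie to disk
#'
#' One 16-bit multi-page TIFF per channel plus 16-bit label stacks for the
#' ground-truth cell and nuclear masks, a CSV of frame times, and a small
#' YAML manifest (channel files, sparse-frame indices, image size). The
#' sparse expression-marker channel stores only its acquired frames; the
#' manifest records which.
#'
#' @param movie A `mig_movie`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_movie <- function(movie, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(image_size = dim(movie$channels[[1]])[1:2],
                   n_frames = length(movie$times),
                   sparse_frames = as.integer(movie$sparse_frames),
                   channels = list())
  for (nm in names(movie$channels)) {
    x <- movie$channels[[nm]]
    frames <- seq_len(dim(x)[3])
    if (nm == "expr_marker") frames <- movie$sparse_frames
    pages <- lapply(frames, function(tt) {
      m <- x[, , tt]
      m[is.na(m)] <- 0
      pmin(pmax(m, 0), 65535) / 65535
    })
    f <- file.path(dir, paste0(nm, ".tif"))
    tiff::writeTIFF(pages, f, bits.per.sample = 16, compression = "none")
    manifest$channels[[nm]] <- basename(f)
  }
  for (nm in c("labels", "nuc_labels")) {
    pages <- lapply(seq_len(dim(movie[[nm]])[3]),
                    function(tt) movie[[nm]][, , tt] / 65535)
    tiff::writeTIFF(pages, file.path(dir, paste0(nm, ".tif")),
                    bits.per.sample = 16, compression = "none")
  }
  utils::write.csv(data.frame(frame = seq_along(movie$times),
                              time_min = movie$times),
                   file.path(dir, "times.csv"), row.names = FALSE)
  yaml::write_yaml(manifest, file.path(dir, "movie.yaml"))
  invisible(dir)
}

#' Read a movie written by [write_movie()]
#'
#' @param dir Directory containing `movie.yaml` and the channel TIFFs.
#' @return A `mig_movie` (without geometry/positions; labels present if the
#'   label stacks were written).
#' @export
read_movie <- function(dir) {
  manifest <- yaml::read_yaml(file.path(dir, "movie.yaml"))
  times <- utils::read.csv(file.path(dir, "times.csv"))$time_min
  Tn <- manifest$n_frames
  H <- manifest$image_size[[1]]; W <- manifest$image_size[[2]]
  channels <- list()
  for (nm in names(manifest$channels)) {
    pages <- tiff::readTIFF(file.path(dir, manifest$channels[[nm]]),
                            all = TRUE)
    x <- array(NA_real_, c(H, W, Tn))
    frames <- if (nm == "expr_marker") unlist(manifest$sparse_frames) else
      seq_len(Tn)
    for (k in seq_along(frames)) x[, , frames[k]] <- pages[[k]] * 65535
    channels[[nm]] <- x
  }
  out <- list(channels = channels, times = times,
              sparse_frames = unlist(manifest$sparse_frames))
  for (nm in c("labels", "nuc_labels")) {
    f <- file.path(dir, paste0(nm, ".tif"))
    if (file.exists(f)) {
      pages <- tiff::readTIFF(f, all = TRUE)
      x <- array(0L, c(H, W, Tn))
      for (k in seq_len(Tn)) x[, , k] <- as.integer(round(pages[[k]] * 65535))
      out[[nm]] <- x
    }
  }
  structure(out, class = "mig_movie")
}

#' Write tidy traces / measurements / metrics tables as CSV
#' @param x A data frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(x, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' Write ground truth (traces, pulses, per-cell parameters) as CSV
#' @param truth A `mig_truth`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_table_csv(traces_from_truth(truth), file.path(dir, "traces.csv"))
  write_table_csv(truth$pulses, file.path(dir, "pulses.csv"))
  write_table_csv(truth$cells, file.path(dir, "cells.csv"))
  invisible(dir)
}

#' Serialize a simulation config to / from YAML
#'
#' The YAML round-trip keeps every numeric preset value explicit (including
#' the seed), so a written condition file fully determines a simulation.
#'
#' @param config A `mig_sim_config`.
#' @param path YAML file path.
#' @return `path` invisibly (write), or a `mig_sim_config` (read).
#' @export
write_sim_config <- function(config, path) {
  x <- unclass(config)
  x$reporter <- unclass(x$reporter)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- yaml::read_yaml(path)
  rp <- do.call(reporter_params, x$reporter)
  x$reporter <- NULL
  dr <- x$dose_response
  x$dose_response <- NULL
  cfg <- do.call(sim_config, c(x, list(reporter = rp)))
  cfg$dose_response <- dr
  cfg
}
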