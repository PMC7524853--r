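#' Scene geometry for rendering synthetic movies
#'
#' Describes how simulated cells are drawn: image size, cell and nuclear
#' sizes, drift, optics and illumination. Cells sit in microfluidic traps,
#' so drift is a bounded random walk of step `drift_per_frame` around a
#' fixed home position, clipped to `max_excursion`; home positions are
#' placed with enough clearance that cells can never overlap.
#'
#' @param image_size `c(height, width)` in pixels.
#' @param n_cells Number of cells to place (matched against the simulated
#'   traces at render time).
#' @param cell_radius_mean,cell_radius_sd Cell radius distribution (px).
#' @param nuclear_area_fraction Nuclear area as a fraction of cell area,
#'   in (0, 0.5). The nucleus is drawn concentric with the cell.
#' @param drift_per_frame Random-walk step per frame (px).
#' @param max_excursion Maximum displacement from the home position (px).
#' @param psf_sigma Gaussian blur applied to the brightfield channels (px);
#'   fluorescence channels are rendered unblurred so the analytic
#'   nuclear:cytoplasmic split is exactly invertible at zero noise.
#' @param ring_width Width of the out-of-focus diffraction ring (px).
#' @param background_level Camera background (AU).
#' @param illumination_gradient Either `NULL` (flat illumination) or a
#'   corner-to-corner multiplicative factor (e.g. `2` for a 2x linear
#'   gradient along the image diagonal) applied to every channel.
#' @param seed Seed for cell placement and drift.
#' @return A list of class `mig_geometry`.
#' @export
scene_geometry <- function(image_size = c(256, 256), n_cells = 20,
                           cell_radius_mean = 12, cell_radius_sd = 1.5,
                           nuclear_area_fraction = 0.12,
                           drift_per_frame = 1, max_excursion = 4,
                           psf_sigma = 1, ring_width = 1.8,
                           background_level = 100,
                           illumination_gradient = NULL,
                           seed = 1L) {
  stopifnot(nuclear_area_fraction > 0, nuclear_area_fraction < 0.5,
            drift_per_frame >= 0, cell_radius_mean > 0)
  structure(list(image_size = image_size, n_cells = n_cells,
                 cell_radius_mean = cell_radius_mean,
                 cell_radius_sd = cell_radius_sd,
                 nuclear_area_fraction = nuclear_area_fraction,
                 drift_per_frame = drift_per_frame,
                 max_excursion = max_excursion,
                 psf_sigma = psf_sigma, ring_width = ring_width,
                 background_level = background_level,
                 illumination_gradient = illumination_gradient,
                 seed = as.integer(seed)),
            class = "mig_geometry")
}

.illumination_field <- function(geometry) {
  H <- geometry$image_size[1]; W <- geometry$image_size[2]
  g <- geometry$illumination_gradient
  if (is.null(g) || identical(g, 1)) return(matrix(1, H, W))
  # linear ramp from 1 to g along the image diagonal
  rr <- matrix(seq_len(H), H, W)
  cc <- matrix(seq_len(W), H, W, byrow = TRUE)
  u <- ((rr - 1) / (H - 1) + (cc - 1) / (W - 1)) / 2
  1 + (g - 1) * u
}

# Place non-overlapping home positions with clearance for drift.
.place_cells <- function(geometry, radii) {
  H <- geometry$image_size[1]; W <- geometry$image_size[2]
  margin <- max(radii) + geometry$max_excursion + 3
  n <- length(radii)
  pos <- matrix(NA_real_, n, 2)
  min_sep <- 2 * (max(radii) + geometry$max_excursion) + 4
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in 1:2000) {
      p <- c(stats::runif(1, margin, H - margin),
             stats::runif(1, margin, W - margin))
      if (i == 1 ||
          all(sqrt(rowSums((pos[seq_len(i - 1), , drop = FALSE] -
                            matrix(p, i - 1, 2, byrow = TRUE))^2)) >= min_sep)) {
        pos[i, ] <- p; placed <- TRUE; break
      }
    }
    if (!placed)
      stop("could not place ", n, " non-overlapping cells in a ",
           H, "x", W, " image; enlarge the image or reduce n_cells")
  }
  pos
}

# Bounded random-walk drift tracks: n x T x 2 offsets from home.
.drift_tracks <- function(geometry, n, Tn, dead, death_frame) {
  off <- array(0, c(n, Tn, 2))
  s <- geometry$drift_per_frame
  if (s <= 0 || Tn == 1) return(off)
  for (i in seq_len(n)) {
    last <- c(0, 0)
    stop_at <- if (dead[i]) death_frame else Tn
    for (tt in 2:Tn) {
      if (tt <= stop_at) {
        step <- stats::rnorm(2, 0, s / sqrt(2))
        last <- last + step
        ex <- sqrt(sum(last^2))
        if (ex > geometry$max_excursion)
          last <- last * geometry$max_excursion / ex
      }
      off[i, tt, ] <- last
    }
  }
  off
}

#' Render simulated traces into a multi-channel time-lapse movie
#'
#' Draws each frame of the six imaging channels from ground-truth dynamics:
#' \itemize{
#'   \item `bf_above` / `bf_below`: out-of-focus brightfield with a bright
#'     (above focus) or dark (below focus) diffraction ring at each cell
#'     boundary, on `background_level` times the illumination field --
#'     the minimal pattern the above/below division trick enhances.
#'   \item `gfp`: each cell's total fluorescence is fixed; the
#'     nuclear:cytoplasmic split is computed analytically so that
#'     `median(nuclear) / median(whole cell) - 1` equals the ground-truth
#'     localization index exactly at zero noise.
#'   \item `nuc_marker`: bright in the nuclear mask only.
#'   \item `reporter`: uniform over the cell, proportional to the reporter
#'     fluorescence.
#'   \item `expr_marker`: constant per cell, rendered only on the
#'     schedule's sparse frames (every 4th post-shift frame by default).
#' }
#' Cells drift on a bounded random walk; dead cells stop drifting and their
#' intensities freeze (the generator freezes their traces). Optionally adds
#' Poisson shot noise plus Gaussian read noise and rounds to integer counts.
#'
#' @param truth A [simulate_traces()] result.
#' @param geometry A [scene_geometry()]; `n_cells` must cover the traces.
#' @param noise Add Poisson + Gaussian camera noise (default TRUE).
#' @param read_noise_sd Gaussian read noise SD in counts.
#' @param quantize Round to integer counts (emulating a 16-bit camera).
#' @return An object of class `mig_movie`: list with `channels` (named list
#'   of height x width x frames arrays), `times`, `sparse_frames`, `labels`
#'   and `nuc_labels` (ground-truth 16-bit-style label stacks), `geometry`,
#'   and per-frame cell centers `positions` (n x frames x 2).
#' @export
render_movie <- function(truth, geometry = scene_geometry(n_cells = nrow(truth$index)),
                         noise = TRUE, read_noise_sd = 2, quantize = TRUE) {
  stopifnot(inherits(truth, "mig_truth"), inherits(geometry, "mig_geometry"))
  n <- nrow(truth$index)
  if (geometry$n_cells < n) geometry$n_cells <- n
  Tn <- ncol(truth$index)
  H <- geometry$image_size[1]; W <- geometry$image_size[2]
  set.seed(geometry$seed + truth$config$seed)

  radii <- pmax(stats::rnorm(n, geometry$cell_radius_mean,
                             geometry$cell_radius_sd), 4)
  home <- .place_cells(geometry, radii)
  death_frame <- which(truth$times >= 60)[1]
  off <- .drift_tracks(geometry, n, Tn, truth$cells$dead, death_frame)
  illum <- .illumination_field(geometry)
  bg <- geometry$background_level

  chan_names <- c("bf_above", "bf_below", "gfp", "nuc_marker",
                  "reporter", "expr_marker")
  channels <- lapply(chan_names, function(x) array(0, c(H, W, Tn)))
  names(channels) <- chan_names
  labels <- array(0L, c(H, W, Tn))
  nuc_labels <- array(0L, c(H, W, Tn))
  positions <- array(NA_real_, c(n, Tn, 2))

  rr <- matrix(seq_len(H), H, W)
  cc <- matrix(seq_len(W), H, W, byrow = TRUE)
  gfp_total_per_px <- 2000   # mean GFP counts per cell pixel
  nuc_marker_level <- 3000
  reporter_gain <- 50        # counts per reporter AU

  for (tt in seq_len(Tn)) {
    ring <- matrix(0, H, W)
    gfp <- matrix(bg, H, W)
    nucm <- matrix(bg, H, W)
    repo <- matrix(bg, H, W)
    expm <- matrix(bg, H, W)
    lab <- matrix(0L, H, W)
    nlab <- matrix(0L, H, W)
    for (i in seq_len(n)) {
      ctr <- home[i, ] + off[i, tt, ]
      positions[i, tt, ] <- ctr
      R <- radii[i]
      # work on a local window around the cell
      r0 <- max(1, floor(ctr[1] - R - 6)); r1 <- min(H, ceiling(ctr[1] + R + 6))
      c0 <- max(1, floor(ctr[2] - R - 6)); c1 <- min(W, ceiling(ctr[2] + R + 6))
      d <- sqrt((rr[r0:r1, c0:c1] - ctr[1])^2 + (cc[r0:r1, c0:c1] - ctr[2])^2)
      ring[r0:r1, c0:c1] <- ring[r0:r1, c0:c1] +
        exp(-(d - R)^2 / (2 * geometry$ring_width^2))
      inside <- d <= R
      rn <- R * sqrt(geometry$nuclear_area_fraction)
      in_nuc <- d <= rn
      a_tot <- sum(inside); a_nuc <- sum(in_nuc)
      idx <- truth$index_clean[i, tt]
      # analytic split: v_nuc = v_cyt * (1 + idx), total fixed
      v_cyt <- gfp_total_per_px * a_tot / (a_nuc * (1 + idx) + (a_tot - a_nuc))
      v_nuc <- v_cyt * (1 + idx)
      sub <- gfp[r0:r1, c0:c1]
      sub[inside] <- v_cyt; sub[in_nuc] <- v_nuc
      gfp[r0:r1, c0:c1] <- sub

      sub <- nucm[r0:r1, c0:c1]; sub[in_nuc] <- bg + nuc_marker_level
      nucm[r0:r1, c0:c1] <- sub
      sub <- repo[r0:r1, c0:c1]
      sub[inside] <- bg + reporter_gain * truth$reporter[i, tt]
      repo[r0:r1, c0:c1] <- sub
      sub <- expm[r0:r1, c0:c1]; sub[inside] <- bg + truth$expr_marker[i]
      expm[r0:r1, c0:c1] <- sub

      sub <- lab[r0:r1, c0:c1]; sub[inside] <- i; lab[r0:r1, c0:c1] <- sub
      sub <- nlab[r0:r1, c0:c1]; sub[in_nuc] <- i; nlab[r0:r1, c0:c1] <- sub
    }
    above <- 1 + 0.6 * ring
    below <- pmax(1 - 0.4 * ring, 0.05)
    if (geometry$psf_sigma > 0) {
      above <- as.matrix(EBImage::gblur(EBImage::Image(above),
                                        sigma = geometry$psf_sigma))
      below <- as.matrix(EBImage::gblur(EBImage::Image(below),
                                        sigma = geometry$psf_sigma))
    }
    channels$bf_above[, , tt] <- bg * illum * above
    channels$bf_below[, , tt] <- bg * illum * below
    channels$gfp[, , tt] <- illum * gfp
    channels$nuc_marker[, , tt] <- illum * nucm
    channels$reporter[, , tt] <- illum * repo
    channels$expr_marker[, , tt] <-
      if (tt %in% truth$schedule$sparse_frames) illum * expm else NA_real_
    labels[, , tt] <- lab
    nuc_labels[, , tt] <- nlab
  }

  if (noise) {
    for (nm in chan_names) {
      x <- channels[[nm]]
      ok <- !is.na(x)
      x[ok] <- stats::rpois(sum(ok), x[ok]) +
        stats::rnorm(sum(ok), 0, read_noise_sd)
      channels[[nm]] <- x
    }
  }
  if (quantize) {
    for (nm in chan_names)
      channels[[nm]] <- round(pmax(pmin(channels[[nm]], 65535), 0))
  }

  structure(list(channels = channels, times = truth$times,
                 sparse_frames = truth$schedule$sparse_frames,
                 labels = labels, nuc_labels = nuc_labels,
                 geometry = geometry, positions = positions),
            class = "mig_movie")
}

#' @export
print.mig_movie <- function(x, ...) {
  d <- dim(x$channels$gfp)
  cat(sprintf("Movie: %d x %d px, %d frames, %d channels, %d ground-truth cells\n",
              d[1], d[2], d[3], length(x$channels), max(x$labels)))
  invisible(x)
}
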