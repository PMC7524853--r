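#' Divide above-focus by below-focus brightfield
#'
#' Pixelwise ratio `above / (below + epsilon)`. Because uneven illumination
#' multiplies both out-of-focus planes by the same field, the division
#' cancels it and leaves the cells' diffraction ring pattern (bright ring
#' above focus over dark ring below focus) on a flat unit background, which
#' is what the segmentation operates on.
#'
#' @param above,below Brightfield images (matrices of equal shape).
#' @param epsilon Stabilizer added to the denominator; default
#'   `1e-6 * median(below)`.
#' @return The divided image (matrix).
#' @export
divide_brightfield <- function(above, below,
                               epsilon = 1e-6 * stats::median(below)) {
  if (!all(dim(above) == dim(below)))
    stop("above and below images must have the same shape")
  if (epsilon <= 0) epsilon <- .Machine$double.eps
  above / (below + epsilon)
}

#' Default segmentation parameters
#'
#' @param smooth_sigma Gaussian smoothing of the ring-deviation image (px).
#' @param threshold Absolute deviation from the unit background above which
#'   a pixel is called ring.
#' @param close_size Diameter of the disc brush used to close the ring into
#'   an annulus before hole filling (px).
#' @param erode_size Diameter of the disc brush used to shrink the filled
#'   region back to the cell boundary (px).
#' @param min_area,max_area Area filter (px).
#' @return A parameter list.
#' @export
segmentation_params <- function(smooth_sigma = 1.5, threshold = 0.35,
                                close_size = 7, erode_size = 5,
                                min_area = 150, max_area = 5000) {
  list(smooth_sigma = smooth_sigma, threshold = threshold,
       close_size = close_size, erode_size = erode_size,
       min_area = min_area, max_area = max_area)
}

#' Segment cells in a divided brightfield image
#'
#' Smoothing, absolute-deviation thresholding of the divided image's ring
#' pattern, morphological closing, hole filling, erosion back to the cell
#' boundary, watershed splitting on the distance transform, and an area
#' filter. This is a documented equivalent of the membrane-pattern
#' segmentation the original analysis delegated to CellX; the package's
#' contribution is the downstream quantification, not the segmenter.
#'
#' @param divided Output of [divide_brightfield()].
#' @param params A [segmentation_params()] list.
#' @return A list of class `mig_regions`: `labels` (integer label matrix,
#'   0 = background) and `features` (data.frame with `label`, `centroid_r`,
#'   `centroid_c`, `area`). A blank image yields zero regions.
#' @export
segment_cells <- function(divided, params = segmentation_params()) {
  dev_img <- abs(divided - 1)
  if (params$smooth_sigma > 0)
    dev_img <- as.matrix(EBImage::gblur(EBImage::Image(dev_img),
                                        sigma = params$smooth_sigma))
  mask <- dev_img > params$threshold
  if (!any(mask)) return(.regions_from_labels(matrix(0L, nrow(divided), ncol(divided))))

  m <- EBImage::Image(mask * 1)
  m <- EBImage::closing(m, EBImage::makeBrush(.odd(params$close_size), "disc"))
  m <- EBImage::fillHull(m)
  if (params$erode_size > 0)
    m <- EBImage::erode(m, EBImage::makeBrush(.odd(params$erode_size), "disc"))
  dm <- EBImage::distmap(m)
  lab <- EBImage::watershed(dm, tolerance = 2)
  lab <- matrix(as.integer(as.matrix(lab)), nrow(divided), ncol(divided))

  # area filter + relabel consecutively
  areas <- tabulate(lab[lab > 0])
  keep <- which(areas >= params$min_area & areas <= params$max_area)
  remap <- integer(length(areas))
  remap[keep] <- seq_along(keep)
  lab[lab > 0] <- remap[lab[lab > 0]]
  .regions_from_labels(lab)
}

.odd <- function(x) { x <- max(1L, round(x)); if (x %% 2 == 0) x + 1L else x }

.regions_from_labels <- function(lab) {
  labs <- sort(unique(lab[lab > 0]))
  if (length(labs) == 0) {
    feats <- data.frame(label = integer(0), centroid_r = numeric(0),
                        centroid_c = numeric(0), area = integer(0))
  } else {
    idx <- which(lab > 0)
    l <- lab[idx]
    r <- (idx - 1) %% nrow(lab) + 1
    c <- (idx - 1) %/% nrow(lab) + 1
    feats <- data.frame(
      label = labs,
      centroid_r = as.numeric(tapply(r, l, mean)[as.character(labs)]),
      centroid_c = as.numeric(tapply(c, l, mean)[as.character(labs)]),
      area = as.integer(tapply(l, l, length)[as.character(labs)]))
  }
  structure(list(labels = lab, features = feats), class = "mig_regions")
}

# Otsu threshold of a value vector (wraps EBImage's histogram Otsu).
.otsu_threshold <- function(v) {
  rng <- range(v)
  if (diff(rng) <= 0) return(NA_real_)
  img <- EBImage::Image(matrix(v, ncol = 1))
  EBImage::otsu(img, range = rng, levels = 256)
}

# Greedy brightest-first contiguous region growth: start from the brightest
# pixel, repeatedly add the brightest 4-neighbour, until n pixels.
.grow_brightest <- function(vals_img, mask_idx, n, nrow_img) {
  v <- vals_img[mask_idx]
  start <- mask_idx[which.max(v)]
  chosen <- start
  frontier <- .neighbors4(start, nrow_img)
  frontier <- frontier[frontier %in% mask_idx]
  while (length(chosen) < n && length(frontier) > 0) {
    fv <- vals_img[frontier]
    pick <- frontier[which.max(fv)]
    chosen <- c(chosen, pick)
    frontier <- setdiff(unique(c(frontier, .neighbors4(pick, nrow_img))), chosen)
    frontier <- frontier[frontier %in% mask_idx]
  }
  chosen
}

.neighbors4 <- function(idx, nr) {
  r <- (idx - 1) %% nr + 1
  out <- c(idx - 1, idx + 1, idx - nr, idx + nr)
  out[!(r == 1 & out == idx - 1) & !(r == nr & out == idx + 1) & out > 0]
}

#' Identify the nuclear submask of each segmented cell
#'
#' For each cell, thresholds the nuclear-marker channel within the cell mask
#' (Otsu) and keeps the largest connected component. If the marker is absent
#' or flat within the cell (no bimodality to threshold), falls back to the
#' brightest contiguous `fallback_fraction` of the cell's GFP pixels, grown
#' greedily from the brightest pixel, with exactly
#' `round(fallback_fraction * area)` pixels. A nuclear mask that would cover
#' the whole cell is shrunk to the fallback fraction with a warning.
#'
#' @param regions A `mig_regions` object (from [segment_cells()] or ground
#'   truth labels via [regions_from_label_matrix()]).
#' @param nuc_marker Nuclear-marker image, or `NULL` to force the fallback.
#' @param gfp GFP image (used by the fallback).
#' @param fallback_fraction Nuclear area fraction for the fallback, in (0,1).
#' @return `regions` with an added `nuc_labels` integer matrix (same label
#'   values as `labels`).
#' @export
identify_nucleus <- function(regions, nuc_marker = NULL, gfp = NULL,
                             fallback_fraction = 0.12) {
  lab <- regions$labels
  nr <- nrow(lab)
  nuc <- matrix(0L, nr, ncol(lab))
  for (li in regions$features$label) {
    mask_idx <- which(lab == li)
    if (length(mask_idx) == 0) next
    chosen <- NULL
    if (!is.null(nuc_marker)) {
      v <- nuc_marker[mask_idx]
      thr <- if (stats::sd(v) > 1e-9) .otsu_threshold(v) else NA_real_
      if (!is.na(thr)) {
        cand <- mask_idx[v > thr]
        if (length(cand) > 0 && length(cand) < length(mask_idx)) {
          chosen <- .largest_component(cand, nr, dim(lab))
        }
      }
    }
    if (is.null(chosen)) {
      src <- if (!is.null(gfp)) gfp else nuc_marker
      if (is.null(src)) next
      n_target <- max(1L, round(fallback_fraction * length(mask_idx)))
      chosen <- .grow_brightest(src, mask_idx, n_target, nr)
    }
    if (length(chosen) >= length(mask_idx)) {
      warning("nuclear mask covered the whole cell (label ", li,
              "); shrinking to fallback fraction")
      src <- if (!is.null(nuc_marker)) nuc_marker else gfp
      n_target <- max(1L, round(fallback_fraction * length(mask_idx)))
      chosen <- .grow_brightest(src, mask_idx, n_target, nr)
    }
    nuc[chosen] <- li
  }
  regions$nuc_labels <- nuc
  regions
}

.largest_component <- function(idx, nr, dims) {
  sub <- matrix(0, dims[1], dims[2])
  sub[idx] <- 1
  cc <- matrix(as.integer(as.matrix(EBImage::bwlabel(EBImage::Image(sub)))),
               dims[1], dims[2])
  tab <- tabulate(cc[cc > 0])
  which(cc == which.max(tab))
}

#' Wrap a ground-truth label matrix as segmentation regions
#' @param lab Integer label matrix (0 = background).
#' @return A `mig_regions` object.
#' @export
regions_from_label_matrix <- function(lab) .regions_from_labels(lab)

#' Measure one cell: the Mig1 localization index and reporter intensities
#'
#' Computes `median_nuc` (median GFP over the nuclear mask), `median_total`
#' (median GFP over the whole cell mask) and the localization index
#' `median_nuc / median_total - 1` -- 0 for uniform Mig1-GFP, positive for
#' nuclear enrichment, bounded below by -1 for nonnegative intensities.
#' Reporter and expression-marker intensities are means over the whole cell
#' (chosen for linearity with expression). A non-positive `median_total`
#' flags the measurement invalid.
#'
#' @param mask_idx Linear pixel indices of the cell mask.
#' @param nuc_idx Linear pixel indices of the nuclear submask (subset).
#' @param gfp GFP image.
#' @param reporter Reporter image or `NULL`.
#' @param expr Expression-marker image or `NULL` (sparse channel frames).
#' @param time Frame time in minutes.
#' @return One-row data.frame: `time_min`, `median_nuc`, `median_total`,
#'   `loc_index`, `reporter`, `expr_marker`, `valid`.
#' @examples
#' img <- matrix(100, 10, 10); img[4:6, 4:6] <- 300
#' cell <- which(img > 0); nuc <- which(img == 300)
#' measure_cell(cell, nuc, img)$loc_index  # 2
#' @export
measure_cell <- function(mask_idx, nuc_idx, gfp, reporter = NULL,
                         expr = NULL, time = NA_real_) {
  median_nuc <- stats::median(gfp[nuc_idx])
  median_total <- stats::median(gfp[mask_idx])
  valid <- length(nuc_idx) > 0 && is.finite(median_total) && median_total > 0
  loc_index <- if (valid) median_nuc / median_total - 1 else NA_real_
  rep_val <- if (!is.null(reporter)) mean(reporter[mask_idx]) else NA_real_
  expr_val <- if (!is.null(expr)) mean(expr[mask_idx]) else NA_real_
  data.frame(time_min = time, median_nuc = median_nuc,
             median_total = median_total, loc_index = loc_index,
             reporter = rep_val, expr_marker = expr_val, valid = valid)
}

#' Measure every cell in every frame of a movie
#'
#' Runs the frame pipeline -- brightfield division, segmentation, nucleus
#' identification, per-cell measurement -- over a whole movie. With
#' `use_truth_masks = TRUE` the movie's ground-truth label stacks replace
#' segmentation and nucleus identification (used by round-trip and
#' illumination-invariance checks). Per-frame failures are logged and
#' skipped, never abort the stack.
#'
#' @param movie A `mig_movie` (or a compatible list of channel arrays with
#'   `times`).
#' @param params [segmentation_params()] for the segmenter.
#' @param use_truth_masks Use `movie$labels` / `movie$nuc_labels` instead of
#'   segmenting.
#' @param fallback_fraction Passed to [identify_nucleus()].
#' @param epsilon Passed to [divide_brightfield()]; `NULL` for the default.
#' @return A data.frame of class `mig_measurements`, one row per detected
#'   cell per frame: `frame`, `time_min`, `cell_label`, `centroid_r`,
#'   `centroid_c`, `area`, `median_nuc`, `median_total`, `loc_index`,
#'   `reporter`, `expr_marker` (NA on non-sparse frames), `valid`.
#' @export
measure_stack <- function(movie, params = segmentation_params(),
                          use_truth_masks = FALSE,
                          fallback_fraction = 0.12, epsilon = NULL) {
  Tn <- length(movie$times)
  rows <- vector("list", Tn)
  for (tt in seq_len(Tn)) {
    res <- tryCatch({
      if (use_truth_masks) {
        regions <- regions_from_label_matrix(movie$labels[, , tt])
        regions$nuc_labels <- movie$nuc_labels[, , tt]
      } else {
        div <- if (is.null(epsilon)) {
          divide_brightfield(movie$channels$bf_above[, , tt],
                             movie$channels$bf_below[, , tt])
        } else {
          divide_brightfield(movie$channels$bf_above[, , tt],
                             movie$channels$bf_below[, , tt], epsilon)
        }
        regions <- segment_cells(div, params)
        regions <- identify_nucleus(regions,
                                    nuc_marker = movie$channels$nuc_marker[, , tt],
                                    gfp = movie$channels$gfp[, , tt],
                                    fallback_fraction = fallback_fraction)
      }
      gfp <- movie$channels$gfp[, , tt]
      repo <- movie$channels$reporter[, , tt]
      expm <- movie$channels$expr_marker[, , tt]
      if (all(is.na(expm))) expm <- NULL
      out <- lapply(seq_len(nrow(regions$features)), function(k) {
        li <- regions$features$label[k]
        mask_idx <- which(regions$labels == li)
        nuc_idx <- which(regions$nuc_labels == li)
        m <- measure_cell(mask_idx, nuc_idx, gfp, repo, expm,
                          time = movie$times[tt])
        cbind(data.frame(frame = tt, cell_label = li,
                         centroid_r = regions$features$centroid_r[k],
                         centroid_c = regions$features$centroid_c[k],
                         area = regions$features$area[k]), m)
      })
      if (length(out)) do.call(rbind, out) else NULL
    }, error = function(e) {
      message("frame ", tt, " skipped: ", conditionMessage(e))
      NULL
    })
    rows[[tt]] <- res
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(frame = integer(0), cell_label = integer(0),
                      centroid_r = numeric(0), centroid_c = numeric(0),
                      area = integer(0), time_min = numeric(0),
                      median_nuc = numeric(0), median_total = numeric(0),
                      loc_index = numeric(0), reporter = numeric(0),
                      expr_marker = numeric(0), valid = logical(0))
  class(out) <- c("mig_measurements", "data.frame")
  out
}
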