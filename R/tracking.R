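#' Optimally link cell regions between two frames
#'
#' One-to-one assignment between the regions of two frames minimizing total
#' centroid distance (optimal bipartite assignment via the Hungarian-method
#' contract of `clue::solve_LSAP`), with pairs farther apart than
#' `max_displacement` rejected and left unmatched.
#'
#' @param regions_a,regions_b Data frames with columns `label`, `centroid_r`,
#'   `centroid_c` (e.g. the `features` element of a `mig_regions`).
#' @param max_displacement Gating distance in pixels (> 0).
#' @return List with `pairs` (data.frame `label_a`, `label_b`, `dist`),
#'   `unmatched_a`, `unmatched_b` (label vectors). Empty inputs give an
#'   empty assignment.
#' @export
link_frames <- function(regions_a, regions_b, max_displacement = 10) {
  stopifnot(max_displacement > 0)
  na <- nrow(regions_a); nb <- nrow(regions_b)
  empty <- data.frame(label_a = integer(0), label_b = integer(0),
                      dist = numeric(0))
  if (na == 0 || nb == 0) {
    return(list(pairs = empty,
                unmatched_a = regions_a$label, unmatched_b = regions_b$label))
  }
  d <- sqrt(outer(regions_a$centroid_r, regions_b$centroid_r, "-")^2 +
            outer(regions_a$centroid_c, regions_b$centroid_c, "-")^2)
  big <- max_displacement * 1e6
  cost <- ifelse(d <= max_displacement, d, big)

  transposed <- na > nb
  cm <- if (transposed) t(cost) else cost
  sol <- clue::solve_LSAP(cm)
  ia <- seq_len(nrow(cm)); ib <- as.integer(sol)
  if (transposed) { tmp <- ia; ia <- ib; ib <- tmp }
  ok <- d[cbind(ia, ib)] <= max_displacement
  pairs <- data.frame(label_a = regions_a$label[ia[ok]],
                      label_b = regions_b$label[ib[ok]],
                      dist = d[cbind(ia, ib)][ok])
  list(pairs = pairs,
       unmatched_a = setdiff(regions_a$label, pairs$label_a),
       unmatched_b = setdiff(regions_b$label, pairs$label_b))
}

#' Build single-cell tracks across a movie
#'
#' Chains frame-to-frame optimal assignments into tracks. A track whose cell
#' is missed in up to `max_gap` consecutive frames can be bridged: at each
#' frame, regions are matched against all open tracks last seen up to
#' `max_gap + 1` frames ago, with the displacement gate relaxed
#' proportionally to the gap length. Unmatched regions start new tracks
#' (divisions produce daughters as new tracks; no lineage is kept). Tracks
#' with fewer than `min_length` entries, or not spanning `require_span`
#' (a `c(t_before, t_after)` pair of times in minutes that the track must
#' reach on both sides), are discarded.
#'
#' @param measurements A `mig_measurements` table (needs `frame`,
#'   `cell_label`, `centroid_r`, `centroid_c`, `time_min`).
#' @param max_displacement Per-frame gating distance (px).
#' @param max_gap Maximum bridged gap in frames (default 1 = one missed
#'   5-min frame).
#' @param min_length Minimum number of entries per track.
#' @param require_span Optional `c(t0, t1)`: keep only tracks with an entry
#'   at time <= t0 and one at time >= t1 (e.g. `c(0, 240)` to demand both
#'   pre-shift and adapted-phase coverage). `NULL` to disable.
#' @return Data frame of class `mig_tracks`: `track_id`, `frame`,
#'   `time_min`, `cell_label`.
#' @export
build_tracks <- function(measurements, max_displacement = 10, max_gap = 1,
                         min_length = 2, require_span = NULL) {
  frames <- sort(unique(measurements$frame))
  time_of <- tapply(measurements$time_min, measurements$frame, `[`, 1)

  # open tracks: list of (id, last_frame, last_r, last_c, entries df)
  next_id <- 1L
  open <- list()
  closed <- list()

  for (f in frames) {
    cur <- measurements[measurements$frame == f,
                        c("cell_label", "centroid_r", "centroid_c")]
    # retire tracks whose gap exceeded max_gap
    if (length(open)) {
      last_fr <- vapply(open, function(tr) tr$last_frame, numeric(1))
      expired <- last_fr < f - 1 - max_gap
      closed <- c(closed, open[expired])
      open <- open[!expired]
    }
    assigned <- rep(FALSE, nrow(cur))
    if (length(open) && nrow(cur)) {
      tr_r <- vapply(open, function(tr) tr$last_r, numeric(1))
      tr_c <- vapply(open, function(tr) tr$last_c, numeric(1))
      gapn <- f - vapply(open, function(tr) tr$last_frame, numeric(1))
      d <- sqrt(outer(tr_r, cur$centroid_r, "-")^2 +
                outer(tr_c, cur$centroid_c, "-")^2)
      gate <- max_displacement * gapn  # relaxed proportionally to the gap
      allowed <- d <= matrix(gate, nrow(d), ncol(d))
      big <- max_displacement * 1e6
      cost <- ifelse(allowed, d, big)
      transposed <- nrow(cost) > ncol(cost)
      cm <- if (transposed) t(cost) else cost
      sol <- clue::solve_LSAP(cm)
      it <- seq_len(nrow(cm)); ic <- as.integer(sol)
      if (transposed) { tmp <- it; it <- ic; ic <- tmp }
      ok <- allowed[cbind(it, ic)]
      for (k in which(ok)) {
        tr <- open[[it[k]]]
        tr$entries <- rbind(tr$entries,
                            data.frame(frame = f, cell_label = cur$cell_label[ic[k]]))
        tr$last_frame <- f
        tr$last_r <- cur$centroid_r[ic[k]]
        tr$last_c <- cur$centroid_c[ic[k]]
        open[[it[k]]] <- tr
        assigned[ic[k]] <- TRUE
      }
    }
    for (k in which(!assigned)) {
      open[[length(open) + 1]] <- list(
        id = next_id, last_frame = f,
        last_r = cur$centroid_r[k], last_c = cur$centroid_c[k],
        entries = data.frame(frame = f, cell_label = cur$cell_label[k]))
      next_id <- next_id + 1L
    }
  }
  closed <- c(closed, open)
  if (!length(closed)) {
    out <- data.frame(track_id = integer(0), frame = integer(0),
                      time_min = numeric(0), cell_label = integer(0))
    class(out) <- c("mig_tracks", "data.frame")
    return(out)
  }

  keep <- vapply(closed, function(tr) {
    if (nrow(tr$entries) < min_length) return(FALSE)
    if (!is.null(require_span)) {
      tt <- time_of[as.character(tr$entries$frame)]
      if (!(min(tt) <= require_span[1] && max(tt) >= require_span[2]))
        return(FALSE)
    }
    TRUE
  }, logical(1))
  closed <- closed[keep]

  out <- do.call(rbind, lapply(closed, function(tr) {
    data.frame(track_id = tr$id, frame = tr$entries$frame,
               time_min = as.numeric(time_of[as.character(tr$entries$frame)]),
               cell_label = tr$entries$cell_label)
  }))
  if (is.null(out))
    out <- data.frame(track_id = integer(0), frame = integer(0),
                      time_min = numeric(0), cell_label = integer(0))
  out$track_id <- match(out$track_id, sort(unique(out$track_id)))
  class(out) <- c("mig_tracks", "data.frame")
  out
}

#' Assemble per-cell traces from tracks and measurements
#'
#' Joins tracks with the per-frame measurement table into the tidy per-cell
#' trace format the metrics module consumes. Invalid measurements become
#' missing points; tracks with no valid localization measurement at all are
#' dropped with a message.
#'
#' @param tracks A `mig_tracks` table.
#' @param measurements The matching `mig_measurements` table.
#' @param strain,hexose Condition labels attached to every trace.
#' @return A `mig_traces` data.frame (`cell_id`, `time_min`, `loc_index`,
#'   `reporter`, `expr_marker`, `alive`, `strain`, `hexose`).
#' @export
assemble_traces <- function(tracks, measurements, strain = NA_character_,
                            hexose = NA_character_) {
  key_t <- paste(tracks$frame, tracks$cell_label)
  key_m <- paste(measurements$frame, measurements$cell_label)
  m <- measurements[match(key_t, key_m), ]
  out <- data.frame(
    cell_id = tracks$track_id,
    time_min = tracks$time_min,
    loc_index = ifelse(!is.na(m$valid) & m$valid, m$loc_index, NA_real_),
    reporter = m$reporter,
    expr_marker = m$expr_marker,
    alive = TRUE,
    strain = strain, hexose = hexose,
    stringsAsFactors = FALSE
  )
  n_valid <- tapply(!is.na(out$loc_index), out$cell_id, sum)
  bad <- as.integer(names(n_valid)[n_valid == 0])
  if (length(bad)) {
    message("dropping ", length(bad), " track(s) with no valid measurements")
    out <- out[!out$cell_id %in% bad, ]
  }
  out <- out[order(out$cell_id, out$time_min), ]
  rownames(out) <- NULL
  class(out) <- c("mig_traces", "data.frame")
  out
}
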