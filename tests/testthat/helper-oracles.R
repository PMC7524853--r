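# Independent brute-force oracles used to cross-check the implementation.
# These deliberately use plain loops rather than the package's vectorized
# code paths.

# Local maxima with plateau-centre semantics, by literal run scanning.
oracle_find_peaks <- function(x) {
  n <- length(x)
  peaks <- integer(0)
  i <- 2
  while (i <= n - 1) {
    if (x[i] > x[i - 1]) {
      j <- i
      while (j < n && x[j + 1] == x[i]) j <- j + 1
      if (j < n && x[j + 1] < x[i]) {
        peaks <- c(peaks, floor((i + j) / 2))
      }
      i <- j + 1
    } else i <- i + 1
  }
  peaks
}

# Topographic prominence by definition: walk outwards sample by sample until
# a strictly higher sample (or the series end), tracking the minimum; the
# prominence is the peak height minus the higher of the two side bases.
oracle_prominence <- function(x, i) {
  h <- x[i]
  base_l <- h
  j <- i - 1
  while (j >= 1) {
    if (x[j] > h) break
    if (x[j] < base_l) base_l <- x[j]
    j <- j - 1
  }
  if (j < 1 && i > 1) base_l <- min(base_l, min(x[1:(i - 1)]))
  base_r <- h
  j <- i + 1
  while (j <= length(x)) {
    if (x[j] > h) break
    if (x[j] < base_r) base_r <- x[j]
    j <- j + 1
  }
  h - max(base_l, base_r)
}

# Full brute-force pulse detector mirroring detect_pulses' documented
# contract (window restriction, prominence threshold, greedy separation by
# decreasing prominence with earlier-time tie-break).
oracle_detect <- function(time, x, window = c(60, 480), min_prominence = 0.1,
                          min_separation = 15) {
  inw <- which(time >= window[1] & time <= window[2])
  tw <- time[inw]; xw <- x[inw]
  pk <- oracle_find_peaks(xw)
  if (!length(pk)) return(data.frame(time = numeric(0), prominence = numeric(0)))
  prom <- vapply(pk, function(i) oracle_prominence(xw, i), numeric(1))
  keep <- prom >= min_prominence
  pk <- pk[keep]; prom <- prom[keep]
  if (!length(pk)) return(data.frame(time = numeric(0), prominence = numeric(0)))
  ord <- order(-prom, tw[pk])
  kept <- integer(0)
  for (k in ord) {
    if (!length(kept) ||
        all(abs(tw[pk[kept]] - tw[pk[k]]) >= min_separation))
      kept <- c(kept, k)
  }
  kept <- sort(kept)
  data.frame(time = tw[pk[kept]], prominence = prom[kept])
}

# Exhaustive optimal assignment for small cost matrices (n x m, n <= m).
oracle_assignment <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  stopifnot(n <= m, n <= 6)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (k in seq_along(v))
      for (p in perms(v[-k])) out[[length(out) + 1]] <- c(v[k], p)
    out
  }
  best <- NULL; best_cost <- Inf
  for (p in perms(seq_len(m))) {
    sel <- p[seq_len(n)]
    cst <- sum(cost[cbind(seq_len(n), sel)])
    if (cst < best_cost) { best_cost <- cst; best <- sel }
  }
  list(assignment = best, cost = best_cost)
}

# Intersection-over-union of two pixel index sets.
iou <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# Match detected labels to ground-truth labels by maximal overlap; returns
# per-truth-cell best IoU.
match_iou <- function(det_labels, truth_labels) {
  truths <- sort(setdiff(unique(as.vector(truth_labels)), 0))
  vapply(truths, function(tl) {
    t_idx <- which(truth_labels == tl)
    dl <- det_labels[t_idx]
    dl <- dl[dl > 0]
    if (!length(dl)) return(0)
    best <- as.integer(names(which.max(table(dl))))
    iou(which(det_labels == best), t_idx)
  }, numeric(1))
}

# Small rendered test scene shared across imaging tests.
make_test_movie <- function(n_cells = 10, seed = 5, noise = TRUE,
                            quantize = TRUE, gradient = NULL,
                            schedule = make_schedule(30, 10, -60, 120, 4),
                            strain = "wt", hexose = "glucose") {
  cfg <- preset(strain, hexose, n_cells = n_cells, seed = seed)
  truth <- simulate_traces(cfg, schedule)
  geom <- scene_geometry(image_size = c(256, 256), n_cells = n_cells,
                         seed = 2, illumination_gradient = gradient)
  list(truth = truth,
       movie = render_movie(truth, geom, noise = noise, quantize = quantize))
}
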