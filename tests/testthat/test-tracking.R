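mkreg <- function(r, c, label = seq_along(r)) {
  data.frame(label = label, centroid_r = r, centroid_c = c)
}

test_that("identical frames link to themselves at zero cost", {
  a <- mkreg(c(10, 50, 90), c(10, 50, 90))
  res <- link_frames(a, a, max_displacement = 5)
  expect_equal(res$pairs$label_a, res$pairs$label_b)
  expect_equal(sum(res$pairs$dist), 0)
  expect_length(res$unmatched_a, 0)
})

test_that("a disappearing cell is unmatched without disturbing the others", {
  a <- mkreg(c(10, 50, 90), c(10, 50, 90))
  b <- mkreg(c(11, 51), c(10, 50), label = c(7, 8))
  res <- link_frames(a, b, max_displacement = 5)
  expect_equal(nrow(res$pairs), 2)
  expect_equal(res$unmatched_a, 3)
  expect_equal(res$pairs$label_b[res$pairs$label_a == 1], 7)
  # empty inputs
  e <- link_frames(a[0, ], b, max_displacement = 5)
  expect_equal(nrow(e$pairs), 0)
  expect_equal(e$unmatched_b, c(7, 8))
})

test_that("assignment matches the exhaustive optimum on small problems", {
  set.seed(21)
  for (k in 1:50) {
    na <- sample(2:6, 1); nb <- sample.int(7 - na, 1) + na - 1
    a <- mkreg(runif(na, 0, 100), runif(na, 0, 100))
    b <- mkreg(runif(nb, 0, 100), runif(nb, 0, 100))
    d <- sqrt(outer(a$centroid_r, b$centroid_r, "-")^2 +
              outer(a$centroid_c, b$centroid_c, "-")^2)
    res <- link_frames(a, b, max_displacement = 1000)
    got <- sum(res$pairs$dist)
    expect_equal(got, oracle_assignment(d)$cost, tolerance = 1e-9)
  }
})

test_that("tracks chain, bridge gaps and honour filters", {
  # one cell present in all frames, another appearing mid-movie
  meas <- data.frame(
    frame = c(1:6, 4:6),
    cell_label = c(rep(1L, 6), rep(2L, 3)),
    centroid_r = c(10, 11, 12, 13, 14, 15, 60, 61, 62),
    centroid_c = 10,
    time_min = c(-10, 0, 10, 20, 30, 40, 20, 30, 40))
  tk <- build_tracks(meas, max_displacement = 5, min_length = 2)
  expect_equal(length(unique(tk$track_id)), 2)
  expect_equal(sum(tk$track_id == 1), 6)
  # span filter excludes the mid-movie birth
  tk2 <- build_tracks(meas, max_displacement = 5,
                      require_span = c(-10, 40))
  expect_equal(length(unique(tk2$track_id)), 1)
  # a one-frame detection dropout is bridged (gap <= max_gap)
  meas_gap <- meas[!(meas$frame == 3 & meas$centroid_r == 12), ]
  tk3 <- build_tracks(meas_gap, max_displacement = 5, max_gap = 1,
                      min_length = 4)
  expect_equal(length(unique(tk3$track_id[tk3$cell_label == 1])), 1)
  # but a two-frame dropout is not, at max_gap = 1
  meas_gap2 <- meas[!(meas$frame %in% c(3, 4) & meas$cell_label == 1), ]
  tk4 <- build_tracks(meas_gap2, max_displacement = 5, max_gap = 1,
                      min_length = 1)
  expect_equal(length(unique(tk4$track_id[tk4$cell_label == 1])), 2)
})

test_that("tracking a rendered movie recovers ground-truth identities", {
  tm <- make_test_movie(n_cells = 12, schedule = make_schedule(30, 10, -60, 120, 4))
  mov <- tm$movie
  res <- analyze_movie(mov, strain = "wt", hexose = "glucose")
  expect_equal(length(unique(res$traces$cell_id)), 12)
  # identify each measured region with the nearest true cell centre
  m <- res$measurements
  truth_of <- mapply(function(f, r, c) {
    which.min((mov$positions[, f, 1] - r)^2 + (mov$positions[, f, 2] - c)^2)
  }, m$frame, m$centroid_r, m$centroid_c)
  key <- paste(m$frame, m$cell_label)
  tk <- res$tracks
  tk$truth <- truth_of[match(paste(tk$frame, tk$cell_label), key)]
  links_ok <- unlist(tapply(tk$truth, tk$track_id,
                            function(v) head(v, -1) == tail(v, -1)))
  expect_gte(mean(links_ok), 0.99)

  # assembled traces track the ground-truth index closely
  tr <- res$traces
  err2 <- 0; nn <- 0
  for (id in unique(tr$cell_id)) {
    sub <- tr[tr$cell_id == id, ]
    ti <- tk$truth[tk$track_id == id][1]
    truth_series <- tm$truth$index_clean[ti, match(sub$time_min, tm$truth$times)]
    ok <- !is.na(sub$loc_index)
    err2 <- err2 + sum((sub$loc_index[ok] - truth_series[ok])^2)
    nn <- nn + sum(ok)
  }
  expect_lt(sqrt(err2 / nn), 0.1)
})

test_that("every measured region belongs to at most one track", {
  tm <- make_test_movie(n_cells = 8, schedule = make_schedule(30, 10, -30, 60, 4))
  res <- analyze_movie(tm$movie, strain = "wt", hexose = "glucose")
  keys <- paste(res$tracks$frame, res$tracks$cell_label)
  expect_equal(anyDuplicated(keys), 0)
  expect_lte(length(unique(res$tracks$track_id)),
             max(table(res$measurements$frame)) + 8)
})
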