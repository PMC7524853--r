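test_that("brightfield division: identity, scaling, shape contract", {
  a <- matrix(runif(100, 50, 200), 10, 10)
  expect_lt(max(abs(divide_brightfield(a, a) - 1)), 1e-5)
  expect_lt(max(abs(divide_brightfield(2 * a, a) - 2)), 1e-5)
  expect_error(divide_brightfield(a, matrix(1, 5, 5)), "shape")
})

test_that("division cancels a multiplicative illumination field", {
  base_a <- matrix(100, 40, 40); base_b <- matrix(100, 40, 40)
  base_a[15:25, 15:25] <- 160; base_b[15:25, 15:25] <- 60  # a 'cell'
  g <- outer(seq(1, 2, length.out = 40), seq(1, 2, length.out = 40)) / 2 + 0.5
  d_flat <- divide_brightfield(base_a, base_b)
  d_grad <- divide_brightfield(base_a * g, base_b * g)
  expect_lt(max(abs(d_flat - d_grad)), 1e-6)
})

test_that("segmentation finds synthetic cells accurately and filters areas", {
  tm <- make_test_movie(n_cells = 20, schedule = make_schedule(30, 30, -30, 30, 2))
  mov <- tm$movie
  div <- divide_brightfield(mov$channels$bf_above[, , 1],
                            mov$channels$bf_below[, , 1])
  reg <- segment_cells(div)
  ious <- match_iou(reg$labels, mov$labels[, , 1])
  expect_gte(sum(ious >= 0.7), 19)   # >= 19/20 detected at IoU >= 0.7
  # blank frame: zero regions, not an error
  blank <- segment_cells(matrix(1, 128, 128))
  expect_equal(nrow(blank$features), 0)
  # area filter removes everything when min_area exceeds all cells
  p <- segmentation_params(min_area = 1e5)
  expect_equal(nrow(segment_cells(div, p)$features), 0)
})

test_that("nucleus identification uses the marker and honours the fallback rule", {
  # constructed cell: disk cell with a 12%-area marker disk
  img <- matrix(0, 60, 60)
  rr <- row(img); cc <- col(img)
  cell <- (rr - 30)^2 + (cc - 30)^2 <= 20^2
  nucd <- (rr - 30)^2 + (cc - 30)^2 <= 7^2   # ~12% of the cell disk
  lab <- matrix(0L, 60, 60); lab[cell] <- 1L
  marker <- matrix(0, 60, 60); marker[nucd] <- 1
  reg <- regions_from_label_matrix(lab)
  reg <- identify_nucleus(reg, nuc_marker = marker)
  expect_setequal(which(reg$nuc_labels == 1), which(nucd))
  # flat marker: brightest-fraction fallback with exact pixel count
  flat <- matrix(5, 60, 60)
  gfp <- matrix(runif(3600), 60, 60)
  reg2 <- identify_nucleus(regions_from_label_matrix(lab), nuc_marker = flat,
                           gfp = gfp, fallback_fraction = 0.12)
  expect_equal(sum(reg2$nuc_labels == 1), round(0.12 * sum(cell)))
  expect_true(all(which(reg2$nuc_labels == 1) %in% which(cell)))
})

test_that("nucleus recovery on rendered cells is accurate", {
  tm <- make_test_movie(n_cells = 8, schedule = make_schedule(30, 30, -30, 30, 2))
  mov <- tm$movie
  div <- divide_brightfield(mov$channels$bf_above[, , 1],
                            mov$channels$bf_below[, , 1])
  reg <- segment_cells(div)
  reg <- identify_nucleus(reg, mov$channels$nuc_marker[, , 1],
                          mov$channels$gfp[, , 1])
  ious <- match_iou(reg$nuc_labels, mov$nuc_labels[, , 1])
  expect_true(all(ious >= 0.8))
})

test_that("the localization index follows the median-ratio formula exactly", {
  # hand-computed cases
  img <- matrix(100, 20, 20)
  cell <- 1:400
  nuc <- which(matrix(row(img) <= 8, 20, 20))  # < 50% of the cell
  expect_equal(measure_cell(cell, nuc, img)$loc_index, 0)
  img2 <- img; img2[nuc] <- 300
  expect_equal(measure_cell(cell, nuc, img2)$loc_index, 2)
  img3 <- img; img3[nuc] <- 50
  expect_equal(measure_cell(cell, nuc, img3)$loc_index, -0.5)
  # scale invariance of the ratio of medians
  expect_equal(measure_cell(cell, nuc, img2 * 37.5)$loc_index, 2)

  # property: equals the closed-form median ratio on random masks
  set.seed(11)
  for (k in 1:200) {
    n <- sample(30:200, 1)
    vals <- matrix(rgamma(n, 5, 0.05), n, 1)
    nuc_n <- sample(seq_len(max(1, n %/% 3)), 1)
    nuc_i <- sample(n, nuc_n)
    got <- measure_cell(seq_len(n), nuc_i, vals)$loc_index
    expect_identical(got, median(vals[nuc_i]) / median(vals) - 1)
  }
})

test_that("non-positive whole-cell median flags the measurement invalid", {
  img <- matrix(0, 10, 10)
  m <- measure_cell(1:100, 1:10, img)
  expect_false(m$valid)
  expect_true(is.na(m$loc_index))
})

test_that("measure_stack walks a movie and respects the sparse channel", {
  tm <- make_test_movie(n_cells = 10, schedule = make_schedule(30, 10, -30, 60, 4))
  mov <- tm$movie
  meas <- measure_stack(mov)
  # >= 95% of (frame, true cell) pairs measured
  expect_gte(nrow(meas[meas$valid, ]), 0.95 * 10 * length(mov$times))
  # expression marker missing exactly off the sparse frames
  on_sparse <- meas$frame %in% mov$sparse_frames
  expect_true(all(is.na(meas$expr_marker[!on_sparse])))
  expect_true(all(!is.na(meas$expr_marker[on_sparse])))
  # a blank movie gives an empty table
  blank <- list(channels = list(
    bf_above = array(100, c(64, 64, 3)), bf_below = array(100, c(64, 64, 3)),
    gfp = array(100, c(64, 64, 3)), nuc_marker = array(100, c(64, 64, 3)),
    reporter = array(100, c(64, 64, 3)), expr_marker = array(NA_real_, c(64, 64, 3))),
    times = c(0, 5, 10), sparse_frames = integer(0))
  expect_equal(nrow(measure_stack(blank)), 0)
})
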