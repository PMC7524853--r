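test_that("basal level is the pre-shift mean, with its error contract", {
  expect_equal(compute_basal(c(-60, -30, -10), c(0.1, 0.1, 0.1)), 0.1)
  expect_true(is.na(compute_basal(c(0, 5, 10), c(1, 2, 3))))
  # Monte-Carlo recovery: b = 0.05, sigma = 0.02, 9 pre-shift frames, 200 cells
  cfg <- sim_config(basal_level = 0.05, noise_sd = 0.02, n_cells = 200,
                    seed = 5L)
  tr <- simulate_traces(cfg, make_schedule())
  td <- traces_from_truth(tr)
  basals <- vapply(split(td, td$cell_id), function(d)
    compute_basal(d$time_min, d$loc_index), numeric(1))
  expect_lt(abs(mean(basals) - 0.05), 0.01)
})

test_that("short-term metrics find the early maximum and its time", {
  tt <- seq(0, 60, 5)
  x <- dnorm(tt, 30, 10); x <- 1.2 * x / max(x)
  st <- short_term_metrics(tt, x)
  expect_equal(st$max_short, 1.2)
  expect_equal(st$t_max_short, 30)
  expect_gte(st$max_short, st$mean_short)
  # monotone decreasing: first in-window time wins
  st2 <- short_term_metrics(tt, seq(1, 0, length.out = length(tt)))
  expect_equal(st2$t_max_short, 0)
  # too few points
  expect_true(is.na(short_term_metrics(c(0, 30), c(1, 2))$max_short))
})

test_that("long-term mean respects its window and coverage contract", {
  tt <- seq(0, 720, 5)
  x <- ifelse(tt >= 240 & tt <= 480, 0.4, 5)  # out-of-window points differ
  expect_equal(long_term_mean(tt, x), 0.4)
  # window metrics ignore everything outside their window
  x2 <- x; x2[tt < 240 | tt > 480] <- -99
  expect_equal(long_term_mean(tt, x2), 0.4)
  # 40% coverage -> missing
  x3 <- x; inw <- which(tt >= 240 & tt <= 480)
  x3[inw[seq_len(ceiling(0.6 * length(inw)))]] <- NA
  expect_true(is.na(long_term_mean(tt, x3)))
})

test_that("pulse detector resolves constructed double bumps", {
  tt <- seq(-240, 720, 5)
  basal <- 0.05
  x <- basal + 0.5 * exp(-(tt - 200)^2 / (2 * (15 / 2.355)^2)) +
    0.3 * exp(-(tt - 260)^2 / (2 * (15 / 2.355)^2))
  pl <- detect_pulses(tt, x, min_prominence = 0.1, basal = basal)
  expect_equal(nrow(pl), 2)
  expect_equal(pl$time, c(200, 260))
  expect_lt(max(abs(pl$height - c(0.5, 0.3))), 0.02)
  expect_true(all(pl$width > 5 & pl$width < 40))
  # flat trace: no pulses
  expect_equal(nrow(detect_pulses(tt, rep(0.05, length(tt)), basal = 0.05)), 0)
})

test_that("pulse detector equals the brute-force prominence oracle", {
  set.seed(31)
  for (k in 1:100) {
    n <- sample(20:200, 1)
    tt <- seq(60, by = 5, length.out = n)
    x <- cumsum(rnorm(n, 0, 0.1)) + rnorm(n, 0, 0.05)
    mp <- runif(1, 0.05, 0.4)
    ms <- sample(c(10, 15, 25), 1)
    got <- detect_pulses(tt, x, window = range(tt), min_prominence = mp,
                         min_separation = ms, basal = 0)
    want <- oracle_detect(tt, x, window = range(tt), min_prominence = mp,
                          min_separation = ms)
    expect_identical(got$time, want$time)
    expect_equal(got$prominence, want$prominence, tolerance = 1e-12)
  }
})

test_that("raising min_prominence never increases the pulse count", {
  set.seed(8)
  tt <- seq(60, 480, 5)
  for (k in 1:20) {
    x <- cumsum(rnorm(length(tt), 0, 0.08))
    counts <- vapply(c(0.05, 0.1, 0.2, 0.4), function(mp)
      nrow(detect_pulses(tt, x, window = range(tt), min_prominence = mp,
                         basal = 0)), numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("mean pulse height averages heights and handles emptiness", {
  pl <- data.frame(time = c(100, 200), peak_value = c(0.6, 0.4),
                   height = c(0.5, 0.3), prominence = c(0.5, 0.3),
                   width = c(12, 12))
  expect_equal(mean_pulse_height(pl), 0.4)
  expect_true(is.na(mean_pulse_height(pl[0, ])))
})

test_that("expression metrics: window mean and maturation-lagged onset", {
  tt <- seq(-240, 720, 5)
  expect_equal(expression_metrics(tt, rep(0, length(tt)))$expr_mean_long, 0)
  expect_true(is.na(expression_metrics(tt, rep(0, length(tt)))$expr_onset))
  expect_equal(expression_metrics(tt, rep(5, length(tt)))$expr_mean_long, 5)
  # derepression at 60 min, maturation 30 min -> onset detected in [90, 120]
  p <- reporter_params(repressed_rate = 0.1, derepressed_rate = 0.8,
                       maturation_delay = 30, degradation_rate = 0.025,
                       derepression_onset = 60)
  set.seed(2)
  f <- reporter_series(p, tt) + rnorm(length(tt), 0, 0.3)
  on <- expression_metrics(tt, f)$expr_onset
  expect_gte(on, 90)
  expect_lte(on, 120)
})

test_that("per-cell metric recovery from simulated traces", {
  cfg <- preset("wt", "glucose", n_cells = 100, seed = 14L)
  tr <- simulate_traces(cfg, make_schedule())
  mt <- compute_trace_metrics(traces_from_truth(tr))
  m <- mt$metrics
  expect_lt(abs(mean(m$basal) - cfg$basal_level), 0.01)
  expect_lte(abs(median(m$t_max_short) - cfg$peak_time), 5)
  truth_win <- tr$pulses[tr$pulses$time >= 60 & tr$pulses$time <= 480, ]
  true_rate <- nrow(truth_win) / 100 / 7
  expect_lt(abs(mean(m$pulse_rate) - true_rate) / true_rate, 0.15)
  expect_lt(abs(mean(m$mean_pulse_height, na.rm = TRUE) -
                mean(truth_win$height)), 0.05)
  # group ordering: wild type shuttles, the hxk2 deletion does not (glucose)
  cfg2 <- preset("hxk2d", "glucose", n_cells = 100, seed = 15L)
  m2 <- compute_trace_metrics(
    traces_from_truth(simulate_traces(cfg2, make_schedule())))$metrics
  expect_gt(mean(m$mean_long), mean(m2$mean_long))
  expect_gt(mean(m$pulse_rate), 4 * mean(m2$pulse_rate))
})
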