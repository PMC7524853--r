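test_that("a degenerate config yields flat traces at the basal level", {
  cfg <- sim_config(initial_amplitude = 0, pulse_rate = 0, noise_sd = 0,
                    plateau_level = 0.05, basal_level = 0.05, n_cells = 4)
  tr <- simulate_traces(cfg, make_schedule())
  expect_true(all(tr$index == 0.05))
  expect_equal(nrow(tr$pulses), 0)
})

test_that("simulation is bit-identical for a fixed seed", {
  cfg <- preset("wt", "glucose", n_cells = 8, seed = 11L)
  s <- make_schedule()
  a <- simulate_traces(cfg, s)
  b <- simulate_traces(cfg, s)
  expect_identical(a$index, b$index)
  expect_identical(a$pulses, b$pulses)
  expect_identical(a$expr_marker, b$expr_marker)
  # and the trace-only table too
  expect_identical(traces_from_truth(a), traces_from_truth(b))
})

test_that("realized pulse counts match the configured rate", {
  # rate 2/h over the 240-480 min window: expected 8 pulses per cell
  cfg <- sim_config(pulse_rate = 2, n_cells = 200, seed = 4L, cell_cv = 0.3)
  tr <- simulate_traces(cfg, make_schedule())
  counts <- vapply(seq_len(200), function(i) {
    sum(tr$pulses$cell == i & tr$pulses$time >= 240 & tr$pulses$time <= 480)
  }, numeric(1))
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - 8), 3 * se)
})

test_that("pulse heights match the configured distribution over many cells", {
  cfg <- sim_config(pulse_rate = 2, n_cells = 200, seed = 9L,
                    plateau_level = 0.05, basal_level = 0.05,
                    initial_amplitude = 0)
  # with no plateau or initial response, apex height ~ drawn amplitude
  tr <- simulate_traces(cfg, make_schedule())
  per_cell <- tapply(tr$pulses$amplitude, tr$pulses$cell, mean)
  se <- sd(per_cell) / sqrt(length(per_cell))
  expect_lt(abs(mean(per_cell) - cfg$pulse_height_mean), 3 * se)
  # recorded apex heights include neighbouring-bump overlap, never less
  # than ~the drawn amplitude
  expect_true(all(tr$pulses$height > tr$pulses$amplitude - 1e-6))
})

test_that("pulses respect the post-initial window and the refractory gap", {
  cfg <- sim_config(pulse_rate = 3, n_cells = 50, seed = 2L)
  tr <- simulate_traces(cfg, make_schedule())
  expect_true(all(tr$pulses$time > 60))
  gaps <- unlist(tapply(tr$pulses$time, tr$pulses$cell,
                        function(x) diff(sort(x))))
  expect_true(all(gaps >= cfg$pulse_refractory - 1e-9))
})

test_that("non-responders never pulse", {
  cfg <- sim_config(pulse_rate = 2, responder_fraction = 0, n_cells = 20,
                    seed = 3L)
  tr <- simulate_traces(cfg, make_schedule())
  expect_equal(nrow(tr$pulses), 0)
})

test_that("reporter model: repressed-forever with zero rate is identically zero", {
  p <- reporter_params(repressed_rate = 0, derepression_onset = "never")
  expect_equal(reporter_series(p, seq(-240, 720, 5)), rep(0, 193))
})

test_that("reporter fluorescence is causal: nothing before onset + maturation", {
  p <- reporter_params(repressed_rate = 0, derepressed_rate = 1,
                       maturation_delay = 30, degradation_rate = 0.025,
                       derepression_onset = 60)
  tt <- seq(-240, 720, 5)
  f <- reporter_series(p, tt)
  expect_true(all(f[tt <= 90] == 0))
  expect_true(all(f[tt > 90] > 0))
  # property over random parameter draws
  set.seed(42)
  for (k in 1:25) {
    onset <- runif(1, 0, 300); mat <- runif(1, 0, 90)
    p <- reporter_params(repressed_rate = 0,
                         derepressed_rate = runif(1, 0.1, 2),
                         maturation_delay = mat,
                         degradation_rate = runif(1, 0.005, 0.1),
                         derepression_onset = onset)
    f <- reporter_series(p, tt)
    expect_true(all(f[tt <= onset + mat] == 0))
  }
})

test_that("reporter approaches the closed-form steady state rate/degradation", {
  p <- reporter_params(repressed_rate = 0.1, derepressed_rate = 0.8,
                       maturation_delay = 30, degradation_rate = 0.05,
                       derepression_onset = 0)
  f <- reporter_series(p, c(-100, 0, 2000))
  expect_equal(f[1], 0.1 / 0.05)        # repressed steady state
  expect_equal(f[3], 0.8 / 0.05, tolerance = 1e-6)  # derepressed limit
})

test_that("dying cells freeze their trace, reporter and pulses", {
  cfg <- preset("oeHXK2", "mannose", n_cells = 100, seed = 6L)
  tr <- simulate_traces(cfg, make_schedule())
  expect_gt(sum(tr$cells$dead), 0)
  expect_lt(sum(tr$cells$dead), 100)
  # death strikes high expression-marker cells, threshold consistent
  expect_true(all(tr$expr_marker[tr$cells$dead] > tr$death_threshold))
  expect_true(all(tr$expr_marker[!tr$cells$dead] <= tr$death_threshold))
  i <- which(tr$cells$dead)[1]
  frozen <- tr$times >= 60
  expect_equal(length(unique(tr$index_clean[i, frozen])), 1)
  expect_equal(length(unique(tr$reporter[i, frozen])), 1)
  expect_true(all(tr$pulses$time[tr$pulses$cell == i] < 60))
  expect_true(all(!tr$alive[i, frozen]))
})

test_that("cell-to-cell jitter is mean-preserving", {
  set.seed(1)
  j <- migshuttle:::.jitter(200000, 0.3)
  expect_equal(mean(j), 1, tolerance = 0.005)
  expect_equal(sd(j) / mean(j), 0.3, tolerance = 0.01)
})
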