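test_that("group summary reproduces the t-interval by hand", {
  s <- summarize_group(c(1, 2, 3))
  expect_equal(s$mean, 2)
  expect_equal(s$sd, 1)
  half <- qt(0.975, df = 2) / sqrt(3)  # 4.303 * sd / sqrt(n)
  expect_equal(s$ci_low, 2 - half, tolerance = 1e-6)
  expect_equal(s$ci_high, 2 + half, tolerance = 1e-6)
  expect_true(is.na(s$p_vs_reference))
  # identical degenerate groups: no significance
  s2 <- summarize_group(rep(1, 4), rep(1, 4))
  expect_false(s2$significant)
  # n < 2: no CI
  expect_true(is.na(summarize_group(5)$ci_low))
})

test_that("well-separated generator groups are detected with near-certain power", {
  sched <- make_schedule()
  win <- sched$times >= 240 & sched$times <= 480
  hits <- 0
  for (r in 1:50) {
    a <- simulate_traces(preset("wt", "glucose", n_cells = 60,
                                seed = 100 + r), sched)
    b <- simulate_traces(preset("hxk2d", "glucose", n_cells = 60,
                                seed = 600 + r), sched)
    pa <- summarize_group(rowMeans(a$index[, win]), rowMeans(b$index[, win]))
    if (pa$significant) hits <- hits + 1
  }
  expect_equal(hits, 50)  # mean_long differs by >> 5 within-group SDs
})

test_that("permutation test agrees with Welch on a clear difference", {
  set.seed(9)
  a <- rnorm(40, 0, 1); b <- rnorm(40, 2, 1)
  expect_true(summarize_group(a, b, test = "permutation")$significant)
  expect_false(summarize_group(a, a, test = "permutation")$significant)
})

test_that("fold change contract and generator recovery", {
  expect_equal(fold_change(8, 8)$fold, 1)
  expect_equal(fold_change(8, 1)$fold, 8)
  expect_true(is.na(fold_change(5, 0)$fold))
  expect_equal(fold_change(5, 0)$difference, 5)
  # derepressed vs repressed generator groups with production rate ratio 4
  sched <- make_schedule()
  rep_on <- reporter_params(repressed_rate = 0.1, derepressed_rate = 0.4,
                            derepression_onset = 60)
  cfg_on <- sim_config(n_cells = 150, seed = 31L, reporter = rep_on)
  cfg_off <- sim_config(n_cells = 150, seed = 32L)
  mean_expr <- function(cfg) {
    tr <- simulate_traces(cfg, sched)
    mean(compute_trace_metrics(traces_from_truth(tr))$metrics$expr_mean_long)
  }
  fc <- fold_change(mean_expr(cfg_on), mean_expr(cfg_off))
  expect_lt(abs(fc$fold - 4) / 4, 0.15)
})

test_that("dose response: null, saturating and degenerate cases", {
  set.seed(12)
  # independent: |rho| < 0.1 at n = 500
  x <- rlnorm(500, 6, 0.5); y <- rnorm(500, 0.3, 0.05)
  dr0 <- dose_response(x, y)
  expect_lt(abs(dr0$rho), 0.1)
  # saturating coupling via the generator at default noise
  cfg <- sim_config(n_cells = 300, seed = 41L, initial_amplitude = 0.3,
                    pulse_rate = 0, plateau_level = 0.45,
                    expression_marker_mean = 900, expression_marker_sd = 600,
                    dose_response = list(K = 700, hill = 2))
  tr <- simulate_traces(cfg, make_schedule())
  m <- compute_trace_metrics(traces_from_truth(tr))$metrics
  dr <- dose_response(m$expr_marker_level, m$mean_long)
  expect_gt(dr$rho, 0.8)
  expect_true(all(diff(dr$bins$mean_long) > 0))  # monotone bins
  # overexpression-rescue preset: same monotone sign
  cfg2 <- preset("oeHXK1", "glucose", n_cells = 200, seed = 42L)
  m2 <- compute_trace_metrics(
    traces_from_truth(simulate_traces(cfg2, make_schedule())))$metrics
  expect_gt(dose_response(m2$expr_marker_level, m2$mean_long)$rho, 0.5)
  # all cells in one bin: correlation only
  dr1 <- dose_response(rep(100, 50) + rnorm(50, 0, 1e-6), rnorm(50), n_bins = 1)
  expect_equal(nrow(dr1$bins), 0)
})

test_that("viability filter recovers the toxicity threshold", {
  sched <- make_schedule()
  cfg <- preset("oeHXK2", "mannose", n_cells = 200, seed = 22L)
  tr <- simulate_traces(cfg, sched)
  m <- compute_trace_metrics(traces_from_truth(tr))$metrics
  vf <- viability_filter(m)
  expect_equal(vf$n_excluded, sum(tr$cells$dead))
  expect_lt(abs(vf$expr_threshold - tr$death_threshold) / tr$death_threshold,
            0.2)
  # nothing excluded without deaths
  cfg0 <- preset("wt", "glucose", n_cells = 20, seed = 2L)
  m0 <- compute_trace_metrics(
    traces_from_truth(simulate_traces(cfg0, sched)))$metrics
  vf0 <- viability_filter(m0)
  expect_equal(vf0$n_excluded, 0)
  expect_true(is.na(vf0$expr_threshold))
  # all dead: empty output with a warning
  m_dead <- m0; m_dead$dead <- TRUE
  expect_warning(vfd <- viability_filter(m_dead), "dead")
  expect_equal(nrow(vfd$viable), 0)
})

test_that("report assembles summaries, folds and the matrix for a single condition", {
  sched <- make_schedule()
  m <- compute_trace_metrics(traces_from_truth(
    simulate_traces(preset("wt", "glucose", n_cells = 20, seed = 3L), sched)))
  rep <- build_report(list("wt:glucose" = m$metrics))
  expect_s3_class(rep, "mig_report")
  expect_equal(length(unique(rep$summary$condition)), 1)
  expect_equal(rep$fold_changes$fold, 1)     # reference vs itself
  expect_false(rep$matrix$derepressed)
  expect_true(rep$matrix$agree)
  # empty input warns and returns an empty report
  expect_warning(r0 <- build_report(list()), "no conditions")
  expect_equal(nrow(r0$summary), 0)
})
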