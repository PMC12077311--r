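test_that("burst detection on a constructed fixture is exact", {
  # ON (t=1..4) with 3 synthesis events, one removal inside; then a
  # second ON interval with no synthesis; a final ON interval left open
  tr <- make_traj(
    times  = c(1,   1.5, 2.0, 2.5, 3.0, 4,   6,   7,   9),
    states = c(1,   1,   1,   1,   1,   0,   1,   0,   1),
    counts = c(0,   1,   2,   1,   2,   2,   2,   2,   2),
    kinds  = c("switch", "synthesis", "synthesis", "removal", "synthesis",
               "switch", "switch", "switch", "switch"),
    t_end = 10, initial_state = 0L, initial_count = 0L)
  rec <- detect_bursts(tr)
  expect_equal(nrow(rec), 2)            # the open third interval is censored
  expect_equal(rec$t_start, c(1, 6))
  expect_equal(rec$duration, c(3, 1))
  expect_equal(rec$size, c(3L, 0L))     # zero-size bursts retained
  # burst count equals the number of complete ON dwells
  expect_equal(nrow(rec), length(dwell_times(tr)$on_durations))
})

test_that("burst detection refuses multi-state trajectories", {
  lad <- promoter_ladder(c(0, 5, 10), c(1, 1), c(1, 1), 1)
  tr <- gillespie_mstate(lad, t_max = 50, seed = 1)
  expect_error(detect_bursts(tr), "two-state")
})

test_that("simulated burst sizes match the exact mean (k/h)(1+f/h)^-1", {
  # bursting regime (N, eps, A) = (1e4, 1e4, 0.005), rho = 1
  rates <- expand_params(reduced_params(1e4, 0.005, 1e4), rho = 1)
  tr <- gillespie_two_state(rates, t_max = 250, seed = 31)
  rec <- detect_bursts(tr)
  expect_gt(nrow(rec), 1e4)
  delta_exact <- (rates$k / rates$h) / (1 + rates$f / rates$h)  # = N/eps = 1
  se <- sd(rec$size) / sqrt(nrow(rec))
  expect_lt(abs(mean(rec$size) * (1 - 0.005) - delta_exact), 3 * se + 0.005)
  # sizes are consistent with a geometric law in this regime
  expect_gt(burst_size_geometric_test(rec)$p.value, 0.01)
})

test_that("the geometric test is calibrated and has power against Poisson", {
  set.seed(202)
  pvals_null <- replicate(60, burst_size_geometric_test(
    rgeom(1e4, prob = 1 / 11))$p.value)
  expect_lt(mean(pvals_null < 0.01), 0.05)   # near-nominal size
  pvals_alt <- replicate(30, burst_size_geometric_test(
    rpois(1e4, lambda = 5))$p.value)
  expect_gt(mean(pvals_alt < 0.01), 0.9)     # power > 0.9
  # degenerate sizes are rejected outright
  expect_lt(burst_size_geometric_test(rep(4L, 200))$p.value, 1e-10)
  expect_error(burst_size_geometric_test(1:10), "at least 50")
})

test_that("summary statistics on a constructed two-dwell fixture", {
  tr <- make_traj(
    times  = c(1, 2, 3, 5, 6),
    states = c(1, 1, 0, 1, 0),
    counts = c(0, 1, 1, 1, 1),
    kinds  = c("switch", "synthesis", "switch", "switch", "switch"),
    t_end = 6, initial_state = 0L, initial_count = 0L)
  s <- summarize_trajectory(tr, burn_in = 0)
  expect_equal(s$mean_T_on, mean(c(2, 1)))   # ON dwells (1,3) and (5,6)
  expect_equal(s$mean_T_off, 2)              # OFF dwell (3,5)
  expect_equal(s$mean_burst_size, 0.5)       # sizes 1 and 0
  # time-weighted mean count: count 1 from t=2 onward
  expect_equal(s$mean_n, 4 / 6)
})

test_that("noiseless plug-in statistics invert exactly", {
  # analytic summary statistics at (N, A, eps) = (100, 0.1, 10), rho = 1:
  # T_ON = 1/h, T_OFF = 1/f, <n> = N A, E[size] = k/h
  s <- list(mean_T_on = 1 / 9, mean_T_off = 1, mean_n = 10,
            mean_burst_size = 100 / 9)
  est <- estimate_params(s)
  expect_equal(est$N, 100, tolerance = 1e-12)
  expect_equal(est$A, 0.1, tolerance = 1e-12)
  expect_equal(est$eps, 10, tolerance = 1e-12)
  # the uncorrected estimator returns the literal recipe delta = mean size
  est_raw <- estimate_params(s, bias_correct = FALSE)
  expect_equal(est_raw$delta, 100 / 9)
  expect_error(estimate_params(list(mean_T_on = 0, mean_T_off = 1,
                                    mean_n = 1, mean_burst_size = 1)),
               "strictly positive")
})

test_that("A is the dwell-time ratio", {
  s <- list(mean_T_on = 1, mean_T_off = 9, mean_n = 5, mean_burst_size = 2)
  expect_equal(estimate_params(s)$A, 0.1)
})

test_that("parameter recovery tightens with simulated time", {
  rates <- gene_rates(100, 1, 9, 1)
  rel_err <- function(t_max, seed) {
    co <- coef(telegraph_fit(gillespie_two_state(rates, t_max, seed)))
    max(abs(co[c("N", "A", "eps")] / c(100, 0.1, 10) - 1))
  }
  short <- vapply(1:6, function(s) rel_err(500, 300 + s), numeric(1))
  long <- vapply(1:6, function(s) rel_err(5000, 400 + s), numeric(1))
  expect_lt(median(long), median(short))
})

test_that("occupancy in the fast-switching near-ON regime is unimodal", {
  rates <- expand_params(reduced_params(40, 0.9, 20), rho = 1)
  tr <- gillespie_two_state(rates, t_max = 5000, seed = 51)
  expect_equal(count_modes(occupancy_pmf(tr)), 1)
})
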