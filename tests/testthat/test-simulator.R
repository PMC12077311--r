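rates_ref <- gene_rates(100, 1, 9, 1)   # (N, A, eps) = (100, 0.1, 10)

test_that("identical seeds give bit-identical trajectories", {
  a <- gillespie_two_state(rates_ref, t_max = 200, seed = 11)
  b <- gillespie_two_state(rates_ref, t_max = 200, seed = 11)
  expect_identical(a, b)
  c <- gillespie_two_state(rates_ref, t_max = 200, seed = 12)
  expect_false(identical(a$times, c$times))
})

test_that("trajectories satisfy their structural invariants", {
  tr <- gillespie_two_state(rates_ref, t_max = 500, seed = 21)
  expect_true(all(diff(tr$times) > 0))
  expect_true(all(tr$counts >= 0))
  # replaying event kinds from the initial count reproduces the counts
  delta <- c(synthesis = 1L, removal = -1L,
             switch = 0L)[as.character(tr$event_kinds)]
  expect_identical(as.integer(tr$initial_count + cumsum(delta)), tr$counts)
  # counts change only on synthesis/removal, states only on switch
  st <- c(tr$initial_state, tr$states)
  expect_true(all((diff(st) != 0) == (tr$event_kinds == "switch")))
})

test_that("k = 0 from an empty cell produces only switch events", {
  tr <- gillespie_two_state(gene_rates(0, 1, 2, 1), t_max = 100, seed = 3)
  expect_true(all(tr$counts == 0))
  expect_true(all(tr$event_kinds == "switch"))
})

test_that("fast-switching A near 1 recovers the Poisson mean N", {
  # A = 1 - 1e-12 surrogate for a promoter that is effectively always ON
  rates <- expand_params(reduced_params(30, 1 - 1e-12, 10), rho = 1)
  tr <- gillespie_two_state(rates, t_max = 3000, seed = 5)
  seg <- telegraph:::traj_segments(tr, 0.2)
  m <- sum(seg$durations * seg$counts) / sum(seg$durations)
  # Monte-Carlo SE of the time-averaged count, via batch means
  expect_lt(abs(m - 30), 3 * 0.5)
  expect_gt(m, 25)
})

test_that("occupancy is time-weighted, sums to one, and nears the exact law", {
  tr <- gillespie_two_state(rates_ref, t_max = 2e4, seed = 7)
  occ <- occupancy_pmf(tr, burn_in = 0.2)
  expect_equal(sum(occ$probs), 1)
  ex <- exact_pmf(reduce_params(rates_ref))
  expect_lt(accumulated_difference(occ, ex), 0.05)
  # stationary initialization makes burn_in irrelevant up to MC error
  trs <- gillespie_two_state(rates_ref, t_max = 2e4, seed = 8,
                             initial = "stationary")
  d <- accumulated_difference(occupancy_pmf(trs, 0), occupancy_pmf(trs, 0.5))
  expect_lt(d, 0.1)
})

test_that("a constant-count trajectory yields a point-mass occupancy", {
  tr <- make_traj(times = c(1, 2, 3), states = c(1, 0, 1),
                  counts = c(4, 4, 4), kinds = rep("switch", 3),
                  t_end = 10, initial_state = 0L, initial_count = 4L)
  occ <- occupancy_pmf(tr, 0)
  expect_equal(unname(occ$probs[5]), 1)
})

test_that("state-resolved occupancy partitions the occupancy and estimates A", {
  tr <- gillespie_two_state(rates_ref, t_max = 2e4, seed = 9)
  sro <- state_resolved_occupancy(tr, 0.2)
  expect_equal(sum(sro$alpha) + sum(sro$beta), 1)
  occ <- occupancy_pmf(tr, 0.2)
  expect_equal(sro$alpha + sro$beta, unname(occ$probs), tolerance = 1e-12)
  # A = 0.1; MC standard error of the ON fraction over ~2e4 dwell cycles
  expect_lt(abs(sro$on_probability - 0.1), 3 * 0.003)
})

test_that("dwell times are exponential with means 1/h and 1/f", {
  tr <- gillespie_two_state(rates_ref, t_max = 1.5e4, seed = 13)
  dw <- dwell_times(tr)
  n_on <- length(dw$on_durations); n_off <- length(dw$off_durations)
  expect_gt(n_off, 1e4)
  expect_lt(abs(mean(dw$on_durations) - 1 / 9),
            3 * (1 / 9) / sqrt(n_on))
  expect_lt(abs(mean(dw$off_durations) - 1),
            3 * 1 / sqrt(n_off))
  expect_gt(ks.test(dw$off_durations, "pexp", 1)$p.value, 0.01)
  expect_gt(ks.test(dw$on_durations, "pexp", 9)$p.value, 0.01)
})

test_that("censored boundary dwells are excluded", {
  # single switch: no complete dwell on either side
  tr <- make_traj(times = 5, states = 1, counts = 0, kinds = "switch",
                  t_end = 10, initial_state = 0L, initial_count = 0L)
  expect_warning(dw <- dwell_times(tr), "complete")
  expect_length(dw$on_durations, 0)
  expect_length(dw$off_durations, 0)
  # three switches: exactly one complete dwell each
  tr <- make_traj(times = c(1, 4, 6), states = c(1, 0, 1), counts = c(0, 0, 0),
                  kinds = rep("switch", 3), t_end = 10)
  dw <- dwell_times(tr)
  expect_equal(dw$on_durations, 3)   # (1, 4) while ON
  expect_equal(dw$off_durations, 2)  # (4, 6) while OFF
})

test_that("the M = 2 ladder reproduces the two-state process", {
  lad <- promoter_ladder(c(0, 100), up_rates = 1, down_rates = 9, rho = 1)
  # same seed: the channel thresholds coincide, trajectories are identical
  a <- gillespie_mstate(lad, t_max = 500, seed = 17)
  b <- gillespie_two_state(rates_ref, t_max = 500, seed = 17)
  expect_identical(a$times, b$times)
  expect_identical(a$counts, b$counts)
  # different seeds: occupancies agree within Monte-Carlo error
  a2 <- gillespie_mstate(lad, t_max = 2e4, seed = 18)
  b2 <- gillespie_two_state(rates_ref, t_max = 2e4, seed = 19)
  expect_lt(accumulated_difference(occupancy_pmf(a2), occupancy_pmf(b2)), 0.1)
})

test_that("a slow-switching 3-state ladder gives a trimodal occupancy", {
  lad <- promoter_ladder(c(0, 15, 45), up_rates = c(0.02, 0.02),
                         down_rates = c(0.02, 0.02), rho = 1)
  tr <- gillespie_mstate(lad, t_max = 5e4, seed = 4)
  expect_equal(count_modes(occupancy_pmf(tr, 0.1)), 3)
})

test_that("a ladder that cannot leave OFF produces no molecules", {
  lad <- promoter_ladder(c(0, 10), up_rates = 0, down_rates = 1, rho = 1)
  tr <- gillespie_mstate(lad, t_max = 100, seed = 2)
  expect_length(tr$times, 0)
  expect_equal(occupancy_pmf(tr, 0)$probs[[1]], 1)
})

test_that("ladder validation rejects malformed specifications", {
  expect_error(promoter_ladder(c(1, 2), 1, 1, 1), "k_0")
  expect_error(promoter_ladder(c(0, 5, 3), c(1, 1), c(1, 1), 1), "increasing")
  expect_error(promoter_ladder(c(0, 5), c(1, 1), 1, 1), "length")
  expect_error(gillespie_two_state(rates_ref, t_max = -1, seed = 1),
               "positive")
})

test_that("simulate() on a model object derives child seeds by offset", {
  m <- telegraph_model(N = 100, A = 0.1, eps = 10)
  trs <- simulate(m, nsim = 3, seed = 40, t_max = 50)
  expect_length(trs, 3)
  expect_identical(trs[[2]]$times,
                   gillespie_two_state(m$rates, 50, seed = 41)$times)
})
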