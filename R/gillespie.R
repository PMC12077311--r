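#' Exact stochastic simulation of the two-state gene
#'
#' Direct-method Gillespie simulation of the four-channel process:
#' synthesis at rate `k` while ON, per-molecule removal at rate `rho*n`,
#' and promoter switching ON->OFF at rate `h`, OFF->ON at rate `f`.
#' Two uniforms per event; statistically exact, no leaping.
#'
#' @param rates a [gene_rates()] (or [telegraph_model()]) object.
#' @param t_max simulation horizon (> 0).
#' @param seed integer RNG seed; recorded in the trajectory.
#' @param initial either `NULL` (promoter OFF, count 0 — the
#'   burst-observation default), the string `"stationary"` (promoter
#'   Bernoulli(A), count drawn from [exact_pmf()]), or a list/vector
#'   `c(state, count)`.
#' @return An object of class `"trajectory"`: list with numeric `times`
#'   (strictly increasing event times), integer `states` (0 = OFF,
#'   1 = ON; for ladders 1..M-1 are ON tiers), integer `counts` (copy
#'   number after each event), factor `event_kinds` (levels
#'   `synthesis`, `removal`, `switch`), plus `seed`, `t_end`,
#'   `initial_state`, `initial_count` and the generating `params`.
#' @examples
#' tr <- gillespie_two_state(gene_rates(100, 1, 9, 1), t_max = 50, seed = 1)
#' tr
#' @export
gillespie_two_state <- function(rates, t_max, seed, initial = NULL) {
  rates <- as_gene_rates(rates)
  if (!is.numeric(t_max) || t_max <= 0) stop("t_max must be positive")
  init <- resolve_initial(initial, reduce_params(rates), seed)
  set.seed(seed)
  raw <- ssa_two_state(rates$k, rates$f, rates$h, rates$rho,
                       t_max, init$state, init$count)
  new_trajectory(raw, seed = seed, t_end = t_max,
                 initial_state = init$state, initial_count = init$count,
                 params = rates)
}

resolve_initial <- function(initial, reduced, seed) {
  if (is.null(initial)) return(list(state = 0L, count = 0L))
  if (identical(initial, "stationary")) {
    set.seed(seed + 1L)
    pmf <- exact_pmf(reduced)
    count <- sample(pmf$n, 1, prob = pmf$probs / sum(pmf$probs))
    state <- stats::rbinom(1, 1, reduced$A)
    return(list(state = as.integer(state), count = as.integer(count)))
  }
  initial <- unlist(initial)
  if (length(initial) != 2 || any(initial < 0) || initial[1] > 1)
    stop("initial must be NULL, \"stationary\", or (state, count)")
  list(state = as.integer(initial[1]), count = as.integer(initial[2]))
}

#' Promoter ladder specification
#'
#' An `M`-state promoter `OFF, ON_1, ..., ON_{M-1}` with strictly
#' increasing synthesis rates `k_0 = 0 < k_1 < ... < k_{M-1}` and
#' transitions only between adjacent states.
#'
#' @param synth_rates length-`M` vector of synthesis rates, first entry 0,
#'   strictly increasing.
#' @param up_rates length-`M-1` vector; `up_rates[j]` is the rate from
#'   state `j-1` to `j`.
#' @param down_rates length-`M-1` vector; `down_rates[j]` is the rate
#'   from state `j` to `j-1`.
#' @param rho per-molecule removal rate (> 0).
#' @return An object of class `"promoter_ladder"`.
#' @examples
#' promoter_ladder(c(0, 15, 45), up_rates = c(0.02, 0.02),
#'                 down_rates = c(0.02, 0.02), rho = 1)
#' @export
promoter_ladder <- function(synth_rates, up_rates, down_rates, rho) {
  M <- length(synth_rates)
  if (M < 2) stop("invalid ladder: need at least 2 promoter states")
  if (synth_rates[1] != 0) stop("invalid ladder: k_0 must be 0")
  if (any(diff(synth_rates) <= 0))
    stop("invalid ladder: synthesis rates must be strictly increasing")
  if (length(up_rates) != M - 1 || length(down_rates) != M - 1)
    stop("invalid ladder: up_rates and down_rates must have length M-1")
  if (any(up_rates < 0) || any(down_rates < 0) || rho <= 0)
    stop("invalid ladder: rates must be non-negative, rho positive")
  structure(list(synth_rates = as.numeric(synth_rates),
                 up_rates = as.numeric(up_rates),
                 down_rates = as.numeric(down_rates),
                 rho = rho, M = M),
            class = "promoter_ladder")
}

#' Exact simulation of the M-state promoter ladder
#'
#' Generalizes [gillespie_two_state()] to `M` promoter states; with
#' `M = 2` and `synth_rates = c(0, k)` it reproduces the two-state
#' process in distribution. In a slow-switching regime with well
#' separated `N_j = k_j/rho` the occupancy histogram is `M`-modal.
#'
#' @param ladder a [promoter_ladder()].
#' @param t_max simulation horizon (> 0).
#' @param seed integer RNG seed.
#' @param initial optional `c(state, count)`; default state 0, count 0.
#' @return A `"trajectory"`, as in [gillespie_two_state()].
#' @export
gillespie_mstate <- function(ladder, t_max, seed, initial = NULL) {
  if (!inherits(ladder, "promoter_ladder")) stop("invalid ladder")
  if (!is.numeric(t_max) || t_max <= 0) stop("t_max must be positive")
  if (is.null(initial)) initial <- c(0L, 0L)
  initial <- as.integer(unlist(initial))
  if (length(initial) != 2 || initial[1] < 0 || initial[1] >= ladder$M ||
      initial[2] < 0)
    stop("initial must be (state in 0..M-1, count >= 0)")
  set.seed(seed)
  raw <- ssa_mstate(ladder$synth_rates, ladder$up_rates, ladder$down_rates,
                    ladder$rho, t_max, initial[1], initial[2])
  new_trajectory(raw, seed = seed, t_end = t_max,
                 initial_state = initial[1], initial_count = initial[2],
                 params = ladder)
}

new_trajectory <- function(raw, seed, t_end, initial_state, initial_count,
                           params) {
  kinds <- factor(c("synthesis", "removal", "switch")[raw$kinds],
                  levels = c("synthesis", "removal", "switch"))
  structure(list(times = raw$times,
                 states = as.integer(raw$states),
                 counts = as.integer(raw$counts),
                 event_kinds = kinds,
                 seed = seed, t_end = t_end,
                 initial_state = as.integer(initial_state),
                 initial_count = as.integer(initial_count),
                 params = params),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d events on [0, %g], seed %s\n",
              length(x$times), x$t_end,
              if (is.null(x$seed) || is.na(x$seed)) "unknown" else x$seed))
  tab <- table(x$event_kinds)
  cat(sprintf("  synthesis %d, removal %d, switch %d\n",
              tab[["synthesis"]], tab[["removal"]], tab[["switch"]]))
  cat(sprintf("  final state %d, final count %d\n",
              utils::tail(c(x$initial_state, x$states), 1),
              utils::tail(c(x$initial_count, x$counts), 1)))
  invisible(x)
}

#' @export
as.data.frame.trajectory <- function(x, ...) {
  data.frame(time = x$times, state = x$states, count = x$counts,
             event_kind = as.character(x$event_kinds))
}

#' Simulate trajectories from a model object
#'
#' `simulate` method for [telegraph_model()]: runs
#' [gillespie_two_state()] `nsim` times with child seeds derived from
#' `seed` by indexed offset.
#'
#' @param object a `"telegraph"` model.
#' @param nsim number of trajectories.
#' @param seed base integer seed.
#' @param t_max simulation horizon.
#' @param initial as in [gillespie_two_state()].
#' @param ... unused.
#' @return A single trajectory if `nsim = 1`, else a list of them.
#' @export
simulate.telegraph <- function(object, nsim = 1, seed = 1, t_max = 100,
                               initial = NULL, ...) {
  out <- lapply(seq_len(nsim) - 1L, function(i)
    gillespie_two_state(object$rates, t_max, seed + i, initial))
  if (nsim == 1) out[[1]] else out
}

# piecewise-constant value of the trajectory over time: boundaries
# c(0, times, t_end) with values c(initial, after-event values)
traj_segments <- function(traj, burn_in = 0) {
  if (burn_in < 0 || burn_in >= 1) stop("burn_in must be in [0, 1)")
  b <- burn_in * traj$t_end
  starts <- c(0, traj$times)
  ends <- c(traj$times, traj$t_end)
  counts <- c(traj$initial_count, traj$counts)
  states <- c(traj$initial_state, traj$states)
  keep <- ends > b
  if (!any(keep)) stop("empty post-burn-in window")
  starts <- pmax(starts[keep], b)
  list(durations = ends[keep] - starts, counts = counts[keep],
       states = states[keep])
}

#' Time-weighted occupancy distribution of a trajectory
#'
#' The empirical stationary distribution of the copy number: each count
#' value is weighted by the total time the trajectory spent at it (not
#' by the number of events), over `[burn_in * t_end, t_end]`.
#'
#' @param traj a `"trajectory"`.
#' @param burn_in fraction of the horizon to discard, in `[0, 1)`.
#' @return A [copy_number_pmf()] summing to 1 exactly (zero tail mass).
#' @examples
#' tr <- gillespie_two_state(gene_rates(100, 1, 9, 1), 200, seed = 2)
#' occupancy_pmf(tr)
#' @export
occupancy_pmf <- function(traj, burn_in = 0.2) {
  seg <- traj_segments(traj, burn_in)
  w <- vapply(split(seg$durations, seg$counts), sum, numeric(1))
  probs <- numeric(max(seg$counts) + 1)
  probs[as.integer(names(w)) + 1] <- w / sum(seg$durations)
  copy_number_pmf(probs, tail_mass = 0)
}

#' Promoter-state-resolved occupancy
#'
#' Splits the time-weighted occupancy by promoter activity: `alpha`
#' carries the mass observed while the promoter is ON (any tier > 0)
#' and `beta` while OFF. `sum(alpha) + sum(beta) = 1` and `sum(alpha)`
#' estimates the stationary ON probability `A`.
#'
#' @inheritParams occupancy_pmf
#' @return List with numeric vectors `alpha` and `beta` (indexed by
#'   count `0..n_max`, jointly summing to 1) and `on_probability =
#'   sum(alpha)`.
#' @export
state_resolved_occupancy <- function(traj, burn_in = 0.2) {
  seg <- traj_segments(traj, burn_in)
  tot <- sum(seg$durations)
  nmax <- max(seg$counts)
  alpha <- beta <- numeric(nmax + 1)
  on <- seg$states > 0
  for (which_on in c(TRUE, FALSE)) {
    sel <- on == which_on
    if (!any(sel)) next
    w <- vapply(split(seg$durations[sel], seg$counts[sel]), sum, numeric(1))
    idx <- as.integer(names(w)) + 1
    if (which_on) alpha[idx] <- w / tot else beta[idx] <- w / tot
  }
  list(alpha = alpha, beta = beta, on_probability = sum(alpha))
}

#' Dwell times of the promoter states
#'
#' Durations of maximal constant-promoter-state intervals. The first
#' and last intervals are censored (no observed switch bounds them) and
#' are excluded, so for Markov switching the returned ON durations are
#' iid Exponential(`h`) and OFF durations Exponential(`f`) samples.
#'
#' @param traj a `"trajectory"`.
#' @return List with numeric vectors `on_durations` and
#'   `off_durations`. For ladder trajectories "ON" is any tier > 0.
#' @export
dwell_times <- function(traj) {
  sw <- traj$event_kinds == "switch"
  st <- traj$times[sw]
  ss <- traj$states[sw]     # state entered at each switch
  if (length(st) < 2) {
    warning("no complete dwell intervals (need at least two switch events)")
    return(list(on_durations = numeric(0), off_durations = numeric(0)))
  }
  durs <- diff(st)
  state_during <- ss[-length(ss)]
  # within a ladder, consecutive switches can stay on the same side of
  # ON/OFF; merge adjacent intervals with the same activity
  on <- state_during > 0
  runs <- rle(on)
  bounds <- cumsum(c(0, runs$lengths))
  merged <- vapply(seq_along(runs$values), function(i)
    sum(durs[(bounds[i] + 1):bounds[i + 1]]), numeric(1))
  vals <- runs$values
  keep <- rep(TRUE, length(vals))
  # ladders can switch tier without changing ON/OFF activity, so a
  # boundary run sharing activity with the censored edge interval is
  # itself censored; for the two-state model activity alternates at
  # every switch and nothing is dropped here
  if ((traj$initial_state > 0) == vals[1]) keep[1] <- FALSE
  if ((ss[length(ss)] > 0) == vals[length(vals)]) keep[length(vals)] <- FALSE
  list(on_durations = merged[keep & vals],
       off_durations = merged[keep & !vals])
}
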