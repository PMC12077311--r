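#' Detect transcriptional bursts in a two-state trajectory
#'
#' A burst is a complete (uncensored) maximal ON interval; its size is
#' the number of synthesis events during the interval. Removals during
#' ON do not reduce the size, and zero-synthesis ON intervals are
#' retained as bursts of size 0 (the geometric burst-size law has mass
#' at 0 — dropping them would bias the mean upward).
#'
#' @param traj a two-state `"trajectory"` (states in \{0, 1\}).
#' @return A data.frame with columns `t_start` (time of the OFF->ON
#'   switch), `duration` (ON dwell length) and `size` (synthesis
#'   events during the interval).
#' @examples
#' tr <- gillespie_two_state(gene_rates(1e4, 50, 9950, 1), 20, seed = 3)
#' head(detect_bursts(tr))
#' @export
detect_bursts <- function(traj) {
  if (any(traj$states > 1) || traj$initial_state > 1)
    stop("unsupported: burst detection is defined for two-state trajectories")
  sw <- which(traj$event_kinds == "switch")
  sw_times <- traj$times[sw]
  sw_states <- traj$states[sw]
  on_idx <- which(sw_states == 1)
  # complete ON intervals need a following switch (back to OFF)
  on_idx <- on_idx[on_idx < length(sw)]
  starts <- sw_times[on_idx]
  ends <- sw_times[on_idx + 1]
  syn_times <- traj$times[traj$event_kinds == "synthesis"]
  size <- findInterval(ends, syn_times, left.open = TRUE) -
    findInterval(starts, syn_times, left.open = TRUE)
  data.frame(t_start = starts, duration = ends - starts,
             size = as.integer(size))
}

#' Chi-square test of geometric burst sizes
#'
#' Goodness-of-fit of observed burst sizes against a geometric law on
#' \{0, 1, 2, ...\} whose success probability is estimated from the
#' sample mean (`p = 1/(1 + mean)`, the moment estimate of `h/(k+h)`).
#' Bins with expected count below 5 are pooled with their neighbor, and
#' one degree of freedom is charged for the estimated parameter. A
#' geometric burst-size distribution favors the bursting limit of the
#' two-state model; systematic rejection points to a different
#' promoter-state structure.
#'
#' @param records a data.frame from [detect_bursts()], or a numeric
#'   vector of sizes. At least 50 sizes are required.
#' @return List (class `"htest"`) with `statistic`, `parameter` (df),
#'   `p.value` and the estimated success probability.
#' @export
burst_size_geometric_test <- function(records) {
  sizes <- if (is.data.frame(records)) records$size else records
  n <- length(sizes)
  if (n < 50) stop("domain error: need at least 50 burst records")
  if (any(sizes < 0) || any(sizes != floor(sizes)))
    stop("burst sizes must be non-negative integers")
  p_hat <- 1 / (1 + mean(sizes))
  kmax <- max(sizes)
  probs <- stats::dgeom(0:kmax, prob = p_hat)
  probs <- c(probs, max(1 - sum(probs), 0))      # tail bin k > kmax
  obs <- tabulate(sizes + 1L, nbins = kmax + 1L)
  obs <- c(obs, 0)
  # pool adjacent bins left-to-right until each group expects >= 5
  grp <- integer(length(probs)); g <- 1L; acc <- 0
  for (i in seq_along(probs)) {
    grp[i] <- g
    acc <- acc + n * probs[i]
    if (acc >= 5 && i < length(probs)) { g <- g + 1L; acc <- 0 }
  }
  if (acc < 5 && g > 1) grp[grp == g] <- g - 1L   # merge trailing light group
  E <- tapply(n * probs, grp, sum)
  O <- tapply(obs, grp, sum)
  if (length(E) < 3)
    stop("domain error: too few distinct size classes for a chi-square test")
  stat <- sum((O - E)^2 / E)
  df <- length(E) - 2                             # one estimated parameter
  pval <- stats::pchisq(stat, df, lower.tail = FALSE)
  structure(list(statistic = c("X-squared" = stat),
                 parameter = c(df = df),
                 p.value = pval,
                 estimate = c(prob = p_hat),
                 method = "Chi-square goodness-of-fit to a geometric burst-size law",
                 data.name = deparse(substitute(records))),
            class = "htest")
}

#' Summary statistics of a two-state trajectory
#'
#' The four observables of the moment-based inference recipe: mean ON
#' and OFF dwell times (uncensored intervals only), the time-weighted
#' mean copy number, and the mean burst size.
#'
#' @param traj a two-state `"trajectory"`.
#' @param records optional burst records from [detect_bursts()]
#'   (recomputed when omitted).
#' @param burn_in burn-in fraction for the occupancy mean.
#' @return An object of class `"burst_summary"`: list with
#'   `mean_T_on`, `mean_T_off`, `mean_n`, `mean_burst_size`,
#'   `n_bursts`, `n_dwells_on`, `n_dwells_off`.
#' @export
summarize_trajectory <- function(traj, records = NULL, burn_in = 0.2) {
  if (is.null(records)) records <- detect_bursts(traj)
  dw <- dwell_times(traj)
  seg <- traj_segments(traj, burn_in)
  structure(list(
    mean_T_on = mean(dw$on_durations),
    mean_T_off = mean(dw$off_durations),
    mean_n = sum(seg$durations * seg$counts) / sum(seg$durations),
    mean_burst_size = mean(records$size),
    n_bursts = nrow(records),
    n_dwells_on = length(dw$on_durations),
    n_dwells_off = length(dw$off_durations)),
    class = "burst_summary")
}

#' @export
print.burst_summary <- function(x, ...) {
  cat("Trajectory summary statistics\n")
  cat(sprintf("  mean T_ON  = %.5g  (%d dwells)\n", x$mean_T_on, x$n_dwells_on))
  cat(sprintf("  mean T_OFF = %.5g  (%d dwells)\n", x$mean_T_off, x$n_dwells_off))
  cat(sprintf("  mean copy number <n> = %.5g\n", x$mean_n))
  cat(sprintf("  mean burst size = %.5g  (%d bursts)\n",
              x$mean_burst_size, x$n_bursts))
  invisible(x)
}

#' Moment-based parameter estimation
#'
#' The summary-statistic inference recipe: the ON probability is
#' `A = T_ON/(T_ON + T_OFF)`, the burst scale `delta` from the mean
#' burst size, `N = <n>/A`, and `eps = N/delta`.
#'
#' The expected number of synthesis events in one ON interval is `k/h`
#' (synthesis at rate `k` racing exponential switch-off at rate `h`),
#' whereas the burst scale is `delta = N/eps = (k/h)(1+f/h)^{-1} =
#' (k/h)(1-A)`. With `bias_correct = TRUE` (default) the sample mean
#' burst size is therefore multiplied by `(1 - A_hat)`; in the bursting
#' regime `A << 1` the correction is negligible and the plain
#' mean-burst-size prescription is recovered, but outside it the
#' correction removes a relative bias of size `A` in `delta` and `eps`.
#'
#' @param stats a `"burst_summary"` (or a list with fields `mean_T_on`,
#'   `mean_T_off`, `mean_n`, `mean_burst_size`).
#' @param bias_correct scale the mean burst size by `(1 - A_hat)` so
#'   that it estimates `delta = N/eps` exactly rather than `k/h`.
#' @return A [reduced_params()] object.
#' @examples
#' s <- list(mean_T_on = 1/9, mean_T_off = 1, mean_n = 10,
#'           mean_burst_size = 100/9)   # E[size] = k/h
#' estimate_params(s)   # recovers (N, A, eps) = (100, 0.1, 10)
#' @export
estimate_params <- function(stats, bias_correct = TRUE) {
  need <- c("mean_T_on", "mean_T_off", "mean_n", "mean_burst_size")
  if (!all(need %in% names(stats)))
    stop("stats must carry ", paste(need, collapse = ", "))
  with(stats, {
    if (!all(is.finite(c(mean_T_on, mean_T_off, mean_n, mean_burst_size))) ||
        mean_T_on <= 0 || mean_T_off <= 0 || mean_n <= 0 ||
        mean_burst_size <= 0)
      stop("estimation error: all summary statistics must be strictly positive")
    A <- mean_T_on / (mean_T_on + mean_T_off)
    delta <- if (bias_correct) mean_burst_size * (1 - A) else mean_burst_size
    N <- mean_n / A
    reduced_params(N = N, A = A, eps = N / delta)
  })
}

#' Fit the two-state model to a trajectory by summary statistics
#'
#' Convenience wrapper tying the estimation pipeline together:
#' [detect_bursts()] -> [summarize_trajectory()] -> [estimate_params()].
#'
#' @param traj a two-state `"trajectory"`.
#' @param burn_in burn-in fraction for the occupancy mean.
#' @return An object of class `"telegraph_fit"` with components
#'   `params` (the estimated [reduced_params()]), `stats`, `records`
#'   and `traj_seed`.
#' @examples
#' tr <- gillespie_two_state(gene_rates(100, 1, 9, 1), 2000, seed = 4)
#' fit <- telegraph_fit(tr)
#' coef(fit)
#' @export
telegraph_fit <- function(traj, burn_in = 0.2) {
  records <- detect_bursts(traj)
  stats <- summarize_trajectory(traj, records, burn_in)
  params <- estimate_params(stats)
  structure(list(params = params, stats = stats, records = records,
                 traj_seed = traj$seed),
            class = "telegraph_fit")
}

#' @export
coef.telegraph_fit <- function(object, ...) {
  p <- object$params
  c(N = p$N, A = p$A, eps = p$eps, delta = p$delta)
}

#' @export
print.telegraph_fit <- function(x, ...) {
  cat("Two-state model fit (summary-statistic estimator)\n")
  print(x$params)
  invisible(x)
}

#' @export
summary.telegraph_fit <- function(object, ...) {
  cat("Two-state model fit (summary-statistic estimator)\n\n")
  print(object$stats)
  cat("\nEstimated parameters:\n")
  print(object$params)
  gt <- tryCatch(burst_size_geometric_test(object$records),
                 error = function(e) NULL)
  if (!is.null(gt))
    cat(sprintf("\nGeometric burst-size test: X2 = %.3g, df = %d, p = %.3g\n",
                gt$statistic, gt$parameter, gt$p.value))
  invisible(object)
}

#' Count histogram modes after pooling and smoothing
#'
#' Counts local maxima of a copy-number pmf after (i) pooling adjacent
#' bins so that each pooled bin carries expected mass of at least
#' `min_expected` observations and (ii) a 3-bin moving-average smooth —
#' a reproducible, scale-free way to call unimodality vs multimodality
#' of occupancy histograms.
#'
#' @param pmf a [copy_number_pmf()].
#' @param n_obs nominal observation count for the pooling rule.
#' @param min_expected pooling threshold.
#' @return Integer number of local modes.
#' @export
count_modes <- function(pmf, n_obs = 1000, min_expected = 5) {
  p <- as.numeric(pmf$probs)
  # pool adjacent bins until each holds >= min_expected/n_obs mass;
  # compare pooled bins as densities (mass per unit width), since the
  # pooled widths differ
  thr <- min_expected / n_obs
  pooled <- numeric(0); width <- integer(0); acc <- 0; w <- 0L
  for (pi in p) {
    acc <- acc + pi; w <- w + 1L
    if (acc >= thr) {
      pooled <- c(pooled, acc); width <- c(width, w)
      acc <- 0; w <- 0L
    }
  }
  if (w > 0) { pooled <- c(pooled, acc); width <- c(width, w) }
  x <- pooled / width
  if (length(x) >= 3)   # 3-bin moving average, ends kept as-is
    x <- c(x[1], (x[-c(1, 2)] + x[-c(1, length(x))] + x[-c(length(x) - 1,
           length(x))]) / 3, x[length(x)])
  if (length(x) < 3) return(1L)
  # candidate peaks: local maxima including the edges
  up <- c(TRUE, diff(x) > 0)
  dn <- c(diff(x) < 0, TRUE)
  peaks <- which(up & dn)
  if (length(peaks) < 2) return(max(length(peaks), 1L))
  # two maxima are distinct modes only if separated by a dip of at
  # least 20% of the smaller peak; otherwise merge (drop the smaller)
  repeat {
    if (length(peaks) < 2) break
    merged <- FALSE
    for (i in seq_len(length(peaks) - 1)) {
      valley <- min(x[peaks[i]:peaks[i + 1]])
      small <- min(x[peaks[i]], x[peaks[i + 1]])
      if (valley > 0.8 * small) {
        peaks <- peaks[-(i + if (x[peaks[i]] < x[peaks[i + 1]]) 0 else 1)]
        merged <- TRUE
        break
      }
    }
    if (!merged) break
  }
  length(peaks)
}
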