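#' Negative-binomial parameters of the bursting limit
#'
#' In the bursting limit (`A << 1`, `eps, N >> 1` with `delta = N/eps`
#' held finite) the stationary copy-number law converges to a negative
#' binomial with shape `r = A*eps` (mean number of bursts per mRNA
#' lifetime) and burst scale `delta` (mean burst size).
#'
#' @param r shape `A*eps` (> 0).
#' @param delta burst scale `N/eps` (> 0).
#' @return An object of class `"nb_params"`.
#' @examples
#' nb_params(r = 1, delta = 10)
#' @export
nb_params <- function(r, delta) {
  if (!is.finite(r) || r <= 0) stop("r must be strictly positive")
  if (!is.finite(delta) || delta <= 0) stop("delta must be strictly positive")
  structure(list(r = r, delta = delta), class = "nb_params")
}

#' Bursting-limit (negative binomial) pmf
#'
#' `p_n = ((r)_n / n!) (delta/(1+delta))^n (1/(1+delta))^r`, the
#' negative binomial law governing mRNA numbers in transcriptional
#' bursts. Evaluated through `stats::dnbinom` (log-space internally)
#' with `size = r`, `prob = 1/(1+delta)`.
#'
#' @param params an [nb_params()] object (or a `reduced_params`, from
#'   which `r = A*eps` and `delta = N/eps` are taken).
#' @param n_max truncation point; chosen as for [exact_pmf()] when
#'   omitted.
#' @return A [copy_number_pmf()].
#' @examples
#' nb_pmf(nb_params(1, 10), n_max = 50)  # geometric, ratio 10/11
#' @export
nb_pmf <- function(params, n_max = NULL) {
  params <- as_nb_params(params)
  r <- params$r; delta <- params$delta
  m <- r * delta
  v <- m * (1 + delta)
  if (is.null(n_max))
    n_max <- ceiling(m + 10 * sqrt(v) + 20)
  p <- 1 / (1 + delta)
  probs <- stats::dnbinom(0:n_max, size = r, prob = p)
  while (1 - sum(probs) > 1e-9) {
    n_max <- ceiling(n_max * 1.5)
    probs <- stats::dnbinom(0:n_max, size = r, prob = p)
  }
  copy_number_pmf(probs, tail_mass = max(1 - sum(probs), 0))
}

#' Generating function of the bursting-limit distribution
#'
#' `(1 + delta*(1-z))^(-r)`; equals 1 at `z = 1`.
#'
#' @param params an [nb_params()] (or `reduced_params`) object.
#' @param z evaluation point(s) in `[0, 1]`.
#' @return Numeric vector.
#' @export
nb_pgf <- function(params, z) {
  params <- as_nb_params(params)
  if (any(z < 0 | z > 1)) stop("z must lie in [0, 1]")
  (1 + params$delta * (1 - z))^(-params$r)
}

as_nb_params <- function(x) {
  if (inherits(x, "nb_params")) return(x)
  if (inherits(x, c("reduced_params", "telegraph", "gene_rates"))) {
    p <- as_reduced_params(x)
    return(nb_params(r = p$A * p$eps, delta = p$delta))
  }
  if (is.list(x) && all(c("r", "delta") %in% names(x)))
    return(nb_params(x$r, x$delta))
  stop("cannot interpret input as negative-binomial parameters")
}

#' Accumulated difference between two copy-number distributions
#'
#' `sum_n |p_n - q_n|` over the union support, plus both truncated tail
#' masses, giving an upper bound on the full-support L1 distance. This
#' is the metric used to certify convergence of the exact law to its
#' negative-binomial bursting limit.
#'
#' @param p,q [copy_number_pmf()] objects; shorter support is padded
#'   with zeros.
#' @return A single number in `[0, 2]`.
#' @examples
#' red <- reduced_params(100, 0.01, 10)
#' accumulated_difference(exact_pmf(red), nb_pmf(red))  # < 1e-2
#' @export
accumulated_difference <- function(p, q) {
  np <- length(p$probs); nq <- length(q$probs)
  len <- max(np, nq)
  pp <- c(p$probs, numeric(len - np))
  qq <- c(q$probs, numeric(len - nq))
  sum(abs(pp - qq)) + p$tail_mass + q$tail_mass
}

#' Parameter-regime diagnostics
#'
#' Advisory classification of a parameter set: the bursting limit
#' applies when the promoter is mostly OFF but switches and synthesizes
#' fast (`A <= 0.05`, `eps >= 10`, `N >= 10`); slow switching
#' (`eps < 1`) produces bimodal copy-number distributions.
#'
#' @param reduced parameters, as in [exact_pmf()].
#' @return List with the reduced parameters, logical flags
#'   `bursting_limit` and `bimodal_regime`, and a one-line `regime`
#'   label.
#' @examples
#' bursting_regime_diagnostics(reduced_params(1e4, 0.005, 1e4))
#' @export
bursting_regime_diagnostics <- function(reduced) {
  reduced <- as_reduced_params(reduced)
  bursting <- reduced$A <= 0.05 && reduced$eps >= 10 && reduced$N >= 10
  bimodal <- reduced$eps < 1
  regime <- if (bursting) "bursting limit (negative binomial applies)"
            else if (bimodal) "slow switching (bimodal copy-number law)"
            else "intermediate/fast switching (unimodal, near-Poisson as A -> 1)"
  list(N = reduced$N, A = reduced$A, eps = reduced$eps,
       delta = reduced$delta,
       bursting_limit = bursting, bimodal_regime = bimodal,
       regime = regime)
}
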