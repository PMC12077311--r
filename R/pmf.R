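#' Copy-number probability mass function container
#'
#' A truncated pmf over molecule counts `n = 0..n_max` with explicit
#' bookkeeping of the truncated tail mass, so that every pmf in the
#' package satisfies `sum(probs) + tail_mass == 1` up to rounding.
#'
#' @param probs numeric vector of probabilities for `n = 0, 1, ...`.
#' @param tail_mass upper bound on the probability mass beyond the
#'   truncation point (>= 0).
#' @return An object of class `"copy_number_pmf"`: list with `probs`
#'   (named by count), `n` (integer support) and `tail_mass`.
#' @export
copy_number_pmf <- function(probs, tail_mass = 0) {
  probs <- as.numeric(probs)
  if (any(!is.finite(probs)) || any(probs < -1e-12))
    stop("probabilities must be finite and non-negative")
  probs <- pmax(probs, 0)
  if (!is.finite(tail_mass) || tail_mass < 0)
    stop("tail_mass must be non-negative")
  if (abs(sum(probs) + tail_mass - 1) > 1e-6)
    stop("validation error: probabilities plus tail mass must sum to 1")
  structure(list(probs = stats::setNames(probs, seq_along(probs) - 1L),
                 n = seq_along(probs) - 1L,
                 tail_mass = tail_mass),
            class = "copy_number_pmf")
}

#' @export
print.copy_number_pmf <- function(x, ...) {
  cat(sprintf("copy_number_pmf on n = 0..%d (tail mass %.3g)\n",
              max(x$n), x$tail_mass))
  m <- pmf_mean(x)
  cat(sprintf("  mean = %.6g, variance = %.6g, Fano = %.6g\n",
              m, pmf_var(x), pmf_var(x) / m))
  invisible(x)
}

# numeric moments of a truncated pmf (tail ignored)
pmf_mean <- function(pmf) sum(pmf$n * pmf$probs)
pmf_var  <- function(pmf) sum(pmf$n^2 * pmf$probs) - pmf_mean(pmf)^2

#' Exact steady-state copy-number distribution
#'
#' The stationary distribution of the two-state master equation,
#' \deqn{\phi_n = \frac{N^n}{n!}\frac{(A\epsilon)_n}{(\epsilon)_n}
#'   M(A\epsilon+n, \epsilon+n, -N),}
#' evaluated in log space through the Kummer transformation (the
#' transformed series has positive terms only, so no cancellation occurs
#' even at `N = 1e4`).
#'
#' If `n_max` is omitted it is chosen from the closed-form moments as
#' `ceiling(mean + 10*sd + 20)`, widened with `N + 10*sqrt(N)` (at small
#' `A` the pmf keeps a secondary bump near `n = N` that a purely
#' moment-based rule misses), and then extended adaptively until the
#' truncated tail mass is below `1e-9`.
#'
#' @param reduced a [reduced_params()], [telegraph_model()] or
#'   [gene_rates()] object.
#' @param n_max optional truncation point; chosen automatically when
#'   omitted.
#' @return A [copy_number_pmf()].
#' @examples
#' p <- exact_pmf(reduced_params(100, 0.1, 10))
#' sum(p$probs) + p$tail_mass
#' @export
exact_pmf <- function(reduced, n_max = NULL) {
  reduced <- as_reduced_params(reduced)
  N <- reduced$N; A <- reduced$A; eps <- reduced$eps
  if (N == 0) {
    probs <- c(1, numeric(if (is.null(n_max)) 0 else n_max))
    return(copy_number_pmf(probs, 0))
  }
  mom <- moments(reduced)
  auto <- is.null(n_max)
  if (auto)
    n_max <- ceiling(max(mom$mean + 10 * sqrt(mom$variance),
                         N + 10 * sqrt(N)) + 20)
  lp <- exact_pmf_log(N, A, eps, n_max)
  if (auto) {
    # extend until the tail is certifiably below 1e-9
    while (1 - sum(exp(lp)) > 1e-9) {
      if (n_max > 2e5)
        stop("precision error: pmf truncation did not reach 1e-9 tail mass")
      n_max <- ceiling(n_max * 1.5)
      lp <- exact_pmf_log(N, A, eps, n_max)
    }
  }
  probs <- exp(lp)
  copy_number_pmf(probs, tail_mass = max(1 - sum(probs), 0))
}

# log phi_n for n = 0..n_max; b - a = eps*(1-A) is constant in n
exact_pmf_log <- function(N, A, eps, n_max) {
  n <- 0:n_max
  Ae <- A * eps
  logM <- vapply(n, function(nn) kummer_m_log_neg(Ae + nn, eps + nn, N),
                 numeric(1))
  n * log(N) - lgamma(n + 1) + lpochhammer(Ae, n) - lpochhammer(eps, n) + logM
}

#' Probability generating function of the exact distribution
#'
#' `phi(z) = M(A*eps, eps, N(z-1))`, the generating function
#' `sum_n phi_n z^n` of [exact_pmf()]. Equals 1 at `z = 1`; its
#' derivatives at `z = 1` give the factorial moments (first factorial
#' moment `N*A`).
#'
#' @param reduced parameters, as in [exact_pmf()].
#' @param z evaluation point(s) in `[0, 1]`.
#' @return `phi(z)` as a numeric vector.
#' @examples
#' pgf_eval(reduced_params(100, 0.1, 10), c(0, 0.5, 1))
#' @export
pgf_eval <- function(reduced, z) {
  reduced <- as_reduced_params(reduced)
  if (any(z < 0 | z > 1)) stop("z must lie in [0, 1]")
  vapply(z, function(zz) {
    x <- reduced$N * (1 - zz)
    exp(kummer_m_log_neg(reduced$A * reduced$eps, reduced$eps, x))
  }, numeric(1))
}

#' Closed-form stationary moments
#'
#' Mean `N*A`, Fano factor `1 + N(1-A)/(1+eps)` and variance
#' `mean * Fano` of the exact stationary distribution.
#'
#' @param x a model, `reduced_params` or `gene_rates` object.
#' @param ... unused.
#' @return List with `mean`, `variance`, `fano`.
#' @examples
#' moments(reduced_params(100, 0.001, 10))$fano  # 10.08...
#' @export
moments <- function(x, ...) UseMethod("moments")

#' @rdname moments
#' @export
moments.reduced_params <- function(x, ...) {
  m <- x$N * x$A
  fano <- 1 + x$N * (1 - x$A) / (1 + x$eps)
  list(mean = m, variance = m * fano, fano = fano)
}

#' @rdname moments
#' @export
moments.telegraph <- function(x, ...) moments(x$reduced)

#' @rdname moments
#' @export
moments.gene_rates <- function(x, ...) moments(reduce_params(x))

#' @rdname moments
#' @export
moments.copy_number_pmf <- function(x, ...) {
  m <- pmf_mean(x)
  v <- pmf_var(x)
  list(mean = m, variance = v, fano = v / m)
}
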