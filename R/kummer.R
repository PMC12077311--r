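#' Pochhammer symbol (rising factorial)
#'
#' `(x)_n = x (x+1) ... (x+n-1)`, with `(x)_0 = 1`.
#'
#' @param x real number.
#' @param n non-negative integer.
#' @return The rising factorial as a double.
#' @examples
#' pochhammer(3, 4)  # 3*4*5*6 = 360
#' pochhammer(1, 5)  # 5!
#' @export
pochhammer <- function(x, n) {
  if (length(n) != 1 || !is.finite(n) || n < 0 || n != floor(n))
    stop("n must be a single non-negative integer")
  if (n == 0) return(1)
  prod(x + seq_len(n) - 1)
}

# log (x)_n for x > 0; vectorized over n
lpochhammer <- function(x, n) lgamma(x + n) - lgamma(x)

# log of the 1F1 series sum for a > 0, b > 0, z > 0: every term is
# positive, so the sum is done on log terms with a running-max
# log-sum-exp.  Terms t_j satisfy t_0 = 1,
# t_{j+1}/t_j = (a+j) z / ((b+j)(j+1)); the peak sits near j ~ z for
# a, b << z, so the initial horizon covers z plus a generous margin and
# doubles if the final terms are not yet negligible.
hyp1f1_log_pos <- function(a, b, z) {
  stopifnot(a > 0, b > 0, z > 0)
  jmax <- ceiling(z + 12 * sqrt(z + 10) + a + 50)
  repeat {
    j <- seq_len(jmax)
    logt <- cumsum(log(a + j - 1) - log(b + j - 1) + log(z) - log(j))
    m <- max(0, logt)
    s <- m + log1p(sum(exp(logt - m)) + exp(-m) - 1)
    # converged when the tail term is negligible against the sum
    if (logt[jmax] < s + log(1e-18)) return(s)
    if (jmax > 1e7) stop("kummer_m: series failed to converge (precision error)")
    jmax <- jmax * 2
  }
}

# plain double-precision Taylor summation; used off the positive-series
# fast paths (small |z|, or sign-changing coefficient patterns)
hyp1f1_direct <- function(a, b, z, tol = 1e-15) {
  term <- 1
  s <- 1
  smax <- 1
  for (j in 0:10000) {
    term <- term * (a + j) * z / ((b + j) * (j + 1))
    s <- s + term
    smax <- max(smax, abs(s))
    if (abs(term) < tol * max(abs(s), 1e-300) && j > abs(z))
      break
  }
  if (abs(term) >= tol * max(abs(s), 1e-300))
    stop("kummer_m: series failed to converge (precision error)")
  # catastrophic cancellation guard: intermediate sums much larger than
  # the result mean the alternating series lost the leading digits
  if (smax > abs(s) * 1e6 && abs(s) > 0)
    warning("kummer_m: possible cancellation; result may have reduced accuracy")
  s
}

#' Confluent hypergeometric function of the first kind
#'
#' Evaluates Kummer's function `M(a, b, z)` (also written 1F1). For
#' negative arguments the Kummer transformation
#' `M(a,b,z) = e^z M(b-a, b, -z)` is applied so that (whenever
#' `b - a > 0`) the series has positive terms only, avoiding the severe
#' cancellation of the alternating Taylor series at large negative `z`.
#' Positive-term series are summed in log space, so arguments as large
#' as `z = -1e4` (as needed by [exact_pmf()] with `N` up to `1e4`) are
#' handled stably.
#'
#' @param a,b,z real arguments; `b` must not be zero or a negative
#'   integer.
#' @return `M(a, b, z)` as a double (may overflow to `Inf` for very
#'   large positive `z`).
#' @examples
#' kummer_m(2, 2, 1)         # collapses to exp(1)
#' kummer_m(0.5, 1.7, -50)
#' @export
kummer_m <- function(a, b, z) {
  stopifnot(length(a) == 1, length(b) == 1, length(z) == 1)
  if (!all(is.finite(c(a, b, z)))) stop("arguments must be finite")
  if (b <= 0 && b == floor(b))
    stop("domain error: b must not be zero or a negative integer")
  if (z == 0) return(1)
  if (a == 0) return(1)
  if (a == b) return(exp(z))
  if (z < 0) {
    if (b - a > 0 && b > 0) return(exp(z + hyp1f1_log_pos(b - a, b, -z)))
    return(hyp1f1_direct(a, b, z))
  }
  if (a > 0 && b > 0) return(exp(hyp1f1_log_pos(a, b, z)))
  hyp1f1_direct(a, b, z)
}

# log M(a, b, -x) for x >= 0 with b - a > 0, b > 0: the numerically
# stable route used by exact_pmf and pgf_eval
kummer_m_log_neg <- function(a, b, x) {
  stopifnot(x >= 0, b - a > 0, b > 0)
  if (x == 0) return(0)
  -x + hyp1f1_log_pos(b - a, b, x)
}
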