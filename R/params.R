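#' Raw kinetic rates of the two-state gene
#'
#' Bundle and validate the four rate constants of the two-state
#' (telegraph) model: synthesis while ON, promoter switching in both
#' directions, and first-order removal per molecule.
#'
#' @param k synthesis rate while the promoter is ON (events per unit
#'   time, >= 0).
#' @param f OFF -> ON switching rate (> 0).
#' @param h ON -> OFF switching rate (> 0).
#' @param rho per-molecule removal rate (> 0). Removal is degradation for
#'   mature mRNA, or release of the completed transcript for nascent-RNA
#'   assays.
#' @return An object of class `"gene_rates"`: a named list with fields
#'   `k`, `f`, `h`, `rho`.
#' @examples
#' gene_rates(k = 100, f = 1, h = 9, rho = 1)
#' @seealso [reduce_params()], [reduced_params()]
#' @export
gene_rates <- function(k, f, h, rho) {
  vals <- c(k = k, f = f, h = h, rho = rho)
  if (!all(is.finite(vals)))
    stop("invalid rates: all of k, f, h, rho must be finite numbers")
  if (k < 0)
    stop("invalid rates: k must be non-negative")
  if (f <= 0 || h <= 0 || rho <= 0)
    stop("invalid rates: f, h and rho must be strictly positive")
  structure(list(k = k, f = f, h = h, rho = rho), class = "gene_rates")
}

#' Reduced (dimensionless) parameters of the two-state gene
#'
#' The coordinate system in which the steady-state distribution is
#' expressed: `N = k/rho` is the mean copy number with the promoter
#' always ON, `A = f/(f+h)` the stationary ON probability,
#' `eps = (f+h)/rho` the ratio of switching to removal rates, and
#' `delta = N/eps` the burst scale (mean burst size in the bursting
#' limit).
#'
#' @param N mean copy number with promoter always ON (>= 0).
#' @param A stationary ON probability, strictly inside (0, 1).
#' @param eps switching-to-removal rate ratio (> 0).
#' @return An object of class `"reduced_params"`: named list with fields
#'   `N`, `A`, `eps` and the derived `delta = N/eps`.
#' @examples
#' reduced_params(N = 100, A = 0.1, eps = 10)
#' @export
reduced_params <- function(N, A, eps) {
  vals <- c(N = N, A = A, eps = eps)
  if (!all(is.finite(vals)))
    stop("invalid parameters: N, A, eps must be finite")
  if (N < 0) stop("invalid parameters: N must be non-negative")
  if (A <= 0 || A >= 1)
    stop("invalid parameters: A must lie strictly inside (0, 1)")
  if (eps <= 0) stop("invalid parameters: eps must be strictly positive")
  structure(list(N = N, A = A, eps = eps, delta = N / eps),
            class = "reduced_params")
}

#' Map raw rates to reduced parameters
#'
#' @param rates a [gene_rates()] object.
#' @return A [reduced_params()] object with `N = k/rho`, `A = f/(f+h)`,
#'   `eps = (f+h)/rho`, `delta = N/eps`.
#' @examples
#' reduce_params(gene_rates(100, 1, 9, 1))   # N = 100, A = 0.1, eps = 10
#' @export
reduce_params <- function(rates) {
  rates <- as_gene_rates(rates)
  reduced_params(N = rates$k / rates$rho,
                 A = rates$f / (rates$f + rates$h),
                 eps = (rates$f + rates$h) / rates$rho)
}

#' Map reduced parameters back to raw rates
#'
#' Inverse of [reduce_params()] at a given removal rate: `k = N*rho`,
#' `f = A*eps*rho`, `h = (1-A)*eps*rho`.
#'
#' @param reduced a [reduced_params()] object.
#' @param rho removal rate (> 0) fixing the time scale.
#' @return A [gene_rates()] object; `reduce_params(expand_params(p, rho))`
#'   recovers `p`.
#' @examples
#' expand_params(reduced_params(100, 0.1, 10), rho = 1)  # k=100, f=1, h=9
#' @export
expand_params <- function(reduced, rho) {
  reduced <- as_reduced_params(reduced)
  if (!is.finite(rho) || rho <= 0)
    stop("invalid rates: rho must be strictly positive")
  gene_rates(k = reduced$N * rho,
             f = reduced$A * reduced$eps * rho,
             h = (1 - reduced$A) * reduced$eps * rho,
             rho = rho)
}

#' Two-state transcription model object
#'
#' The central model constructor. Supply either raw rates `(k, f, h, rho)`
#' or reduced parameters `(N, A, eps)` plus an optional `rho` (default 1)
#' fixing the time scale; both representations are stored.
#'
#' @param k,f,h,rho raw rates, see [gene_rates()].
#' @param N,A,eps reduced parameters, see [reduced_params()].
#' @return An object of class `"telegraph"` with components `rates`
#'   (class `gene_rates`) and `reduced` (class `reduced_params`).
#' @examples
#' m <- telegraph_model(N = 100, A = 0.1, eps = 10)
#' moments(m)
#' @export
telegraph_model <- function(k = NULL, f = NULL, h = NULL, rho = NULL,
                            N = NULL, A = NULL, eps = NULL) {
  raw_given <- !is.null(k) || !is.null(f) || !is.null(h)
  red_given <- !is.null(N) || !is.null(A) || !is.null(eps)
  if (raw_given && red_given)
    stop("supply either raw rates (k, f, h, rho) or reduced parameters ",
         "(N, A, eps), not both")
  if (raw_given) {
    if (is.null(rho)) stop("raw parameterization needs rho")
    rates <- gene_rates(k, f, h, rho)
    reduced <- reduce_params(rates)
  } else if (red_given) {
    if (is.null(rho)) rho <- 1
    reduced <- reduced_params(N, A, eps)
    rates <- expand_params(reduced, rho)
  } else {
    stop("no parameters supplied")
  }
  structure(list(rates = rates, reduced = reduced), class = "telegraph")
}

#' @export
print.telegraph <- function(x, ...) {
  r <- x$rates; p <- x$reduced
  cat("Two-state transcription model\n")
  cat(sprintf("  rates:   k = %g, f = %g, h = %g, rho = %g\n",
              r$k, r$f, r$h, r$rho))
  cat(sprintf("  reduced: N = %g, A = %g, eps = %g (delta = %g)\n",
              p$N, p$A, p$eps, p$delta))
  fn <- 1 + p$N * (1 - p$A) / (1 + p$eps)
  cat(sprintf("  stationary mean = %g, Fano factor = %g\n", p$N * p$A, fn))
  invisible(x)
}

#' @export
print.gene_rates <- function(x, ...) {
  cat(sprintf("gene_rates: k = %g, f = %g, h = %g, rho = %g\n",
              x$k, x$f, x$h, x$rho))
  invisible(x)
}

#' @export
print.reduced_params <- function(x, ...) {
  cat(sprintf("reduced_params: N = %g, A = %g, eps = %g, delta = %g\n",
              x$N, x$A, x$eps, x$delta))
  invisible(x)
}

# Internal coercions: accept telegraph / gene_rates / reduced_params /
# plain named lists wherever one representation is needed.
as_gene_rates <- function(x) {
  if (inherits(x, "telegraph")) return(x$rates)
  if (inherits(x, "gene_rates")) return(x)
  if (inherits(x, "reduced_params"))
    stop("raw rates required: use expand_params(reduced, rho) first")
  if (is.list(x) && all(c("k", "f", "h", "rho") %in% names(x)))
    return(gene_rates(x$k, x$f, x$h, x$rho))
  stop("cannot interpret input as gene rates")
}

as_reduced_params <- function(x) {
  if (inherits(x, "telegraph")) return(x$reduced)
  if (inherits(x, "reduced_params")) return(x)
  if (inherits(x, "gene_rates")) return(reduce_params(x))
  if (is.list(x) && all(c("N", "A", "eps") %in% names(x)))
    return(reduced_params(x$N, x$A, x$eps))
  stop("cannot interpret input as reduced parameters")
}
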