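---
title: "The two-state model of transcriptional bursting: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The two-state model of transcriptional bursting: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(telegraph)
```

## The model and its assumptions

The package implements the two-state ("telegraph") model of gene
expression: a promoter switches OFF→ON at rate $f$ and ON→OFF at rate
$h$ (both first-order, so dwell times are exponential); while ON,
transcripts appear at rate $k$; each of the $n$ transcripts present is
removed independently at rate $\rho$. The state is the pair (promoter
state, $n$), and the stationary probabilities $\alpha_n$ (ON) and
$\beta_n$ (OFF) satisfy the coupled birth–death balance equations with
$\phi_n = \alpha_n + \beta_n$ the marginal copy-number law.

Two interpretations are supported by the same mathematics. For mature
mRNA, $\rho$ is degradation. For live imaging of nascent transcription
spots, $n$ is the number of elongating transcripts, $k$ the initiation
rate and $\rho$ the release rate of completed transcripts; treating
release as a first-order event is an approximation to the underlying
deterministic elongation, which the time-rescaling diagnostic (below)
makes testable.

All stationary quantities depend only on the reduced parameters
$N = k/\rho$, $A = f/(f+h)$, $\epsilon = (f+h)/\rho$ (and the derived
burst scale $\delta = N/\epsilon$); $\rho$ fixes the time scale for
simulation. The marginal law is
$$\phi_n = \frac{N^n}{n!}\,\frac{(A\epsilon)_n}{(\epsilon)_n}\,
  \mathrm{M}(A\epsilon + n,\ \epsilon + n,\ -N),$$
with generating function $\phi(z) = \mathrm{M}(A\epsilon, \epsilon,
N(z-1))$, mean $NA$ and Fano factor $1 + N(1-A)/(1+\epsilon)$. The
closed-form moments are not taken on faith: the test suite checks them
against the numeric moments of the pmf, and the pmf itself against a
direct sparse solve of the truncated stationary master equation.

`A` is restricted to the open interval $(0,1)$ ($f,h>0$ in the model);
the Poisson limit $A \to 1$ is reached by evaluating at
$1 - 10^{-12}$, which avoids special-casing degenerate chains while
agreeing with Poisson($N$) to better than $10^{-6}$ in L1.

## Numerical evaluation of the Kummer function

$\phi_n$ needs $\mathrm{M}(a, b, z)$ at $z = -N$ with $N$ up to $10^4$,
where the raw Taylor series alternates and loses all significant digits
in double precision. The evaluator therefore applies the Kummer
transformation $\mathrm{M}(a,b,z) = e^z \mathrm{M}(b-a, b, -z)$
whenever $z < 0$ and $b - a > 0$ — in the pmf's parameterization
$b - a = \epsilon(1-A) > 0$ always — so the transformed series has
positive terms only. The positive-term series is summed on the log
scale (cumulative log-ratios plus a running-max log-sum-exp), which
avoids overflow of intermediate terms near $e^{N}$; the result is the
*logarithm* of $\mathrm{M}$, which combines exactly with the log-scale
prefactors $n\log N - \log n! + \log (A\epsilon)_n - \log (\epsilon)_n$
of $\phi_n$. Summation stops when the current term falls below
$10^{-18}$ of the running sum past the series peak, and the horizon
doubles if that is not reached. Off this fast path (sign-changing
coefficient patterns a user may request directly) a plain double
summation with a cancellation guard is used. Accuracy on the pmf's
domain is at the $10^{-10}$ relative level, verified against 50-digit
reference values.

### Truncation of the pmf

The truncation point starts from the closed-form moments,
$n_{\max} = \lceil \text{mean} + 10\,\text{sd} + 20 \rceil$, widened
with $N + 10\sqrt{N}$: at small $A$ the pmf keeps a secondary bump near
$n = N$ (mass $\sim A$) that a purely moment-based rule misses
entirely. The truncation then *extends adaptively* until the tail mass
$1 - \sum_n \phi_n$ falls below $10^{-9}$; the remaining tail is stored
on the pmf object, and every distribution comparison in the package
(`accumulated_difference()`) adds tail masses to the summed
$|p_n - q_n|$, so reported L1 distances are upper bounds on the
full-support distance.

## The bursting limit

For $A \ll 1$, $\epsilon, N \gg 1$ with $\delta = N/\epsilon$ fixed,
$h$ and $k$ dominate: the promoter flickers ON briefly and rarely, each
ON episode emits a geometric number of transcripts, and the stationary
law converges to the negative binomial
$\tilde\phi_n = \frac{(A\epsilon)_n}{n!} (\tfrac{\delta}{1+\delta})^n
(\tfrac{1}{1+\delta})^{A\epsilon}$ with generating function
$(1+\delta(1-z))^{-A\epsilon}$. The pmf is evaluated with
`stats::dnbinom` (R's log-space implementation, `size` $= A\epsilon$,
`prob` $= 1/(1+\delta)$), which is robust at large shape; an
independent ratio-recurrence oracle in the tests confirms it to
$10^{-10}$. The accumulated difference between exact and limiting laws
is of order $A$ (checked as $\le 2A$), and decreases monotonically in
$\epsilon$ at fixed $(A, \delta)$.

The regime diagnostics are advisory labels only: "bursting" when
$A \le 0.05$, $\epsilon \ge 10$, $N \ge 10$; "bimodal" when
$\epsilon < 1$ (promoter slower than removal, so the occupancy
histogram develops a peak near 0 and one near $N$).

## Exact simulation

The simulator is the direct (first-reaction-free) Gillespie method —
two uniforms per event, one for the exponential waiting time and one
for channel choice — over the four channels synthesis ($k$, ON only),
removal ($\rho n$), ON→OFF ($h$), OFF→ON ($f$). The inner loop is
compiled (Rcpp) but consumes R's own RNG stream, so `set.seed(seed)`
makes trajectories bit-reproducible and multi-run experiments derive
child seeds by indexed offset. No tau-leaping or hybrid approximation
is offered: exactness is the point, and the compiled loop simulates
$\sim 10^7$ events per second.

The default initial condition is promoter OFF with zero molecules (the
natural burst-observation setting); `initial = "stationary"` samples
the exact pmf and Bernoulli($A$) instead. Occupancy statistics default
to a burn-in of 20% of the horizon, which is conservative for every
parameter set used in the tests (relaxation time $\sim \max(1/\rho,
1/(f+h))$, orders of magnitude below the horizons used).

The M-state ladder generalization (`gillespie_mstate()`) allows states
$\mathrm{OFF}, \mathrm{ON}_1, \dots, \mathrm{ON}_{M-1}$ with strictly
increasing synthesis rates and nearest-neighbour transitions. In a
slow-switching regime with well-separated $N_j = k_j/\rho$ the
occupancy histogram is $M$-modal — the observable that distinguishes
genuinely multi-state promoters from two-state bursting, and the reason
the two-state model with $\epsilon \gg 1$ can masquerade as multi-state
in fluorescence traces. Synthesis-period distributions in ladders are
left to the user: dwell compositions follow a Gamma law only for
irreversible progressions, so nothing of the sort is asserted by the
package.

## Burst statistics and the estimator

A burst is a complete (both ends observed) maximal ON interval; its
size counts synthesis events, not net copy-number change (removals
during ON would otherwise bias sizes downward), and zero-size bursts
are retained since the geometric law has mass at zero. Censored
boundary dwells are excluded from all dwell statistics, which keeps the
exponentiality tests unbiased.

The moment estimator follows the summary-statistic recipe:
$\hat A = \bar T_{\mathrm{ON}} / (\bar T_{\mathrm{ON}} +
\bar T_{\mathrm{OFF}})$, $\hat N = \bar n / \hat A$,
$\hat\epsilon = \hat N / \hat\delta$. For $\hat\delta$ there is a
genuine choice: the sample mean burst size estimates $k/h$ (synthesis
racing exponential switch-off), whereas the burst scale is
$\delta = N/\epsilon = (k/h)(1+f/h)^{-1} = (k/h)(1-A)$. The two
coincide in the bursting regime but differ by a relative bias $A$
outside it, which propagates one-for-one into $\hat\epsilon$. The
default estimator therefore multiplies the mean burst size by
$(1-\hat A)$ — exact, costless, and reducing to the plain prescription
as $A \to 0$; `bias_correct = FALSE` gives the uncorrected version.
With the correction, simulated recovery at $(N, A, \epsilon) =
(100, 0.1, 10)$ over $10^5$ time units is accurate to well under 1% on
all three parameters.

The geometric goodness-of-fit test bins sizes on $\{0, 1, \dots\}$
with success probability estimated as $1/(1+\bar{x})$, pools adjacent
bins below an expected count of 5, and charges one degree of freedom
for the estimated parameter. It holds its nominal 1% size under the
geometric null and has power above 0.9 against a Poisson alternative
of equal mean at $n = 10^4$ — the operational contrast between
two-state bursting and a constitutive (or fast-cycling multi-state)
promoter.

Mode counting for uni/multimodality calls pools adjacent histogram
bins to a minimum expected mass, compares pooled bins as densities
(mass per unit width), applies a 3-bin moving average, and merges
adjacent maxima unless separated by a dip of at least 20% of the
smaller peak — the prominence rule is what makes the count stable on
finite-time occupancy histograms.

## Time rescaling

For nascent-transcript traces, removal (release of finished
transcripts) is not first-order in clock time, but a birth–death
description is recovered by rescaling time with the cumulative integral
of the signal: `rescale_time()` computes
$\tau_i = \int_{t_0}^{t_i} F(t)\,dt$ by the trapezoid rule on the given
samples (no resampling — the operational reading of the procedure; an
alternative reading via an estimated survival density exists and is
deliberately not implemented). In rescaled time, a promoter-OFF decay
window should be log-linear; `log_decay_fit()` fits OLS of
$\log F$ on $\tau$ in a user-supplied window (the OFF window is marked
by the experimenter, not auto-detected — change-point detection is out
of scope). Unnormalized $\tau$ is the default; normalization by the
total integral is available for cross-trace comparability, and slopes
are only meaningful relative to that choice. The canonical fixture
$F(t) = 1/(1+t)$ has $\tau = \log(1+t)$ exactly, so the pipeline must
return slope $-1$ with $R^2 = 1$; it does, to $10^{-6}$.

## What the synthetic data does and does not show

All test inputs are generated by the package's own simulator and
fixture generators at the model's reference parameter sets — e.g.
$(N, \epsilon, A) = (100, 10, 0.1)$ and $(100, 10, 0.01)$ for the
limit comparison, $(10^4, 10^4, 0.005)$ for the bursting regime,
$(60, 0.75, \cdot)$ for bimodality — with horizons of $10^4$–$10^5$
time units (a few million events), chosen so Monte-Carlo standard
errors sit comfortably inside the stated tolerances. Passing tests
certify internal consistency of theory, simulation and inference under
the model's own assumptions: exponential dwells, constant rates,
perfect burst observation, no measurement noise beyond the optional
Gaussian gain model of `synth_trace()`. They do not certify that real
promoters are two-state, that fluorescence is linear in transcript
number, or that real burst detection from noisy traces is error-free —
on real data the estimator inherits whatever segmentation errors
produce the dwell and size inputs.

## Numerical and design choices, in brief

- Truncation: moment rule + $N$-bump widening + adaptive extension to
  tail $< 10^{-9}$; tails carried explicitly and added to L1 bounds.
- Kummer evaluation: transformation to positive-term series, log-space
  summation, $10^{-18}$ relative term cutoff, doubling horizon;
  cancellation guard on the general-purpose path.
- Probability comparisons: L1 on the union support plus tails.
- Estimator: $(1-\hat A)$ burst-size bias correction by default.
- Geometric test: expected-count-5 pooling, df $=$ bins $- 2$.
- Ties/degenerates: $N = 0$ short-circuits to a point mass; all-zero
  traces rescale to $\tau \equiv 0$ and refuse normalization;
  single-switch trajectories return empty dwell lists with a warning.
- Determinism: one seed per run; child seeds by indexed offset.

## Known limitations

Time-dependent (relaxation) probabilities are not implemented — all
analytics are stationary. Burst detection requires the promoter state,
so it applies to simulated or pre-segmented data, not raw fluorescence
(hidden-Markov segmentation is out of scope, as is full-likelihood or
Bayesian inference from copy-number histograms). The Kummer evaluator
is tuned for the pmf's parameter domain ($z < 0$, $b > a > 0$);
far outside it, it falls back to plain summation and warns when
cancellation may have cost accuracy.
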