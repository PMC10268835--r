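---
title: "Mutational biases, completion experiments and the distribution of mutation rates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mutational biases, completion experiments and the distribution of mutation rates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(mutpie)
```

## The problem

When a bacterial population adapts — say, *Pseudomonas fluorescens* SBW25
evolving the wrinkly spreader (WS) morphotype at a static air–liquid
interface — many different mutations can produce the same phenotype. Their
rates are anything but equal: target sizes differ by orders of magnitude
between genes, and individual mutations range from cold sites to strong
hotspots. mutpie provides the simulation machinery to ask what that
imbalance does to two practical questions:

1. **Discoverability** — how many independent mutants must an experiment
   sequence before it has seen *every* mutational route to the phenotype,
   or before it can estimate their relative rates?
2. **Predictability** — when absolute rates fluctuate according to some
   distribution, how reliably does a larger mutational target actually
   out-mutate a smaller one, within a species or between related species?

Selection, population size and population structure are deliberately out of
scope: every analysis here isolates the mutational origin of variation. The
model system's published tables ship as fixtures (`ws_gene_setup()`,
`aws_spectrum()`), so all worked analyses run offline.

## Mutation pie charts and their imbalance metrics

A **mutation pie chart (MPC)** assigns each mutational element (a mutation,
gene or pathway) its relative mutation rate: a probability vector. One
laboratory observation of a mutant is modelled as a single categorical draw
from the MPC. Three scalar summaries of imbalance are implemented:

* the **unevenness index** $U = 1 - H'/\ln n$, with
  $H' = -\sum_i p_i \ln p_i$ Shannon's diversity index and the convention
  $0 \ln 0 = 0$. $U = 0$ on the even chart, $U = 1$ when one element takes
  everything. This is the workhorse metric: its range does not depend on
  $n$;
* the **Gini coefficient**
  $G = \frac{1}{2 n^2 \bar p} \sum_{i,j} |p_i - p_j|$ (maximum $1 - 1/n$);
* **SLS2**, the sum of the two largest shares (minimum $2/n$).

All three are invariant under permutation of the shares and under global
rescaling of the pre-normalization weights, so counts, rates or
frequencies can be fed in interchangeably. Metrics refuse single-share
charts rather than return a value: with $n = 1$, $\ln n = 0$ and the
normalization is undefined; the "one share takes all" limit is understood
among $n \ge 2$ shares.

```{r}
mpc_metrics(aws_spectrum())
```

The observed *aws* fluctuation-test spectrum (12 mutations, 41 mutants, one
20/41 hotspot) has $U = 0.315$.

## Completion experiments

A **completion experiment** draws mutants until every element has been seen
at least once and reports the number of draws — the coupon collector's
waiting time with unequal coupon probabilities. For the even $m$-chart,
closed forms guide experimental design: mean $m H_m \approx
m(\ln m + \gamma + 1/(2m))$, standard deviation
$\sqrt{m^2 H^{(2)}_m - m H_m} \approx
\sqrt{\pi^2 m^2/6 - (\ln m + 1 + \gamma)m - 1/(12m)}$, expected
$m/(m-k)$ further draws after $k$ discoveries, and the
maximum-likelihood total $m$ solving
$obs = m/m + m/(m-1) + \dots + m/(m-k+1)$ (the expanded sum equals
$m(H_m - H_{m-k})$; we use the sum itself). For an arbitrary chart the
expected value is the integral
$E\{C_m\} = \int_0^\infty \big(1 - \prod_i (1 - e^{-p_i x})\big)\,dx$,
evaluated by adaptive quadrature (relative tolerance 1e-6; the upper limit
is doubled until the integrand is below 1e-12, justified by its
$e^{-p_{\min} x}$ decay). A Karush–Kuhn–Tucker argument shows the even
chart minimizes this expectation at fixed $m$ — unevenness always slows
completion.

```{r}
c(mean_50 = expected_completion_even(50), sd_50 = sd_completion_even(50),
  after_40_of_50 = expected_additional(50, 40))
```

**Simulator design.** The default simulator uses the exact Poissonization
of the collector's problem rather than drawing categories one at a time:
embedding observations in a unit-rate marked Poisson process, the first
arrival of element $i$ falls at $X_i \sim \mathrm{Exp}(p_i)$ independently
across elements, completion occurs at $T = \max_i X_i$, and the number of
draws is distributed as $n + \sum_i \mathrm{Pois}(p_i (T - X_i))$. This is
distribution-exact and turns $10^5$ replicates into a handful of
vectorized array operations. A literal block-categorical sampler is kept
as `method = "direct"`, and the test suite checks the two against each
other and against the quadrature mean — three independent routes to the
same law. Poisson means beyond $2^{30}$ (possible for nearly degenerate
charts) switch to the normal limit, and counts accumulate as doubles.

One numerical caveat worth recording: the even 16-chart's completion
distribution has $P(C \le 50) = 0.4999897$ by inclusion–exclusion, so its
median sits on a razor edge — empirical medians at $10^5$ replicates are
50 or 51 depending on the seed, and the exact median is 51.

## Estimating an MPC from finite data

`estimation_error_experiment()` implements a three-compartment design: a
truth compartment (the real MPC), an observation compartment (multinomial
samples of increasing size) and a modelling compartment that sees only the
counts. The estimator is the plug-in share vector over a *known* number of
categories, unobserved categories entering as zero shares. The known-$n$
reading is a deliberate choice: with unknown $n$ the unevenness of a
single observation is undefined, whereas error curves here are defined
from one observation up (where $\hat U = 1$ exactly). Errors are signed,
$\hat U - U_{true}$, so underestimation is negative. The characteristic
result — bias vanishes within a few hundred observations while the 95%
error band stays wide for much longer — is asserted in the test suite as a
qualitative ordering.

## The distribution of mutation rates (DMR)

Absolute per-mutation rates are modelled as i.i.d. draws from a
**log-normal** distribution: most rates are tiny, none are zero, a few are
hotspot-sized. Parameters `mu` and `sigma` are those of the underlying
normal; mean $e^{\mu+\sigma^2/2}$, median $e^\mu$, mode $e^{\mu-\sigma^2}$,
CV $\sqrt{e^{\sigma^2}-1}$. The unbounded support is kept (no truncation at
biologically implausible rates); instead `sample_rates()` counts draws
above $10^{-2}\,\mathrm{gen}^{-1}$ in an attribute, which stays zero in any
realistic regime. A moment-matched gamma family (shape $1/(e^{\sigma^2}-1)$)
is available for shape-sensitivity comparisons.

Sampling an MPC *from* a DMR — each of $n$ sites drawing its rate
independently, then normalizing — links the two views. Normalization
cancels $e^\mu$ exactly, so every unevenness-related output depends on
`sigma` alone; the package exploits this by checking seed-identical results
across different `mu`. The total mutation rate (TMR) to the phenotype is
the across-sites sum: heavy-skewed for few sites, asymptotically normal by
the central limit theorem (`tmr_distribution()`, `tmr_asymptotics()`).
Skewness uses the adjusted Fisher–Pearson estimator. Note that for very
dispersed DMRs convergence is slow in both senses: the sum's true skewness
is $\mathrm{skew}_1/\sqrt{n}$, which at $\sigma = 1.72$ still exceeds 2 at
$n = 1000$, and the empirical skewness estimator itself needs sixth
moments — oracle checks are therefore run at moderate $\sigma$.

The probability of exact mutational parallelism between two independent
realizations reduces to $Pr_{para} = e^{\sigma^2}/n$, clamped at 1 (with a
warning) where the formula exceeds it.

## Calibrating the DMR from one observed spectrum

`calibrate_sigma()` estimates `sigma` by simulation-based maximum
likelihood, with the DMR mean pinned to the experimentally measured
average rate ($5\times10^{-11}\,\mathrm{gen}^{-1}$ for the WS system): for
each grid value of `sigma` (default grid 0.1–4.5 in steps of 0.05),
$\mu = \ln(\text{mean}) - \sigma^2/2$, a batch of 12-site MPCs is sampled
and the density of their unevenness evaluated at the observed
$U_{obs} = 0.315$. The density estimator is a fixed 100-bin histogram on
$[0,1]$ with a ±1-bin smoothing average — at this resolution the ML
location is insensitive to the estimator's details. The 95% CI is the
`sigma` range where $U_{obs}$ lies between the simulated 2.5% and 97.5%
quantiles, boundaries linearly interpolated where the quantile curves
cross the observed value. ML and CI are computed from the *same* draws, so
there is no resampling inconsistency. Sampling noise in $U_{obs}$ itself
(41 mutants) is not propagated — the calibration treats the observed
unevenness as a fixed input.

Two parameter conventions coexist in the fixtures: the headline calibration
(mean $5\times10^{-11}$, $\sigma = 1.72$, hence $\mu = -25.20$) and a
variant ($\hat\mu = -25.15$, $\hat\sigma = 1.69$) used for the
500-mutation pathway analyses; both are kept as stated rather than
reconciled. The default replicate budget is $2\times10^4$ MPCs per grid
point — a desk-scale setting (the original analyses used $10^6$) under
which the ML `sigma` is reproducible to about ±0.1 and the CI bounds to a
few hundredths; the package's tests use tolerances sized accordingly. The
"aws setup" means 12 exchangeable sites (the 12 distinct mutations), not
the 3-gene aggregation.

```{r, eval = FALSE}
cal <- calibrate_sigma(unevenness(aws_spectrum()), mean = 5e-11,
                       n_sites = 12)
glance(cal)
autoplot(cal)
```

## Repeatability of target-size advantages

Pathway A has $r$-fold more sites than pathway B; every site draws its
rate from the same log-normal DMR. `prob_larger_wins()` estimates by Monte
Carlo the probability that A's summed rate exceeds B's (no analytical form
is known for log-normal sums); `r_threshold()` finds the smallest integer
$r$ at which that probability reaches 95%. The default design sets the
small pathway to a single site — the conservative configuration, since a
many-site small pathway concentrates its own sum and only helps the large
one — and `n_small` stays an explicit parameter because the absolute sizes
behind the published curves are not stated. With $\sigma = 1.72$ the
threshold lands around 8, comfortably below the quoted bound of 15: large
target-size ratios are robust to DMR stochasticity, while small ones are
routinely overturned by hotspots.

## Synthetic generators

* `random_mpc_dirichlet(n, concentration)` — symmetric Dirichlet shares.
* `mpc_at_unevenness(n, target_u)` — a chart with prescribed unevenness.
  The Dirichlet concentration whose *expected* unevenness matches the
  target comes from the closed form
  $E[U] = 1 + (\psi(a+1) - \psi(na+1))/\ln n$ (digamma root-finding, no
  Monte Carlo), followed by rejection until a draw lands within the
  tolerance (default ±0.005, budget 10^4 tries). Draws are exchangeable and
  unordered; only $U$ itself is controlled, so results on fixed-$U$
  ensembles are comparable to, not identical with, any particular
  published ensemble.
* `mutant_stream()` — i.i.d. categorical observations from a chart.

All generators consume R's global RNG: `set.seed()` gives exact
reproducibility, matching the convention of the field's simulation
packages.

## Problem sizes and runtime

Defaults were chosen so the full reproduction runs on a laptop core:
$10^5$ completion replicates (seconds via the race sampler), $10^5$
500-site MPCs for the unevenness distribution, $2\times10^4$ MPCs per
calibration grid point, $10^5$ Monte-Carlo pairs per candidate ratio in
the repeatability search. The test suite uses smaller replicate counts
with 3–4 standard-error guards for stochastic assertions.

## Limitations

* No selection, fitness, population size or origin-fixation dynamics: the
  package quantifies the mutational origin of variation only.
* One DMR for all mutation types and environments; per-type or
  per-environment spectra would be a straightforward extension.
* The plug-in unevenness estimator is the only spectrum estimator; no
  shrinkage or Bayesian variants.
* Synthetic fixed-$U$ MPCs capture the unevenness value, not any
  particular ordering or gene structure of real spectra — passing tests on
  them show correctness of the machinery, not realism of any single chart.
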