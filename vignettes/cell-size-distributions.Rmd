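---
title: "Fitting cell-size distributions and screening for gamma-deviant mutants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fitting cell-size distributions and screening for gamma-deviant mutants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sizescreen)
```

## The model

A Coulter-type channelyzer counts cells per discrete volume channel, so the
raw datum for one strain is a binned frequency histogram over size values in
femtoliters. Budding-yeast cell volumes in a steadily proliferating
population are strongly right-skewed, and across ploidies and carbon sources
they are well described by the two-parameter gamma distribution with density

$$f(x) = \frac{\beta^\alpha}{\Gamma(\alpha)}\, x^{\alpha-1} e^{-\beta x},
\qquad x > 0,$$

shape $\alpha$ (dimensionless) and rate $\beta$ (per fL), mean
$\alpha/\beta$. Wild-type fits sit near $\alpha \approx 4\text{–}8$,
$\beta \approx 0.04\text{–}0.09$; richer media push both the mean size and
the shape upward. Gamma distributions arise naturally as aggregates of many
exponential and power-law subprocesses — consistent with bursty gene
expression producing gamma-distributed protein levels whose aggregate sets
cell mass — but nothing in the pipeline depends on that interpretation: the
gamma is used as an empirically validated *reference pattern*, and the
screen measures departure from it.

The pipeline runs, per strain:

1. resample $n$ per-cell values from each strain's histogram (the study
   used $n = 1000$);
2. reject normality (Shapiro–Wilk) and lognormality (Shapiro–Wilk on logs);
3. fit gamma, lognormal and Weibull by maximum likelihood and compare
   families by the Anderson–Darling (AD) statistic, with the
   three-parameter generalized gamma as a complexity control via BIC;
4. test the composite gamma hypothesis with a parametric-bootstrap AD
   test, and test/rank against a *fixed* reference gamma whose parameters
   are the arithmetic mean of wild-type fits
   (`reference_null()`; the packaged haploid pair averages to
   shape 3.8277, rate 0.078949);
5. rank strains by the fixed-null AD statistic, keep the worst $k$
   samples (default 50), collapse replicate samples to unique strains,
   and annotate the top/bottom 5% of median sizes as `lge`/`whi`.

## Resampling from binned data

Channel histograms give frequencies, not cells. `resample_cells()` draws a
multinomial sample over bins with probabilities proportional to frequency
and places each drawn cell at its bin center; a deterministic mode
(`round(freq * n)` with largest-remainder correction) is available where a
fixed composition is preferred. Bin centers are what instruments export, so
bin *edges* are inferred at midpoints of consecutive centers, with the two
edge bins extended symmetrically.

Center-resampling produces heavily tied samples (≈ 200 distinct values per
1000 cells on a 256-channel grid). The EDF statistics and Shapiro–Wilk test
tolerate ties but are slightly distorted by them, so a `jitter` flag offers
uniform within-bin smearing; it is **off by default** because the discrete
sample is what the frequency table actually supports, and the distortion is
small at this channel resolution (it raises the mean fixed-null A² by
roughly 0.1 without moving the 1% rejection rate out of its calibration
band — see the screening tests). Tied samples are never silently
deduplicated; the Shapiro–Wilk wrapper warns instead.

Debris: cultures often show a spurious spike in the smallest channels from
small-particle debris. No trimming is applied by default, since trimming
changes the very tail structure the screen scores;
`screen_config(min_size = ...)` provides an explicit cutoff for users who
want one.

## Maximum-likelihood fits

The gamma fit is exact profile maximum likelihood: with
$s = \ln \bar{x} - \overline{\ln x}$, the shape solves
$\ln\alpha - \psi(\alpha) = s$ by Newton iteration started at the Minka
closed-form approximation $\alpha_0 = (3 - s + \sqrt{(s-3)^2 + 24s})/(12s)$,
and $\hat\beta = \hat\alpha/\bar{x}$, which makes the fitted mean equal the
sample mean exactly. Convergence demands an absolute score below $10^{-10}$
within 100 iterations; non-convergence with a usable iterate is a flag on
the result, not an exception, while degenerate inputs (all values equal,
nonpositive values, $n < 8$) are hard errors. The Weibull shape is found by
the analogous Newton iteration on its profile score; lognormal estimates
are closed-form log moments (MLE convention, divisor $n$).

The generalized gamma is parameterized with density
$\propto x^{\alpha p - 1} e^{-(\beta x)^p}$, which reduces to the gamma at
$p = 1$ and, via $y = x^p$, reduces fitting to a gamma fit on transformed
data. The optimizer is an outer one-dimensional profile search on $p$ over
$[0.15, 6]$ with the inner gamma fit on $y$; $p = 1$ is always evaluated
explicitly, so the maximized log-likelihood can never fall below the gamma
fit's (the nesting identity the tests assert). The published analysis did
not name its parameterization; this one was chosen for the clean gamma
nesting. On gamma data the likelihood-ratio statistic for the extra
parameter is $\chi^2_1$-distributed, so BIC (penalty $\ln n$ vs LR median
≈ 0.45) prefers the two-parameter gamma essentially always — the behavior
the acceptance suite verifies.

## Goodness-of-fit calibration

`edf_statistics()` computes the classical EDF statistics from the
probability transforms $u_{(i)}$ of the sorted sample (clamped to
$[10^{-12}, 1-10^{-12}]$ before logs; clamp events are counted on the
result). Two nulls need two very different calibrations:

* **Composite gamma** (parameters estimated from the tested sample):
  packaged tests hide their calibration internals, so the transparent
  standard here is the parametric bootstrap — draw $B$ samples of size $n$
  from the fitted gamma, *refit each one*, recompute A², and report
  $p = (1 + \#\{A^2_b \ge A^2_{obs}\})/(B+1)$, strictly in $(0,1]$ and
  bit-reproducible for fixed $(B, \text{seed})$. Default $B = 999$;
  $B < 99$ is refused rather than returning an uncalibrated p-value.
  Because the attainable p-values are multiples of $1/(B+1)$, a test at
  $\alpha = 0.01$ with $B = 199$ operates at level $1/200 = 0.005$;
  third-decimal differences from any previously published composite
  p-values are expected.
* **Fixed gamma null** (fully specified): the statistic's classical
  asymptotic distribution applies. It is computed from the alternating
  Anderson–Darling series with the inner integrals evaluated by adaptive
  quadrature, accurate to ~$10^{-8}$ across the support (checked against
  the classical critical values 2.492 → 0.05 and against direct
  simulation). For $n < 50$ the asymptotics are replaced by a bootstrap
  from the null (no refitting).

## The screen

`screen_cohort()` derives every strain's seed deterministically from the
master seed and the strain id, so results are independent of cohort order
and bit-reproducible end to end. Per-strain failures (e.g. a degenerate
histogram) are recorded in the row's `status` and ranked last, never
dropped and never fatal to the cohort. Ranking uses the fixed-null AD
*statistic* (worst first, ties broken by strain id) — under a fixed null
the statistic and its p-value order identically, and the statistic stays
informative beyond the floating-point floor of the p-value. The screening
significance level is a raw $\alpha = 0.01$ per strain with no
multiple-testing correction — deliberately permissive, since the screen's
output is a ranking rather than a family of confirmatory tests; the
`fixed_null_p` column supports any correction a user prefers downstream.

Size classes are ordinal: exactly $\lceil qN \rceil$ strains in each tail
($q = 0.05$ by default), ties broken by strain id so the classification is
deterministic even for identical medians.

## What the synthetic generator does and does not emulate

`simulate_cohort()` draws per-cell volumes and bins them onto a
256-channel linear grid over 5–250 fL (a channelyzer window typical for
yeast; configurable). Cells per histogram default to 50,000, a realistic
acquisition count. Class constructions:

* `wildtype_gamma` — gamma draws at the printed rich-medium diploid fit
  (shape 6.624628, rate 0.060432) unless overridden;
* `shifted_gamma` — rate divided by a shift factor: larger mean, same
  shape (factor 1 reproduces the wild-type draw bit-for-bit);
* `left_skew` — a large location minus a gamma draw, nonpositive draws
  rejected. This mirror-image construction is used instead of a
  max-of-two-gammas device because the maximum of two iid right-skewed
  variables remains right-skewed (checked by direct simulation: sample
  skewness positive in 100/100 seeds across parameter settings), whereas
  the reflected gamma has skewness $-2/\sqrt{\text{shape}}$ by
  construction, and truncation at zero is negligible for the default
  location (170 fL) and tail parameters;
* `multimodal` — a gamma mixture with well-separated component means
  (defaults: equal weights at 60 and 150 fL, component CV ≈ 18%);
* `debris` — a base histogram plus 3% of mass spread over the three
  smallest channels, emulating small-particle debris peaks.

What passing tests on these cohorts show: the pipeline's statistical
machinery is calibrated (null rejection rates at nominal level through the
full resample-and-test path, including binning effects) and has power
against the mutant shapes of interest (spike-ins rank at the top with
sensitivity ≈ 1). What they do not show: real mutant histograms include
instrument drift, debris structure, and aneuploid or mixed populations the
generator does not model; the mixture construction is a stand-in for
whatever generates multimodality in real cultures, not a biological claim.
Agreement with any particular measured dataset can only be checked against
that dataset.

## Numerical and design choices

* Seeds: one master seed; per-strain seeds via a 31-ary string hash of the
  strain id modulo $2^{31}-1$ (`derive_seed()`), all within 32-bit range.
* Weighted medians use the upper discrete-median convention: the smallest
  bin whose cumulative frequency strictly exceeds 0.5 (a bin where the
  cumulative sum equals 0.5 exactly does not yet contain the median cell).
* Wilcoxon rank-sum: exact mode enumerates all assignments of pooled
  midranks (so exact p-values exist under ties, e.g. identical multisets
  give $p = 1$); the normal mode uses the tie-corrected variance with an
  optional continuity correction. Two-sided p-values throughout, printed
  with the conventional `< 2.2e-16` floor while the raw value is retained.
* Kruskal–Wallis with every pooled value identical is defined as
  $H = 0$, $p = 1$.
* Nemenyi post-hoc p-values come from the studentized range with infinite
  degrees of freedom on tie-corrected mean-rank differences.
* Interface: this is an R analysis package; its surface is the exported
  functions plus `run_config()`/`run_screen()`, which validate a full run
  configuration, execute the pipeline, and write the screening tables with
  a JSON provenance record (config, seeds, version) sufficient to
  regenerate every output byte-for-byte. No shell executable is shipped;
  `scripts/acceptance.R` shows the Rscript pattern for batch use.

## Problem sizes used in the test suite

Simulation-based checks run at sizes chosen to keep Monte Carlo error
small relative to the asserted bands while remaining desk-scale: composite
type-I calibration uses 3000 replicates at $n = 1000$, $B = 199$ (the
operating level 0.005 makes smaller designs noise-dominated);
model-selection and power checks use 100 seeds; spike-in recovery uses 100
cohorts of 100 strains at 20,000 cells per histogram; Kruskal–Wallis
calibration uses three groups of 25 over 2000 replicates, where the
chi-square reference is in its asymptotic regime.

## Known limitations

* Composite-null p-values are bootstrap-granular (multiples of
  $1/(B+1)$); exact small-sample AD tables are out of scope.
* The asymptotic fixed-null p-value ignores finite-$n$ corrections below
  $n \approx 50$ (the automatic bootstrap fallback covers that range).
* Bin-center resampling understates within-bin variance slightly; jitter
  is the remedy where a continuous sample is required.
* Discrete distributions, censored/truncated likelihoods, Bayesian fits
  and explicit mixture modeling are out of scope; multimodality is
  *detected* (via goodness of fit), not modeled.
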