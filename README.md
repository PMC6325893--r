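# sizescreen

Cell-size distribution fitting and gamma-deviance screening for Coulter
histograms.

## The problem

Coulter-type channelyzers report the volumes of single cells (in
femtoliters) as counts per discrete size channel. In budding yeast the
resulting size distributions are strongly right-skewed and are well
described by a two-parameter gamma distribution,

    X ~ Gamma(shape = α, rate = β),   E[X] = α/β,

with wild-type fits around α ≈ 4–8 and β ≈ 0.04–0.09 fL⁻¹ depending on
ploidy and carbon source. That regularity turns the gamma family into a
*screening metric*: mutants whose size histograms cannot be fitted by a
gamma — left-skewed, multimodal, or otherwise deranged — can be ranked by
their departure from a reference gamma null, and the worst offenders are
strongly enriched for genes acting in transcription and other
gene-expression processes.

`sizescreen` implements that analysis as a tested, reusable pipeline for
anyone with binned size-frequency data (one histogram per strain):

* **histogram I/O** — read/write wide or long frequency tables, normalize,
  and resample per-cell values from channel histograms by seeded
  multinomial sampling (`resample_cells()`, default n = 1000 cells, with
  optional within-bin jitter and a deterministic rounding mode);
* **distribution fitting** — maximum-likelihood gamma, lognormal, Weibull
  and generalized-gamma fits with AIC/BIC model selection
  (`fit_gamma()`, `model_select()`); the gamma fit solves
  ln α − ψ(α) = ln x̄ − mean(ln x) by Newton iteration;
* **goodness of fit** — Shapiro–Wilk normality and lognormality screens,
  Anderson–Darling / Kolmogorov–Smirnov / Cramér–von Mises EDF statistics,
  a parametric-bootstrap-calibrated composite gamma test
  (`ad_test_fitted_gamma()`), and a fixed-null gamma test with classical
  asymptotic p-values (`ad_test_fixed()`);
* **cohort screening** — `screen_cohort()` runs the whole battery per
  strain, ranks strains by the fixed-null AD statistic
  (`rank_deviants()`), and annotates `lge`/`whi` size classes
  (`classify_size()`, 5% tails);
* **group statistics** — Wilcoxon rank-sum (exact tie-aware enumeration or
  normal approximation), Kruskal–Wallis, and Nemenyi post-hoc comparisons;
* **synthetic data** — `simulate_cohort()` builds channelyzer-style
  cohorts with known ground truth (wild-type gamma, size-shifted,
  left-skewed, multimodal and debris-spiked classes) so every stage is
  testable without any measured data.

The packaged reference table
(`system.file("extdata", "wildtype_fit_reference.tsv", package = "sizescreen")`)
ships the published per-sample fit statistics for 29 diploid (BY4743) and
2 haploid (BY4741) wild-type samples; averaging the two haploid gamma fits
with `reference_null()` yields the fixed screening null
gamma(3.8277, 0.078949).

## Worked example

Simulate a 20-strain cohort (18 wild-type-like strains at the haploid
reference parameters, 2 multimodal mutants), screen it against the fixed
reference null, and look at the worst fits:

```r
library(sizescreen)

spec <- synthetic_spec(
  classes = c(wildtype_gamma = 18, multimodal = 2),
  params = list(wildtype_gamma = list(shape = 3.8277, rate = 0.078949)),
  cells_per_strain = 20000, seed = 7)
sim <- simulate_cohort(spec)

cfg <- screen_config(seed = 42, B = 199,
                     null_shape = 3.8277, null_rate = 0.078949)
tab <- screen_cohort(sim$cohort, cfg)
head(tab[order(tab$deviant_rank), ], 4)
```

```
               strain gamma_shape gamma_ad gamma_ad_p fixed_null_ad fixed_null_p median_fl size_class deviant_rank
20     multimodal_002       4.490  36.4751      0.005      1336.212      0.00000     91.47        lge            1
19     multimodal_001       4.342  41.0620      0.005      1142.420      0.00000     90.51     normal            2
12 wildtype_gamma_012       3.845   0.8553      0.035         2.759      0.03633     44.39     normal            3
1  wildtype_gamma_001       3.769   0.8419      0.020         2.246      0.06753     44.39     normal            4
```

The two injected multimodal mutants are ranked worst by orders of
magnitude (fixed-null A² > 1100 versus < 3 for every null strain), their
composite-gamma bootstrap p-values sit at the attainable floor
1/(B+1) = 0.005, and they are also among the largest strains
(median ≈ 91 fL versus ≈ 44 fL).

Per-strain objects tell the same story:

```r
h   <- sim$cohort[[1]]                      # one wild-type-like histogram
smp <- resample_cells(h, n = 1000, seed = 11)
fit_gamma(smp)
#> <fit_result> gamma (n = 1000): shape = 3.782621, rate = 0.07457159 | loglik -4586.0361, BIC 9185.8878
ad_test_fitted_gamma(smp, B = 199, seed = 11)
#> <gof_result> AD = 0.347849 vs composite gamma null, p = 0.47 (bootstrap)
shapiro_wilk(smp)
#> <gof_result> SW = 0.943248 vs composite normal null, p = < 2.2e-16 (analytic)
```

A gamma-distributed sample of 1000 cells decisively fails the normality
test while comfortably passing the composite gamma test — the wild-type
signature the screen is built on.

`run_screen(run_config(...))` wraps the same pipeline for a cohort file on
disk and writes `screen.tsv`, `deviants.tsv` and a `provenance.json`
(config echo, seeds, package version) from which the run can be
regenerated exactly.

## Vignette

`vignettes/cell-size-distributions.Rmd` documents the model and its
assumptions, the calibration choices (bootstrap vs asymptotic p-values,
binning and tie effects, jitter), what the synthetic generator does and
does not emulate, and known limitations.
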