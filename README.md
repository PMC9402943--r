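# inflammclock

An R package implementing a transcriptomic **inflammatory aging clock
(iAge)** for glioblastoma-style tumor cohorts, together with the survival
and stemness analyses built around it and a synthetic-cohort generator
that makes every stage testable without access to the original tumor
databases.

## The science in brief

Chronic low-grade inflammation rises with age, and inflammation-related
gene (IRG) expression in tumors carries both an aging signal and
prognostic information. The clock works on a panel of ~200 IRG:

1. **Screen**: for each gene, the Spearman correlation
   β<sub>j</sub> = ρ(X<sub>j</sub>, age) with chronological age;
   a gene is selected when |β<sub>j</sub>| ≥ 0.5.
2. **Score**: iAge = C · Σ<sub>j</sub> β<sub>j</sub>X̃<sub>ij</sub> over the
   selected genes, with X̃ per-gene normalized expression and C an explicit
   calibration. The default fixes one cohort constant so that
   mean(iAge) = mean(age) exactly; iAge is then a positive affine map of
   the weighted score, so rankings are preserved.
3. **Subtype**: the cohort median of iAge splits patients into high- and
   low-iAge subtypes (ties go low), which are compared with Kaplan–Meier
   curves and the log-rank test; per-gene prognostic value is quantified
   by univariate Cox regression, and iAge is correlated with the four
   stem-cell indices (mRNAsi, EREG-mRNAsi, mDNAsi, EREG-mDNAsi).

The Kaplan–Meier estimator (with Greenwood variance), the two-group
log-rank test, and univariate Cox regression (Breslow ties,
Newton–Raphson) are implemented from first principles and validated in
the test suite against brute-force oracles and the `survival` package.
Fitted clocks serialize to JSON and replay on validation cohorts with
frozen weights and calibration. See the methods vignette
(`vignettes/inflammatory-aging-clock.Rmd`) for the model, its
assumptions, and every numerical choice.

## Worked example

```r
library(inflammclock)

co <- generateCohort(simConfig(seed = 1))   # 168 patients, 200-gene panel
co
#> InflammCohort: 200 genes x 168 samples
#>   age (years): 59.1 +/- 12.1
#>   events: 134/168 with known survival
#>   stemness indices: present
#>   synthetic truth: present

model <- fitIAgeClock(co)
model
#> IAgeModel: 38 of 200 genes selected (|beta| >= 0.5 )
#>   normalization: minmax01 | calibration: cohort_constant
#>   shift = 5.735, C = 10.58

iage <- scoreCohort(model, co)
head(iage, 3)
#>   sample_id   raw_score iage_years
#> 1     P0001 -1.83139575   41.28340
#> 2     P0002  0.01080791   60.76843
#> 3     P0003 -2.23737283   36.98937

sub <- classifyByMedian(iage)
table(sub$subtype)
#>  low_iage high_iage
#>        84        84

cl <- clinicalData(co)
lr <- logrankTest(cl$survival_time_days / 365.25, cl$event, sub$subtype)
c(chi_square = lr$chi_square, p = lr$p_value)
#> chi-square 16.45, p = 4.99e-05

correlateStemness(iage, co)[1:4, ]
#>   variable       index     rho  p_value n_complete
#> 1     iage      mrnasi -0.5337 9.36e-14        168
#> 2     iage ereg_mrnasi -0.0140 8.57e-01        168
#> 3     iage      mdnasi -0.4160 2.05e-08        168
#> 4     iage ereg_mdnasi -0.0849 2.74e-01        168
```

Reading: 38 of 200 genes pass the age screen; iAge tracks chronological
age (Spearman 0.97 on this synthetic cohort, where 38 genes are linked to
age by construction); the high-iAge subtype has significantly worse
overall survival (log-rank p ≈ 5×10⁻⁵); and iAge correlates negatively
with mRNAsi/mDNAsi while the EREG indices are null — the pattern the
generator encodes.

`runPipeline()` chains the whole analysis (simulate/load → filter → fit →
score → subtype → survival → associations → frozen-weight validation
replay), writes every intermediate as TSV/JSON and emits a run manifest;
it accepts a YAML config and a single seed from which all per-stage
seeds are derived.

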