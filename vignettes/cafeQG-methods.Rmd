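---
title: "Models and methods behind cafeQG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cafeQG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`cafeQG` analyses capillary-feeder (CAFE) assays of food intake measured
on panels of inbred lines: per-vial intake volumes for groups of
same-sex flies, replicated within each line and sex. This vignette lays
out the statistical models, the choices made where the design was
genuinely open, and what the synthetic panels used in testing do and do
not establish about real data.

## 1. Assay reduction

Each vial record carries the total volume drawn from three capillaries
over 24 h, the number of flies alive at the end of the assay, and a
batch identifier linking it to fly-free control vials kept in the same
humid chamber. Per-fly intake is

$$y = \frac{\text{total}_{\mu L} - \overline{\text{evap}}_{\text{batch}}}{\text{flies alive}}.$$

Two deliberate conventions:

* **Negative adjusted intakes are retained and flagged**, never floored
  at zero. Flooring would bias low-consumption lines upward; a vial
  whose reading falls below the evaporation estimate is informative
  about measurement spread. For the same reason `readAssayTable()`
  warns on (rather than rejects) negative raw totals: under the
  variance scale of these data, honest measurement error can cross
  zero for low-intake genotypes.
* **Vials with no surviving flies are quarantined with a warning**, not
  silently dropped, so a survivorship problem is visible to the analyst.

Line summaries use the sample SD (n − 1 denominator), matching the REML
framework downstream, and the coefficient of environmental variation
$CV_E = 100\,\sigma_E/\text{mean}$ in percent. Cells with fewer than 3
replicates (configurable) are flagged for exclusion from $CV_E$
analyses: a SD estimated from two vials is too noisy to support a
variance-GWAS trait, while the mean remains usable.

## 2. Variance components by REML

The pooled model is
$$Y_{lsr} = \mu + S_s + L_l + (SL)_{ls} + E_{lsr},$$
with sex fixed and line and sex-by-line random,
$L \sim N(0, \sigma^2_L)$, $SL \sim N(0, \sigma^2_{SL})$,
$E \sim N(0, \sigma^2_E)$; the per-sex reduced model drops the
interaction. Broad-sense heritabilities are
$H^2 = (\sigma^2_L + \sigma^2_{SL})/(\sigma^2_L + \sigma^2_{SL} +
\sigma^2_E)$ pooled and $\sigma^2_L/(\sigma^2_L + \sigma^2_E)$ per sex.

**Algorithm.** Because every random effect is constant within a
line-by-sex cell, the restricted likelihood factors exactly into a
within-cell part (depending only on $\sigma^2_E$) and a cell-mean part
whose covariance is block-diagonal over lines with blocks of size at
most two. The implementation maximizes this exact reduction with
analytic gradients (bounded quasi-Newton with `nlminb`, relative
tolerance 1e-14, followed by a Newton polish on interior coordinates).
This is why `fitTwoWayMixed()` on a 182-line panel takes well under a
second and matches the closed-form balanced ANOVA estimators to 1e-8 —
a tolerance an average-information iteration with numerical stopping
rules would not reliably reach. Components are constrained
non-negative; estimates on the boundary are reported with `NA` standard
errors. Standard errors elsewhere come from the observed information
(numerical Hessian of the analytic gradient). Degenerate inputs
(zero total variance) return all-zero components rather than iterating
on a flat objective.

**ANOVA table.** Type III mean squares come from `car::Anova` under sum
contrasts. F denominators for the pooled model follow the classical
unrestricted-mixed-model expectations: Sex and Line are tested against
the Sex-by-Line mean square, Sex-by-Line against Error. Legacy
statistical packages synthesize unbalanced-data denominators in ways
that are not exactly reproducible from a published table, so the
variance components — not the F statistics — are the quantities this
package treats as primary.

**Cross-sex genetic correlation.** The estimator is
$r_{GS} = \mathrm{cov}_{MF}/(\sigma_{LM}\,\sigma_{LF})$ with the
numerator the sample covariance of female and male line means (over
lines measured in both sexes) and the denominators the square roots of
the per-sex REML among-line components, each fit using all lines
measured in that sex. The phrase "among-line standard deviation" is
ambiguous between this convention and a plain Pearson correlation of
line means; both are computed and reported, the REML-denominator form
as primary. Because numerator and denominators come from different
estimators, the ratio can exceed 1 in finite samples; the raw value is
always reported alongside a clamped copy with a warning.

## 3. Micro-environmental variance

Heterogeneity of within-line variance across lines is tested by one-way
ANOVA of absolute deviations from the line center: the mean (Levene)
or the median (Brown-Forsythe; midpoint convention for even counts,
which is the default of R's `median` and the common choice when the
source does not specify). The statistic is computed directly from group
sums — O(N) per test, which is what makes the 500-panel calibration
checks cheap — and is verified in the tests against both a brute-force
`lm`-based ANOVA and `car::leveneTest`.

**A calibration warning that users of 6-replicate designs should know:**
with ~180 lines and only 6 vials per cell, the mean-centered Levene
test is strongly anticonservative (null rejection far above 5% at
$\alpha = 0.05$), while the midpoint-median Brown-Forsythe variant is
conservative. This is a property of the deviation-ANOVA procedures at
small group sizes — `car::leveneTest` reproduces it exactly — and the
package's property tests document it. Calibration of the implementation
is therefore demonstrated at 24 vials per line, where the mean-centered
test attains its nominal level; with 6-replicate data, Levene P-values
should be read as evidence ordering, not as calibrated error rates.

Pearson correlations (cross-sex $CV_E$, mean-vs-$CV_E$, and cross-trait
scans) use the t reference with n − 2 df and Fisher-z 95% limits
$\tanh(\mathrm{atanh}\,r \pm z_{0.975}/\sqrt{n-3})$, delegated to
`cor.test`; pairs with missing values are dropped and n is always
reported, since printed intervals in the literature often cannot be
inverted to a unique n. Cross-trait scans add a Benjamini-Hochberg
column but report unadjusted P as primary, mirroring the nominal
reporting convention of panel-wide trait correlation tables. Note one
structural fact the tests also document: if within-line SD does not
scale with the mean, $CV_E$ is mechanically anti-correlated with the
mean because the mean enters its denominator — a small negative
mean-$CV_E$ correlation is therefore expected even without any shared
genetic control.

## 4. Genome-wide association

Association runs at the line level on four codings per trait: female,
male, their average, and the female-minus-male difference (equivalent
to testing the sex-by-line interaction). The scan is two-step:

1. **Covariates.** A linear model of the line-level trait on Wolbachia
   infection and inversion karyotypes; marginal F tests per term;
   the adjusted trait is residuals plus grand mean. Constant covariates
   are dropped (identity adjustment in the limit), aliased covariates
   are an error naming the terms.
2. **Polygenic background.** A genomic relatedness matrix
   $G = X_c X_c^{\top}/(m\,\bar v)$ from mean-centered,
   mean-imputed genotypes; the null model
   $y = \mu + g + e$, $\mathrm{Var}(g) = \sigma^2_g G$, is fit once by
   REML on the eigenbasis of $G$; each variant is then tested by GLS
   under the fixed null covariance with a per-variant residual scale,
   giving exactly t-distributed statistics with n − 2 df when the
   covariance is proportional to the truth. With $G = I$ the scan
   reduces exactly to OLS, which the tests assert to 1e-10.

Genotypes are homozygous 0/2 codes (inbred lines); missing calls drop
the line for that variant only. The reported `effect` is the slope on
the 0/2 coding — the per-allele substitution effect; homozygous classes
differ by twice it. This convention matters when comparing scan effects
with validation contrasts and is stated on every output. Variants are
filtered at MAF ≥ 0.05 (inclusive boundary) and flagged at the nominal
$P < 10^{-5}$ reporting threshold and the Bonferroni level
$0.05/m$. Gene assignment uses 1-based inclusive arithmetic on GFF3
gene bodies extended by 1000 bp: a variant exactly 1000 bp beyond a
gene end is assigned, 1001 bp is not.

## 5. Validation statistics

* **Dunnett many-to-one tests** for knockdown-vs-control means. The
  correlation matrix of the comparison statistics always has the
  one-factor form $R = \mathrm{diag}(1-\lambda^2) + \lambda\lambda^{\top}$
  with $\lambda_i = \sqrt{n_i/(n_i + n_0)}$, so the two-sided family
  tail is an exact two-dimensional integral over the common factor and
  the pooled-SD scale. It is evaluated by deterministic Gauss-Hermite
  (48 nodes) by Gauss-Legendre (96 nodes) quadrature — accurate to
  about 1e-7 against high-precision `mvtnorm::pmvt` in the tests, fully
  reproducible without a Monte-Carlo seed, and fast enough for
  500-panel FWER calibration. The single-comparison case reduces
  analytically to the pooled two-sample t-test.
* **Pairwise Levene tests** for knockdown-vs-control variances: the
  k = 2 case of the deviation ANOVA.
* **SNP-cross t-tests.** In the validation cross design, F1 genotypes —
  not vials — are the randomized experimental unit, so class means are
  computed over genotype means and compared with a pooled-variance
  t-test per sex. A class with a single genotype falls back to
  vial-level units with a warning and a flag; vial-level units can also
  be requested explicitly, and the unit used is always recorded.
* **Effect attenuation.** `beavisComparison()` reports the ratio of a
  validation effect to a scan effect on the same contrast. Scan effects
  at loci selected for passing a threshold are upward-biased (the
  winner's curse / Beavis effect); the acceptance script demonstrates
  this by planting a weak variant and averaging its estimated effect
  conditional on detection.

## 6. The synthetic-data generator

The generator inverts the analysis model: line effects, sex-by-line
effects and vial noise are drawn exactly as the mixed model assumes,
vial totals are per-fly intake times flies per vial plus a batch
evaporation constant and vial-level noise, and genotypes are biallelic
homozygous codes with target MAFs realized exactly (the minor allele is
assigned to `round(maf * n_lines)` lines). Within-line SDs are drawn
log-normally per line and sex — the log scale guarantees positivity and
gives a natural meaning to "heritability of micro-environmental
variance" as the among-line share of log-SD variance; no published
distributional form exists for this quantity, so log-normal is a
modeling choice, not an inference. Random streams are split per
component (line effects, covariates, genotypes, noise, evaporation) so
that, for example, changing the variant count does not perturb
phenotypes — a property the regression tests rely on.

Default conditions (chosen once, as the study conditions): 182 lines,
2 sexes, 6 vials of 8 flies; variance components 8.21, 1.92, 12.66
µL²/fly²; sex effect 0.88 µL/fly (back-derived from the sex mean square
under balance); grand mean 12 µL/fly, which places $CV_E$ near 30%, a
realistic feeding-assay scale consistent with those variance
components; log-SD dispersion 0.2 with among-line share 0.3; Wolbachia
frequency 0.53 with a zero default effect; evaporation 1.5 ± 0.1 µL per
vial with a batch SD of 0.2.

**What passing tests do and do not show.** The generator draws Gaussian
effects, independent variants (no linkage disequilibrium), no
genotype-covariate correlation, and no vial-position or day effects
beyond the shared evaporation batch. Recovery and calibration results
on these panels certify the estimators under the model's own
assumptions; they do not certify robustness to skewed intake
distributions, LD between causal and tested variants, or block effects
confounded with lines — all of which real panels can contain.

## 7. Problem sizes and tolerances used in the checks

Monte-Carlo checks run at the sizes that make their arguments sharp at
desk scale: 200 panels for REML recovery (bias within 3 Monte-Carlo
SEs per component and for $H^2$), 500 panels for Levene type-I and for
Dunnett family-wise error (counts inside the exact binomial 95% band),
100 seeds for planted-variant power at $P < 10^{-5}$, a $10^6$-draw
Monte-Carlo oracle for the Dunnett k = 2 tail, and pooled
Kolmogorov-Smirnov uniformity for null scan P-values. Deterministic
oracle equivalences use tolerance 1e-8 (balanced REML vs closed form)
or 1e-10 (deviation ANOVA vs brute force; identity-GRM scan vs OLS).
Convergence tolerances: REML relative parameter change 1e-14 with
gradient-norm stopping at 1e-10; association null REML optimized on
$\log \delta \in [-12, 12]$.

## 8. Known limitations

* The per-sex and pooled models assume a common error variance across
  cells; under heritable $CV_E$ the reported $\sigma^2_E$ estimates the
  panel-average within-line variance.
* $CV_E$ is undefined for non-positive line means; such cells are
  excluded with reasons rather than imputed.
* No double generalized linear models or DHGLM variance-effect
  estimation: the $CV_E$ summary-statistic route only.
* No LD-aware fine-mapping, LOCO scheme, permutation thresholds, or
  epistasis; association is strictly single-variant.
* Dunnett quadrature assumes the one-factor many-to-one structure; it
  is not a general multivariate-t integrator.
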