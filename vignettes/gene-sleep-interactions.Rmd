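---
title: "Genome-wide gene-by-sleep-duration interaction analysis for blood pressure: methods"
author: "gxesleep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome-wide gene-by-sleep-duration interaction analysis for blood pressure: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

Both habitually short and habitually long sleep are associated with elevated
blood pressure (BP), and the effect of a genetic variant on BP may differ
between short, normal and long sleepers. Detecting such gene-environment
(G×E) interactions genome-wide requires very large samples, harmonized
phenotypes across dozens of cohorts, per-cohort regression scans with
heteroskedasticity-robust inference, multi-level meta-analysis, and careful
multiple-testing control. `gxesleep` implements that full chain as a tested
pipeline, together with a synthetic multi-population cohort generator so
that every stage can be exercised, end to end, with known ground truth and
no access to individual-level consortium data.

# Models and tests

For each variant with dosage $G \in [0,2]$, exposure indicator
$E \in \{0,1\}$ (short or long total sleep time), BP trait $Y$ (SBP, DBP or
PP, in mmHg) and covariate sets $C_1$, $C_2$, two linear models are fitted
by OLS:

$$\text{M1:}\quad Y = \beta_0 + \beta_E E + \beta_G G + \beta_{G \times E}\, E \cdot G + \boldsymbol\beta_{C_1}' C_1$$

$$\text{M2:}\quad Y = \beta_0 + \beta_G^{(m)} G + \boldsymbol\beta_{C_2}' C_2$$

$C_1$ contains age, age², sex, the exposure main effect and its age, age²
and sex interactions, principal components, and study-centre dummies; $C_2$
is the subset without any exposure-bearing column. Sex and sex×E columns are
dropped in sex-stratified runs.

All inference uses the heteroskedasticity-consistent sandwich covariance
$(X'X)^{-1} X' \mathrm{diag}(r^2) X (X'X)^{-1}$ (HC0 by default; HC1 and
HC3 selectable). Four tests are reported per variant:

* 1 df Wald tests of the marginal effect ($\beta_G^{(m)}$ from M2), main
  effect ($\beta_G$ from M1) and interaction effect
  ($\beta_{G\times E}$ from M1);
* the 2 df joint test $\chi^2 = \boldsymbol\beta' V^{-1} \boldsymbol\beta$
  of $(\beta_G, \beta_{G\times E})$ with their robust 2×2 covariance,
  including the off-diagonal term.

P-values are computed in log space so that tests with $|z| > 38$ (which
underflow double precision) remain representable and comparable.

The choice of the robust (rather than model-based) SE for every 1 df test
was open; we use the robust SE uniformly, since it is the quantity the
sandwich covariance makes available and mixing estimators across tests
would make the 1 df and 2 df results incoherent.

# Harmonization protocol

Per cohort, in order:

1. repeated within-visit BP readings are averaged;
2. medicated samples receive +15 mmHg (SBP) and +10 mmHg (DBP);
3. PP = SBP − DBP is derived from the *adjusted* values, which makes the
   medication shift of PP exactly +5 mmHg — a property the tests check;
4. samples are restricted to age ≥ 18 years and total sleep time (TST)
   within [3, 14] hours (inclusive), and any sample missing an analysis
   field is excluded (complete-case rule);
5. each trait is winsorized at 6 SD from its mean, in a single pass (the
   mean and SD are computed once on the analysis sample, before clamping);
6. exposures are derived by regressing TST on age, sex and age×sex and
   dichotomizing the residuals at their 20th/80th percentiles:
   STST = 1 iff residual ≤ 20th percentile, LTST = 1 iff residual ≥ 80th.
   Ties at a cutoff are exposed, matching the inequality directions of the
   protocol. Quantiles use the standard interpolated empirical estimator.

Two ordering questions were genuinely open and are fixed here as design
choices: medication adjustment precedes winsorization (trait construction
is completed before outlier control, and the +5 PP invariant requires PP to
be formed from adjusted values), and the exposures are derived once on the
combined filtered sample and reused in sex-stratified runs (the residual
model includes sex, implying a single pooled derivation). Principal
components and centre dummies are included in both $C_1$ and $C_2$; the
reduced set is reduced only with respect to exposure terms. Sex is coded
0 = male, 1 = female.

# Variant-level filters

A variant enters a given analysis stratum only if: minor allele frequency
≥ 0.1%; imputation quality R² ≥ 0.3; and MAC×R² ≥ 20 within each of the
exposed, unexposed and total samples, where MAC = min(Σg, 2n − Σg) on
dosages. Duplicated chrom:pos:allele records, monomorphic variants and
non-autosomal records are discarded. Dosages are used as-is (no rounding to
hard calls), the imputed-data convention.

# Meta-analysis

Cohort tables are first expressed on a common effect allele (swapped-allele
records have betas negated and frequencies complemented; strand-ambiguous
A/T and C/G variants are flagged). Within each population group, each 1 df
effect family is pooled by fixed-effects inverse-variance weighting, and
the (main, interaction) vector by its 2 df generalization
$V_\text{meta} = (\sum_i V_i^{-1})^{-1}$,
$\boldsymbol\beta_\text{meta} = V_\text{meta} \sum_i V_i^{-1} \boldsymbol\beta_i$.
Genomic-control lambdas are computed from the pooled statistics — one per
effect family, since the four tests have different nulls — as the observed
median statistic over the theoretical χ² median (0.455 for 1 df, 1.386 for
2 df), and applied only when λ > 1: 1 df SEs are inflated by √λ, the 2 df
statistic is divided by λ (equivalently its pooled covariance is inflated),
and p-values are recomputed. The cross-population meta-analysis treats each
group-level estimate as one input to the same machinery and applies a
second GC pass; the lambdas used at each level are recorded in the output.
Fewer than 100 variants yield λ = 1 with a warning rather than a noisy
median estimate. No random-effects or heterogeneity model is fitted, and
variants present in any number of cohorts are pooled — eligibility rules
are applied downstream, at discovery.

# Locus discovery and prioritization

A meta-analysis is eligible for discovery only with pooled N strictly above
20,000 or at least 3 contributing cohorts. Variants within 1 Mb of the MHC
(chr6:28,510,120–33,480,577 on GRCh38 — the region is named by convention;
these are the GRCh38 coordinates) are masked. Three routes define
significant variants:

* **1 df route**: interaction p < 5×10⁻⁹ and BH FDR < 0.05, the FDR
  computed over all variants of the analysis;
* **2 df route**: joint p < 5×10⁻⁹ and FDR < 0.05, independent of the 1 df
  selection;
* **two-step route**: screen on the marginal effect (p < 10⁻⁵, giving $z$
  variants), then test the interaction at 0.05/$N_G$ with FDR < 0.05
  computed within the screened set. $N_G$ is the effective number of
  independent tests: the smallest number of principal components of the
  screened variants' dosage correlation matrix explaining 99.5% of the
  variance (the established simpleM default; the exact criterion was not
  prescribed, so this is a documented choice).

Significant variants are clumped greedily: the most significant unassigned
variant leads a locus and captures every significant variant within
±500 kb on its chromosome; loci whose leads are in LD (r² ≥ 0.1, computed
on the simulated or user-supplied genotype matrix, which stands in for an
external LD reference panel) are merged into the stronger locus. "500 kb
regions" is interpreted as a ±500 kb radius around the lead — the radius
reading matches the sparsity of reported loci — and is configurable. Ties
on p are broken by larger |beta|, then position, making clumping invariant
to input row order.

Lead loci are then classified: 1 df / two-step loci are prioritized
(class X) when farther than 1 Mb from known gene-sleep interaction loci;
2 df loci enter prioritization only when their marginal effect is
insignificant (p > 5×10⁻⁹ and FDR > 0.05) and they are over 1 Mb from known
BP loci, and are labelled interaction-driven (class Y) when the interaction
p is smaller than the main-effect p, otherwise supported (class Z). Without
a known-locus table novelty is reported as unknown, never claimed. Sex
heterogeneity of prioritized leads is tested by the two-sample Z-test
$(\beta_F - \beta_M)/\sqrt{se_F^2 + se_M^2}$ with Bonferroni threshold
0.05/Q over the Q loci tested in both sexes.

# The synthetic-cohort generator

The generator is first-class, tested code: it defines the study conditions
under which every downstream claim is verified.

* **Genotypes.** Ancestral effect-allele frequencies are drawn log-uniformly
  over a configurable range (default 0.001–0.5, so the rare 0.1–2% end is
  represented); each population group's frequency is a Balding–Nichols
  Beta$(p(1-F)/F, (1-p)(1-F)/F)$ draw around the ancestral value, giving
  one-parameter control of cross-population divergence (default F = 0.05).
  Genotypes are Hardy–Weinberg Binomial(2, af) draws expressed as dosages.
  Imputation R² is drawn Uniform(0.3, 1) per variant and feeds only the
  filter arithmetic — it never perturbs dosages, because the filters are
  its only consumer. Planted variants' frequencies and R² can be pinned.
* **Exposure.** TST ~ Normal(7.5 − 0.01·(age − 50) + 0.2·sex, 1.2) hours,
  truncated to [2, 15] — deliberately wider than the [3, 14] analysis
  window so the harmonization filter is exercised. The generative exposure
  indicator is produced by the same residual-percentile code harmonization
  later re-runs, so planted interaction effects refer to exactly the
  exposure the analysis sees (20% prevalence by construction).
* **Phenotypes.** SBP/DBP are built from age, sex, centre and PC effects
  plus planted per-variant contributions $\beta_\text{main} G +
  \beta_{G\times E} G E$ and Gaussian noise with SD 8 mmHg. The noise SD is
  a residual (post-covariate) spread chosen so that the planted-effect
  recovery experiments the suite runs (−5 mmHg per allele at MAF 2% in
  20,000 samples) sit in the well-powered regime a discovery consortium
  operates in; it was fixed once by an a-priori power calculation. Planted
  PP effects are added through SBP so PP = SBP − DBP inherits them. Two
  raw readings per visit carry independent 2 mmHg measurement noise.
  Medicated samples (Bernoulli, default prevalence 15%) have raw readings
  lowered by exactly 15/10 mmHg — the amounts the harmonization adjustment
  adds back, emulating that adjustment's rationale.
* The linear planted-effect model is an assumption of this artifact: no
  claim is made that real cohorts' exposure effects are generated this way.

What the generator does *not* emulate — and what passing tests therefore do
not establish about real data: relatedness/kinship structure (cohorts with
known relatedness would supply null-model residuals as the trait, which
this package accepts as a pre-computed column but never computes), X
chromosome variants, genotype missingness and hard calls, realistic LD
(variants are independent unless constructed otherwise, so the LD pruning
and $N_G$ machinery is exercised with synthetic block structure),
fine-grained admixture, and real sleep-measurement error structure.

# Numerical choices and degenerate inputs

* OLS solves via the Cholesky factor of $X'X$; rank deficiency is an error
  naming the collinear columns, never a silent drop.
* An analysis stratum with a constant exposure (e.g. E ≡ 0) is refused:
  M1 must not silently degrade into M2.
* A variant with constant dosage, or with no exposed carriers (E·G ≡ 0),
  is skipped for that stratum and logged.
* Constant vectors are a warning no-op in winsorization and r² = 0 with a
  warning in LD.
* λ < 1 never deflates; λ from fewer than 100 statistics is fixed at 1.
* All row orders are deterministic (chromosome, position, alleles) and all
  randomness flows from a single integer seed per cohort, derived from the
  run's master seed; a stored configuration reproduces a run exactly.

# Problem sizes used by the test suite

The suite verifies the pipeline's statistical claims at sizes chosen to
make the relevant asymptotics visible while staying desk-scale: null
calibration on 2,000 variants in a 2,000-sample cohort (type-I error of
the interaction test, mean of the 2 df statistic, and all four GC lambdas);
95% CI coverage of a planted −5 mmHg × STST effect at MAF 10% over 100
replicates of n = 10,000; and full-route locus recovery (scan → meta →
discovery) of a planted MAF-2% interaction in 20,000 samples split over
three cohorts, 100 replicates. The bundled demo analysis under `analysis/`
uses three cohorts of 2,000 samples over a 500-variant panel.

# Known limitations

Beyond the generator's idealizations listed above: only dichotomous
exposures and quantitative traits are supported (no binary outcomes, no
continuous-exposure interactions); fixed-effects meta only; no
sample-overlap correction; no liftover (coordinates are hg38 throughout);
and all functional annotation of discovered loci is out of scope. The
multiple GC passes (population level, then cross-population) compound; the
λ applied at each level is reported so users can audit the total
correction.
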