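---
title: "Methods: recall-by-genotype untargeted metabolomics with metaboRBG"
author: "metaboRBG"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Methods: recall-by-genotype untargeted metabolomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The study design and the statistical problem

A recall-by-genotype (RBG) study selects stored biobank samples by genotype
rather than phenotype: carriers of a rare functional variant (here, a
loss-of-function *APOC3* variant as a genetic proxy for apoC-III-lowering
therapy) are each matched to two non-carrier controls of the same cohort and
sex, with age matched within the same clinic visit. Plasma samples are
profiled by untargeted UHPLC-MS in four acquisition datasets (HILIC and
lipids chromatography, each in positive and negative ionisation), yielding
thousands of (m/z, retention-time) *features* with positive peak areas and
frequent non-detection. The scientific question is which features — and
after annotation, which metabolites and lipid classes — differ between
carriers and non-carriers.

`metaboRBG` implements the full analysis as a deterministic pipeline over a
`MetaboExperiment` (a `SummarizedExperiment` holding the peak-area matrix,
feature metadata and the sample design), together with a seeded synthetic
study generator that carries ground truth for validation.

# Quality control and filtering

Filters run in a fixed order, each appending to a per-stage log (ids, reason
codes, in/removed/out counts; conservation `in = removed + out` is asserted
by the test suite):

1. **Pooled-QC feature filter.** A pooled QC sample (mixture of all study
   samples) is injected repeatedly. Features with relative standard
   deviation RSD = 100·sd/mean > 30% or detection rate < 70% across QC
   injections are removed. RSD is computed on the *raw* peak areas with the
   n−1 standard deviation — the convention of the pooled-QC literature; a
   feature with fewer than two present QC values has undefined RSD and is
   caught by the detection rule.
2. **Sample filter.** Within each acquisition dataset, study samples (never
   QC injections) with > 50% missing features or a total peak area (TPA)
   above mean + 3 SD are excluded. Both rules are evaluated on the same
   input rather than sequentially, so the outcome does not depend on rule
   order. Because the four acquisitions are physically distinct injections
   with distinct intensity scales, the thresholds are computed per dataset;
   a sample failing in any dataset is dropped entirely — with one feature
   table spanning all four acquisitions, partially-present samples would
   complicate every downstream contract for negligible gain.
3. **Class-missingness filter.** Features missing in > 30% of carriers *and*
   > 30% of non-carriers are removed. Features heavily missing in only one
   class are deliberately retained: one-sided missingness is exactly the
   signal the presence/absence track tests. (The converse risk — that the
   both-classes rule could remove a strongly differentially missing feature
   whose minor class also exceeds 30% — is real; `runMissingnessScan()` can
   be pointed at the pre-filter table if that matters for a given study.)

# Normalization and transformation

**Probabilistic quotient normalization (PQN).** Under the multiplicative
dilution model \(v_{fi} = d_i p_f \varepsilon_{fi}\), the per-sample
dilution \(d_i\) is estimated as the median of the ratios
\(v_{fi}/\mathrm{ref}_f\) and divided out. The reference spectrum is the
feature-wise median over *study samples* (configurable to the pooled-QC
median): with a handful of QC injections the study-sample median is the more
robust estimate, and it keeps the reference on the same dilution scale as
the samples it normalizes. No total-area pre-normalization is applied first:
TPA has already been used for sample exclusion, and under the multiplicative
model PQN alone identifies the quotients.

**Rank inverse-normal transform (INT).** Each feature's present values are
mapped to \(\Phi^{-1}((r - 0.5)/n)\) with average ranks for ties, forcing an
approximately standard-normal marginal whatever the input distribution.
Ranks are computed over **study samples only**: pooled-QC injections
approximate the mean profile, and letting them occupy mid-distribution ranks
measurably inflates the study samples' quantiles (we observed a ~4% upward
bias in recovered effects before excluding them). The 0.5/n offset and
average-tie rule keep the transform deterministic.

**Left-censored imputation** (`half_min` by default: half the feature's
minimum present value) exists only for the second sensitivity analysis; the
primary analysis never imputes, leaving real missingness to the
presence/absence track.

# The two association tracks

**Abundance track.** For each feature, transformed abundance is modelled on
carrier status (coded 0/1; at a minor-allele frequency of ~0.25% there are
no rare homozygotes, so the carrier contrast is the per-allele effect) with
age and sex as fixed covariates, in three datasets: combined, mothers only,
young participants only. Sex is dropped automatically where constant
(mothers). When any subject contributes repeated samples in a dataset, a
linear mixed model with a per-subject random intercept is fitted by maximum
likelihood (`lme4`); the combined dataset additionally carries a
family-level intercept, since mother–offspring pairs can only co-occur
there. Otherwise the model is OLS; a vectorized OLS path (grouping features
by missingness pattern) is used in the scan and is tested to equal the
per-feature fit to 1e−10. P-values are two-sided Wald tests on the genotype
coefficient (t for OLS, normal for ML mixed fits); non-convergence is
reported via a flag, never by dropping the feature. Within each dataset, BH
adjustment is applied across all tested features with the four acquisitions
pooled — one FDR decision per analysis. A feature is *associated* when
q < 0.05 in at least one of the three analyses. Fold changes
(carrier mean / non-carrier mean) are computed on normalized,
*untransformed* data; variance explained per fixed effect is the incremental
R² when added last to a simple OLS over all samples (repeats treated as
independent, matching how such surveys are usually reported). Clinical
lipid measures (HDL/LDL/TAG) go through the same models untransformed. In
the primary mode only fasting samples are analysed; the two sensitivity
modes retain non-fasting samples or analyse the imputed table.

**Missingness track.** Features below the limit of detection in one
genotype class produce missing-not-at-random patterns invisible to the
abundance models. For every retained feature, a 2×2 table of
missing/present by genotype over the combined dataset is tested by Fisher's
exact test; the two-sided p-value uses the point-probability construction
(sum of hypergeometric probabilities not exceeding the observed table's,
within a 1e−7 relative tolerance — the conventional definition, matching
`stats::fisher.test`, which serves as an independent cross-check in the test
suite). A zero margin returns p = 1 with a degeneracy flag. BH is applied
across tested features; the discovered set is reported with its overlap
against the abundance-associated set by inclusion–exclusion.

# Post-processing

Annotation deduplication collapses, within each dataset, features sharing a
metabolite label to the member with the smallest p-value (exact ties broken
by the smaller feature id for run-to-run stability); unannotated features
pass through as features. Class summaries tabulate deduplicated metabolites
by lipid class with column percentages and direction-of-effect tallies. The
heatmap view residualizes transformed values on age and sex (genotype
excluded, so genotype structure survives), drops incomplete rows
(complete-case default; the imputed view is available), and orders both axes
by Ward's minimum-variance clustering on Euclidean distances — the metric
under which Ward's criterion is defined; `hclust(method = "ward.D2")`
implements it and is checked against a from-definition agglomerator in the
tests. An optional second rendering excludes the on-target TAG class, which
sharpens carrier/control separation when the primary-target signal
dominates. The cohort table reports group means/SDs with two-sided Wilcoxon
rank-sum tests — exact when both groups have ≤ 20 observations without
ties, normal approximation with continuity correction otherwise — starred
as `***`/`**`/`*` at 0.001/0.01/0.05.

# The synthetic study generator

`simulateStudy()` emulates the design the analysis assumes:

\[
\log v_{fi} = b_f + \delta_f\,\sigma_b\,g_i + u_{f,s(i)} + \epsilon_{fi}
  + \log d_i
\]

with feature baselines \(b_f \sim N(\log 10^5, 1)\) (log-normal abundances:
the distribution is a modelling choice matching positive, right-skewed peak
areas), class-structured standardized effects \(\delta_f\), a subject random
intercept and residual jointly of SD `biolSD` (split 1:3 in variance), and
log-normal per-sample dilution of SD `dilutionSD`. Controls are generated
two per carrier, matched on cohort and sex with age within ±1 year (clinics
are age-banded, so within-visit matching is a ±1 y band). A configurable
fraction of carriers contributes a repeat sample; a configurable fraction of
young carriers shares a family id with a carrier mother, exercising the
pedigree term. Pooled-QC injections are the pooled mean profile with
multiplicative noise of CV `techRSD`%. A subset of annotated metabolites
yields 2–3 redundant features (parent value times independent technical
noise, sharing the label). Censoring removes all values below the
`lodQuantile` quantile of the pooled study-sample distribution — this single
mechanism is what turns negative genotype effects into carrier-biased
missingness. A synthetic clinical-lipids table (HDL/LDL/TAG, with carrier
effects in the directions expected for an APOC3 loss-of-function allele) is
returned alongside. Identical configurations and seeds give byte-identical
output.

Default condition choices: 26 carriers (11 mothers), 1:2 matching, repeat
probability 0.4, ~200 parent features across seven classes with effects of
±0.5–1 SD in the lipid classes and zero in the unassigned class, 10%
LOD censoring, 8 QC injections, technical CV 10%, biological SD 0.5 (log
scale), dilution SD 0.2. Effect sizes are chosen for testability — large
enough that a ~100-sample study has power — not to mimic any reported
per-metabolite distribution, which the motivating design does not publish.

What the generator does *not* emulate: retention-time drift, correlated
feature blocks beyond duplicate groups, adduct mass arithmetic, batch
effects, or non-multiplicative matrix effects. Passing tests therefore
demonstrate correctness of the statistical machinery under the stated model,
not robustness to every artefact of real acquisitions.

# Calibration experiments and their design

The test suite validates the pipeline against ground truth at fixed problem
sizes, chosen once:

* **Null FDR** (both tracks): 2000-feature, 60-subject studies over 50
  seeds, with no repeated measures or family links so the OLS scan carries
  the calibration (the mixed path has its own OLS-equivalence test); the
  realized false-discovery proportion among q < 0.05 calls must stay within
  0.05 + 3 Monte-Carlo SEs.
* **Effect recovery**: standardized effects {0.5, 1.0, 1.5} at 60 subjects,
  25 seeds, with 10 affected features among 2000. The benchmark
  ("transform-consistent truth") is a finite-n Monte-Carlo oracle: the
  expected INT group contrast of an iid two-group normal mixture at the
  analysis sample sizes. The affected fraction is kept sparse (~0.5%)
  because of a genuine limitation documented below; detection counts must
  increase strictly across the grid.
* **PQN dilution recovery**: dilution SD 0.3, no effects, 1000-feature
  panel (a realistic single-acquisition size; the median quotient's
  precision scales as \(1.25\,\sigma_b/\sqrt{n_\mathrm{features}}\), so tiny
  panels cannot reach the r ≥ 0.99 bar that full-scale panels do).
* **MNAR detection**: −2 SD effects with 20% LOD censoring over 20 seeds;
  the Fisher scan's discoveries must be enriched for truly affected
  features (odds ratio > 1, Haldane-corrected) in ≥ 18 of 20 seeds.
* **Exact oracles**: BH, Fisher, OLS and Ward linkage against
  brute-force/from-definition implementations on ≥ 100 random instances
  each; filter bookkeeping against a 12-feature/25-sample hand fixture; and
  byte-identical end-to-end reruns under a fixed seed.

# Numerical and degenerate-input choices

* LOD quantile uses R's default (type 7) sample quantile; `lodQuantile = 0`
  is the identity and values exactly at the threshold survive (`< lod` is
  censored).
* INT requires ≥ 3 present values; an all-tied feature is an error unless
  the caller opts into an all-zero transform (the pipeline's matrix wrapper
  does, flagging the feature as degenerate).
* A sample sharing no present feature with the PQN reference is an error
  naming the sample; a single-sample acquisition has undefined TPA SD and
  applies no TPA cut.
* OLS with fewer observations than parameters, or a rank-deficient design,
  yields a flagged non-converged record, never a silent drop; the same
  applies to `lmer` non-convergence (any optimizer warning clears the
  `converged` flag but the estimate is retained).
* Fisher tables with a zero margin return p = 1 (uninformative) with a
  degeneracy attribute.

# Known limitations

* **PQN compositional coupling.** When a substantial fraction of features
  carries a same-signed genotype effect, the median quotient partially
  absorbs it, attenuating recovered effects (≈ 15–19% at a 20% affected
  fraction in our measurements) and inducing small opposite-signed apparent
  effects in null features. This is a property of quotient normalization
  itself, not of this implementation; it is why the recovery calibration
  uses a sparse-signal design, and it should temper interpretation of
  small effects in studies where one class of lipids dominates the
  signal.
* The union-over-three-datasets association rule controls FDR within each
  analysis but not over the union; under the global null the union's
  realized FDP stays near per-analysis levels because the datasets overlap,
  and the calibration test bounds it empirically.
* Mixed-model p-values are Wald-normal on ML fits; at very small cluster
  counts these are anti-conservative relative to likelihood-ratio or
  Satterthwaite approaches.
* The RSD filter assumes the pooled-QC injections bracket the study run;
  drift correction (e.g. QC-spline signal correction) is out of scope.
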