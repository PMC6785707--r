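---
title: "Gene-set polygenic scores over an omnigenic background: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-set polygenic scores over an omnigenic background: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The question the pipeline answers

Under a highly polygenic — possibly *omnigenic* — architecture, essentially
every gene expressed in trait-relevant tissue contributes something to
heritability. A polygenic risk score (PRS) restricted to *any* SNP set will
then explain a nonzero share of case-control variance: a **floor effect**.
The interesting question about a candidate gene set is therefore not "does
its PRS associate with the phenotype?" but "does it explain **more** than an
arbitrary set of the same size would?". `omniprs` implements the full
machinery to pose that question on multi-cohort case-control panels:

1. a **leave-one-out (LOO)** loop over cohorts: a pooled training GWAS on
   all-but-one study, risk-allele orientation, LD pruning, restriction of the
   score to a SNP set, selection of a p-value inclusion threshold *inside the
   training data*, and a single nested logistic evaluation on the held-out
   cohort;
2. **Stouffer's Z** sample-size-weighted meta-analysis of the held-out
   results, with median / IQR / range summaries of the nested Nagelkerke
   $R^2$;
3. an **experiment-wise permutation null** (phenotypes shuffled within
   study, the entire pipeline re-run);
4. a **floor estimate** from random genic and non-genic SNP sets of matched
   size, drawn from LD-pruned pools.

Because real consortium genotypes cannot ship with a package, the first-class
`syndata` module simulates panels with the statistical structure the analysis
assumes, and every downstream claim is tested against those simulations.

# The generative model

## Liability threshold with an omnigenic background

Each SNP $j$ receives an ancestral frequency $p_j \sim U(\text{maf range})$
and a liability-scale effect $\beta_j$ drawn zero-mean Gaussian — every SNP
has an effect (the omnigenic background). SNPs mapped to a designated *core*
gene set have their effect-size variance multiplied by `core_enrichment`
before a global rescaling enforces

$$\sum_j 2 p_j (1-p_j)\, \beta_j^2 \;=\; h^2_{\text{liability}}$$

exactly (to 1e-12; a `[0,1)` bound on $h^2$ is enforced). With the default
global rescaling, the ratio of core to non-core effect-size variances equals
`core_enrichment` by construction. Setting `prop_causal_genic` switches to an
explicit split of $h^2$ between genic and non-genic SNPs (value 1 places all
liability variance in genic SNPs — the configuration used for the
genic-versus-non-genic floor contrast); with an explicit split *and*
enrichment, the enrichment is relative to the non-core *genic* SNPs only.

The Gaussian shape of the effect-size distribution is a modelling choice —
field practice offers no canonical alternative at this scale, and a
heavier-tailed background would only sharpen the core-set contrasts the tests
check.

## Cohorts

Study allele frequencies drift around the ancestral values via a
Balding–Nichols Beta distribution with Wright's $F$ = `study_drift_f`;
genotypes are Hardy–Weinberg draws at the study frequencies. Liability is
the centred genetic score standardized to variance $h^2$ plus
$N(0, 1-h^2)$ noise; a sample is a case when liability exceeds
$\Phi^{-1}(1-\text{prevalence})$. Cases and controls are *ascertained*:
batches are rejection-sampled until the exact configured counts are reached
(a capped loop; the cap is named in the error when prevalence makes a
stratum unreachable). Genotype missingness is applied uniformly, and
`n_covariates` study-correlated Gaussian columns stand in for principal
components — they exercise the covariate-adjustment contract without
implementing PCA.

All randomness flows from one root seed through `derive_seed(seed, tag,
index)` (a 31-bit multiplicative string hash), so any stage can be re-run in
isolation and the whole bundle is bit-reproducible, including at the
serialized level.

## Default study conditions

Chosen once to emulate a multi-cohort case-control consortium at desk scale:

| parameter | default | rationale |
|---|---|---|
| studies | 6, unequal (400…200 samples) | cross-cohort structure without cluster-scale cost |
| SNPs / genes | 2000 / 300 on 10 Mb | keeps both genic (~50%) and non-genic SNPs plentiful |
| $h^2$ liability | 0.3 | typical common-variant heritability for a psychiatric trait |
| prevalence | 0.10 | liability threshold \(\approx 1.28\); keeps ascertainment tractable |
| MAF range | 0.05–0.5 | common variants, the PRS regime |
| drift $F$ | 0.02 | mild between-cohort stratification |
| missing rate | 0.01 | post-QC-like missingness |
| core set | 50 genes | a "pathway-sized" candidate set |
| genic margins | 5 kb upstream, 1 kb downstream | the conventional genic definition |

The permutation-calibration analysis runs on a smaller panel (60–100 cases,
80–120 controls per study): a null-calibration check needs no power, and the
100 re-runs of the full pipeline dominate its cost. The replicate analyses
(core-set recovery, floor direction) use 10 replicate panels, 20 comparison
sets for recovery and 10 random sets per pool for the floor — the floor
module itself defaults to the conventional 50 sets per pool.

# The analysis pipeline

## Training side

The training GWAS is one pooled ("mega") logistic regression per SNP —
phenotype on additive dosage plus covariates plus 0/1 study indicators —
fitted by IRLS in compiled code, with Wald two-sided p-values; samples
missing a dosage are dropped for that SNP only, and monomorphic SNPs are
flagged with $\ln\text{OR}=0,\ p=1$. A per-study meta-analysis would be the
main alternative; the pooled form with indicators is the closer analogue of
a consortium mega-analysis and needs no per-study convergence bookkeeping.

All statistics are then **risk-oriented**: when $\ln\text{OR}<0$ the effect
and other alleles are swapped and the sign flipped, so every weight is
non-negative and training and test cohorts agree on the risk allele
(idempotent; ties keep A1).

**LD pruning** follows the indep-pairwise convention: a 50-SNP window
sliding by 5, removing — deterministically, the later-positioned SNP of the
first offending pair in genomic order — until no retained pair within a
window exceeds $r^2 = 0.25$ (0.01 for the random-set pools). $r^2$ is the
squared Pearson correlation of dosages over pairwise-complete samples;
monomorphic SNPs have $r^2 \equiv 0$. Pruning runs on the pooled training
genotypes of the current LOO iteration: the discovery set *is* the training
data, and a config switch (`prune = NULL`) provides the unpruned
genome-wide mode. Because windows overlap, pairs wholly contained in the
previous window are already resolved and are skipped — an exact
optimization, asserted equal to a brute-force rescan oracle in the tests.

## Scores and threshold selection

A score at cutoff $t$ sums $\ln\text{OR}_j \times$ (risk-allele dosage) over
the set's SNPs with training $p_j < t$ (strict); missing genotypes
contribute zero and decrement a per-sample valid-genotype count, which is
carried as a covariate — the reason the score is a *sum*, not a mean. Nine
cutoffs (0.0001…0.5) are evaluated **on training data only**: covariates +
valid count + score against covariates + valid count, and the cutoff with
the largest likelihood-ratio $\chi^2$ wins (ties to the smallest cutoff;
all-degenerate grids are a named error). Exactly one score is ever evaluated
per held-out study, so held-out p-values need no multiplicity correction.

## Held-out evaluation and meta-analysis

On the held-out cohort the selected score enters a nested logistic
comparison (LRT, 1 df). Explained variance is the **nested Nagelkerke
$R^2$**: with $\ell_0$ the intercept-only, $\ell_b$ the covariates-only and
$\ell_f$ the covariates+score log-likelihoods on the same samples,

$$R^2_{\text{nested}} = R^2_N(\ell_f, \ell_0) - R^2_N(\ell_b, \ell_0),
\qquad R^2_N(\ell, \ell_0) = \frac{1 - e^{2(\ell_0-\ell)/n}}{1 - e^{2\ell_0/n}},$$

clipped at zero for reporting. Held-out records combine as

$$z_i = \mathrm{sign}_i \, \Phi^{-1}(1 - p_i/2), \qquad
z_{\text{meta}} = \frac{\sum_i \sqrt{n_i}\, z_i}{\sqrt{\sum_i n_i}},$$

with $n_i$ = cases + controls (effective sample size
$4/(1/n_{\text{cases}}+1/n_{\text{controls}})$ available by option) and a
two-sided meta p. Degenerate (flagged) records are excluded with a logged
count; $p = 0$ is clamped to the smallest representable positive. $R^2$
summaries use R's default linear-interpolation (type 7) quantiles.

# Numerical choices and degenerate inputs

* Logistic fits drop rank-deficient columns with a warning; separation is
  detected on the standardized scale ($|\beta_j|\,\mathrm{sd}(x_j) > 15$),
  flagged, and capped rather than fatal — flagged records never enter the
  meta-analysis.
* The Hardy–Weinberg QC test is a 1-df Pearson chi-square without continuity
  correction; monomorphic counts are trivially consistent (p = 1). The QC
  chain applies, in order: SNP missingness ≥ 0.05; sample missingness ≥ 0.02
  or $|F_{het}| \ge 0.2$ with $F_{het} = 1 - \text{obs het}/\text{exp het}$
  over retained SNPs; SNP missingness ≥ 0.02; case-control missingness
  difference ≥ 0.02; HWE $p \le 10^{-6}$ in controls or $\le 10^{-10}$ in
  cases. All thresholds retain-if-below.
* Genic margins are boundary-inclusive (a SNP exactly 5 kb upstream is
  genic) and strand-aware — a minus-strand gene's upstream is its
  high-coordinate side — with `strand_aware = FALSE` available since the
  convention is not universal.
* Random sets have exact size (`min(set_size, pool)`), not Poisson-jittered
  sizes: determinism is worth more than mimicking a mean.
* An empty scored set yields an all-zero score with a warning; the
  evaluation layer treats the resulting constant predictor as a flagged
  record.

# What the simulations do and do not establish

The generator reproduces: unequal cohort sizes, ascertained case-control
sampling, cohort-level allele-frequency drift, an omnigenic effect-size
background with optional core enrichment, covariate structure correlated
with study membership, and missing hard calls. It deliberately omits:
linkage-disequilibrium blocks beyond drift-induced correlation (so pruning
removes little on default panels), X-chromosome inheritance, imputation
dosages, gene-size or SNP-density matching of random sets, and any realistic
minor-allele-frequency spectrum. Passing tests therefore demonstrate the
pipeline's *statistical mechanics* — calibration of individual held-out
tests, recovery of planted enrichment, direction of the genic floor — not
performance on real LD-structured genomes.

# Known limitations

**The experiment-wise permutation null is anti-conservative by
construction.** Each held-out test is individually calibrated (uniform
p-values under permutation; the suite asserts this), but the $k$ leave-one-out
z-scores of one experiment are not independent: study $t$'s phenotypes are
*test* data in iteration $t$ and *training* data in every other iteration,
so $\mathrm{cov}(z_s, z_t) \approx \sqrt{n_s n_t}/N \approx 1/(k-1)$ under
the null when training weights are re-estimated per permutation. Summed over
all pairs this adds approximately one full unit of variance:
$\mathrm{var}(z_{\text{meta}}) \approx 2$ *regardless of the number of
cohorts*, inflating the experiment-wise rejection rate at $\alpha = 0.05$
to roughly 0.15–0.20. `analysis/06_loo_correlation_diagnostic.R` measures
this directly on a 6-study panel (per-study z variances ≈ 1, pairwise
correlation ≈ 0.18, $\mathrm{var}(z_{\text{meta}}) \approx 1.9$), and
`analysis/04_permutation_null.R` shows the resulting experiment-wise rate
(18/100 at $\alpha=0.05$ on its panel). The package
implements the permutation experiment as specified — full re-training per
permutation — and reports the honest rate; a permutation scheme that froze
the training weights would restore $z_{\text{meta}} \sim N(0,1)$ but would
no longer test the pipeline end-to-end. Consequence: the Stouffer meta
p-values from overlapping-training LOO designs are best read as *relative*
evidence (candidate set versus matched random floor, as in the core-recovery
analysis) rather than as calibrated absolute tail probabilities.

Other limitations: Wald GWAS p-values can be conservative at very low minor
allele counts; the pooled-GWAS route assumes a shared effect across cohorts;
and the proportional-allocation "expected share" assumes equal per-SNP
contributions, which the omnigenic model itself only approximates.

# Problem sizes used by the shipped analyses

The numbered scripts under `analysis/` and the acceptance script run, per
invocation: one 6-study panel simulation (~1700 samples × 2000 SNPs, a few
seconds); one LOO pass = 6 pooled GWAS + 6 prunings (~15 s); the permutation
null = 100 LOO passes on the reduced panel (~5 min); and the replicate
analyses = 10 panels × (1 + 20) or (10 + 10) set evaluations sharing
training per panel (~4–5 min each). Training-side computations (GWAS,
orientation, pruning) are computed once per held-out study and shared across
SNP sets and permutations wherever they are provably identical; the tests
assert exact equality of the shared and unshared paths.
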