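---
title: "Methods and design of gwasfunnel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of gwasfunnel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gwasfunnel)
```

# The problem

Genome-wide association in a cohort of ~100 individuals cannot reach
genome-wide significance, and risk models built on the few SNPs that pass
exploratory thresholds tend to be badly overfitted: leave-one-out accuracy
looks strong while accuracy on an external cohort collapses toward the
majority-class rate. `gwasfunnel` implements the complete desk-scale
workflow around this phenomenon — quality control, calibrated single-SNP
association, a two-stage candidate funnel, wrapper-based marker selection,
honest and optimistic evaluation protocols, and external stratified
bootstrap validation — together with a synthetic-data module that plants
known genetic architectures so that every claim the pipeline makes can be
checked against ground truth.

# Quality control

`apply_qc()` runs six filters in a fixed order, each on the output of the
previous one, and reports per-step removal counts (order matters, as it
does in PLINK; the final survivor set is *not* order-invariant, which is
why the report makes the order explicit):

1. sample call rate ≥ 0.95;
2. SNP call rate ≥ 0.95;
3. minor-allele frequency ≥ 0.05;
4. Hardy–Weinberg exact p ≥ 10⁻⁶, computed in controls only;
5. per-sample heterozygosity within 3 SD of the cohort mean;
6. pairwise relatedness ≤ 0.1875 with greedy removal of one member per
   flagged pair (the sample in the most flagged pairs goes first; ties by
   sample order).

The defaults are the community-standard PLINK tutorial values; the exact
thresholds used by any particular study are configurable via
`qc_thresholds()`.

**HWE exact test.** `hwe_exact_test()` is the exact conditional test:
given the observed allele counts, the probability of each heterozygote
count in the parity-constrained support is computed by the standard
recurrence, and the p-value sums the probabilities of all outcomes no more
probable than the observed one. The test suite verifies it against an
independent closed-form enumeration (multinomial/`lchoose` arithmetic) on
*every* genotype table with up to 60 alleles.

**Relatedness.** Full IBD estimation is out of scope at desk scale; the
statistic is the genotype-correlation (GCTA-style) kinship estimate
`mean[(g_i−2p)(g_j−2p)/(2p(1−p))]/2`, which is ~0.25 for full siblings and
~0 for unrelated pairs; 0.1875 is the conventional cutoff between 2nd- and
3rd-degree relatives. The estimate has sampling error of order
`1/sqrt(2m)`, so meaningful use needs a few hundred SNPs or more.

**Caveats.** The heterozygosity filter is a z-score rule: re-applying QC
to an already filtered cohort recomputes the z-scores and can "peel" new
tail samples. QC is therefore idempotent on clean data but not in
pathological generality. The sex-concordance check of array workflows is a
no-op here because only autosomal data are modelled.

# Association and genomic control

`logistic_assoc()` fits, per SNP, the additive logistic model
`logit P(case) = β₀ + β_g·g + covariates` (genotype g = minor-allele copy
count; minor allele determined in the analysis sample, ties at MAF 0.5
broken alphabetically for determinism). Wald p-values are used, matching
standard PLINK logistic output. Pathological fits are never reported as
numbers: SNPs with no variation are flagged `monomorphic`,
quasi-separated fits (|β| > 12, SE > 20, or fitted probabilities at the
boundary) are flagged `separation`, IRLS failures `not_converged`.
Flagged SNPs are excluded from λGC, since silent ±∞ effects would corrupt
calibration — and separations are routine at n = 96.

`lambda_gc()` computes the genomic inflation factor as the median of the
1-df chi-square quantiles implied by the p-values divided by the null
median `qchisq(0.5, 1) = 0.4549364`, plus observed-vs-uniform QQ pairs on
the −log₁₀ scale. On null simulations (n = 500, 10,000 SNPs, sex-only
model) the suite requires λGC ∈ [0.9, 1.1] and Kolmogorov–Smirnov
uniformity of the p-values at α = 0.01.

`pca_covariates()` provides principal-component covariates (per-SNP mean
imputation, standardisation, SVD scores scaled by singular values) with a
deterministic sign convention: the largest-magnitude loading on each
component is made positive. Whether PCs help at n = 96 is data-dependent —
in very small homogeneous cohorts they often inflate rather than deflate
λGC — so the package exposes the multi-model comparison but defaults to
the sex-only model.

Candidate funnels use two thresholds: stringent P < 10⁻⁴ (trait-specific
GWAS hits) and lenient P < 10⁻² (the pool handed to marker selection);
`candidate_union()` forms the per-trait sets and their deduplicated union.
Bonferroni (α/m) and Benjamini–Hochberg step-up masks are reported for
context via `multiple_testing()`.

# Comorbidity rule mining

`rule_stats()` reduces visit records to patient-level presence (a patient
either has a code or not; duplicates are ignored) and computes, for an
antecedent D and consequent C: support = P(D∧C), confidence = P(C|D),
lift = P(C|D)/P(C), and the 1-df Pearson chi-square on the 2×2 table
without continuity correction (configurable). Any zero margin makes lift
and chi-square undefined — flagged, not an error. `mine_rules()` ranks
rules around an anchor disease by lift (ties: support, then code order)
and exports a network edge list.

Two modelling notes. *Temporal ordering is not modelled*: the statistics
are co-occurrence, not sequence, so "C after onset of D" readings are
outside the contract. *Lift has a hard ceiling*: for any joint
distribution, lift ≤ 1/max(P(C), P(D)). The visit simulator validates
that a requested planted lift is feasible (`lift·P(C) ≤ 1` and the
implied P(C|¬D) ∈ [0,1], i.e. `lift·P(D) ≤ 1` when the marginal of C is
to be preserved) and rejects impossible configurations up front.

# Wrapper selection and the leakage contrast

`best_first_search()` is classic best-first over the feature-subset
lattice, starting from the empty set: an open list is kept ordered by
LOOCV accuracy; the best open node is expanded by all single-feature
additions; the search stops after `stale_limit` consecutive expansions
without improving the global best. `stale_limit` defaults to 5 (the
convention of the standard wrapper implementations this protocol
descends from); with an unbounded budget the search provably visits every
subset, and the suite checks exact agreement with exhaustive search on
≤10-feature problems. Ties are broken toward smaller subsets, then
lexicographic feature order, so results are platform-deterministic. The
empty subset is legal output — on pure noise with the zero-rule metric the
search returns it with score equal to the majority fraction. Accuracy is
the only scored metric (AUC is recorded downstream but never optimised).

Two protocols consume the search:

- `fixed_subset_workflow()` — the fix-once discovery protocol: one search
  on the full discovery data; the subset is frozen for all later
  evaluation. Its score is the LOOCV accuracy of the selected subset on
  the same data — an *optimistic* quantity, because the selection saw
  every sample.
- `embedded_selection_cv()` — the leakage-safe protocol: for every
  held-out sample the entire funnel (screen + search) is re-run on the
  remaining n−1 only, and the held-out prediction uses that fold's subset.
  The aggregated honest accuracy is unbiased by selection.

On pure-noise cohorts (n = 96, 2,000 null SNPs) the gap between the two is
the size of the selection-leakage artifact; the suite requires it to
average ≥ 20 accuracy points over 20 seeds. With 1-NN scoring the honest
accuracy on noise typically lands *below* 50% (the selected noise features
anti-generalise), which makes the gap if anything larger.

**The screen.** Searching thousands of candidates inside every fold is
intractable, so `search_config(screen_top_k = k)` adds a univariate
pre-screen — keep the k features most |Pearson-correlated| with the labels
— that is recomputed per training fold in the embedded protocol and
applied to the full data in the fix-once protocol, keeping the two
protocols comparable. In the full pipeline the screen role is played by
the lenient GWAS funnel (P < 10⁻²).

# Classifier registry and evaluation

The registry mirrors a fourteen-learner workbench. `zero_rule` (majority
class, ties to controls) and `one_rule` (best per-feature-value majority
rule, ties by feature order) are implemented exactly as specified — note
that `one_rule` treats each distinct value as a level, which is intended
for genotype features; on continuous features it will memorise the
training data. `knn` binds to the compiled FNN backend (k = 1 default,
with a vectorised distance-matrix LOOCV fast path verified against the
explicit train/predict loop). The remaining entries are native
implementations or nearest-equivalent substitutes, since no tree/SVM/NB
package is assumed: Gaussian naive Bayes; linear soft-margin SVMs trained
by full-batch (`svm_lib`) or Pegasos-style stochastic (`svm_sgd`)
subgradient descent on standardised features; maximum-likelihood logistic
regression for `smo_logistic` and `logistic_model_tree`; Gaussian-kernel
weighted voting for `lwl`; CART-style Gini trees for `c45_tree` (depth 6)
and, shallower, for the rule learners `part`/`ripper` (depth 3); a
per-split feature-sampled `random_tree`; and `random_forest` as 100
bagged random trees with vote-fraction probabilities. Substitutions are
deliberate: these names denote *protocol slots*, and exact replication of
any one workbench's internals is not a goal. Stochastic learners draw
from a seed embedded in the spec and restore the caller's RNG stream, so
surrounding pipelines stay reproducible.

Evaluation follows three protocols:

- LOOCV (`loocv_accuracy()`): n train/predict rounds. For the zero rule
  this analytically equals the majority fraction when classes are
  unbalanced — e.g. 46/50 → 52.08%, 34/62 → 64.58%, 42/54 → 56.25% — and
  collapses to 0 on exactly balanced data (the familiar LOOCV pathology of
  constant classifiers).
- Repeated stratified k-fold CV (`repeated_stratified_cv()`, default
  10×10): within-class round-robin assignment keeps fold class
  proportions within one sample of the cohort's.
- Stratified bootstrap external validation
  (`stratified_bootstrap_external()`, default B = 1000): the model is
  fitted once on discovery data; every replicate resamples the external
  predictions with replacement *within class*, so replicate class counts
  equal the originals exactly. Accuracy and rank-based AUC (midranks, half
  credit for ties, verified against the O(n²) pairwise oracle) are
  summarised as mean ± SD with percentile CIs (plain percentile, not BCa —
  no correction is part of the contract).

# The synthetic-data module

`simulate_genotypes()` draws per-SNP minor-allele frequencies uniformly on
[`maf_low`, `maf_high`] (default [0.05, 0.5]) and builds each genotype as
the sum of two independent latent-Gaussian gametes thresholded at
`qnorm(maf)` — a Gaussian-copula scheme. Because the two gametes are
independent Bernoulli(maf) draws, every SNP is at exact HWE marginally;
within an LD block the latent gametes follow an AR(1) process with
parameter `ld_rho`, inducing positive genotype correlation between
adjacent SNPs. Missingness is completely at random.

`simulate_phenotypes()` draws each trait as
Bernoulli(logistic(η)), with
η = intercept + β_sex·[sex = female] + Σ β_j·g_j + Σ γ_ij·g_i·g_j +
w·Z_shared, where Z_shared is a standard-normal liability shared by all
traits of the cohort and w (`trait_correlation` ∈ [0,1)) is its
coefficient — w = 0 gives independent traits. Missing genotypes enter η at
the per-SNP mean dosage. Ground truth (causal ids, interaction pairs,
realised prevalence) is returned for parameter-recovery testing. Target
prevalences are achieved by intercept tuning
(`intercept_for_prevalence()`, a monotone root-find), and designed
case/control counts (e.g. 80/16) by `resample_to_counts()` — both regimes
occur in practice.

`simulate_visits()` plants comorbidity structure: a planted pair (D, C)
with target lift L receives P(C|D) = L·P(C) and
P(C|¬D) = P(C)(1−L·P(D))/(1−P(D)), preserving C's marginal exactly;
feasibility (both conditionals in [0,1]) is validated at configuration
time.

**Chosen constants.** Real small-cohort architectures are unknown, so
the planted-effect regime is a package design choice made once, by power
analysis: causal SNPs at MAF ≈ 0.35 with per-allele log-odds 1.25
(OR ≈ 3.5) in a balanced n = 96 cohort give single-SNP screen power ≈ 0.9
at α = 10⁻², the minimal regime in which small-cohort recovery is
demonstrable at all. Weaker effects make every downstream recovery claim
vacuous at this n; stronger ones make it trivial.

**What a green test does not establish.** The generator produces
independent or block-AR(1) SNPs in one homogeneous population; it does not
emulate realistic human LD maps, admixture or population structure,
X-chromosome dosage, genotyping batch effects, or case–control
ascertainment bias. Recovery results on this world say the machinery
works, not that the same effect sizes are recoverable in real array data.

# The pipeline

`run_pipeline()` chains the stages — optional comorbidity mining, QC
(discovery only), per-trait sex-adjusted GWAS with λGC, candidate funnels,
marker selection on the lenient pool, evaluation of the final model on the
marker panel versus the stringent-GWAS panel (LOOCV, optional 10×10 CV,
external stratified bootstrap), optional eQTL annotation — and writes
every artifact as headed TSV/JSON plus a manifest with seeds, versions and
the two cohorts' sample ids. Overlapping discovery/external ids are a hard
stop (leakage guard), and external samples never enter QC statistics,
GWAS, or selection; the manifest makes this auditable. A sample can be a
case for one trait and a control for another (the comorbid design).
Re-running the same configuration reproduces byte-identical numbers.

The package is an R library by design: the exported stage functions plus
`run_pipeline()` are the interface, and every tabular artifact declares
its coding in a header line for downstream tools.

# Annotation

`filter_palindromic()` excludes a SNP iff its alleles are complementary
(A/T or C/G) *and* its MAF is ≥ 0.40 — inclusive at the boundary, as the
convention is stated. Palindromic SNPs below the cutoff pass through
flagged `palindromic-low-maf`; no strand flipping is attempted.
`eqtl_join()` left-joins selected SNPs onto a user-supplied cis-eQTL table
by rsID (the table is expected to be GRCh38, ±1 Mb cis windows upstream of
this package), flags records with q < 0.05, emits one empty-annotation row
per unmatched SNP, and treats conflicting duplicates for one
(snp, gene, tissue) key as an error. Slopes are emitted as supplied; no
allele-direction harmonisation of effect signs is attempted.

# Numerical conventions

- Additive genotype coding counts the minor allele *as determined in the
  analysis sample*; MAF-0.5 ties break alphabetically.
- Wald inference throughout; separation is flagged, never numeric.
- Best-first ties: smaller subset, then lexicographic order; improvement
  must exceed 10⁻⁹ to reset the stale counter.
- 1-NN distance ties resolve to the lowest sample index.
- All stochastic stages consume explicit seeds and restore the caller's
  RNG state; identical seeds give bit-identical outputs.
- p-values of exactly 0 from underflow are clamped to the smallest
  positive double so that (0, 1] contracts hold.

# Known limitations

- No mixed-model association, imputation, dosage regression, or
  meta-analysis; no X/Y/MT handling.
- Relatedness is a correlation estimate, not IBD; it needs several hundred
  SNPs to be meaningful.
- `one_rule` on continuous features memorises; it is meant for genotypes.
- The SVM substitutes are linear; kernel behaviour of the workbench
  originals is not reproduced.
- Binary PLINK BED payloads are not parsed (BIM/FAM metadata are); text
  PED/MAP is the supported interchange format.
- Comorbidity mining is pairwise co-occurrence only — no multi-antecedent
  itemsets, no temporal sequence.
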