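---
title: "Benchmarking genotype encodings and classifiers for SNP-based disease risk prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking genotype encodings and classifiers for SNP-based disease risk prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(snpbench)
```

## The problem

Genome-wide association studies (GWAS) genotype hundreds of thousands of
single-nucleotide polymorphisms (SNPs) in case-control cohorts. Beyond
locus discovery, the same data can train machine-learning models that
predict an individual's disease risk from genotype alone. Two design
choices dominate such pipelines and are surprisingly easy to get wrong:

1. **How genotypes are encoded as numeric features.** A biallelic genotype
   (AA / AB / BB, with A the major and B the minor allele) can be encoded
   as a minor-allele count (*additive*, one feature), as two allele-presence
   indicators (*recessive/dominant*, two features), or as three one-hot
   genotype indicators (*genotypic*, three features). All three carry the
   same information — each is losslessly invertible — but they present it
   differently, and a learner's ability to exploit it depends on the
   representation. Each encoding also implies a different genetic risk
   model.
2. **Which classification algorithm is used.** Model families differ in
   flexibility, interpretability and cost, and no single family dominates
   across data types.

`snpbench` implements a complete, leakage-free benchmarking protocol for
answering both questions on any case-control genotype collection, plus a
simulator so that the entire pipeline is testable without access to real
(typically controlled-access) cohorts. Its statistical layer — matched-rank
inference with the Friedman test, the Iman–Davenport correction and
Shaffer's static post-hoc procedure — also works directly on published
average-rank tables, and the package bundles one such table set from a
large seven-disease benchmark (882 experimental settings) as a worked
example (`ref_encoding_ranks()`, `ref_classifier_ranks()`,
`ref_classifier_pairwise()`).

## The evaluation protocol

For one dataset, one association threshold, one encoding and one
classifier, `run_setting()` executes a **5×2 outer cross-validation**:
five repetitions of a stratified random half/half split, each half used
once for training and once for testing. Per outer fold:

1. **Per-fold SNP selection.** Five single-marker association tests
   (allelic, dominant, recessive, genotypic, Cochran–Armitage trend —
   the classic genome-wide `--model` battery) are computed **on the
   training half only**; a SNP is retained if its minimum p-value over the
   five tests falls below the setting's threshold. The default threshold
   ladder is $10^{-3}, \dots, 10^{-8}$, so retained sets are nested across
   thresholds within every fold.
2. **Encoding and standardization.** Retained SNPs are encoded and each
   feature standardized to mean 0, variance 1 using training-half
   statistics only; missing genotypes are imputed with the training-fold
   feature mean *before* centering, so they map to exactly 0.
3. **Inner tuning.** A stratified 5-fold inner cross-validation evaluates
   every combination in the classifier's parameter grid and the
   combination with the highest fold-averaged AUC is selected (first
   occurrence wins ties; failing combinations score 0).
4. **Evaluation.** The tuned classifier is fit on the full training half
   and its AUC (Mann–Whitney formulation, ties counting ½) measured on the
   held-out half.

The ten fold AUCs are averaged into a single measurement per setting —
the ten folds of one 5×2 design are not independent, so the downstream
rank tests must see one number per setting. The splits are generated once
per dataset and reused for every threshold, encoding and classifier, which
makes the settings *matched* across treatments, as the Friedman test
requires. AUC is used throughout because case/control ratios are typically
imbalanced (the simulator default mirrors a common ~2,000 cases vs ~1,500
controls design, a ~4:3 ratio).

Two deliberate failure-handling rules keep the design totally ordered: a
fold that retains zero SNPs is recorded at AUC 0.5 and flagged (an
informationless model), and a setting that errors is recorded as `NA`
without stopping the run.

### Classifier families

Seven families are supported behind a uniform fit/score contract
(`fit_classifier()` / `score_classifier()`); the score is always a
real-valued ranking, which AUC needs. Training is delegated to standard
implementations — `rpart` (decision tree), `ranger` (random forest),
`e1071` (linear and RBF-kernel SVM, scored by their decision values),
`nnet` (single-hidden-layer MLP) — while kNN and LVQ are implemented in
the package, because off-the-shelf versions do not expose the required
real-valued score (inverse-distance-weighted class probability for kNN; for
LVQ, a plain multipass LVQ1 with a small fixed codebook per class, scored
as distance-to-nearest-control-prototype minus
distance-to-nearest-case-prototype).

Default tuning grids are documented in `?classifier_spec`. Two mappings
deserve a note. The decision tree's pruning-confidence grid is expressed
through `rpart`'s complexity parameter `cp` (spanning weak to aggressive
pruning), since `rpart` prunes by cost-complexity rather than by
confidence intervals. The MLP grid tunes hidden-layer size
({2, 4, 8, 16, 32, #features}) and weight decay; `nnet` optimizes by
BFGS, so a learning-rate grid has no equivalent and regularization via
decay plays that role. The "#features" hidden-size option is encoded as
`size = 0` and resolved at fit time.

All randomness flows from one experiment master seed through named
substreams (splits, inner folds, per-fold classifier initialization), so a
full `run_experiment()` is exactly reproducible.

## The rank-inference layer

Given a results table of mean AUCs over $n$ matched problems and $k$
treatments, `rank_problems()` ranks treatments within each problem from
best (rank 1) to worst (rank $k$), averaging tied ranks. With average
ranks $R_j$, the Friedman statistic is

$$F = \frac{12n}{k(k+1)}\left[\sum_j R_j^2 - \frac{k(k+1)^2}{4}\right],$$

approximately $\chi^2_{k-1}$ for large designs. The package reports the
less conservative Iman–Davenport transform

$$F_{ID} = \frac{(n-1)F}{n(k-1) - F},$$

referred to the $F$ distribution with $(k-1,\,(k-1)(n-1))$ degrees of
freedom. When every problem produces the identical ranking, $F$ attains
its maximum $n(k-1)$ and the transform diverges; the p-value is then
reported as the limiting 0 with a degeneracy flag.

If the omnibus test rejects, all $m = k(k-1)/2$ pairs are compared by

$$z = \frac{R_i - R_j}{\sqrt{k(k+1)/(6n)}}$$

with two-sided normal p-values (computed through `pnorm` on the negative
half-line, which stays accurate at the $10^{-13}$ scales that large
benchmark families produce). Two multiplicity corrections are provided.
The **Nemenyi** correction multiplies every raw p by $m$. **Shaffer's
static method** exploits the logical structure of all-pairs equality
hypotheses: if the treatments split into groups of sizes $a_1, a_2, \dots$
(a partition of $k$) with equality exactly within groups, the number of
true hypotheses is $\sum_i \binom{a_i}{2}$, so only certain counts are
achievable (`shaffer_true_counts()`; e.g. $\{0,1,3\}$ for $k=3$). The
sorted p-values are multiplied by the step-down multipliers
$t_i = \max\{s \in S(k): s \le m-i+1\}$, with a running maximum enforcing
monotonicity and a cap at 1. Shaffer-adjusted p-values are never larger
than Nemenyi-adjusted ones.

`cd_groups()` turns the adjusted family into critical-distance-diagram
data: treatments ordered by average rank and the maximal consecutive runs
within which no pairwise hypothesis is rejected. The default
$\alpha = 0.001$ is deliberately stringent, fitting families of dozens of
comparisons.

### Analyzing published average-rank tables

Because ties are resolved by average ranks, every rank sum is a multiple
of 0.5; a printed two-decimal average rank over $n$ problems can therefore
be converted back to the *exact* rank sum by `reconstruct_rank_sums()`
whenever $0.25/n$ exceeds the rounding error. The bundled worked example
reproduces a published benchmark's entire inference layer this way:

```{r}
rs <- reconstruct_rank_sums(ref_classifier_ranks(), n = 42)
rs$rank_sums          # sums total 42 * 7 * 8 / 2 = 1176
friedman_test_ranks(rs)$p.value
head(posthoc_pairwise(rs), 4)
cd_groups(rs)$groups
```

The grouping splits the seven families into a statistically
indistinguishable leading group (both SVMs, MLP, random forest, kNN) and a
clearly worse pair (decision tree, LVQ) — the qualitative headline of the
source benchmark. A note on that benchmark's annotations: its per-classifier
and per-disease encoding comparisons are printed as $k=3, n=6$ groupings in
places, but the printed p-values are arithmetically consistent only with
one problem per (dataset × threshold) setting, i.e. $n = 42$ per classifier
and $n = 294$ overall; `ref_encoding_ranks()` therefore records those `n`
values, and the reproduction tests use them.

## The simulator

`simulate_cohort()` draws genotypes per SNP under Hardy–Weinberg
equilibrium from its minor-allele frequency and assigns disease status
from a logistic model over a configurable set of causal SNPs (additive,
dominant, recessive or genotype-specific odds ratios). Individuals are
accumulated by rejection until the case and control quotas are met
exactly — a prospective sampling scheme under which odds-ratio recovery is
approximately correct for rare-to-moderate prevalence; the default
baseline prevalence is 10%. Missingness is applied MCAR after phenotype
assignment (nothing in the emulated design suggests an informative
missingness process). Allele symbols are fixed as A (major) / B (minor).

What the simulator deliberately does **not** model: linkage
disequilibrium, population stratification, relatedness, sex chromosomes
and genotyping-batch artifacts. Passing tests on simulated data therefore
demonstrate the correctness and calibration of the pipeline's machinery,
not the absolute predictive performance achievable on real cohorts, where
LD both helps (tagging) and hurts (redundant features) and confounding
inflates association statistics. Real effect-size spectra are also not
calibrated to any particular disease; the shipped architectures are
illustrative.

Marker QC (`apply_qc()`) mirrors standard practice: exclusion-list removal
first, then MAF < 5%, then missing-call fraction > 5%, then a 1-df
chi-square HWE goodness-of-fit test at $p < 0.001$, each marker labelled
with the first rule it fails. Two readings deserve a note: a "genotyping
rate less than 5%" rule is implemented as *missing-call fraction above
5%* (the literal reading would discard nearly every marker), and the HWE
test is the deterministic chi-square variant rather than an exact test,
applied by default to all samples of the cohort under test, with a
`per-cohort` mode (cases alone, controls alone, then pooled — a marker
must survive all three) for merged case-control panels.

## Numerical and design choices

* **Association tests** use no continuity correction (matching the common
  genome-wide `--model` convention); degenerate margins return statistic
  0, p = 1 with a flag, and a genotypic test with an empty genotype column
  drops the column and reduces to 1 df, keeping the minimum-p filter
  total. Missing genotypes are dropped per SNP (standard practice).
* **Standardization** divides by the population (divide-by-n) standard
  deviation; either convention satisfies "unit variance", and one is fixed
  for reproducibility. Binary-encoded features are standardized like all
  others. Constant features map to 0.
* **MAF ties** (exactly 0.5) designate the lexicographically smaller
  allele symbol as minor, making the designation deterministic.
* **Stratified halves** in the 5×2 splits guarantee both classes in every
  half at imbalanced case/control ratios.
* **Inner-CV aggregation** averages AUC across inner folds (rather than
  pooling scores), keeping each fold's ranking self-contained.

## Problem sizes used in the shipped checks

The package's own test suite exercises the full pipeline at reduced but
non-trivial scale, chosen to give each check clear statistical resolution:
null-calibration of the five association tests on 2,000 simulated null
SNPs at 500 cases / 500 controls (empirical type-I error at
$\alpha = 0.05$ within [0.04, 0.06]); odds-ratio recovery over 60
simulated cohorts of 1,000 + 1,000; and a three-study directional
benchmark (2,000 SNPs, 400 cases / 300 controls, eight additive causal
SNPs with odds ratios 1.3–1.8, thresholds $10^{-3}$ and $10^{-4}$, three
encodings × linear SVM / random forest / kNN with reduced grids) on which
the additive encoding attains the best Friedman average rank — the
directional result one expects when the generating risk model is
additive. The statistical layer itself is checked against the bundled
published tables at their printed precision.

## Limitations

The pairwise normal approximation and the Iman–Davenport F reference are
asymptotic in $n$; for very small designs (e.g. $k$ close to or exceeding
$n$) the omnibus test is unreliable and the package does not attempt
exact small-sample null distributions. Comparison families with missing
cells are rejected rather than imputed. Bergmann–Hommel-style dynamic
corrections are out of scope; Shaffer's static schedule is the supported
step-down method.
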