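---
title: "Attributing expression deregulation to gene dosage: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attributing expression deregulation to gene dosage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`cnadose` estimates how much of a tumor cohort's expression deregulation
is attributable to copy-number gene dosage. This vignette is the package's
account of the statistical machinery: the models, their assumptions, the
parameters that matter, what the synthetic-data generator does and does
not emulate, and the places where the design was genuinely open.

## 1. Copy-number segmentation

Marker-level log2 copy ratios are modelled with a homogeneous 5-state
hidden Markov model, one state per integer copy number 0–4. Emissions are
Gaussian with means `log2(CN/2)` — i.e. (−∞, −1, 0, +0.585, +1) — except
that the homozygous-deletion mean is floored at −2.0 to keep the
likelihood finite; the default emission SD is 0.25 on the log2 scale,
typical of mid-2000s SNP arrays after normalisation. Transitions use a
single per-marker self-transition probability (default 0.999) with the
remaining mass spread uniformly over the other four states, and a uniform
initial distribution.

Assumptions worth stating:

* **Homogeneous transitions.** The chain does not scale transition
  probabilities with inter-marker distance. Genotyping-console HMMs may do
  so; their parameters are not published, so the simplest stationary chain
  is used and the choice is part of the documented contract: segmentation
  is invariant to adding a constant below `emission_sd/10` to all ratios
  *only when* the state means are re-centred identically (tested).
* **Decoding.** The Viterbi path (compiled, O(n·K²)) is taken per arm;
  maximal runs of constant state become segments. Boundaries sit at the
  midpoint between adjacent markers of differing state; the first and
  last segments are anchored at the first marker and one base past the
  last marker, so segments tile the marker span. All intervals are
  0-based half-open, converted only at the BED boundary.
* **Unpaired mode.** Ratios are assumed pre-referenced against a normal
  panel; there is no paired-normal, purity, or ploidy correction.

CNA filters mirror array practice: at least 50 CN-altered markers, at
least 500 kb, and at most 50% of bases (inclusive, measured against the
*union* of intervals so overlapping annotations are not double-counted)
inside germline constitutive CNVs. States 3 and 4 are pooled afterwards
because high-level amplification is rare and never recurrent enough to
analyse separately. The stricter "> 2.5 Mb" rule that defines a CN
alteration for *burden* purposes is deliberately applied downstream, in
`compute_burden()`, so that the ≥ 500 kb call set remains available for
cross-platform concordance, where agreement is scored per segment as
≥ 50% same-direction coverage, binned by segment size.

## 2. Burden, groups, and gene status

`%CN-AG` is the altered fraction of a fixed 3,000 Mb haploid genome
(configurable; the synthetic runs use their own genome size as the
denominator). Per-arm percentages use arm lengths as denominators, so the
per-arm altered bases always sum to the genome-level altered bases
(tested conservation property).

Tumors are ranked by burden and split into low/medium/high groups; when
the cohort size is not divisible by three, the extra tumors go to the
lower groups first (31 → 11/10/10). Ties are broken by sample id, which
makes the grouping invariant to input order.

Gene status: any ≥ 1 bp overlap with a deletion CNA gives CN1, with a gain
CN3, otherwise CN2. A gene hit by both a gain and a loss in one tumor
takes the status of the larger overlap; exact ties go to the gain, a
heuristic reflecting the dominance of gains in this tumor type. The rule
is validated against a per-base brute-force scan in the tests.

## 3. Expression status and SAM

The per-tumor caller works on **linear** intensities: up requires
intensity ≥ 2× the control mean *and* above the mean + 1 SD; down requires
≤ 0.5× *and* below the mean − 1 SD. The dual cutoff makes the call robust
both for low-variance genes (the fold-change clause binds) and
high-variance genes (the SD clause binds). A doubling rule applied to
log2 values would correspond to squaring the intensity and is not
biologically meaningful, hence the linear-scale decision; matrices
declare their scale in the file header and are converted on read.

The SAM implementation follows the classic two-class unpaired recipe:

* `d = (mean difference) / (s_i + s0)` with `s_i` the pooled standard
  error; a zero denominator yields `d = 0` rather than a blow-up.
* `s0` minimises the coefficient of variation of the window-wise MAD of
  `d` across 100 quantile windows of `s_i`, over the {0, 5, …, 100}
  percentile grid of candidates.
* The null is built from class-label assignments: exhaustive when at most
  2,000 assignments exist (e.g. all 924 at 6+6, enumerated and verified
  against an independent per-gene oracle in the tests), otherwise seeded
  Monte-Carlo (default 1,000).
* Delta is the smallest band whose estimated FDR — median permutation
  false positives × π0 / called — meets the target; the "general FDR 0%"
  operating point simply demands a median of zero false positives.
* A per-gene local fdr is estimated as π0·f0(d)/f(d) from kernel densities
  of the permutation null and the observed d; calls additionally require
  local fdr < 0.10 and linear fold change ≥ 1.5 (or ≤ 1/1.5). The local
  fdr is an approximation: the reference SAM implementation's exact local
  FDR rule is version-dependent and undocumented, so bit-compatibility is
  not a goal — the documented cutoffs are.

Per-arm deregulation enrichment uses a 2×2 chi-square (arm vs rest of the
universe, no continuity correction — verified against the hand formula)
with a one-sided enrichment flag at p < 0.05. Sample clustering on gene-set
profiles is plain average-linkage agglomeration on Euclidean distances
(deterministic; ties resolved by `hclust`'s ordering), cut into k groups,
with cluster–burden association by Fisher's exact test (Monte-Carlo above
60 observations) and Newick export of the dendrogram.

## 4. Attribution

The cross-tabulation pools per-tumor counts as **ratios of means** (sum of
deregulated counts over sum of class sizes). This is the only convention
that reproduces the shipped cohort's per-class averages, and it weights
tumors by their class sizes rather than averaging unstable per-tumor
ratios. The dosage difference — the CN-altered rate minus the two-copy
rate, in percentage points — is the direct-dosage estimate; a 2×2
chi-square on the pooled counts accompanies it.

The regression layer is ordinary least squares plus the Pearson
correlation; a zero-variance burden vector raises an explicit error
rather than returning NaN. The arm-level decomposition is forward
stepwise selection by partial-F p-value (enter at p < 0.05) — the classic
"MLR" — reporting entry order, adjusted R², and the first predictor's
share of the final model R² (the "arm X accounts for Y% of variation"
statistic). Forward selection is checked against exhaustive best-subset
enumeration on ≤ 6 predictors in the tests; collinear or constant
predictors are dropped with a warning.

Exclusive-set logic: genes SAM-called versus controls in the high-burden
group but not the low-burden group are the candidates for dosage-driven
deregulation; the conservative bound is the fraction of that set
CN-altered in at least 4 of the high-burden tumors (strata reported at
≥ 6, 4–5, 1–3, 0). Per-gene correlations of expression with
amplified-arm burden use raw p < 0.05 with **no** multiplicity
correction, matching the source analysis convention; a Benjamini-Hochberg
flag exists but is off by default.

## 5. Survival

Analysis is cause-specific: deaths from the primary tumor are events;
deaths of other or unknown cause are censored at the death time; patients
who refused treatment are excluded (warned and counted). FIGO stage is
coded ordinally IB1 < IB2 < IIA < IIB < IIIB < IVA < IVB; the source
tables do not state a coding, and any order-preserving one gives the same
rank statistics. Kaplan–Meier, log-rank and Cox (Breslow ties) delegate to
the `survival` package; the "survival rate" is the crude end-of-follow-up
alive-or-censored proportion, with KM curves produced alongside. The ROC
burden cutoff maximises Youden's J over observed burden values
(high = burden ≥ cutoff), ties resolved toward the lower cutoff, and is
checked against an exhaustive threshold scan. Monotone-likelihood Cox fits
(perfect separation) are flagged and capped at |β| = 15 rather than left
to diverge.

## 6. The synthetic cohort: what it emulates, and what it does not

The generator's defaults are the study conditions the pipeline targets:

| parameter | default | meaning |
|---|---|---|
| `n_tumors`, `n_controls` | 31, 17 | cohort sizes |
| burden strata | 0.5 ± 0.6, 5.4 ± 2.4, 19.2 ± 6.6 (%) | low/medium/high targets, remainder-to-low sizes (11/10/10) |
| genome | 8 arms, 300 Mb, 2 kb spacing, 2,000 genes | 1/10-scale genome for desk-scale runtime (~150k markers) |
| `amplified_arm`, `amp_arm_gain_share` | "3q", 0.55 | the analog arm carries ~55% of gained genome |
| `gain_fraction` | 2/3 | gains:losses ≈ 2:1 |
| `segment_length_range_mb` | 0.6–12 | planted CNA lengths; all pass the marker/length filters at 2 kb spacing |
| `marker_noise_sd` | 0.25 | log2 marker noise |
| `direct_dosage_fraction` | 0.05 | fraction of CN-altered genes with a direct dosage response |
| `dosage_effect` | 3 | expression × (CN/2)³; makes a 3-copy gain (≈ 3.4×) reliably clear the 2× call cutoff while a null gene stays put |
| `n_trans_genes`, `trans_effect_slope` | 40, 0.02 | trans module ≈ 2% of genes, +0.02 log2 per % amplified-arm burden — per-gene correlation r ≈ 0.7 at the default noise, detectable at n = 27 without inflating the two-copy deregulation rate by more than ~0.4 points |
| `noise_sd` | 0.35 | log2 expression noise; keeps the null per-tumor call rate below 1% |
| baseline | log2 ~ N(6, 1.5) | RMA-like intensity scale |
| `survival_beta`, `baseline_hazard` | 0.12, 0.007 /month | hazard ratio ≈ 9 between burden extremes, ~50% events — sized so a 3-group log-rank at n = 31 has power > 0.8 |
| `figo_noise_sd` | 1.55 | latent-score noise targeting Spearman ρ ≈ 0.5 between stage and burden (1/√(1+σ²) ≈ 0.54) |

Because the genome is 1/10 scale, thresholds tied to absolute length
scale with it in synthetic runs: the burden rule "> 2.5 Mb" becomes
0.25 Mb (`burden_min_length = 2.5e5`) while the marker-count and ≥ 500 kb
call filters are kept at their real values (a 2 kb spacing makes both
attainable).

What the generator does **not** emulate: raw probe chemistry and CEL
intensities, RMA normalisation itself, probe-to-gene collapsing, tumor
purity and subclonality, allele-specific signal, waviness/GC artifacts,
linkage between neighbouring genes' expression, and any real pathway
structure — trans genes are an i.i.d. random subset. Passing planted-truth
tests therefore demonstrates correctness of the inference chain under the
stated noise model, not robustness to array artifacts or biological
confounding.

Determinism: every stochastic routine takes a seed; identical
(config, seed) reproduce byte-identical cohorts, and the pipeline writes
an md5 manifest so whole runs can be compared by hash.

## 7. Problem sizes used by the test suite

Chosen as desk-scale renditions of each property: exhaustive Viterbi
checks enumerate all 5^n paths for n ≤ 11 by incremental expansion
(5¹² ≈ 244M path scores would dominate memory for no extra insight);
breakpoint recovery uses 100 replicates of a 2,000-marker arm with a
400-marker planted gain; SAM calibration uses 1,000 genes × (10+10)
samples with 200 permutations over 10 seeds; attribution recovery runs
the full default-scale pipeline over 10 seeds for each planted fraction
in {0, 0.05, 0.15}; the null log-rank calibration uses 200 replicates
with a marker-sparse genome (markers are irrelevant to the survival
stage).

## 8. Known limitations

* The HMM has no distance-dependent transitions and no explicit
  outlier state; isolated noisy markers are absorbed by the
  self-transition prior instead.
* The gene universe for CN alignment is whatever annotation is supplied;
  the shipped cohort tables distinguish "all CN-altered genes" from
  "altered genes also on the expression array", and the package follows
  the table columns rather than guessing the exact array mapping.
* The local-fdr estimate is density-based and approximate (see §3).
* The exclusive-set bound is a *recurrence* bound, not a causal
  estimate; it inherits the arbitrariness of the ≥ 4-tumor threshold
  (configurable).
* Cross-platform concordance assumes both call sets share a coordinate
  system; no liftover is provided.
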