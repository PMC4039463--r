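# cnadose

How much of a tumor's transcriptome deregulation is explained by gene
dosage? `cnadose` is an R package for analysts integrating SNP-array copy
number with expression microarrays in tumor cohorts. It implements the
full inference chain for attributing per-gene expression changes to
copy-number alterations (CNAs), exercised end to end on a synthetic cohort
with planted ground truth, and recomputes the headline statistics of a
published cervical carcinoma cohort whose summary tables ship with the
package as plain text.

## The method

Marker-level log2 copy ratios are smoothed and segmented with a 5-state
hidden Markov model (states = integer copy numbers 0–4, Gaussian emissions
centred at log2(CN/2), homozygous deletions floored at −2). Segments
become CNAs after the standard filters: ≥ 50 CN-altered markers, ≥ 500 kb,
and ≤ 50% overlap with germline constitutive CNVs; amplification states 3
and 4 are pooled. Per tumor, the percentage of CN-altered genome is

    %CN-AG = 100 × Σ length(CNA > 2.5 Mb) / 3,000 Mb

and genes overlapping a CNA get status CN1 (one-copy loss), CN3 (3–4
copies) or CN2 (no alteration).

On the expression side, each gene in each tumor is called against the
control baseline (mean x̄ and SD s on the linear intensity scale):
**up** iff intensity ≥ 2·x̄ and > x̄ + s; **down** iff ≤ 0.5·x̄ and
< x̄ − s; otherwise unchanged. Group-level differential expression uses a
from-scratch SAM (Significance Analysis of Microarrays): per-gene
d = (x̄₁ − x̄₂)/(s_i + s₀), the fudge constant s₀ chosen by
coefficient-of-variation minimisation over a percentile grid, a
class-label permutation null (exhaustive when ≤ 2,000 assignments), the
delta band selected at a target median-false-positive FDR, a linear
fold-change cutoff, and a permutation-density local fdr.

Attribution then proceeds by:

- **cross-tabulation** — pooled deregulation rate among CN-altered genes
  minus the rate among 2-copy genes (ratio-of-means convention), the
  direct gene-dosage estimate in percentage points;
- **regression** — deregulated-gene count on %CN-AG (OLS + Pearson), and
  forward-stepwise decomposition of burden over chromosome arms with the
  first arm's share of the model R²;
- **exclusive sets** — genes SAM-called only in high-burden tumors,
  bounded above by their CNA recurrence (altered in ≥ 4 tumors);
- **per-gene correlation** of expression with amplified-arm burden
  (trans effects);
- **survival** — Kaplan–Meier/log-rank on burden groups, a Youden-optimal
  ROC burden cutoff, Cox adjustment for FIGO stage, and Spearman
  co-linearity checks.

The synthetic-cohort generator plants all of it — integer-CN segments
meeting per-stratum burden targets, a preferentially amplified "3q
analog", direct-dosage genes scaling as (CN/2)^k, trans genes driven by
amplified-arm burden, and burden-linked survival/FIGO — so every stage is
testable against known truth.

## Worked example

Recompute the shipped cohort's headline statistics:

```r
library(cnadose)
print(reproduce_tables())
#> Cohort headline statistics
#>    burden: mean 8.1% (SD 8.9) over 31 tumors; groups 0.5 / 5.4 / 19.2
#>    deregulated: 14.4% of CN-altered vs 9.1% of 2-copy genes (difference 5.3 points)
#>    CN-altered share of deregulated genes: 12.0%
#>    deregulated ~ burden: y = 32.1x + 1733 (r = 0.50, p = 0.00734)
#>    exclusive sets: shared 81.1%, exclusive-high 49.1%, dosage bound 22.9%
#>    survival: 64.3% of 28 treated patients; mean time to death 19.1 months
#>    ROC split: cutoff 17.1% -> high n = 7 (mean 22.2%, 71.4% died; log-rank p = 0.00534)
#>    FIGO ~ burden Spearman rho = 0.54 (p = 0.0028)
```

Only 14.4% of CN-altered genes are deregulated versus 9.1% of two-copy
genes: the 5.3-point difference is the fraction of CN-altered genes
plausibly deregulated directly by dosage, and only 12% of all deregulated
genes carry a CNA at all — most deregulation is trans or dosage-independent.
Patients above the ROC burden cutoff (17.1% CN-AG) die far more often
(71.4% vs 23.8%, log-rank p = 0.005).

The same chain on a synthetic cohort with a 5% planted direct-dosage
fraction:

```r
co    <- generate_cohort(cohort_config(direct_dosage_fraction = 0.05), seed = 1)
cnas  <- filter_cnas(collapse_cn4(viterbi_segment(co$markers, hmm_params())))
dos   <- map_genes_to_cn(cnas, co$genome, samples = names(co$markers))
calls <- call_expression_status(co$expr, control_baseline(co$controls))
print(crosstab_attribution(dos, calls))
#> Dosage attribution over 31 tumors:
#>    CN-altered genes deregulated: 6.2%
#>    2-copy genes deregulated:     0.9%
#>    dosage difference:            5.3 points (chi-square p = 2.7e-212)
#>    deregulated genes CN-altered: 37.1%
```

The recovered difference (5.3 points) matches the planted 5% up to call
noise. `run_pipeline()` orchestrates all stages from a YAML config and
writes TSV outputs plus an md5 manifest; a thin command-line wrapper lives
in `inst/scripts/run_pipeline.R`.

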