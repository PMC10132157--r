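---
title: "Quantifying PSMA expression heterogeneity: models and methods"
author: "PSMAhet authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying PSMA expression heterogeneity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PSMAhet)
```

## The problem

Prostate-specific membrane antigen (PSMA, encoded by *FOLH1*) is the
target of an expanding family of radioligand imaging and therapy agents
for metastatic castration-resistant prostate cancer (mCRPC). Whether a
patient benefits depends not only on the average PSMA level but on how
uniformly the protein is expressed across that patient's metastases and
within each metastasis: a single PSMA-negative lesion escapes a
PSMA-directed therapeutic no matter how avid the others are. PSMAhet
provides the statistical machinery to quantify this two-level
heterogeneity from multi-site immunohistochemistry (IHC) cohorts, to
find transcriptional programs and candidate alternative targets
associated with PSMA-low disease across several RNA-seq cohorts, and to
relate *FOLH1* promoter/intronic methylation to expression.

## IHC scoring and classification

Each tissue core is scored on a 3-level chromogen intensity scale (0 =
none, 1 = faint, 2 = prominent). The H-score is the intensity-weighted
sum of the percentages of cells at each level,

$$H = 0\cdot p_0 + 1\cdot p_1 + 2\cdot p_2, \qquad p_0+p_1+p_2=100,$$

so it ranges 0–200 (three levels, not the 4-level 0–300 convention; the
level count and the cutoff are configuration parameters). Duplicate
cores from the same site are averaged (`aggregateCores()`); missing
cores are excluded from the denominator, never imputed as zero. A site
is *low/negative* when its (core-averaged) H-score is at most 20, and
*positive* strictly above 20; ties sit on the low/negative side because
the cutoff is defined inclusively.

Patients are classified by their site-level statuses
(`classifyPatientPattern()`): *uniformly low/negative* when every scored
site is ≤ 20, *uniformly high* when every site is > 20, and
*heterogeneous* otherwise. A single-site patient can be either uniform
class but never heterogeneous; such patients are retained in pattern
frequencies because real rapid-autopsy cohorts contain them (site counts
range from 1 to over 20).

AR/NE molecular subtypes (AR+/NE−, AR+/NE+, AR−/NE+, AR−/NE−) are
called from IHC of AR-axis markers (AR, NKX3.1) and neuroendocrine-axis
markers (synaptophysin, INSM1). The exact thresholds of the published
IHC classification are not standardised, so `subtypeThresholds()`
defaults to "axis positive if **any** axis marker has H-score > 20",
mirroring the PSMA cutoff; both the cutoffs and the any/all rule are
explicit parameters and are recorded in results, because this is a
genuinely open choice.

## The pair-difference heterogeneity index

For a unit (a patient with $N$ labelled metastatic sites, or a site
with $N$ individually classified cores) with category counts
$n_1,\dots,n_K$, the heterogeneity index is the exact probability that
two members drawn **without replacement** carry different labels:

$$D = 1 - \sum_k \frac{n_k(n_k-1)}{N(N-1)}.$$

$D = 0$ iff the unit is homogeneous and $D = 1$ iff all members differ.
It relates to the Gini–Simpson index $1-\sum_k p_k^2$ (a
with-replacement probability) by $D = \tfrac{N}{N-1}(1-\sum p_k^2)$ —
an identity the test suite verifies to $10^{-12}$, alongside exhaustive
agreement with brute-force pair enumeration for every composition with
$N \le 8$ and up to four categories. Shannon ($-\sum p_k \ln p_k$) and
Gini–Simpson indices are provided as companion measures and
cross-checked against `vegan::diversity()`.

### Cohort-level estimate

The cohort summary is the *mean outcome of 1,000 randomly sampled
pairs*: each draw picks a unit and then an unordered pair of its members
uniformly, and records whether the labels differ
(`cohortPairEstimate()`). Units with fewer than two labelled members
carry no pair information and are excluded (their number is reported via
`n_units_used`). Two weightings are supported:

* **unit** (default): units are drawn uniformly, so every patient
  contributes equally regardless of how many sites were sampled. The
  estimate converges to the equal-weight mean of the per-unit
  closed-form $D$.
* **pair**: units are drawn proportionally to their $\binom{N}{2}$
  member pairs, equivalent to pooling all pairs.

Equal patient weighting is the default because the cohort-level quantity
is heterogeneity summarized *across patients*, and pair weighting would
let heavily sampled patients dominate.

### BCa confidence limits

Confidence limits come from a nonparametric bias-corrected and
accelerated (BCa) bootstrap (`bcaInterval()`). Resampling is done at the
**unit** level (a cluster bootstrap over patients, or over sites for the
intratumoral level) to respect within-patient correlation. The
resampled statistic is the equal-weight mean of the per-unit
closed-form $D$ rather than a re-sampled pair mean: the estimand is the
same, but one layer of Monte Carlo noise is removed. The bias term
$z_0$ is the normal quantile of the fraction of bootstrap means below
the observed mean (half-counting ties); the acceleration $a$ is the
jackknife skewness $\sum d_i^3 / (6 (\sum d_i^2)^{3/2})$ over
leave-one-unit-out means. When the bootstrap distribution is degenerate
(for example, a cohort of identical homogeneous patients) the interval
collapses to zero width at the point estimate rather than producing
undefined quantiles. With $z_0 = 0$ and $a = 0$ the limits reduce to
percentile limits, and the implementation is cross-checked against
`boot::boot.ci(type = "bca")`.

Treatment-era comparisons of per-patient heterogeneity use the
two-sample Kolmogorov–Smirnov test (asymptotic two-sided p, which is
robust to the ties that discrete $D$ values produce; exact small-sample
p-values are out of scope) and Gaussian kernel density estimates with
Silverman's rule-of-thumb bandwidth for display (`eraComparison()`).

## Differential expression and consensus

Within each RNA-seq cohort, tumors are assigned to PSMA-low and
PSMA-high groups by splitting at the per-data-set mean of *FOLH1* FPKM
(`splitByMean()`). The mean is taken on the FPKM scale and samples
exactly at the mean go to the high group; both choices are documented
defaults for a rule whose tie behaviour and scale are otherwise
unspecified. Analyses are restricted to AR+/NE− tumors
(`restrictToSubtype()`) to avoid confounding by subtype-specific
expression.

Genes pass a minimum-expression filter (FPKM ≥ 1 in ≥ 20% of samples by
default; `filterMinExpression()`), then each gene is tested with a
two-sided Welch t-test on $\log_2(\mathrm{FPKM}+1)$
(`differentialExpression()`), with Benjamini–Hochberg adjustment over
the tested genes. This is a deliberate, recorded substitute for a
moderated (empirical-Bayes) linear-model fit: the package's
contribution is the cross-cohort consensus and target-refinement logic,
and any two-group test slots in behind the same interface. The
substitution and the pseudocount are written into the result metadata.
Fold change is $2^{|\Delta|}$ where $\Delta$ is the difference of group
means on the log scale; the +1 pseudocount is a parameter.

A **consensus gene** (`consensusGenes()`) must pass FDR ≤ 0.05 and fold
change > 2 *with the same direction* in at least 2 of the data sets.
Genes significant in opposite directions in different cohorts are
excluded and logged — the source rule does not state this case, and
directional consistency is the conservative reading. Target refinement
(`filterTargetLists()`) applies the same thresholds restricted to a
curated list (druggable-genome tier 1 or surfaceome), requiring support
in at least 1 data set; symbol matching is case-insensitive and
unmatched symbols are reported, never silently dropped. Ranked
shortlists sort by absolute mean fold change with alphabetical
tie-breaking (`rankByMeanFC()`), so the top-k is reproducible.

Protein–mRNA concordance (`regressProteinMrna()`) is an ordinary
least-squares fit with Pearson $r$, $r^2$, and a two-sided p from the t
distribution with $n-2$ df.

## Methylation

The COMPARE-MS assay enriches methylated DNA and quantifies it by qPCR.
The published description normalizes sample Ct values to a fully
methylated control and reports a 0–100% methylation index without
printing the formula; PSMAhet adopts the standard efficiency-1 doubling
model

$$\mathrm{MI} = 100 \times 2^{\,Ct_{\mathrm{control}} - Ct_{\mathrm{sample}}},$$

clipped to [0, 100] (clipping is flagged), with the amplification
efficiency exposed as a parameter. An undetermined sample Ct means no
methylated template amplified and yields MI = 0 with a flag; an
undetermined control is an error. MI halves per additional sample cycle
— `methylationIndex(23, 22)` is exactly 50%.

Per-CpG bisulfite calls are read from the Bismark coverage dialect
(`readBismarkCoverage()`; 1-based positions, with a converter for
0-based bedGraph-style input). The file's percentage column is checked
against the counts (0.1 tolerance) and then recomputed from counts.
Region-level methylation over a user-supplied interval — e.g. the
*FOLH1* intron-2 amplicon `chr11:49228686-49228864` (hg19) — is the
coverage-weighted mean $\sum m_i / \sum (m_i + u_i)$ over CpGs with
coverage ≥ 5 (`regionMethylation()`). DMR *discovery* is deliberately
out of scope; only summarization of supplied regions is provided.
Methylation–expression association reuses the OLS/Pearson contract with
methylation as the predictor.

## The synthetic-data generator

Because per-site H-scores and the cohort RNA-seq matrices behind the
original study are not public at desk scale, every pipeline stage is
validated against `simulateCohort()`, `simulateExpression()` and
`simulateMethylation()`, which plant known truth and record it in a
`truth` object. The defaults emulate the rapid-autopsy study design:

* 52 patients; per-patient site counts from a negative binomial
  (size 2.2, mean 8.5) truncated to [1, 21], which reproduces the
  published cohort shape (median 7 sites, range 1–21); 2 duplicate
  cores per site.
* Patient patterns drawn from (0.25, 0.44, 0.31) over uniform-low /
  heterogeneous / uniform-high — the observed study frequencies, used
  as a default, not a reproduction claim. `exactPatternCounts = TRUE`
  plants largest-remainder counts (13/23/16 at $n=52$) for exact
  recovery checks.
* Bimodal true H-scores: low component N(4, 4) truncated to [0, 20]
  (genuinely negative tumors cluster near zero), high component
  N(120, 45) truncated to (20, 200]. Core-level observation noise is
  N(0, 8), clipped to [0, 200]. Heterogeneous patients always receive
  at least two sites and at least one site of each component, so the
  planted label is recoverable exactly at zero noise.
* `intraHetFrac` (default 5%) of multi-core sites put cores on opposite
  components, planting intratumoral heterogeneity; without it,
  within-site heterogeneity would arise from noise alone and estimator
  tests would have no planted truth.
* Expression: three cohorts of 60 samples (half per H-score component,
  exact counts), per-gene baseline $\log_2$ FPKM ~ N(5, 1.5), sample
  noise SD 0.5, and 100 of 2,000 genes shifted by ±1 in opposite
  directions per group (a planted 4-fold change). The baseline is
  centred well above the +1 pseudocount so that planted fold changes
  are not artefacts of the log transform. *FOLH1* is linearly coupled
  to the latent H-score ($\log_2$ FPKM $= 1 + 0.02H$, noise SD 0.3), so
  the mean split recovers the planted groups imperfectly — by design,
  since the real mean split is also contaminated.
* Methylation: $\Delta Ct = 0.5 + 0.8\times \log_2(\mathrm{FPKM}_{FOLH1}+1)$
  plus N(0, 0.3) noise, floored at zero (a sample cannot amplify before
  the fully methylated control), giving the planted inverse
  methylation–expression relation.

What the generator does **not** emulate: spatial structure within
sections, batch effects, library-size artefacts, count-level noise
(FPKM values are drawn directly on the log scale), subtype–site
interactions, and pathologist-specific scoring bias. Passing tests
therefore demonstrate correctness of the statistical machinery under a
clean, known data-generating process, not robustness to every artefact
of real cohorts.

Distributional forms are the package's inventions; only the cohort
shape constants and H-score bimodality follow the published cohort
description. Every artifact of a run is a pure function of
`(config, seed)`, and all stochastic estimators require an explicit
seed, which is recorded in their results.

## Validation scale and numerical choices

The shipped test suite exercises, among others: exhaustive
oracle-vs-closed-form agreement for all label compositions with
$N \le 8$, $K \le 4$; the $D$–Gini–Simpson identity on 10,000 random
compositions; estimator recovery on a 200-patient cohort (100
replicates of 1,000 sampled pairs, within ±0.03 of the known
equal-weight mean); BCa coverage on 300 simulated 50-patient cohorts
against a population truth computed from one 20,000-patient cohort;
BH agreement with a brute-force step-up on 1,000 random p-vectors;
consensus recall/false-discovery operating characteristics over 20
seeds at the default plant and under a null plant; and a determinism
check of the end-to-end pipeline. These problem sizes were chosen so
the full suite runs in a few minutes on a single CPU while keeping
Monte Carlo error well below the tested tolerances.

Numerical conventions worth knowing: ties at the PSMA cutoff are
low/negative; samples exactly at the mean split go high; bootstrap
quantiles use R's type-7 interpolation; $z_0$ is clamped away from
±∞ when the bootstrap distribution is extremely one-sided; the
consensus mean fold change averages $2^{|\log_2 FC|}$ over supporting
cohorts only. In the consensus operating characteristics, *FOLH1*
itself is excluded from the false-discovery count because the grouping
is defined on it — its differential expression is planted by
construction, not discovered.

## Limitations

* The Welch substitute lacks empirical-Bayes variance moderation, so
  with very small groups (< 10 per arm) it is less powerful than a
  moderated fit; the consensus logic is unaffected.
* BCa intervals are known to be slightly anti-conservative for very
  small numbers of clusters; with fewer than ~20 eligible units the
  reported limits should be read cautiously.
* The COMPARE-MS index formula assumes amplification efficiency 1 per
  cycle; a mis-specified efficiency rescales the index monotonically
  but does not change sign or ordering of associations.
* Subtype thresholds are placeholders for an external classification
  whose exact IHC cutoffs are not published; they are surfaced in
  configuration and recorded in outputs.
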