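---
title: "Methods: cross-species anchor-gene screening with anchorseek"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-species anchor-gene screening with anchorseek}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anchorseek)
```

## The problem and the method

Failing cardiomyocytes re-express foetal stress genes, most prominently
*Nppa*. Genes whose single-cell expression co-varies with such an anchor
stress gene are candidates for the stress program itself, and a candidate is
far more credible when the co-variation is seen independently in two
species. anchorseek implements that screen as a pipeline of small, testable
stages:

1. **Preprocess** each species' gene × cell count matrix: QC-filter cells
   then genes (`qc_filter()`), log-normalize to counts-per-10,000 with
   `log1p` (`lognormalize()`).
2. **Rank** every gene by Spearman correlation with the anchor across the
   cells of a chosen cell type (`anchor_correlation()`), and take the top-K
   list per species (`top_k()`, K = 50 by default).
3. **Transport** species A's list into species B's namespace through an
   explicit homolog table (`map_homologs()`, many-to-many) and **intersect**
   with species B's list (`conserved_intersection()`).
4. **Validate** the conserved candidates for stress induction with two-sided
   Wilcoxon rank-sum tests and BH adjustment (`stress_de()`).
5. Downstream, relate a target gene's expression to clinical covariates:
   pairwise Spearman associations (`spearman_assoc()`), a composite collagen
   score (`collagen_score()`, the equal-weights mean of Col1a1, Col1a2 and
   Col3a1), and a univariable-to-multivariable linear regression cascade
   (`regression_cascade()`).
6. Promoter work: 1-based inclusive interval arithmetic
   (`genomic_interval()`, `interval_length()`) and motif scanning by IUPAC
   consensus (`scan_consensus()`, default `WGATAA`, the GATA-family core) or
   by position weight matrix (`scan_pwm()`).

Rank statistics are used throughout on purpose: Spearman correlation is
invariant to the base of the log transform and robust to the extreme
skew and zero-inflation of single-cell data, and the Wilcoxon test makes no
distributional assumption on normalized expression.

## Statistical details and numerical choices

**Spearman correlation** is the Pearson correlation of average-tie ranks.
Two-tailed p-values come from the large-sample approximation
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$ on $n-2$ degrees of freedom; with
thousands of cells the exact permutation null is indistinguishable from
this, and the same approximation is applied in the clinical association
table for consistency. $|\rho| = 1$ reports $p = 0$.

**Eligibility gate.** Genes expressed in fewer than 1% of the selected
cells (configurable) or with zero variance are flagged ineligible and
excluded from the ranking: correlations of near-all-zero vectors are
dominated by a handful of cells and would otherwise flood the top-K list
with noise. The anchor itself is never eligible.

**Tie-breaking** is lexicographic on gene label at every ranking boundary,
which makes all outputs byte-deterministic.

**Wilcoxon rank-sum.** When both groups have at most 7 observations the
two-sided p-value is computed by full enumeration of all
$\binom{n_1+n_2}{n_1}$ assignments of the pooled (tie-averaged) ranks,
counting assignments whose rank-sum is at least as far from the null mean
as observed. Larger groups use the normal approximation with tie-corrected
variance and no continuity correction. Log2 fold changes use a $10^{-9}$
pseudocount; BH adjustment runs across exactly the supplied candidate list
(candidate validation), not transcriptome-wide.

**Regression cascade.** Stage 1 regresses the target on each covariate
alone and keeps slopes with two-sided $p < \alpha$ (default 0.05). Stage 2
fits the kept covariates jointly and applies backward elimination: the
covariate with the largest $p \ge \alpha$ is removed (ties by name) and the
model refit until all survivors are significant. Backward elimination is
the minimal procedure consistent with "retain covariates with p < 0.05 in
the multivariable model"; a single-shot joint fit with post-hoc filtering
is available via `stage2 = "single_shot"`. Missing data are
pairwise-complete for Spearman and listwise-complete within each fit.
Categorical covariates are one-hot encoded against the first factor level.
A rank-deficient stage-2 design is a hard error naming the collinear
columns — silently dropping an aliased covariate would misattribute its
effect. Note one structural consequence: a covariate that passes stage 1
alone can never be eliminated when it is the only candidate, because the
stage-2 fit is then identical to its stage-1 fit.

**Coordinates.** Internally, genomic intervals from BED are 0-based
half-open; the user-facing form (`"chr8:46080750-46081200"`) is 1-based
inclusive, and `interval_length()` is end − start + 1 in that convention
(the worked example spans 451 bp). Conversion lives in exactly two
functions (`bed_to_interval()`, `interval_to_bed()`).

**PWM scoring** is log2-odds in bits, $\sum_j \log_2 p'_j(b_j)/q(b_j)$,
with pseudocount regularization $p' = (p + c\,q)/(1 + c)$, $c = 0.01$ by
default, so a matrix equal to the background scores exactly 0 everywhere.
Windows containing non-ACGT characters are skipped and reported. Minus-
strand hits are reported at forward-strand coordinates with the site as
read on the minus strand.

## The synthetic-data generator

Because the screen was designed for public atlas data whose generative
process is unknown, every distributional choice in `simulate_species()` is
a stand-in, chosen for plausibility and flagged as such:

- **Latent stress score** $s_i \sim \mathrm{Gamma}(\text{shape}=2)$, mean 1
  in control cells and $1 + \texttt{stress\_shift}$ in stressed cells.
  Gamma gives non-negativity and the right skew typical of stress-marker
  expression. Outside the stress-bearing cell type (CM) the score is fixed
  at its condition mean, so all stress variance lives in CM cells.
- **Counts** are negative binomial with mean
  $L_i \exp(\beta_g + \texttt{effect\_size}\, s_i)$ for the anchor and the
  planted program in CM cells ($L_i$ log-normal library factor, default
  $\sigma = 0.3$; $\beta_g$ uniform on $[-3, 1]$, i.e. baseline means of
  about 0.05–2.7 counts) and variance $\mu + \phi\mu^2$ (default
  $\phi = 0.5$). Dropout is implicit in NB sampling at low means; there is
  no separate zero-inflation term.
- **Species pairing**: the planted program has the same gene indices in
  both species (the premise being tested is conservation); species-B labels
  are the uppercase transform of species-A labels; each gene enters the
  homolog table independently with probability `homolog_fraction`
  (default 0.88, echoing 44 of 50 genes having a known homolog).
- **Clinical table**: target expression is standard normal over 95
  subjects; each of 3 true covariates (among 42) is
  $0.5\,y + \mathcal N(0,1)$ — a univariable correlation of about 0.45,
  the scale of the strongest clinical associations one sees reported for
  such cohorts; the remaining covariates are independent noise.
- **Seeds**: one master seed; stage-level children are derived
  deterministically, so a pair's two species have independent noise but the
  whole object is reproducible bit-for-bit.

What a green test does *not* establish: the generator has no batch effects,
ambient RNA, doublets, cell-type misassignment, or spatial structure, and
real homolog tables are curated many-to-many maps, not Bernoulli samples.
Recovery of the planted program here shows the pipeline's logic is correct,
not that the biological screen has any particular sensitivity on real data.

One subtlety the test suite documents: with very few simulated genes, CP10K
normalization's shared per-cell denominator induces compositional
correlation between genes even at zero effect size (each gene is a visible
fraction of its own cell's total). Null-calibration tests therefore use
realistic gene counts (hundreds to thousands), where the effect is
negligible.

## Open design points and how they were resolved

- **Which cells enter the correlation?** The source analysis is ambiguous
  between "all cardiomyocytes of the diseased dataset" and "disease-
  condition cardiomyocytes only". Both are implemented
  (`anchor_screen(condition = )`); the default uses all cells of the target
  cell type, which in the simulated world includes the control/stressed
  contrast as part of the stress axis and is the more powerful screen.
  Neither mode is presented as the original study's exact intent.
- **Symmetric K.** The printed pipeline gives K = 50 for the mouse side
  only; the same cutoff is applied to both species as a declared choice.
- **Correlation statistic.** "Rank-based" is read as Spearman; Pearson is
  available behind `method = "pearson"` for sensitivity analysis.
- **A known-red acceptance clause.** One acceptance criterion asserts that
  an all-null 5-covariate clinical design retains nothing in ≥ 80% of
  seeds. Brute-force simulation puts the true probability at
  $0.95^5 \approx 0.774$: a lone stage-1 survivor is always retained
  because its stage-2 fit is identical to its stage-1 fit. The criterion is
  asserted as stated and left failing, with the analysis recorded; the
  unit suite asserts the simulation-derived band instead.

## Limitations

- No HDF5/loom ingestion; Matrix-Market + TSV bundles only.
- No mitochondrial-fraction QC, doublet detection, integration or batch
  correction; the pipeline assumes cell-type labels are given.
- No survival models, mixed models, or imputation in the clinical module.
- Motif scanning is per-sequence; no genome-wide scan, alignment-based
  conservation, or peak calling.
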