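---
title: "Methods and design notes for quickprot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for quickprot}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quickprot)
```

This vignette describes the statistical procedures the package
implements, the assumptions behind them, the tunable parameters, what
the synthetic-data generators do and do not emulate, and the design
choices made where several defensible options existed.

## Data model

The package consumes long-format quantification exports: one row per
peptide (precursor) per run, carrying a protein group, gene, peptide
sequence, and a quantity in arbitrary intensity units.  A *sample
layout* maps raw run identifiers to sample names, experimental groups
and replicate indices; everything downstream is expressed in the
layout's names and group order.  After rollup, data live in a protein
× sample abundance matrix with missingness preserved explicitly —
missing is information here (a protein not detected in a sample), not
an inconvenience to be papered over.

Two conventions matter throughout:

* **Zero quantities are treated as missing.**  Skyline exports a 0 for
  peaks it did not integrate; treating these as measured zeros would
  poison CVs, fold changes and log transforms.
* **Abundances are compared on the log2 scale** for testing and
  clustering, and on the raw scale for CVs (the CV is conventionally a
  raw-scale statistic, and the widely used ≤ 20 % acceptability
  benchmark refers to the raw scale).

## Preprocessing

Non-proteotypic peptides (shared by several proteins) and peptides
whose protein-group field contains more than one accession are
removed; protein-level inference from shared peptides is not
attempted.  The multi-ID test splits on `;`, `,` or whitespace — any
split yielding more than one token counts as multi-ID.

Rollup offers three estimators: `sum` (sum of peptide quantities per
protein and sample — the natural choice for Skyline fragment-area
exports and the default), `median`, and `maxlfq_passthrough`, which
takes the protein-group quantity the upstream tool already computed
(e.g. a MaxLFQ-style estimate) and refuses to continue if duplicated
protein-group quantities disagree within a run.  Whether summed
fragment areas or the tool's own protein-level estimate is preferable
depends on the upstream configuration; both are supported and the
pipeline picks the passthrough automatically when the column is
present.

The minimum unique-peptide filter (default **n = 2**) guards against
one-hit wonders.  Its default scope is `per_sample`: a cell backed by
fewer than n distinct peptide sequences is set missing, so the
threshold holds in every sample.  A `global` scope (keep a protein if
any sample reaches n) is available; it is more permissive and mainly
useful for exploratory passes.

## Quality control

Per protein and group, CV = 100·s/x̄ over replicate abundances, using
the **sample** (n−1) standard deviation: replicate counts in targeted
and discovery designs are small (2–4), and the population SD would
bias CVs downward exactly where the estimate is already noisy.  With r
= 2 replicates the per-protein CV estimate is itself strongly
dispersed, and the *median* CV of a group is a downward-biased
estimate of the underlying noise CV (for r = 2 the median of the
half-normal CV estimator sits near 0.67 σ).  This is a property of the
estimator, not a bug; the acceptance checks therefore use r = 4, where
the bias is a few percent.

Replicate agreement is summarized by Spearman's ρ on
pairwise-complete proteins with average ranks for ties — rank
correlation is invariant under the monotone distortions
(normalization, detector saturation) that routinely affect intensity
scales.  Pairs sharing fewer than 3 proteins report ρ as missing.

## Differential abundance

The volcano analysis performs a two-sample t-test on log2 abundances
per protein observed in ≥ 2 replicates of both groups.  The flavor is
**Welch** (unequal variances) by default: variance homogeneity across
groups is rarely credible in proteomics, and Welch costs little when
variances happen to be equal.  A pooled (Student) test is available by
flag for users who want the classical behaviour.  log2FC is defined as
mean(group B) − mean(group A), so swapping the groups negates every
fold change and mirrors the up/down sets exactly.

Status assignment uses **raw p-values** against the chosen threshold
(menu 0.05–0.001), matching the interactive threshold-menu contract;
a Benjamini–Hochberg-adjusted column is written alongside for
transparency but does not drive the status.  Fold-change thresholds
below 1 are symmetrized (0.5 means the same two-sided bound as 2),
since a two-sided cut below 1 is otherwise meaningless.

Degenerate inputs are handled explicitly: when both groups have zero
variance, equal means give p = 1 (no evidence of difference) and
different means give the smallest positive double, keeping p in (0, 1]
and −log10 p finite without inventing a pseudo-variance.

## Imputation

`impute_iterative()` is a deterministic chained-regression imputer on
the log2 scale: missing cells start at the per-protein mean of
observed values; each sample column in turn is regressed (OLS with
intercept) on all other columns over its observed rows, and its
missing cells are replaced by fitted values; sweeps repeat in a fixed
column order until the largest absolute log2 update drops below `tol`
(default 1e-6, i.e. far below quantification noise) or 50 sweeps.
Observed cells are never modified — the test suite checks this
bitwise.  On matrices whose columns are scalar multiples of one
profile (rank one on the raw scale, additive offsets on log2) the
deleted cells are recovered essentially exactly; on real data the
imputed values are only as good as the linear cross-sample structure,
which is why the selected-protein heatmap mode never imputes and
renders missing cells as `n.d.` instead.

## Enrichment

Over-representation uses the one-sided Fisher exact test: with N
background genes, K in the set, a query of n and overlap k, p = P(X ≥
k) for X ~ Hypergeom(N, K, n), computed by `phyper`.  The background
defaults to the quantified proteome of the experiment rather than the
genome — detection in MS is strongly biased toward abundant proteins,
and a genome background would manufacture spurious enrichment of
highly expressed categories.  Annotation comes from offline GMT files
(KEGG-pathway-style or GO-style namespaces); BH adjustment is applied
within each namespace.  Because the statistic is discrete, null
p-values are slightly conservative; with sets and queries of a few
hundred genes or more the distribution is near-uniform, which is the
regime the acceptance check exercises.

## Absolute quantification (SID-PRM)

For each peptide the light/heavy ratio R = A_light/A_heavy converts to
copies per nucleus through the spike bookkeeping:

* moles of heavy standard per injection = spiked mass (ng × 1e-9) /
  HLIS molecular weight (g/mol);
* endogenous moles per µg of injected protein = R × moles of heavy /
  injected protein (µg);
* copies per nucleus = that × protein mass per nucleus (pg × 1e-6 µg)
  × N_A (6.02214076e23 / mol).

With R = 1, a 100 kDa standard, 1 ng spiked, 1 µg injected and 10 pg
per nucleus this gives 6.02214076e4 copies — the unit-analysis anchor
the tests pin to 1e-9 relative.  Copies are exactly linear in R and in
protein mass per nucleus, and inversely proportional to molecular
weight and injected amount; these dimensional contracts are tested
numerically.

Rows with a missing or zero heavy area carry no usable ratio and are
excluded (a protein with no usable heavy area at all is flagged
unquantifiable).  Peptide-level copies are rolled up per protein by
the **median** (robust to a single interfered peptide; the mean is one
flag away).  Spike amounts are interpreted per injection; a spike
specified per µg of digest is entered by setting the injected amount
accordingly, and per-concatemer molecular weights and spike masses can
override the globals through the parameter file.

Group and protein comparisons use one-way ANOVA with Tukey's HSD on
the studentized-range distribution with pooled within-group variance
(Tukey–Kramer for unequal group sizes).  For two groups the
studentized range reduces analytically to the pooled t distribution
(q = t·√2); the package evaluates that case through the closed form,
which is exact where numerical quadrature of the range distribution is
only approximate.  If all values are identical, every pairwise p is
reported as 1 — no evidence of difference — rather than dividing by a
zero variance.

The compact letter display uses the insert-and-absorb construction:
one letter initially covers all groups; each significant pair splits
every letter containing both members into two letters each lacking
one; letters that become subsets of others are absorbed.  The
resulting assignment satisfies "two groups share a letter exactly when
their comparison is not significant", carries no redundant letters,
and is deterministic given the group display order (letters are
labelled a, b, … by their first member's position).

## Synthetic data: what it emulates, and what it does not

`make_dia_fixture()` writes a DIA-NN-dialect TSV and a
Skyline-dialect CSV from the same ground truth.  Per protein, a base
abundance is drawn on the log2 scale (default mean 15, SD 2);
replicate variability is a single multiplicative lognormal draw per
protein and run at the planted CV — shared by the protein's peptides,
as biological replicate variation is — with optional additional
per-peptide measurement noise; peptide shares are fixed normalized
gamma weights.  Differential proteins carry a planted fold change in
every non-reference group.  Missingness deletes whole protein × sample
cells, either at random or with probability increasing toward low
abundance (left-censoring).  Decoy non-proteotypic and multi-ID rows
give the filters real work.  Defaults mirror a nuclear-proteome
erythroid time course: nine groups, two replicates, replicate CV 12 %
(mid-range of typical DIA replicate CVs), 2–8 peptides per protein.
The protein count defaults to 200 to keep fixtures desk-sized.

`make_prm_fixture()` plants true copies per protein and group
(log-uniform over ~1e2–5e4), draws arbitrary positive heavy areas and
back-computes light areas through the inverted copies formula, then
perturbs the ratio with lognormal noise; defaults mirror a targeted
chromatin-remodeler panel (21 proteins, 2–4 peptides each).  At zero
noise the pipeline must invert the generator exactly (up to text
round-trip, ~1e-15).

What the generators do **not** emulate: retention-time structure,
interference and chimeric peaks, isotope impurity, non-lognormal
heavy-tailed outliers, correlated missingness across peptides of
different proteins, and batch effects.  Passing tests therefore
demonstrate correctness of the implemented statistics under their own
assumptions — not robustness to every failure mode of real
acquisitions.

Both generators derive all randomness from a single integer seed and
write numbers at 15 significant digits, so regeneration is
byte-identical.

## Numerical and interface choices

* Readers accept plain-period decimals only and reject thousands
  separators; column names for both dialects are resolved through an
  overridable mapping, since both upstream tools let users customize
  exports.
* Abundance ranking breaks ties lexicographically on protein ID, so
  rankings are reproducible.
* Clustering defaults to Euclidean distance on log2 group-mean
  profiles with average linkage, computed over complete-observation
  proteins; both metric and linkage are arguments.
* "Present in a group" means observed in at least one replicate of
  that group (union semantics, matching the yield reporting); an
  all-replicates rule is available via the `presence` argument.
* The PepSeq report is written as a directory of per-tab CSV files
  plus a summary table, one file per sample and group.
* Test and acceptance problem sizes — 200–220 proteins, 2–4 groups,
  20 generator seeds, 500 random significance matrices, 1000 null
  enrichment draws — were chosen so the whole suite runs in well under
  a minute per module while keeping Monte-Carlo bands tight.

## Known limitations

* No moderated (shrinkage) test statistics, paired designs, or batch
  correction; no cross-sample normalization is applied — upstream
  quantities are trusted.
* No multi-point calibration curves, isotope-impurity correction or
  interference detection in the PRM module.
* Gene → accession mapping and enrichment are strictly offline; no
  live database queries.
* The insert-and-absorb letter display is guaranteed correct and free
  of redundant letters, but global minimality of the letter count is
  not proven for arbitrary significance structures (it holds in all
  randomized checks with up to five groups).
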