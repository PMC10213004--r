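---
title: "Methods: multi-omic miRNA target nomination and microglial cell states"
author: "mirshift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-omic miRNA target nomination and microglial cell states}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirshift)
```

# The problem

A microRNA represses many genes weakly rather than a few genes strongly,
so no single assay identifies its targets reliably. The strategy
implemented here triangulates: a gene is *nominated* as a putative
target only when (i) it is predicted in silico by several algorithms
and supported by AGO-CLIP binding evidence, and (ii) it sits in the top
fraction of features *anticorrelated* with the miRNA in a perturbation
experiment — upregulated proteins/transcripts after miRNA knock-down
(KD), downregulated after overexpression (OE). The motivating system is
mmu-miR-132-3p in mouse hippocampus, where the nominated targets
converge on microglia; the second half of the package therefore
analyses microglial cell states (homeostatic, DAM, IRM, CRM, cycling)
with signature scoring, composition-shift testing and pseudotime
trends.

# Seed-match sites and the binding-site census

For a mature miRNA written 5'→3', the *seed* is positions 2–7 (the
extended seed 2–8). The canonical target-strand site strings are

* 6mer — reverse complement of positions 2–7;
* 7mer-m8 — reverse complement of positions 2–8;
* 7mer-A1 — 6mer followed by an `A` (the adenosine opposite position 1);
* 8mer — 7mer-m8 followed by that `A`.

```{r}
seed_patterns("UAACAGUCUACAGCCAUGGUCG", name = "mmu-miR-132-3p")
```

Because the 8mer contains both 7mers and the 6mer, a naive scan counts
one 8mer locus four times. `scan_sequences()` therefore reports each
locus once with its *most specific* type (precedence 8mer > 7mer-m8 >
7mer-A1 > 6mer) and suppresses lower-precedence matches nested inside a
reported site; distinct, non-nested sites may still overlap. `N` never
matches; IUPAC ambiguity codes other than `N` are rejected rather than
guessed at. Offset-6mers and non-canonical (seedless or
3'-compensatory) sites are deliberately out of scope: only the four
canonical classes are censused, and the "6mer" class is strictly
positions 2–7. Coordinates are 1-based inclusive on the supplied
sense-strand UTR.

`summarize_census()` aggregates hits per evidence group (e.g.
proteomics-derived vs transcriptomics-derived vs non-changing targets):
mean ± SEM of total sites per target, and mean ± SEM of per-target
type proportions. Targets with zero sites count toward the totals (as
0) but are excluded from proportion averages, where their proportions
are undefined.

# The nomination cascade

* `select_predicted()` — a gene is predicted when at least
  `min_predictors` (default 2) of the prediction algorithms flag it
  *and* its CLIP evidence count reaches `min_clip`. The
  high-confidence CLIP cutoff is not a published number; the default of
  3 supporting experiments is this package's choice and is a plain
  argument.
* `top_fraction()` — features ranked by log fold change (not by signed
  t statistic), `k = ceiling(q * N)` selected; the ceiling convention
  reproduces 6116 → 306 and 5995 → 300 at `q = 0.05`. Boundary ties
  break by smaller p, then lexicographic id, so selections are
  reproducible. The fraction is taken over the full ranking, not only
  over features with the anticipated sign.
* `nominate()` — the intersection of the selected and predicted sets;
  `overlap_summary()` does the cross-dataset bookkeeping (union,
  membership matrix, proteomics∩transcriptomics).

For single-cell datasets the "selected" set is the significant,
anticorrelated DEGs per cell type from `wilcoxon_de()` (adjusted
p < 0.05, sign opposite to the miRNA change).

# Proteome differential abundance

`preprocess_proteome()` applies the presence filter — a protein must be
observed in at least 75% of the samples of *every* group — then scales
each sample to a non-missing total of 10^6 (RPM). Missing values are
explicit `NA`, never zero, which is what makes the presence filter
meaningful. Outlier samples are not detected automatically: exclusion
is an explicit argument, because outlier calls in practice come from a
human looking at a PCA.

`protein_de()` tests `log2(RPM + 1)` group means (the +1 offset is this
package's choice; it only matters for very dim proteins). The default
moderated method shrinks per-protein variances toward a pooled prior
estimated from the spread of log sample variances (empirical-Bayes
moderated t, delegated to limma), which stabilises inference at
n ≈ 10 per group; a plain Welch t is available for comparison, and the
two agree closely at large n when protein variances are heterogeneous.
Benjamini–Hochberg adjustment runs over the proteins actually tested;
proteins with fewer than two observations in a group get `NA` and do
not inflate the burden.

# Single-cell pipeline

QC (`qc_filter()`) removes cells expressing fewer than 500 genes, cells
with a mitochondrial UMI fraction above 0.15, and doublets (score
above 0.25). All three boundaries are strict in the stated direction —
a cell at exactly 500 genes or exactly 15% mitochondrial reads is
kept. Normalisation (`normalize_cells()`) scales each cell to 10^4
UMIs and applies `log1p`.

`wilcoxon_de()` is a two-sided rank-sum test per gene. When both sides
have at most 12 cells the p value is *exact*, computed from the
tie-aware permutation distribution of the rank sum (a dynamic program
over doubled midranks, so ties cost nothing in accuracy); larger
comparisons use the normal approximation with tie and continuity
corrections. The fold change is the Seurat-style natural log of
pseudocounted means of de-logged normalised values,
`ln((mean(expm1 x_A) + 1) / (mean(expm1 x_B) + 1))`. Every gene
expressed in at least one cell of the subset is tested; the default
multiplicity correction is Bonferroni (matching the headline usage),
with BH and an all-genes burden available by flags, since published
descriptions alternate between the two. `find_markers()` applies the
same test one-vs-rest per cluster, prefiltered at logFC > 0.25, with
markers defined as logFC > 0.5 (natural log) and p < 0.05.

# Cell-state analysis

`module_score()` is the binned-control signature score: genes are
binned into 24 groups by mean expression (on expression *rank*, so
bins are near-equally occupied), and each signature gene contributes
100 control genes sampled from its own bin. The score is the mean
signature expression minus the mean control expression per cell, which
cancels per-cell depth and overall expression level; forcing the
control pool to equal the signature yields exactly zero, a useful
self-test. The control draw is seeded, so scores are reproducible.
`assign_states()` labels each cell by the argmax score — deliberately
*not* re-clustering, since cluster annotation by these very scores is
how states are defined in practice — with ties broken by signature
name order and flagged.

`composition_test()` tests a state's proportion between two conditions
with the 1-df Pearson chi-squared on the 2×2 (state vs rest ×
condition) table. Yates continuity correction is off by default (the
convention is configurable); a permutation p from label shuffles is
available as a finite-sample check. Note that the permutation
distribution lives on a lattice and includes the equality mass, so it
tracks the *continuity-corrected* asymptotic p; the uncorrected p is
smaller by roughly the lattice mass at the observed table.

`pseudotime_trends()` takes externally computed pseudotime values in
[0, 1] (trajectory inference itself is out of scope) and returns, per
gene and condition, a sliding-window mean over a fixed grid of 50
window centres with half-width 1.5 grid steps; windows with fewer than
5 cells are linearly interpolated from their neighbours and flagged
rather than silently reported.

# Enrichment and qPCR utilities

`fisher_enrichment()` is the one-sided hypergeometric test per
annotation set, BH-adjusted across sets, with the additional coverage
filter that a passing set must contain at least 1% of the query. The
default universe is the union of the annotation sets and the query;
an explicit background can be supplied. `ddct()` implements
relative-quantification fold changes: per sample
ΔCt = Ct(gene) − mean Ct(housekeeping genes) (arithmetic mean of Ct,
i.e. geometric mean of expression), ΔΔCt across groups, fold =
2^(−ΔΔCt). The fold is invariant to global Ct offsets and inverts when
treated and calibrator swap.

# The synthetic study

Every stage is testable offline because `sim_config()` +
`gen_utrs()` / `gen_evidence()` / `gen_proteome()` / `gen_sc()`
generate all inputs with planted ground truth. The defaults *are* the
study conditions the pipeline is validated under:

| knob | default | why |
|---|---|---|
| gene universe / true targets | 2000 / 50 | desk-scale analogue of a 6k proteome with tens of targets |
| repression effect | 1 log2 unit | a clearly planted but not caricatural miRNA effect |
| proteome noise SD | 0.5 log2, n = 10/group | matches the power regime of ~10 animals/group |
| predictor sensitivity/specificity | 0.9 / 0.95, 7 predictors | realistic per-algorithm operating point |
| CLIP evidence | Poisson(6) true / Poisson(0.5) false | separates cleanly at the ≥3-experiments cutoff |
| cell states | homeostatic / DAM / IRM, DAM 10% → 20% | the composition shift the state arm must detect |
| counts | NB (dispersion 0.4), log-normal library sizes | standard scRNA noise model |

One master seed drives an independent, label-hashed RNG stream per
artifact (UTRs, evidence, proteome, per-condition cells, the shared
expression profile), so enlarging one artifact never perturbs another
and identical configurations yield byte-identical fixture bundles
(`write_fixture_bundle()` writes FASTA/TSV/MTX/GMT/JSON plus an md5
manifest). UTR backgrounds are i.i.d. with the configured GC; planted
sites are placed by rejection so they never overlap, and their exact
positions are recorded — by construction every planted string is
findable by substring search, though the scanner may legitimately
report an upgraded type when background bases happen to extend a
planted site. State programs avoid true-target genes so the two layers
of planted signal remain separable.

What the generator does *not* emulate — and hence what passing tests
cannot certify about real data: ambient RNA and soup, batch effects
between runs, UMI saturation, cell-type misannotation, correlated
predictor errors, peptide-level missingness structure, or
spectral-level proteomics artifacts. Results on real data depend on
upstream steps (mapping, clustering, doublet scoring, trajectory
inference) that are explicitly inputs here.

# Numerical choices and degenerate inputs

* Exact rank-sum enumeration is capped at 12 cells per side
  (24-cell DP, cached across genes by tie pattern); beyond that the
  tie/continuity-corrected normal approximation takes over. All-tied
  comparisons return p = 1.
* `top_fraction()` and `assign_states()` break ties deterministically
  (p then id; signature name order), never randomly.
* Degenerate 2×2 margins, empty groups, sub-minimum cell counts and
  missing housekeeping measurements return `NA`/empty results with
  warnings instead of errors wherever an analysis can sensibly
  continue.
* The chi-squared closed form is computed in double precision from the
  start; integer tables as large as whole-tissue atlases cannot
  overflow it.

# Problem sizes used in the shipped checks

The package's own validation (test suite and `scripts/acceptance.R`)
runs at desk scale, chosen to finish in minutes on one CPU while
keeping every statistical claim testable: 1000 random 500-nt UTRs for
the scanner-vs-oracle identity; 200 random small-group instances for
the exact Wilcoxon identity; 20 simulated studies for nomination
recall/precision; 2000 null and 500 shifted replicates at 1500
cells/condition for composition-test calibration and power; 600–1200
cells and 600–1000 genes for the state-scoring checks.

# Known limitations

* The nomination cascade treats identifiers as a case-sensitive exact
  namespace; ortholog or alias mapping is the caller's responsibility.
* The moderated test assumes roughly exchangeable per-protein
  variances; with strongly homoscedastic data its p values differ
  slightly from Welch's by design (stronger pooling).
* The binding-site census counts sites, not efficacy: no context
  scoring, conservation, or thermodynamics.
* Signature gene lists ship as editable GMT files; the shipped
  synthetic programs are placeholders for user-curated state
  signatures, not a published signature set.
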