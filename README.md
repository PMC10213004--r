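# mirshift

Multi-omic nomination of microRNA targets and microglial cell-state
analysis, with a synthetic-data generator that makes the entire
pipeline testable end to end against planted ground truth.

## The problem

MicroRNAs repress many genes weakly, so no single assay identifies
their targets reliably. `mirshift` implements a triangulating pipeline
(motivated by mmu-miR-132-3p in mouse hippocampus): a gene is
nominated as a putative target only when

1. **predicted** — flagged by at least *m* of several target-prediction
   algorithms **and** supported by at least *c* AGO-CLIP experiments
   (`select_predicted()`, defaults *m* = 2, *c* = 3), and
2. **anticorrelated** — among the top fraction *q* of features moving
   against the miRNA perturbation: ranked by log fold change,
   `k = ⌈qN⌉` selected (`top_fraction()`, default *q* = 0.05; up after
   knock-down, down after overexpression),

with `nominate()` taking the intersection and `overlap_summary()` the
cross-dataset bookkeeping. Around this core the package provides:

* **seed-site census** — canonical site strings for a miRNA seed
  (8mer = rc(2–8)+A, 7mer-m8 = rc(2–8), 7mer-A1 = rc(2–7)+A,
  6mer = rc(2–7)), a UTR scanner with most-specific-type precedence,
  and per-group mean ± SEM site summaries;
* **proteomics** — 75%-per-group presence filter, RPM normalisation,
  empirical-Bayes moderated t (or Welch) on log2(RPM+1),
  Benjamini–Hochberg adjustment;
* **single cell** — QC (≥500 genes, ≤15% mito, doublet score ≤0.25),
  10^4-UMI log normalisation, two-sided Wilcoxon rank-sum DE per cell
  type (exact and tie-aware up to 12 cells per side), one-vs-rest
  marker detection, pseudobulk-vs-proteome Pearson concordance;
* **cell states** — binned-control module scores (24 bins, 100
  controls/gene), argmax state assignment, 2×2 chi-squared (and
  permutation) composition-shift tests, sliding-window pseudotime
  trends;
* **utilities** — hypergeometric set enrichment with a ≥1%-of-query
  coverage filter, BH adjustment, ΔΔCt qPCR fold changes
  (fold = 2^(−ΔΔCt));
* **synthetic data** — `sim_config()` and `gen_*()` plant true targets,
  seed sites, predictor/CLIP evidence, proteome shifts and
  negative-binomial cell states so every stage can be validated
  without any download.

## Worked example

Nominate targets from a simulated knock-down study and census their
binding sites:

```r
library(mirshift)

seed_patterns("UAACAGUCUACAGCCAUGGUCG", name = "mmu-miR-132-3p")
#> <site_patterns> mmu-miR-132-3p miRNA UAACAGUCUACAGCCAUGGUCG
#>       8mer    7mer-m8    7mer-A1       6mer
#> "GACUGUUA"  "GACUGUU"  "ACUGUUA"   "ACUGUU"

cfg      <- sim_config(seed = 1)          # 2000 genes, 50 true targets
truth    <- sim_truth(cfg)
evidence <- gen_evidence(cfg, truth)
prot     <- gen_proteome(cfg, truth, direction = "KD")
de       <- protein_de(preprocess_proteome(prot$intensity, prot$groups))
ranked   <- data.frame(id = de$protein, logFC = de$log2FC, p = de$p)
putative <- nominate(top_fraction(ranked, q = 0.05, direction = "up"),
                     select_predicted(evidence, min_predictors = 2,
                                      min_clip = 3))
length(putative)                          #> 43
mean(putative %in% truth$true_target_ids) #> 1     (precision)
mean(truth$true_target_ids %in% putative) #> 0.86  (recall)

pats  <- seed_patterns("UAACAGUCUACAGCCAUGGUCG")
utrs  <- gen_utrs(cfg, pats, truth)
hits  <- scan_sequences(utrs$utrs, pats)
grp   <- ifelse(names(utrs$utrs) %in% putative, "Proteomics", "Non-changing")
summarize_census(hits, setNames(grp, names(utrs$utrs)))$totals
#>                     group   n mean_sites  sem_sites
#> Proteomics     Proteomics  43  2.1860465 0.06865109
#> Non-changing Non-changing 157  0.1910828 0.04530348
```

The nominated genes carry ~2.2 planted seed sites each versus ~0.2
background hits in non-changing genes. The cell-state arm on the same
planted study:

```r
cfg2  <- sim_config(seed = 1, n_genes = 1000, n_true_targets = 20,
                    n_cells_per_condition = 600, genes_per_program = 30,
                    program_strength = 2)
tr    <- sim_truth(cfg2)
ctrl  <- gen_sc(cfg2, tr, condition = "control",   direction = "KD")
pert  <- gen_sc(cfg2, tr, condition = "perturbed", direction = "KD")
cells <- cell_bundle(cbind(ctrl$counts, pert$counts),
                     rbind(ctrl$meta, pert$meta))
cells <- normalize_cells(qc_filter(cells, min_genes = 50))

scores <- score_signatures(cells, tr$state_programs, seed = 1)
states <- assign_states(scores)
shift  <- composition_test(states$state, cells$meta$condition, "DAM")
shift$table
#>            in_state
#> conditions  DAM other
#>   control    63   495
#>   perturbed 131   423
sprintf("chi-squared = %.2f, p = %.2g", shift$statistic, shift$p)
#> "chi-squared = 29.47, p = 5.7e-08"
```

The simulated DAM expansion (10% → 20% of microglia) is detected with
χ² = 29.5 on the 2×2 state-by-condition table.

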