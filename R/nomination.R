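## The target-selection cascade: predictor/CLIP selection, top-fraction
## anticorrelation selection, cross-omic intersection and overlap
## bookkeeping, plus cell-type annotation summaries.

#' Select in silico predicted targets from an evidence table
#'
#' A gene is a predicted target when it is flagged by at least
#' `min_predictors` prediction algorithms *and* its AGO-CLIP evidence
#' count (number of supporting CLIP experiments) reaches `min_clip` —
#' the high-confidence threshold.
#'
#' @param evidence data.frame with a `gene` column, predictor flag
#'   columns `pred1..predK` (logical or 0/1) and an integer
#'   `clip_evidence` column.
#' @param min_predictors minimum number of agreeing predictors (default
#'   2).
#' @param min_clip minimum CLIP evidence count (default 3).
#' @return character vector of selected gene identifiers.
#' @export
select_predicted <- function(evidence, min_predictors = 2L, min_clip = 3L) {
  cols <- grep("^pred[0-9]+$", names(evidence), value = TRUE)
  if (!length(cols))
    stop("no predictor columns (pred1..predK) found in evidence table")
  if (!all(c("gene", "clip_evidence") %in% names(evidence)))
    stop("evidence table must have `gene` and `clip_evidence` columns")
  if (min_predictors < 1L || min_predictors > length(cols))
    stop("min_predictors must lie in [1, ", length(cols), "]")
  flags <- as.matrix(evidence[cols])
  if (!all(flags %in% c(0, 1)))
    stop("predictor columns must be logical or 0/1")
  hits <- rowSums(flags) >= min_predictors & evidence$clip_evidence >= min_clip
  sort(evidence$gene[hits])
}

#' Top fraction of a ranked feature table
#'
#' Returns the `ceil(q * N)` features with the most extreme log
#' fold-change: the largest for `direction = "up"`, the smallest for
#' `"down"`.  Ties at the selection boundary are broken by smaller p
#' value, then lexicographic identifier, so the selection is
#' deterministic.
#'
#' @param ranked data.frame with columns `id`, `logFC` and (optionally)
#'   `p`.
#' @param q fraction to select, in (0, 1); default 0.05.
#' @param direction `"up"` or `"down"`.
#' @return character vector of selected identifiers (length
#'   `ceiling(q * nrow(ranked))`).
#' @export
top_fraction <- function(ranked, q = 0.05, direction = c("up", "down")) {
  direction <- match.arg(direction)
  stopifnot(q > 0, q < 1, all(c("id", "logFC") %in% names(ranked)))
  if (!nrow(ranked)) {
    warning("empty ranked table; returning empty selection")
    return(character(0))
  }
  p <- if ("p" %in% names(ranked)) ranked$p else rep(0, nrow(ranked))
  p[is.na(p)] <- Inf
  key <- if (direction == "up") -ranked$logFC else ranked$logFC
  key[is.na(key)] <- Inf
  ord <- order(key, p, ranked$id)
  k <- ceiling(q * nrow(ranked))
  ranked$id[ord[seq_len(k)]]
}

#' Nominate putative targets
#'
#' The intersection of a perturbation-selected feature set (e.g. the top
#' 5% proteins anticorrelated to the miRNA) with the in silico predicted
#' target set.
#'
#' @param selected,predicted character vectors over the same identifier
#'   namespace (case-sensitive exact match).
#' @return sorted character vector, `selected` intersect `predicted`.
#' @export
nominate <- function(selected, predicted) {
  sort(intersect(selected, predicted))
}

#' Overlap bookkeeping across datasets
#'
#' Given per-dataset putative-target sets (named list, e.g. `prot_KD`,
#' `prot_OE`, `sc_KD`, `sc_OE`), computes the union, a membership
#' matrix, all pairwise intersection sizes, the global intersection, and
#' the cross-omic intersection of (proteomics union) with
#' (transcriptomics union), where dataset names starting with `prot`
#' count as proteomics and the rest as transcriptomics.
#'
#' @param sets named list (>= 2) of character vectors.
#' @return list with `union`, `n_union`, `membership` (logical matrix
#'   gene x dataset), `pairwise` (matrix of intersection sizes),
#'   `global_intersection` and `cross_omic` (character vector).
#' @export
overlap_summary <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 2L, !is.null(names(sets)))
  sets <- lapply(sets, unique)
  u <- sort(Reduce(union, sets))
  membership <- vapply(sets, function(s) u %in% s, logical(length(u)))
  if (length(u) == 1L) membership <- matrix(membership, nrow = 1L,
                                            dimnames = list(u, names(sets)))
  rownames(membership) <- u
  k <- length(sets)
  pairwise <- matrix(0L, k, k, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(k)) for (j in seq_len(k))
    pairwise[i, j] <- length(intersect(sets[[i]], sets[[j]]))
  prot <- grepl("^prot", names(sets))
  cross <- if (any(prot) && any(!prot)) {
    sort(intersect(Reduce(union, sets[prot]), Reduce(union, sets[!prot])))
  } else character(0)
  list(union = u, n_union = length(u), membership = membership,
       pairwise = pairwise,
       global_intersection = sort(Reduce(intersect, sets)),
       cross_omic = cross)
}

#' Cell-type annotation percentages of a gene set
#'
#' Tabulates consensus cell-type expression labels over a gene set.
#' Genes may carry several labels; each (gene, label) assignment
#' contributes one unit, genes without annotation fall into an
#' `"unknown"` bucket, and percentages sum to 100 over labels.
#'
#' @param genes character vector of gene identifiers.
#' @param annotations named list mapping gene -> character vector of
#'   cell-type labels.
#' @return data.frame with columns `cell_type`, `n_assignments`,
#'   `percent`.
#' @export
annotate_celltypes <- function(genes, annotations) {
  stopifnot(is.character(genes), is.list(annotations))
  labels <- lapply(genes, function(g) {
    lab <- annotations[[g]]
    if (is.null(lab) || !length(lab)) "unknown" else unique(lab)
  })
  tab <- table(unlist(labels))
  out <- data.frame(cell_type = names(tab),
                    n_assignments = as.integer(tab),
                    percent = 100 * as.integer(tab) / sum(tab),
                    stringsAsFactors = FALSE)
  out[order(-out$percent, out$cell_type), , drop = FALSE]
}
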