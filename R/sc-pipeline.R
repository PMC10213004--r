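## Single-cell QC, normalisation, Wilcoxon differential expression,
## marker detection and proteome concordance.

#' Bundle single-cell counts with cell metadata
#'
#' Light container tying a genes x cells count matrix to per-cell
#' metadata (and, after [normalize_cells()], a normalised matrix).
#'
#' @param counts genes x cells matrix of non-negative integer counts
#'   (dense or [Matrix::Matrix]).
#' @param meta data.frame with one row per cell; must contain a
#'   `condition` column, and for QC a `mito_frac` and (optionally)
#'   `doublet_score` column.  A `cell_type` column is required for
#'   per-cell-type testing.
#' @return object of class `cell_bundle`.
#' @export
cell_bundle <- function(counts, meta) {
  counts <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
  stopifnot(ncol(counts) == nrow(meta))
  if (any(counts@x < 0) || any(counts@x != round(counts@x)))
    stop("counts must be non-negative integers")
  if ("mito_frac" %in% names(meta) &&
      any(meta$mito_frac < 0 | meta$mito_frac > 1, na.rm = TRUE))
    stop("mito_frac must lie in [0, 1]")
  if (is.null(colnames(counts)) && "barcode" %in% names(meta))
    colnames(counts) <- meta$barcode
  structure(list(counts = counts, meta = meta, norm = NULL),
            class = "cell_bundle")
}

#' @export
print.cell_bundle <- function(x, ...) {
  cat("<cell_bundle>", nrow(x$counts), "genes x", ncol(x$counts), "cells",
      if (!is.null(x$norm)) "(normalised)" else "(raw)", "\n")
  invisible(x)
}

#' Quality-control filter for single cells
#'
#' Removes cells expressing fewer than `min_genes` genes, cells with a
#' mitochondrial UMI fraction greater than `max_mito`, and likely
#' doublets (doublet score greater than `max_doublet`).  All boundaries
#' are strict in the stated direction, so a cell at exactly `min_genes`
#' expressed genes or exactly `max_mito` mitochondrial fraction is
#' retained.
#'
#' @param bundle a [cell_bundle()].
#' @param min_genes,max_mito,max_doublet QC thresholds (defaults 500,
#'   0.15, 0.25).
#' @param strict if `TRUE`, a missing `doublet_score` column is an
#'   error; otherwise the doublet rule is skipped with a warning.
#' @return the filtered `cell_bundle`, with a `qc_report` attribute
#'   (cells failing each rule and total removed).
#' @export
qc_filter <- function(bundle, min_genes = 500L, max_mito = 0.15,
                      max_doublet = 0.25, strict = FALSE) {
  stopifnot(inherits(bundle, "cell_bundle"))
  n_expressed <- Matrix::colSums(bundle$counts > 0)
  fail_genes <- n_expressed < min_genes
  fail_mito <- if ("mito_frac" %in% names(bundle$meta))
    bundle$meta$mito_frac > max_mito else rep(FALSE, ncol(bundle$counts))
  if ("doublet_score" %in% names(bundle$meta)) {
    fail_doublet <- bundle$meta$doublet_score > max_doublet
  } else if (strict) {
    stop("metadata has no doublet_score column")
  } else {
    warning("no doublet_score column; doublet rule skipped")
    fail_doublet <- rep(FALSE, ncol(bundle$counts))
  }
  drop <- fail_genes | fail_mito | fail_doublet
  out <- cell_bundle(bundle$counts[, !drop, drop = FALSE],
                     bundle$meta[!drop, , drop = FALSE])
  attr(out, "qc_report") <- list(n_input = length(drop),
                                 fail_min_genes = sum(fail_genes),
                                 fail_max_mito = sum(fail_mito),
                                 fail_max_doublet = sum(fail_doublet),
                                 n_removed = sum(drop))
  out
}

#' Library-size normalisation and log transform
#'
#' Scales each cell's counts to a total of `target_sum` UMIs and applies
#' the natural log(1 + x) transform, storing the result in
#' `bundle$norm`.
#'
#' @param bundle a [cell_bundle()] (after QC).
#' @param target_sum per-cell total after scaling (default 1e4).
#' @return the bundle with a populated `norm` matrix.
#' @export
normalize_cells <- function(bundle, target_sum = 1e4) {
  stopifnot(inherits(bundle, "cell_bundle"))
  totals <- Matrix::colSums(bundle$counts)
  if (any(totals == 0))
    stop("zero-count cell(s) present; apply qc_filter first")
  scaled <- bundle$counts %*% Matrix::Diagonal(x = target_sum / totals)
  dimnames(scaled) <- dimnames(bundle$counts)
  norm <- scaled
  norm@x <- log1p(norm@x)
  bundle$norm <- norm
  bundle
}

## ---- rank-sum machinery ----------------------------------------------

## Exact null distribution of the group-A rank sum for a given pooled
## rank multiset (ties allowed), by dynamic programming over doubled
## midranks (kept integer).  Returns two-sided p for observed sum.
rank_sum_exact_p <- function(r2, nA, w2) {
  n <- length(r2)
  maxs <- sum(r2)
  ## P[k + 1, s + 1] = number of k-subsets with doubled-rank sum s
  P <- matrix(0, nA + 1L, maxs + 1L)
  P[1L, 1L] <- 1
  for (r in r2) {
    kmax <- min(nA, n)  # rows to update, top-down to avoid reuse
    for (k in seq.int(min(nA, kmax), 1L)) {
      src <- P[k, seq_len(maxs + 1L - r)]
      P[k + 1L, seq.int(r + 1L, maxs + 1L)] <-
        P[k + 1L, seq.int(r + 1L, maxs + 1L)] + src
    }
  }
  dist <- P[nA + 1L, ]
  total <- sum(dist)
  pl <- sum(dist[seq_len(w2 + 1L)]) / total
  pg <- sum(dist[seq.int(w2 + 1L, maxs + 1L)]) / total
  min(1, 2 * min(pl, pg))
}

## Two-sided Wilcoxon rank-sum p value.  Exact enumeration (tie-aware)
## when both groups are at most `exact_limit` cells; otherwise the
## normal approximation with tie and continuity corrections.
## `cache` optionally memoises exact distributions across genes.
rank_sum_p <- function(xA, xB, exact_limit = 12L, cache = NULL) {
  nA <- length(xA); nB <- length(xB); n <- nA + nB
  r <- rank(c(xA, xB))
  W <- sum(r[seq_len(nA)])
  if (nA <= exact_limit && nB <= exact_limit) {
    r2 <- as.integer(round(2 * r))
    w2 <- as.integer(round(2 * W))
    if (!is.null(cache)) {
      key <- paste(c(nA, sort(r2), w2), collapse = ",")
      hit <- cache[[key]]
      if (!is.null(hit)) return(hit)
      val <- rank_sum_exact_p(sort(r2), nA, w2)
      cache[[key]] <- val
      return(val)
    }
    return(rank_sum_exact_p(sort(r2), nA, w2))
  }
  mu <- nA * (n + 1) / 2
  ties <- table(r)
  sigma2 <- nA * nB / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

## Seurat-style natural-log fold change of pseudocounted means of
## de-logged normalised expression.
ln_fold_change <- function(normA, normB) {
  log((rowMeans(expm1(normA)) + 1) / (rowMeans(expm1(normB)) + 1))
}

#' Wilcoxon differential expression within one cell type
#'
#' Two-sided Wilcoxon rank-sum test per gene comparing two conditions
#' within a cell type, on the normalised matrix.  Small comparisons
#' (both sides at most 12 cells) use the exact, tie-aware null
#' distribution; larger ones the normal approximation with tie and
#' continuity corrections.  Fold change is the natural log of the
#' pseudocounted de-logged means, `ln((mean(expm1 xA) + 1) /
#' (mean(expm1 xB) + 1))`, with the first contrast level as numerator.
#' Every gene expressed in at least one cell of the subset is tested;
#' multiplicity correction defaults to Bonferroni over the genes tested.
#'
#' @param bundle normalised [cell_bundle()].
#' @param cell_type cell type to subset (matched against
#'   `meta$cell_type`); `NULL` uses all cells (pseudo-bulk contrast).
#' @param contrast length-2 character: (numerator condition, denominator
#'   condition), matched against `meta$condition`.
#' @param correction `"bonferroni"` (default) or `"bh"`.
#' @param universe multiplicity burden: `"tested"` genes (default) or
#'   `"all"` genes in the matrix.
#' @param min_cells minimum cells per side (default 3); below it an
#'   empty table is returned with a warning.
#' @return data.frame per tested gene: `gene`, `logFC` (natural log),
#'   `p`, `p_adj`, `comparison`.
#' @export
wilcoxon_de <- function(bundle, cell_type = NULL, contrast,
                        correction = c("bonferroni", "bh"),
                        universe = c("tested", "all"), min_cells = 3L) {
  stopifnot(inherits(bundle, "cell_bundle"), length(contrast) == 2L)
  if (is.null(bundle$norm)) stop("run normalize_cells() first")
  correction <- match.arg(correction)
  universe <- match.arg(universe)
  keep <- if (is.null(cell_type)) rep(TRUE, nrow(bundle$meta))
          else bundle$meta$cell_type == cell_type
  selA <- keep & bundle$meta$condition == contrast[1]
  selB <- keep & bundle$meta$condition == contrast[2]
  comparison <- paste0(contrast[1], "_vs_", contrast[2],
                       if (!is.null(cell_type)) paste0("@", cell_type))
  if (sum(selA) < min_cells || sum(selB) < min_cells) {
    warning("fewer than ", min_cells, " cells on one side of ", comparison)
    return(data.frame(gene = character(0), logFC = numeric(0),
                      p = numeric(0), p_adj = numeric(0),
                      comparison = character(0)))
  }
  xA <- as.matrix(bundle$norm[, selA, drop = FALSE])
  xB <- as.matrix(bundle$norm[, selB, drop = FALSE])
  expressed <- rowSums(xA) + rowSums(xB) > 0
  xA <- xA[expressed, , drop = FALSE]
  xB <- xB[expressed, , drop = FALSE]
  cache <- new.env(parent = emptyenv())
  p <- vapply(seq_len(nrow(xA)), function(i)
    rank_sum_p(xA[i, ], xB[i, ], cache = cache), numeric(1))
  m <- if (universe == "all") nrow(bundle$norm) else length(p)
  p_adj <- if (correction == "bonferroni") pmin(1, p * m)
           else bh_adjust(p, m = m)
  data.frame(gene = rownames(xA), logFC = ln_fold_change(xA, xB),
             p = p, p_adj = p_adj, comparison = comparison,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' One-vs-rest marker detection per cluster
#'
#' For each cluster, genes whose natural-log fold change over all other
#' cells exceeds `screen_logfc` are screened in and Wilcoxon-tested;
#' markers are the screened genes with fold change above `marker_logfc`
#' and p below `marker_p`.  Singleton clusters are skipped with a
#' warning.
#'
#' @param bundle normalised [cell_bundle()].
#' @param clusters per-cell cluster labels (length = cells).
#' @param screen_logfc prefilter on positive log fold change (default
#'   0.25).
#' @param marker_logfc,marker_p marker thresholds (defaults 0.5 and
#'   0.05).
#' @return data.frame: `cluster`, `gene`, `logFC`, `p`, `marker`
#'   (logical).
#' @export
find_markers <- function(bundle, clusters, screen_logfc = 0.25,
                         marker_logfc = 0.5, marker_p = 0.05) {
  stopifnot(inherits(bundle, "cell_bundle"),
            length(clusters) == ncol(bundle$counts))
  if (is.null(bundle$norm)) stop("run normalize_cells() first")
  if (length(unique(clusters)) < 2L) stop("need at least 2 clusters")
  out <- list()
  for (cl in sort(unique(as.character(clusters)))) {
    sel <- clusters == cl
    if (sum(sel) < 2L) {
      warning("cluster ", cl, " is a singleton; skipped")
      next
    }
    xA <- as.matrix(bundle$norm[, sel, drop = FALSE])
    xB <- as.matrix(bundle$norm[, !sel, drop = FALSE])
    lfc <- ln_fold_change(xA, xB)
    screened <- which(lfc > screen_logfc)
    if (!length(screened)) next
    cache <- new.env(parent = emptyenv())
    p <- vapply(screened, function(i)
      rank_sum_p(xA[i, ], xB[i, ], cache = cache), numeric(1))
    out[[cl]] <- data.frame(cluster = cl,
                            gene = rownames(bundle$norm)[screened],
                            logFC = lfc[screened], p = p,
                            marker = lfc[screened] > marker_logfc &
                              p < marker_p,
                            row.names = NULL, stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(data.frame(
    cluster = character(0), gene = character(0), logFC = numeric(0),
    p = numeric(0), marker = logical(0)))))
}

#' Proteome vs pseudo-bulk fold-change concordance
#'
#' Pearson correlation of protein log2 fold changes with pseudo-bulked
#' single-cell natural-log fold changes (computed over all cells
#' combined), over the genes shared by both tables.
#'
#' @param sc_de data.frame with `gene` and `logFC` columns (e.g.
#'   [wilcoxon_de()] with `cell_type = NULL`).
#' @param prot_de data.frame with `protein` and `log2FC` columns
#'   ([protein_de()] output).
#' @return list with `r` (Pearson), `n_pairs`, and the joined `pairs`
#'   data.frame; `r` is `NA` with a warning when fewer than 3 pairs are
#'   shared.
#' @export
pseudobulk_corr <- function(sc_de, prot_de) {
  stopifnot(all(c("gene", "logFC") %in% names(sc_de)),
            all(c("protein", "log2FC") %in% names(prot_de)))
  pairs <- merge(sc_de[, c("gene", "logFC")],
                 prot_de[, c("protein", "log2FC")],
                 by.x = "gene", by.y = "protein")
  pairs <- pairs[stats::complete.cases(pairs), , drop = FALSE]
  if (nrow(pairs) < 3L) {
    warning("fewer than 3 shared gene/protein pairs")
    return(list(r = NA_real_, n_pairs = nrow(pairs), pairs = pairs))
  }
  list(r = stats::cor(pairs$logFC, pairs$log2FC), n_pairs = nrow(pairs),
       pairs = pairs)
}
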