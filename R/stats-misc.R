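## Set-enrichment testing, multiplicity adjustment and delta-delta-Ct
## fold changes.

#' Benjamini-Hochberg adjustment with explicit NA handling
#'
#' Step-up adjusted p values, clipped at 1 and monotone along the
#' p-value ranking.  `NA` inputs are excluded from the multiplicity
#' burden `m` and returned as `NA`.
#'
#' @param p numeric vector of p values in `[0, 1]` (NA allowed).
#' @param m multiplicity burden; defaults to the number of non-`NA`
#'   values, but may be set larger (e.g. all genes in a dataset).
#' @return adjusted p values, same length and order as `p`.
#' @export
bh_adjust <- function(p, m = NULL) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  if (!any(ok)) return(out)
  if (is.null(m)) m <- sum(ok)
  out[ok] <- stats::p.adjust(p[ok], method = "BH", n = max(m, sum(ok)))
  out
}

#' Fisher (hypergeometric) gene-set enrichment with coverage filter
#'
#' For each annotation set, tests over-representation of the query in
#' the set with the one-sided hypergeometric tail
#' `P(X >= overlap)`, adjusts across sets by Benjamini-Hochberg, and
#' flags sets passing both the significance cut (`p_adj < alpha`) and
#' the coverage filter (overlap at least `min_frac` of the query).
#'
#' @param query character vector of gene identifiers; must be contained
#'   in the universe.
#' @param sets named list of annotation gene sets (e.g. [read_gmt()]).
#' @param universe background gene universe; defaults to the union of
#'   all annotation sets and the query.
#' @param alpha adjusted-significance cut (default 0.05).
#' @param min_frac minimum overlap as a fraction of the query (default
#'   0.01).
#' @param top_n number of top-ranked sets returned (default 20; `Inf`
#'   for all).
#' @return data.frame ranked by p: `set`, `set_size`, `overlap`,
#'   `overlap_frac` (of query), `p`, `p_adj`, `pass`.
#' @export
fisher_enrichment <- function(query, sets, universe = NULL, alpha = 0.05,
                              min_frac = 0.01, top_n = 20L) {
  stopifnot(is.list(sets), !is.null(names(sets)), length(query) > 0)
  query <- unique(query)
  if (is.null(universe)) universe <- union(unlist(sets), query)
  universe <- unique(universe)
  if (!all(query %in% universe))
    stop("query contains identifiers outside the universe")
  N <- length(universe)
  n <- length(query)
  res <- lapply(names(sets), function(nm) {
    K <- length(intersect(sets[[nm]], universe))
    k <- length(intersect(sets[[nm]], query))
    p <- if (k == 0L) 1 else
      stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, set_size = K, overlap = k,
               overlap_frac = k / n, p = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$p_adj <- bh_adjust(res$p)
  res$pass <- res$p_adj < alpha & res$overlap_frac >= min_frac
  res <- res[order(res$p, res$set), , drop = FALSE]
  rownames(res) <- NULL
  utils::head(res, top_n)
}

#' Group annotation sets by Jaccard similarity
#'
#' Convenience single-linkage grouping of gene sets whose pairwise
#' Jaccard index reaches `threshold`; useful to condense redundant
#' pathway hits for plotting.  (The analogous condensing of published
#' figures is a manual curation step; this helper is an automated
#' approximation, not a reproduction of it.)
#'
#' @param sets named list of gene sets.
#' @param threshold Jaccard similarity to merge at (default 0.5).
#' @return integer vector of group ids, named by set.
#' @export
jaccard_groups <- function(sets, threshold = 0.5) {
  k <- length(sets)
  grp <- seq_len(k)
  find <- function(i) { while (grp[i] != i) i <- grp[i]; i }
  if (k > 1L) for (i in seq_len(k - 1L)) for (j in seq.int(i + 1L, k)) {
    jac <- length(intersect(sets[[i]], sets[[j]])) /
      length(union(sets[[i]], sets[[j]]))
    if (!is.nan(jac) && jac >= threshold) grp[find(j)] <- find(i)
  }
  roots <- vapply(seq_len(k), find, integer(1))
  stats::setNames(match(roots, unique(roots)), names(sets))
}

#' Relative qPCR fold change by the delta-delta-Ct method
#'
#' Per sample, `dCt = Ct(gene) - mean Ct(housekeeping genes)`;
#' `ddCt = mean dCt(treated) - mean dCt(calibrator)`; fold change =
#' `2^(-ddCt)`.  Per-sample fold changes relative to the calibrator mean
#' are reported for dispersion.  Samples missing any housekeeping
#' measurement are dropped with a warning.
#'
#' @param ct data.frame with columns `sample`, `gene`, `ct` and a
#'   `group` column identifying each sample's condition.
#' @param gene gene of interest.
#' @param housekeeping character vector of housekeeping gene names.
#' @param treated,calibrator group labels.
#' @return list: `fold` (scalar), `ddct`, `dct` (per sample) and
#'   `per_sample_fold`.
#' @export
ddct <- function(ct, gene, housekeeping, treated, calibrator) {
  stopifnot(all(c("sample", "gene", "ct", "group") %in% names(ct)),
            length(housekeeping) >= 1L)
  if (any(ct$ct <= 0, na.rm = TRUE)) stop("Ct values must be positive")
  samples <- unique(ct$sample)
  dct <- numeric(0); grp <- character(0)
  for (s in samples) {
    sub <- ct[ct$sample == s, , drop = FALSE]
    hk <- sub$ct[match(housekeeping, sub$gene)]
    gct <- sub$ct[match(gene, sub$gene)]
    if (anyNA(hk) || is.na(gct)) {
      warning("sample ", s, " dropped (missing measurement)")
      next
    }
    dct <- c(dct, gct - mean(hk))
    names(dct)[length(dct)] <- s
    grp <- c(grp, unique(sub$group))
  }
  if (!any(grp == treated) || !any(grp == calibrator))
    stop("treated or calibrator group has no usable samples")
  ddct_val <- mean(dct[grp == treated]) - mean(dct[grp == calibrator])
  list(fold = 2^(-ddct_val), ddct = ddct_val, dct = dct,
       per_sample_fold = 2^(-(dct - mean(dct[grp == calibrator]))))
}
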