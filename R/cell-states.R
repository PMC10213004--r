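## Signature (module) scoring with binned controls, argmax state
## assignment, composition-shift testing and pseudotime trends.

#' Module score of a gene signature with binned control genes
#'
#' Per-cell score of a signature: the mean normalised expression of the
#' signature genes minus the mean of control genes drawn, for each
#' signature gene, from the same average-expression bin.  Genes are
#' binned into `n_bins` by their mean expression across cells;
#' `n_ctrl` controls are sampled per signature gene (with replacement
#' when a bin is small).  Subtracting expression-matched controls makes
#' the score robust to per-cell depth and to the overall expression
#' level of the signature.
#'
#' @param bundle normalised [cell_bundle()].
#' @param signature character vector of gene identifiers; genes missing
#'   from the matrix are dropped with a warning.
#' @param n_bins number of average-expression bins (default 24).
#' @param n_ctrl control genes sampled per signature gene (default 100).
#' @param seed integer seed for the control draw; fixed seed implies an
#'   identical score vector.
#' @param control_pool optional explicit control gene set overriding the
#'   binned sampling (e.g. the signature itself, which yields a score of
#'   exactly 0 for every cell).
#' @return numeric vector of per-cell scores.
#' @export
module_score <- function(bundle, signature, n_bins = 24L, n_ctrl = 100L,
                         seed = 1L, control_pool = NULL) {
  stopifnot(inherits(bundle, "cell_bundle"))
  if (is.null(bundle$norm)) stop("run normalize_cells() first")
  genes <- rownames(bundle$norm)
  missing <- setdiff(signature, genes)
  if (length(missing))
    warning(length(missing), " signature gene(s) absent from the matrix")
  signature <- intersect(signature, genes)
  if (!length(signature)) stop("signature empty after filtering")
  sig_mean <- Matrix::colMeans(bundle$norm[signature, , drop = FALSE])
  if (!is.null(control_pool)) {
    control_pool <- intersect(control_pool, genes)
    ctrl_mean <- Matrix::colMeans(bundle$norm[control_pool, , drop = FALSE])
    return(unname(sig_mean - ctrl_mean))
  }
  avg <- Matrix::rowMeans(bundle$norm)
  ## cut on the rank of average expression => near-equal bin occupancy
  bins <- cut(rank(avg, ties.method = "first"), breaks = n_bins,
              labels = FALSE)
  ctrl <- with_seed(seed, {
    unlist(lapply(signature, function(g) {
      pool <- genes[bins == bins[match(g, genes)]]
      sample(pool, n_ctrl, replace = length(pool) < n_ctrl)
    }))
  })
  ## controls are pooled; a gene sampled twice counts twice
  ctrl_mean <- Matrix::colMeans(bundle$norm[ctrl, , drop = FALSE])
  unname(sig_mean - ctrl_mean)
}

#' Score several signatures into a cells x signatures matrix
#'
#' @param bundle normalised [cell_bundle()].
#' @param signatures named list of gene vectors (e.g. from
#'   [read_gmt()]).
#' @inheritParams module_score
#' @return numeric matrix, cells x signatures.
#' @export
score_signatures <- function(bundle, signatures, n_bins = 24L,
                             n_ctrl = 100L, seed = 1L) {
  stopifnot(is.list(signatures), !is.null(names(signatures)))
  out <- vapply(names(signatures), function(nm)
    module_score(bundle, signatures[[nm]], n_bins = n_bins,
                 n_ctrl = n_ctrl, seed = artifact_seed(seed, nm)),
    numeric(ncol(bundle$norm)))
  rownames(out) <- colnames(bundle$norm)
  out
}

#' Assign each cell to the state with the highest signature score
#'
#' @param scores cells x signatures score matrix (from
#'   [score_signatures()]).
#' @return data.frame: `state` (argmax signature), `margin` (top minus
#'   second score; 0 marks a tie, broken deterministically by signature
#'   column-name order) and `tie` flag.
#' @export
assign_states <- function(scores) {
  stopifnot(is.matrix(scores), ncol(scores) >= 1L)
  ## deterministic tie-break: earlier column name wins
  ord <- order(colnames(scores))
  scores <- scores[, ord, drop = FALSE]
  idx <- apply(scores, 1L, which.max)
  top <- scores[cbind(seq_len(nrow(scores)), idx)]
  second <- if (ncol(scores) == 1L) rep(-Inf, nrow(scores)) else
    apply(scores, 1L, function(x) sort(x, decreasing = TRUE)[2L])
  margin <- top - second
  data.frame(state = colnames(scores)[idx], margin = margin,
             tie = margin == 0, row.names = rownames(scores),
             stringsAsFactors = FALSE)
}

#' Composition-shift test for one cell state between two conditions
#'
#' Builds the 2 x 2 table (cells in `state` vs all other states, by
#' condition) and tests homogeneity of the state's proportion with the
#' Pearson chi-squared statistic (1 df, no continuity correction by
#' default).  A permutation p value from label shuffles is available as
#' a finite-sample check.  A normalised composition table (per-condition
#' state fractions with raw counts) is returned alongside.
#'
#' @param assignments per-cell state labels.
#' @param conditions per-cell condition labels (exactly 2 distinct).
#' @param state the state whose proportion is tested.
#' @param correct apply Yates continuity correction (default `FALSE`).
#' @param n_perm number of label permutations for the permutation p
#'   (0 = skip, default).
#' @param seed seed for the permutation draw.
#' @return list: `statistic`, `p`, `p_perm` (or `NA`), `table` (2 x 2),
#'   `composition` (data.frame condition x state: `n`, `fraction`).
#' @export
composition_test <- function(assignments, conditions, state,
                             correct = FALSE, n_perm = 0L, seed = 1L) {
  stopifnot(length(assignments) == length(conditions))
  conditions <- factor(conditions)
  if (nlevels(conditions) != 2L) stop("exactly two conditions required")
  in_state <- factor(assignments == state, levels = c(TRUE, FALSE),
                     labels = c(state, "other"))
  tab <- table(conditions, in_state)
  comp_tab <- table(conditions, assignments)
  composition <- as.data.frame(comp_tab, stringsAsFactors = FALSE)
  names(composition) <- c("condition", "state", "n")
  composition$fraction <- composition$n /
    rowSums(comp_tab)[composition$condition]
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("degenerate 2x2 table (zero margin); returning NA")
    return(list(statistic = NA_real_, p = NA_real_, p_perm = NA_real_,
                table = tab, composition = composition))
  }
  a <- as.numeric(tab[1, 1]); b <- as.numeric(tab[1, 2])
  c <- as.numeric(tab[2, 1]); d <- as.numeric(tab[2, 2])
  N <- a + b + c + d
  num <- abs(a * d - b * c)
  if (correct) num <- max(0, num - N / 2)
  stat <- N * num^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
  p <- stats::pchisq(stat, df = 1L, lower.tail = FALSE)
  p_perm <- NA_real_
  if (n_perm > 0L) {
    x <- assignments == state
    obs <- stat
    p_perm <- with_seed(seed, {
      n1 <- sum(conditions == levels(conditions)[1])
      hits <- 0L
      for (i in seq_len(n_perm)) {
        perm <- sample(x)
        a2 <- as.numeric(sum(perm[seq_len(n1)])); b2 <- n1 - a2
        c2 <- sum(perm) - a2; d2 <- N - n1 - c2
        num2 <- abs(a2 * d2 - b2 * c2)
        if (correct) num2 <- max(0, num2 - N / 2)
        s2 <- N * num2^2 / ((a2 + b2) * (c2 + d2) * (a2 + c2) * (b2 + d2))
        if (s2 >= obs - 1e-12) hits <- hits + 1L
      }
      (hits + 1) / (n_perm + 1)
    })
  }
  list(statistic = unname(stat), p = unname(p), p_perm = p_perm,
       table = tab, composition = composition)
}

#' Smoothed gene-expression trends along pseudotime
#'
#' Per gene and condition, a sliding-window mean of normalised
#' expression over a fixed pseudotime grid shared across conditions.
#' The grid has `n_windows` centres in (0, 1); each window spans 1.5
#' grid steps on either side of its centre.  Windows holding fewer than
#' `min_cells` cells are linearly interpolated from the nearest valid
#' windows and flagged.
#'
#' @param bundle normalised [cell_bundle()].
#' @param pseudotime numeric in `[0, 1]`, one value per cell.
#' @param genes genes to profile; absent genes are skipped with a
#'   warning.
#' @param conditions per-cell condition labels; every condition needs at
#'   least `min_condition_cells` cells.
#' @param n_windows number of grid points (default 50).
#' @param min_cells minimum cells per window before interpolation
#'   (default 5).
#' @param min_condition_cells minimum cells per condition (default 20).
#' @return data.frame: `gene`, `condition`, `t` (grid), `mean_expr`,
#'   `n_cells`, `interpolated`.
#' @export
pseudotime_trends <- function(bundle, pseudotime, genes, conditions,
                              n_windows = 50L, min_cells = 5L,
                              min_condition_cells = 20L) {
  stopifnot(inherits(bundle, "cell_bundle"),
            length(pseudotime) == ncol(bundle$norm),
            length(conditions) == ncol(bundle$norm))
  if (any(pseudotime < 0 | pseudotime > 1, na.rm = TRUE))
    stop("pseudotime must lie in [0, 1]")
  absent <- setdiff(genes, rownames(bundle$norm))
  if (length(absent)) {
    warning("gene(s) absent, skipped: ", paste(absent, collapse = ", "))
    genes <- setdiff(genes, absent)
  }
  grid <- (seq_len(n_windows) - 0.5) / n_windows
  half <- 1.5 / n_windows
  out <- list()
  for (cond in unique(conditions)) {
    sel <- which(conditions == cond & !is.na(pseudotime))
    if (length(sel) < min_condition_cells)
      stop("condition `", cond, "` has fewer than ", min_condition_cells,
           " cells with pseudotime")
    t_c <- pseudotime[sel]
    for (g in genes) {
      expr <- as.numeric(bundle$norm[g, sel])
      m <- n <- numeric(n_windows)
      for (k in seq_len(n_windows)) {
        inw <- abs(t_c - grid[k]) <= half
        n[k] <- sum(inw)
        m[k] <- if (n[k] > 0) mean(expr[inw]) else NA_real_
      }
      sparse <- n < min_cells
      if (any(sparse) && any(!sparse)) {
        m[sparse] <- stats::approx(grid[!sparse], m[!sparse],
                                   xout = grid[sparse], rule = 2)$y
      }
      out[[length(out) + 1L]] <-
        data.frame(gene = g, condition = cond, t = grid, mean_expr = m,
                   n_cells = n, interpolated = sparse,
                   stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
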