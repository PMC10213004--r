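## Bulk proteome preprocessing (presence filter + RPM) and differential
## abundance testing (moderated or Welch t).

#' Write / read a proteome abundance TSV with a two-row header
#'
#' Row 1 holds sample names, row 2 the group label of each sample
#' (`control` / `perturbed`); subsequent rows are one protein each.
#' Missing observations are written as `NA`.
#'
#' @param intensity proteins x samples numeric matrix.
#' @param groups factor/character of group labels per sample.
#' @param path file path.
#' @return `write_proteome()`: `path` invisibly; `read_proteome()`: list
#'   with `intensity` and `groups`.
#' @export
write_proteome <- function(intensity, groups, path) {
  stopifnot(is.matrix(intensity), ncol(intensity) == length(groups))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("protein", colnames(intensity)), collapse = "\t"), con)
  writeLines(paste(c("group", as.character(groups)), collapse = "\t"), con)
  utils::write.table(data.frame(protein = rownames(intensity), intensity,
                                check.names = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_proteome
#' @export
read_proteome <- function(path) {
  hdr <- readLines(path, n = 2L)
  samples <- strsplit(hdr[1], "\t")[[1]][-1]
  groups <- factor(strsplit(hdr[2], "\t")[[1]][-1])
  body <- utils::read.table(path, sep = "\t", skip = 2L, header = FALSE,
                            row.names = 1L, na.strings = "NA")
  intensity <- as.matrix(body)
  colnames(intensity) <- samples
  list(intensity = intensity, groups = groups)
}

#' Presence filter and RPM normalisation of a proteome matrix
#'
#' Removes proteins not observed (non-`NA`) in at least `min_presence`
#' of the samples of *every* group, then scales each sample column so
#' its non-`NA` intensity sum equals 1e6 (reads/intensity per million).
#' Samples listed in `exclude` (e.g. outliers identified by PCA) are
#' dropped before filtering.
#'
#' @param intensity proteins x samples matrix, linear scale, `NA`
#'   allowed.
#' @param groups group label per sample (two or more samples per group).
#' @param min_presence required observed fraction per group (default
#'   0.75).
#' @param exclude character vector of sample (column) names to drop.
#' @return list with filtered, normalised `intensity` and the matching
#'   `groups`.
#' @export
preprocess_proteome <- function(intensity, groups, min_presence = 0.75,
                                exclude = NULL) {
  stopifnot(is.matrix(intensity), ncol(intensity) == length(groups))
  groups <- factor(groups)
  if (length(exclude)) {
    keep <- !(colnames(intensity) %in% exclude)
    intensity <- intensity[, keep, drop = FALSE]
    groups <- droplevels(groups[keep])
  }
  if (any(table(groups) == 0L) || nlevels(groups) < 2L)
    stop("each group must contain at least one sample after exclusion")
  present <- !is.na(intensity)
  ok <- rep(TRUE, nrow(intensity))
  for (g in levels(groups)) {
    cols <- groups == g
    ok <- ok & rowMeans(present[, cols, drop = FALSE]) >= min_presence
  }
  intensity <- intensity[ok, , drop = FALSE]
  totals <- colSums(intensity, na.rm = TRUE)
  intensity <- sweep(intensity, 2L, totals / 1e6, "/")
  list(intensity = intensity, groups = groups)
}

## Row-wise Welch t-test on a log2 matrix, NA-aware.
welch_rows <- function(x, g1, g2) {
  n1 <- rowSums(!is.na(x[, g1, drop = FALSE]))
  n2 <- rowSums(!is.na(x[, g2, drop = FALSE]))
  m1 <- rowMeans(x[, g1, drop = FALSE], na.rm = TRUE)
  m2 <- rowMeans(x[, g2, drop = FALSE], na.rm = TRUE)
  v1 <- apply(x[, g1, drop = FALSE], 1L, stats::var, na.rm = TRUE)
  v2 <- apply(x[, g2, drop = FALSE], 1L, stats::var, na.rm = TRUE)
  se2 <- v1 / n1 + v2 / n2
  t <- (m2 - m1) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t), df)
  bad <- n1 < 2L | n2 < 2L
  t[bad] <- NA; p[bad] <- NA
  list(logFC = m2 - m1, t = t, p = p)
}

#' Differential protein abundance
#'
#' Tests perturbed vs control group means of `log2(RPM + 1)` abundances.
#' The default `moderated` method fits a per-protein linear model and
#' shrinks the residual variances toward a pooled prior (empirical-Bayes
#' moderated t, via limma), which stabilises small-sample inference; the
#' `welch` alternative is a plain per-protein Welch t-test.
#' Benjamini-Hochberg adjustment is computed over the proteins actually
#' tested (proteins with fewer than two observations in a group get `NA`
#' statistics and are excluded from the multiplicity burden).
#'
#' @param prep list from [preprocess_proteome()] (`intensity`, `groups`).
#' @param method `"moderated"` (default) or `"welch"`.
#' @return data.frame per protein: `log2FC` (perturbed - control), `t`,
#'   `p`, `p_adj`.
#' @export
protein_de <- function(prep, method = c("moderated", "welch")) {
  method <- match.arg(method)
  x <- log2(prep$intensity + 1)
  if (is.null(rownames(x))) rownames(x) <- paste0("p", seq_len(nrow(x)))
  groups <- factor(prep$groups)
  stopifnot(nlevels(groups) == 2L)
  g1 <- groups == levels(groups)[1]   # control
  g2 <- groups == levels(groups)[2]   # perturbed
  n1 <- rowSums(!is.na(x[, g1, drop = FALSE]))
  n2 <- rowSums(!is.na(x[, g2, drop = FALSE]))
  testable <- n1 >= 2L & n2 >= 2L
  if (method == "moderated") {
    design <- stats::model.matrix(~groups)
    fit <- limma::eBayes(limma::lmFit(x, design))
    res <- data.frame(log2FC = fit$coefficients[, 2L],
                      t = fit$t[, 2L], p = fit$p.value[, 2L])
  } else {
    w <- welch_rows(x, g1, g2)
    res <- data.frame(log2FC = w$logFC, t = w$t, p = w$p)
  }
  res$log2FC[!testable] <- rowMeans(x[, g2, drop = FALSE], na.rm = TRUE)[!testable] -
    rowMeans(x[, g1, drop = FALSE], na.rm = TRUE)[!testable]
  res$t[!testable] <- NA_real_
  res$p[!testable] <- NA_real_
  res$p_adj <- bh_adjust(res$p)
  rownames(res) <- rownames(x)
  res <- cbind(protein = rownames(x), res)
  rownames(res) <- NULL
  res
}
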