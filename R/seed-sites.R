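## Canonical miRNA seed-match site derivation, UTR scanning with
## most-specific-type precedence, and the per-group binding-site census.

SITE_TYPES <- c("8mer", "7mer-m8", "7mer-A1", "6mer")

rna_revcomp <- function(x) {
  stopifnot(grepl("^[ACGU]+$", x))
  chartr("ACGU", "UGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

#' Canonical seed-match site strings for a miRNA
#'
#' Derives the four canonical target-site strings, written 5'->3' on the
#' target (mRNA) strand in the RNA alphabet:
#'
#' * `6mer`: reverse complement of miRNA positions 2-7 (the seed);
#' * `7mer-m8`: reverse complement of positions 2-8;
#' * `7mer-A1`: the 6mer followed by an `A` (the adenosine opposite
#'   miRNA position 1);
#' * `8mer`: the 7mer-m8 followed by the `A`.
#'
#' By construction the 8mer contains the 7mer-m8 as a prefix and the
#' 7mer-A1 as a suffix, and both 7mers contain the 6mer.
#'
#' @param mirna mature miRNA sequence, 5'->3', RNA alphabet (`ACGU`),
#'   length >= 8.  `T` is accepted and converted to `U`.
#' @param name optional miRNA name, carried in the result's attributes.
#' @return a named character vector of class `site_patterns` with entries
#'   `8mer`, `7mer-m8`, `7mer-A1`, `6mer`.
#' @examples
#' seed_patterns("UAACAGUCUACAGCCAUGGUCG", name = "mmu-miR-132-3p")
#' @export
seed_patterns <- function(mirna, name = NULL) {
  stopifnot(is.character(mirna), length(mirna) == 1L)
  seq <- chartr("Tt", "Uu", toupper(mirna))
  if (!grepl("^[ACGU]+$", seq))
    stop("miRNA sequence must use the A/C/G/U alphabet")
  if (nchar(seq) < 8L)
    stop("miRNA sequence must be at least 8 nt to define seed sites")
  six <- rna_revcomp(substr(seq, 2L, 7L))
  sev <- rna_revcomp(substr(seq, 2L, 8L))
  pats <- c("8mer" = paste0(sev, "A"), "7mer-m8" = sev,
            "7mer-A1" = paste0(six, "A"), "6mer" = six)
  structure(pats, class = "site_patterns", mirna = seq, name = name)
}

#' @export
print.site_patterns <- function(x, ...) {
  nm <- attr(x, "name")
  cat("<site_patterns>", if (!is.null(nm)) nm else "", "miRNA",
      attr(x, "mirna"), "\n")
  print(stats::setNames(as.character(x), names(x)))
  invisible(x)
}

## Validate / coerce UTR input to a named character vector in the RNA
## alphabet (T -> U).  Accepts a Biostrings XStringSet or a named
## character vector.  N is allowed (and never matches); other letters
## are rejected.
as_utr_strings <- function(utrs) {
  if (methods::is(utrs, "XStringSet")) utrs <- as.character(utrs)
  stopifnot(is.character(utrs))
  if (is.null(names(utrs)) || anyDuplicated(names(utrs)))
    stop("UTRs must have unique names")
  utrs <- chartr("Tt", "Uu", toupper(utrs))
  bad <- grepl("[^ACGUN]", utrs)
  if (any(bad))
    stop("non-nucleotide characters (other than N) in UTR(s): ",
         paste(utils::head(names(utrs)[bad], 5), collapse = ", "))
  utrs
}

#' Scan UTR sequences for canonical miRNA seed-match sites
#'
#' Finds every occurrence of the four canonical site strings and reports
#' each locus exactly once with its most specific type, using precedence
#' 8mer > 7mer-m8 > 7mer-A1 > 6mer: any lower-precedence match whose
#' interval lies inside an already-reported site is suppressed (so an
#' 8mer is not additionally counted as the 7mers and 6mer it contains).
#' Distinct, non-nested sites may still overlap.  `N` positions never
#' match.
#'
#' @param utrs named character vector or [Biostrings::DNAStringSet] /
#'   `RNAStringSet` of UTR sequences (sense strand; `T` is treated
#'   as `U`).
#' @param patterns a `site_patterns` object from [seed_patterns()].
#' @return data.frame with columns `utr_id`, `start` (1-based,
#'   inclusive), `end`, `site_type` (factor with the four canonical
#'   levels), ordered by UTR then position.
#' @export
scan_sequences <- function(utrs, patterns) {
  stopifnot(inherits(patterns, "site_patterns"))
  utrs <- as_utr_strings(utrs)
  hits <- vector("list", length(utrs))
  subject <- Biostrings::RNAStringSet(utrs)
  for (i in seq_along(utrs)) {
    cand_start <- integer(0); cand_end <- integer(0); cand_type <- integer(0)
    for (k in seq_along(SITE_TYPES)) {
      m <- Biostrings::matchPattern(patterns[[SITE_TYPES[k]]], subject[[i]],
                                    fixed = TRUE)
      if (length(m)) {
        cand_start <- c(cand_start, Biostrings::start(m))
        cand_end <- c(cand_end, Biostrings::end(m))
        cand_type <- c(cand_type, rep.int(k, length(m)))
      }
    }
    if (!length(cand_start)) next
    ## precedence order: type rank, then position
    ord <- order(cand_type, cand_start)
    acc_start <- integer(0); acc_end <- integer(0); acc_type <- integer(0)
    for (j in ord) {
      nested <- any(acc_start <= cand_start[j] & cand_end[j] <= acc_end)
      if (!nested) {
        acc_start <- c(acc_start, cand_start[j])
        acc_end <- c(acc_end, cand_end[j])
        acc_type <- c(acc_type, cand_type[j])
      }
    }
    hits[[i]] <- data.frame(utr_id = names(utrs)[i], start = acc_start,
                            end = acc_end, site_type = acc_type,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(hits, list(
    data.frame(utr_id = character(0), start = integer(0), end = integer(0),
               site_type = integer(0), stringsAsFactors = FALSE))))
  out <- out[order(match(out$utr_id, names(utrs)), out$start, out$site_type), ]
  out$site_type <- factor(SITE_TYPES[out$site_type], levels = SITE_TYPES)
  rownames(out) <- NULL
  out
}

#' Per-group binding-site census
#'
#' Summarises scanned seed-match sites per evidence group (e.g.
#' `Proteomics`, `Transcriptomics`, `Non-changing`): the mean +/- SEM of
#' the total number of sites per target, and the mean +/- SEM of the
#' per-target proportion of each site type.  Targets with zero sites
#' contribute a total of 0 but are excluded from the proportion averages
#' (their type proportions are undefined).
#'
#' @param hits data.frame from [scan_sequences()] (`utr_id`,
#'   `site_type`, ...).
#' @param target_groups named character vector mapping target (UTR) id to
#'   group label; every target considered must appear here, including
#'   targets with no hits.
#' @return list with elements `totals` (per group: `n`, `mean_sites`,
#'   `sem_sites`), `type_props` (per group x site type: `mean_prop`,
#'   `sem_prop`) and `per_target` (per target: group, total and per-type
#'   counts and proportions).
#' @export
summarize_census <- function(hits, target_groups) {
  stopifnot(is.character(target_groups), !is.null(names(target_groups)))
  extra <- setdiff(unique(hits$utr_id), names(target_groups))
  if (length(extra))
    stop("hits contain targets absent from target_groups: ",
         paste(utils::head(extra, 5), collapse = ", "))
  targets <- names(target_groups)
  counts <- matrix(0L, length(targets), length(SITE_TYPES),
                   dimnames = list(targets, SITE_TYPES))
  if (nrow(hits)) {
    tab <- table(factor(hits$utr_id, levels = targets),
                 factor(hits$site_type, levels = SITE_TYPES))
    counts[] <- as.integer(tab)
  }
  total <- rowSums(counts)
  props <- counts / ifelse(total > 0, total, NA_real_)
  per_target <- data.frame(target = targets,
                           group = unname(target_groups),
                           total = as.integer(total),
                           counts, props * 1,
                           check.names = FALSE,
                           stringsAsFactors = FALSE)
  names(per_target)[4:11] <- c(paste0("n_", SITE_TYPES),
                               paste0("prop_", SITE_TYPES))
  groups <- unique(unname(target_groups))
  totals <- data.frame(group = groups,
                       n = vapply(groups, function(g)
                         sum(target_groups == g), integer(1)),
                       mean_sites = vapply(groups, function(g)
                         mean(total[target_groups == g]), numeric(1)),
                       sem_sites = vapply(groups, function(g)
                         sem(total[target_groups == g]), numeric(1)),
                       stringsAsFactors = FALSE)
  tp <- expand.grid(group = groups, site_type = SITE_TYPES,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tp$mean_prop <- mapply(function(g, ty)
    mean(props[target_groups == g, ty], na.rm = TRUE), tp$group, tp$site_type)
  tp$sem_prop <- mapply(function(g, ty)
    sem(props[target_groups == g, ty]), tp$group, tp$site_type)
  tp$mean_prop[is.nan(tp$mean_prop)] <- NA_real_
  list(totals = totals, type_props = tp, per_target = per_target)
}
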