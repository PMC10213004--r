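## Internal helpers shared across modules.

#' Derive a per-artifact RNG seed from the master seed
#'
#' One master integer seed drives one independent stream per artifact type
#' (UTRs, evidence, proteome, cells, ...), so that e.g. adding UTRs to a
#' simulation does not perturb the cell draw.  The sub-seed is a
#' deterministic hash of the artifact label folded into the master seed,
#' kept below 2^31.
#'
#' @param seed master integer seed.
#' @param what character label of the artifact stream.
#' @return an integer seed.
#' @keywords internal
artifact_seed <- function(seed, what) {
  stopifnot(is.numeric(seed), length(seed) == 1L, length(what) == 1L)
  h <- 0
  for (b in utf8ToInt(what)) h <- (h * 131 + b) %% 2147483563
  as.integer((as.numeric(seed) %% 2147483563 + h * 7919) %% 2147483563) + 1L
}

## Evaluate `expr` under a temporary RNG state seeded with `seed`,
## restoring the caller's .Random.seed afterwards.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

## Standard error of the mean; NA for n < 2 (undefined).
sem <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

## Rank-based AUC of `score` for separating positives (label TRUE) from
## negatives; equals the Wilcoxon statistic scaled to [0, 1].
rank_auc <- function(score, positive) {
  stopifnot(length(score) == length(positive))
  pos <- as.logical(positive)
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(score)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Read a GMT gene-set file
#'
#' Thin wrapper around [fgsea::gmtPathways()] returning a named list of
#' unique gene identifiers per set.
#'
#' @param path path to a GMT file.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  sets <- fgsea::gmtPathways(path)
  lapply(sets, unique)
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param description description field written to column 2 (recycled).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = "na") {
  stopifnot(is.list(sets), !is.null(names(sets)), all(nzchar(names(sets))))
  description <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
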