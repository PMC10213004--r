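# Independent brute-force oracles used across test files.  These are
# deliberately naive re-derivations (substring loops, exhaustive
# enumeration, closed forms) kept separate from the package's own code
# paths.

# All windows of each site pattern found by plain substring comparison,
# then the precedence/nesting filter applied by a direct double loop.
oracle_scan_one <- function(seq, patterns) {
  seq <- chartr("Tt", "Uu", toupper(seq))
  types <- c("8mer", "7mer-m8", "7mer-A1", "6mer")
  cand <- list()
  for (ty in types) {
    pat <- patterns[[ty]]
    k <- nchar(pat)
    L <- nchar(seq)
    if (L < k) next
    starts <- which(vapply(seq_len(L - k + 1L), function(s)
      substr(seq, s, s + k - 1L) == pat, logical(1)))
    for (s in starts)
      cand[[length(cand) + 1L]] <- list(start = s, end = s + k - 1L,
                                        type = ty,
                                        rank = match(ty, types))
  }
  if (!length(cand))
    return(data.frame(start = integer(0), end = integer(0),
                      site_type = character(0)))
  ord <- order(vapply(cand, `[[`, 1, "rank"),
               vapply(cand, `[[`, 1, "start"))
  acc <- list()
  for (i in ord) {
    x <- cand[[i]]
    nested <- FALSE
    for (a in acc)
      if (a$start <= x$start && x$end <= a$end) { nested <- TRUE; break }
    if (!nested) acc[[length(acc) + 1L]] <- x
  }
  out <- data.frame(start = vapply(acc, `[[`, 1L, "start"),
                    end = vapply(acc, `[[`, 1L, "end"),
                    site_type = vapply(acc, `[[`, "", "type"))
  out[order(out$start, out$site_type), , drop = FALSE]
}

# Exhaustive-enumeration two-sided rank-sum p: enumerate every
# assignment of nA of the pooled observations to group A, compare the
# rank sum to the observed one.
oracle_rank_sum_p <- function(xA, xB) {
  pooled <- c(xA, xB)
  r <- rank(pooled)
  nA <- length(xA)
  w_obs <- sum(r[seq_len(nA)])
  combos <- utils::combn(length(pooled), nA)
  w_all <- apply(combos, 2L, function(idx) sum(r[idx]))
  pl <- mean(w_all <= w_obs + 1e-9)
  pg <- mean(w_all >= w_obs - 1e-9)
  min(1, 2 * min(pl, pg))
}

# One-sided hypergeometric enrichment tail by direct summation.
oracle_hyper_tail <- function(k, K, N, n) {
  s <- 0
  for (x in k:min(K, n))
    s <- s + choose(K, x) * choose(N - K, n - x) / choose(N, n)
  s
}

# Random UTR-like sequence.
random_seq <- function(len, alphabet = c("A", "C", "G", "U")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# Small default config for fast unit tests.
tiny_cfg <- function(seed = 1L, ...) {
  sim_config(seed = seed, n_genes = 300L, n_true_targets = 12L,
             n_utrs = 60L, utr_len = 300L, n_cells_per_condition = 250L,
             genes_per_program = 25L, ...)
}
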