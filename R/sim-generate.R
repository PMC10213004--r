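## Generators for every pipeline input, with planted ground truth.

#' Generate 3'UTR sequences with planted seed-match sites
#'
#' Background bases are i.i.d. with the configured GC fraction; for every
#' true target UTR the requested number of sites of each type is planted
#' at non-overlapping positions (rejection placement), and the exact
#' position and type of every planted site is recorded in the truth.
#' UTR identifiers are gene identifiers; true targets are listed first so
#' that every true target owns a UTR.
#'
#' @param cfg a [sim_config()].
#' @param patterns a `site_patterns` object from [seed_patterns()]; the
#'   site strings are planted in the DNA alphabet (`U` -> `T`).
#' @param truth optional precomputed truth (from an earlier generator
#'   call) to keep gene identities consistent; computed from `cfg` when
#'   missing.
#' @return list with `utrs` (named character vector, DNA alphabet),
#'   `planted` (data.frame `utr_id`, `start`, `site_type`) and `truth`.
#' @export
gen_utrs <- function(cfg, patterns, truth = sim_truth(cfg)) {
  stopifnot(inherits(cfg, "sim_config"), inherits(patterns, "site_patterns"))
  site_dna <- chartr("U", "T", unclass(patterns))
  want <- cfg$planted_sites[cfg$planted_sites > 0]
  lens <- nchar(site_dna[names(want)])
  if (length(want) && sum(rep(lens, want)) > cfg$utr_len)
    stop("requested planted sites do not fit in utr_len = ", cfg$utr_len)
  if (length(want) && max(lens) >= cfg$utr_len)
    stop("utr_len must exceed the longest site pattern")
  ids <- unique(c(truth$true_target_ids, truth$genes))[seq_len(cfg$n_utrs)]
  is_target <- ids %in% truth$true_target_ids
  base_probs <- c(A = (1 - cfg$gc) / 2, C = cfg$gc / 2,
                  G = cfg$gc / 2, T = (1 - cfg$gc) / 2)
  planted <- list()
  utrs <- with_seed(artifact_seed(cfg$seed, "utrs"), {
    vapply(seq_along(ids), function(i) {
      seq <- sample(names(base_probs), cfg$utr_len, replace = TRUE,
                    prob = base_probs)
      if (is_target[i] && length(want)) {
        occupied_start <- integer(0); occupied_end <- integer(0)
        for (ty in names(want)) {
          len <- nchar(site_dna[[ty]])
          for (k in seq_len(want[[ty]])) {
            placed <- FALSE
            for (try in seq_len(10000L)) {
              s <- sample.int(cfg$utr_len - len + 1L, 1L)
              e <- s + len - 1L
              if (!any(s <= occupied_end & e >= occupied_start)) {
                seq[s:e] <- strsplit(site_dna[[ty]], "")[[1]]
                occupied_start <- c(occupied_start, s)
                occupied_end <- c(occupied_end, e)
                planted[[length(planted) + 1L]] <<-
                  data.frame(utr_id = ids[i], start = s, site_type = ty,
                             stringsAsFactors = FALSE)
                placed <- TRUE
                break
              }
            }
            if (!placed)
              stop("could not place all requested sites in utr_len = ",
                   cfg$utr_len)
          }
        }
      }
      paste(seq, collapse = "")
    }, character(1))
  })
  names(utrs) <- ids
  planted <- do.call(rbind, c(planted, list(
    data.frame(utr_id = character(0), start = integer(0),
               site_type = character(0), stringsAsFactors = FALSE))))
  list(utrs = utrs, planted = planted, truth = truth)
}

#' Generate predictor and AGO-CLIP evidence correlated with planted truth
#'
#' Each of the `cfg$n_predictors` in silico predictors flags a true
#' target with probability `predictor_sens` and a non-target with
#' probability `1 - predictor_spec`; CLIP supporting-experiment counts
#' are Poisson with mean `clip_lambda_true` for true targets and
#' `clip_lambda_false` otherwise.
#'
#' @inheritParams gen_utrs
#' @return data.frame with columns `gene`, `pred1..predK` (logical) and
#'   `clip_evidence` (integer).
#' @export
gen_evidence <- function(cfg, truth = sim_truth(cfg)) {
  stopifnot(inherits(cfg, "sim_config"))
  is_true <- truth$genes %in% truth$true_target_ids
  n <- length(truth$genes)
  with_seed(artifact_seed(cfg$seed, "evidence"), {
    flags <- matrix(NA, n, cfg$n_predictors)
    p_hit <- ifelse(is_true, cfg$predictor_sens, 1 - cfg$predictor_spec)
    for (j in seq_len(cfg$n_predictors))
      flags[, j] <- stats::runif(n) < p_hit
    clip <- stats::rpois(n, ifelse(is_true, cfg$clip_lambda_true,
                                   cfg$clip_lambda_false))
  })
  out <- data.frame(gene = truth$genes, flags, clip_evidence = clip,
                    stringsAsFactors = FALSE)
  names(out)[1 + seq_len(cfg$n_predictors)] <-
    paste0("pred", seq_len(cfg$n_predictors))
  out
}

#' Generate a perturbation proteome with planted target repression
#'
#' Per-protein log2 baselines are drawn once; sample values are Normal
#' around them with SD `proteome_sd`.  Because the miRNA is a negative
#' regulator, knocking it down (`direction = "KD"`) raises true-target
#' abundance by `repression_log2` log2 units in the perturbed group,
#' and overexpressing it (`"OE"`) lowers it by the same amount.
#' Missing values (`NA`) are injected preferentially at low abundance.
#'
#' @inheritParams gen_utrs
#' @param direction `"KD"` (targets up in perturbed group) or `"OE"`
#'   (targets down).
#' @return list with `intensity` (proteins x samples matrix, linear
#'   scale, `NA` = not observed), `groups` (factor `control` /
#'   `perturbed` per sample) and `truth`.
#' @export
gen_proteome <- function(cfg, truth = sim_truth(cfg),
                         direction = c("KD", "OE")) {
  stopifnot(inherits(cfg, "sim_config"), cfg$n_samples_per_group >= 2L)
  direction <- match.arg(direction)
  shift <- if (direction == "KD") cfg$repression_log2 else -cfg$repression_log2
  n <- length(truth$genes)
  ns <- cfg$n_samples_per_group
  is_true <- truth$genes %in% truth$true_target_ids
  with_seed(artifact_seed(cfg$seed, paste0("proteome_", direction)), {
    baseline <- stats::rnorm(n, mean = 10, sd = 1.5)
    log2mat <- matrix(stats::rnorm(n * 2 * ns, mean = baseline,
                                   sd = cfg$proteome_sd), n, 2 * ns)
    log2mat[is_true, ns + seq_len(ns)] <-
      log2mat[is_true, ns + seq_len(ns)] + shift
    ## dropout: up to ~25% at the very bottom of the abundance range,
    ## negligible for bright proteins
    thr <- stats::quantile(baseline, 0.15)
    p_na <- 0.25 * stats::plogis((thr - log2mat) / 0.5)
    log2mat[stats::runif(length(log2mat)) < p_na] <- NA
  })
  intensity <- 2^log2mat
  dimnames(intensity) <- list(truth$genes,
                              c(paste0("ctrl_", seq_len(ns)),
                                paste0(tolower(direction), "_", seq_len(ns))))
  groups <- factor(rep(c("control", "perturbed"), each = ns),
                   levels = c("control", "perturbed"))
  list(intensity = intensity, groups = groups, direction = direction,
       truth = truth)
}

#' Generate single-cell counts over discrete cell states
#'
#' Cells are drawn from the configured states with the condition's
#' proportions.  Per-gene relative expression is a softmax of a shared
#' baseline plus `program_strength` on that state's program genes;
#' counts are negative binomial with log-normal library sizes.  In a
#' perturbed condition, true-target means in the affected states are
#' multiplied by `2^(repression_log2)` for a miRNA knock-down
#' (`direction = "KD"`, de-repression) or `2^(-repression_log2)` for an
#' overexpression (`"OE"`).
#'
#' @inheritParams gen_proteome
#' @param condition a condition name from `cfg$state_props`.
#' @param perturbed logical; whether the planted target effect applies.
#'   Defaults to every condition except the first one declared in
#'   `cfg$state_props`.
#' @param affected_states states in which targets respond; default all.
#' @return list with `counts` (genes x cells sparse dgCMatrix) and
#'   `meta` (data.frame: `barcode`, `condition`, `run`, `cell_type`,
#'   `true_state`, `mito_frac`, `doublet_score`), plus `truth`.
#' @export
gen_sc <- function(cfg, truth = sim_truth(cfg), condition = "control",
                   direction = c("KD", "OE"),
                   perturbed = condition != names(cfg$state_props)[1],
                   affected_states = truth$states) {
  stopifnot(inherits(cfg, "sim_config"))
  direction <- match.arg(direction)
  if (!condition %in% names(cfg$state_props))
    stop("no state proportions declared for condition `", condition, "`")
  props <- cfg$state_props[[condition]]
  mult <- if (direction == "KD") 2^cfg$repression_log2
          else 2^(-cfg$repression_log2)
  n_genes <- length(truth$genes)
  n_cells <- cfg$n_cells_per_condition
  is_target <- truth$genes %in% truth$true_target_ids
  ## the baseline gene profile is shared by all conditions of a study:
  ## it gets its own RNG stream so that both conditions (and any re-run)
  ## see the same per-state expression programs
  base <- with_seed(artifact_seed(cfg$seed, "sc_profile"),
                    stats::rnorm(n_genes, 0, 1))
  profile <- vapply(truth$states, function(s) {
    eta <- base + cfg$program_strength *
      (truth$genes %in% truth$state_programs[[s]])
    p <- exp(eta); p / sum(p)
  }, numeric(n_genes))
  with_seed(artifact_seed(cfg$seed, paste0("sc_", condition, "_", direction)), {
    state <- sample(truth$states, n_cells, replace = TRUE, prob = props)
    libsize <- stats::rlnorm(n_cells, meanlog = log(5000), sdlog = 0.3)
    counts <- matrix(0L, n_genes, n_cells)
    for (s in truth$states) {
      idx <- which(state == s)
      if (!length(idx)) next
      mu <- outer(profile[, s], libsize[idx])
      if (perturbed && s %in% affected_states)
        mu[is_target, ] <- mu[is_target, ] * mult
      counts[, idx] <- stats::rnbinom(length(mu), mu = mu,
                                      size = 1 / cfg$nb_dispersion)
    }
    mito <- stats::runif(n_cells, cfg$mito_frac_range[1],
                         cfg$mito_frac_range[2])
    doublet <- stats::rbeta(n_cells, 1.2, 10)
    run <- paste0("run", 1L + (seq_len(n_cells) - 1L) %% 2L)
  })
  barcodes <- sprintf("%s_cell%05d", condition, seq_len(n_cells))
  dimnames(counts) <- list(truth$genes, barcodes)
  meta <- data.frame(barcode = barcodes, condition = condition,
                     run = run, cell_type = "MG", true_state = state,
                     mito_frac = mito, doublet_score = doublet,
                     stringsAsFactors = FALSE)
  list(counts = methods::as(methods::as(Matrix::Matrix(counts), "CsparseMatrix"),
                            "generalMatrix"),
       meta = meta, truth = truth)
}

#' Write a complete fixture bundle to disk
#'
#' Generates every pipeline input from one configuration and writes:
#' UTR FASTA, evidence TSV, proteome TSV (two-row header), Matrix Market
#' counts with features/barcodes TSVs, cell metadata TSV, state-program
#' signatures GMT, a truth JSON, and a `manifest.json` listing the md5
#' hash of every file.  Identical configurations (including the seed)
#' produce byte-identical bundles.
#'
#' @inheritParams gen_utrs
#' @param outdir output directory, created if needed.
#' @param mirna miRNA sequence used to derive the planted site strings.
#' @param direction perturbation direction for proteome and single-cell
#'   data.
#' @return the manifest, invisibly (named list: file -> md5).
#' @export
write_fixture_bundle <- function(cfg, outdir,
                                 mirna = "UAACAGUCUACAGCCAUGGUCG",
                                 direction = "KD") {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(outdir, 2) != 0) stop("outdir not writable: ", outdir)
  truth <- sim_truth(cfg)
  pats <- seed_patterns(mirna)
  u <- gen_utrs(cfg, pats, truth)
  ev <- gen_evidence(cfg, truth)
  pr <- gen_proteome(cfg, truth, direction)
  sc_ctrl <- gen_sc(cfg, truth, condition = names(cfg$state_props)[1],
                    direction = direction)
  sc_pert <- gen_sc(cfg, truth, condition = names(cfg$state_props)[2],
                    direction = direction)
  counts <- cbind(sc_ctrl$counts, sc_pert$counts)
  meta <- rbind(sc_ctrl$meta, sc_pert$meta)

  paths <- c(utrs = "utrs.fasta", evidence = "evidence.tsv",
             proteome = "proteome.tsv", counts = "counts.mtx",
             features = "features.tsv", barcodes = "barcodes.tsv",
             metadata = "metadata.tsv", signatures = "signatures.gmt",
             truth = "truth.json")
  f <- function(x) file.path(outdir, paths[[x]])

  Biostrings::writeXStringSet(Biostrings::DNAStringSet(u$utrs), f("utrs"))
  utils::write.table(ev, f("evidence"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_proteome(pr$intensity, pr$groups, f("proteome"))
  Matrix::writeMM(counts, f("counts"))
  writeLines(rownames(counts), f("features"))
  writeLines(colnames(counts), f("barcodes"))
  utils::write.table(meta, f("metadata"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_gmt(truth$state_programs, f("signatures"),
            description = "synthetic state program")
  jsonlite::write_json(list(
    true_target_ids = truth$true_target_ids,
    planted_site_table = u$planted,
    true_state_labels = stats::setNames(meta$true_state, meta$barcode),
    planted_effects = stats::setNames(
      rep(cfg$repression_log2, length(truth$true_target_ids)),
      truth$true_target_ids),
    state_programs = truth$state_programs),
    f("truth"), digits = NA, pretty = TRUE)

  files <- unname(paths)
  missing <- files[!file.exists(file.path(outdir, files))]
  if (length(missing)) stop("failed to write: ", paste(missing, collapse = ", "))
  manifest <- as.list(tools::md5sum(file.path(outdir, files)))
  names(manifest) <- files
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Read a truth JSON written by [write_fixture_bundle()]
#'
#' @param path path to `truth.json`.
#' @return named list mirroring the written structure.
#' @export
read_truth <- function(path) {
  tr <- jsonlite::read_json(path, simplifyVector = TRUE)
  tr$true_target_ids <- as.character(tr$true_target_ids)
  tr
}
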