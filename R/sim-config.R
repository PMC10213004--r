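## Simulation configuration for the synthetic multi-omic study.

#' Simulation configuration
#'
#' Bundles every knob of the synthetic study into one validated object.
#' The defaults describe the study conditions the pipeline is tested
#' under: a 2000-gene universe with 50 true miRNA targets repressed by
#' one log2 unit, ten proteome samples per group with SD 0.5, seven
#' in silico predictors at 0.9 sensitivity / 0.95 specificity, AGO-CLIP
#' evidence counts Poisson(6) for true targets vs Poisson(0.5) otherwise,
#' and negative-binomial single cells distributed over three microglial
#' states (homeostatic, DAM, IRM) whose DAM fraction doubles from 10% to
#' 20% in the perturbed condition.
#'
#' @param seed master integer RNG seed; one independent stream is derived
#'   per artifact type, so e.g. changing `n_utrs` does not perturb the
#'   cell draw.
#' @param n_utrs number of UTR records to generate.
#' @param utr_len UTR length in bases.
#' @param gc background GC fraction in (0, 1).
#' @param planted_sites named integer vector, site type -> number of
#'   sites planted per true target (names from
#'   `c("8mer","7mer-m8","7mer-A1","6mer")`).
#' @param n_genes size of the gene universe.
#' @param n_true_targets number of planted true targets.
#' @param predictor_sens,predictor_spec per-predictor sensitivity and
#'   specificity.
#' @param clip_lambda_true,clip_lambda_false Poisson means of the CLIP
#'   supporting-experiment count for true / non-targets.
#' @param n_samples_per_group proteome samples per group (>= 2).
#' @param repression_log2 planted repression effect size (log2 units).
#' @param proteome_sd log2 proteome noise SD.
#' @param n_cells_per_condition cells drawn per condition.
#' @param state_props named list: condition -> named probability vector
#'   over cell states (each summing to 1).
#' @param program_strength additive boost, on the log scale of relative
#'   expression, of a state's program genes in cells of that state.
#' @param nb_dispersion negative-binomial dispersion (var = mu + disp *
#'   mu^2).
#' @param mito_frac_range length-2 numeric, range of simulated
#'   mitochondrial UMI fractions.
#' @param genes_per_program program genes per cell state.
#' @param n_predictors number of in silico prediction algorithms.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_utrs = 200L,
                       utr_len = 500L,
                       gc = 0.45,
                       planted_sites = c("8mer" = 1L, "7mer-m8" = 1L),
                       n_genes = 2000L,
                       n_true_targets = 50L,
                       predictor_sens = 0.9,
                       predictor_spec = 0.95,
                       clip_lambda_true = 6,
                       clip_lambda_false = 0.5,
                       n_samples_per_group = 10L,
                       repression_log2 = 1,
                       proteome_sd = 0.5,
                       n_cells_per_condition = 1000L,
                       state_props = list(
                         control   = c(homeostatic = 0.75, DAM = 0.10,
                                       IRM = 0.15),
                         perturbed = c(homeostatic = 0.65, DAM = 0.20,
                                       IRM = 0.15)),
                       program_strength = 1.5,
                       nb_dispersion = 0.4,
                       mito_frac_range = c(0.01, 0.10),
                       genes_per_program = 40L,
                       n_predictors = 7L) {
  cfg <- list(seed = as.integer(seed), n_utrs = as.integer(n_utrs),
              utr_len = as.integer(utr_len), gc = gc,
              planted_sites = planted_sites,
              n_genes = as.integer(n_genes),
              n_true_targets = as.integer(n_true_targets),
              predictor_sens = predictor_sens,
              predictor_spec = predictor_spec,
              clip_lambda_true = clip_lambda_true,
              clip_lambda_false = clip_lambda_false,
              n_samples_per_group = as.integer(n_samples_per_group),
              repression_log2 = repression_log2,
              proteome_sd = proteome_sd,
              n_cells_per_condition = as.integer(n_cells_per_condition),
              state_props = state_props,
              program_strength = program_strength,
              nb_dispersion = nb_dispersion,
              mito_frac_range = mito_frac_range,
              genes_per_program = as.integer(genes_per_program),
              n_predictors = as.integer(n_predictors))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  counts <- c("n_utrs", "utr_len", "n_genes", "n_true_targets",
              "n_samples_per_group", "n_cells_per_condition",
              "genes_per_program", "n_predictors")
  for (f in counts)
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || cfg[[f]] < 1)
      stop("`", f, "` must be a count >= 1")
  fracs <- c(gc = cfg$gc, sens = cfg$predictor_sens,
             spec = cfg$predictor_spec, mito_lo = cfg$mito_frac_range[1],
             mito_hi = cfg$mito_frac_range[2])
  if (any(fracs < 0 | fracs > 1))
    stop("fractions must lie in [0, 1]")
  if (cfg$gc <= 0 || cfg$gc >= 1) stop("`gc` must lie in (0, 1)")
  if (cfg$nb_dispersion <= 0) stop("`nb_dispersion` must be positive")
  if (!length(cfg$planted_sites) ||
      !all(names(cfg$planted_sites) %in% SITE_TYPES))
    stop("`planted_sites` must be named by canonical site types")
  if (any(cfg$planted_sites < 0)) stop("planted site counts must be >= 0")
  if (cfg$n_true_targets > cfg$n_genes)
    stop("more true targets than genes")
  if (!is.list(cfg$state_props) || is.null(names(cfg$state_props)))
    stop("`state_props` must be a named list of per-condition vectors")
  states <- names(cfg$state_props[[1]])
  for (p in cfg$state_props) {
    if (!identical(names(p), states))
      stop("all conditions must declare the same states, in order")
    if (abs(sum(p) - 1) > 1e-9)
      stop("state proportions must sum to 1")
    if (any(p < 0)) stop("state proportions must be non-negative")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> seed", x$seed, "|", x$n_genes, "genes,",
      x$n_true_targets, "true targets |", x$n_utrs, "UTRs x",
      x$utr_len, "nt |", x$n_samples_per_group, "samples/group |",
      x$n_cells_per_condition, "cells/condition over",
      length(names(x$state_props[[1]])), "states\n")
  invisible(x)
}

#' Planted ground truth of a simulation
#'
#' Deterministic gene universe and planted truth shared by every
#' generator: which genes are true targets, and which genes form each
#' cell state's expression program.  Programs avoid true targets so the
#' two layers of planted signal stay separable.
#'
#' @param cfg a [sim_config()].
#' @return list with `genes`, `true_target_ids`, `states` and
#'   `state_programs` (named list of program gene vectors).
#' @export
sim_truth <- function(cfg) {
  genes <- sprintf("g%04d", seq_len(cfg$n_genes))
  states <- names(cfg$state_props[[1]])
  with_seed(artifact_seed(cfg$seed, "truth"), {
    true_targets <- sort(sample(genes, cfg$n_true_targets))
    pool <- setdiff(genes, true_targets)
    need <- cfg$genes_per_program * length(states)
    if (need > length(pool))
      stop("gene universe too small for the requested state programs")
    prog <- sample(pool, need)
    programs <- split(prog, rep(states, each = cfg$genes_per_program))
    programs <- programs[states]
  })
  list(genes = genes, true_target_ids = true_targets,
       states = states, state_programs = programs)
}
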