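#' Simulation configuration for the synthetic screen and cohort generators
#'
#' Bundles every tunable of the synthetic-data module: library geometry
#' (genes, targets, controls, guides per target), screen sampling (replicates,
#' sequencing depth per pgRNA, negative-binomial dispersion, generations of
#' selection, in-vivo bottleneck noise), Poly(A)-seq sampling, and the survival
#' cohort (size, log-hazard per SD of median 3' UTR usage, censoring rate).
#'
#' Defaults mirror the screen design the generators emulate: 8 biological
#' replicates, ~2500-fold sequencing coverage per pgRNA, 150 negative-control
#' and 150 positive-control pgRNAs, 8-10 guides per target, and six Poly(A)-seq
#' runs per condition.
#'
#' @param seed Integer seed; with a fixed config the generators are
#'   bit-reproducible.
#' @param n_genes Number of genes in the synthetic poly(A)-site landscape.
#'   The first `n_targets` are "expressed" targets; the remainder are
#'   unexpressed genes whose sites feed the negative-control pool.
#' @param n_targets Number of targeted proximal poly(A) signals.
#' @param n_neg_controls,n_pos_controls Control pgRNA totals (defaults 150).
#' @param guides_min,guides_max Retained pgRNAs per target (defaults 8 and 10).
#' @param n_replicates Screen replicates per arm (default 8).
#' @param depth_per_pgrna Mean sequencing coverage per pgRNA (default 2500).
#' @param nb_dispersion Negative-binomial dispersion of counts (default 0.05;
#'   `size = 1/nb_dispersion`).
#' @param generations Cell generations between day 0 and day 20 (default 10);
#'   only the product effect x generations matters.
#' @param selection_effects Named numeric vector, target id -> per-generation
#'   log fitness effect; unnamed targets have effect 0.
#' @param bottleneck_cv Coefficient of variation of the extra multiplicative
#'   gamma noise applied to the in-vivo arm (default 0.5).
#' @param apa_shift_effects Named numeric vector, gene -> logit shift of the
#'   distal fraction in group B of the Poly(A)-seq simulation.
#' @param polyaseq_n Poly(A)-seq runs per group (default 6).
#' @param polyaseq_depth Mean per-gene total 3' end count (default 500).
#' @param cohort_size Number of patients in the synthetic cohort (default 120).
#' @param cox_beta Log hazard ratio per SD of the per-sample median 3' UTR
#'   usage (default 0; negative values make long-UTR samples lower risk).
#' @param censor_rate Expected fraction of censored subjects, in `[0, 1)`.
#'
#' @return A list of class `sim_config`.
#' @examples
#' cfg <- sim_config(seed = 1, n_genes = 40, n_targets = 6)
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 120L,
                       n_targets = 20L,
                       n_neg_controls = 150L,
                       n_pos_controls = 150L,
                       guides_min = 8L,
                       guides_max = 10L,
                       n_replicates = 8L,
                       depth_per_pgrna = 2500,
                       nb_dispersion = 0.05,
                       generations = 10,
                       selection_effects = numeric(),
                       bottleneck_cv = 0.5,
                       apa_shift_effects = numeric(),
                       polyaseq_n = 6L,
                       polyaseq_depth = 500,
                       cohort_size = 120L,
                       cox_beta = 0,
                       censor_rate = 0.3) {
  chk_count <- function(x, nm, min = 1) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != floor(x))
      abort(sprintf("`%s` must be a single integer >= %s", nm, min))
    as.integer(x)
  }
  chk_pos <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x <= 0)
      abort(sprintf("`%s` must be a single positive number", nm))
    as.numeric(x)
  }
  chk_effects <- function(x, nm) {
    if (length(x) > 0 && (!is.numeric(x) || is.null(names(x)) || any(names(x) == "")))
      abort(sprintf("`%s` must be a named numeric vector", nm))
    x
  }
  if (!is.numeric(censor_rate) || censor_rate < 0 || censor_rate >= 1)
    abort("`censor_rate` must lie in [0, 1)")
  cfg <- list(
    seed            = chk_count(seed, "seed", min = 0),
    n_genes         = chk_count(n_genes, "n_genes"),
    n_targets       = chk_count(n_targets, "n_targets"),
    n_neg_controls  = chk_count(n_neg_controls, "n_neg_controls"),
    n_pos_controls  = chk_count(n_pos_controls, "n_pos_controls", min = 0),
    guides_min      = chk_count(guides_min, "guides_min"),
    guides_max      = chk_count(guides_max, "guides_max"),
    n_replicates    = chk_count(n_replicates, "n_replicates"),
    depth_per_pgrna = chk_pos(depth_per_pgrna, "depth_per_pgrna"),
    nb_dispersion   = chk_pos(nb_dispersion, "nb_dispersion"),
    generations     = chk_pos(generations, "generations"),
    selection_effects = chk_effects(selection_effects, "selection_effects"),
    bottleneck_cv   = chk_pos(bottleneck_cv, "bottleneck_cv"),
    apa_shift_effects = chk_effects(apa_shift_effects, "apa_shift_effects"),
    polyaseq_n      = chk_count(polyaseq_n, "polyaseq_n", min = 2),
    polyaseq_depth  = chk_pos(polyaseq_depth, "polyaseq_depth"),
    cohort_size     = chk_count(cohort_size, "cohort_size"),
    cox_beta        = as.numeric(cox_beta),
    censor_rate     = as.numeric(censor_rate)
  )
  if (cfg$depth_per_pgrna < 1) abort("`depth_per_pgrna` must be >= 1")
  if (cfg$guides_min > cfg$guides_max) abort("`guides_min` must be <= `guides_max`")
  if (cfg$n_targets >= cfg$n_genes)
    abort("`n_genes` must exceed `n_targets` (extra genes seed the control pool)")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  genes: %d (%d targets), controls: %d neg / %d pos\n",
              x$n_genes, x$n_targets, x$n_neg_controls, x$n_pos_controls))
  cat(sprintf("  screen: %d replicates, depth %g x, dispersion %g, %g generations\n",
              x$n_replicates, x$depth_per_pgrna, x$nb_dispersion, x$generations))
  cat(sprintf("  cohort: n = %d, cox_beta = %g, censor_rate = %g, seed = %d\n",
              x$cohort_size, x$cox_beta, x$censor_rate, x$seed))
  invisible(x)
}

# run code under a derived seed without disturbing the caller's RNG stream;
# offsets keep the generators' streams independent of one another
with_sim_seed <- function(cfg, offset, code) {
  seed <- (cfg$seed + offset) %% .Machine$integer.max
  withr::with_seed(as.integer(seed), code)
}
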