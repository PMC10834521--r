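#' Simulate a patient cohort with 3' UTR usage profiles and survival
#'
#' Per-sample, per-gene distal-usage values in `[0, 1]` are logit-normal: each
#' gene has a baseline, each sample a global shift (so that samples genuinely
#' differ in overall 3' UTR length), plus residual noise. Survival times are
#' exponential with hazard `h0 * exp(cox_beta * z)` where `z` is the
#' standardized per-sample median usage; censoring is by an independent
#' exponential time calibrated so that roughly `censor_rate` of subjects are
#' censored under the null.
#'
#' @param cfg A [sim_config()]; uses `cohort_size`, `n_genes`, `cox_beta`,
#'   `censor_rate`.
#' @param sample_sd SD of the per-sample global logit shift (default 0.5).
#' @param resid_sd SD of residual per-gene noise (default 1).
#' @param h0 Baseline hazard per day (default 1/1000).
#' @return A list of two tibbles: `profiles` (`sample_id`, `gene`, `usage`)
#'   and `survival` (`sample_id`, `time`, `event`, `z` — the standardized
#'   median usage used in the hazard).
#' @export
gen_cohort <- function(cfg, sample_sd = 0.5, resid_sd = 1, h0 = 1e-3) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$cohort_size < 9) abort("`cohort_size` must be >= 9 for terciles")
  with_sim_seed(cfg, 707L, {
    ns <- cfg$cohort_size; ng <- cfg$n_genes
    samples <- pad_id("pt", seq_len(ns))
    genes <- pad_id("gene", seq_len(ng))
    gene_base <- rnorm(ng, 0, 1)
    sample_shift <- rnorm(ns, 0, sample_sd)
    usage <- plogis(outer(sample_shift, gene_base, "+") +
                      matrix(rnorm(ns * ng, 0, resid_sd), ns, ng))
    profiles <- tibble(
      sample_id = rep(samples, each = ng),
      gene = rep(genes, times = ns),
      usage = as.vector(t(usage))
    )
    med <- apply(usage, 1, median)
    z <- as.vector(scale(med))
    rate <- h0 * exp(cfg$cox_beta * z)
    t_event <- rexp(ns, rate)
    if (cfg$censor_rate > 0) {
      c_rate <- h0 * cfg$censor_rate / (1 - cfg$censor_rate)
      t_cens <- rexp(ns, c_rate)
    } else {
      t_cens <- rep(Inf, ns)
    }
    survival <- tibble(
      sample_id = samples,
      time = pmin(t_event, t_cens),
      event = as.integer(t_event <= t_cens),
      z = z
    )
    list(profiles = profiles, survival = survival)
  })
}
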