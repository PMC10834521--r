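#' Simulate two-condition Poly(A)-seq proximal/distal counts
#'
#' Per gene, per sample: the total 3'-end read count is negative binomial
#' around a gene-specific mean, and the distal read fraction is logit-normal
#' around a gene baseline, shifted by `cfg$apa_shift_effects` (logit units) in
#' group B. The default emulates six Poly(A)-seq runs per condition.
#'
#' @param cfg A [sim_config()]; `n_genes`, `polyaseq_n`, `polyaseq_depth`,
#'   `nb_dispersion` and `apa_shift_effects` are used.
#' @param sample_sd Between-sample SD of the distal-fraction logit
#'   (default 0.3).
#' @return Long tibble (`gene`, `sample`, `group` in `A`/`B`, `proximal`,
#'   `distal`) with attribute `truth` giving each gene's baseline logit and
#'   true shift (accessor [polyaseq_truth()]).
#' @export
gen_polyaseq_counts <- function(cfg, sample_sd = 0.3) {
  stopifnot(inherits(cfg, "sim_config"))
  shifts <- cfg$apa_shift_effects
  genes <- pad_id("gene", seq_len(cfg$n_genes))
  unknown <- setdiff(names(shifts), genes)
  if (length(unknown) > 0)
    abort(sprintf("apa_shift_effects name unknown gene(s): %s",
                  paste(unknown, collapse = ", ")))
  with_sim_seed(cfg, 606L, {
    g <- cfg$n_genes; ns <- cfg$polyaseq_n
    base_logit <- rnorm(g, 0, 1)
    mu_g <- rlnorm(g, log(cfg$polyaseq_depth), 0.5)
    shift <- setNames(rep(0, g), genes)
    shift[names(shifts)] <- shifts
    samples <- tibble(
      sample = c(sprintf("A_s%d", seq_len(ns)), sprintf("B_s%d", seq_len(ns))),
      group = rep(c("A", "B"), each = ns)
    )
    grid <- tidyr::expand_grid(gene_i = seq_len(g), samples)
    m <- nrow(grid)
    logit_frac <- base_logit[grid$gene_i] +
      ifelse(grid$group == "B", shift[grid$gene_i], 0) +
      rnorm(m, 0, sample_sd)
    total <- rnbinom(m, mu = mu_g[grid$gene_i], size = 1 / cfg$nb_dispersion)
    distal <- rbinom(m, total, plogis(logit_frac))
    out <- tibble(
      gene = genes[grid$gene_i], sample = grid$sample, group = grid$group,
      proximal = total - distal, distal = distal
    )
    attr(out, "truth") <- tibble(gene = genes, base_logit = base_logit,
                                 shift = unname(shift))
    out
  })
}

#' Ground truth attached to simulated Poly(A)-seq counts
#' @param counts Output of [gen_polyaseq_counts()].
#' @return Tibble of per-gene baseline logits and true shifts.
#' @export
polyaseq_truth <- function(counts) {
  truth <- attr(counts, "truth")
  if (is.null(truth)) abort("`counts` carries no simulation ground truth")
  truth
}
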