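#' Simulate pgRNA screen counts across arms and replicates
#'
#' Generative model for a pooled pgRNA dropout/enrichment screen: plasmid
#' relative abundances are log-normal; counts in every sample are negative
#' binomial around depth x relative abundance; between day 0 and day 20 the
#' abundance of each pgRNA is multiplied by `exp(effect x generations x
#' efficacy)`, where the per-pgRNA editing efficacy is Beta(5, 1) and applied
#' only to pgRNAs whose target has a non-zero selection effect; the in-vivo
#' arm adds one extra multiplicative gamma noise layer (mean 1, CV
#' `bottleneck_cv`) per pgRNA and replicate, modelling the engraftment
#' bottleneck. Arms share the day-0 reference per replicate.
#'
#' @param library Library tibble from [build_library()].
#' @param cfg A [sim_config()]; `cfg$selection_effects` must be keyed by
#'   `target_id`s present in the library.
#' @return A long count tibble (`pgRNA_id`, `sample_id`, `arm`, `replicate`,
#'   `count`) with attribute `truth` (per-pgRNA effect and efficacy) readable
#'   via [screen_truth()].
#' @export
gen_screen_counts <- function(library, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  stopifnot_cols(library, c("pgRNA_id", "target_id", "category"))
  if (nrow(library) == 0) abort("`library` must be non-empty")
  eff <- cfg$selection_effects
  unknown <- setdiff(names(eff), unique(library$target_id))
  if (length(unknown) > 0)
    abort(sprintf("selection_effects name unknown target(s): %s",
                  paste(unknown, collapse = ", ")))
  with_sim_seed(cfg, 505L, {
    n <- nrow(library)
    size <- 1 / cfg$nb_dispersion
    depth_total <- cfg$depth_per_pgrna * n
    rel <- local({ a <- rlnorm(n, 0, 0.5); a / sum(a) })
    effect <- unname(ifelse(library$target_id %in% names(eff),
                            eff[library$target_id], 0))
    efficacy <- ifelse(effect != 0, rbeta(n, 5, 1), 1)
    nb_sample <- function(abund, sample_id, arm, replicate) {
      tibble(pgRNA_id = library$pgRNA_id, sample_id = sample_id,
             arm = arm, replicate = replicate,
             count = rnbinom(n, mu = depth_total * abund / sum(abund),
                             size = size))
    }
    growth <- exp(effect * cfg$generations * efficacy)
    out <- vector("list", 1 + 3 * cfg$n_replicates)
    out[[1]] <- nb_sample(rel, "plasmid", "plasmid", NA_integer_)
    j <- 2
    for (r in seq_len(cfg$n_replicates)) {
      d20 <- rel * growth
      shape <- 1 / cfg$bottleneck_cv^2
      vivo <- d20 * rgamma(n, shape = shape, rate = shape)
      out[[j]] <- nb_sample(rel, sprintf("day0_r%d", r), "day0", r)
      out[[j + 1]] <- nb_sample(d20, sprintf("invitro_d20_r%d", r), "invitro_d20", r)
      out[[j + 2]] <- nb_sample(vivo, sprintf("invivo_d20_r%d", r), "invivo_d20", r)
      j <- j + 3
    }
    counts <- purrr::list_rbind(out)
    attr(counts, "truth") <- tibble(
      pgRNA_id = library$pgRNA_id, target_id = library$target_id,
      category = library$category, effect = effect, efficacy = efficacy
    )
    counts
  })
}

#' Ground truth attached to simulated screen counts
#' @param counts Output of [gen_screen_counts()].
#' @return Tibble of per-pgRNA true effects and efficacies.
#' @export
screen_truth <- function(counts) {
  truth <- attr(counts, "truth")
  if (is.null(truth)) abort("`counts` carries no simulation ground truth")
  truth
}

#' Simulate paired guide reads from a count table
#'
#' Expands each (pgRNA, sample) count into that many read pairs carrying the
#' pgRNA's two guide sequences. A fraction `error_rate` of pairs is corrupted
#' into discordant pairs — the second read swapped in from a different pgRNA —
#' to exercise the concordance-discard logic of the counting stage. Intended
#' for small configurations; screen-scale analyses start from counts.
#'
#' @param library Library tibble (needs `pgRNA_id`, `seq_left`, `seq_right`).
#' @param counts Long count tibble.
#' @param error_rate Fraction of discordant pairs, in `[0, 0.2]`.
#' @param seed Integer seed.
#' @return Tibble of read pairs: `read1`, `read2`, `sample_id`.
#' @export
gen_paired_reads <- function(library, counts, error_rate = 0, seed = 1L) {
  if (error_rate < 0 || error_rate > 0.2)
    abort("`error_rate` must lie in [0, 0.2]")
  stopifnot_cols(library, c("pgRNA_id", "seq_left", "seq_right"))
  stopifnot_cols(counts, c("pgRNA_id", "sample_id", "count"))
  withr::with_seed(as.integer(seed), {
    idx <- rep(seq_len(nrow(counts)), counts$count)
    lib_row <- match(counts$pgRNA_id[idx], library$pgRNA_id)
    if (anyNA(lib_row)) abort("counts reference pgRNAs absent from the library")
    reads <- tibble(
      read1 = library$seq_left[lib_row],
      read2 = library$seq_right[lib_row],
      sample_id = counts$sample_id[idx]
    )
    if (error_rate > 0 && nrow(reads) > 0 && nrow(library) > 1) {
      bad <- which(runif(nrow(reads)) < error_rate)
      # pgRNAs of one target share guides, so a swapped-in read2 must be checked
      # against the full pair table to guarantee the corrupted pair is discordant
      pair_key <- paste(library$seq_left, library$seq_right)
      pending <- bad
      for (tries in seq_len(50)) {
        if (length(pending) == 0) break
        other <- (lib_row[pending] + sample.int(nrow(library) - 1L,
                                                length(pending), replace = TRUE) - 1L) %%
          nrow(library) + 1L
        new2 <- library$seq_right[other]
        ok <- !(paste(reads$read1[pending], new2) %in% pair_key)
        reads$read2[pending[ok]] <- new2[ok]
        pending <- pending[!ok]
      }
    }
    reads
  })
}
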