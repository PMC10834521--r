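#' Generate a synthetic poly(A)-site landscape
#'
#' Each gene gets two poly(A) sites in its 3' UTR — one proximal, one distal in
#' transcription order — on a toy single-chromosome-per-gene coordinate system.
#' Sites carry a 6-nt signal hexamer interval (0-based half-open), a signal
#' class, a tissue-support count and a detected-sample fraction, emulating a
#' PolyA-DB style annotation. The first `n_targets` genes are flagged expressed
#' (screen targets); the remaining genes are unexpressed and feed the
#' negative-control pool.
#'
#' @param cfg A [sim_config()].
#' @return A tibble with one row per site: `gene`, `site_id`, `chrom`,
#'   `strand`, `hexamer_start`, `hexamer_end`, `signal_class`, `rank`
#'   (`"proximal"`/`"distal"`), `tissue_count`, `sample_fraction`, `expressed`.
#' @examples
#' gen_pas_landscape(sim_config(seed = 7, n_genes = 4, n_targets = 2))
#' @export
gen_pas_landscape <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_sim_seed(cfg, 101L, {
    n <- cfg$n_genes
    gene <- pad_id("gene", seq_len(n))
    strand <- sample(c("+", "-"), n, replace = TRUE)
    # transcript-order positions of the two hexamers within the 3' UTR
    tx_prox <- 500L + sample.int(1500L, n, replace = TRUE)
    tx_dist <- tx_prox + 500L + sample.int(2500L, n, replace = TRUE)
    span <- 10000L
    per_gene <- tibble(
      gene = gene, strand = strand,
      chrom = paste0("chr_", gene),
      tx_prox = tx_prox, tx_dist = tx_dist
    )
    long <- tidyr::pivot_longer(per_gene, c("tx_prox", "tx_dist"),
                                names_to = "rank", values_to = "tx_pos")
    long$rank <- ifelse(long$rank == "tx_prox", "proximal", "distal")
    # genome coordinate: transcription runs left-to-right on "+", right-to-left on "-"
    long$hexamer_start <- ifelse(long$strand == "+", long$tx_pos, span - long$tx_pos - 6L)
    long$hexamer_end <- long$hexamer_start + 6L
    m <- nrow(long)
    long$signal_class <- sample(c("AATAAA", "ATTAAA", "other"), m,
                                replace = TRUE, prob = c(0.7, 0.2, 0.1))
    long$tissue_count <- 1L + rpois(m, 12)
    long$sample_fraction <- round(rbeta(m, 4, 2), 4)
    long$site_id <- paste0(long$gene, "_", substr(long$rank, 1, 4))
    long$expressed <- long$gene %in% gene[seq_len(cfg$n_targets)]
    long |>
      select("gene", "site_id", "chrom", "strand", "hexamer_start",
             "hexamer_end", "signal_class", "rank", "tissue_count",
             "sample_fraction", "expressed") |>
      arrange(.data$gene, dplyr::desc(.data$rank == "proximal"))
  })
}

#' Generate candidate guides around each poly(A) signal
#'
#' Emulates a GuideScan-style candidate table: for every site, all candidate
#' cut positions fall within 100 bp up- or downstream of the signal hexamer
#' (plus an occasional cut inside the hexamer, which design-time filtering
#' removes). On-target scores are Uniform(0, 100); 2-mismatch off-target site
#' counts are Poisson(0.5) and 3-mismatch counts Poisson(10). Guide
#' "sequences" are random 20-mers used as exact-match tokens by the counting
#' module.
#'
#' @param sites Site tibble from [gen_pas_landscape()] (any subset).
#' @param cfg A [sim_config()].
#' @param n_per_side Candidates drawn on each side of the hexamer (default 8).
#' @return Tibble of candidates: `guide_id`, `gene`, `site_id`, `chrom`,
#'   `strand`, `sequence`, `cut_position` (inter-base, 0-based), `side`
#'   (`upstream`/`downstream`/`within`, in transcription order),
#'   `on_target_score`, `offtargets_2mm`, `offtargets_3mm`.
#' @export
gen_guide_candidates <- function(sites, cfg, n_per_side = 8L) {
  stopifnot(inherits(cfg, "sim_config"))
  if (nrow(sites) == 0) abort("`sites` must be non-empty")
  stopifnot_cols(sites, c("site_id", "gene", "chrom", "strand",
                          "hexamer_start", "hexamer_end"))
  with_sim_seed(cfg, 202L, {
    one_site <- function(s) {
      hs <- s$hexamer_start; he <- s$hexamer_end
      left <- sample(seq(hs - 100L, hs), n_per_side)
      right <- sample(seq(he, he + 100L), n_per_side)
      inside <- sample(seq(hs + 1L, he - 1L), 1L)
      cut <- c(left, right, inside)
      genomic_side <- rep(c("left", "right", "within"),
                          c(n_per_side, n_per_side, 1L))
      side <- ifelse(genomic_side == "within", "within",
                     ifelse((genomic_side == "left") == (s$strand == "+"),
                            "upstream", "downstream"))
      k <- length(cut)
      tibble(
        guide_id = paste0(s$site_id, "_g", sprintf("%02d", seq_len(k))),
        gene = s$gene, site_id = s$site_id, chrom = s$chrom, strand = s$strand,
        sequence = random_seqs(k),
        cut_position = cut, side = side,
        on_target_score = round(runif(k, 0, 100), 2),
        offtargets_2mm = rpois(k, 0.5),
        offtargets_3mm = rpois(k, 10)
      )
    }
    out <- purrr::map(seq_len(nrow(sites)), function(i) one_site(sites[i, ])) |>
      purrr::list_rbind()
    # exact-match counting requires unique tokens
    while (anyDuplicated(out$sequence) > 0) {
      dup <- duplicated(out$sequence)
      out$sequence[dup] <- random_seqs(sum(dup))
    }
    out
  })
}

random_seqs <- function(k, len = 20L) {
  vapply(seq_len(k), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}
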