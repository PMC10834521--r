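#' Select the proximal poly(A) site to target per gene
#'
#' Filters sites on tissue support and detected-sample fraction, then returns,
#' per gene, the most proximal passing site — "proximal" in transcription
#' order, i.e. the smallest hexamer coordinate on the plus strand and the
#' largest on the minus strand. Genes with no passing site are omitted.
#'
#' @param sites Tibble of poly(A) sites with `gene`, `strand`,
#'   `hexamer_start`, `tissue_count`, `sample_fraction` columns.
#' @param min_tissues Minimum tissue-support count (inclusive).
#' @param min_fraction Minimum detected-sample fraction (inclusive).
#' @return Tibble, one row per retained gene.
#' @export
select_target_pas <- function(sites, min_tissues = 5L, min_fraction = 0.2) {
  stopifnot_cols(sites, c("gene", "strand", "hexamer_start",
                          "tissue_count", "sample_fraction"))
  sites |>
    filter(.data$tissue_count >= min_tissues,
           .data$sample_fraction >= min_fraction) |>
    group_by(.data$gene) |>
    filter(if (dplyr::first(.data$strand) == "+") {
      .data$hexamer_start == min(.data$hexamer_start)
    } else {
      .data$hexamer_start == max(.data$hexamer_start)
    }) |>
    slice(1) |>
    ungroup()
}

#' Filter candidate guides on off-target and on-target criteria
#'
#' Retains guides with at most two 2-mismatch off-target sites, at most thirty
#' 3-mismatch off-target sites, and an on-target score of at least 30
#' ("more than" exclusions are strict, so the boundaries are inclusive).
#' Guides cutting inside the signal hexamer (`side == "within"`) are also
#' removed since they cannot flank a clean excision. Order-preserving and
#' idempotent.
#'
#' @param candidates Tibble from [gen_guide_candidates()] or a GuideScan-style
#'   table with the same columns.
#' @param max_offtargets_2mm,max_offtargets_3mm,min_score Inclusive thresholds.
#' @return The retained rows, in input order.
#' @export
filter_guides <- function(candidates, max_offtargets_2mm = 2L,
                          max_offtargets_3mm = 30L, min_score = 30) {
  stopifnot_cols(candidates, c("on_target_score", "offtargets_2mm",
                               "offtargets_3mm", "side"))
  if (nrow(candidates) == 0) return(candidates)
  if (any(candidates$offtargets_2mm < 0) || any(candidates$offtargets_3mm < 0))
    abort("off-target counts must be non-negative")
  candidates |>
    filter(.data$offtargets_2mm <= max_offtargets_2mm,
           .data$offtargets_3mm <= max_offtargets_3mm,
           .data$on_target_score >= min_score,
           .data$side != "within")
}

#' Enumerate all pgRNA pairs that excise a poly(A) signal
#'
#' Combines filtered candidates for one site in a pairwise fashion and keeps
#' every pair whose deletion interval — the span between the two cut sites,
#' 0-based half-open — fully contains the signal hexamer. Pair efficiency is
#' the weaker of the two on-target scores; pair specificity is the elementwise
#' sum of the guides' off-target counts.
#'
#' @param candidates Filtered candidate tibble for one site.
#' @param site One-row site tibble (needs `site_id`, `hexamer_start`,
#'   `hexamer_end`).
#' @param partial_overlap If `TRUE`, accept pairs whose deletion interval only
#'   overlaps (rather than contains) the hexamer.
#' @return Tibble of pairs: `pgRNA_id`, `target_id`, ids/sequences/cuts of the
#'   left and right guide, `deletion_start`, `deletion_end`, `pair_efficiency`,
#'   `offtargets_2mm_sum`, `offtargets_3mm_sum`.
#' @export
enumerate_pairs <- function(candidates, site, partial_overlap = FALSE) {
  stopifnot_cols(site, c("site_id", "hexamer_start", "hexamer_end"))
  cand <- candidates[candidates$site_id == site$site_id[1], , drop = FALSE]
  empty <- tibble(
    pgRNA_id = character(), target_id = character(), gene = character(),
    chrom = character(), strand = character(),
    guide_left_id = character(), guide_right_id = character(),
    seq_left = character(), seq_right = character(),
    cut_left = integer(), cut_right = integer(),
    deletion_start = integer(), deletion_end = integer(),
    hexamer_start = integer(), hexamer_end = integer(),
    pair_efficiency = numeric(),
    offtargets_2mm_sum = integer(), offtargets_3mm_sum = integer()
  )
  if (nrow(cand) < 2) return(empty)
  hs <- site$hexamer_start[1]; he <- site$hexamer_end[1]
  idx <- combn(nrow(cand), 2)
  a <- cand[idx[1, ], ]; b <- cand[idx[2, ], ]
  left <- ifelse(a$cut_position <= b$cut_position, TRUE, FALSE)
  lo <- ifelse(left, a$cut_position, b$cut_position)
  hi <- ifelse(left, b$cut_position, a$cut_position)
  keep <- if (partial_overlap) lo < he & hi > hs else lo <= hs & hi >= he
  if (!any(keep)) return(empty)
  a <- a[keep, ]; b <- b[keep, ]
  lo <- lo[keep]; hi <- hi[keep]; left <- left[keep]
  gl <- ifelse(left, a$guide_id, b$guide_id)
  gr <- ifelse(left, b$guide_id, a$guide_id)
  sl <- ifelse(left, a$sequence, b$sequence)
  sr <- ifelse(left, b$sequence, a$sequence)
  tibble(
    pgRNA_id = paste0(site$site_id[1], "|", gl, "|", gr),
    target_id = site$site_id[1],
    gene = cand$gene[1], chrom = cand$chrom[1], strand = cand$strand[1],
    guide_left_id = gl, guide_right_id = gr,
    seq_left = sl, seq_right = sr,
    cut_left = as.integer(lo), cut_right = as.integer(hi),
    deletion_start = as.integer(lo), deletion_end = as.integer(hi),
    hexamer_start = as.integer(hs), hexamer_end = as.integer(he),
    pair_efficiency = pmin(a$on_target_score, b$on_target_score),
    offtargets_2mm_sum = as.integer(a$offtargets_2mm + b$offtargets_2mm),
    offtargets_3mm_sum = as.integer(a$offtargets_3mm + b$offtargets_3mm)
  ) |>
    arrange(.data$pgRNA_id)
}

#' Rank and select pgRNAs per target
#'
#' Targets with fewer than `k_min` candidate pairs are dropped (recorded in the
#' `dropped_targets` attribute); targets with more than `k_max` are reduced to
#' `k_max` by ranking on pair efficiency (descending), then 2-mismatch
#' off-target sum (ascending), then 3-mismatch sum (ascending), with a final
#' deterministic tie-break on `pgRNA_id`.
#'
#' @param pairs Tibble of enumerated pairs across targets (column `target_id`).
#' @param k_min,k_max Minimum and maximum pgRNAs per target (defaults 8, 10).
#' @return The selected pairs; attribute `dropped_targets` lists targets with
#'   fewer than `k_min` pairs.
#' @export
select_pgrnas <- function(pairs, k_min = 8L, k_max = 10L) {
  stopifnot_cols(pairs, c("target_id", "pgRNA_id", "pair_efficiency",
                          "offtargets_2mm_sum", "offtargets_3mm_sum"))
  n_per <- table(pairs$target_id)
  dropped <- names(n_per)[n_per < k_min]
  kept <- pairs |>
    filter(!(.data$target_id %in% dropped)) |>
    arrange(.data$target_id, dplyr::desc(.data$pair_efficiency),
            .data$offtargets_2mm_sum, .data$offtargets_3mm_sum,
            .data$pgRNA_id) |>
    group_by(.data$target_id) |>
    slice(seq_len(k_max)) |>
    ungroup() |>
    arrange(.data$target_id, .data$pgRNA_id)
  attr(kept, "dropped_targets") <- dropped
  kept
}

#' Draw distribution-matched negative-control pgRNAs
#'
#' Repeatedly draws `n` pgRNAs without replacement from a pool (pairs designed
#' against poly(A) signals of unexpressed genes) and accepts the first draw
#' whose two-sample Kolmogorov-Smirnov statistic against the targeting library
#' is at most `ks_tol` for pair efficiency *and* for total off-target count.
#' If no draw passes within `max_iter` attempts, the best-seen draw is
#' returned with attribute `matched = FALSE` and a warning.
#'
#' @param control_pool Candidate control pairs (>= `n` rows).
#' @param reference The targeting library to match.
#' @param n Number of controls to select (default 150).
#' @param seed Integer seed for the draws.
#' @param max_iter Maximum number of draws (default 100).
#' @param ks_tol Acceptance threshold on both KS statistics (default 0.1).
#' @return `n` selected control pairs with attributes `matched`,
#'   `ks_efficiency`, `ks_offtargets`, `n_draws`.
#' @export
pick_controls <- function(control_pool, reference, n = 150L, seed = 1L,
                          max_iter = 100L, ks_tol = 0.1) {
  stopifnot_cols(control_pool, c("pgRNA_id", "pair_efficiency",
                                 "offtargets_2mm_sum", "offtargets_3mm_sum"))
  if (nrow(control_pool) < n)
    abort(sprintf("control pool has %d pgRNAs but %d are requested",
                  nrow(control_pool), n))
  ref_eff <- reference$pair_efficiency
  ref_off <- reference$offtargets_2mm_sum + reference$offtargets_3mm_sum
  pool_off <- control_pool$offtargets_2mm_sum + control_pool$offtargets_3mm_sum
  ks_stat <- function(x, y) {
    suppressWarnings(unname(ks.test(x, y)$statistic))
  }
  withr::with_seed(as.integer(seed), {
    best <- NULL; best_score <- Inf
    for (i in seq_len(max_iter)) {
      idx <- sample.int(nrow(control_pool), n)
      d_eff <- ks_stat(control_pool$pair_efficiency[idx], ref_eff)
      d_off <- ks_stat(pool_off[idx], ref_off)
      if (max(d_eff, d_off) < best_score) {
        best_score <- max(d_eff, d_off)
        best <- list(idx = idx, d_eff = d_eff, d_off = d_off, draws = i)
      }
      if (d_eff <= ks_tol && d_off <= ks_tol) break
    }
    out <- control_pool[best$idx, , drop = FALSE]
    matched <- best$d_eff <= ks_tol && best$d_off <= ks_tol
    if (!matched)
      warn(sprintf(paste0("no control draw matched the library within ks_tol = %g ",
                          "after %d draws; returning best seen (KS %.3f / %.3f)"),
                   ks_tol, max_iter, best$d_eff, best$d_off))
    attr(out, "matched") <- matched
    attr(out, "ks_efficiency") <- best$d_eff
    attr(out, "ks_offtargets") <- best$d_off
    attr(out, "n_draws") <- best$draws
    out
  })
}

#' Design a complete pgRNA library from a site landscape
#'
#' End-to-end designer: selects the proximal target site per expressed gene,
#' filters candidate guides, enumerates and ranks pairs, assembles the
#' negative-control set from unexpressed genes with distribution matching, and
#' appends opaque gene-knockout positive-control pgRNAs.
#'
#' @param sites Output of [gen_pas_landscape()] (or a compatible site table
#'   with an `expressed` flag).
#' @param candidates Output of [gen_guide_candidates()].
#' @param cfg A [sim_config()].
#' @param min_tissues,min_fraction Passed to [select_target_pas()].
#' @return Library tibble, one row per pgRNA, with `category` in
#'   `targeting` / `neg_control` / `pos_control`.
#' @export
build_library <- function(sites, candidates, cfg,
                          min_tissues = 1L, min_fraction = 0) {
  stopifnot(inherits(cfg, "sim_config"))
  filt <- filter_guides(candidates)
  proximal <- sites |>
    filter(.data$rank == "proximal") |>
    select_target_pas(min_tissues = min_tissues, min_fraction = min_fraction)
  pairs_for <- function(site_ids) {
    purrr::map(site_ids, function(sid) {
      enumerate_pairs(filt, proximal[proximal$site_id == sid, ])
    }) |> purrr::list_rbind()
  }
  target_sites <- proximal$site_id[proximal$expressed]
  ctrl_sites <- proximal$site_id[!proximal$expressed]
  targeting <- pairs_for(target_sites) |> select_pgrnas(cfg$guides_min, cfg$guides_max)
  ctrl_pool <- pairs_for(ctrl_sites) |> select_pgrnas(cfg$guides_min, cfg$guides_max)
  negs <- pick_controls(ctrl_pool, targeting, n = cfg$n_neg_controls,
                        seed = cfg$seed + 303L)
  targeting$category <- "targeting"
  negs$category <- "neg_control"
  pos <- gen_pos_controls(cfg)
  lib <- bind_rows(as_tibble(targeting), as_tibble(negs), pos) |>
    arrange(.data$category, .data$target_id, .data$pgRNA_id)
  attr(lib, "dropped_targets") <- attr(targeting, "dropped_targets")
  lib
}

# opaque gene-KO positive controls (essential / tumour-suppressor genes);
# pairing geometry is not modelled for these records
gen_pos_controls <- function(cfg, n_genes = 15L) {
  if (cfg$n_pos_controls == 0) return(NULL)
  with_sim_seed(cfg, 404L, {
    per <- ceiling(cfg$n_pos_controls / n_genes)
    gene <- rep(pad_id("ko_gene", seq_len(n_genes)), each = per)[seq_len(cfg$n_pos_controls)]
    k <- cfg$n_pos_controls
    tibble(
      pgRNA_id = paste0(gene, "|ko", sprintf("%03d", seq_len(k))),
      target_id = gene, gene = gene,
      seq_left = random_seqs(k), seq_right = random_seqs(k),
      pair_efficiency = round(runif(k, 30, 100), 2),
      offtargets_2mm_sum = rpois(k, 1),
      offtargets_3mm_sum = rpois(k, 20),
      category = "pos_control"
    )
  })
}

#' Summarise library composition
#'
#' @param library A library tibble from [build_library()].
#' @return A tibble with per-category pgRNA and target totals.
#' @export
library_summary <- function(library) {
  stopifnot_cols(library, c("pgRNA_id", "target_id", "category"))
  library |>
    group_by(.data$category) |>
    summarise(n_pgRNAs = n(),
              n_targets = dplyr::n_distinct(.data$target_id),
              .groups = "drop")
}
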