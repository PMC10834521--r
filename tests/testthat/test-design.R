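mk_site <- function(site_id = "s1", hs = 100L, strand = "+", gene = "g1") {
  tibble::tibble(gene = gene, site_id = site_id, chrom = "chr1",
                 strand = strand, hexamer_start = hs, hexamer_end = hs + 6L)
}

mk_cand <- function(site, cuts, score = 50, off2 = 0L, off3 = 0L,
                    side = NULL) {
  hs <- site$hexamer_start; he <- site$hexamer_end
  if (is.null(side)) {
    side <- ifelse(cuts <= hs, "upstream",
                   ifelse(cuts >= he, "downstream", "within"))
  }
  tibble::tibble(
    guide_id = paste0(site$site_id, "_g", seq_along(cuts)),
    gene = site$gene, site_id = site$site_id, chrom = site$chrom,
    strand = site$strand, sequence = paste0("seq", seq_along(cuts)),
    cut_position = as.integer(cuts), side = side,
    on_target_score = rep_len(score, length(cuts)),
    offtargets_2mm = as.integer(rep_len(off2, length(cuts))),
    offtargets_3mm = as.integer(rep_len(off3, length(cuts)))
  )
}

test_that("the most proximal passing site is selected per gene, in transcription order", {
  sites <- tibble::tibble(
    gene = c("g1", "g1", "g2", "g2", "g3"),
    strand = c("+", "+", "-", "-", "+"),
    hexamer_start = c(100L, 900L, 100L, 900L, 50L),
    tissue_count = c(10L, 10L, 10L, 10L, 1L),
    sample_fraction = c(0.5, 0.5, 0.5, 0.5, 0.5)
  )
  sel <- select_target_pas(sites, min_tissues = 5, min_fraction = 0.2)
  expect_equal(sel$hexamer_start[sel$gene == "g1"], 100)   # + strand: leftmost
  expect_equal(sel$hexamer_start[sel$gene == "g2"], 900)   # - strand: rightmost
  expect_false("g3" %in% sel$gene)                         # fails min_tissues
})

test_that("minus-strand proximal selection matches a transcription-order oracle", {
  set.seed(42)
  for (i in 1:20) {
    n <- sample(2:5, 1)
    sites <- tibble::tibble(
      gene = "g", strand = sample(c("+", "-"), 1),
      hexamer_start = sample.int(10000, n),
      tissue_count = 10L, sample_fraction = 0.9
    )
    sel <- select_target_pas(sites, 1, 0)
    want <- if (sites$strand[1] == "+") min(sites$hexamer_start) else max(sites$hexamer_start)
    expect_equal(sel$hexamer_start, want)
  }
})

test_that("guide filtering applies the stated inclusive boundaries", {
  s <- mk_site()
  cand <- dplyr::bind_rows(
    mk_cand(s, 50, score = 29.9),                      # score just below 30
    mk_cand(s, 51, score = 30, off2 = 2, off3 = 30),   # all boundaries inclusive
    mk_cand(s, 52, score = 80, off2 = 3),              # >2 two-mismatch
    mk_cand(s, 53, score = 80, off3 = 31),             # >30 three-mismatch
    mk_cand(s, 103, score = 80)                        # cuts within the hexamer
  )
  cand$guide_id <- paste0("c", 1:5)
  kept <- filter_guides(cand)
  expect_equal(kept$guide_id, "c2")
  expect_identical(filter_guides(kept), kept)          # idempotent
  expect_identical(filter_guides(cand[0, ]), cand[0, ])
  expect_error(filter_guides(dplyr::mutate(cand, offtargets_2mm = -1L)),
               "non-negative")
})

test_that("pair enumeration enforces hexamer containment", {
  s <- mk_site(hs = 100L)
  cand <- mk_cand(s, c(90, 120))
  pairs <- enumerate_pairs(cand, s)
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$deletion_start, 90)
  expect_equal(pairs$deletion_end, 120)

  # 3 upstream x 4 downstream, all clearing the hexamer -> 12 pairs
  cand2 <- mk_cand(s, c(80, 85, 90, 110, 115, 120, 125))
  expect_equal(nrow(enumerate_pairs(cand2, s)), 12)

  # a downstream cut inside the hexamer forms no pairs
  cand3 <- mk_cand(s, c(90, 104))
  expect_equal(nrow(enumerate_pairs(cand3, s)), 0)
})

test_that("enumeration + selection match brute force on random instances", {
  set.seed(7)
  for (i in 1:60) {
    s <- mk_site(hs = 100L)
    k <- sample(4:20, 1)
    cand <- mk_cand(s, cuts = sample(seq(0, 206), k),
                    score = round(runif(k, 0, 100), 2),
                    off2 = rpois(k, 1), off3 = rpois(k, 10))
    cand <- filter_guides(cand)
    if (nrow(cand) < 2) next
    got <- enumerate_pairs(cand, s)
    want <- oracle_enumerate_pairs(cand, s$hexamer_start, s$hexamer_end)
    expect_equal(nrow(got), nrow(want))
    o1 <- order(got$deletion_start, got$deletion_end, got$pair_efficiency)
    o2 <- order(want$lo, want$hi, want$eff)
    expect_equal(got$deletion_start[o1], want$lo[o2])
    expect_equal(got$deletion_end[o1], want$hi[o2])
    expect_equal(got$pair_efficiency[o1], want$eff[o2])
    expect_equal(got$offtargets_2mm_sum[o1], want$off2[o2])
    expect_equal(got$offtargets_3mm_sum[o1], want$off3[o2])
    # every emitted deletion contains the hexamer
    expect_true(all(got$deletion_start <= s$hexamer_start &
                      got$deletion_end >= s$hexamer_end))

    sel <- select_pgrnas(got, k_min = 8, k_max = 10)
    if (nrow(got) < 8) {
      expect_equal(nrow(sel), 0)
    } else {
      expect_equal(nrow(sel), min(10, nrow(got)))
      # brute-force ranking oracle
      ord <- got[order(-got$pair_efficiency, got$offtargets_2mm_sum,
                       got$offtargets_3mm_sum, got$pgRNA_id), ]
      expect_setequal(sel$pgRNA_id, ord$pgRNA_id[seq_len(min(10, nrow(got)))])
    }
  }
})

test_that("targets below the pgRNA minimum are dropped and logged", {
  s <- mk_site(hs = 100L)
  cand <- mk_cand(s, c(80, 85, 90, 110, 115, 120))    # 3 x 3 = 9 pairs
  nine <- enumerate_pairs(cand, s)
  expect_equal(nrow(nine), 9)
  kept <- select_pgrnas(nine)
  expect_equal(nrow(kept), 9)                          # within [8, 10]: kept whole
  seven <- nine[1:7, ]
  dropped <- select_pgrnas(seven)
  expect_equal(nrow(dropped), 0)
  expect_equal(attr(dropped, "dropped_targets"), "s1")
})

test_that("control matching draws until the KS criterion is met", {
  set.seed(3)
  ref <- tibble::tibble(
    pgRNA_id = paste0("t", 1:300),
    pair_efficiency = runif(300, 30, 100),
    offtargets_2mm_sum = rpois(300, 1),
    offtargets_3mm_sum = rpois(300, 20)
  )
  pool <- dplyr::mutate(ref, pgRNA_id = paste0("c", 1:300))
  picked <- pick_controls(pool, ref, n = 150, seed = 11)
  expect_equal(nrow(picked), 150)
  expect_true(attr(picked, "matched"))
  # recompute the KS statistics on the returned set
  d_eff <- suppressWarnings(ks.test(picked$pair_efficiency,
                                    ref$pair_efficiency)$statistic)
  d_off <- suppressWarnings(ks.test(
    picked$offtargets_2mm_sum + picked$offtargets_3mm_sum,
    ref$offtargets_2mm_sum + ref$offtargets_3mm_sum)$statistic)
  expect_lte(unname(d_eff), 0.1)
  expect_lte(unname(d_off), 0.1)
  expect_error(pick_controls(pool[1:100, ], ref, n = 150), "150")
})

test_that("a designed library satisfies its composition invariants", {
  scr <- small_screen(seed = 41)
  lib <- scr$lib
  summ <- library_summary(lib)
  expect_equal(summ$n_pgRNAs[summ$category == "neg_control"], 40)
  expect_equal(summ$n_pgRNAs[summ$category == "pos_control"], 10)
  per_target <- dplyr::count(dplyr::filter(lib, category == "targeting"),
                             target_id)
  expect_true(all(per_target$n >= 8 & per_target$n <= 10))
  tg <- dplyr::filter(lib, category != "pos_control")
  expect_true(all(tg$deletion_start <= tg$hexamer_start &
                    tg$deletion_end >= tg$hexamer_end))
  expect_false(any(duplicated(lib$pgRNA_id)))
})
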