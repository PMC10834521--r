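test_that("sim_config validates its fields", {
  expect_s3_class(sim_config(seed = 7), "sim_config")
  expect_error(sim_config(depth_per_pgrna = 0), "positive")
  expect_error(sim_config(nb_dispersion = -1), "positive")
  expect_error(sim_config(censor_rate = 1), "censor_rate")
  expect_error(sim_config(n_genes = 10, n_targets = 10), "exceed")
  expect_error(sim_config(selection_effects = c(1, 2)), "named")
})

test_that("pas landscape has two ordered sites per gene and is deterministic", {
  cfg <- sim_config(seed = 7, n_genes = 100, n_targets = 10)
  sites <- gen_pas_landscape(cfg)
  expect_equal(nrow(sites), 200)
  expect_equal(sum(sites$rank == "proximal"), 100)
  expect_true(all(sites$hexamer_end - sites$hexamer_start == 6))
  # proximal 5' of distal in transcription order on both strands
  wide <- tidyr::pivot_wider(sites[, c("gene", "strand", "rank", "hexamer_start")],
                             names_from = "rank", values_from = "hexamer_start")
  plus <- wide$strand == "+"
  expect_true(all(wide$proximal[plus] < wide$distal[plus]))
  expect_true(all(wide$proximal[!plus] > wide$distal[!plus]))
  expect_identical(sites, gen_pas_landscape(cfg))
  expect_false(identical(sites, gen_pas_landscape(sim_config(seed = 8, n_genes = 100, n_targets = 10))))
})

test_that("guide candidates stay within 100 bp of the hexamer", {
  cfg <- small_cfg(seed = 11)
  sites <- gen_pas_landscape(cfg)
  cands <- gen_guide_candidates(sites, cfg)
  joined <- dplyr::left_join(cands,
                             sites[, c("site_id", "hexamer_start", "hexamer_end")],
                             by = "site_id")
  expect_true(all(joined$cut_position >= joined$hexamer_start - 100))
  expect_true(all(joined$cut_position <= joined$hexamer_end + 100))
  expect_false(any(duplicated(cands$sequence)))
  expect_identical(cands, gen_guide_candidates(sites, cfg))
})

test_that("off-target draws follow the stated Poisson rates", {
  cfg <- sim_config(seed = 13, n_genes = 320, n_targets = 10)
  cands <- gen_guide_candidates(gen_pas_landscape(cfg), cfg)
  expect_gt(nrow(cands), 10000)
  # Poisson(10): MC tolerance 4 SE on the mean
  se3 <- sqrt(10 / nrow(cands))
  expect_lt(abs(mean(cands$offtargets_3mm) - 10), 4 * se3)
  se2 <- sqrt(0.5 / nrow(cands))
  expect_lt(abs(mean(cands$offtargets_2mm) - 0.5), 4 * se2)
  expect_true(all(cands$on_target_score >= 0 & cands$on_target_score <= 100))
})

test_that("screen counts are centred under the null and shifted by effects", {
  scr <- small_screen(seed = 21)
  res <- screen_score(scr$counts, scr$lib, n_sub = 200, seed = 1)
  tgt <- tidy(res)[tidy(res)$category == "targeting", ]
  # all-null construction: mean l2fc across targeting pgRNAs ~ 0
  se <- sd(tgt$mean_l2fc) / sqrt(nrow(tgt))
  expect_lt(abs(mean(tgt$mean_l2fc)), 3 * se + 0.05)

  scr2 <- small_screen(seed = 21, effects = c(gene_001_prox = -0.5))
  truth <- screen_truth(scr2$counts)
  expect_true(all(truth$effect[truth$target_id == "gene_001_prox"] == -0.5))
  d20 <- dplyr::filter(scr2$counts, arm == "invitro_d20")
  hit <- dplyr::semi_join(d20, dplyr::filter(truth, effect != 0), by = "pgRNA_id")
  ctl <- dplyr::semi_join(d20, dplyr::filter(truth, category == "neg_control"),
                          by = "pgRNA_id")
  expect_lt(mean(hit$count), mean(ctl$count))
  expect_identical(dplyr::as_tibble(scr2$counts),
                   dplyr::as_tibble(gen_screen_counts(scr2$lib, scr2$cfg)))
})

test_that("unknown selection-effect keys are rejected", {
  scr <- small_screen(seed = 3)
  cfg_bad <- sim_config(seed = 3, n_genes = 40, n_targets = 8,
                        selection_effects = c(not_a_target = 1))
  expect_error(gen_screen_counts(scr$lib, cfg_bad), "unknown target")
})

test_that("polyaseq counts respect shifts and determinism", {
  cfg <- sim_config(seed = 5, n_genes = 60,
                    apa_shift_effects = c(gene_002 = 2), polyaseq_depth = 500)
  pa <- gen_polyaseq_counts(cfg)
  expect_equal(nrow(pa), 60 * 12)
  frac <- pa$distal / pmax(pa$proximal + pa$distal, 1)
  g2 <- pa$gene == "gene_002"
  expect_gt(mean(frac[g2 & pa$group == "B"]), mean(frac[g2 & pa$group == "A"]))
  expect_identical(dplyr::as_tibble(pa),
                   dplyr::as_tibble(gen_polyaseq_counts(cfg)))
  expect_error(gen_polyaseq_counts(sim_config(apa_shift_effects = c(nope = 1))),
               "unknown gene")
})

test_that("cohort generator links survival to median 3' UTR usage", {
  cfg <- sim_config(seed = 6, cohort_size = 200, n_genes = 120,
                    cox_beta = log(2))
  coh <- gen_cohort(cfg)
  expect_true(all(coh$profiles$usage >= 0 & coh$profiles$usage <= 1))
  expect_true(all(coh$survival$time > 0))
  med <- sample_median_utr(coh$profiles)
  fit <- cox_hr(dplyr::rename(med, value = median_utr), coh$survival,
                covariate = "continuous")
  expect_gt(fit$loghr, 0)                     # higher usage -> higher hazard
  expect_lt(abs(fit$loghr - log(2)), 3 * fit$se)
  coh2 <- gen_cohort(cfg)
  expect_identical(coh$profiles, coh2$profiles)
  expect_identical(coh$survival, coh2$survival)
})

test_that("censoring rate is close to its target under the null", {
  cfg <- sim_config(seed = 8, cohort_size = 600, n_genes = 100,
                    censor_rate = 0.3)
  coh <- gen_cohort(cfg)
  expect_lt(abs(mean(coh$survival$event == 0) - 0.3), 0.06)
})

test_that("paired reads round-trip counts at zero error rate", {
  scr <- small_screen(seed = 31, depth_per_pgrna = 3)
  counts <- dplyr::filter(scr$counts, sample_id %in% c("day0_r1", "day0_r2"))
  reads <- gen_paired_reads(scr$lib, counts, error_rate = 0, seed = 4)
  expect_identical(reads, gen_paired_reads(scr$lib, counts, error_rate = 0, seed = 4))
  tallied <- tally_counts(reads, scr$lib)
  merged <- dplyr::left_join(counts,
                             dplyr::rename(tallied, tallied = count),
                             by = c("pgRNA_id", "sample_id"))
  expect_equal(merged$tallied, merged$count)
  expect_equal(nrow(discard_summary(tallied)), 0)
})

test_that("corrupted pairs are discarded at about the error rate", {
  scr <- small_screen(seed = 32, depth_per_pgrna = 100)
  counts <- dplyr::filter(scr$counts, sample_id == "day0_r1")
  n_pairs <- sum(counts$count)
  expect_gt(n_pairs, 10000)
  reads <- gen_paired_reads(scr$lib, counts, error_rate = 0.1, seed = 5)
  tallied <- tally_counts(reads, scr$lib)
  disc <- sum(discard_summary(tallied)$n)
  frac <- disc / n_pairs
  se <- sqrt(0.1 * 0.9 / n_pairs)
  expect_lt(abs(frac - 0.1), 4 * se)
  # conservation: assigned + discarded = processed
  expect_equal(sum(tallied$count) + disc, n_pairs)
})
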