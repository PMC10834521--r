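test_that("sample median usage matches a sort-based oracle", {
  prof <- tibble::tibble(sample_id = "s1", gene = paste0("g", 1:3),
                         usage = c(0.2, 0.4, 0.9))
  expect_equal(sample_median_utr(prof, min_genes = 3)$median_utr, 0.4)
  prof2 <- tibble::tibble(sample_id = "s1", gene = paste0("g", 1:4),
                          usage = rep(0.5, 4))
  expect_equal(sample_median_utr(prof2, min_genes = 4)$median_utr, 0.5)
  set.seed(1)
  for (i in 1:20) {
    n <- sample(3:12, 1)
    u <- runif(n)
    prof <- tibble::tibble(sample_id = "s", gene = paste0("g", 1:n), usage = u)
    s <- sort(u)
    want <- if (n %% 2 == 1) s[(n + 1) / 2] else mean(s[n / 2 + 0:1])
    expect_equal(sample_median_utr(prof, min_genes = n)$median_utr, want)
  }
  expect_error(sample_median_utr(prof, min_genes = 100), "fewer than 100")
  bad <- tibble::tibble(sample_id = "s", gene = "g", usage = 1.2)
  expect_error(sample_median_utr(bad, min_genes = 1), "\\[0, 1\\]")
})

test_that("tercile stratification partitions with near-equal sizes", {
  v9 <- tibble::tibble(sample_id = sprintf("s%02d", 1:9), value = (1:9) / 10)
  t9 <- stratify_terciles(v9)
  expect_equal(as.vector(table(t9$tercile)), c(3, 3, 3))
  v10 <- tibble::tibble(sample_id = sprintf("s%02d", 1:10), value = (1:10) / 11)
  t10 <- stratify_terciles(v10)
  expect_equal(as.vector(table(t10$tercile)), c(4, 3, 3))
  expect_equal(sort(t10$sample_id[t10$tercile == "short"]), sprintf("s%02d", 1:4))
  # all-tied values: deterministic assignment by sample_id, sizes differ <= 1
  vt <- tibble::tibble(sample_id = sprintf("s%02d", 1:11), value = 0.5)
  tt <- stratify_terciles(vt)
  sizes <- as.vector(table(tt$tercile))
  expect_lte(max(sizes) - min(sizes), 1)
  expect_identical(tt, stratify_terciles(vt))
  expect_equal(tt$tercile[tt$sample_id == "s01"], factor("short", levels = levels(tt$tercile)))
  expect_error(stratify_terciles(v9[1:5, ]), "at least 9")
})

test_that("logrank on identical groups is null and matches the hand-worked table", {
  surv <- tibble::tibble(sample_id = sprintf("s%02d", 1:12),
                         time = rep(c(2, 4, 6, 8, 10, 12), 2),
                         event = rep(c(1, 1, 0, 1, 1, 0), 2))
  strata <- tibble::tibble(sample_id = surv$sample_id,
                           tercile = factor(rep(c("short", "long"), each = 6),
                                            levels = c("short", "medium", "long")))
  km <- km_logrank(strata, surv)
  expect_equal(km$chisq, 0, tolerance = 1e-12)
  expect_equal(km$p, 1)

  # 6-subject table: oracle risk-set arithmetic frozen from the closed form
  surv6 <- tibble::tibble(sample_id = paste0("p", 1:6),
                          time = c(1, 3, 5, 2, 4, 6),
                          event = c(1, 0, 1, 1, 1, 0))
  st6 <- tibble::tibble(sample_id = paste0("p", 1:6),
                        tercile = factor(rep(c("short", "long"), each = 3),
                                         levels = c("short", "medium", "long")))
  o <- oracle_logrank(surv6$time, surv6$event, grp = rep(c(0, 1), each = 3))
  expect_equal(o$O - o$E, 2 - 2.2666666667, tolerance = 1e-9)
  expect_equal(o$V, 0.9622222222, tolerance = 1e-9)
  km6 <- km_logrank(st6, surv6)
  expect_equal(km6$chisq, o$chisq, tolerance = 1e-7)
  expect_equal(km6$chisq, 0.0739030023, tolerance = 1e-7)
  expect_equal(km6$p, 0.785736538, tolerance = 1e-7)

  # symmetry: swapping group labels leaves the statistic unchanged
  st_swap <- dplyr::mutate(st6, tercile = factor(
    ifelse(tercile == "short", "long", "short"),
    levels = c("short", "medium", "long")))
  expect_equal(km_logrank(st_swap, surv6)$chisq, km6$chisq, tolerance = 1e-12)
  expect_error(km_logrank(st6[1:3, ], surv6), "non-empty")
})

test_that("Cox fit matches an independent partial-likelihood maximiser", {
  set.seed(3)
  n <- 20
  x <- rep(c(1, 0), each = n / 2)                  # 1 = short tercile
  time <- round(rexp(n, 0.1 * exp(0.8 * x)), 6)    # continuous: no ties
  surv <- tibble::tibble(sample_id = sprintf("s%02d", 1:n), time = time,
                         event = rep(1L, n))
  strata <- tibble::tibble(
    sample_id = surv$sample_id,
    tercile = factor(ifelse(x == 1, "short", "long"),
                     levels = c("short", "medium", "long")))
  fit <- cox_hr(strata, surv)
  expect_equal(fit$loghr, oracle_cox_loghr(time, rep(1, n), x),
               tolerance = 1e-6)
  expect_equal(fit$log2_hr, fit$loghr / log(2))
  expect_true(fit$converged)
})

test_that("Cox sign convention: short tercile vs long reference", {
  cfg <- sim_config(seed = 17, cohort_size = 300, n_genes = 120,
                    cox_beta = -log(2))   # longer UTRs protective ... short risky
  coh <- gen_cohort(cfg)
  med <- sample_median_utr(coh$profiles)
  strata <- stratify_terciles(dplyr::rename(med, value = median_utr))
  fit <- cox_hr(strata, coh$survival)
  expect_gt(fit$log2_hr, 0)   # short group has the higher hazard
  km <- km_logrank(strata, coh$survival)
  expect_lt(km$p, 0.05)
})

test_that("single-gene stratification composes terciles with the logrank test", {
  cfg <- sim_config(seed = 19, cohort_size = 60, n_genes = 120)
  coh <- gen_cohort(cfg)
  out <- gene_stratify(coh$profiles, "gene_005", coh$survival)
  vals <- coh$profiles |>
    dplyr::filter(gene == "gene_005") |>
    dplyr::select(sample_id, value = usage)
  ref <- km_logrank(stratify_terciles(vals), coh$survival)
  expect_equal(out$chisq, ref$chisq)
  expect_equal(out$p, ref$p)
  expect_error(gene_stratify(coh$profiles, "gene_999", coh$survival),
               "not present")
})

test_that("regulator correlation and LOF rates follow their definitions", {
  med <- tibble::tibble(sample_id = sprintf("s%d", 1:30),
                        median_utr = runif(30))
  expr <- tibble::tibble(sample_id = med$sample_id,
                         expression = med$median_utr)
  expect_equal(regulator_correlation(med, expr)$r, 1)
  set.seed(23)
  expr2 <- dplyr::mutate(expr, expression = rnorm(30))
  expect_lt(abs(regulator_correlation(med, expr2)$r), 0.5)

  mut <- tibble::tibble(gene = c("Atg7", "Trp53", "Brca2"),
                        lof_count = c(0L, 5L, 5L),
                        cds_length_kb = c(2.1, 2, 10))
  rates <- lof_rate(mut, n_patients = 424)
  expect_equal(rates$rate[rates$gene == "Atg7"], 0)
  expect_equal(rates$rate[rates$gene == "Trp53"], 5 / (2 * 424))
  expect_equal(rates$gene, c("Trp53", "Brca2", "Atg7"))   # ranked, ties by gene
  expect_setequal(rates$gene, mut$gene)
})
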