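#' Per-sample median 3' UTR usage
#'
#' The global 3' UTR length statistic: the median over a sample's non-missing
#' gene-level distal-usage values (values near 0 = globally shorter 3' UTRs),
#' computed only for samples observing at least `min_genes` genes.
#'
#' @param profiles Long tibble (`sample_id`, `gene`, `usage`), `usage` in
#'   `[0, 1]`, `NA` allowed.
#' @param min_genes Minimum observed genes per sample (default 100).
#' @return Tibble (`sample_id`, `median_utr`, `n_genes_observed`).
#' @export
sample_median_utr <- function(profiles, min_genes = 100L) {
  stopifnot_cols(profiles, c("sample_id", "gene", "usage"))
  ok <- profiles$usage[!is.na(profiles$usage)]
  if (length(ok) > 0 && (min(ok) < 0 || max(ok) > 1))
    abort("`usage` values must lie in [0, 1]")
  out <- profiles |>
    filter(!is.na(.data$usage)) |>
    group_by(.data$sample_id) |>
    summarise(median_utr = median(.data$usage),
              n_genes_observed = n(), .groups = "drop")
  short <- out$sample_id[out$n_genes_observed < min_genes]
  if (length(short) > 0)
    abort(sprintf("sample(s) with fewer than %d observed genes: %s",
                  min_genes, paste(utils::head(short, 5), collapse = ", ")))
  out
}

#' Stratify a cohort into short / medium / long terciles
#'
#' Rank-based terciles of a per-sample statistic (median 3' UTR usage, or a
#' single gene's usage): ranks `1..ceiling(n/3)` are `short`, the top
#' `floor(n/3)` ranks are `long`, the rest `medium`, so group sizes never
#' differ by more than one. Ties are broken by stable ordering on
#' `(value, sample_id)`.
#'
#' @param values Tibble with `sample_id` and `value` columns (>= 9 samples).
#' @return `values` with a `tercile` column
#'   (factor `short` < `medium` < `long`).
#' @export
stratify_terciles <- function(values) {
  stopifnot_cols(values, c("sample_id", "value"))
  n <- nrow(values)
  if (n < 9) abort("need at least 9 samples for terciles")
  ord <- order(values$value, values$sample_id)
  r <- integer(n); r[ord] <- seq_len(n)
  cut_short <- ceiling(n / 3)
  cut_long <- n - floor(n / 3)
  values$tercile <- factor(
    ifelse(r <= cut_short, "short", ifelse(r > cut_long, "long", "medium")),
    levels = c("short", "medium", "long")
  )
  values
}

join_strata <- function(strata, survival) {
  stopifnot_cols(strata, c("sample_id", "tercile"))
  stopifnot_cols(survival, c("sample_id", "time", "event"))
  if (any(survival$time <= 0)) abort("survival times must be positive")
  inner_join(strata |> select("sample_id", "tercile"),
             survival |> select("sample_id", "time", "event"),
             by = "sample_id") |>
    filter(.data$tercile %in% c("short", "long")) |>
    mutate(tercile = droplevels(.data$tercile))
}

#' Kaplan-Meier curves and logrank test, short vs long tercile
#'
#' Compares overall survival between the short- and long-3'-UTR terciles
#' (the medium tercile is excluded) with Kaplan-Meier estimates and a
#' two-sided two-group logrank test.
#'
#' @param strata Output of [stratify_terciles()].
#' @param survival Tibble (`sample_id`, `time`, `event` with 1 = event,
#'   0 = censored).
#' @return Object of class `utr_km`: list with `fit` (a
#'   [survival::survfit()]), `test` (a [survival::survdiff()]), `chisq`, `p`,
#'   and the group table `data`.
#' @export
km_logrank <- function(strata, survival) {
  df <- join_strata(strata, survival)
  if (length(unique(df$tercile)) < 2)
    abort("both the short and the long group must be non-empty")
  if (sum(df$event) == 0) abort("no events in the two groups")
  sdf <- survival::survdiff(survival::Surv(time, event) ~ tercile, data = df)
  fit <- survival::survfit(survival::Surv(time, event) ~ tercile, data = df)
  p <- pchisq(sdf$chisq, df = 1, lower.tail = FALSE)
  structure(list(fit = fit, test = sdf, chisq = unname(sdf$chisq), p = p,
                 data = df),
            class = "utr_km")
}

#' @export
print.utr_km <- function(x, ...) {
  cat("<utr_km> two-group logrank, short vs long tercile\n")
  cat(sprintf("  n = %d, events = %d, chisq = %.3f, p = %.4g\n",
              nrow(x$data), sum(x$data$event), x$chisq, x$p))
  invisible(x)
}

#' Univariate Cox model of the short-vs-long stratification
#'
#' Proportional-hazards fit with the long-UTR tercile as reference, so a
#' positive log2 hazard ratio means the short-3'-UTR group has higher hazard.
#' A continuous mode regresses on a numeric per-sample statistic instead
#' (supplied as the `value` column of `strata`).
#'
#' @param strata Output of [stratify_terciles()] (needs `value` for the
#'   continuous mode).
#' @param survival As in [km_logrank()].
#' @param covariate `"tercile"` (default) or `"continuous"` (standardized
#'   `value`).
#' @return Object of class `utr_cox`: list with `fit`, `log2_hr`, `loghr`,
#'   `se`, `p` (Wald), `converged`.
#' @export
cox_hr <- function(strata, survival, covariate = c("tercile", "continuous")) {
  covariate <- match.arg(covariate)
  if (covariate == "tercile") {
    df <- join_strata(strata, survival)
    df$x <- as.integer(df$tercile == "short")   # reference = long
  } else {
    stopifnot_cols(strata, c("sample_id", "value"))
    df <- inner_join(strata |> select("sample_id", "value"),
                     survival |> select("sample_id", "time", "event"),
                     by = "sample_id")
    df$x <- as.vector(scale(df$value))
  }
  fit <- survival::coxph(survival::Surv(time, event) ~ x, data = df,
                         control = survival::coxph.control(eps = 1e-11,
                                                           toler.chol = 1e-13,
                                                           iter.max = 50))
  conv <- is.finite(coef(fit)) && is.finite(sqrt(fit$var[1, 1]))
  if (!conv) warn("Cox model did not converge to a finite estimate")
  s <- summary(fit)
  structure(list(fit = fit,
                 loghr = unname(coef(fit)),
                 log2_hr = unname(coef(fit)) / log(2),
                 se = s$coefficients[1, "se(coef)"],
                 p = s$coefficients[1, "Pr(>|z|)"],
                 converged = conv,
                 covariate = covariate),
            class = "utr_cox")
}

#' @export
print.utr_cox <- function(x, ...) {
  cat(sprintf("<utr_cox> %s covariate: log2(HR) = %.3f (loghr %.3f +/- %.3f), p = %.4g\n",
              x$covariate, x$log2_hr, x$loghr, x$se, x$p))
  invisible(x)
}

#' Stratify and test survival on a single gene's 3' UTR usage
#'
#' Terciles of one gene's usage values across the cohort, then short-vs-long
#' Kaplan-Meier/logrank — the single-gene analogue of the global median
#' stratification.
#'
#' @param profiles Long usage tibble (`sample_id`, `gene`, `usage`).
#' @param gene Gene to stratify on.
#' @param survival As in [km_logrank()].
#' @param min_fraction Minimum fraction of the cohort observing the gene.
#' @return A `utr_km` object (with the strata in `$strata`).
#' @export
gene_stratify <- function(profiles, gene, survival, min_fraction = 0.5) {
  stopifnot_cols(profiles, c("sample_id", "gene", "usage"))
  vals <- profiles |>
    filter(.data$gene == !!gene, !is.na(.data$usage)) |>
    select("sample_id", value = "usage")
  n_cohort <- dplyr::n_distinct(profiles$sample_id)
  if (nrow(vals) == 0) abort(sprintf("gene '%s' not present in the cohort", gene))
  if (nrow(vals) < min_fraction * n_cohort)
    abort(sprintf("gene '%s' observed in %d/%d samples (< min fraction %g)",
                  gene, nrow(vals), n_cohort, min_fraction))
  strata <- stratify_terciles(vals)
  out <- km_logrank(strata, survival)
  out$strata <- strata
  out
}

#' Correlation of global 3' UTR length with a regulator's expression
#'
#' @param median_utr Tibble (`sample_id`, `median_utr`).
#' @param expression Tibble (`sample_id`, `expression`).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return List with `r`, `p`, `n`.
#' @export
regulator_correlation <- function(median_utr, expression,
                                  method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot_cols(median_utr, c("sample_id", "median_utr"))
  stopifnot_cols(expression, c("sample_id", "expression"))
  df <- inner_join(median_utr, expression, by = "sample_id")
  if (nrow(df) < 3) abort("need >= 3 paired samples")
  ct <- suppressWarnings(cor.test(df$median_utr, df$expression, method = method))
  list(r = unname(ct$estimate), p = ct$p.value, n = nrow(df))
}

#' Loss-of-function mutation rate per kilobase per patient
#'
#' @param mutations Tibble (`gene`, `lof_count`, `cds_length_kb`).
#' @param n_patients Cohort size.
#' @return Tibble ranked by descending `rate` (ties by `gene`), with a `rank`
#'   column.
#' @export
lof_rate <- function(mutations, n_patients) {
  stopifnot_cols(mutations, c("gene", "lof_count", "cds_length_kb"))
  if (n_patients <= 0) abort("`n_patients` must be positive")
  if (any(mutations$cds_length_kb <= 0)) abort("`cds_length_kb` must be positive")
  mutations |>
    mutate(rate = .data$lof_count / .data$cds_length_kb / n_patients) |>
    arrange(dplyr::desc(.data$rate), .data$gene) |>
    mutate(rank = row_number())
}
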