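#' Per-pgRNA pseudocounts proportional to library representation
#'
#' The pseudocount added to raw counts before fold-change computation is
#' proportional to each pgRNA's relative representation in the plasmid pool:
#' `psi_i = mean_mass * n * f_i` with `f_i = plasmid_i / sum(plasmid)` and `n`
#' the number of pgRNAs, so that `mean(psi) = mean_mass` and abundant pgRNAs
#' are regularized more in absolute terms but identically in relative terms.
#'
#' @param plasmid_counts Non-negative integer vector (optionally named by
#'   pgRNA id).
#' @param mean_mass Mean pseudocount mass per pgRNA (default 10).
#' @return Positive numeric vector, same names as the input.
#' @examples
#' compute_pseudocounts(c(100, 300))  # 5, 15
#' @export
compute_pseudocounts <- function(plasmid_counts, mean_mass = 10) {
  if (any(plasmid_counts < 0) || anyNA(plasmid_counts))
    abort("plasmid counts must be non-negative and non-missing")
  tot <- sum(plasmid_counts)
  if (tot <= 0) abort("plasmid counts sum to zero")
  mean_mass * length(plasmid_counts) * plasmid_counts / tot
}

#' Raw fold changes of an arm against its day-0 reference
#'
#' Pseudocounted, depth-scaled fold change per pgRNA and replicate:
#' `FC = ((c_arm + psi) / D_arm) / ((c_ref + psi) / D_ref)` where `D` is the
#' sample's total assigned count. Arms share the day-0 reference of the same
#' replicate.
#'
#' @param counts Long count tibble (`pgRNA_id`, `sample_id`, `arm`,
#'   `replicate`, `count`).
#' @param psi Pseudocount vector named by pgRNA id (see
#'   [compute_pseudocounts()]).
#' @param arm Arm to compare (e.g. `"invitro_d20"`).
#' @param reference_arm Reference arm (default `"day0"`).
#' @return Tibble (`pgRNA_id`, `arm`, `replicate`, `fc`), `fc` strictly
#'   positive.
#' @export
fold_changes <- function(counts, psi, arm, reference_arm = "day0") {
  stopifnot_cols(counts, c("pgRNA_id", "sample_id", "arm", "replicate", "count"))
  if (is.null(names(psi))) abort("`psi` must be named by pgRNA_id")
  a <- counts[counts$arm == arm, ]
  b <- counts[counts$arm == reference_arm, ]
  if (nrow(a) == 0) abort(sprintf("no samples in arm '%s'", arm))
  if (nrow(b) == 0) abort(sprintf("no samples in reference arm '%s'", reference_arm))
  if (!setequal(unique(a$replicate), unique(b$replicate)))
    abort("arm and reference arm have different replicate structures")
  depth <- counts |>
    group_by(.data$sample_id) |>
    summarise(depth = sum(.data$count), .groups = "drop")
  if (any(depth$depth == 0))
    abort(sprintf("zero-depth sample(s): %s",
                  paste(depth$sample_id[depth$depth == 0], collapse = ", ")))
  add_psi <- function(df) {
    p <- psi[df$pgRNA_id]
    if (anyNA(p)) abort("`psi` is missing entries for some pgRNAs")
    df$psi <- unname(p)
    left_join(df, depth, by = "sample_id")
  }
  a <- add_psi(a); b <- add_psi(b)
  merged <- inner_join(
    a |> select("pgRNA_id", "replicate", a_count = "count",
                a_psi = "psi", a_depth = "depth"),
    b |> select("pgRNA_id", "replicate", b_count = "count", b_depth = "depth"),
    by = c("pgRNA_id", "replicate")
  )
  merged |>
    mutate(fc = ((.data$a_count + .data$a_psi) / .data$a_depth) /
             ((.data$b_count + .data$a_psi) / .data$b_depth),
           arm = arm) |>
    select("pgRNA_id", "arm", "replicate", "fc")
}

#' Normalize fold changes to the negative-control median
#'
#' Divides each replicate's fold changes by that replicate's median over the
#' negative-control pgRNAs (those targeting poly(A) signals of unexpressed
#' genes), so that the per-replicate control median equals exactly 1, and adds
#' the log2 column. Scale changes of the raw fold changes leave the output
#' invariant.
#'
#' @param fc Raw fold-change tibble from [fold_changes()].
#' @param library Library tibble supplying `category` and `target_id` per
#'   pgRNA (or a tibble with those columns).
#' @return Fold-change tibble with `category`, `target_id`, normalized `fc`
#'   and `l2fc` columns.
#' @export
normalize_fc <- function(fc, library) {
  stopifnot_cols(fc, c("pgRNA_id", "replicate", "fc"))
  stopifnot_cols(library, c("pgRNA_id", "target_id", "category"))
  out <- left_join(fc, library |> select("pgRNA_id", "target_id", "category"),
                   by = "pgRNA_id")
  if (anyNA(out$category)) abort("fold-change table has pgRNAs absent from the library")
  out <- out |>
    group_by(.data$arm, .data$replicate) |>
    mutate(.ctrl_med = median(.data$fc[.data$category == "neg_control"])) |>
    ungroup()
  if (anyNA(out$.ctrl_med))
    abort("a replicate has no negative-control pgRNAs")
  out |>
    mutate(fc = .data$fc / .data$.ctrl_med, l2fc = log2(.data$fc)) |>
    select("pgRNA_id", "target_id", "category", "arm", "replicate",
           "fc", "l2fc")
}

# target / control value sets under the two pooling modes
pooled_values <- function(fc, ids, pooling) {
  sub <- fc[fc$pgRNA_id %in% ids, ]
  if (pooling == "replicate_pooled") return(sub$l2fc)
  sub |>
    group_by(.data$pgRNA_id) |>
    summarise(v = mean(.data$l2fc), .groups = "drop") |>
    pull("v")
}

#' Wilcoxon p value for one target against the negative controls
#'
#' Two-sided rank-sum test of the target's normalized log2 fold-changes
#' against the full negative-control distribution. `replicate_pooled`
#' (default) pools pgRNA x replicate values across all replicates to maximise
#' power; `pgRNA_mean` compares per-pgRNA means.
#'
#' @param fc Normalized fold-change tibble from [normalize_fc()].
#' @param target_id Target to test.
#' @param pooling `"replicate_pooled"` or `"pgRNA_mean"`.
#' @return Two-sided p value.
#' @export
target_pvalue <- function(fc, target_id,
                          pooling = c("replicate_pooled", "pgRNA_mean")) {
  pooling <- match.arg(pooling)
  stopifnot_cols(fc, c("pgRNA_id", "target_id", "category", "l2fc"))
  tgt_ids <- unique(fc$pgRNA_id[fc$target_id == target_id])
  ctl_ids <- unique(fc$pgRNA_id[fc$category == "neg_control"])
  if (length(tgt_ids) == 0) abort(sprintf("no pgRNAs for target '%s'", target_id))
  if (length(ctl_ids) == 0) abort("no negative-control pgRNAs")
  x <- pooled_values(fc, tgt_ids, pooling)
  y <- pooled_values(fc, ctl_ids, pooling)
  ranksum_test(x, y)$p.value
}

#' Per-target screen results
#'
#' Computes, for every non-negative-control target, the mean normalized log2
#' fold-change (mean of per-pgRNA means), the pooled two-sided Wilcoxon p
#' against the negative controls, the pgRNA count and the direction.
#'
#' @inheritParams target_pvalue
#' @return Tibble (`target_id`, `category`, `arm`, `n_pgRNAs`, `mean_l2fc`,
#'   `direction`, `p`).
#' @export
screen_results <- function(fc, pooling = c("replicate_pooled", "pgRNA_mean")) {
  pooling <- match.arg(pooling)
  stopifnot_cols(fc, c("pgRNA_id", "target_id", "category", "arm", "l2fc"))
  ctl_ids <- unique(fc$pgRNA_id[fc$category == "neg_control"])
  if (length(ctl_ids) == 0) abort("no negative-control pgRNAs")
  y <- pooled_values(fc, ctl_ids, pooling)
  targets <- fc |>
    filter(.data$category != "neg_control") |>
    distinct(.data$target_id, .data$category)
  per_pg <- fc |>
    filter(.data$category != "neg_control") |>
    group_by(.data$target_id, .data$pgRNA_id) |>
    summarise(m = mean(.data$l2fc), .groups = "drop")
  res <- per_pg |>
    group_by(.data$target_id) |>
    summarise(n_pgRNAs = n(), mean_l2fc = mean(.data$m), .groups = "drop")
  res$p <- vapply(res$target_id, function(t) {
    ids <- unique(fc$pgRNA_id[fc$target_id == t])
    ranksum_test(pooled_values(fc, ids, pooling), y)$p.value
  }, numeric(1))
  res |>
    left_join(targets, by = "target_id") |>
    mutate(arm = fc$arm[1],
           direction = ifelse(.data$mean_l2fc >= 0, "enriched", "depleted")) |>
    select("target_id", "category", "arm", "n_pgRNAs", "mean_l2fc",
           "direction", "p")
}

#' Empirical FDR by negative-control subsampling
#'
#' Builds `n_sub` "fake targets" of `k` negative-control pgRNAs each, computes
#' each fake target's pooled Wilcoxon p against the full control set (sampled
#' members not excluded), and reports, per real target, the value of the fake-p
#' empirical CDF at the target's p — the fraction of control-only pseudo-targets
#' at least as extreme. FDR is therefore monotone non-decreasing in p.
#'
#' @param results Target table from [screen_results()].
#' @param fc Normalized fold-change tibble from [normalize_fc()].
#' @param n_sub Number of subsampled fake targets (default 10000).
#' @param k pgRNAs per fake target (default 10).
#' @param seed Integer seed for the subsampling.
#' @param pooling Pooling mode, as in [target_pvalue()].
#' @param floor If `TRUE`, report `1/n_sub` instead of 0 when a target's p
#'   beats every fake p.
#' @return `results` with an `fdr` column.
#' @export
empirical_fdr <- function(results, fc, n_sub = 10000L, k = 10L, seed = 1L,
                          pooling = c("replicate_pooled", "pgRNA_mean"),
                          floor = FALSE) {
  pooling <- match.arg(pooling)
  stopifnot_cols(results, c("target_id", "p"))
  fake_p <- fake_target_pvalues(fc, n_sub = n_sub, k = k, seed = seed,
                                pooling = pooling)
  fdr <- ecdf(fake_p)(results$p)
  if (floor) fdr <- pmax(fdr, 1 / n_sub)
  results$fdr <- fdr
  results
}

#' Null p-value distribution from control-only fake targets
#'
#' @inheritParams empirical_fdr
#' @return Numeric vector of `n_sub` fake-target p values.
#' @export
fake_target_pvalues <- function(fc, n_sub = 10000L, k = 10L, seed = 1L,
                                pooling = c("replicate_pooled", "pgRNA_mean")) {
  pooling <- match.arg(pooling)
  stopifnot_cols(fc, c("pgRNA_id", "category", "l2fc"))
  ctl <- fc |>
    filter(.data$category == "neg_control") |>
    group_by(.data$pgRNA_id) |>
    summarise(vals = list(.data$l2fc), m = mean(.data$l2fc), .groups = "drop")
  n_ctl <- nrow(ctl)
  if (n_ctl < k)
    abort(sprintf("need at least k = %d control pgRNAs, have %d", k, n_ctl))
  if (pooling == "pgRNA_mean") {
    y <- ctl$m
    per_pg_sum <- rank(y)          # one value per control pgRNA
    m_per <- 1L
  } else {
    y <- unlist(ctl$vals)
    r <- rank(y)
    per_pg_sum <- rowsum_by(r, rep(seq_len(n_ctl), lengths(ctl$vals)))
    m_per <- length(ctl$vals[[1]])
    if (!all(lengths(ctl$vals) == m_per))
      abort("control pgRNAs have unequal replicate counts")
  }
  ny <- length(y)
  m <- k * m_per
  withr::with_seed(as.integer(seed), {
    picks <- matrix(0L, nrow = n_sub, ncol = k)
    for (i in seq_len(n_sub)) picks[i, ] <- sample.int(n_ctl, k)
    # fake values are copies of control values: the rank sum of the fake set
    # within c(fake, controls) reduces to the fake members' control-set ranks
    # plus closed-form tie offsets (each value appears exactly twice)
    w0 <- matrix(per_pg_sum[picks], nrow = n_sub)
    w <- rowSums(w0) + 0.5 * m + m * (m - 1) / 2
    ranksum_p_normal(w, nx = m, ny = ny, tie_term = 6 * m)
  })
}

rowsum_by <- function(x, g) {
  as.vector(rowsum(x, g))
}

#' Call enriched and depleted targets
#'
#' A target is `enriched` if its mean normalized log2 fold-change is at least
#' `lfc_cut` with empirical FDR strictly below `fdr_cut`; `depleted` if at
#' most `-lfc_cut` with FDR below `fdr_cut`; otherwise `not_called`.
#'
#' @param results Target table with `mean_l2fc` and `fdr` columns.
#' @param fdr_cut FDR threshold (strict; default 0.05).
#' @param lfc_cut Absolute log2 fold-change threshold (default 0.5).
#' @return `results` with a `call` column.
#' @export
call_hits <- function(results, fdr_cut = 0.05, lfc_cut = 0.5) {
  stopifnot_cols(results, c("mean_l2fc", "fdr"))
  results |>
    mutate(call = dplyr::case_when(
      .data$fdr < fdr_cut & .data$mean_l2fc >= lfc_cut ~ "enriched",
      .data$fdr < fdr_cut & .data$mean_l2fc <= -lfc_cut ~ "depleted",
      TRUE ~ "not_called"
    ))
}

#' Negative-control dispersion QC
#'
#' Fraction of negative-control pgRNAs whose per-pgRNA mean normalized log2
#' fold-change lies within two standard deviations of the control median —
#' the library-health statistic of a well-behaved screen (about 95% under
#' normality).
#'
#' @param fc Normalized fold-change tibble, or a numeric vector of
#'   per-control values.
#' @return Fraction in `[0, 1]`.
#' @export
qc_dispersion <- function(fc) {
  if (is.data.frame(fc)) {
    stopifnot_cols(fc, c("pgRNA_id", "category", "l2fc"))
    x <- fc |>
      filter(.data$category == "neg_control") |>
      group_by(.data$pgRNA_id) |>
      summarise(m = mean(.data$l2fc), .groups = "drop") |>
      pull("m")
  } else {
    x <- fc
  }
  if (length(x) < 3) abort("need at least 3 negative-control values")
  s <- sd(x)
  if (s == 0) return(1)       # degenerate: all values identical
  mean(abs(x - median(x)) <= 2 * s)
}

#' Score a screen arm end to end
#'
#' Convenience pipeline: plasmid-based pseudocounts, fold changes against
#' day 0, control-median normalization, per-target pooled Wilcoxon tests,
#' empirical FDR by control subsampling, and hit calling.
#'
#' @param counts Long count tibble including a `plasmid` arm.
#' @param library Library tibble.
#' @param arm Arm to score (default `"invitro_d20"`).
#' @param mean_mass Pseudocount mass (default 10).
#' @param n_sub,k,seed Empirical-FDR subsampling parameters.
#' @param fdr_cut,lfc_cut Hit-calling thresholds.
#' @param pooling Pooling mode for the Wilcoxon tests.
#' @return A tibble of per-target results of class `apa_screen_result`, with
#'   the normalized fold-change table in attribute `fc`
#'   (accessor [screen_fc()]).
#' @export
screen_score <- function(counts, library, arm = "invitro_d20",
                         mean_mass = 10, n_sub = 10000L, k = 10L, seed = 1L,
                         fdr_cut = 0.05, lfc_cut = 0.5,
                         pooling = c("replicate_pooled", "pgRNA_mean")) {
  pooling <- match.arg(pooling)
  plasmid <- counts |>
    filter(.data$arm == "plasmid") |>
    group_by(.data$pgRNA_id) |>
    summarise(count = mean(.data$count), .groups = "drop")
  psi <- compute_pseudocounts(setNames(plasmid$count, plasmid$pgRNA_id),
                              mean_mass = mean_mass)
  fc <- fold_changes(counts, psi, arm = arm) |>
    normalize_fc(library)
  res <- screen_results(fc, pooling = pooling) |>
    empirical_fdr(fc, n_sub = n_sub, k = k, seed = seed, pooling = pooling) |>
    call_hits(fdr_cut = fdr_cut, lfc_cut = lfc_cut)
  structure(res, fc = fc, arm = arm,
            params = list(mean_mass = mean_mass, n_sub = n_sub, k = k,
                          seed = seed, fdr_cut = fdr_cut, lfc_cut = lfc_cut,
                          pooling = pooling),
            class = c("apa_screen_result", class(res)))
}

#' Normalized fold-change table of a scored screen
#' @param x An `apa_screen_result`.
#' @return The normalized fold-change tibble.
#' @export
screen_fc <- function(x) {
  stopifnot(inherits(x, "apa_screen_result"))
  attr(x, "fc")
}
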