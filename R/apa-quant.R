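#' Gene-level APA metrics from proximal/distal 3'-end counts
#'
#' Adds the two standard per-sample statistics of the two-site model:
#' `red = log2((distal + c) / (proximal + c))` (relative-end difference) and
#' `rdu = (distal + c) / (proximal + distal + 2c)` (relative distal usage,
#' strictly inside (0, 1)). The continuity constant `c` is applied
#' symmetrically so that `red` is antisymmetric under swapping the two counts
#' and `rdu(p, d) = 1 - rdu(d, p)`.
#'
#' @param counts Tibble with `gene`, `sample`, `proximal`, `distal` columns
#'   (extra columns are carried through).
#' @param c Continuity constant (default 0.5).
#' @return The input with `red` and `rdu` columns appended.
#' @export
gene_apa_metrics <- function(counts, c = 0.5) {
  stopifnot_cols(counts, c("gene", "sample", "proximal", "distal"))
  if (any(counts$proximal < 0) || any(counts$distal < 0))
    abort("counts must be non-negative")
  if (c <= 0 && any(counts$proximal + counts$distal == 0))
    abort("zero total counts require a positive continuity constant")
  counts |>
    mutate(red = log2((.data$distal + c) / (.data$proximal + c)),
           rdu = (.data$distal + c) / (.data$proximal + .data$distal + 2 * c))
}

# Welch two-sided t on two vectors with explicit handling of the degenerate
# zero-variance cases (t.test() errors on constant data)
welch_p <- function(a, b) {
  va <- stats::var(a); vb <- stats::var(b)
  if (va + vb == 0) {
    d <- mean(b) - mean(a)
    return(list(t = if (d == 0) 0 else Inf * sign(d),
                p = if (d == 0) 1 else 0))
  }
  ht <- t.test(b, a, var.equal = FALSE)
  list(t = unname(ht$statistic), p = ht$p.value)
}

#' Differential APA between two groups of samples
#'
#' Per gene, a two-sided t test (Welch by default) on the per-sample `red`
#' values of the two groups. `delta_red = mean(B) - mean(A)`; with group A as
#' the reference (e.g. normal) and B the comparison (e.g. tumour), a negative
#' `delta_red` means 3' UTR shortening in B.
#'
#' @param quant Tibble from [gene_apa_metrics()] with a `group` column (two
#'   levels) or, equivalently, columns `gene`, `sample`, `group`, `red`.
#' @param ref Reference group label (defaults to the first level
#'   alphabetically).
#' @param var_equal Use the pooled-variance Student t instead of Welch.
#' @return Tibble of class `apa_diff`: `gene`, `mean_red_ref`,
#'   `mean_red_alt`, `delta_red`, `t`, `p`, `direction`
#'   (`shortened`/`lengthened`).
#' @export
diff_apa <- function(quant, ref = NULL, var_equal = FALSE) {
  stopifnot_cols(quant, c("gene", "sample", "group", "red"))
  lev <- sort(unique(quant$group))
  if (length(lev) != 2) abort("`group` must have exactly two levels")
  ref <- ref %||% lev[1]
  if (!ref %in% lev) abort(sprintf("unknown reference group '%s'", ref))
  alt <- setdiff(lev, ref)
  sizes <- quant |> count(.data$gene, .data$group)
  if (any(sizes$n < 2)) abort("each group needs >= 2 samples per gene")
  res <- quant |>
    group_by(.data$gene) |>
    summarise(
      mean_red_ref = mean(.data$red[.data$group == ref]),
      mean_red_alt = mean(.data$red[.data$group == alt]),
      stat = list(if (var_equal) {
        ht <- t.test(.data$red[.data$group == alt],
                     .data$red[.data$group == ref], var.equal = TRUE)
        list(t = unname(ht$statistic), p = ht$p.value)
      } else {
        welch_p(.data$red[.data$group == ref], .data$red[.data$group == alt])
      }),
      .groups = "drop"
    ) |>
    mutate(delta_red = .data$mean_red_alt - .data$mean_red_ref,
           t = purrr::map_dbl(.data$stat, "t"),
           p = purrr::map_dbl(.data$stat, "p"),
           direction = ifelse(.data$delta_red < 0, "shortened", "lengthened")) |>
    select("gene", "mean_red_ref", "mean_red_alt", "delta_red", "t", "p",
           "direction")
  structure(res, ref = ref, alt = alt,
            class = c("apa_diff", class(res)))
}

#' Genes with dual-assay support for differential APA
#'
#' Retains genes significant in the Poly(A)-seq comparison (p below `alpha`)
#' that are also significant, with the same direction of 3' UTR change, in an
#' RNA-seq-derived APA measure.
#'
#' @param polyaseq An [diff_apa()] result (columns `gene`, `p`, `direction`).
#' @param rnaseq Tibble with `gene`, `direction`, `significant` columns.
#' @param alpha Poly(A)-seq significance threshold (default 0.05).
#' @return The supported subset of `polyaseq`.
#' @export
cross_support <- function(polyaseq, rnaseq, alpha = 0.05) {
  stopifnot_cols(polyaseq, c("gene", "p", "direction"))
  stopifnot_cols(rnaseq, c("gene", "direction", "significant"))
  polyaseq |>
    filter(.data$p < alpha) |>
    inner_join(rnaseq |> filter(.data$significant) |>
                 select("gene", rnaseq_direction = "direction"),
               by = "gene") |>
    filter(.data$direction == .data$rnaseq_direction) |>
    select(-"rnaseq_direction") |>
    mutate(rnaseq_supported = TRUE)
}

#' Cross-classify APA changes by differential expression
#'
#' Joins differential-APA calls with differential-expression results and
#' labels each gene `shortened+DE`, `lengthened+DE`, or `APA-only`; "DE"
#' requires both significance and an absolute expression log2 fold-change of
#' at least `l2fc_cut`.
#'
#' @param diff An [diff_apa()] result (or any table with `gene`, `direction`).
#' @param de Tibble with `gene`, `l2fc`, `significant`.
#' @param l2fc_cut Expression threshold (default 1).
#' @return `diff` with `expression_l2fc`, `expression_significant` and
#'   `class` columns.
#' @export
apa_expression_classify <- function(diff, de, l2fc_cut = 1) {
  stopifnot_cols(diff, c("gene", "direction"))
  stopifnot_cols(de, c("gene", "l2fc", "significant"))
  diff |>
    left_join(de |> select("gene", expression_l2fc = "l2fc",
                           expression_significant = "significant"),
              by = "gene") |>
    mutate(class = dplyr::case_when(
      .data$expression_significant & abs(.data$expression_l2fc) >= l2fc_cut &
        .data$direction == "shortened" ~ "shortened+DE",
      .data$expression_significant & abs(.data$expression_l2fc) >= l2fc_cut &
        .data$direction == "lengthened" ~ "lengthened+DE",
      TRUE ~ "APA-only"
    ))
}

#' Percent distal isoform from band intensities
#'
#' The RT-PCR readout: the percent of total lane signal arising from bands
#' assigned to distal poly(A)-site products.
#'
#' @param intensities Numeric band intensities.
#' @param is_distal Logical flags, one per band.
#' @return Percent in `[0, 100]`.
#' @examples
#' pdi(c(2, 1, 1), c(FALSE, TRUE, TRUE))  # 50
#' @export
pdi <- function(intensities, is_distal) {
  if (length(intensities) != length(is_distal))
    abort("`intensities` and `is_distal` must have equal length")
  if (any(intensities < 0)) abort("band intensities must be non-negative")
  tot <- sum(intensities)
  if (tot <= 0) abort("total band signal must be positive")
  100 * sum(intensities[is_distal]) / tot
}

#' Isoform-stability classification from a transcription-shutoff time course
#'
#' Least-squares slope of percent distal isoform against time after
#' transcription inhibition (e.g. Actinomycin D). A decreasing distal share
#' means the distal (long 3' UTR) isoform decays faster.
#'
#' @param hours,pdi Numeric vectors (>= 3 timepoints).
#' @param eps Dead band in percent per hour below which the series is called
#'   `indistinguishable` (default 0.5).
#' @return List with `slope` (percent/hour), `intercept`, `classification`.
#' @export
stability_timecourse <- function(hours, pdi, eps = 0.5) {
  if (length(hours) != length(pdi)) abort("`hours` and `pdi` lengths differ")
  if (length(hours) < 3) abort("need at least 3 timepoints")
  fit <- lm(pdi ~ hours)
  slope <- unname(coef(fit)[2])
  cls <- if (abs(slope) < eps) "indistinguishable"
         else if (slope < 0) "distal_less_stable" else "proximal_less_stable"
  list(slope = slope, intercept = unname(coef(fit)[1]), classification = cls)
}

#' Cross-dataset concordance of per-gene values
#'
#' Pearson correlation (two-sided p from the t transform) over the genes
#' shared between two named value sets — e.g. mouse screen effects vs human
#' tumour APA changes.
#'
#' @param x,y Numeric vectors named by gene.
#' @return List with `r`, `p`, `n` (shared genes).
#' @export
concordance <- function(x, y) {
  if (is.null(names(x)) || is.null(names(y)))
    abort("`x` and `y` must be named by gene")
  shared <- intersect(names(x), names(y))
  xs <- x[shared]; ys <- y[shared]
  keep <- is.finite(xs) & is.finite(ys)
  xs <- xs[keep]; ys <- ys[keep]
  if (length(xs) < 3) abort("need >= 3 shared genes with finite values")
  ct <- cor.test(xs, ys, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(xs))
}
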