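#' Tidy a scored screen
#'
#' @param x An `apa_screen_result` from [screen_score()].
#' @param ... Unused.
#' @return A plain tibble of per-target results.
#' @method tidy apa_screen_result
#' @export
tidy.apa_screen_result <- function(x, ...) {
  as_tibble(unclass_result(x))
}

#' One-row summary of a scored screen
#'
#' @inheritParams tidy.apa_screen_result
#' @return Tibble with arm, target/pgRNA totals, hit counts and the
#'   control-dispersion QC fraction.
#' @method glance apa_screen_result
#' @export
glance.apa_screen_result <- function(x, ...) {
  fc <- screen_fc(x)
  tibble(
    arm = attr(x, "arm"),
    n_targets = nrow(x),
    n_pgRNAs = dplyr::n_distinct(fc$pgRNA_id),
    n_neg_controls = dplyr::n_distinct(fc$pgRNA_id[fc$category == "neg_control"]),
    n_enriched = sum(x$call == "enriched"),
    n_depleted = sum(x$call == "depleted"),
    qc_within_2sd = qc_dispersion(fc)
  )
}

#' Tidy a differential-APA result
#'
#' @param x An `apa_diff` from [diff_apa()].
#' @param ... Unused.
#' @return A plain tibble.
#' @method tidy apa_diff
#' @export
tidy.apa_diff <- function(x, ...) as_tibble(unclass_result(x))

#' One-row summary of a differential-APA result
#'
#' @inheritParams tidy.apa_diff
#' @param alpha Significance threshold used for the counts (default 0.05).
#' @return Tibble with gene totals and shortened/lengthened significant
#'   counts.
#' @method glance apa_diff
#' @export
glance.apa_diff <- function(x, alpha = 0.05, ...) {
  tibble(
    n_genes = nrow(x),
    n_significant = sum(x$p < alpha),
    n_shortened = sum(x$p < alpha & x$direction == "shortened"),
    n_lengthened = sum(x$p < alpha & x$direction == "lengthened"),
    ref = attr(x, "ref"), alt = attr(x, "alt")
  )
}

#' Tidy Kaplan-Meier curves of a stratified cohort
#'
#' @param x A `utr_km` from [km_logrank()].
#' @param ... Unused.
#' @return Tibble of the step curves: `tercile`, `time`, `n_risk`, `n_event`,
#'   `estimate` (survival), `std_error`.
#' @method tidy utr_km
#' @export
tidy.utr_km <- function(x, ...) {
  f <- x$fit
  strata_lab <- sub("^tercile=", "", rep(names(f$strata), f$strata))
  tibble(tercile = strata_lab, time = f$time, n_risk = f$n.risk,
         n_event = f$n.event, estimate = f$surv, std_error = f$std.err)
}

#' @rdname tidy.utr_km
#' @method glance utr_km
#' @export
glance.utr_km <- function(x, ...) {
  tibble(n = nrow(x$data), events = sum(x$data$event),
         chisq = x$chisq, p = x$p)
}

#' Tidy a univariate Cox fit
#'
#' @param x A `utr_cox` from [cox_hr()].
#' @param ... Unused.
#' @return One-row tibble with `loghr`, `log2_hr`, `se`, `p`, `converged`.
#' @method tidy utr_cox
#' @export
tidy.utr_cox <- function(x, ...) {
  tibble(covariate = x$covariate, loghr = x$loghr, log2_hr = x$log2_hr,
         se = x$se, p = x$p, converged = x$converged)
}

#' @rdname tidy.utr_cox
#' @method glance utr_cox
#' @export
glance.utr_cox <- function(x, ...) tidy(x)

unclass_result <- function(x) {
  cls <- class(x)
  class(x) <- setdiff(cls, c("apa_screen_result", "apa_diff"))
  for (a in c("fc", "arm", "params", "ref", "alt")) attr(x, a) <- NULL
  x
}
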