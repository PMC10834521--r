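#' Two-sided Wilcoxon rank-sum test
#'
#' The workhorse statistic of the screen: compares one target's normalized
#' log2 fold-changes against the negative-control distribution. Ties are
#' handled with midranks throughout. For combined `n <= exact_limit` the null
#' distribution of the rank sum is enumerated over all
#' `choose(n, length(x))` group assignments of the observed midranks and the
#' two-sided p is twice the smaller tail (capped at 1); above the limit a
#' tie-corrected normal approximation without continuity correction is used.
#'
#' @param x,y Numeric vectors (target and control values).
#' @param exact_limit Combined-size cutoff for exact enumeration (default 12).
#' @return List with `statistic` (rank sum of `x`), `p.value`, and `method`
#'   (`"exact"` or `"normal"`).
#' @examples
#' ranksum_test(c(3, 4), c(1, 2))$p.value  # 1/3
#' @export
ranksum_test <- function(x, y, exact_limit = 12L) {
  if (length(x) == 0 || length(y) == 0) abort("both groups must be non-empty")
  if (anyNA(x) || anyNA(y)) abort("NA values are not allowed")
  nx <- length(x); ny <- length(y); n <- nx + ny
  r <- rank(c(x, y))
  w <- sum(r[seq_len(nx)])
  if (n <= exact_limit) {
    sums <- combn(n, nx, function(i) sum(r[i]))
    eps <- 1e-9
    p_lo <- mean(sums <= w + eps)
    p_hi <- mean(sums >= w - eps)
    list(statistic = w, p.value = min(1, 2 * min(p_lo, p_hi)),
         method = "exact")
  } else {
    mu <- nx * (n + 1) / 2
    ties <- table(r)
    sigma2 <- (nx * ny / 12) * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) return(list(statistic = w, p.value = 1, method = "normal"))
    z <- (w - mu) / sqrt(sigma2)
    list(statistic = w, p.value = 2 * pnorm(-abs(z)), method = "normal")
  }
}

# fast path used by the empirical-FDR subsampler: the rank sum of `x` within
# c(x, y), for many x-subsets of a fixed y, all reduced to precomputed ranks
ranksum_p_normal <- function(w, nx, ny, tie_term) {
  n <- nx + ny
  mu <- nx * (n + 1) / 2
  sigma2 <- (nx * ny / 12) * ((n + 1) - tie_term / (n * (n - 1)))
  z <- (w - mu) / sqrt(sigma2)
  2 * pnorm(-abs(z))
}
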