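# Shared fixtures and independent oracles used across the suite.

small_cfg <- function(seed = 1, ...) {
  sim_config(seed = seed, n_genes = 30, n_targets = 5, n_neg_controls = 30,
             n_pos_controls = 10, cohort_size = 30, ...)
}

# a designed library + screen counts at modest scale
small_screen <- function(seed = 1, effects = numeric(), ...) {
  cfg <- sim_config(seed = seed, n_genes = 40, n_targets = 8,
                    n_neg_controls = 40, n_pos_controls = 10,
                    selection_effects = effects, ...)
  sites <- gen_pas_landscape(cfg)
  cands <- gen_guide_candidates(sites, cfg)
  lib <- suppressWarnings(build_library(sites, cands, cfg))
  counts <- gen_screen_counts(lib, cfg)
  list(cfg = cfg, sites = sites, lib = lib, counts = counts)
}

# independent full-enumeration Wilcoxon oracle: two-sided p over all
# rank assignments, midranks for ties
oracle_ranksum_p <- function(x, y) {
  n <- length(x) + length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_along(x)])
  all_w <- apply(combn(n, length(x)), 2, function(i) sum(r[i]))
  lo <- sum(all_w <= w_obs + 1e-9) / length(all_w)
  hi <- sum(all_w >= w_obs - 1e-9) / length(all_w)
  min(1, 2 * min(lo, hi))
}

# brute-force pair enumeration: plain loops, containment rule, min-score
# efficiency, elementwise off-target sums
oracle_enumerate_pairs <- function(cand, hs, he) {
  out <- list()
  n <- nrow(cand)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    lo <- min(cand$cut_position[c(i, j)])
    hi <- max(cand$cut_position[c(i, j)])
    if (lo <= hs && hi >= he) {
      out[[length(out) + 1]] <- data.frame(
        lo = lo, hi = hi,
        eff = min(cand$on_target_score[c(i, j)]),
        off2 = cand$offtargets_2mm[i] + cand$offtargets_2mm[j],
        off3 = cand$offtargets_3mm[i] + cand$offtargets_3mm[j]
      )
    }
  }
  if (length(out) == 0) {
    return(data.frame(lo = integer(), hi = integer(), eff = numeric(),
                      off2 = integer(), off3 = integer()))
  }
  do.call(rbind, out)
}

# independent Welch statistic/p from the closed form
oracle_welch <- function(a, b) {
  m <- length(a); n <- length(b)
  va <- var(a) / m; vb <- var(b) / n
  t <- (mean(b) - mean(a)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (m - 1) + vb^2 / (n - 1))
  list(t = t, p = 2 * pt(-abs(t), df))
}

# independent logrank O-E and variance over explicit risk sets
oracle_logrank <- function(time, event, grp) {
  ev_times <- sort(unique(time[event == 1]))
  O <- 0; E <- 0; V <- 0
  for (t in ev_times) {
    at <- time >= t
    n <- sum(at); n1 <- sum(at & grp == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & grp == 1)
    O <- O + d1; E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  list(O = O, E = E, V = V, chisq = (O - E)^2 / V)
}

# independent Cox log partial likelihood for one covariate, no tied events
oracle_cox_loghr <- function(time, event, x) {
  logpl <- function(beta) {
    s <- 0
    for (i in which(event == 1)) {
      risk <- time >= time[i]
      s <- s + beta * x[i] - log(sum(exp(beta * x[risk])))
    }
    s
  }
  optimize(logpl, c(-10, 10), maximum = TRUE, tol = 1e-10)$maximum
}

# minimal hand-built library usable by the fold-change / counting fixtures
toy_library <- function(n = 3) {
  tibble::tibble(
    pgRNA_id = paste0("pg", seq_len(n)),
    target_id = paste0("t", seq_len(n)),
    gene = paste0("g", seq_len(n)),
    seq_left = paste0("L", seq_len(n)),
    seq_right = paste0("R", seq_len(n)),
    pair_efficiency = 50, offtargets_2mm_sum = 0L, offtargets_3mm_sum = 0L,
    category = "targeting"
  )
}
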