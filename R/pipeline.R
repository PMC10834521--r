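#' Run one pipeline stage, writing artifacts and a provenance manifest
#'
#' Thin orchestration layer over the package's functions, mirroring a shell
#' workflow: `simulate` (landscape + candidates), `design` (library + BED),
#' `count` (paired reads -> counts), `score` (screen statistics per arm),
#' `apa` (Poly(A)-seq differential APA), `survive` (cohort stratification,
#' logrank and Cox). Every stage writes its tables under `out_dir` together
#' with a `manifest_<stage>.json` recording inputs, parameters, seed and the
#' package version, sufficient to re-run the stage. With the same config and
#' seed, outputs are byte-identical.
#'
#' @param stage One of `"simulate"`, `"design"`, `"count"`, `"score"`,
#'   `"apa"`, `"survive"`.
#' @param cfg A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @param in_dir Directory holding the upstream stage's artifacts (defaults
#'   to `out_dir`).
#' @param ... Stage-specific overrides: `arm`, `n_sub`, `k`, `error_rate`.
#' @return Named list of written file paths, invisibly.
#' @export
run_stage <- function(stage = c("simulate", "design", "count", "score",
                                "apa", "survive"),
                      cfg, out_dir, in_dir = out_dir, ...) {
  stage <- match.arg(stage)
  stopifnot(inherits(cfg, "sim_config"))
  dots <- list(...)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, paste0(...))
  pin <- function(...) {
    f <- file.path(in_dir, paste0(...))
    if (!file.exists(f)) abort(sprintf("required input '%s' not found; run the upstream stage first", f))
    f
  }
  meta <- list(stage = stage, seed = cfg$seed,
               package = as.character(utils::packageVersion("apascreen")))
  written <- switch(stage,
    simulate = {
      sites <- gen_pas_landscape(cfg)
      cands <- gen_guide_candidates(sites, cfg)
      write_table(sites, p("sites.tsv"), "sites", meta = meta)
      readr::write_tsv(cands, p("candidates.tsv"))
      list(sites = p("sites.tsv"), candidates = p("candidates.tsv"))
    },
    design = {
      sites <- read_table(pin("sites.tsv"), "sites")
      cands <- readr::read_tsv(pin("candidates.tsv"), show_col_types = FALSE)
      lib <- build_library(sites, cands, cfg)
      write_table(lib, p("library.tsv"), "library", meta = meta)
      export_bed(lib, sites, p("library.bed"))
      list(library = p("library.tsv"), bed = p("library.bed"))
    },
    count = {
      lib <- read_table(pin("library.tsv"), "library")
      reads <- read_table(pin("read_pairs.tsv"), "read_pairs")
      counts <- tally_counts(reads, lib)
      samples <- infer_sample_meta(unique(counts$sample_id))
      counts <- left_join(counts, samples, by = "sample_id")
      write_table(counts, p("counts.tsv"), "counts", meta = meta)
      readr::write_tsv(discard_summary(counts), p("discards.tsv"))
      list(counts = p("counts.tsv"), discards = p("discards.tsv"))
    },
    score = {
      lib <- read_table(pin("library.tsv"), "library")
      counts <- read_table(pin("counts.tsv"), "counts")
      arm <- dots$arm %||% "invitro_d20"
      res <- screen_score(counts, lib, arm = arm,
                          n_sub = dots$n_sub %||% 10000L,
                          k = dots$k %||% 10L, seed = cfg$seed)
      readr::write_tsv(as_tibble(res), p("target_results_", arm, ".tsv"))
      readr::write_tsv(screen_fc(res), p("fold_changes_", arm, ".tsv"))
      list(results = p("target_results_", arm, ".tsv"),
           fc = p("fold_changes_", arm, ".tsv"))
    },
    apa = {
      pa <- read_table(pin("polyaseq.tsv"), "polyaseq")
      quant <- gene_apa_metrics(pa)
      diff <- diff_apa(quant)
      readr::write_tsv(as_tibble(diff), p("diff_apa.tsv"))
      list(diff_apa = p("diff_apa.tsv"))
    },
    survive = {
      prof <- read_table(pin("cohort.tsv"), "cohort")
      clin <- read_table(pin("clinical.tsv"), "clinical")
      med <- sample_median_utr(prof, min_genes = min(100L, cfg$n_genes))
      strata <- stratify_terciles(med |> rename(value = "median_utr"))
      km <- km_logrank(strata, clin)
      cox <- cox_hr(strata, clin)
      readr::write_tsv(strata, p("strata.tsv"))
      readr::write_tsv(tidy(km), p("km_curves.tsv"))
      jsonlite::write_json(
        list(logrank_chisq = km$chisq, logrank_p = km$p,
             cox_log2_hr = cox$log2_hr, cox_p = cox$p),
        p("survival_results.json"), auto_unbox = TRUE, digits = NA)
      list(strata = p("strata.tsv"), km = p("km_curves.tsv"),
           results = p("survival_results.json"))
    })
  manifest <- c(meta, list(
    out_dir = out_dir, in_dir = in_dir, files = written,
    params = dots,
    config = unclass(cfg)[!vapply(unclass(cfg), is.null, logical(1))]
  ))
  jsonlite::write_json(manifest, p("manifest_", stage, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(written)
}

# sample ids of the simulators encode arm and replicate
infer_sample_meta <- function(sample_ids) {
  m <- stringr::str_match(sample_ids, "^(plasmid|day0|invitro_d20|invivo_d20)(?:_r(\\d+))?$")
  if (anyNA(m[, 2]))
    abort(sprintf("cannot infer arm/replicate from sample id(s): %s",
                  paste(sample_ids[is.na(m[, 2])], collapse = ", ")))
  tibble(sample_id = sample_ids, arm = m[, 2],
         replicate = as.integer(m[, 3]))
}
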