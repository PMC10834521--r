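# column contracts for the on-disk TSV formats; "int" rejects silent
# float-to-integer coercion
apascreen_schemas <- list(
  sites = list(gene = "chr", site_id = "chr", chrom = "chr", strand = "chr",
               hexamer_start = "int", hexamer_end = "int", signal_class = "chr",
               rank = "chr", tissue_count = "int", sample_fraction = "dbl",
               expressed = "lgl"),
  library = list(pgRNA_id = "chr", target_id = "chr", gene = "chr",
                 seq_left = "chr", seq_right = "chr",
                 pair_efficiency = "dbl", offtargets_2mm_sum = "int",
                 offtargets_3mm_sum = "int", category = "chr"),
  counts = list(pgRNA_id = "chr", sample_id = "chr", arm = "chr",
                replicate = "int", count = "int"),
  read_pairs = list(read1 = "chr", read2 = "chr", sample_id = "chr"),
  polyaseq = list(gene = "chr", sample = "chr", group = "chr",
                  proximal = "int", distal = "int"),
  cohort = list(sample_id = "chr", gene = "chr", usage = "dbl"),
  clinical = list(sample_id = "chr", time = "dbl", event = "int"),
  mutations = list(gene = "chr", lof_count = "int", cds_length_kb = "dbl")
)

check_schema <- function(df, schema, path = "<table>") {
  miss <- setdiff(names(schema), names(df))
  if (length(miss) > 0)
    abort(sprintf("%s: missing required column(s): %s",
                  path, paste(miss, collapse = ", ")))
  for (col in names(schema)) {
    x <- df[[col]]
    type <- schema[[col]]
    ok <- switch(type,
      chr = is.character(x) || is.factor(x),
      dbl = is.numeric(x),
      lgl = is.logical(x),
      int = {
        if (!is.numeric(x)) FALSE
        else if (any(!is.na(x) & x != floor(x)))
          abort(sprintf("%s: column '%s' must be integer-valued (found a fractional value)",
                        path, col))
        else TRUE
      })
    if (!ok)
      abort(sprintf("%s: column '%s' must be of type %s", path, col, type))
    if (type == "int") df[[col]] <- as.integer(df[[col]])
  }
  df
}

#' Read a typed pipeline table
#'
#' Schema-validated TSV reader for the pipeline's on-disk formats. Leading
#' `#`-comment lines (metadata headers written by [write_table()]) are
#' skipped. Validation errors name the offending column.
#'
#' @param path File path.
#' @param schema One of `"sites"`, `"library"`, `"counts"`, `"read_pairs"`,
#'   `"polyaseq"`, `"cohort"`, `"clinical"`, `"mutations"`.
#' @return A validated tibble.
#' @export
read_table <- function(path, schema) {
  schema <- rlang::arg_match(schema, names(apascreen_schemas))
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  check_schema(df, apascreen_schemas[[schema]], path = path)
}

#' Write a typed pipeline table
#'
#' TSV with an optional `#`-prefixed metadata header block (diffable
#' provenance: parameters, seed, package version).
#'
#' @param df Table to write (validated against the schema first).
#' @param path Output path.
#' @inheritParams read_table
#' @param meta Optional named list written as `# key: value` header lines.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path, schema, meta = NULL) {
  schema <- rlang::arg_match(schema, names(apascreen_schemas))
  df <- check_schema(df, apascreen_schemas[[schema]])
  keep <- names(apascreen_schemas[[schema]])
  df <- df[, c(keep, setdiff(names(df), keep)), drop = FALSE]
  lines <- character()
  if (!is.null(meta)) {
    lines <- sprintf("# %s: %s", names(meta),
                     vapply(meta, function(v) paste(format(v), collapse = ","),
                            character(1)))
  }
  if (length(lines) > 0) {
    writeLines(lines, path)
    readr::write_tsv(df, path, append = TRUE, col_names = TRUE)
  } else {
    readr::write_tsv(df, path)
  }
  invisible(path)
}

#' Export library deletion intervals and hexamers as BED6
#'
#' Writes genome-browser-ready BED6 records (0-based half-open, strand
#' column populated): one record per targeting/control pgRNA deletion
#' interval and one per poly(A)-signal hexamer, sorted by (chrom, start).
#'
#' @param library Library tibble (pos-control records without coordinates are
#'   skipped).
#' @param sites Site tibble from [gen_pas_landscape()] (or compatible).
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
export_bed <- function(library, sites, path) {
  stopifnot_cols(sites, c("chrom", "hexamer_start", "hexamer_end",
                          "site_id", "strand"))
  hex <- tibble(
    chrom = sites$chrom, start = sites$hexamer_start, end = sites$hexamer_end,
    name = paste0("hexamer|", sites$site_id), score = 0L,
    strand = sites$strand
  )
  lib <- library |>
    filter(!is.na(.data$deletion_start))
  del <- tibble(
    chrom = lib$chrom, start = lib$deletion_start, end = lib$deletion_end,
    name = paste0("deletion|", lib$pgRNA_id), score = 0L, strand = lib$strand
  )
  bed <- bind_rows(hex, del) |> arrange(.data$chrom, .data$start, .data$end)
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' Read a BED6 file back into a tibble
#'
#' @param path BED path.
#' @return Tibble (`chrom`, `start`, `end`, `name`, `score`, `strand`),
#'   coordinates 0-based half-open as on disk.
#' @export
read_bed <- function(path) {
  readr::read_tsv(path,
                  col_names = c("chrom", "start", "end", "name", "score",
                                "strand"),
                  col_types = "ciicic", progress = FALSE)
}
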