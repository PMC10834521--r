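#' Build a guide-pair index for read assignment
#'
#' @param library Library tibble with `pgRNA_id`, `seq_left`, `seq_right`.
#' @return An index object used by [assign_read_pair()] / [tally_counts()].
#' @export
pair_index <- function(library) {
  stopifnot_cols(library, c("pgRNA_id", "seq_left", "seq_right"))
  if (anyDuplicated(library$pgRNA_id) > 0)
    abort("duplicate pgRNA_id in library")
  key <- paste(library$seq_left, library$seq_right)
  if (anyDuplicated(key) > 0)
    abort("duplicate (guide1, guide2) sequence pair in library")
  structure(list(
    pgRNA_id = library$pgRNA_id,
    seq_left = library$seq_left,
    seq_right = library$seq_right,
    key = key
  ), class = "pair_index")
}

#' Assign one read pair to a pgRNA, enforcing pair concordance
#'
#' A pair is assigned iff read 1 matches a library guide-1 sequence and read 2
#' matches a guide-2 sequence *of the same pgRNA* (unique best hit). Anything
#' else is discarded with a reason: `unmapped1`/`unmapped2` (a read matches no
#' library guide), `discordant` (both map, but to no common pgRNA), or
#' `ambiguous` (more than one pgRNA fits, possible only with `max_mismatch`
#' > 0). Matching is exact by default; `max_mismatch` allows per-read Hamming
#' mismatches between equal-length sequences.
#'
#' @param read1,read2 Guide sequences.
#' @param index A [pair_index()].
#' @param max_mismatch Per-read Hamming tolerance (default 0 = exact).
#' @return The pgRNA id, or `NA` with attribute `reason`.
#' @export
assign_read_pair <- function(read1, read2, index, max_mismatch = 0L) {
  stopifnot(inherits(index, "pair_index"))
  hit1 <- match_guide(read1, index$seq_left, max_mismatch)
  if (length(hit1) == 0)
    return(structure(NA_character_, reason = "unmapped1"))
  hit2 <- match_guide(read2, index$seq_right, max_mismatch)
  if (length(hit2) == 0)
    return(structure(NA_character_, reason = "unmapped2"))
  both <- intersect(hit1, hit2)
  if (length(both) == 1) return(index$pgRNA_id[both])
  if (length(both) == 0) return(structure(NA_character_, reason = "discordant"))
  structure(NA_character_, reason = "ambiguous")
}

# rows of `pool` matching `read` within `max_mismatch` Hamming distance;
# only best-distance hits are returned
match_guide <- function(read, pool, max_mismatch = 0L) {
  if (max_mismatch == 0L) return(which(pool == read))
  d <- hamming_dist(read, pool)
  d[is.na(d)] <- Inf
  best <- min(d)
  if (best > max_mismatch) integer() else which(d == best)
}

hamming_dist <- function(read, pool) {
  nc <- nchar(pool)
  out <- rep(NA_real_, length(pool))
  same <- nc == nchar(read)
  if (!any(same)) return(out)
  rchars <- strsplit(read, "")[[1]]
  out[same] <- vapply(strsplit(pool[same], ""), function(p) {
    sum(p != rchars)
  }, numeric(1))
  out
}

#' Tally concordant read pairs into a pgRNA count matrix
#'
#' Vectorised counterpart of [assign_read_pair()] over a read-pair table.
#' Per sample, assigned + discarded equals the total pairs processed; the
#' discard tally is broken down by reason.
#'
#' @param read_pairs Tibble with `read1`, `read2`, `sample_id`.
#' @param library Library tibble (or a prebuilt [pair_index()]).
#' @param sample_meta Optional tibble (`sample_id`, `arm`, `replicate`) merged
#'   onto the counts; samples missing from it raise an error.
#' @return Long count tibble (`pgRNA_id`, `sample_id`, `count`, plus metadata
#'   columns when supplied), covering every library pgRNA x sample, with
#'   attribute `discards` (per-sample, per-reason tallies).
#' @export
tally_counts <- function(read_pairs, library, sample_meta = NULL) {
  stopifnot_cols(read_pairs, c("read1", "read2", "sample_id"))
  idx <- if (inherits(library, "pair_index")) library else pair_index(library)
  samples <- unique(read_pairs$sample_id)
  if (!is.null(sample_meta)) {
    stopifnot_cols(sample_meta, c("sample_id", "arm", "replicate"))
    missing <- setdiff(samples, sample_meta$sample_id)
    if (length(missing) > 0)
      abort(sprintf("sample_map does not cover sample(s): %s",
                    paste(missing, collapse = ", ")))
    samples <- unique(c(samples, sample_meta$sample_id))
  }
  n_reads <- nrow(read_pairs)
  hit1 <- match(read_pairs$read1, idx$seq_left)
  hit2 <- match(read_pairs$read2, idx$seq_right)
  # exact unique sequences: first match on each side is complete; concordance
  # then reduces to the (read1, read2) pair being a library pair
  pair_row <- match(paste(read_pairs$read1, read_pairs$read2), idx$key)
  reason <- dplyr::case_when(
    !is.na(pair_row) ~ "assigned",
    is.na(hit1) ~ "unmapped1",
    is.na(hit2) ~ "unmapped2",
    TRUE ~ "discordant"
  )
  grid <- tidyr::expand_grid(pgRNA_id = idx$pgRNA_id, sample_id = samples)
  assigned <- tibble(
    pgRNA_id = idx$pgRNA_id[pair_row[!is.na(pair_row)]],
    sample_id = read_pairs$sample_id[!is.na(pair_row)]
  ) |>
    count(.data$pgRNA_id, .data$sample_id, name = "count")
  counts <- grid |>
    left_join(assigned, by = c("pgRNA_id", "sample_id")) |>
    mutate(count = tidyr::replace_na(.data$count, 0L))
  if (!is.null(sample_meta)) {
    counts <- left_join(counts, sample_meta, by = "sample_id")
  }
  discards <- tibble(sample_id = read_pairs$sample_id, reason = reason) |>
    filter(.data$reason != "assigned") |>
    count(.data$sample_id, .data$reason, name = "n")
  attr(counts, "discards") <- discards
  attr(counts, "n_pairs_processed") <- n_reads
  counts
}

#' Per-sample discard summary of a tallied count table
#' @param counts Output of [tally_counts()].
#' @return Tibble (`sample_id`, `reason`, `n`).
#' @export
discard_summary <- function(counts) {
  d <- attr(counts, "discards")
  if (is.null(d)) abort("`counts` carries no discard summary")
  d
}
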