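#' Census parameters
#'
#' @param head_limit Number of reads from the head of each library entered
#'   into the identical-read census (default 10 million, the leading
#'   segment size used for full-scale libraries; desk-scale analyses pass
#'   the library size).
#' @param ratio_threshold Candidate reads must have a between-library count
#'   ratio exceeding this value in either direction (default 3, the "3:1"
#'   screen).
#' @return An object of class `census_params`.
#' @export
census_params <- function(head_limit = 1e7, ratio_threshold = 3.0) {
  stopifnot(head_limit >= 1, ratio_threshold >= 1)
  structure(list(head_limit = as.double(head_limit),
                 ratio_threshold = as.double(ratio_threshold)),
            class = "census_params")
}

#' Count identical reads in the leading segment of a library
#'
#' Exact string multiplicity of each distinct read sequence among the first
#' `head_limit` reads.  Mates are counted as individual reads and no
#' reverse-complement collapsing is performed: identity means identical
#' orientation.
#'
#' @param reads A read table or `groomed_library`.
#' @param head_limit Number of leading reads to census.
#' @return A tibble with columns `sequence` and `count`, one row per
#'   distinct sequence.
#' @export
count_identical_reads <- function(reads, head_limit = 1e7) {
  reads <- as_read_table(reads)
  seqs <- head(reads$seq, head_limit)
  if (length(seqs) == 0L) return(tibble(sequence = character(0),
                                        count = integer(0)))
  tab <- table(seqs)
  tibble(sequence = names(tab), count = as.integer(tab))
}

#' Match census counts across two libraries
#'
#' Joins two census tables on identical sequence.  For sequences present in
#' both libraries the ratio `count_b / count_a` is computed; sequences seen
#' in only one library are retained with `in_both = FALSE` and a ratio
#' marker of `Inf` (absent from library A) or `0` (absent from library B),
#' and are excluded from ratio ranking by default.
#'
#' @param counts_a,counts_b Census tables from [count_identical_reads()].
#' @return A tibble with columns `sequence`, `count_a`, `count_b`, `ratio`
#'   and `in_both`.
#' @export
cross_census <- function(counts_a, counts_b) {
  j <- full_join(
    rename(counts_a, count_a = "count"),
    rename(counts_b, count_b = "count"),
    by = "sequence"
  )
  j$count_a[is.na(j$count_a)] <- 0L
  j$count_b[is.na(j$count_b)] <- 0L
  j$in_both <- j$count_a > 0L & j$count_b > 0L
  j$ratio <- ifelse(j$count_a > 0L, j$count_b / j$count_a, Inf)
  as_tibble(j[, c("sequence", "count_a", "count_b", "ratio", "in_both")])
}

#' Rank candidate differential reads by count-ratio extremity
#'
#' Keeps entries present in both libraries whose ratio exceeds the
#' threshold in either direction and orders them by extremity
#' `max(ratio, 1/ratio)` descending, breaking ties by higher total count
#' and then lexicographically by sequence, so the ordering is invariant to
#' input order.
#'
#' @param entries Output of [cross_census()].
#' @param ratio_threshold Ratio screen (default 3).
#' @return The filtered, ordered tibble with an added `extremity` column.
#' @export
select_candidates <- function(entries, ratio_threshold = 3.0) {
  stopifnot(ratio_threshold >= 1)
  e <- entries[entries$in_both &
                 (entries$ratio > ratio_threshold |
                    entries$ratio < 1 / ratio_threshold), , drop = FALSE]
  e$extremity <- pmax(e$ratio, 1 / e$ratio)
  e <- e[order(-e$extremity, -(e$count_a + e$count_b), e$sequence), ,
         drop = FALSE]
  as_tibble(e)
}
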