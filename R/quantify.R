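#' Quantification parameters
#'
#' A read is scored as derived from a transcript when some ungapped
#' placement of the read (in either orientation) against the transcript's
#' reading frame achieves at least `min_identity` identical bases out of
#' `identity_window` (the nominal read length); placements overhanging the
#' frame ends count the overhang as mismatches.  Reads trimmed below
#' `identity_window` by grooming have the threshold scaled proportionally
#' (at least 90% of the read length with the defaults).
#'
#' @param min_identity Minimum identical bases (default 90).
#' @param identity_window Nominal read length (default 100).
#' @param reference_id Identifier of the reference transcript against which
#'   relative abundances are expressed (the 40S ribosomal protein SA
#'   transcript in the bundled dataset).
#' @return An object of class `quant_params`.
#' @export
quant_params <- function(min_identity = 90L, identity_window = 100L,
                         reference_id = NULL) {
  min_identity <- as.integer(min_identity)
  identity_window <- as.integer(identity_window)
  stopifnot(min_identity > 0L, min_identity <= identity_window)
  structure(list(min_identity = min_identity,
                 identity_window = identity_window,
                 reference_id = reference_id),
            class = "quant_params")
}

#' Does a read match a transcript's reading frame?
#'
#' @param read_seq One or more read sequences (character).
#' @param transcript A `transcript` object, or a plain ORF sequence string.
#' @param params A [quant_params()] object.
#' @return Logical vector: `TRUE` where the read matches the frame in
#'   either orientation at the identity criterion.
#' @export
read_matches_frame <- function(read_seq, transcript,
                               params = quant_params()) {
  orf <- if (inherits(transcript, "transcript")) orf_sequence(transcript)
         else transcript
  fwd <- .cpp_frame_matches(read_seq, orf, params$min_identity,
                            params$identity_window)
  rc <- .cpp_frame_matches(reverse_complement(read_seq), orf,
                           params$min_identity, params$identity_window)
  fwd | rc
}

#' Count frame-matching reads for each transcript
#'
#' @param transcripts A list of `transcript` objects (or named character
#'   vector of ORF sequences).
#' @param reads A read table or `groomed_library`.
#' @param params A [quant_params()] object.
#' @return Integer vector of matching-read counts, named by transcript id.
#' @export
count_frame_matches <- function(transcripts, reads,
                                params = quant_params()) {
  reads <- as_read_table(reads)
  orfs <- transcript_orfs(transcripts)
  seqs <- reads$seq
  rc <- reverse_complement(seqs)
  vapply(orfs, function(orf) {
    sum(.cpp_frame_matches(seqs, orf, params$min_identity,
                           params$identity_window) |
          .cpp_frame_matches(rc, orf, params$min_identity,
                             params$identity_window))
  }, integer(1))
}

transcript_orfs <- function(transcripts) {
  if (is.character(transcripts)) {
    stopifnot(!is.null(names(transcripts)))
    return(transcripts)
  }
  if (inherits(transcripts, "transcript")) transcripts <- list(transcripts)
  setNames(
    vapply(transcripts, orf_sequence, character(1)),
    vapply(transcripts, function(t) t$id, character(1))
  )
}

#' Quantify relative transcript abundance in one library
#'
#' Counts reads matching each transcript's reading frame (a read matching
#' several transcripts counts once for each; there is no competitive
#' assignment), expresses the count as a fraction of all groomed reads
#' scanned, normalises by frame length, and reports the log10 abundance
#' relative to the reference transcript in the same library.  The
#' reference's `log10_relative` is exactly 0 by construction.  Transcripts
#' with zero matching reads get `raw_abundance` 0 and `log10_relative`
#' `-Inf`, with a warning: they cannot enter ratio analysis.
#'
#' @param transcripts A list of `transcript` objects or named character
#'   vector of ORF sequences.
#' @param reads A read table or `groomed_library`.
#' @param params A [quant_params()] object with a non-`NULL`
#'   `reference_id`.
#' @param library_id Label recorded in the output (default `"library"`).
#' @return A tibble with columns `transcript_id`, `library_id`,
#'   `matching_reads`, `total_reads`, `frame_length`, `raw_abundance`,
#'   `log10_relative`.
#' @export
quantify_library <- function(transcripts, reads, params,
                             library_id = "library") {
  stopifnot(!is.null(params$reference_id))
  reads <- as_read_table(reads)
  orfs <- transcript_orfs(transcripts)
  if (!params$reference_id %in% names(orfs)) {
    stop("reference transcript '", params$reference_id,
         "' absent from the transcript set", call. = FALSE)
  }
  total <- nrow(reads)
  stopifnot(total > 0L)
  matches <- count_frame_matches(orfs, reads, params)
  frame_len <- nchar(orfs)
  raw <- (matches / total) / frame_len
  ref_raw <- raw[[params$reference_id]]
  if (ref_raw <= 0) {
    stop("reference transcript '", params$reference_id,
         "' has zero matching reads; normalisation undefined",
         call. = FALSE)
  }
  if (any(matches == 0L)) {
    warning(sum(matches == 0L),
            " transcript(s) with zero matching reads; log10_relative",
            " reported as -Inf and excluded from ratio analysis",
            call. = FALSE)
  }
  tibble(
    transcript_id = names(orfs),
    library_id = library_id,
    matching_reads = unname(matches),
    total_reads = total,
    frame_length = unname(frame_len),
    raw_abundance = unname(raw),
    log10_relative = unname(log10(raw / ref_raw))
  )
}
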