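#' Grooming parameters
#'
#' A read is kept when it contains a contiguous run of at least
#' `min_run_length` positions whose Phred score is at least `min_phred`
#' (the default 20 keeps scores "greater than 19", i.e. base-call error
#' probability below 1%).  When `trim_to_run` is `TRUE` the read is trimmed
#' to that run so that downstream exact-identity steps operate on clean
#' sequence.
#'
#' @param min_run_length Minimum run length in nucleotides (default 80).
#' @param min_phred Minimum Phred score within the run (default 20).
#' @param trim_to_run Trim kept reads to the qualifying run (default `TRUE`)
#'   or keep them full length.
#' @return An object of class `groom_params`.
#' @export
groom_params <- function(min_run_length = 80L, min_phred = 20L,
                         trim_to_run = TRUE) {
  min_run_length <- as.integer(min_run_length)
  min_phred <- as.integer(min_phred)
  stopifnot(min_run_length > 0L, min_phred >= 0L, is.logical(trim_to_run))
  structure(list(min_run_length = min_run_length, min_phred = min_phred,
                 trim_to_run = trim_to_run),
            class = "groom_params")
}

# Longest contiguous run of TRUE; ties broken leftmost.
# Returns c(start, length) or c(0, 0) when no TRUE present.
longest_true_run <- function(ok) {
  if (!any(ok)) return(c(0L, 0L))
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cand <- which(r$values)
  best <- cand[which.max(r$lengths[cand])]   # which.max is leftmost on ties
  c(starts[best], r$lengths[best])
}

#' Groom a single read
#'
#' Finds the longest contiguous run of positions with quality at least
#' `min_phred` (leftmost on ties).  If the run reaches `min_run_length` the
#' read is kept -- trimmed to the run when `trim_to_run` is set -- otherwise
#' it is rejected.
#'
#' @param read A one-row read table (or list) with elements `seq` and
#'   `qual`.
#' @param params A [groom_params()] object.
#' @return The (possibly trimmed) read as a list, or `NULL` when rejected.
#' @export
groom_read <- function(read, params = groom_params()) {
  q <- phred_scores(read$qual[[1]])
  run <- longest_true_run(q >= params$min_phred)
  if (run[2L] < params$min_run_length) return(NULL)
  out <- as.list(read)
  if (params$trim_to_run) {
    from <- run[1L]
    to <- run[1L] + run[2L] - 1L
    out$seq <- substr(out$seq, from, to)
    out$qual <- substr(out$qual, from, to)
  }
  out
}

#' Groom a read library
#'
#' Applies [groom_read()] to every read independently, preserving input
#' order.  Mates are groomed independently, so a pair may lose one mate.
#'
#' @param reads A read table (see [read_fastq()]).
#' @param params A [groom_params()] object.
#' @return An object of class `groomed_library`: a list with elements
#'   `reads` (the kept, possibly trimmed, read table), `n_input`, `n_kept`
#'   and `params`.
#' @export
groom_library <- function(reads, params = groom_params()) {
  reads <- as_read_table(reads)
  n <- nrow(reads)
  if (n == 0L) {
    return(structure(list(reads = reads, n_input = 0L, n_kept = 0L,
                          params = params),
                     class = "groomed_library"))
  }
  starts <- integer(n)
  lens <- integer(n)
  for (i in seq_len(n)) {
    run <- longest_true_run(utf8ToInt(reads$qual[i]) >= params$min_phred + 33L)
    starts[i] <- run[1L]
    lens[i] <- run[2L]
  }
  keep <- lens >= params$min_run_length
  kept <- reads[keep, , drop = FALSE]
  if (params$trim_to_run && nrow(kept) > 0L) {
    from <- starts[keep]
    to <- from + lens[keep] - 1L
    kept$seq <- substr(kept$seq, from, to)
    kept$qual <- substr(kept$qual, from, to)
  }
  structure(list(reads = kept, n_input = n, n_kept = nrow(kept),
                 params = params),
            class = "groomed_library")
}

#' @export
print.groomed_library <- function(x, ...) {
  cat(sprintf(
    "groomed_library: kept %d / %d reads (run >= %d nt at Phred >= %d%s)\n",
    x$n_kept, x$n_input, x$params$min_run_length, x$params$min_phred,
    if (x$params$trim_to_run) ", trimmed" else ""))
  invisible(x)
}
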