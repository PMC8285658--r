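# Brute-force oracles and small generators used across the test files.
# These deliberately re-derive every answer by enumeration, independent of
# the package's implementations.

rand_dna <- function(n) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

q_string <- function(scores) intToUtf8(as.integer(scores) + 33L)

q_const <- function(n, q = 40L) strrep(intToUtf8(q + 33L), n)

make_read_table <- function(seqs, quals = NULL, ids = NULL) {
  if (is.null(quals)) quals <- vapply(nchar(seqs), q_const, character(1))
  if (is.null(ids)) ids <- sprintf("read_%04d", seq_along(seqs))
  tibble::tibble(id = ids, mate = 0L, seq = seqs, qual = quals)
}

# Error-free reads tiling a transcript at a fixed start step, both mates
# synthesised as forward-strand and reverse-complement windows.
tile_reads <- function(tx, read_len = 100L, step = 3L) {
  L <- nchar(tx)
  starts <- seq(1L, L - read_len + 1L, by = step)
  fwd <- substring(tx, starts, starts + read_len - 1L)
  rc <- transwalker::reverse_complement(fwd)
  make_read_table(c(fwd, rc))
}

# Oracle: longest contiguous run of qualities >= min_phred, leftmost on
# ties, by scanning every (start, end) pair.
bf_longest_run <- function(q, min_phred) {
  n <- length(q)
  best <- c(0L, 0L)
  for (s in seq_len(n)) {
    for (e in s:n) {
      if (all(q[s:e] >= min_phred)) {
        len <- e - s + 1L
        if (len > best[2L]) best <- c(s, len)
      }
    }
  }
  best
}

# Oracle: exact-duplicate tally by sort and run-length encoding.
bf_census <- function(seqs) {
  if (length(seqs) == 0L) {
    return(tibble::tibble(sequence = character(0), count = integer(0)))
  }
  r <- rle(sort(seqs))
  tibble::tibble(sequence = r$values, count = r$lengths)
}

# Oracle: maximum-scoring ungapped window by enumerating every
# (peptide start, query start, length) triple.
bf_best_window <- function(peptide, query, m) {
  p <- strsplit(peptide, "")[[1]]
  q <- strsplit(query, "")[[1]]
  best <- 0
  for (i in seq_along(p)) {
    for (j in seq_along(q)) {
      len_max <- min(length(p) - i, length(q) - j) + 1L
      s <- 0
      for (l in seq_len(len_max)) {
        s <- s + m[p[i + l - 1L], q[j + l - 1L]]
        if (s > best) best <- s
      }
    }
  }
  best
}

# Oracle: longest complete reading frame by enumerating every ATG..stop
# span on both strands.
bf_orf <- function(contig) {
  best <- NULL
  for (strand in c("+", "-")) {
    s <- if (strand == "+") contig else
      transwalker::reverse_complement(contig)
    L <- nchar(s)
    for (a in seq_len(L - 5L)) {
      if (substr(s, a, a + 2L) != "ATG") next
      p <- a + 3L
      while (p + 2L <= L) {
        cod <- substr(s, p, p + 2L)
        if (cod %in% c("TAA", "TAG", "TGA")) {
          len <- p + 2L - a + 1L
          better <- is.null(best) || len > best$len ||
            (len == best$len && strand == "+" && best$strand == "-") ||
            (len == best$len && strand == best$strand && a < best$start)
          if (better) best <- list(start = a, end = p + 2L, len = len,
                                   strand = strand)
          break
        }
        p <- p + 3L
      }
    }
  }
  if (is.null(best)) return(NULL)
  list(start = best$start, end = best$end, strand = best$strand)
}

# Oracle: frame-match criterion by evaluating every ungapped placement of
# the read (one orientation) against the ORF; overhang counts as mismatch.
bf_frame_match_one <- function(read, orf, min_identity, identity_window) {
  L <- nchar(read)
  M <- nchar(orf)
  thr <- if (L >= identity_window) min_identity else
    ceiling(min_identity * L / identity_window)
  rd <- strsplit(read, "")[[1]]
  of <- strsplit(orf, "")[[1]]
  for (d in seq(-(L - 1L), M - 1L)) {
    i <- seq_len(L)
    j <- d + i
    ok <- j >= 1L & j <= M
    if (sum(rd[ok] == of[j[ok]]) >= thr) return(TRUE)
  }
  FALSE
}

bf_frame_match <- function(read, orf, min_identity = 90L,
                           identity_window = 100L) {
  bf_frame_match_one(read, orf, min_identity, identity_window) ||
    bf_frame_match_one(transwalker::reverse_complement(read), orf,
                       min_identity, identity_window)
}
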