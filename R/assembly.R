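#' Walking-assembly parameters
#'
#' Controls the transcriptome walker.  Each appended base is called from up
#' to `column_pool` reads that overlap the growing contig end exactly by at
#' least `min_overlap` nucleotides and extend past it; of those, the
#' `column_top` observations with the highest base quality vote on the
#' consensus.  An alternate base supported by more than `snp_fraction` of
#' the voters is recorded as a SNP, but the canonical (majority) base
#' always defines the contig.
#'
#' @param min_overlap Minimum exact overlap in nucleotides (default 80;
#'   raise towards 95 to separate transcripts sharing common motifs, lower
#'   towards 60 for sparsely covered transcripts).
#' @param column_pool Reads examined per column (default 40).
#' @param column_top Highest-quality reads that vote (default 20).
#' @param snp_fraction Alternate-base fraction above which a SNP is
#'   recorded (default 0.10).
#' @param max_walk_length Safety bound on contig length (default 50000).
#' @param orf_flank Nucleotides of untranslated context retained on each
#'   side of the reading frame in the reported transcript (default 100).
#' @param min_orf_length Shortest open reading frame accepted as a
#'   complete transcript (default 150 nt; chance micro-frames inside reads
#'   are shorter, genuine coding frames longer).
#' @return An object of class `walk_params`.
#' @export
walk_params <- function(min_overlap = 80L, column_pool = 40L,
                        column_top = 20L, snp_fraction = 0.10,
                        max_walk_length = 50000L, orf_flank = 100L,
                        min_orf_length = 150L) {
  min_overlap <- as.integer(min_overlap)
  stopifnot(min_overlap > 0L, column_top <= column_pool,
            snp_fraction > 0, snp_fraction < 1, max_walk_length > 0L,
            orf_flank >= 0L, min_orf_length >= 6L)
  structure(list(min_overlap = min_overlap,
                 column_pool = as.integer(column_pool),
                 column_top = as.integer(column_top),
                 snp_fraction = snp_fraction,
                 max_walk_length = as.integer(max_walk_length),
                 orf_flank = as.integer(orf_flank),
                 min_orf_length = as.integer(min_orf_length)),
            class = "walk_params")
}

#' Build the exact-overlap read index
#'
#' Indexes every read in both orientations (the library is assumed
#' non-stranded) by its first `min_overlap` bases, supporting the walker's
#' query "all reads whose prefix equals a given k-mer".
#'
#' @param reads A read table or `groomed_library`.
#' @param min_overlap Prefix length to index (must equal the walk
#'   `min_overlap`).
#' @return An object of class `overlap_index`.
#' @export
build_overlap_index <- function(reads, min_overlap = 80L) {
  reads <- as_read_table(reads)
  min_overlap <- as.integer(min_overlap)
  keep <- nchar(reads$seq) >= min_overlap
  fwd_seq <- reads$seq[keep]
  fwd_qual <- reads$qual[keep]
  rc_seq <- reverse_complement(fwd_seq)
  rc_qual <- vapply(fwd_qual, function(q) {
    intToUtf8(rev(utf8ToInt(q)))
  }, character(1), USE.NAMES = FALSE)
  seqs <- c(fwd_seq, rc_seq)
  quals <- c(fwd_qual, rc_qual)
  lens <- nchar(seqs)
  meanq <- vapply(quals, function(q) mean(utf8ToInt(q)) - 33, numeric(1),
                  USE.NAMES = FALSE)
  env <- new.env(parent = emptyenv(), size = max(1L, length(seqs)))
  pref <- substr(seqs, 1L, min_overlap)
  idx <- split(seq_along(seqs), pref)
  list2env(idx, envir = env)
  structure(list(env = env, seq = seqs, qual = quals, len = lens,
                 meanq = meanq, min_overlap = min_overlap,
                 n_reads = sum(keep)),
            class = "overlap_index")
}

#' Query the overlap index for reads starting with a k-mer
#'
#' @param index An [build_overlap_index()] object.
#' @param kmer A k-mer of length `min_overlap`.
#' @return Integer indices into the index's (two-orientation) read pool.
#' @export
query_overlap_index <- function(index, kmer) {
  stopifnot(nchar(kmer) == index$min_overlap)
  get0(kmer, envir = index$env, ifnotfound = integer(0))
}

#' Call the consensus base for one walk column
#'
#' Of at most `column_pool` observations (the caller truncates), the
#' `column_top` with the highest base quality vote; the canonical base is
#' the majority among voters, ties broken by higher summed quality and then
#' alphabetically.  If the most frequent alternate base exceeds
#' `snp_fraction` of the voters, a SNP record is emitted alongside.
#'
#' @param bases Character vector of observed bases.
#' @param quals Integer vector of matching Phred scores.
#' @param params A [walk_params()] object.
#' @return A list with `base` and `snp` (a one-row tibble with
#'   `canonical_base`, `alternate_base`, `alternate_fraction`, `n_voters`,
#'   or `NULL`).
#' @export
call_consensus_column <- function(bases, quals, params = walk_params()) {
  n <- length(bases)
  stopifnot(n >= 1L, n == length(quals))
  # highest-quality voters; quality ties keep the caller's (deterministic)
  # longest-overlap-first order so no base is systematically favoured
  ord <- order(-quals)
  take <- ord[seq_len(min(params$column_top, n))]
  vb <- bases[take]
  vq <- quals[take]
  cnt <- tapply(rep.int(1L, length(vb)), vb, sum)
  sq <- tapply(vq, vb, sum)
  u <- names(cnt)
  o <- order(-as.integer(cnt), -as.numeric(sq), u)
  canonical <- u[o[1L]]
  snp <- NULL
  if (length(u) > 1L) {
    alt <- u[o[2L]]
    frac <- as.integer(cnt[alt]) / length(vb)
    if (frac > params$snp_fraction) {
      snp <- tibble(canonical_base = canonical, alternate_base = alt,
                    alternate_fraction = frac, n_voters = length(vb))
    }
  }
  list(base = canonical, snp = snp)
}

# Collect up to column_pool observations of the base one past the contig's
# right end: reads (either orientation) whose prefix matches a contig
# suffix by >= min_overlap and which extend past the end.  Reads are taken
# longest-overlap first, then by descending mean quality, as the pool
# truncation rule.
collect_column_observations <- function(index, contig, params) {
  L <- nchar(contig)
  mo <- index$min_overlap
  max_o <- min(max(index$len) - 1L, L)
  ids <- integer(0)
  obase <- character(0)
  oqual <- integer(0)
  if (max_o < mo) {
    return(list(ids = ids, base = obase, qual = oqual))
  }
  for (o in seq(max_o, mo)) {
    key <- substr(contig, L - o + 1L, L - o + mo)
    cand <- get0(key, envir = index$env, ifnotfound = integer(0))
    if (length(cand) == 0L) next
    cand <- cand[index$len[cand] > o]
    if (o > mo && length(cand) > 0L) {
      tail_ok <- substr(index$seq[cand], mo + 1L, o) ==
        substr(contig, L - o + mo + 1L, L)
      cand <- cand[tail_ok]
    }
    cand <- setdiff(cand, ids)
    if (length(cand) == 0L) next
    cand <- cand[order(-index$meanq[cand])]
    ids <- c(ids, cand)
    obase <- c(obase, substr(index$seq[cand], o + 1L, o + 1L))
    oqual <- c(oqual, utf8ToInt(paste0(substr(index$qual[cand],
                                              o + 1L, o + 1L),
                                       collapse = "")) - 33L)
    if (length(ids) >= params$column_pool) break
  }
  keep <- seq_len(min(length(ids), params$column_pool))
  list(ids = ids[keep], base = obase[keep], qual = oqual[keep])
}

#' Extend a contig by walking consensus columns
#'
#' Repeatedly collects reads overlapping the contig end by at least
#' `min_overlap`, calls the consensus for the next base, and appends it.
#' The walk terminates when no qualifying read remains (`"no_reads"`), when
#' the contig reaches `max_walk_length` (`"max_length"`), when the same
#' end state recurs (`"repeat"`, guarding against walks through repetitive
#' sequence), or after `max_steps` columns (`"max_steps"`).
#'
#' @param contig Starting contig (length at least `min_overlap`).
#' @param direction `"right"` or `"left"`.
#' @param index An [build_overlap_index()] object.
#' @param params A [walk_params()] object.
#' @param max_steps Maximum columns to append in this call.
#' @param visited Optional environment carrying the walk's visited-state
#'   set across chunked calls.
#' @return A list with `contig` (extended), `snps` (tibble with `position`
#'   on the returned contig, 1-based), `steps` and `stop_reason` (`NA` when
#'   stopped by `max_steps` exhaustion with walking still possible).
#' @export
extend_contig <- function(contig, direction = c("right", "left"), index,
                          params = walk_params(), max_steps = Inf,
                          visited = NULL) {
  direction <- match.arg(direction)
  stopifnot(nchar(contig) >= params$min_overlap,
            params$min_overlap == index$min_overlap)
  if (is.null(visited)) visited <- new.env(parent = emptyenv())
  work <- if (direction == "left") reverse_complement(contig) else contig
  snps <- list()
  steps <- 0L
  reason <- NA_character_
  repeat {
    if (steps >= max_steps) break
    L <- nchar(work)
    if (L >= params$max_walk_length) { reason <- "max_length"; break }
    state <- substr(work, L - params$min_overlap + 1L, L)
    if (!is.null(get0(state, envir = visited))) { reason <- "repeat"; break }
    assign(state, TRUE, envir = visited)
    obs <- collect_column_observations(index, work, params)
    if (length(obs$ids) == 0L) { reason <- "no_reads"; break }
    cc <- call_consensus_column(obs$base, obs$qual, params)
    work <- paste0(work, cc$base)
    steps <- steps + 1L
    if (!is.null(cc$snp)) {
      rec <- cc$snp
      rec$position <- L + 1L
      rec$observations <- paste0(obs$base, collapse = "")
      rec$observation_quals <- paste0(intToUtf8(obs$qual + 33L),
                                      collapse = "")
      snps[[length(snps) + 1L]] <- rec
    }
  }
  snp_tbl <- if (length(snps) > 0L) bind_rows(snps) else
    tibble(canonical_base = character(0), alternate_base = character(0),
           alternate_fraction = numeric(0), n_voters = integer(0),
           position = integer(0), observations = character(0),
           observation_quals = character(0))
  if (direction == "left") {
    Lw <- nchar(work)
    out <- reverse_complement(work)
    if (nrow(snp_tbl) > 0L) {
      snp_tbl$position <- Lw - snp_tbl$position + 1L
      snp_tbl$canonical_base <- complement_base(snp_tbl$canonical_base)
      snp_tbl$alternate_base <- complement_base(snp_tbl$alternate_base)
    }
  } else {
    out <- work
  }
  cols <- c("position", "canonical_base", "alternate_base",
            "alternate_fraction", "n_voters", "observations",
            "observation_quals")
  list(contig = out, snps = snp_tbl[, cols], steps = steps,
       stop_reason = reason)
}

complement_base <- function(b) {
  chartr("ACGTN", "TGCAN", b)
}

#' Locate the longest complete open reading frame in a contig
#'
#' Searches both strands for the longest span starting `ATG` and ending at
#' the first in-frame stop codon (`TAA`, `TAG`, `TGA`).  Nested `ATG`s
#' sharing a stop yield the outermost (longest) frame.  Ties are broken in
#' favour of the forward strand, then the smallest start.
#'
#' @param contig A contig sequence (ACGTN).
#' @return A list with 1-based inclusive `start`, `end` (last base of the
#'   stop codon) and `strand` (`"+"` or `"-"`, coordinates on the searched
#'   strand), or `NULL` when no complete frame exists.
#' @export
find_complete_orf <- function(contig) {
  stopifnot(nchar(contig) >= 6L)
  best <- NULL
  for (strand in c("+", "-")) {
    s <- if (strand == "+") contig else reverse_complement(contig)
    cand <- orfs_on_strand(s)
    if (is.null(cand)) next
    if (is.null(best) || cand$len > best$len) {
      best <- c(cand, strand = strand)
    }
  }
  if (is.null(best)) return(NULL)
  list(start = best$start, end = best$end, strand = best$strand)
}

# Longest ATG..stop span on one strand; smallest start on ties.
orfs_on_strand <- function(s) {
  L <- nchar(s)
  best <- NULL
  for (f in 1:3) {
    ncod <- (L - f + 1L) %/% 3L
    if (ncod < 2L) next
    starts <- seq.int(f, by = 3L, length.out = ncod)
    codons <- substring(s, starts, starts + 2L)
    is_stop <- codons %in% c("TAA", "TAG", "TGA")
    is_atg <- codons == "ATG"
    stop_idx <- which(is_stop)
    atg_idx <- which(is_atg)
    if (length(stop_idx) == 0L || length(atg_idx) == 0L) next
    prev_stop <- 0L
    for (si in stop_idx) {
      a <- atg_idx[atg_idx > prev_stop & atg_idx < si]
      if (length(a) > 0L) {
        a0 <- a[1L]
        len <- (si - a0 + 1L) * 3L
        st <- starts[a0]
        if (is.null(best) || len > best$len ||
            (len == best$len && st < best$start)) {
          best <- list(start = st, end = starts[si] + 2L, len = len)
        }
      }
      prev_stop <- si
    }
  }
  best
}

#' Assemble a transcript by transcriptome walking from a seed read
#'
#' Extends the seed in both directions by consensus walking until each
#' direction terminates (no qualifying reads, a repeated end state, or the
#' length bound): walking is always continued so that the complete protein
#' coding sequence, including both START and STOP codons, is recovered
#' rather than the first chance frame encountered.  The contig is then
#' re-oriented so its longest complete reading frame (of at least
#' `min_orf_length` nt) lies on the forward strand, trimmed to the frame
#' plus `orf_flank` nucleotides of context per side, and SNP records are
#' mapped to the final coordinates.
#'
#' @param seed Seed sequence (a groomed read), length at least
#'   `min_overlap`.
#' @param index An [build_overlap_index()] object over the groomed library.
#' @param params A [walk_params()] object.
#' @param id Identifier for the assembled transcript.
#' @return On success, an object of class `transcript`: a list with `id`,
#'   `sequence`, `orf_start`, `orf_end` (1-based inclusive, the stop codon
#'   included), `translation` (stop codon excluded), `snps` and
#'   `stop_reasons`.  On failure, an object of class `walk_failure`
#'   carrying the partial contig.
#' @export
assemble_transcript <- function(seed, index, params = walk_params(),
                                id = "contig_1") {
  if (nchar(seed) < params$min_overlap) {
    stop("seed shorter than min_overlap (", params$min_overlap, " nt)",
         call. = FALSE)
  }
  contig <- seed
  left_total <- 0L
  chunk <- 200L
  visited_r <- new.env(parent = emptyenv())
  visited_l <- new.env(parent = emptyenv())
  right_done <- FALSE
  left_done <- FALSE
  reasons <- c(right = NA_character_, left = NA_character_)
  snps <- list()   # positions in seed-anchored global coordinates
  repeat {
    if (!right_done) {
      ext <- extend_contig(contig, "right", index, params,
                           max_steps = chunk, visited = visited_r)
      contig <- ext$contig
      if (nrow(ext$snps) > 0L) {
        ext$snps$position <- ext$snps$position - left_total
        snps[[length(snps) + 1L]] <- ext$snps
      }
      if (!is.na(ext$stop_reason)) {
        right_done <- TRUE
        reasons["right"] <- ext$stop_reason
      }
    }
    if (!left_done) {
      ext <- extend_contig(contig, "left", index, params,
                           max_steps = chunk, visited = visited_l)
      left_total <- left_total + ext$steps
      contig <- ext$contig
      if (nrow(ext$snps) > 0L) {
        ext$snps$position <- ext$snps$position - left_total
        snps[[length(snps) + 1L]] <- ext$snps
      }
      if (!is.na(ext$stop_reason)) {
        left_done <- TRUE
        reasons["left"] <- ext$stop_reason
      }
    }
    if (right_done && left_done) break
    if (nchar(contig) >= params$max_walk_length) break
  }
  snp_tbl <- if (length(snps) > 0L) bind_rows(snps) else
    tibble(position = integer(0), canonical_base = character(0),
           alternate_base = character(0), alternate_fraction = numeric(0),
           n_voters = integer(0), observations = character(0),
           observation_quals = character(0))
  snp_tbl$position <- snp_tbl$position + left_total
  orf <- if (nchar(contig) >= 6L) find_complete_orf(contig) else NULL
  if (!is.null(orf) && orf$end - orf$start + 1L < params$min_orf_length) {
    orf <- NULL
  }
  if (is.null(orf)) {
    return(structure(list(id = id, contig = contig, snps = snp_tbl,
                          stop_reasons = reasons),
                     class = "walk_failure"))
  }
  if (orf$strand == "-") {
    L <- nchar(contig)
    contig <- reverse_complement(contig)
    if (nrow(snp_tbl) > 0L) {
      snp_tbl$position <- L - snp_tbl$position + 1L
      snp_tbl$canonical_base <- complement_base(snp_tbl$canonical_base)
      snp_tbl$alternate_base <- complement_base(snp_tbl$alternate_base)
      snp_tbl <- snp_tbl[order(snp_tbl$position), , drop = FALSE]
    }
    # ORF coordinates as found on the minus strand are already expressed
    # on the re-oriented (now forward) contig.
  }
  # trim to the reading frame plus orf_flank nucleotides of context
  from <- max(1L, orf$start - params$orf_flank)
  to <- min(nchar(contig), orf$end + params$orf_flank)
  contig <- substr(contig, from, to)
  orf$start <- orf$start - from + 1L
  orf$end <- orf$end - from + 1L
  if (nrow(snp_tbl) > 0L) {
    snp_tbl <- snp_tbl[snp_tbl$position >= from & snp_tbl$position <= to, ,
                       drop = FALSE]
    snp_tbl$position <- snp_tbl$position - from + 1L
  }
  orf_seq <- substr(contig, orf$start, orf$end)
  translation <- translate_frame(substr(orf_seq, 1L, nchar(orf_seq) - 3L), 1L)
  structure(list(id = id, sequence = contig, orf_start = orf$start,
                 orf_end = orf$end, translation = translation,
                 snps = snp_tbl, stop_reasons = reasons),
            class = "transcript")
}

#' @export
print.transcript <- function(x, ...) {
  cat(sprintf(
    "transcript %s: %d nt contig, ORF %d..%d (%d nt, %d aa), %d SNP(s)\n",
    x$id, nchar(x$sequence), x$orf_start, x$orf_end,
    x$orf_end - x$orf_start + 1L, nchar(x$translation), nrow(x$snps)))
  invisible(x)
}

#' @export
print.walk_failure <- function(x, ...) {
  cat(sprintf(
    "walk failure %s: no complete reading frame in %d nt contig (stops: right=%s, left=%s)\n",
    x$id, nchar(x$contig), x$stop_reasons["right"], x$stop_reasons["left"]))
  invisible(x)
}

#' Extract the open-reading-frame sequence of a transcript
#'
#' @param transcript A `transcript` object.
#' @return The ORF nucleotide sequence including START and STOP codons.
#' @export
orf_sequence <- function(transcript) {
  substr(transcript$sequence, transcript$orf_start, transcript$orf_end)
}
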