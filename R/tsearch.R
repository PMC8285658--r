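#' Fetch a BLOSUM scoring matrix
#'
#' Returns one of the standard BLOSUM substitution matrices, modified so
#' that any pair involving a stop symbol (`*`) scores the matrix minimum:
#' translated read windows running through a stop codon are thereby
#' penalised maximally rather than rewarded for stop-stop agreement.
#'
#' @param name One of `"BLOSUM45"`, `"BLOSUM50"`, `"BLOSUM62"`,
#'   `"BLOSUM80"`, `"BLOSUM100"`.
#' @return A numeric scoring matrix with amino-acid letter dimnames.
#' @export
blosum_matrix <- function(name = "BLOSUM62") {
  choices <- c("BLOSUM45", "BLOSUM50", "BLOSUM62", "BLOSUM80", "BLOSUM100")
  name <- match.arg(name, choices)
  env <- new.env()
  utils::data(list = name, package = "Biostrings", envir = env)
  m <- env[[name]]
  if ("*" %in% rownames(m)) {
    m["*", ] <- min(m)
    m[, "*"] <- min(m)
  }
  m
}

#' Best ungapped local window score between a peptide and a protein query
#'
#' Maximum-scoring ungapped local segment under a BLOSUM matrix, computed
#' by the standard running-sum-reset-at-zero recurrence along every
#' alignment diagonal.  A peptide identical to a query segment scores the
#' sum of the diagonal matrix entries of its residues; when every pair
#' score is negative the optimum is the empty segment with score 0.
#'
#' @param peptide A peptide string (may contain `*` from translated stop
#'   codons and `X` for ambiguous codons).
#' @param query A query protein string (20 amino-acid letters plus `X`).
#' @param matrix Matrix name passed to [blosum_matrix()], or a scoring
#'   matrix.
#' @return A list with elements `score`, `query_offset`, `peptide_offset`
#'   (1-based starts of the optimal segment; 0 when the segment is empty)
#'   and `length`.
#' @export
best_window_score <- function(peptide, query, matrix = "BLOSUM62") {
  m <- if (is.character(matrix)) blosum_matrix(matrix) else matrix
  p <- strsplit(peptide, "", fixed = TRUE)[[1]]
  q <- strsplit(query, "", fixed = TRUE)[[1]]
  np <- length(p)
  nq <- length(q)
  empty <- list(score = 0, query_offset = 0L, peptide_offset = 0L,
                length = 0L)
  if (np == 0L || nq == 0L) return(empty)
  pi_ <- match(p, rownames(m))
  qi <- match(q, colnames(m))
  if (anyNA(pi_)) stop("unknown residue '", p[which(is.na(pi_))[1]],
                       "' in peptide", call. = FALSE)
  if (anyNA(qi)) stop("unknown residue '", q[which(is.na(qi))[1]],
                      "' in query", call. = FALSE)
  best <- empty
  for (d in seq(-(np - 1L), nq - 1L)) {
    i0 <- max(1L, 1L - d)            # peptide start on this diagonal
    j0 <- i0 + d                     # query start
    len <- min(np - i0, nq - j0) + 1L
    if (len <= 0L) next
    s <- m[cbind(pi_[i0:(i0 + len - 1L)], qi[j0:(j0 + len - 1L)])]
    cs <- cumsum(s)
    prev <- cummin(c(0, cs[-len]))   # best (lowest) prefix before each end
    gain <- cs - prev
    k <- which.max(gain)
    if (gain[k] > best$score) {
      # segment start = position just after the prefix minimum
      st <- which(c(0, cs[-len])[seq_len(k)] == prev[k])[1L]
      best <- list(score = unname(gain[k]),
                   query_offset = j0 + st - 1L,
                   peptide_offset = i0 + st - 1L,
                   length = k - st + 1L)
    }
  }
  best
}

#' Screen a read library against protein queries by translated BLOSUM search
#'
#' Translates every read in all six frames and reports each (read, frame,
#' query) triple whose best ungapped window score reaches `min_score`.
#' The searches are intended to run at relatively low stringency so that
#' distant homologues seed the assembler; unrelated reads passing the
#' screen are expected and are winnowed later by assembly and
#' identification.
#'
#' @param reads A read table or `groomed_library`.
#' @param queries A protein query table with columns `id` and `residues`
#'   (see [read_fasta()]).
#' @param matrix BLOSUM matrix name (default `"BLOSUM62"`).
#' @param min_score Minimum raw window score (default 40, roughly 8-10
#'   identical residues under BLOSUM62).
#' @return A tibble of hits: `read_id`, `frame` (one of `+1,+2,+3,-1,-2,-3`),
#'   `query_id`, `score`, `query_offset`, `read_offset` (residues, 1-based),
#'   `width`.
#' @export
screen_library <- function(reads, queries, matrix = "BLOSUM62",
                           min_score = 40L) {
  reads <- as_read_table(reads)
  m <- blosum_matrix(matrix)
  hits <- vector("list", 64L)
  nh <- 0L
  for (i in seq_len(nrow(reads))) {
    if (nchar(reads$seq[i]) < 3L) next
    frames <- six_frame_translations(reads$seq[i])
    for (f in names(frames)) {
      if (nchar(frames[[f]]) == 0L) next
      for (j in seq_len(nrow(queries))) {
        w <- best_window_score(frames[[f]], queries$residues[j], m)
        if (w$score >= min_score) {
          nh <- nh + 1L
          if (nh > length(hits)) hits <- c(hits, vector("list", length(hits)))
          hits[[nh]] <- tibble(
            read_id = reads$id[i], frame = f, query_id = queries$id[j],
            score = w$score, query_offset = w$query_offset,
            read_offset = w$peptide_offset, width = w$length
          )
        }
      }
    }
  }
  if (nh == 0L) {
    return(tibble(read_id = character(0), frame = character(0),
                  query_id = character(0), score = numeric(0),
                  query_offset = integer(0), read_offset = integer(0),
                  width = integer(0)))
  }
  bind_rows(hits[seq_len(nh)])
}
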