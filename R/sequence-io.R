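#' Read a 4-line FASTQ file into a read table
#'
#' Parses Phred+33 FASTQ into the flat read table used throughout the
#' package: one row per read with its identifier, mate number, sequence and
#' quality string.  Only the bases `A`, `C`, `G`, `T`, `N` are accepted;
#' anything else is rejected rather than silently converted, because the
#' identical-read census downstream relies on exact string identity.
#'
#' @param path Path to a FASTQ file (optionally gzip-compressed).
#' @param mate Mate number to record for every read: `1L`, `2L`, or `0L`
#'   for unpaired (the default).
#' @return A tibble with columns `id` (character), `mate` (integer),
#'   `seq` (character, uppercase ACGTN) and `qual` (character, Phred+33
#'   encoded, same width as `seq`).
#' @seealso [write_fastq()], [phred_scores()]
#' @export
read_fastq <- function(path, mate = 0L) {
  stopifnot(file.exists(path))
  x <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE),
    error = function(e) {
      stop("malformed FASTQ in '", path, "': ", conditionMessage(e),
           call. = FALSE)
    }
  )
  seqs <- toupper(as.character(x))
  quals <- as.character(S4Vectors::mcols(x)$qualities)
  bad <- grep("[^ACGTN]", seqs)
  if (length(bad) > 0L) {
    stop("invalid base character in record ", bad[1L], " ('",
         names(x)[bad[1L]], "') of '", path, "'", call. = FALSE)
  }
  mism <- which(nchar(seqs) != nchar(quals))
  if (length(mism) > 0L) {
    stop("sequence/quality length mismatch in record ", mism[1L], " ('",
         names(x)[mism[1L]], "') of '", path, "'", call. = FALSE)
  }
  tibble(
    id = as.character(names(x)),
    mate = rep(as.integer(mate), length(x)),
    seq = unname(seqs),
    qual = unname(quals)
  )
}

#' Write a read table to 4-line Phred+33 FASTQ
#'
#' @param reads A read table as returned by [read_fastq()] or
#'   [simulate_reads()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  reads <- as_read_table(reads)
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$id
  Biostrings::writeXStringSet(
    x, path, format = "fastq",
    qualities = Biostrings::BStringSet(reads$qual)
  )
  invisible(path)
}

#' Read a nucleotide or protein FASTA file
#'
#' @param path Path to a FASTA file.
#' @param type `"dna"` or `"protein"`.
#' @return A tibble with columns `id` and `seq` (for `"dna"`) or `id` and
#'   `residues` (for `"protein"`).  Protein records must be non-empty and
#'   must not contain an internal stop (`*`) symbol.
#' @export
read_fasta <- function(path, type = c("dna", "protein")) {
  type <- match.arg(type)
  if (type == "dna") {
    x <- Biostrings::readDNAStringSet(path)
    return(tibble(id = as.character(names(x)),
                  seq = unname(toupper(as.character(x)))))
  }
  x <- Biostrings::readAAStringSet(path)
  res <- unname(toupper(as.character(x)))
  if (any(nchar(res) == 0L)) {
    stop("empty protein record in '", path, "'", call. = FALSE)
  }
  if (any(grepl("\\*", res))) {
    stop("stop symbol '*' inside protein record in '", path, "'",
         call. = FALSE)
  }
  tibble(id = as.character(names(x)), residues = res)
}

#' Write sequences to FASTA
#'
#' @param ids Character vector of record names.
#' @param seqs Character vector of sequences (DNA or protein).
#' @param path Output path.
#' @param type `"dna"` or `"protein"`.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(ids, seqs, path, type = c("dna", "protein")) {
  type <- match.arg(type)
  x <- if (type == "dna") Biostrings::DNAStringSet(seqs)
       else Biostrings::AAStringSet(seqs)
  names(x) <- ids
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Reverse complement of ACGTN sequences
#'
#' Standard Watson-Crick complement, reversed; `N` maps to `N`.  Vectorised.
#'
#' @param x Character vector of sequences over `{A,C,G,T,N}`.
#' @return Character vector of reverse complements.
#' @export
reverse_complement <- function(x) {
  if (length(x) == 0L) return(character(0))
  bad <- grep("[^ACGTN]", x)
  if (length(bad) > 0L) {
    stop("invalid base character in sequence ", bad[1L], call. = FALSE)
  }
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Six-frame translation of a nucleotide sequence
#'
#' Translates frames +1, +2, +3 of the sequence and +1, +2, +3 of its
#' reverse complement under the standard genetic code.  Stop codons are
#' rendered as `*`, any codon containing `N` as `X`, and a trailing partial
#' codon is dropped.
#'
#' @param x A single sequence over `{A,C,G,T,N}`, length at least 3.
#' @return A character vector of 6 peptides named
#'   `"+1","+2","+3","-1","-2","-3"`.
#' @export
six_frame_translations <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  if (nchar(x) < 3L) {
    stop("sequence shorter than 3 nt cannot be translated", call. = FALSE)
  }
  fwd <- vapply(1:3, function(f) translate_frame(x, f), character(1))
  rc <- reverse_complement(x)
  rev <- vapply(1:3, function(f) translate_frame(rc, f), character(1))
  setNames(c(fwd, rev), c("+1", "+2", "+3", "-1", "-2", "-3"))
}

# Translate one forward frame (offset 1..3), dropping the partial codon.
translate_frame <- function(x, frame) {
  n <- nchar(x) - frame + 1L
  n <- (n %/% 3L) * 3L
  if (n < 3L) return("")
  s <- substr(x, frame, frame + n - 1L)
  as.character(Biostrings::translate(Biostrings::DNAString(s),
                                     if.fuzzy.codon = "X"))
}

#' Decode a Phred+33 quality string to integer scores
#'
#' @param qual A single Phred+33 quality string.
#' @return Integer vector of Phred scores (ASCII minus 33).
#' @export
phred_scores <- function(qual) {
  if (nchar(qual) == 0L) return(integer(0))
  utf8ToInt(qual) - 33L
}

#' Encode integer Phred scores as a Phred+33 string
#'
#' @param scores Integer vector of Phred scores in `[0, 60]`.
#' @return A single quality string.
#' @export
phred_string <- function(scores) {
  stopifnot(all(scores >= 0L), all(scores <= 60L))
  if (length(scores) == 0L) return("")
  intToUtf8(as.integer(scores) + 33L)
}

# Accept either a plain read tibble or a groomed_library and return the
# underlying read tibble.
as_read_table <- function(x) {
  if (inherits(x, "groomed_library")) return(x$reads)
  stopifnot(is.data.frame(x), all(c("id", "seq", "qual") %in% names(x)))
  x
}
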