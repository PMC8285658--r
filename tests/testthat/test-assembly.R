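# Build a transcript with a real reading frame: utr5 + ATG + codons + stop.
make_tx <- function(n_codons = 120L, utr5 = 100L, utr3 = 100L) {
  codons <- sample(setdiff(
    as.vector(outer(outer(c("A","C","G","T"), c("A","C","G","T"), paste0),
                    c("A","C","G","T"), paste0)),
    c("TAA", "TAG", "TGA")), n_codons, TRUE)
  orf <- paste0("ATG", paste0(codons, collapse = ""), "TAA")
  list(seq = paste0(rand_dna(utr5), orf, rand_dna(utr3)),
       orf_start = utr5 + 1L, orf_end = utr5 + nchar(orf))
}

test_that("overlap index answers prefix queries exactly", {
  # empty set
  idx <- build_overlap_index(make_read_table(character(0)), 80L)
  expect_length(query_overlap_index(idx, strrep("A", 80)), 0L)

  # single read: its own 80-mer prefix retrieves it
  set.seed(3)
  r <- rand_dna(100)
  idx <- build_overlap_index(make_read_table(r), 80L)
  expect_equal(idx$seq[query_overlap_index(idx, substr(r, 1, 80))], r)

  # random set vs brute-force scan over both orientations
  seqs <- replicate(60, rand_dna(100))
  idx <- build_overlap_index(make_read_table(seqs), 80L)
  pool <- c(seqs, reverse_complement(seqs))
  for (i in 1:10) {
    src <- sample(pool, 1)
    off <- sample(1:21, 1)
    k <- substr(src, off, off + 79L)
    got <- sort(idx$seq[query_overlap_index(idx, k)])
    want <- sort(pool[substr(pool, 1, 80) == k])
    expect_equal(got, want)
  }
})

test_that("consensus columns follow the 40/20 vote and the >10% SNP rule", {
  p <- walk_params()

  cc <- call_consensus_column(rep("A", 20), rep(40L, 20), p)
  expect_equal(cc$base, "A")
  expect_null(cc$snp)

  # 17 A + 3 G at equal quality: canonical A, SNP G at 0.15
  cc <- call_consensus_column(c(rep("A", 17), rep("G", 3)), rep(40L, 20), p)
  expect_equal(cc$base, "A")
  expect_equal(cc$snp$alternate_base, "G")
  expect_equal(cc$snp$alternate_fraction, 0.15)

  # 2 C + 2 T, equal summed quality: alphabetic tie-break, SNP T at 0.5
  cc <- call_consensus_column(c("C", "T", "C", "T"), rep(40L, 4), p)
  expect_equal(cc$base, "C")
  expect_equal(cc$snp$alternate_base, "T")
  expect_equal(cc$snp$alternate_fraction, 0.5)

  # only the top-quality reads vote: 20 high-quality A beat 20 low-quality G
  cc <- call_consensus_column(c(rep("G", 20), rep("A", 20)),
                              c(rep(10L, 20), rep(40L, 20)), p)
  expect_equal(cc$base, "A")
  expect_null(cc$snp)

  # a 10% alternate exactly at the threshold is NOT a SNP (strict >)
  cc <- call_consensus_column(c(rep("A", 18), rep("G", 2)), rep(40L, 20), p)
  expect_null(cc$snp)
})

test_that("walking reconstructs a clean tiled transcript exactly", {
  set.seed(97)
  tx <- make_tx(150L)   # 456-nt frame in a ~656-nt transcript
  reads <- tile_reads(tx$seq, 100L, 3L)
  idx <- build_overlap_index(reads, 80L)
  seed <- substr(tx$seq, 201, 300)
  tr <- assemble_transcript(seed, idx, walk_params())
  expect_s3_class(tr, "transcript")
  expect_equal(orf_sequence(tr),
               substr(tx$seq, tx$orf_start, tx$orf_end))
  expect_true(grepl(tr$sequence, tx$seq, fixed = TRUE))
  expect_equal(nrow(tr$snps), 0L)
  # transcript invariants
  expect_equal((tr$orf_end - tr$orf_start + 1L) %% 3L, 0L)
  expect_equal(substr(tr$sequence, tr$orf_start, tr$orf_start + 2L), "ATG")
  expect_true(substr(tr$sequence, tr$orf_end - 2L, tr$orf_end) %in%
                c("TAA", "TAG", "TGA"))
  expect_equal(nchar(tr$translation),
               (tr$orf_end - tr$orf_start + 1L) / 3L - 1L)

  # determinism: identical inputs give identical output
  tr2 <- assemble_transcript(seed, idx, walk_params())
  expect_identical(tr$sequence, tr2$sequence)

  # orientation invariance: reverse-complementing every read changes nothing
  idx_rc <- build_overlap_index(
    make_read_table(reverse_complement(reads$seq), ids = reads$id), 80L)
  tr3 <- assemble_transcript(seed, idx_rc, walk_params())
  expect_identical(tr$sequence, tr3$sequence)
})

test_that("walks stop at coverage gaps and fail without overlaps", {
  set.seed(13)
  tx <- rand_dna(600)
  left <- tile_reads(substr(tx, 1, 300), 100L, 2L)
  right <- tile_reads(substr(tx, 350, 600), 100L, 2L)
  idx <- build_overlap_index(dplyr::bind_rows(left, right), 80L)
  ext <- extend_contig(substr(tx, 101, 200), "right", idx, walk_params())
  expect_equal(ext$stop_reason, "no_reads")
  # cannot walk past the gap at position 300
  expect_lte(100L + ext$steps, 300L)

  # a seed with no overlapping reads at all fails with the seed as contig
  seed <- rand_dna(100)
  idx0 <- build_overlap_index(make_read_table(rand_dna(100)), 80L)
  res <- assemble_transcript(seed, idx0, walk_params())
  expect_s3_class(res, "walk_failure")
  expect_equal(res$contig, seed)

  # short seeds are rejected up front
  expect_error(assemble_transcript(rand_dna(40), idx0, walk_params()),
               "min_overlap")
})

test_that("a planted 20% variant yields the majority base plus a SNP record", {
  set.seed(29)
  tx <- make_tx(120L)
  p <- 250L                      # inside the frame
  starts <- seq(1L, nchar(tx$seq) - 99L, by = 1L)
  fwd <- substring(tx$seq, starts, starts + 99L)
  covers <- which(starts <= p & starts + 99L >= p)
  carrier <- covers[seq_along(covers) %% 5 == 0]   # 20% of covering reads
  true_base <- substr(tx$seq, p, p)
  alt_base <- setdiff(c("A", "C", "G", "T"), true_base)[1]
  for (i in carrier) {
    pos <- p - starts[i] + 1L
    substr(fwd[i], pos, pos) <- alt_base
  }
  reads <- make_read_table(c(fwd, reverse_complement(fwd)))
  idx <- build_overlap_index(reads, 80L)
  tr <- assemble_transcript(substr(tx$seq, 1, 100), idx, walk_params())
  expect_s3_class(tr, "transcript")
  expect_equal(orf_sequence(tr), substr(tx$seq, tx$orf_start, tx$orf_end))
  # the SNP is recorded at the planted column with the planted alternate
  off <- regexpr(substr(tr$sequence, 1, 80), tx$seq, fixed = TRUE)[1]
  snp_global <- tr$snps$position + off - 1L
  expect_true(p %in% snp_global)
  rec <- tr$snps[snp_global == p, ]
  expect_equal(rec$canonical_base, true_base)
  expect_equal(rec$alternate_base, alt_base)
  expect_gt(rec$alternate_fraction, 0.10)
})

test_that("an 80-nt minimum overlap does not cross a shared 70-nt motif", {
  set.seed(41)
  motif <- rand_dna(70)
  txA <- paste0(rand_dna(250), motif, rand_dna(250))
  txB <- paste0(rand_dna(250), motif, rand_dna(250))
  reads <- dplyr::bind_rows(tile_reads(txA, 100L, 2L),
                            tile_reads(txB, 100L, 2L))
  idx <- build_overlap_index(reads, 80L)
  ext <- extend_contig(substr(txA, 101, 200), "right", idx, walk_params())
  expect_true(grepl(ext$contig, txA, fixed = TRUE))
  expect_false(grepl(substr(txB, 321, 420), ext$contig, fixed = TRUE))
})

test_that("reading-frame finding equals brute-force enumeration", {
  # minimal frame
  orf <- find_complete_orf("ATGAAATAG")
  expect_equal(orf, list(start = 1L, end = 9L, strand = "+"))

  # nested ATGs sharing a stop: outermost chosen
  s <- paste0("CC", "ATGATGAAATAA", "CC")
  orf <- find_complete_orf(s)
  expect_equal(substr(s, orf$start, orf$start + 2), "ATG")
  expect_equal(orf$start, 3L)
  expect_equal(orf$end, 14L)

  set.seed(53)
  for (i in 1:40) {
    ctg <- rand_dna(sample(60:240, 1))
    got <- find_complete_orf(ctg)
    want <- bf_orf(ctg)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got, want)
    }
  }
})
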