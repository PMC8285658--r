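make_orf <- function(n_codons = 100L) {
  codons <- sample(setdiff(
    as.vector(outer(outer(c("A","C","G","T"), c("A","C","G","T"), paste0),
                    c("A","C","G","T"), paste0)),
    c("TAA", "TAG", "TGA")), n_codons, TRUE)
  paste0("ATG", paste0(codons, collapse = ""), "TAA")
}

test_that("the 90/100 identity criterion is applied exactly", {
  set.seed(19)
  orf <- make_orf(120L)
  p <- quant_params()

  # an exact 100-nt frame substring matches
  read <- substr(orf, 51, 150)
  expect_true(read_matches_frame(read, orf, p))
  # and so does its reverse complement
  expect_true(read_matches_frame(reverse_complement(read), orf, p))

  # 10 substitutions (90 identical) still matches; 11 (89) does not
  mutate_at <- function(s, k) {
    pos <- sample(nchar(s), k)
    ch <- strsplit(s, "")[[1]]
    for (q in pos) ch[q] <- setdiff(c("A","C","G","T"), ch[q])[1]
    paste0(ch, collapse = "")
  }
  expect_true(read_matches_frame(mutate_at(read, 10L), orf, p))
  expect_false(read_matches_frame(mutate_at(read, 11L), orf, p))

  # overhanging placements count overhang as mismatch: a read overlapping
  # the frame start by 90 exact bases matches, by 89 does not
  expect_true(read_matches_frame(paste0(rand_dna(10), substr(orf, 1, 90)),
                                 orf, p))
  expect_false(read_matches_frame(paste0(rand_dna(11), substr(orf, 1, 89)),
                                  orf, p))
})

test_that("frame matching agrees with brute force over random placements", {
  set.seed(83)
  orf <- make_orf(60L)
  p <- quant_params()
  cases <- character(0)
  # near-matches, random junk, rc placements, trimmed reads
  for (i in 1:25) {
    kind <- i %% 5
    s <- if (kind == 0) rand_dna(100)
    else {
      st <- sample(nchar(orf) - 99L, 1)
      r <- substr(orf, st, st + 99L)
      ch <- strsplit(r, "")[[1]]
      k <- sample(0:14, 1)
      for (q in sample(100, k)) ch[q] <- sample(c("A","C","G","T"), 1)
      r <- paste0(ch, collapse = "")
      if (kind == 2) r <- reverse_complement(r)
      if (kind == 3) r <- substr(r, 1, 85)   # groomed shorter than 100
      r
    }
    cases <- c(cases, s)
  }
  got <- read_matches_frame(cases, orf, p)
  want <- vapply(cases, bf_frame_match, logical(1), orf = orf,
                 min_identity = p$min_identity,
                 identity_window = p$identity_window,
                 USE.NAMES = FALSE)
  expect_equal(got, want)
})

test_that("quantification normalises exactly to the reference", {
  set.seed(59)
  ref <- make_orf(80L)
  other <- make_orf(80L)
  orfs <- c(REF = ref, OTH = other)
  p <- quant_params(reference_id = "REF")

  # library drawn 100% from the reference: reference at 0, other at -Inf
  starts <- sample(nchar(ref) - 99L, 300, TRUE)
  lib <- make_read_table(substring(ref, starts, starts + 99L))
  expect_warning(q <- quantify_library(orfs, lib, p), "zero matching")
  expect_identical(q$log10_relative[q$transcript_id == "REF"], 0)
  expect_identical(q$log10_relative[q$transcript_id == "OTH"], -Inf)

  # a transcript planted at 10x the reference read density with equal
  # frame length sits at log10_relative ~ 1
  starts10 <- sample(nchar(other) - 99L, 3000, TRUE)
  lib2 <- make_read_table(c(substring(ref, starts, starts + 99L),
                            substring(other, starts10, starts10 + 99L)))
  q <- quantify_library(orfs, lib2, p)
  expect_identical(q$log10_relative[q$transcript_id == "REF"], 0)
  expect_lt(abs(q$log10_relative[q$transcript_id == "OTH"] - 1), 0.05)

  # scale invariance: doubling every read leaves log10_relative unchanged
  q2 <- quantify_library(orfs, dplyr::bind_rows(lib2, lib2), p)
  expect_equal(q2$log10_relative, q$log10_relative)

  # reference absent or unmatched -> error
  expect_error(quantify_library(orfs, lib2,
                                quant_params(reference_id = "NOPE")),
               "absent")
  junk <- make_read_table(replicate(20, rand_dna(100)))
  expect_error(suppressWarnings(quantify_library(orfs, junk, p)),
               "zero matching reads; normalisation undefined")
})

test_that("estimated log ratios converge to the planted value with coverage", {
  set.seed(67)
  ref <- make_orf(90L)
  oth <- make_orf(90L)
  orfs <- c(REF = ref, OTH = oth)
  p <- quant_params(reference_id = "REF")
  err <- vapply(c(200L, 800L, 3200L), function(n) {
    s1 <- sample(nchar(ref) - 99L, n, TRUE)
    s2 <- sample(nchar(oth) - 99L, 2L * n, TRUE)
    lib <- make_read_table(c(substring(ref, s1, s1 + 99L),
                             substring(oth, s2, s2 + 99L)))
    q <- quantify_library(orfs, lib, p)
    abs(q$log10_relative[q$transcript_id == "OTH"] - log10(2))
  }, numeric(1))
  expect_lt(err[3], 0.05)
  expect_lt(err[3], err[1] + 0.02)  # tighter at higher coverage
})
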