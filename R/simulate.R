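#' Simulation configuration
#'
#' Defines the synthetic study the generator emulates: a set of transcripts
#' each carrying one complete open reading frame flanked by untranslated
#' regions, per-transcript abundances spanning several log units, a
#' heavy-tailed (truncated Cauchy, median near 1) law for between-condition
#' abundance ratios with a small set of planted outliers, and two libraries
#' of 100-nt paired reads with per-base substitution errors and Phred
#' qualities.
#'
#' Defaults describe the desk-scale study conditions used throughout the
#' package's tests; the methods vignette records why each value was
#' chosen.
#'
#' @param n_transcripts Number of transcripts (default 50); transcript 1 is
#'   the reference with ratio exactly 1.
#' @param orf_length_range ORF length range in nt, multiples of 3 including
#'   START and STOP codons (default 300-900).
#' @param utr_length_range UTR length range in nt on each side (default
#'   50-150).
#' @param log10_abundance_range Range of control log10 abundance relative
#'   to the reference (default -1.5 to 0; the reference sits at 0).
#' @param x0_true,gamma_true Location and scale of the null ratio law.
#' @param ratio_trunc Truncation bounds of the null law (kept positive and
#'   bounded, default `c(0.45, 1.55)`).
#' @param outlier_ratios_up,outlier_ratios_down Planted outlier ratios;
#'   must lie outside `ratio_trunc`.
#' @param read_length Read length in nt (default 100).
#' @param fragment_length Paired-end fragment length in nt (default 250,
#'   clamped to the transcript).
#' @param coverage Mean read pairs per transcript per unit relative
#'   abundance (Poisson).
#' @param error_rate Per-base substitution probability (default 0.005).
#' @param quality_correct,quality_error Phred score assigned to correct and
#'   erroneous base calls (defaults 40 and 22).
#' @param seed Integer seed making every generator step deterministic.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_transcripts = 50L,
                       orf_length_range = c(300L, 900L),
                       utr_length_range = c(50L, 150L),
                       log10_abundance_range = c(-1.5, 0),
                       x0_true = 1.0, gamma_true = 0.08,
                       ratio_trunc = c(0.45, 1.55),
                       outlier_ratios_up = c(2.2, 3.0),
                       outlier_ratios_down = c(0.07, 0.10, 0.30),
                       read_length = 100L, fragment_length = 250L,
                       coverage = 200, error_rate = 0.005,
                       quality_correct = 40L, quality_error = 22L,
                       seed = 1L) {
  stopifnot(n_transcripts >= 1L,
            orf_length_range[1L] %% 3L == 0L,
            orf_length_range[2L] %% 3L == 0L,
            orf_length_range[1L] >= 9L,
            diff(orf_length_range) >= 0,
            utr_length_range[1L] >= 0L,
            ratio_trunc[1L] > 0, ratio_trunc[1L] < ratio_trunc[2L],
            all(outlier_ratios_up > ratio_trunc[2L] |
                  length(outlier_ratios_up) == 0L),
            all(outlier_ratios_down < ratio_trunc[1L] |
                  length(outlier_ratios_down) == 0L),
            all(outlier_ratios_down > 0),
            read_length >= 1L, fragment_length >= read_length,
            coverage > 0, error_rate >= 0, error_rate < 1,
            quality_correct >= 0L, quality_correct <= 60L,
            quality_error >= 0L, quality_error <= 60L)
  structure(list(n_transcripts = as.integer(n_transcripts),
                 orf_length_range = as.integer(orf_length_range),
                 utr_length_range = as.integer(utr_length_range),
                 log10_abundance_range = log10_abundance_range,
                 x0_true = x0_true, gamma_true = gamma_true,
                 ratio_trunc = ratio_trunc,
                 outlier_ratios_up = outlier_ratios_up,
                 outlier_ratios_down = outlier_ratios_down,
                 read_length = as.integer(read_length),
                 fragment_length = as.integer(fragment_length),
                 coverage = coverage, error_rate = error_rate,
                 quality_correct = as.integer(quality_correct),
                 quality_error = as.integer(quality_error),
                 seed = as.integer(seed)),
            class = "sim_config")
}

NON_STOP_CODONS <- {
  b <- c("A", "C", "G", "T")
  all_codons <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all_codons, c("TAA", "TAG", "TGA"))
}

random_dna <- function(n) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# One transcript: UTR + ATG + stop-free codons + stop + UTR.
random_transcript <- function(config) {
  orf_len <- sample(seq(config$orf_length_range[1L],
                        config$orf_length_range[2L], by = 3L), 1L)
  utr5 <- sample(config$utr_length_range[1L]:config$utr_length_range[2L], 1L)
  utr3 <- sample(config$utr_length_range[1L]:config$utr_length_range[2L], 1L)
  n_codons <- orf_len / 3L - 2L
  orf <- paste0("ATG",
                paste0(sample(NON_STOP_CODONS, n_codons, replace = TRUE),
                       collapse = ""),
                sample(c("TAA", "TAG", "TGA"), 1L))
  list(sequence = paste0(random_dna(utr5), orf, random_dna(utr3)),
       orf_start = utr5 + 1L, orf_end = utr5 + orf_len)
}

transcript_kmers <- function(seq, k) {
  L <- nchar(seq)
  if (L < k) return(character(0))
  starts <- seq_len(L - k + 1L)
  substring(seq, starts, starts + k - 1L)
}

#' Generate a synthetic transcriptome
#'
#' Each transcript is a random UTR + `ATG` + random stop-free codons + stop
#' codon + random UTR.  Transcripts are rejection-sampled so that (a) the
#' designed reading frame is the longest complete frame of the transcript
#' on either strand (so assembly and the generator agree on ground truth)
#' and (b) no two transcripts share an exact 80-mer in either orientation
#' (unless `allow_shared_kmers` requests a repeat fixture).  Deterministic
#' under the config seed.
#'
#' @param config A [sim_config()] object.
#' @param allow_shared_kmers Skip the shared-80-mer rejection (default
#'   `FALSE`).
#' @return A tibble with columns `id`, `sequence`, `orf_start`, `orf_end`,
#'   `is_reference`.
#' @export
generate_transcriptome <- function(config, allow_shared_kmers = FALSE) {
  withr::with_seed(config$seed, {
    seen <- new.env(parent = emptyenv())
    out <- vector("list", config$n_transcripts)
    for (i in seq_len(config$n_transcripts)) {
      for (attempt in 1:200) {
        tx <- random_transcript(config)
        orf <- find_complete_orf(tx$sequence)
        ok <- !is.null(orf) && orf$strand == "+" &&
          orf$start == tx$orf_start && orf$end == tx$orf_end
        if (ok && !allow_shared_kmers) {
          km <- c(transcript_kmers(tx$sequence, 80L),
                  transcript_kmers(reverse_complement(tx$sequence), 80L))
          if (any(vapply(km, function(k) !is.null(get0(k, envir = seen)),
                         logical(1)))) {
            ok <- FALSE
          } else {
            for (k in km) assign(k, TRUE, envir = seen)
          }
        }
        if (ok) break
      }
      if (!ok) stop("could not generate transcript ", i,
                    " under the configured constraints", call. = FALSE)
      out[[i]] <- tibble(id = sprintf("TX_%03d", i),
                         sequence = tx$sequence,
                         orf_start = tx$orf_start, orf_end = tx$orf_end)
    }
    res <- bind_rows(out)
    res$is_reference <- seq_len(nrow(res)) == 1L
    res
  })
}

# Draw from the truncated Cauchy null ratio law by rejection.
draw_null_ratios <- function(n, config) {
  out <- numeric(0)
  while (length(out) < n) {
    u <- runif(2L * n + 16L)
    x <- config$x0_true + config$gamma_true * tan(pi * (u - 0.5))
    x <- x[x >= config$ratio_trunc[1L] & x <= config$ratio_trunc[2L]]
    out <- c(out, x)
  }
  out[seq_len(n)]
}

#' Assign ground-truth abundances and between-condition ratios
#'
#' Control log10 abundances are uniform over the configured range (the
#' reference transcript sits at 0); the noise-condition abundance is
#' `control + log10(r)` with `r` drawn from the truncated Cauchy null law,
#' except for planted outliers, which receive the configured ratios.  The
#' reference keeps ratio exactly 1.
#'
#' @param transcripts Output of [generate_transcriptome()].
#' @param config A [sim_config()] object.
#' @return The ground-truth tibble: transcripts plus `log10_control`,
#'   `log10_noise`, `true_ratio` and `outlier`
#'   (`"null"`/`"up"`/`"down"`).
#' @export
assign_abundances <- function(transcripts, config) {
  n <- nrow(transcripts)
  n_up <- length(config$outlier_ratios_up)
  n_down <- length(config$outlier_ratios_down)
  stopifnot(n >= 1L + n_up + n_down)
  withr::with_seed(config$seed + 1L, {
    ctrl <- runif(n, config$log10_abundance_range[1L],
                  config$log10_abundance_range[2L])
    ctrl[1L] <- 0
    ratio <- draw_null_ratios(n, config)
    ratio[1L] <- 1.0
    outlier <- rep("null", n)
    pool <- sample(2:n, n_up + n_down)
    if (n_up > 0L) {
      up_idx <- pool[seq_len(n_up)]
      ratio[up_idx] <- config$outlier_ratios_up
      outlier[up_idx] <- "up"
    }
    if (n_down > 0L) {
      down_idx <- pool[n_up + seq_len(n_down)]
      ratio[down_idx] <- config$outlier_ratios_down
      outlier[down_idx] <- "down"
    }
    truth <- transcripts
    truth$log10_control <- ctrl
    truth$log10_noise <- ctrl + log10(ratio)
    truth$true_ratio <- ratio
    truth$outlier <- outlier
    truth
  })
}

#' Simulate a paired-end read library for one condition
#'
#' Per-transcript read-pair counts are Poisson with mean
#' `coverage * 10^log10_abundance`; fragment starts are uniform; mate 1 is
#' the fragment's leading `read_length` bases and mate 2 the reverse
#' complement of its trailing `read_length` bases.  Substitution errors
#' are i.i.d. at `error_rate`, with quality `quality_error` at error
#' positions and `quality_correct` elsewhere.  Deterministic under the
#' config seed and condition.
#'
#' @param truth Ground truth from [assign_abundances()].
#' @param condition `"control"` or `"noise"`.
#' @param config A [sim_config()] object.
#' @return A read table (columns `id`, `mate`, `seq`, `qual`) with both
#'   mates of each pair.
#' @export
simulate_reads <- function(truth, condition = c("control", "noise"),
                           config) {
  condition <- match.arg(condition)
  log_ab <- if (condition == "control") truth$log10_control else
    truth$log10_noise
  seed_off <- if (condition == "control") 2L else 3L
  withr::with_seed(config$seed + seed_off, {
    rl <- config$read_length
    parts <- vector("list", nrow(truth))
    for (i in seq_len(nrow(truth))) {
      tx <- truth$sequence[i]
      L <- nchar(tx)
      if (L < rl) stop("transcript ", truth$id[i],
                       " shorter than the read length", call. = FALSE)
      frag <- min(config$fragment_length, L)
      n_pairs <- rpois(1L, config$coverage * 10^log_ab[i])
      if (n_pairs == 0L) next
      starts <- sample.int(L - frag + 1L, n_pairs, replace = TRUE)
      r1 <- substring(tx, starts, starts + rl - 1L)
      r2 <- reverse_complement(substring(tx, starts + frag - rl,
                                         starts + frag - 1L))
      ids <- sprintf("%s_%s_%05d", condition, truth$id[i],
                     seq_len(n_pairs))
      parts[[i]] <- tibble(
        id = rep(ids, 2L),
        mate = rep(c(1L, 2L), each = n_pairs),
        seq = c(r1, r2),
        qual = strrep(intToUtf8(config$quality_correct + 33L), rl)
      )
    }
    reads <- bind_rows(parts)
    if (nrow(reads) > 0L && config$error_rate > 0) {
      reads <- apply_substitution_errors(reads, config)
    }
    reads
  })
}

# Apply i.i.d. substitution errors and mark error positions with the
# error-state quality.
apply_substitution_errors <- function(reads, config) {
  rl <- nchar(reads$seq)
  n_err <- rbinom(nrow(reads), rl, config$error_rate)
  qe <- intToUtf8(config$quality_error + 33L)
  bases <- c("A", "C", "G", "T")
  for (i in which(n_err > 0L)) {
    pos <- sample.int(rl[i], n_err[i])
    s <- strsplit(reads$seq[i], "", fixed = TRUE)[[1]]
    q <- strsplit(reads$qual[i], "", fixed = TRUE)[[1]]
    for (p in pos) {
      s[p] <- sample(setdiff(bases, s[p]), 1L)
      q[p] <- qe
    }
    reads$seq[i] <- paste0(s, collapse = "")
    reads$qual[i] <- paste0(q, collapse = "")
  }
  reads
}

#' Simulate a complete two-condition experiment
#'
#' Convenience wrapper running [generate_transcriptome()],
#' [assign_abundances()] and [simulate_reads()] for both conditions.
#'
#' @param config A [sim_config()] object.
#' @return A list with `truth`, `control` and `noise` read tables, and
#'   `config`.
#' @export
simulate_experiment <- function(config = sim_config()) {
  tx <- generate_transcriptome(config)
  truth <- assign_abundances(tx, config)
  list(truth = truth,
       control = simulate_reads(truth, "control", config),
       noise = simulate_reads(truth, "noise", config),
       config = config)
}
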