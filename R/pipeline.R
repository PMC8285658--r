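#' Bundled locust auditory-organ abundance table
#'
#' The packaged reference dataset: 500 desert-locust (Schistocerca
#' gregaria) Mueller's-organ mRNA transcripts with log10 abundances,
#' relative to the 40S ribosomal protein SA transcript, measured in a
#' control and a noise-exposed transcriptome.  This is the input to the
#' reference ratio analysis (see [locust_noise_analysis()]).
#'
#' @return A tibble with columns `transcript_id`, `accession`,
#'   `log10_control`, `log10_noise`, `putative_function`.
#' @export
locust_abundance_table <- function() {
  path <- system.file("extdata", "locust_abundance_table.tsv",
                      package = "transwalker", mustWork = TRUE)
  as_tibble(utils::read.delim(path, colClasses = c(
    transcript_id = "character", accession = "character",
    log10_control = "numeric", log10_noise = "numeric",
    putative_function = "character")))
}

#' Curated reference selection for the bundled dataset
#'
#' The transcripts called increased (8) and decreased (18) in the curated
#' analysis of the bundled dataset, with their published 3-decimal
#' abundance ratios.  Used to validate that the package's fit and tail
#' selection reproduce the reference result.
#'
#' @return A tibble with columns `transcript_id`, `direction`, `ratio`.
#' @export
locust_reference_selection <- function() {
  path <- system.file("extdata", "locust_reference_selection.tsv",
                      package = "transwalker", mustWork = TRUE)
  as_tibble(utils::read.delim(path, colClasses = c(
    transcript_id = "character", direction = "character",
    ratio = "numeric")))
}

#' Reference ratio analysis of the bundled locust dataset
#'
#' One-command reproduction of the statistical analysis: abundance ratios
#' from the bundled table, a 0.2-wide-bin histogram, the least-squares
#' Cauchy fit, and tail selection at CDF 0.05 / 0.95.  The histogram edges
#' are anchored at 0.05 (bins ... [0.85, 1.05), [1.05, 1.25) ...), the
#' documented setting under which the fit reproduces the dataset's curated
#' selection of 8 increased and 18 decreased transcripts; see the methods
#' vignette for how this anchor was chosen.
#'
#' @param bin_width Histogram bin width (default 0.2).
#' @param origin Histogram edge anchor (default 0.05).
#' @param p_low,p_high Tail probabilities (defaults 0.05, 0.95).
#' @return A list with `table`, `ratios`, `histogram`, `fit`, `selection`.
#' @export
locust_noise_analysis <- function(bin_width = 0.2, origin = 0.05,
                                  p_low = 0.05, p_high = 0.95) {
  tab <- locust_abundance_table()
  ratios <- ratios_from_log_table(tab)
  h <- build_histogram(ratios, bin_width = bin_width, origin = origin)
  fit <- fit_cauchy(h)
  sel <- select_tails(ratios, fit, p_low = p_low, p_high = p_high)
  list(table = tab, ratios = ratios, histogram = h, fit = fit,
       selection = sel)
}

#' Run the full pipeline on two read libraries
#'
#' Orchestrates grooming, the identical-read census (and optionally the
#' translated BLOSUM search), walking assembly from the top census
#' candidates, reading-frame quantification of both libraries, and the
#' ratio / Cauchy-fit / tail-selection analysis.  All stages are
#' deterministic, so a rerun under the same inputs and parameters gives
#' identical output; when `out_dir` is given, every artifact is written
#' and a manifest with md5 content hashes is saved, and the slow assembly
#' stage is cached keyed on a hash of its inputs and parameters.
#'
#' @param reads_a,reads_b Read tables for the two conditions (a = control,
#'   b = noise/treatment).
#' @param groom A [groom_params()] object.
#' @param census A [census_params()] object.
#' @param walk A [walk_params()] object.
#' @param quant A [quant_params()] object; its `reference_id` must name an
#'   assembled transcript, or supply `reference_seq` instead.
#' @param reference_seq Optional reference transcript sequence; the
#'   assembled transcript whose frame it matches is used as the
#'   normalisation reference.
#' @param queries Optional protein query table; when given, reads hitting
#'   the queries (translated BLOSUM screen) are added to the seed pool.
#' @param min_score BLOSUM screen threshold (default 40).
#' @param max_transcripts Assemble at most this many distinct transcripts
#'   (default 20).
#' @param bin_width,origin,p_low,p_high Ratio-analysis settings (see
#'   [build_histogram()] and [select_tails()]).
#' @param out_dir Optional output directory for artifacts + manifest.
#' @return A list with `groomed_a`, `groomed_b`, `census`, `candidates`,
#'   `transcripts`, `failures`, `abundance` (both libraries),
#'   `ratios`, `fit`, `selection`, `manifest`.
#' @export
run_full <- function(reads_a, reads_b,
                     groom = groom_params(),
                     census = census_params(head_limit = Inf),
                     walk = walk_params(),
                     quant = quant_params(),
                     reference_seq = NULL,
                     queries = NULL, min_score = 40L,
                     max_transcripts = 20L,
                     bin_width = 0.2, origin = 0.05,
                     p_low = 0.05, p_high = 0.95,
                     out_dir = NULL) {
  manifest <- list(params = list(
    groom = unclass(groom), census = unclass(census),
    walk = unclass(walk), quant = unclass(quant),
    min_score = min_score, max_transcripts = max_transcripts,
    bin_width = bin_width, origin = origin,
    p_low = p_low, p_high = p_high))

  ga <- groom_library(reads_a, groom)
  gb <- groom_library(reads_b, groom)
  manifest$stages$groom <- list(
    a = list(n_input = ga$n_input, n_kept = ga$n_kept),
    b = list(n_input = gb$n_input, n_kept = gb$n_kept))

  ca <- count_identical_reads(ga, census$head_limit)
  cb <- count_identical_reads(gb, census$head_limit)
  crossed <- cross_census(ca, cb)
  cand <- select_candidates(crossed, census$ratio_threshold)
  manifest$stages$census <- list(
    distinct_a = nrow(ca), distinct_b = nrow(cb),
    matched_both = sum(crossed$in_both),
    single_library = sum(!crossed$in_both),
    candidates = nrow(cand))

  seeds <- cand$sequence
  if (!is.null(queries)) {
    hits <- screen_library(ga, queries, min_score = min_score)
    hit_reads <- ga$reads[ga$reads$id %in% hits$read_id, , drop = FALSE]
    seeds <- unique(c(seeds, hit_reads$seq))
    manifest$stages$tsearch <- list(hits = nrow(hits),
                                    seed_reads = nrow(hit_reads))
  }

  all_reads <- bind_rows(ga$reads, gb$reads)
  assembly_key <- rlang::hash(list(all_reads$seq, seeds, unclass(walk),
                                   max_transcripts))
  cache_file <- if (!is.null(out_dir)) {
    file.path(out_dir, paste0("assembly-", assembly_key, ".rds"))
  }
  if (!is.null(cache_file) && file.exists(cache_file)) {
    asm <- readRDS(cache_file)
  } else {
    asm <- assemble_from_seeds(seeds, all_reads, walk, quant,
                               max_transcripts)
    if (!is.null(cache_file)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      saveRDS(asm, cache_file)
    }
  }
  transcripts <- asm$transcripts
  manifest$stages$assembly <- list(seeds_tried = asm$seeds_tried,
                                   assembled = length(transcripts),
                                   failures = length(asm$failures))
  if (length(transcripts) == 0L) {
    stop("assembly produced no complete transcripts", call. = FALSE)
  }

  if (!is.null(reference_seq)) {
    quant$reference_id <- find_reference_transcript(transcripts,
                                                    reference_seq, quant)
  }
  qa <- quantify_library(transcripts, ga, quant, library_id = "control")
  qb <- quantify_library(transcripts, gb, quant, library_id = "noise")
  abundance <- bind_rows(qa, qb)
  manifest$stages$quantify <- list(
    transcripts = length(transcripts),
    total_reads_a = qa$total_reads[1L], total_reads_b = qb$total_reads[1L])

  log_table <- tibble(transcript_id = qa$transcript_id,
                      log10_control = qa$log10_relative,
                      log10_noise = qb$log10_relative)
  finite <- is.finite(log_table$log10_control) &
    is.finite(log_table$log10_noise)
  ratios <- ratios_from_log_table(log_table[finite, , drop = FALSE])
  fit <- NULL
  selection <- NULL
  h <- build_histogram(ratios, bin_width = bin_width, origin = origin)
  fit_ok <- sum(h$counts > 0) >= 3L
  if (fit_ok) {
    fit <- fit_cauchy(h)
    selection <- select_tails(ratios, fit, p_low = p_low, p_high = p_high)
    manifest$stages$ratios <- list(
      n_ratios = nrow(ratios), x0 = fit$x0, gamma = fit$gamma,
      decreased = nrow(selection$decreased),
      increased = nrow(selection$increased))
  } else {
    manifest$stages$ratios <- list(n_ratios = nrow(ratios),
                                   note = "too few occupied bins to fit")
  }

  result <- list(groomed_a = ga, groomed_b = gb, census = crossed,
                 candidates = cand, transcripts = transcripts,
                 failures = asm$failures, abundance = abundance,
                 ratios = ratios, histogram = h, fit = fit,
                 selection = selection, manifest = manifest)
  if (!is.null(out_dir)) {
    result$manifest <- write_run_artifacts(result, out_dir)
  }
  result
}

# Assemble transcripts from a ranked seed pool, skipping seeds already
# explained by an assembled contig and deduplicating identical ORFs.
assemble_from_seeds <- function(seeds, reads, walk, quant,
                                max_transcripts) {
  index <- build_overlap_index(reads, walk$min_overlap)
  transcripts <- list()
  failures <- list()
  orf_seen <- character(0)
  contig_seen <- character(0)
  tried <- 0L
  for (s in seeds) {
    if (length(transcripts) >= max_transcripts) break
    if (nchar(s) < walk$min_overlap) next
    if (length(contig_seen) > 0L &&
        any(vapply(contig_seen, function(ctg) {
          read_matches_frame(s, ctg, quant)
        }, logical(1)))) next
    tried <- tried + 1L
    res <- assemble_transcript(s, index, walk,
                               id = sprintf("walk_%03d", tried))
    if (inherits(res, "transcript")) {
      contig_seen <- c(contig_seen, res$sequence)
      orf <- orf_sequence(res)
      if (!orf %in% orf_seen) {
        orf_seen <- c(orf_seen, orf)
        transcripts[[length(transcripts) + 1L]] <- res
      }
    } else {
      contig_seen <- c(contig_seen, res$contig)
      failures[[length(failures) + 1L]] <- res
    }
  }
  list(transcripts = transcripts, failures = failures, seeds_tried = tried)
}

# Identify the assembled transcript corresponding to a known reference
# sequence by frame identity.
find_reference_transcript <- function(transcripts, reference_seq, quant) {
  orfs <- transcript_orfs(transcripts)
  ref_orf <- find_complete_orf(reference_seq)
  if (is.null(ref_orf)) stop("reference_seq has no complete reading frame",
                             call. = FALSE)
  oriented <- if (ref_orf$strand == "-") reverse_complement(reference_seq)
              else reference_seq
  target <- substr(oriented, ref_orf$start, ref_orf$end)
  hit <- which(orfs == target)
  if (length(hit) == 0L) {
    stop("no assembled transcript matches the reference sequence frame",
         call. = FALSE)
  }
  names(orfs)[hit[1L]]
}

# Write pipeline artifacts and a manifest with md5 hashes.
write_run_artifacts <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  tsv <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  paths <- c(paths, tsv(result$census, "census.tsv"))
  paths <- c(paths, tsv(result$candidates, "candidates.tsv"))
  if (length(result$transcripts) > 0L) {
    p <- file.path(out_dir, "transcripts.fasta")
    write_fasta(
      ids = vapply(result$transcripts, function(t) {
        sprintf("%s orf=%d..%d", t$id, t$orf_start, t$orf_end)
      }, character(1)),
      seqs = vapply(result$transcripts, function(t) t$sequence,
                    character(1)),
      path = p)
    paths <- c(paths, p)
    snps <- bind_rows(lapply(result$transcripts, function(t) {
      if (nrow(t$snps) == 0L) return(NULL)
      cbind(tibble(contig = t$id),
            t$snps[, c("position", "canonical_base", "alternate_base",
                       "alternate_fraction")])
    }))
    if (!is.null(snps) && nrow(snps) > 0L) {
      paths <- c(paths, tsv(snps, "snps.tsv"))
    }
  }
  paths <- c(paths, tsv(result$abundance, "abundances.tsv"))
  paths <- c(paths, tsv(result$ratios, "ratios.tsv"))
  if (!is.null(result$selection)) {
    sel <- bind_rows(
      mutate(result$selection$increased, direction = "increased"),
      mutate(result$selection$decreased, direction = "decreased"))
    paths <- c(paths, tsv(sel, "selection.tsv"))
    fitj <- file.path(out_dir, "fit.json")
    jsonlite::write_json(unclass(result$fit), fitj, auto_unbox = TRUE,
                         digits = NA)
    paths <- c(paths, fitj)
  }
  manifest <- result$manifest
  manifest$files <- lapply(setNames(nm = basename(paths)), function(b) {
    list(md5 = unname(tools::md5sum(file.path(out_dir, b))))
  })
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  manifest
}
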