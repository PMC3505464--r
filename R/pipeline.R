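# End-to-end orchestration: a config of file paths and thresholds drives
# preprocess -> map -> known annotation -> novel discovery -> optional
# target scan -> chip analysis, with a machine-readable run report.
# `make_fixture()` writes a complete synthetic input set with ground truth.

#' Assemble a run configuration
#'
#' @param genome path to the reference genome FASTA.
#' @param reads path to the raw read FASTQ/FASTA.
#' @param mature,precursors,links known-miRNA catalog files (see
#'   [mirna_catalog()]); all three `NULL` to skip annotation.
#' @param contaminants path to the contaminant FASTA (optional).
#' @param transcripts path to transcript FASTA for target scanning
#'   (optional).
#' @param chip_signals,chip_background chip TSVs (optional; both or
#'   neither).
#' @param adapter 3' adapter sequence or `NULL` for pre-trimmed reads.
#' @param min_len,max_len read length bounds.
#' @param max_mismatch,max_shift known-annotation tolerances.
#' @param max_hits mapping placement cap.
#' @param max_mismatches,max_bulges duplex ceilings for candidate calls.
#' @param max_score target-scan reporting ceiling.
#' @param floor,min_abundance chip detection floor and low-abundance cutoff.
#' @param seed integer seed for any stochastic step.
#' @return list of class `run_config`.
#' @export
run_config <- function(genome, reads, mature = NULL, precursors = NULL,
                       links = NULL, contaminants = NULL,
                       transcripts = NULL, chip_signals = NULL,
                       chip_background = NULL, adapter = NULL,
                       min_len = 18, max_len = 26, max_mismatch = 2,
                       max_shift = 2, max_hits = 20, max_mismatches = 6,
                       max_bulges = 3, max_score = 5, floor = 32,
                       min_abundance = 100, seed = 1) {
  cfg <- list(genome = genome, reads = reads, mature = mature,
              precursors = precursors, links = links,
              contaminants = contaminants, transcripts = transcripts,
              chip_signals = chip_signals,
              chip_background = chip_background, adapter = adapter,
              min_len = min_len, max_len = max_len,
              max_mismatch = max_mismatch, max_shift = max_shift,
              max_hits = max_hits, max_mismatches = max_mismatches,
              max_bulges = max_bulges, max_score = max_score,
              floor = floor, min_abundance = min_abundance, seed = seed)
  stopifnot(min_len >= 18 - 2, max_len <= 30, max_mismatch >= 0,
            max_bulges >= 0, max_mismatches >= 0)
  class(cfg) <- "run_config"
  cfg
}

# FNV-1a over the JSON serialisation: cheap, deterministic config hash.
config_hash <- function(cfg) {
  s <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, null = "null")
  h <- 2166136261
  for (b in utf8ToInt(as.character(s))) {
    h <- bitwXor(as.integer(h %% 2^31), b) * 16777619
    h <- h %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Run the full pipeline
#'
#' Executes preprocess, mapping, known annotation (when a catalog is
#' configured), novel hairpin discovery, optional target scanning of the
#' novel candidates, and chip analysis (when chip tables are configured).
#' Identical config + seed gives identical outputs.
#'
#' @param config a [run_config()].
#' @param out_dir optional directory for report JSON and TSV outputs.
#' @return object of class `mirfill_run`: list with `report` (summary
#'   counts and percentages), `preprocess`, `mapping_summary`, `known`
#'   (family tables or `NULL`), `candidates`, `targets` (or `NULL`),
#'   `chip` (or `NULL`) and `config_hash`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  contaminants <- if (!is.null(config$contaminants)) {
    as.character(Biostrings::readDNAStringSet(config$contaminants))
  } else character()

  pre <- stage("preprocess", preprocess_reads(
    config$reads, adapter = config$adapter, min_len = config$min_len,
    max_len = config$max_len, contaminants = contaminants))

  index <- stage("map", build_index(
    Biostrings::readDNAStringSet(config$genome)))
  mapping <- stage("map", map_reads(pre$reads, index,
                                    max_hits = config$max_hits))
  msum <- summarize_mapping(pre$reads, mapping)

  known <- NULL
  known_sequences <- character()
  if (!is.null(config$mature)) {
    catalog <- stage("annotate", mirna_catalog(config$mature,
                                               config$precursors,
                                               config$links))
    structures <- lapply(split(catalog$precursor_seq, catalog$precursor_id),
                         function(s) fold(s[1]))
    matches <- stage("annotate", annotate_reads(
      pre$reads, catalog, structures = structures,
      max_mismatch = config$max_mismatch, max_shift = config$max_shift))
    known <- family_table(matches)
    known_sequences <- unique(matches$sequence)
  }

  candidates <- stage("discover", discover_hairpins(
    mapping, pre$reads, index, known_sequences = known_sequences,
    max_mismatches = config$max_mismatches,
    max_bulges = config$max_bulges, max_hits_per_read = config$max_hits))

  targets <- NULL
  if (!is.null(config$transcripts) && nrow(candidates) > 0) {
    txs <- Biostrings::readDNAStringSet(config$transcripts)
    targets <- stage("targets", do.call(rbind, unlist(recursive = FALSE,
      lapply(seq_len(nrow(candidates)), function(i) {
        lapply(names(txs), function(tx) {
          scan_transcript(canon_dna(candidates$mature_seq[i]),
                          as.character(txs[[tx]]),
                          max_score = config$max_score,
                          mirna_name = sprintf("Can_miR_%02d", i),
                          transcript_id = tx)
        })
      }))))
  }

  chip <- NULL
  if (!is.null(config$chip_signals)) {
    signals <- read.delim(config$chip_signals, stringsAsFactors = FALSE)
    background <- read.delim(config$chip_background,
                             stringsAsFactors = FALSE)
    chip <- stage("chip", chip_analysis(
      signals, background, min_abundance = config$min_abundance,
      floor = config$floor))
  }

  report <- list(
    raw_reads = pre$report$raw_reads,
    clean_reads = pre$report$clean_reads,
    unique_sequences = pre$report$unique_sequences,
    removed = as.list(pre$report$removed),
    aligned_sequences = msum$aligned_sequences,
    percent_aligned = msum$percent_aligned,
    known_mirnas = if (is.null(known)) NA else nrow(known$per_mirna),
    known_families = if (is.null(known)) NA else nrow(known$per_family),
    novel_candidates = nrow(candidates),
    chip_stage = !is.null(chip),
    skipped = c(if (is.null(known)) "annotate",
                if (is.null(targets)) "targets",
                if (is.null(chip)) "chip"),
    config_hash = config_hash(config)
  )
  run <- structure(list(report = report, preprocess = pre$report,
                        mapping_summary = msum, known = known,
                        candidates = candidates, targets = targets,
                        chip = chip, config_hash = report$config_hash),
                   class = "mirfill_run")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    write_candidates(candidates,
                     tsv_path = file.path(out_dir, "novel_candidates.tsv"),
                     structure_path = file.path(out_dir,
                                                "novel_structures.txt"))
    if (!is.null(known)) {
      write.table(known$per_mirna, file.path(out_dir, "known_mirnas.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(known$per_family,
                  file.path(out_dir, "known_families.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(chip)) {
      write.table(chip$de, file.path(out_dir, "chip_de.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      write.table(chip$calls, file.path(out_dir, "chip_calls.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      venn <- stage_overlap(chip$calls)
      jsonlite::write_json(as.list(venn),
                           file.path(out_dir, "venn_regions.json"),
                           auto_unbox = TRUE)
    }
    if (!is.null(targets)) {
      write_targets(targets, file.path(out_dir, "targets.tsv"))
    }
  }
  run
}

#' @export
print.mirfill_run <- function(x, ...) {
  r <- x$report
  cat("mirfill pipeline run (config", r$config_hash, ")\n")
  cat(sprintf("  reads: %d raw -> %d clean, %d unique\n", r$raw_reads,
              r$clean_reads, r$unique_sequences))
  cat(sprintf("  aligned: %d distinct (%.1f%%)\n", r$aligned_sequences,
              r$percent_aligned))
  if (!is.na(r$known_mirnas)) {
    cat(sprintf("  known miRNAs: %d in %d families\n", r$known_mirnas,
                r$known_families))
  }
  cat(sprintf("  novel candidates: %d\n", r$novel_candidates))
  if (length(r$skipped) > 0) {
    cat("  skipped stages:", paste(r$skipped, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a complete synthetic fixture directory
#'
#' Generates a toy genome with planted hairpins, a read population (mature
#' and star reads from each plant, contaminants, background), a known-miRNA
#' catalog disjoint from the plants, three-stage chip tables with known
#' up/down truth, and the ground-truth tables -- everything [run_pipeline()]
#' needs.
#'
#' @param seed integer seed; same seed, same directory content.
#' @param scale `"tiny"` (3 plants, 2,000 reads) or `"demo"` (5 plants,
#'   5,000 reads).
#' @param dir output directory; must not already contain files unless
#'   `force = TRUE`.
#' @param force overwrite a non-empty directory.
#' @return invisibly, a list with the fixture paths, the truth tables and a
#'   ready [run_config()].
#' @export
make_fixture <- function(seed = 1, scale = c("tiny", "demo"), dir,
                         force = FALSE) {
  scale <- match.arg(scale)
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !force) {
    stop("directory not empty (use force = TRUE): ", dir)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n_plants <- if (scale == "tiny") 3L else 5L
  n_reads <- if (scale == "tiny") 2000L else 5000L
  chrom_len <- 10000L

  set.seed(substream_seed(seed, "fixture"))
  hairpins <- lapply(seq_len(n_plants), function(i) {
    planted_hairpin(
      locus_id = sprintf("plant%02d", i), chrom = "chr1",
      start = 1000L + (i - 1L) * 2500L,
      strand = if (i %% 2 == 0) "-" else "+",
      mature_seq = random_dna(sample(20:24, 1)),
      mature_arm = if (i %% 2 == 0) "3p" else "5p",
      star_mutations = 2)
  })
  gen <- generate_genome(1, chrom_len, hairpins, seed = seed)
  contaminants <- make_contaminants(6, seed = seed)
  reads <- simulate_reads(gen$truth, grain_length_profile(), n_reads,
                          mature_fraction = 0.25, star_fraction = 0.10,
                          contaminant_fraction = 0.10,
                          contaminants = contaminants, seed = seed)

  # known catalog disjoint from the plants: synthetic precursors not in the
  # genome; spike matching reads so the annotation stage has work to do
  known <- lapply(1:2, function(i) {
    planted_hairpin(sprintf("known%d", i), "none", 0, "+",
                    mature_seq = random_dna(21), mature_arm = "5p")
  })
  mature <- setNames(vapply(known, `[[`, "", "mature_seq"),
                     c("osa-miR9001", "osa-miR9002"))
  precursors <- setNames(vapply(known, `[[`, "", "precursor_seq"),
                         c("osa-MIR9001", "osa-MIR9002"))
  links <- data.frame(name = names(mature),
                      precursor_id = names(precursors),
                      offset = vapply(known, function(h) h$mature_off - 1L,
                                      integer(1)),
                      arm = "5p", stringsAsFactors = FALSE)
  spike <- data.frame(id = sprintf("known%03d", 1:60),
                      sequence = rep(unname(mature), each = 30),
                      category = "known", locus_id = NA_character_,
                      stringsAsFactors = FALSE)
  reads <- rbind(reads, spike)

  # chip truth: mostly flat probes (the median-scaling anchor) plus up,
  # down and low-abundance ones
  n_probes <- 24L
  pattern <- rep(c("up", "down", "flat", "low"),
                 times = c(4L, 4L, 12L, 4L))
  mult <- t(vapply(pattern, function(p) switch(p,
    up = c(1, 1, 5.53), down = c(1, 0.45, 0.25), flat = c(1, 1, 1),
    low = c(1, 1, 1)), numeric(3)))
  base <- ifelse(pattern == "low", 40, 300 + 50 * seq_len(n_probes))
  truths <- chip_truth(sprintf("probe%02d", seq_len(n_probes)), base, mult,
                       noise_cv = 0.08)
  chip <- simulate_chip(truths, replicates = 3, background_mean = 20,
                        background_sd = 4, seed = seed)

  paths <- list(
    genome = file.path(dir, "genome.fasta"),
    reads = file.path(dir, "reads.fastq"),
    contaminants = file.path(dir, "contaminants.fasta"),
    mature = file.path(dir, "known_mature.fasta"),
    precursors = file.path(dir, "known_precursors.fasta"),
    links = file.path(dir, "known_links.tsv"),
    chip_signals = file.path(dir, "chip_signals.tsv"),
    chip_background = file.path(dir, "chip_background.tsv"),
    truth = file.path(dir, "truth.tsv"),
    chip_truth = file.path(dir, "chip_truth.tsv"))
  Biostrings::writeXStringSet(gen$genome, paths$genome)
  write_fastq(reads$sequence, reads$id, paths$reads)
  cset <- Biostrings::DNAStringSet(contaminants)
  Biostrings::writeXStringSet(cset, paths$contaminants)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(mature),
                              paths$mature)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(precursors),
                              paths$precursors)
  write.table(links, paths$links, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(chip$signals, paths$chip_signals, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(chip$background, paths$chip_background, sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(gen$truth, paths$truth, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(cbind(truths, pattern = pattern), paths$chip_truth,
              sep = "\t", quote = FALSE, row.names = FALSE)

  cfg <- run_config(genome = paths$genome, reads = paths$reads,
                    mature = paths$mature, precursors = paths$precursors,
                    links = paths$links,
                    contaminants = paths$contaminants,
                    chip_signals = paths$chip_signals,
                    chip_background = paths$chip_background, seed = seed)
  invisible(list(paths = paths, truth = gen$truth, chip_truth = truths,
                 chip_pattern = pattern, reads = reads, config = cfg))
}
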