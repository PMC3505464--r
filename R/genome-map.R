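# Exact, ungapped placement of collapsed reads on both strands of the
# reference genome (the zero-mismatch contract of the original SOAP -v 0
# invocation). Any read with more than `max_hits` placements is discarded as
# multi-mapped.

#' Build an exact-match genome index
#'
#' @param genome a named [Biostrings::DNAStringSet] or named character
#'   vector; chromosome names must be unique.
#' @return object of class `genome_index`.
#' @export
build_index <- function(genome) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  stopifnot(methods::is(genome, "DNAStringSet"))
  if (anyDuplicated(names(genome))) stop("duplicate chromosome name")
  structure(list(genome = genome,
                 chrom_len = setNames(Biostrings::width(genome),
                                      names(genome))),
            class = "genome_index")
}

#' @export
print.genome_index <- function(x, ...) {
  cat(sprintf("<genome_index: %d chromosome(s), %d nt>\n",
              length(x$genome), sum(x$chrom_len)))
  invisible(x)
}

# All exact placements of one sequence; 0-based half-open coordinates.
hits_one <- function(sequence, index) {
  if (grepl("N", sequence, fixed = TRUE) || length(index$genome) == 0) {
    return(NULL)
  }
  out <- list()
  pat_f <- Biostrings::DNAString(sequence)
  pat_r <- Biostrings::reverseComplement(pat_f)
  for (cn in names(index$genome)) {
    subject <- index$genome[[cn]]
    for (strand in c("+", "-")) {
      m <- Biostrings::matchPattern(if (strand == "+") pat_f else pat_r,
                                    subject)
      if (length(m) > 0) {
        out[[length(out) + 1L]] <- data.frame(
          chrom = cn, start = Biostrings::start(m) - 1L,
          end = Biostrings::end(m), strand = strand,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) NULL else do.call(rbind, out)
}

#' Map one read to the genome
#'
#' Reports all exact occurrences on both strands, unless their number
#' exceeds `max_hits`, in which case the read is flagged as multi-mapped and
#' no hits are reported.
#'
#' @param sequence read sequence (18-26 nt).
#' @param index a [build_index()] object.
#' @param max_hits placement cap emulating the repeat-reporting limit.
#' @param read_id identifier copied into the hits.
#' @return list with `hits` (data frame read_id/chrom/start/end/strand,
#'   0-based half-open) and `flag` (`"mapped"`, `"unmapped"` or
#'   `"multi_mapped_discarded"`).
#' @export
map_read <- function(sequence, index, max_hits = 20, read_id = "read1") {
  stopifnot(nchar(sequence) >= 18, nchar(sequence) <= 26)
  h <- hits_one(canon_dna(sequence), index)
  if (is.null(h)) {
    return(list(hits = empty_hits(), flag = "unmapped"))
  }
  if (nrow(h) > max_hits) {
    return(list(hits = empty_hits(), flag = "multi_mapped_discarded"))
  }
  list(hits = cbind(data.frame(read_id = read_id, stringsAsFactors = FALSE),
                    h),
       flag = "mapped")
}

empty_hits <- function() {
  data.frame(read_id = character(), chrom = character(), start = integer(),
             end = integer(), strand = character(), stringsAsFactors = FALSE)
}

#' Map a collapsed read table to the genome
#'
#' @param reads data frame with columns `sequence` and `count` (see
#'   [collapse_reads()]); a `read_id` column is added if absent
#'   (`seq<rank>`).
#' @param index a [build_index()] object.
#' @param max_hits placement cap per read.
#' @return list with `hits` (all placements, plus `count` and `sequence`
#'   columns) and `flags` (per-read mapping flag).
#' @export
map_reads <- function(reads, index, max_hits = 20) {
  if (is.null(reads$read_id)) {
    reads$read_id <- sprintf("seq%d", seq_len(nrow(reads)))
  }
  res <- lapply(seq_len(nrow(reads)), function(i) {
    map_read(reads$sequence[i], index, max_hits = max_hits,
             read_id = reads$read_id[i])
  })
  flags <- vapply(res, `[[`, "", "flag")
  hits <- do.call(rbind, lapply(res, `[[`, "hits"))
  if (is.null(hits) || nrow(hits) == 0) {
    hits <- empty_hits()
    hits$count <- integer()
    hits$sequence <- character()
  } else {
    idx <- match(hits$read_id, reads$read_id)
    hits$count <- reads$count[idx]
    hits$sequence <- reads$sequence[idx]
  }
  list(hits = hits, flags = setNames(flags, reads$read_id))
}

#' Mapping summary statistics
#'
#' @param unique_sequences number of distinct clean sequences.
#' @param aligned_sequences number of distinct sequences with at least one
#'   reported placement.
#' @return list of class `mapping_summary` with `percent_aligned` =
#'   `100 * aligned / unique`, rounded half-up to 1 decimal.
#' @examples
#' mapping_summary(974934, 637362)  # 65.4 percent aligned
#' @export
mapping_summary <- function(unique_sequences, aligned_sequences) {
  if (unique_sequences == 0) stop("empty input")
  stopifnot(aligned_sequences <= unique_sequences)
  structure(list(
    unique_sequences = unique_sequences,
    aligned_sequences = aligned_sequences,
    percent_aligned = round_half_up(100 * aligned_sequences /
                                      unique_sequences, 1)
  ), class = "mapping_summary")
}

#' @export
print.mapping_summary <- function(x, ...) {
  cat(sprintf("%d of %d distinct sequences aligned (%.1f%%)\n",
              x$aligned_sequences, x$unique_sequences, x$percent_aligned))
  invisible(x)
}

#' Summarise a mapping run
#'
#' @param reads collapsed read table given to [map_reads()].
#' @param mapping result of [map_reads()].
#' @return a [mapping_summary()].
#' @export
summarize_mapping <- function(reads, mapping) {
  aligned <- length(unique(mapping$hits$read_id))
  mapping_summary(nrow(reads), aligned)
}

#' Write genome hits as 6-column BED
#'
#' 0-based half-open intervals; name = read id, score = read count.
#' @param hits hits data frame from [map_reads()].
#' @param path output path.
#' @export
write_bed <- function(hits, path) {
  bed <- data.frame(chrom = hits$chrom, start = hits$start, end = hits$end,
                    name = hits$read_id,
                    score = if (is.null(hits$count)) 0L else hits$count,
                    strand = hits$strand)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
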