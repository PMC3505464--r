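# Read preprocessing: adapter trimming, 18-26 nt length filtering,
# contaminant removal by exact substring match, and collapsing to unique
# sequences with counts. Mirrors the classic small-RNA cleanup contract.

#' Trim a 3' adapter from one read
#'
#' Finds the leftmost occurrence in the read of a prefix of the adapter with
#' at least `min_overlap` exactly matching bases and removes everything from
#' that position on. Reads with no adapter occurrence are rejected: without
#' adapter read-through they are not genuine short inserts.
#'
#' @param read nucleotide string (U accepted, canonicalised to T).
#' @param adapter adapter sequence (non-empty).
#' @param min_overlap minimum matched adapter prefix length (>= 5).
#' @return list with `insert` (trimmed sequence or `NA`) and `reason`
#'   (`"ok"`, `"empty"`, `"empty_insert"` or `"no_adapter"`).
#' @examples
#' trim_adapter("ACGTACGTTTTTTT", "TTTTTTXXXX", min_overlap = 6)
#' @export
trim_adapter <- function(read, adapter, min_overlap = 6) {
  stopifnot(nchar(adapter) > 0, min_overlap >= 5)
  read <- canon_dna(read)
  adapter <- canon_dna(adapter)
  if (nchar(read) == 0) return(list(insert = NA_character_, reason = "empty"))
  n <- nchar(read)
  for (p in seq_len(n)) {
    avail <- n - p + 1L
    k <- min(avail, nchar(adapter))
    if (k < min_overlap) break
    if (substr(read, p, p + k - 1L) == substr(adapter, 1L, k)) {
      if (p == 1L) return(list(insert = NA_character_,
                               reason = "empty_insert"))
      return(list(insert = substr(read, 1L, p - 1L), reason = "ok"))
    }
  }
  list(insert = NA_character_, reason = "no_adapter")
}

#' Length- and contaminant-filter reads
#'
#' Drops reads outside `[min_len, max_len]` nt, reads containing N
#' (class `"ambiguous"`), and reads occurring as exact substrings of any
#' catalog sequence on either strand (class `"contaminant"`).
#'
#' @param reads character vector of read sequences (already trimmed).
#' @param min_len,max_len retained length bounds (defaults 18 and 26).
#' @param contaminants named character vector of contaminant sequences
#'   (rRNA/tRNA/snRNA/snoRNA catalog); may be empty.
#' @return list with `retained` (character vector) and `removed` (named
#'   integer vector with classes short/long/ambiguous/contaminant).
#' @export
filter_reads <- function(reads, min_len = 18, max_len = 26,
                         contaminants = character()) {
  reads <- canon_dna(reads)
  removed <- c(short = 0L, long = 0L, ambiguous = 0L, contaminant = 0L)
  keep <- rep(TRUE, length(reads))
  len <- nchar(reads)
  amb <- grepl("N", reads, fixed = TRUE)
  removed["ambiguous"] <- sum(amb)
  keep[amb] <- FALSE
  removed["short"] <- sum(!amb & len < min_len)
  keep[!amb & len < min_len] <- FALSE
  removed["long"] <- sum(!amb & len > max_len)
  keep[!amb & len > max_len] <- FALSE
  if (length(contaminants) > 0 && any(keep)) {
    cat_both <- c(canon_dna(contaminants), revcomp(canon_dna(contaminants)))
    uniq <- unique(reads[keep])
    is_cont <- vapply(uniq, function(s)
      any(grepl(s, cat_both, fixed = TRUE)), logical(1))
    bad <- reads %in% uniq[is_cont] & keep
    removed["contaminant"] <- sum(bad)
    keep[bad] <- FALSE
  }
  list(retained = reads[keep], removed = removed)
}

#' Collapse reads to unique sequences with counts
#'
#' @param reads character vector of filtered read sequences.
#' @return data frame with columns `sequence` and `count`, sorted by
#'   descending count with ties broken lexicographically; the sum of counts
#'   equals the number of input reads.
#' @export
collapse_reads <- function(reads) {
  if (length(reads) == 0) {
    return(data.frame(sequence = character(), count = integer(),
                      stringsAsFactors = FALSE))
  }
  tab <- table(canon_dna(reads))
  out <- data.frame(sequence = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$sequence), ]
  rownames(out) <- NULL
  out
}

#' Preprocess a raw small-RNA read set
#'
#' Full cleanup: optional adapter trimming, length filter, contaminant
#' removal, collapsing. Accepts a FASTQ/FASTA path or a character vector of
#' sequences.
#'
#' @param reads file path (FASTA or FASTQ, by extension) or character vector.
#' @param adapter optional 3' adapter; when `NULL` no trimming is done (reads
#'   are taken as already adapter-free inserts).
#' @param min_overlap minimum adapter overlap for [trim_adapter()].
#' @param min_len,max_len retained length bounds.
#' @param contaminants contaminant catalog (named character vector).
#' @return list of class `preprocess_result` with `reads` (collapsed data
#'   frame, see [collapse_reads()]) and `report` (class `preprocess_report`).
#' @export
preprocess_reads <- function(reads, adapter = NULL, min_overlap = 6,
                             min_len = 18, max_len = 26,
                             contaminants = character()) {
  if (is.character(reads) && length(reads) == 1 && file.exists(reads)) {
    fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", reads)) "fastq" else "fasta"
    reads <- as.character(Biostrings::readDNAStringSet(reads, format = fmt))
  }
  reads <- canon_dna(reads)
  raw_n <- length(reads)
  no_adapter <- 0L
  if (!is.null(adapter)) {
    trimmed <- lapply(reads, trim_adapter, adapter = adapter,
                      min_overlap = min_overlap)
    ok <- vapply(trimmed, function(t) t$reason == "ok", logical(1))
    no_adapter <- sum(!ok)
    reads <- vapply(trimmed[ok], `[[`, "", "insert")
  }
  flt <- filter_reads(reads, min_len = min_len, max_len = max_len,
                      contaminants = contaminants)
  collapsed <- collapse_reads(flt$retained)
  hist_tab <- table(factor(nchar(flt$retained), levels = min_len:max_len))
  report <- structure(list(
    raw_reads = raw_n,
    clean_reads = length(flt$retained),
    unique_sequences = nrow(collapsed),
    contaminant_reads = unname(flt$removed["contaminant"]),
    removed = c(no_adapter = no_adapter, flt$removed),
    length_histogram = setNames(as.integer(hist_tab),
                                names(hist_tab))
  ), class = "preprocess_report")
  structure(list(reads = collapsed, report = report),
            class = "preprocess_result")
}

#' @export
print.preprocess_report <- function(x, ...) {
  cat("Small-RNA preprocessing report\n")
  cat(sprintf("  raw reads:          %d\n", x$raw_reads))
  cat(sprintf("  clean reads:        %d (%.1f%%)\n", x$clean_reads,
              if (x$raw_reads > 0) 100 * x$clean_reads / x$raw_reads else 0))
  cat(sprintf("  unique sequences:   %d\n", x$unique_sequences))
  cat("  removed:", paste(sprintf("%s=%d", names(x$removed), x$removed),
                          collapse = " "), "\n")
  invisible(x)
}

#' Write collapsed reads as FASTA
#'
#' Headers follow the `>seq<rank>_x<count>` convention.
#' @param collapsed data frame from [collapse_reads()].
#' @param path output FASTA path.
#' @export
write_collapsed_fasta <- function(collapsed, path) {
  x <- Biostrings::DNAStringSet(collapsed$sequence)
  names(x) <- sprintf("seq%d_x%d", seq_len(nrow(collapsed)), collapsed$count)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
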