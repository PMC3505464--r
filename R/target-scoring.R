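# miRU-style plant miRNA target scoring: slide the reverse complement of the
# miRNA along the transcript, allow at most one (interior) gap, and penalise
# mismatches 1.0, G:U wobbles 0.5 and gapped positions 2.0. A perfect site
# scores 0; sites scoring above `max_score` are not reported.

PAIR_CODES <- c("match", "GU", "mismatch", "gap_m", "gap_t")
CODE_CHARS <- c(match = "|", GU = "o", mismatch = "x",
                gap_m = "-", gap_t = "-")

# classify one aligned column: miRNA base (DNA space) vs target base
classify_pair <- function(mirna_base, target_base) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  if (comp[[mirna_base]] == target_base) return("match")
  if ((mirna_base == "G" && target_base == "T") ||
      (mirna_base == "T" && target_base == "G")) return("GU")
  "mismatch"
}

#' Score a target-site alignment
#'
#' @param codes character vector of per-position codes (`match`, `GU`,
#'   `mismatch`, `gap_m`, `gap_t`) or a compact pairing string using
#'   `|` (match), `o` (G:U), `x` (mismatch), `-` (gap).
#' @return penalty: 1.0 per mismatch + 0.5 per G:U + 2.0 per gapped
#'   position; 0 for a perfect site.
#' @examples
#' score_alignment(c("match", "mismatch", "GU", "mismatch"))  # 2.5
#' @export
score_alignment <- function(codes) {
  if (length(codes) == 1 && !codes %in% PAIR_CODES) {
    ch <- strsplit(codes, "")[[1]]
    lookup <- c("|" = "match", o = "GU", x = "mismatch", "-" = "gap_t")
    if (any(!ch %in% names(lookup))) {
      stop("unknown pairing code: ", paste(setdiff(ch, names(lookup)),
                                           collapse = ""))
    }
    codes <- unname(lookup[ch])
  }
  if (any(!codes %in% PAIR_CODES)) {
    stop("unknown pairing code: ",
         paste(setdiff(codes, PAIR_CODES), collapse = ", "))
  }
  sum((codes == "mismatch") * 1.0 + (codes == "GU") * 0.5 +
        (codes %in% c("gap_m", "gap_t")) * 2.0)
}

# Score and codes for one gapless window (target_window length = miRNA
# length); columns returned from the miRNA 5' end.
align_ungapped <- function(mirna_rc, target_window, mirna) {
  L <- nchar(mirna)
  m <- strsplit(mirna, "")[[1]]
  t <- strsplit(target_window, "")[[1]]
  # miRNA position k pairs target window column L - k + 1
  codes <- vapply(seq_len(L), function(k)
    classify_pair(m[k], t[L - k + 1L]), character(1))
  codes
}

#' Scan a transcript for miRNA target sites
#'
#' Slides the reverse complement of the miRNA across the transcript,
#' considering the gapless placement at every start plus every single
#' interior gap placement (one unopposed miRNA base, or one unopposed
#' transcript base). At each transcript start the best-scoring alignment is
#' kept (ungapped preferred on ties) and reported when its score is at most
#' `max_score`.
#'
#' @param mirna mature miRNA, 20-24 nt (RNA or DNA).
#' @param transcript transcript sequence (DNA).
#' @param max_score reporting ceiling (default 5.0).
#' @param mirna_name,transcript_id identifiers copied to the output.
#' @return data frame sorted by ascending score then position: columns
#'   `mirna_name`, `transcript_id`, `site_start` (0-based), `site_len`,
#'   `score`, `pairing` (string from the miRNA 5' end; `|` match, `o` G:U,
#'   `x` mismatch, `-` gap), `codes` (list column of per-position codes).
#'   Empty when the transcript is shorter than the miRNA.
#' @export
scan_transcript <- function(mirna, transcript, max_score = 5,
                            mirna_name = "mirna", transcript_id = "tx") {
  mirna <- canon_dna(mirna)
  transcript <- canon_dna(transcript)
  L <- nchar(mirna)
  stopifnot(L >= 20, L <= 24)
  n <- nchar(transcript)
  empty <- data.frame(mirna_name = character(), transcript_id = character(),
                      site_start = integer(), site_len = integer(),
                      score = numeric(), pairing = character(),
                      stringsAsFactors = FALSE)
  empty$codes <- list()
  if (n < L) return(empty)
  m <- strsplit(mirna, "")[[1]]
  tch <- strsplit(transcript, "")[[1]]
  rows <- list()
  for (p in 1:(n - L + 1L)) {
    # ungapped
    best_codes <- vapply(seq_len(L), function(k)
      classify_pair(m[k], tch[p + L - k]), character(1))
    best_score <- score_alignment(best_codes)
    best_len <- L
    # one unopposed miRNA base at interior position g (2..L-1): window L-1
    if (p + L - 2L <= n) {
      for (g in 2:(L - 1L)) {
        codes <- character(L)
        tpos <- p + L - 2L   # top transcript coordinate of the window
        ti <- 0L
        for (k in seq_len(L)) {
          if (k == g) { codes[k] <- "gap_t"; next }
          codes[k] <- classify_pair(m[k], tch[tpos - ti])
          ti <- ti + 1L
        }
        sc <- score_alignment(codes)
        if (sc < best_score) {
          best_score <- sc; best_codes <- codes; best_len <- L - 1L
        }
      }
    }
    # one unopposed transcript base between miRNA positions g and g+1:
    # window L+1
    if (p + L <= n) {
      for (g in 1:(L - 1L)) {
        codes <- character(L + 1L)
        tpos <- p + L        # top transcript coordinate of the window
        ti <- 0L
        ci <- 0L
        for (k in seq_len(L)) {
          ci <- ci + 1L
          codes[ci] <- classify_pair(m[k], tch[tpos - ti])
          ti <- ti + 1L
          if (k == g) {
            ci <- ci + 1L
            codes[ci] <- "gap_m"
            ti <- ti + 1L
          }
        }
        sc <- score_alignment(codes)
        if (sc < best_score) {
          best_score <- sc; best_codes <- codes; best_len <- L + 1L
        }
      }
    }
    if (best_score <= max_score) {
      rows[[length(rows) + 1L]] <- list(start = p - 1L, len = best_len,
                                        score = best_score,
                                        codes = best_codes)
    }
  }
  if (length(rows) == 0) return(empty)
  out <- data.frame(
    mirna_name = mirna_name, transcript_id = transcript_id,
    site_start = vapply(rows, `[[`, integer(1), "start"),
    site_len = vapply(rows, `[[`, integer(1), "len"),
    score = vapply(rows, `[[`, numeric(1), "score"),
    pairing = vapply(rows, function(r)
      paste(CODE_CHARS[r$codes], collapse = ""), character(1)),
    stringsAsFactors = FALSE)
  out$codes <- lapply(rows, `[[`, "codes")
  out <- out[order(out$score, out$site_start), ]
  rownames(out) <- NULL
  out
}

#' Map degradome/RACE clone 5' ends onto a target alignment
#'
#' Each clone 5' end falling within the site is converted to a 1-based
#' position counted from the miRNA 5' end (the canonical cleavage register
#' places the product 5' end opposite miRNA position 10); ends outside the
#' site count as off-target.
#'
#' @param alignment one row of [scan_transcript()] output.
#' @param clone_5p_ends integer vector of 0-based transcript offsets.
#' @return list with `position_counts` (named integer vector, miRNA
#'   positions with at least one clone) and `off_target_clones`.
#' @export
map_clones <- function(alignment, clone_5p_ends) {
  codes <- alignment$codes[[1]]
  start0 <- alignment$site_start
  site_end <- start0 + alignment$site_len - 1L    # 0-based inclusive
  # walk columns from the miRNA 5' end; transcript coordinate descends
  tpos <- site_end
  mpos <- 0L
  pos_of_offset <- integer(0)
  for (code in codes) {
    consumes_m <- code %in% c("match", "GU", "mismatch", "gap_t")
    consumes_t <- code %in% c("match", "GU", "mismatch", "gap_m")
    if (consumes_m) mpos <- mpos + 1L
    if (consumes_t) {
      pos_of_offset[as.character(tpos)] <- max(mpos, 1L)
      tpos <- tpos - 1L
    }
  }
  counts <- integer(0)
  off <- 0L
  for (t in clone_5p_ends) {
    key <- as.character(t)
    if (key %in% names(pos_of_offset)) {
      p <- as.character(pos_of_offset[[key]])
      counts[p] <- (if (p %in% names(counts)) counts[[p]] else 0L) + 1L
    } else {
      off <- off + 1L
    }
  }
  list(position_counts = counts, off_target_clones = off)
}

#' Write target alignments as TSV
#'
#' @param alignments data frame from [scan_transcript()] (rows may be
#'   concatenated across miRNAs/transcripts).
#' @param path output path; start is reported 1-based.
#' @export
write_targets <- function(alignments, path) {
  tab <- data.frame(mirna = alignments$mirna_name,
                    transcript = alignments$transcript_id,
                    start = alignments$site_start + 1L,
                    score = alignments$score,
                    pairing = alignments$pairing)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
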