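# Novel miRNA discovery: excise candidate windows around mapped reads
# (20-260 nt flanks in a 20-nt frame), fold each window, locate the miRNA*
# with the canonical 2-nt 3' overhang, score the miRNA/miRNA* duplex and
# accept candidates with <= 3 bulges, <= 6 mismatches and star-read support.

#' Excise candidate precursor windows around a genome hit
#'
#' For each extension `d` in 20, 40, ..., 260 two windows are emitted:
#' one extending upstream of the read (`[start - d, end]`) and one
#' downstream (`[start, end + d]`), clipped at chromosome bounds. For
#' minus-strand hits the window sequence is reverse-complemented so the read
#' appears in sense orientation.
#'
#' @param hit one-row data frame with `chrom`, `start`, `end` (0-based
#'   half-open) and `strand`.
#' @param index a [build_index()] object.
#' @param flank_max,flank_step window enumeration parameters (defaults 260
#'   and 20).
#' @return data frame with one row per window: `win_start`, `win_end`
#'   (0-based half-open, genomic), `seq` (sense orientation), `read_start`
#'   (1-based position of the read within `seq`), `read_len`.
#' @export
excise_windows <- function(hit, index, flank_max = 260, flank_step = 20) {
  clen <- index$chrom_len[[hit$chrom]]
  if (is.null(clen) || hit$start < 0 || hit$end > clen) {
    stop("hit outside chromosome bounds")
  }
  ext <- seq(flank_step, flank_max, by = flank_step)
  wins <- rbind(
    data.frame(ws = pmax(0L, hit$start - ext), we = hit$end),
    data.frame(ws = hit$start, we = pmin(clen, hit$end + ext)))
  wins <- unique(wins)
  chrom_seq <- as.character(index$genome[[hit$chrom]])
  seqs <- substr(rep(chrom_seq, nrow(wins)), wins$ws + 1L, wins$we)
  if (hit$strand == "-") seqs <- revcomp(seqs)
  read_start <- if (hit$strand == "+") hit$start - wins$ws + 1L
  else wins$we - hit$end + 1L
  data.frame(win_start = wins$ws, win_end = wins$we, seq = seqs,
             read_start = as.integer(read_start),
             read_len = hit$end - hit$start, stringsAsFactors = FALSE)
}

#' Locate the miRNA* interval for a mature interval on a folded precursor
#'
#' The star interval consists of the positions pairing with the mature
#' interval, shifted so that each strand of the duplex carries a 2-nt 3'
#' overhang. `NULL` is returned when fewer than `min_paired_frac` of the
#' mature positions are paired, or when the mature interval spans the loop.
#'
#' @param structure a `secondary_structure`.
#' @param mature_interval 1-based `c(start, end)` on the folded sequence.
#' @param min_paired_frac minimum fraction of paired mature positions
#'   (default 0.6).
#' @return 1-based `c(start, end)` of the star interval, or `integer(0)`
#'   with attribute `reason` (`"loop_spanning"` or `"unpaired"`) when no
#'   star can be located.
#' @export
find_star <- function(structure, mature_interval, min_paired_frac = 0.6) {
  partner <- pairing_partners(structure)
  n <- length(partner)
  a <- mature_interval[1]
  b <- mature_interval[2]
  stopifnot(a >= 1, b <= n, a <= b)
  idx <- a:b
  p <- partner[idx]
  # only pairs reaching outside the mature interval define the duplex;
  # stray local pairs within the mature are ignored
  outside <- !is.na(p) & (p < a | p > b)
  if (sum(outside) / length(idx) < min_paired_frac) {
    return(structure(integer(0), reason = "unpaired"))
  }
  q <- p[outside]
  if (any(q > b) && any(q < a)) {
    return(structure(integer(0), reason = "loop_spanning"))
  }
  # along an antiparallel stem i + partner(i) is constant; anchor the star
  # on the modal register so spurious off-register pairs cannot skew it
  reg <- idx[outside] + q
  tab <- table(reg)
  c0 <- as.integer(names(tab)[order(-tab, as.integer(names(tab)))][1])
  s_lo <- c0 - (b - 2L)
  s_hi <- c0 - a + 2L
  star <- c(max(1L, min(s_lo, s_hi)), min(n, max(s_lo, s_hi)))
  if (star[1] <= b && star[2] >= a) {
    return(structure(integer(0), reason = "loop_spanning"))
  }
  star
}

#' miRNA/miRNA* duplex statistics
#'
#' Walks the duplex columns between the mature and star intervals
#' (excluding the 2-nt 3' overhangs), using the paired columns as alignment
#' anchors. Symmetric unpaired columns whose facing bases cannot pair
#' (neither Watson-Crick nor G:U) count as mismatches; asymmetric runs of
#' unpaired positions on one strand count as bulges (one bulge per run,
#' regardless of its length). Short off-register pairing islands, an
#' artifact of maximum base pairing around non-complementary columns, are
#' collapsed before counting.
#'
#' @param structure a `secondary_structure`.
#' @param mature_interval,star_interval 1-based `c(start, end)` intervals;
#'   they must not overlap.
#' @return list with `mismatches`, `bulges`, `mature_interval`,
#'   `star_interval`.
#' @export
duplex_stats <- function(structure, mature_interval, star_interval) {
  a <- mature_interval[1]; b <- mature_interval[2]
  s1 <- star_interval[1]; s2 <- star_interval[2]
  if (max(a, s1) <= min(b, s2)) stop("mature and star intervals overlap")
  partner <- pairing_partners(structure)
  # duplex region: drop each strand's 2-nt 3' overhang (always the last two
  # positions of the interval in sequence orientation)
  m_hi <- b - 2L
  s_lo <- s1
  s_hi <- s2 - 2L
  # anchor columns: mature positions paired into the star duplex region.
  # Nestedness makes their partners strictly decreasing, so the anchors
  # are an antiparallel alignment chain; the regions between consecutive
  # anchors are scored as min(di, dj) symmetric mismatch columns plus one
  # bulge whenever the two sides differ in length.
  anchors_i <- integer(0)
  for (i in a:m_hi) {
    p <- partner[i]
    if (!is.na(p) && p >= s_lo && p <= s_hi) {
      if (length(anchors_i) == 0 || p < partner[anchors_i[length(anchors_i)]]) {
        anchors_i <- c(anchors_i, i)
      }
    }
  }
  # maximum base pairing turns a single non-complementary column into two
  # compensating one-sided gaps by briefly shifting the pairing register;
  # drop such short off-register islands (< 3 anchors) so they score as the
  # symmetric mismatches they represent, keeping bulge counts for genuine
  # one-sided runs only
  if (length(anchors_i) > 0) {
    reg <- anchors_i + partner[anchors_i]
    runs <- rle(reg)
    keep_run <- runs$lengths >= 3L
    if (!any(keep_run)) keep_run[which.max(runs$lengths)] <- TRUE
    anchors_i <- anchors_i[rep(keep_run, runs$lengths)]
  }
  ai <- c(a - 1L, anchors_i, m_hi + 1L)
  aj <- c(s_hi + 1L, partner[anchors_i], s_lo - 1L)
  seq_ch <- strsplit(as_rna(structure$sequence), "")[[1]]
  complementary <- function(x, y) {
    (x == "A" && y == "U") || (x == "U" && y == "A") ||
      (x == "C" && y == "G") || (x == "G" && y == "C") ||
      (x == "G" && y == "U") || (x == "U" && y == "G")
  }
  mm <- 0L
  bulges <- 0L
  for (k in seq_len(length(ai) - 1L)) {
    di <- ai[k + 1L] - ai[k] - 1L
    dj <- aj[k] - aj[k + 1L] - 1L
    # symmetric columns in the gap are duplex mismatches only when the
    # facing bases truly cannot pair; columns the traceback merely left
    # unpaired (or re-paired off-register) are not duplex defects
    for (t in seq_len(min(di, dj))) {
      x <- seq_ch[ai[k] + t]
      y <- seq_ch[aj[k] - t]
      if (!complementary(x, y)) mm <- mm + 1L
    }
    if (di != dj) bulges <- bulges + 1L
  }
  list(mismatches = mm, bulges = bulges,
       mature_interval = mature_interval, star_interval = star_interval)
}

#' Accept or reject a hairpin candidate
#'
#' @param stats duplex statistics from [duplex_stats()].
#' @param star_reads number of reads supporting the star interval.
#' @param known is the mature read already a known-miRNA match?
#' @param max_mismatches,max_bulges duplex ceilings (defaults 6 and 3).
#' @return verdict string: `"accepted"` or `"rejected:<reason>"` with
#'   reason one of `mismatches`, `bulges`, `no_star`, `known`.
#' @export
call_candidate <- function(stats, star_reads, known = FALSE,
                           max_mismatches = 6, max_bulges = 3) {
  if (known) return("rejected:known")
  if (stats$mismatches > max_mismatches) return("rejected:mismatches")
  if (stats$bulges > max_bulges) return("rejected:bulges")
  if (star_reads < 1) return("rejected:no_star")
  "accepted"
}

# Count star-supporting reads: collapsed reads whose exact occurrence in the
# window lies within the star interval extended by +/- shift_tol at each end.
count_star_reads <- function(window_seq, star_interval, reads,
                             mature_seq, shift_tol = 2) {
  lo <- max(1L, star_interval[1] - shift_tol)
  hi <- min(nchar(window_seq), star_interval[2] + shift_tol)
  total <- 0L
  for (i in seq_len(nrow(reads))) {
    s <- reads$sequence[i]
    if (s == mature_seq) next
    p <- regexpr(s, window_seq, fixed = TRUE)[1]
    if (p < 0) next
    if (p >= lo && (p + nchar(s) - 1L) <= hi) total <- total + reads$count[i]
  }
  total
}

#' Discover novel miRNA hairpin candidates
#'
#' For every genome hit of an unannotated read, excises flanking windows,
#' folds them, locates the miRNA*, scores the duplex and applies the
#' acceptance criteria. Among a hit's accepted windows the one with the
#' fewest mismatches + bulges, then the shortest precursor, is reported
#' (one candidate per locus).
#'
#' @param mapping result of [map_reads()] (hits carry `sequence`/`count`).
#' @param reads collapsed read table (used to find star-supporting reads).
#' @param index a [build_index()] object.
#' @param known_sequences character vector of read sequences already matched
#'   to known miRNAs (excluded from candidacy).
#' @param max_mismatches,max_bulges duplex ceilings (defaults 6 and 3).
#' @param min_paired_frac star-search pairing threshold (default 0.6).
#' @param max_hits_per_read skip reads with more genomic placements than
#'   this (already enforced upstream by [map_reads()]).
#' @return data frame of class `hairpin_candidates`: one row per accepted
#'   candidate with locus, mature sequence (RNA), length, abundance,
#'   precursor sequence, dot-bracket, duplex statistics and star-read count.
#' @export
discover_hairpins <- function(mapping, reads, index,
                              known_sequences = character(),
                              max_mismatches = 6, max_bulges = 3,
                              min_paired_frac = 0.6,
                              max_hits_per_read = 20) {
  hits <- mapping$hits
  out <- list()
  if (nrow(hits) > 0) {
    for (r in unique(hits$read_id)) {
      rh <- hits[hits$read_id == r, ]
      mature_seq <- rh$sequence[1]
      if (mature_seq %in% known_sequences) next
      if (nrow(rh) > max_hits_per_read) next
      for (k in seq_len(nrow(rh))) {
        hit <- rh[k, ]
        wins <- excise_windows(hit, index)
        best <- NULL
        for (w in seq_len(nrow(wins))) {
          win <- wins[w, ]
          st <- fold(win$seq)
          m_iv <- c(win$read_start, win$read_start + win$read_len - 1L)
          star <- find_star(st, m_iv, min_paired_frac = min_paired_frac)
          if (length(star) == 0) next
          ds <- tryCatch(duplex_stats(st, m_iv, star),
                         error = function(e) NULL)
          if (is.null(ds)) next
          n_star <- count_star_reads(win$seq, star, reads, mature_seq)
          verdict <- call_candidate(ds, n_star, known = FALSE,
                                    max_mismatches = max_mismatches,
                                    max_bulges = max_bulges)
          if (verdict != "accepted") next
          cand <- list(win = win, st = st, ds = ds, n_star = n_star,
                       key = c(ds$mismatches + ds$bulges, nchar(win$seq)))
          if (is.null(best) ||
              cand$key[1] < best$key[1] ||
              (cand$key[1] == best$key[1] && cand$key[2] < best$key[2])) {
            best <- cand
          }
        }
        if (!is.null(best)) {
          out[[length(out) + 1L]] <- data.frame(
            read_id = r, chrom = hit$chrom,
            start = best$win$win_start, end = best$win$win_end,
            strand = hit$strand,
            mature_seq = as_rna(mature_seq), length = nchar(mature_seq),
            abundance = hit$count,
            precursor_seq = best$win$seq,
            dotbracket = best$st$dotbracket,
            mismatches = best$ds$mismatches, bulges = best$ds$bulges,
            star_start = best$ds$star_interval[1],
            star_end = best$ds$star_interval[2],
            star_reads = best$n_star,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  cand <- if (length(out) == 0) {
    data.frame(read_id = character(), chrom = character(), start = integer(),
               end = integer(), strand = character(),
               mature_seq = character(), length = integer(),
               abundance = integer(), precursor_seq = character(),
               dotbracket = character(), mismatches = integer(),
               bulges = integer(), star_start = integer(),
               star_end = integer(), star_reads = integer(),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, out)
  }
  class(cand) <- c("hairpin_candidates", "data.frame")
  cand
}

#' Write hairpin candidates as a TSV plus a structure file
#'
#' The TSV mirrors the standard novel-candidate table (name, sequence,
#' length, abundance, chromosome); the structure file holds sequence and
#' dot-bracket per candidate in a FASTA-like layout.
#'
#' @param candidates a `hairpin_candidates` data frame.
#' @param tsv_path,structure_path output paths (either may be `NULL`).
#' @export
write_candidates <- function(candidates, tsv_path = NULL,
                             structure_path = NULL) {
  name <- sprintf("Can_miR_%02d", seq_len(nrow(candidates)))
  if (!is.null(tsv_path)) {
    tab <- data.frame(name = name, sequence = candidates$mature_seq,
                      length = candidates$length,
                      abundance = candidates$abundance,
                      chromosome = candidates$chrom,
                      start = candidates$start, strand = candidates$strand)
    write.table(tab, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(structure_path)) {
    lines <- unlist(lapply(seq_len(nrow(candidates)), function(i) {
      c(paste0(">", name[i]), as_rna(candidates$precursor_seq[i]),
        candidates$dotbracket[i])
    }))
    writeLines(lines, structure_path)
  }
  invisible(candidates)
}
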