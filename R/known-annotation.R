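# Known-miRNA annotation: gapless comparison of reads to catalog precursors
# within +/-2 nt of each annotated mature position, tolerating up to two
# mismatches; miRNA/miRNA* accounting and per-family abundance tables.

#' Load or build a known-miRNA catalog
#'
#' A catalog links each mature miRNA to its precursor with the mature's
#' 0-based offset on the precursor and the arm it sits on.
#'
#' @param mature named character vector (or FASTA path) of mature sequences.
#' @param precursors named character vector (or FASTA path) of precursors.
#' @param links data frame (or TSV path) with columns `name`,
#'   `precursor_id`, `offset` (0-based) and `arm` (`5p`/`3p`).
#' @return object of class `mirna_catalog`: data frame with one row per
#'   mature record and the precursor sequence attached.
#' @export
mirna_catalog <- function(mature, precursors, links) {
  read_seqs <- function(x) {
    if (is.character(x) && length(x) == 1 && file.exists(x)) {
      as.character(Biostrings::readDNAStringSet(x))
    } else x
  }
  mature <- canon_dna(read_seqs(mature))
  precursors <- canon_dna(read_seqs(precursors))
  if (is.character(links) && length(links) == 1 && file.exists(links)) {
    links <- read.delim(links, stringsAsFactors = FALSE)
  }
  stopifnot(all(c("name", "precursor_id", "offset", "arm") %in%
                  names(links)),
            all(links$name %in% names(mature)),
            all(links$precursor_id %in% names(precursors)))
  cat_df <- data.frame(
    name = links$name,
    sequence = unname(mature[links$name]),
    precursor_id = links$precursor_id,
    precursor_seq = unname(precursors[links$precursor_id]),
    offset = as.integer(links$offset),
    arm = links$arm,
    stringsAsFactors = FALSE)
  # invariant: the mature sequence occurs at its recorded precursor offset
  at <- substr(cat_df$precursor_seq, cat_df$offset + 1L,
               cat_df$offset + nchar(cat_df$sequence))
  if (!all(at == cat_df$sequence)) {
    stop("mature sequence does not occur at its recorded precursor offset: ",
         paste(cat_df$name[at != cat_df$sequence], collapse = ", "))
  }
  class(cat_df) <- c("mirna_catalog", "data.frame")
  cat_df
}

#' Match a read against the known-miRNA catalog
#'
#' Gapless (Hamming) comparison of the read to each precursor position whose
#' implied 5'/3' shifts from the annotated mature ends are both within
#' +/-2 nt. The best match has the fewest mismatches, then the smallest
#' `|shift5| + |shift3|`, then the lexicographically smallest miRNA name.
#'
#' @param sequence read sequence.
#' @param catalog a [mirna_catalog()].
#' @param max_mismatch mismatch ceiling (default 2).
#' @param max_shift positional-variant tolerance in nt (default 2).
#' @return one-row data frame (`mirna_name`, `mismatches`, `shift5`,
#'   `shift3`, `precursor_id`, `precursor_start`) or `NULL` if no catalog
#'   window is within the mismatch ceiling.
#' @export
match_to_catalog <- function(sequence, catalog, max_mismatch = 2,
                             max_shift = 2) {
  sequence <- canon_dna(sequence)
  L <- nchar(sequence)
  best <- NULL
  for (i in seq_len(nrow(catalog))) {
    rec <- catalog[i, ]
    s <- rec$offset + 1L                      # 1-based mature start
    e <- rec$offset + nchar(rec$sequence)     # 1-based mature end
    P <- nchar(rec$precursor_seq)
    for (shift5 in -max_shift:max_shift) {
      a <- s + shift5
      b <- a + L - 1L
      shift3 <- b - e
      if (abs(shift3) > max_shift) next
      if (a < 1L || b > P) next
      mm <- hamming(sequence, substr(rec$precursor_seq, a, b))
      if (mm > max_mismatch) next
      cand <- data.frame(mirna_name = rec$name, mismatches = mm,
                         shift5 = shift5, shift3 = shift3,
                         precursor_id = rec$precursor_id,
                         precursor_start = a - 1L,
                         stringsAsFactors = FALSE)
      if (is.null(best) ||
          mm < best$mismatches ||
          (mm == best$mismatches &&
             abs(shift5) + abs(shift3) <
               abs(best$shift5) + abs(best$shift3)) ||
          (mm == best$mismatches &&
             abs(shift5) + abs(shift3) ==
               abs(best$shift5) + abs(best$shift3) &&
             rec$name < best$mirna_name)) {
        best <- cand
      }
    }
  }
  best
}

#' Annotate a collapsed read table against the catalog
#'
#' @param reads data frame with `sequence` and `count` columns.
#' @param catalog a [mirna_catalog()].
#' @param structures optional named list of `secondary_structure` objects
#'   per precursor id; when supplied, each match is additionally flagged as
#'   star / mature-arm via [assign_star()].
#' @inheritParams match_to_catalog
#' @return data frame of matches (one row per matched read) with columns
#'   `sequence`, `count`, `mirna_name`, `mismatches`, `shift5`, `shift3`,
#'   `precursor_id`, `precursor_start`, `is_star` (logical, `NA` when
#'   undetermined or no structure given).
#' @export
annotate_reads <- function(reads, catalog, structures = NULL,
                           max_mismatch = 2, max_shift = 2) {
  rows <- list()
  for (i in seq_len(nrow(reads))) {
    m <- match_to_catalog(reads$sequence[i], catalog,
                          max_mismatch = max_mismatch,
                          max_shift = max_shift)
    if (is.null(m)) next
    is_star <- NA
    if (!is.null(structures) && m$precursor_id %in% names(structures)) {
      rec <- catalog[match(m$mirna_name, catalog$name), ]
      iv <- c(m$precursor_start + 1L,
              m$precursor_start + nchar(reads$sequence[i]))
      is_star <- assign_star(structures[[m$precursor_id]], iv, rec$arm)
    }
    rows[[length(rows) + 1L]] <-
      cbind(data.frame(sequence = reads$sequence[i], count = reads$count[i],
                       stringsAsFactors = FALSE),
            m, data.frame(is_star = is_star))
  }
  if (length(rows) == 0) {
    return(data.frame(sequence = character(), count = integer(),
                      mirna_name = character(), mismatches = integer(),
                      shift5 = integer(), shift3 = integer(),
                      precursor_id = character(),
                      precursor_start = integer(), is_star = logical(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Decide whether a precursor interval is on the star arm
#'
#' Uses the precursor's folded structure: the hairpin loop separates the 5p
#' and 3p arms; a read lying entirely on the arm opposite the annotated
#' mature arm is a miRNA* read. Loop-spanning reads are undetermined.
#'
#' @param structure `secondary_structure` of the precursor.
#' @param interval 1-based `c(start, end)` of the read on the precursor.
#' @param mature_arm annotated arm of the mature miRNA (`5p`/`3p`).
#' @return `TRUE` (star), `FALSE` (mature arm) or `NA` (undetermined:
#'   loop-spanning read or unarmed structure).
#' @export
assign_star <- function(structure, interval, mature_arm) {
  arms <- hairpin_arms(structure)
  if (is.null(arms)) return(NA)
  read_arm <- if (interval[2] <= arms$loop[1] - 1L) "5p"
  else if (interval[1] >= arms$loop[2] + 1L) "3p"
  else return(NA)
  read_arm != mature_arm
}

# Locate the main hairpin loop: among all hairpin-closing pairs (no pairs
# inside), take the one enclosed by the most outer pairs (the longest stem).
hairpin_arms <- function(structure) {
  partner <- tryCatch(pairing_partners(structure), error = function(e) NULL)
  if (is.null(partner) || all(is.na(partner))) return(NULL)
  open <- which(!is.na(partner) & partner > seq_along(partner))
  closing <- open[vapply(open, function(i)
    all(is.na(partner[seq(i + 1L, partner[i] - 1L)])), logical(1))]
  if (length(closing) == 0) return(NULL)
  depth <- vapply(closing, function(i)
    sum(open < i & partner[open] > partner[i]), integer(1))
  i5 <- closing[which.max(depth)]
  list(loop = c(i5 + 1L, partner[i5] - 1L))
}

#' Strip a miRNA name to its family
#'
#' `miR159a.2 -> miR159`, `miR444b.2 -> miR444`, `miR1874-5p -> miR1874`,
#' `miR171b-f -> miR171`, `*miR1867 -> miR1867`. Names without a
#' `miR<number>` core are returned unchanged.
#'
#' @param name character vector of miRNA names.
#' @return character vector of family names.
#' @export
mirna_family <- function(name) {
  x <- sub("^\\*", "", name)
  x <- sub("\\*$", "", x)
  has_core <- grepl("miR[0-9]+", x)
  x[has_core] <- sub("^(.*?miR[0-9]+).*$", "\\1", x[has_core])
  x
}

#' Per-miRNA and per-family abundance tables
#'
#' Sums read counts (not unique sequences) per miRNA name; star-flagged
#' reads are tallied separately. Family counts aggregate member counts.
#'
#' @param matches data frame from [annotate_reads()].
#' @return list with `per_mirna` (mirna_name, family, reads, star_reads)
#'   and `per_family` (family, reads, star_reads), both sorted by
#'   descending read count.
#' @export
family_table <- function(matches) {
  if (nrow(matches) == 0) {
    per_mirna <- data.frame(mirna_name = character(), family = character(),
                            reads = integer(), star_reads = integer(),
                            stringsAsFactors = FALSE)
    per_family <- data.frame(family = character(), reads = integer(),
                             star_reads = integer(), stringsAsFactors = FALSE)
    return(list(per_mirna = per_mirna, per_family = per_family))
  }
  star <- !is.na(matches$is_star) & matches$is_star
  names_all <- sort(unique(matches$mirna_name))
  sum_by <- function(df) {
    if (nrow(df) == 0) return(setNames(rep(0L, length(names_all)),
                                       names_all))
    s <- tapply(df$count, factor(df$mirna_name, levels = names_all), sum,
                default = 0L)
    as.integer(s)
  }
  per_mirna <- data.frame(
    mirna_name = names_all,
    family = mirna_family(names_all),
    reads = sum_by(matches[!star, , drop = FALSE]),
    star_reads = sum_by(matches[star, , drop = FALSE]),
    stringsAsFactors = FALSE)
  per_mirna <- per_mirna[order(-per_mirna$reads, per_mirna$mirna_name), ]
  rownames(per_mirna) <- NULL
  fams <- sort(unique(per_mirna$family))
  ffac <- factor(per_mirna$family, levels = fams)
  pf <- data.frame(
    family = fams,
    reads = as.integer(tapply(per_mirna$reads, ffac, sum, default = 0L)),
    star_reads = as.integer(tapply(per_mirna$star_reads, ffac, sum,
                                   default = 0L)),
    stringsAsFactors = FALSE)
  pf <- pf[order(-pf$reads, pf$family), ]
  rownames(pf) <- NULL
  list(per_mirna = per_mirna, per_family = pf)
}
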