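# Synthetic-data module: genomes with planted miRNA hairpins, read
# populations with a realistic length structure, contaminant catalogs and
# three-stage chip signal tables -- all seeded and with ground truth attached,
# so every downstream stage can be tested without external downloads.

#' Construct a planted miRNA hairpin
#'
#' Builds a precursor of the form `ext5 + arm5 + loop + arm3 + ext3` in which
#' one arm carries the mature miRNA and the opposite arm its (near-)reverse
#' complement. The miRNA* sequence is derived with the canonical Dicer
#' geometry: each strand of the miRNA/miRNA* duplex carries a 2-nt 3'
#' overhang. Up to `star_mutations` positions of the star arm are mutated so
#' duplex imperfections (mismatches/bulges) can be exercised.
#'
#' @param locus_id identifier for the planted locus.
#' @param chrom chromosome name the locus is planted on.
#' @param start 0-based genomic offset of the precursor.
#' @param strand `"+"` or `"-"`.
#' @param mature_seq mature miRNA sequence, 20-24 nt (RNA or DNA alphabet).
#' @param mature_arm `"5p"` or `"3p"`: which arm carries the mature miRNA.
#' @param loop_len hairpin loop length in nt (>= 3).
#' @param ext stem extension below the duplex, in nt (>= 2), paired.
#' @param star_mutations number of star-arm positions to mutate (<= 6).
#' @return an object of class `planted_hairpin`: a list with the precursor
#'   sequence (DNA), 1-based mature/star offsets on the precursor, and the
#'   derived `star_seq`.
#' @export
planted_hairpin <- function(locus_id, chrom, start, strand = "+",
                            mature_seq, mature_arm = c("5p", "3p"),
                            loop_len = 12, ext = 10, star_mutations = 0) {
  mature_arm <- match.arg(mature_arm)
  mature_seq <- canon_dna(mature_seq)
  m <- nchar(mature_seq)
  stopifnot(m >= 20, m <= 24, loop_len >= 3, ext >= 2,
            star_mutations >= 0, star_mutations <= 6,
            strand %in% c("+", "-"))

  loop_seq <- random_dna(loop_len)
  ext3 <- random_dna(ext)
  ext5 <- revcomp(ext3)
  star_arm_seq <- revcomp(mature_seq)
  if (star_mutations > 0) {
    pos <- sample.int(m, star_mutations)
    s <- strsplit(star_arm_seq, "")[[1]]
    for (p in pos) s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1)
    star_arm_seq <- paste(s, collapse = "")
  }

  if (mature_arm == "5p") {
    precursor <- paste0(ext5, mature_seq, loop_seq, star_arm_seq, ext3)
    mature_off <- ext + 1L            # 1-based on precursor
  } else {
    precursor <- paste0(ext5, star_arm_seq, loop_seq, mature_seq, ext3)
    mature_off <- ext + m + loop_len + 1L
  }
  P <- nchar(precursor)
  a <- mature_off
  b <- mature_off + m - 1L
  # Perfect-stem partner of position i is P + 1 - i; the star interval has a
  # 2-nt 3' overhang on each duplex strand.
  star_off <- P + 3L - b
  star_end <- P + 3L - a
  stopifnot(star_off >= 1L, star_end <= P)
  star_seq <- substr(precursor, star_off, star_end)

  structure(list(
    locus_id = as.character(locus_id), chrom = as.character(chrom),
    start = as.integer(start), strand = strand,
    mature_seq = mature_seq, star_seq = star_seq, loop_seq = loop_seq,
    mature_arm = mature_arm, precursor_seq = precursor,
    mature_off = as.integer(mature_off), star_off = as.integer(star_off)
  ), class = "planted_hairpin")
}

#' @export
print.planted_hairpin <- function(x, ...) {
  cat(sprintf("<planted_hairpin %s %s:%d(%s) mature %s arm %s>\n",
              x$locus_id, x$chrom, x$start, x$strand,
              as_rna(x$mature_seq), x$mature_arm))
  invisible(x)
}

#' Generate a synthetic genome with planted hairpins
#'
#' Background sequence is i.i.d. uniform over ACGT; each planted precursor is
#' written at its recorded 0-based coordinate (reverse-complemented first for
#' minus-strand loci). Overlapping planted loci are rejected.
#'
#' @param n_chroms number of chromosomes.
#' @param chrom_len length of each chromosome in nt.
#' @param hairpins list of [planted_hairpin()] objects (possibly empty).
#' @param seed integer seed; identical calls are byte-reproducible.
#' @return list with `genome` (a named [Biostrings::DNAStringSet]) and
#'   `truth` (data frame, one row per planted locus; 0-based offsets).
#' @export
generate_genome <- function(n_chroms, chrom_len, hairpins = list(), seed = 1) {
  stopifnot(n_chroms >= 1, chrom_len >= 1)
  set.seed(substream_seed(seed, "genome"))
  chrom_names <- paste0("chr", seq_len(n_chroms))
  seqs <- setNames(random_dna(rep(chrom_len, n_chroms)), chrom_names)

  if (length(hairpins) > 0) {
    ivs <- data.frame(
      locus = vapply(hairpins, `[[`, "", "locus_id"),
      chrom = vapply(hairpins, `[[`, "", "chrom"),
      start = vapply(hairpins, function(h) h$start, integer(1)),
      end = vapply(hairpins, function(h) h$start + nchar(h$precursor_seq),
                   integer(1))
    )
    stopifnot(all(ivs$chrom %in% chrom_names), all(ivs$start >= 0),
              all(ivs$end <= chrom_len))
    for (cn in unique(ivs$chrom)) {
      v <- ivs[ivs$chrom == cn, ]
      v <- v[order(v$start), ]
      if (nrow(v) > 1) {
        bad <- which(v$start[-1] < v$end[-nrow(v)])
        if (length(bad) > 0) {
          stop(sprintf("planted loci overlap on %s: %s and %s", cn,
                       v$locus[bad[1]], v$locus[bad[1] + 1]))
        }
      }
    }
    for (h in hairpins) {
      ins <- if (h$strand == "+") h$precursor_seq else revcomp(h$precursor_seq)
      substr(seqs[[h$chrom]], h$start + 1L, h$start + nchar(ins)) <- ins
    }
  }

  truth <- if (length(hairpins) == 0) {
    data.frame(locus_id = character(), chrom = character(), start = integer(),
               strand = character(), precursor_seq = character(),
               mature_seq = character(), star_seq = character(),
               mature_arm = character(), mature_off = integer(),
               star_off = integer(), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, lapply(hairpins, function(h) {
      data.frame(locus_id = h$locus_id, chrom = h$chrom, start = h$start,
                 strand = h$strand, precursor_seq = h$precursor_seq,
                 mature_seq = h$mature_seq, star_seq = h$star_seq,
                 mature_arm = h$mature_arm, mature_off = h$mature_off,
                 star_off = h$star_off, stringsAsFactors = FALSE)
    }))
  }
  list(genome = Biostrings::DNAStringSet(seqs), truth = truth)
}

#' Read-length profile over 18-26 nt
#'
#' @param probabilities named numeric vector mapping read length (18-26) to
#'   its fraction; fractions must sum to 1 within 1e-9.
#' @return object of class `read_length_profile`.
#' @export
read_length_profile <- function(probabilities) {
  lens <- as.integer(names(probabilities))
  if (any(is.na(lens)) || any(lens < 18) || any(lens > 26)) {
    stop("profile lengths must be integers in 18..26")
  }
  if (abs(sum(probabilities) - 1) > 1e-9) stop("fractions must sum to 1")
  structure(list(lengths = lens, prob = as.numeric(probabilities)),
            class = "read_length_profile")
}

#' Default read-length profile of a grain small-RNA library
#'
#' Bimodal at 21 and 24 nt (fractions 0.223 and 0.505, matching the observed
#' size structure of grain small-RNA populations); the remaining 0.272 is
#' spread uniformly over the other lengths in 18-26.
#' @return a [read_length_profile()].
#' @export
grain_length_profile <- function() {
  other <- setdiff(18:26, c(21L, 24L))
  p <- setNames(rep((1 - 0.223 - 0.505) / length(other), length(other)),
                other)
  p <- c(p, "21" = 0.223, "24" = 0.505)
  read_length_profile(p[order(as.integer(names(p)))])
}

#' Generate a contaminant catalog
#'
#' Random rRNA/tRNA/snoRNA-like sequences used both to spike simulated read
#' populations and as the removal catalog during preprocessing.
#'
#' @param n number of catalog sequences.
#' @param len_range length range to draw from.
#' @param seed integer seed.
#' @return named character vector of DNA sequences.
#' @export
make_contaminants <- function(n = 10, len_range = c(80L, 160L), seed = 1) {
  set.seed(substream_seed(seed, "contaminants"))
  classes <- c("rRNA", "tRNA", "snRNA", "snoRNA")
  lens <- sample(seq(len_range[1], len_range[2]), n, replace = TRUE)
  setNames(random_dna(lens),
           paste0(sample(classes, n, replace = TRUE), "_", seq_len(n)))
}

# End-shifted copy of the mature/star sequence, read off the precursor.
shift_on_precursor <- function(precursor, off, len, d5, d3) {
  a <- off + d5
  b <- off + len - 1L + d3
  if (a < 1L || b > nchar(precursor) || (b - a + 1L) < 18L ||
      (b - a + 1L) > 26L) {
    return(substr(precursor, off, off + len - 1L))
  }
  substr(precursor, a, b)
}

#' Simulate a small-RNA read population
#'
#' Mixes mature and star reads from planted hairpins, contaminant fragments
#' and random background reads. Background/contaminant lengths follow the
#' supplied profile; mature/star reads keep their planted lengths, optionally
#' with uniform end shifts in -2..+2 at rate `shift_rate` (isomiRs).
#'
#' @param truth truth table from [generate_genome()].
#' @param profile a [read_length_profile()].
#' @param n_reads total number of reads (categories sum exactly to this).
#' @param mature_fraction,star_fraction,contaminant_fraction category mixing
#'   fractions in `[0,1]`, summing to at most 1; the remainder is random
#'   background.
#' @param contaminants named character vector (see [make_contaminants()]);
#'   required when `contaminant_fraction > 0`.
#' @param shift_rate fraction of mature/star reads given random end shifts.
#' @param seed integer seed.
#' @param path optional FASTQ output path (fixed quality `#`).
#' @return data frame with columns `id`, `sequence`, `category`, `locus_id`
#'   (NA for background/contaminant reads), invisibly written to `path` if
#'   given.
#' @export
simulate_reads <- function(truth, profile, n_reads,
                           mature_fraction = 0, star_fraction = 0,
                           contaminant_fraction = 0, contaminants = NULL,
                           shift_rate = 0, seed = 1, path = NULL) {
  stopifnot(inherits(profile, "read_length_profile"))
  fr <- c(mature_fraction, star_fraction, contaminant_fraction)
  if (any(fr < 0) || any(fr > 1) || sum(fr) > 1 + 1e-12) {
    stop("fractions must lie in [0,1] and sum to at most 1")
  }
  if ((mature_fraction > 0 || star_fraction > 0) && nrow(truth) == 0) {
    stop("mature/star fractions need a non-empty truth table")
  }
  if (contaminant_fraction > 0 && is.null(contaminants)) {
    stop("contaminant_fraction > 0 needs a contaminant catalog")
  }
  set.seed(substream_seed(seed, "reads"))
  if (n_reads == 0) {
    out <- data.frame(id = character(), sequence = character(),
                      category = character(), locus_id = character(),
                      stringsAsFactors = FALSE)
  } else {
    category <- sample(c("mature", "star", "contaminant", "background"),
                       n_reads, replace = TRUE,
                       prob = c(fr, 1 - sum(fr)))
    sequence <- character(n_reads)
    locus_id <- rep(NA_character_, n_reads)
    draw_len <- function(k) sample(profile$lengths, k, replace = TRUE,
                                   prob = profile$prob)
    for (i in seq_len(n_reads)) {
      cat_i <- category[i]
      if (cat_i %in% c("mature", "star")) {
        row <- truth[sample.int(nrow(truth), 1), ]
        locus_id[i] <- row$locus_id
        off <- if (cat_i == "mature") row$mature_off else row$star_off
        len <- nchar(if (cat_i == "mature") row$mature_seq else row$star_seq)
        if (shift_rate > 0 && runif(1) < shift_rate) {
          sequence[i] <- shift_on_precursor(row$precursor_seq, off, len,
                                            sample(-2:2, 1), sample(-2:2, 1))
        } else {
          sequence[i] <- substr(row$precursor_seq, off, off + len - 1L)
        }
      } else if (cat_i == "contaminant") {
        src <- contaminants[[sample.int(length(contaminants), 1)]]
        L <- min(draw_len(1), nchar(src))
        p <- sample.int(nchar(src) - L + 1L, 1)
        sequence[i] <- substr(src, p, p + L - 1L)
      } else {
        sequence[i] <- random_dna(draw_len(1))
      }
    }
    out <- data.frame(id = sprintf("read%06d", seq_len(n_reads)),
                      sequence = sequence, category = category,
                      locus_id = locus_id, stringsAsFactors = FALSE)
  }
  if (!is.null(path)) write_fastq(out$sequence, out$id, path)
  out
}

#' Write sequences as FASTQ with a fixed dummy quality
#' @param sequences,ids character vectors of equal length.
#' @param path output file.
#' @export
write_fastq <- function(sequences, ids, path) {
  x <- Biostrings::DNAStringSet(sequences)
  names(x) <- ids
  q <- Biostrings::PhredQuality(vapply(nchar(sequences), function(L)
    strrep("#", L), character(1)))
  xq <- Biostrings::QualityScaledDNAStringSet(x, q)
  Biostrings::writeXStringSet(xq, path, format = "fastq", qualities = q)
  invisible(path)
}

#' Per-probe chip ground truth
#'
#' @param probe_id identifiers.
#' @param base_signal positive baseline intensity per probe.
#' @param multipliers length-3 positive vector (G1, G2, G3) or a 3-column
#'   matrix with one row per probe.
#' @param noise_cv multiplicative noise coefficient of variation (>= 0).
#' @return data frame of class `chip_truth`.
#' @export
chip_truth <- function(probe_id, base_signal, multipliers, noise_cv = 0) {
  if (is.null(dim(multipliers))) {
    multipliers <- matrix(multipliers, nrow = length(probe_id), ncol = 3,
                          byrow = TRUE)
  }
  stopifnot(all(multipliers > 0), all(noise_cv >= 0),
            nrow(multipliers) == length(probe_id))
  out <- data.frame(probe_id = as.character(probe_id),
                    base_signal = base_signal,
                    m_g1 = multipliers[, 1], m_g2 = multipliers[, 2],
                    m_g3 = multipliers[, 3], noise_cv = noise_cv,
                    stringsAsFactors = FALSE)
  class(out) <- c("chip_truth", "data.frame")
  out
}

#' Simulate three-stage chip hybridisation signals
#'
#' Per probe, stage and replicate the emitted signal is
#' `background_mean + base_signal * stage_multiplier * eps_mult + eps_add`,
#' with `eps_mult` log-normal (mean 1, CV = `noise_cv`) and `eps_add`
#' Gaussian with sd `background_sd`. Per-chip background statistics are
#' emitted alongside for background subtraction during normalisation.
#'
#' @param truths a [chip_truth()] table.
#' @param replicates biological replicates per stage (>= 2; default 3).
#' @param background_mean,background_sd chip background mean and sd
#'   (`background_sd` must be non-negative).
#' @param seed integer seed.
#' @return list with `signals` (probe_id, stage, replicate, signal) and
#'   `background` (stage, replicate, bg_mean, bg_sd).
#' @export
simulate_chip <- function(truths, replicates = 3, background_mean = 0,
                          background_sd = 0, seed = 1) {
  stopifnot(inherits(truths, "chip_truth"), replicates >= 2)
  if (background_sd < 0) stop("background_sd must be non-negative")
  set.seed(substream_seed(seed, "chip"))
  stages <- c("G1", "G2", "G3")
  grid <- expand.grid(probe = seq_len(nrow(truths)),
                      stage = seq_along(stages),
                      replicate = seq_len(replicates))
  mult <- as.matrix(truths[, c("m_g1", "m_g2", "m_g3")])
  cv <- truths$noise_cv[grid$probe]
  sdlog <- sqrt(log(1 + cv^2))
  eps_mult <- exp(rnorm(nrow(grid), mean = -sdlog^2 / 2, sd = sdlog))
  eps_add <- rnorm(nrow(grid), 0, background_sd)
  signal <- background_mean +
    truths$base_signal[grid$probe] * mult[cbind(grid$probe, grid$stage)] *
    eps_mult + eps_add
  signals <- data.frame(probe_id = truths$probe_id[grid$probe],
                        stage = stages[grid$stage],
                        replicate = grid$replicate,
                        signal = signal, stringsAsFactors = FALSE)
  signals <- signals[order(signals$probe_id, signals$stage,
                           signals$replicate), ]
  rownames(signals) <- NULL
  background <- expand.grid(stage = stages, replicate = seq_len(replicates),
                            stringsAsFactors = FALSE)
  background$bg_mean <- background_mean
  background$bg_sd <- background_sd
  list(signals = signals, background = background)
}
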