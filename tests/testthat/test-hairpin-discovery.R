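# Handmade duplex structures used to pin down the duplex statistics:
# 24-nt toy precursors with mature on [1,10]/[1,12] and star on [15,24].
struct_of <- function(db, seq = strrep("A", nchar(db))) {
  structure(list(sequence = seq, dotbracket = db,
                 pair_count = sum(strsplit(db, "")[[1]] == "(")),
            class = "secondary_structure")
}

test_that("window excision enumerates 13 x 2 clipped, strand-aware windows", {
  set.seed(51)
  chrom <- rand_dna(2000)
  idx <- build_index(c(chr1 = chrom))
  hit <- data.frame(read_id = "r", chrom = "chr1", start = 1000L,
                    end = 1021L, strand = "+", stringsAsFactors = FALSE)
  wins <- excise_windows(hit, idx)
  expect_equal(nrow(wins), 26)
  expect_true(all(wins$win_start >= 0 & wins$win_end <= 2000))
  expect_true(all(substr(wins$seq, wins$read_start,
                         wins$read_start + 20L) ==
                    substr(chrom, 1001, 1021)))
  # near the chromosome start the upstream windows are clipped (and
  # duplicates collapse)
  hit2 <- transform(hit, start = 30L, end = 51L)
  wins2 <- excise_windows(hit2, idx)
  expect_true(all(wins2$win_start >= 0))
  expect_lt(nrow(wins2), 26)
  # minus-strand windows present the read in sense orientation
  hit3 <- transform(hit, strand = "-")
  wins3 <- excise_windows(hit3, idx)
  expect_true(all(substr(wins3$seq, wins3$read_start,
                         wins3$read_start + 20L) ==
                    revcomp(substr(chrom, 1001, 1021))))
  expect_error(excise_windows(transform(hit, end = 3000L), idx), "bounds")
})

test_that("star interval search honours the 2-nt 3' overhang geometry", {
  set.seed(52)
  h <- planted_hairpin("p", "c", 0, mature_seq = rand_dna(21),
                       mature_arm = "5p")
  st <- fold(h$precursor_seq)
  m_iv <- c(h$mature_off, h$mature_off + 20L)
  star <- find_star(st, m_iv)
  expect_equal(star, c(h$star_off, h$star_off + 20L))
  expect_equal(substr(h$precursor_seq, star[1], star[2]), h$star_seq)
  # mirror case: mature on the 3p arm
  h3 <- planted_hairpin("q", "c", 0, mature_seq = rand_dna(22),
                        mature_arm = "3p")
  st3 <- fold(h3$precursor_seq)
  m3 <- c(h3$mature_off, h3$mature_off + 21L)
  star3 <- find_star(st3, m3)
  expect_equal(substr(h3$precursor_seq, star3[1], star3[2]), h3$star_seq)
})

test_that("unpaired or loop-spanning mature intervals yield no star", {
  # mature fully unpaired
  st <- struct_of(paste0(strrep(".", 10), "((((....))))", strrep(".", 2)))
  out <- find_star(st, c(1, 10))
  expect_length(out, 0)
  expect_equal(attr(out, "reason"), "unpaired")
  # read straddling two stems: partners fall on both sides
  st2 <- struct_of("((((....))))((((....))))")
  out2 <- find_star(st2, c(9, 16))
  expect_length(out2, 0)
  expect_equal(attr(out2, "reason"), "loop_spanning")
})

test_that("duplex statistics count symmetric mismatches and one-sided
           bulges", {
  # perfect duplex: mature [1,10] pairs star [15,24] minus the overhangs
  db_perfect <- paste0(strrep("(", 8), strrep(".", 6), strrep(")", 8), "..")
  ds <- duplex_stats(struct_of(db_perfect), c(1, 10), c(15, 24))
  expect_equal(ds$mismatches, 0L)
  expect_equal(ds$bulges, 0L)
  # one symmetric interior loop of size 1: a mismatch, not a bulge
  db_mm <- "(((.((((......)))).))).."
  ds_mm <- duplex_stats(struct_of(db_mm), c(1, 10), c(15, 24))
  expect_equal(ds_mm$mismatches, 1L)
  expect_equal(ds_mm$bulges, 0L)
  # a 2-nt run unpaired on the mature arm only: one bulge
  db_bulge <- "(((..(((((....)))))))).."
  ds_b <- duplex_stats(struct_of(db_bulge), c(1, 12), c(15, 24))
  expect_equal(ds_b$mismatches, 0L)
  expect_equal(ds_b$bulges, 1L)
  expect_error(duplex_stats(struct_of(db_perfect), c(1, 16), c(15, 24)),
               "overlap")
})

test_that("candidate verdicts follow the duplex and star-evidence criteria", {
  mk <- function(mm, b) list(mismatches = mm, bulges = b)
  expect_equal(call_candidate(mk(2, 1), star_reads = 3), "accepted")
  expect_equal(call_candidate(mk(7, 0), star_reads = 3),
               "rejected:mismatches")
  expect_equal(call_candidate(mk(2, 4), star_reads = 3), "rejected:bulges")
  expect_equal(call_candidate(mk(2, 1), star_reads = 0), "rejected:no_star")
  expect_equal(call_candidate(mk(0, 0), star_reads = 5, known = TRUE),
               "rejected:known")
  # boundary: exactly at the ceilings is accepted
  expect_equal(call_candidate(mk(6, 3), star_reads = 1), "accepted")
})

test_that("acceptance is monotone in the mismatch/bulge ceilings", {
  set.seed(53)
  for (i in 1:50) {
    st <- list(mismatches = sample(0:9, 1), bulges = sample(0:5, 1))
    stars <- sample(0:2, 1)
    hi <- call_candidate(st, stars, max_mismatches = 6, max_bulges = 3)
    lo <- call_candidate(st, stars, max_mismatches = 4, max_bulges = 2)
    if (lo == "accepted") expect_equal(hi, "accepted")
  }
})

test_that("planted hairpins are recovered end to end with no background
           false positives", {
  dir <- tempfile()
  fx <- make_fixture(seed = 101, scale = "tiny", dir = dir)
  run <- suppressWarnings(run_pipeline(fx$config))
  cand <- run$candidates
  overlaps <- function(cand_row, truth_row) {
    cand_row$chrom == truth_row$chrom &
      cand_row$start < truth_row$start +
        nchar(truth_row$precursor_seq) &
      cand_row$end > truth_row$start
  }
  recall <- vapply(seq_len(nrow(fx$truth)), function(i)
    any(vapply(seq_len(nrow(cand)), function(j)
      overlaps(cand[j, ], fx$truth[i, ]), logical(1))), logical(1))
  expect_true(all(recall))
  fp <- vapply(seq_len(nrow(cand)), function(j)
    !any(vapply(seq_len(nrow(fx$truth)), function(i)
      overlaps(cand[j, ], fx$truth[i, ]), logical(1))), logical(1))
  expect_equal(sum(fp), 0)
  # every accepted candidate satisfies the published duplex criteria
  expect_true(all(cand$mismatches <= 6))
  expect_true(all(cand$bulges <= 3))
  expect_true(all(cand$star_reads >= 1))
})

test_that("no candidates are reported from a genome without plants", {
  gen <- generate_genome(1, 8000, list(), seed = 54)
  set.seed(54)
  reads <- collapse_reads(replicate(300, rand_dna(sample(18:26, 1))))
  idx <- build_index(gen$genome)
  mp <- map_reads(reads, idx)
  cand <- discover_hairpins(mp, reads, idx)
  expect_equal(nrow(cand), 0)
})
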