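test_that("generate_genome plants precursors at their recorded coordinates", {
  set.seed(7)
  hps <- lapply(1:3, function(i) {
    planted_hairpin(sprintf("p%d", i), "chr1", 500 + (i - 1) * 2000,
                    strand = c("+", "-", "+")[i],
                    mature_seq = rand_dna(21),
                    mature_arm = c("5p", "3p", "5p")[i])
  })
  gen <- generate_genome(1, 10000, hps, seed = 7)
  expect_equal(nrow(gen$truth), 3)
  chrom <- as.character(gen$genome[["chr1"]])
  for (h in hps) {
    planted <- if (h$strand == "+") h$precursor_seq else
      revcomp(h$precursor_seq)
    # substring-search oracle: the precursor occurs exactly once, at its
    # recorded 0-based offset
    occ <- gregexpr(planted, chrom, fixed = TRUE)[[1]]
    expect_equal(as.integer(occ), h$start + 1L)
  }
})

test_that("generate_genome with no hairpins yields an empty truth table", {
  gen <- generate_genome(1, 10000, list(), seed = 1)
  expect_equal(nrow(gen$truth), 0)
  expect_equal(sum(Biostrings::width(gen$genome)), 10000)
})

test_that("seeded genome generation is byte-reproducible", {
  mk <- function() {
    set.seed(7)
    hps <- lapply(1:3, function(i)
      planted_hairpin(sprintf("p%d", i), "chr1", i * 1000,
                      mature_seq = rand_dna(22)))
    generate_genome(1, 10000, hps, seed = 7)
  }
  g1 <- mk()
  g2 <- mk()
  expect_identical(as.character(g1$genome), as.character(g2$genome))
  expect_identical(g1$truth, g2$truth)
})

test_that("overlapping planted loci are rejected with the locus pair", {
  set.seed(1)
  hps <- list(planted_hairpin("a", "chr1", 100, mature_seq = rand_dna(21)),
              planted_hairpin("b", "chr1", 130, mature_seq = rand_dna(21)))
  expect_error(generate_genome(1, 10000, hps, seed = 1), "a and b")
})

test_that("planted star sequence reverse-complements the mature modulo the
           requested mutations", {
  set.seed(3)
  mat <- rand_dna(21)
  h0 <- planted_hairpin("x", "c", 0, mature_seq = mat, star_mutations = 0)
  # with a perfect stem the 2-nt 3'-overhang geometry shifts the star by
  # two: its first 19 nt equal the reverse complement of mature positions
  # 1..19, i.e. positions 3..21 of revcomp(mature)
  rc <- revcomp(mat)
  expect_equal(nchar(h0$star_seq), nchar(mat))
  expect_equal(substr(h0$star_seq, 1, 19), substr(rc, 3, 21))
  set.seed(3)
  h4 <- planted_hairpin("y", "c", 0, mature_seq = mat, star_mutations = 4)
  star_arm0 <- revcomp(mat)
  # mutated star arm differs from the perfect complement at 1..4 positions
  arm_in_prec <- substr(h4$precursor_seq, h4$star_off - 2L,
                        h4$star_off - 2L + nchar(mat) - 1L)
  d <- sum(strsplit(arm_in_prec, "")[[1]] != strsplit(star_arm0, "")[[1]])
  expect_gte(d, 1)
  expect_lte(d, 4)
})

test_that("read-length profile validation rejects bad inputs", {
  expect_error(read_length_profile(c("17" = 1)), "18")
  expect_error(read_length_profile(c("21" = 0.5, "24" = 0.4)), "sum to 1")
  pr <- grain_length_profile()
  expect_equal(sum(pr$prob), 1, tolerance = 1e-9)
  expect_equal(pr$prob[pr$lengths == 21], 0.223)
  expect_equal(pr$prob[pr$lengths == 24], 0.505)
})

test_that("simulated read lengths follow the bimodal 21/24-nt profile", {
  reads <- simulate_reads(data.frame(), grain_length_profile(),
                          n_reads = 20000, seed = 3)
  f21 <- mean(nchar(reads$sequence) == 21)
  f24 <- mean(nchar(reads$sequence) == 24)
  expect_lt(abs(f21 - 0.223), 0.01)
  expect_lt(abs(f24 - 0.505), 0.01)
})

test_that("read categories are exact and degenerate mixtures behave", {
  set.seed(5)
  h <- planted_hairpin("p1", "chr1", 100, mature_seq = rand_dna(21))
  gen <- generate_genome(1, 2000, list(h), seed = 5)
  reads <- simulate_reads(gen$truth, grain_length_profile(), 500,
                          mature_fraction = 1, seed = 5)
  expect_true(all(reads$sequence == h$mature_seq))
  expect_equal(nrow(reads), 500)

  cont <- make_contaminants(5, seed = 5)
  reads <- simulate_reads(gen$truth, grain_length_profile(), 10000,
                          contaminant_fraction = 0.3, contaminants = cont,
                          seed = 5)
  n_cont <- sum(reads$category == "contaminant")
  # binomial 99% interval computed independently
  expect_gte(n_cont, qbinom(0.005, 10000, 0.3))
  expect_lte(n_cont, qbinom(0.995, 10000, 0.3))
  expect_equal(as.integer(table(factor(reads$category,
    c("mature", "star", "contaminant", "background")))) |> sum(), 10000)

  empty <- simulate_reads(gen$truth, grain_length_profile(), 0, seed = 1)
  expect_equal(nrow(empty), 0)
})

test_that("noiseless chip simulation propagates multipliers exactly", {
  tr <- chip_truth("p1", 53, c(1, 1, 5.53), noise_cv = 0)
  chip <- simulate_chip(tr, replicates = 3, background_mean = 0,
                        background_sd = 0, seed = 1)
  means <- tapply(chip$signals$signal, chip$signals$stage, mean)
  expect_equal(as.numeric(means[c("G1", "G2", "G3")]), c(53, 53, 293.09),
               tolerance = 1e-12)

  flat <- chip_truth(c("a", "b"), c(100, 200), c(1, 1, 1), noise_cv = 0)
  cf <- simulate_chip(flat, replicates = 3, seed = 1)
  m <- tapply(cf$signals$signal, list(cf$signals$probe_id,
                                      cf$signals$stage), mean)
  expect_true(all(abs(fold_change(m[, "G1"], m[, "G2"]) - 1) < 1e-9))
})

test_that("chip noise_cv is recovered from simulated replicates", {
  n <- 1000
  tr <- chip_truth(sprintf("p%04d", 1:n), 1000, c(1, 1, 1), noise_cv = 0.1)
  chip <- simulate_chip(tr, replicates = 3, background_mean = 0,
                        background_sd = 0, seed = 11)
  cvs <- tapply(chip$signals$signal,
                list(chip$signals$probe_id, chip$signals$stage),
                function(x) sd(x) / mean(x))
  expect_lt(abs(mean(cvs) - 0.1) / 0.1, 0.2)
})

test_that("chip simulation rejects invalid designs", {
  tr <- chip_truth("p1", 10, c(1, 1, 1))
  expect_error(simulate_chip(tr, replicates = 1), "replicates")
  expect_error(simulate_chip(tr, background_sd = -1), "non-negative")
  expect_error(chip_truth("p1", 10, c(1, 0, 1)), "multipliers > 0")
})
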