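mk_signals <- function(values) {
  # values: named list chip -> numeric vector of probe signals
  do.call(rbind, lapply(names(values), function(cid) {
    parts <- strsplit(cid, ":")[[1]]
    data.frame(probe_id = sprintf("p%02d", seq_along(values[[cid]])),
               stage = parts[1], replicate = as.integer(parts[2]),
               signal = values[[cid]], stringsAsFactors = FALSE)
  }))
}

test_that("normalisation subtracts background, floors at zero and median-
           scales to the reference chip", {
  sig <- mk_signals(list("G1:1" = c(50, 100, 150),
                         "G2:1" = c(100, 200, 300)))
  bg <- data.frame(stage = c("G1", "G2"), replicate = 1L, bg_mean = 0,
                   bg_sd = 1)
  out <- normalize_chip(sig, bg)
  # chip medians 100 and 200 -> factors 1.0 and 0.5 against reference 100
  expect_equal(out$signal[out$stage == "G2"], c(50, 100, 150))
  expect_equal(out$signal[out$stage == "G1"], c(50, 100, 150))
  # raw below background floors at 0
  sig2 <- mk_signals(list("G1:1" = c(5, 100, 195)))
  bg2 <- data.frame(stage = "G1", replicate = 1L, bg_mean = 10, bg_sd = 1)
  out2 <- normalize_chip(sig2, bg2)
  expect_equal(out2$signal[1], 0)
  # identical chips: normalisation is the identity
  sig3 <- mk_signals(list("G1:1" = c(10, 20, 30), "G2:1" = c(10, 20, 30)))
  bg3 <- data.frame(stage = c("G1", "G2"), replicate = 1L, bg_mean = 0,
                    bg_sd = 1)
  expect_equal(normalize_chip(sig3, bg3)$signal, sig3$signal)
  expect_error(normalize_chip(sig, bg[1, ]), "missing background")
})

test_that("detection gates on background SD, CV, repeat spots and floor", {
  # mean 31 fails only the absolute floor
  d1 <- detect_call(c(31, 31, 31), background_sd = 5)
  expect_false(d1$detected)
  expect_equal(d1$reasons, "below_floor")
  # high CV fails
  d2 <- detect_call(c(100, 500, 900), background_sd = 5)
  expect_false(d2$detected)
  expect_true("cv_fail" %in% d2$reasons)
  # all gates pass
  d3 <- detect_call(c(480, 500, 520), background_sd = 50)
  expect_true(d3$detected)
  expect_equal(d3$reasons, character(0))
  # weak signal relative to background noise
  d4 <- detect_call(c(120, 130, 125), background_sd = 50)
  expect_false(d4$detected)
  expect_equal(d4$reasons, "below_3sd")
  # repeat probes below the 50% agreement threshold
  d5 <- detect_call(c(480, 500, 520), background_sd = 5,
                    repeat_pass_fraction = 0.4)
  expect_equal(d5$reasons, "repeat_probe_fail")
})

test_that("detection is monotone in mean signal at fixed cv", {
  means <- c(20, 40, 80, 160, 320)
  det <- vapply(means, function(m)
    detect_call(m * c(0.95, 1, 1.05), background_sd = 20)$detected,
    logical(1))
  expect_equal(det, sort(det))
})

test_that("fold changes reproduce printed values and are reciprocal", {
  expect_equal(fold_change(53, 293), 5.53)
  expect_equal(fold_change(349, 1140), 3.27)
  expect_equal(fold_change(100, 100), 1.00)
  expect_error(fold_change(0, 10), "zero_denominator")
  set.seed(71)
  for (i in 1:50) {
    a <- runif(1, 100, 5000); b <- a * runif(1, 0.25, 4)
    # reciprocity within the error budget of two half-up roundings
    expect_equal(fold_change(a, b) * fold_change(b, a), 1,
                 tolerance = 0.05)
  }
  # half-up rounding at 2 decimals (banker's rounding would give 0.12)
  expect_equal(fold_change(1000, 125), 0.13)
})

test_that("the stage t-test matches a closed-form computation", {
  expect_equal(differential_test(c(5, 5, 5), c(5, 5, 5)), 1)
  # equal-variance two-sample t on raw scale, checked against the formula
  x <- c(1, 2, 3); y <- c(4, 5, 6)
  tstat <- (mean(x) - mean(y)) /
    (sqrt((2 * var(x) + 2 * var(y)) / 4) * sqrt(1 / 3 + 1 / 3))
  p_ref <- 2 * pt(-abs(tstat), df = 4)
  expect_equal(differential_test(x, y, log2 = FALSE), p_ref)
  expect_error(differential_test(1, c(1, 2)), "insufficient_replicates")
})

test_that("regulation classes follow the two-fold consecutive-stage rule", {
  expect_equal(classify_regulation(c(251, 69, 38)), "down")
  expect_equal(classify_regulation(c(100, 100, 100)), "unchanged")
  expect_equal(classify_regulation(c(50, 120, 260)), "up")
  expect_equal(classify_regulation(c(40, 50, 60)), "low_abundance")
  expect_equal(classify_regulation(c(56, 53, 293)), "up")
  expect_warning(out <- classify_regulation(c(100, 300, 100)),
                 "conflicting")
  expect_equal(out, "unchanged")
})

test_that("stage overlap partitions detected probes into 7 Venn regions", {
  calls <- expand.grid(probe_id = sprintf("p%d", 1:8),
                       stage = c("G1", "G2", "G3"),
                       stringsAsFactors = FALSE)
  # p1 G1-only, p2 all three, p3 G1+G2, p4 G3-only, p5-p8 all three
  calls$detected <- with(calls,
    (probe_id == "p1" & stage == "G1") |
    (probe_id == "p3" & stage %in% c("G1", "G2")) |
    (probe_id == "p4" & stage == "G3") |
    probe_id %in% c("p2", "p5", "p6", "p7", "p8"))
  venn <- stage_overlap(calls)
  expect_equal(unname(venn["G1"]), 1L)
  expect_equal(unname(venn["G3"]), 1L)
  expect_equal(unname(venn["G1G2"]), 1L)
  expect_equal(unname(venn["G1G2G3"]), 5L)
  expect_equal(sum(venn), 8L)  # partition property
  # all probes everywhere: the triple intersection holds everything
  calls$detected <- TRUE
  venn2 <- stage_overlap(calls)
  expect_equal(unname(venn2["G1G2G3"]), 8L)
  expect_equal(sum(venn2), 8L)
})

test_that("ddct computes relative folds from threshold cycles", {
  expect_equal(ddct(c(20, 20), c(15, 15)), 1)
  expect_equal(ddct(c(19, 20), c(15, 15)), 2)   # one cycle earlier
  expect_equal(ddct(c(22, 20), c(15, 15)), 0.25)
  expect_error(ddct(c(NA, 20), c(15, 15)), "finite")
})

test_that("chip analysis recovers simulated regulation patterns", {
  # most probes are flat, as on a real chip: median scaling then has a
  # stable anchor and does not distort the changing probes
  n <- 40
  pattern <- rep(c("up", "down", "flat", "low"), times = c(5, 5, 25, 5))
  mult <- t(vapply(pattern, function(p) switch(p,
    up = c(1, 2.5, 2.5), down = c(1, 0.4, 0.4), flat = c(1, 1, 1),
    low = c(1, 1, 1)), numeric(3)))
  base <- ifelse(pattern == "low", 50, 600)
  tr <- chip_truth(sprintf("p%02d", 1:n), base, mult, noise_cv = 0.05)
  chip <- simulate_chip(tr, replicates = 3, background_mean = 20,
                        background_sd = 3, seed = 72)
  an <- chip_analysis(chip$signals, chip$background)
  got <- an$de$regulation[match(tr$probe_id, an$de$probe_id)]
  expect_equal(got[pattern == "up"], rep("up", 5))
  expect_equal(got[pattern == "down"], rep("down", 5))
  expect_equal(got[pattern == "flat"], rep("unchanged", 25))
  expect_equal(got[pattern == "low"], rep("low_abundance", 5))
  # log2 matrix export matches the DE means
  m <- log2_matrix(an$de)
  expect_equal(dim(m), c(n, 3))
  expect_equal(unname(m[1, "G1"]), log2(an$de$mean_g1[1] + 1))
})
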