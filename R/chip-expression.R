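# miRNA-chip expression analysis across three filling stages: background
# subtraction and median scaling, detection calls (3x background SD, CV,
# repeat-probe agreement, absolute floor), stage means, fold changes,
# Student's t-tests, 2-fold regulation classes, stage-overlap (Venn)
# partition and 2^-ddCt for qRT-PCR.

#' Normalise a chip signal table
#'
#' Per chip (= stage x replicate): subtract the chip's background mean,
#' floor at 0, then scale so every chip's median equals the cross-chip
#' reference median (the first chip's median, for determinism; an explicit
#' `ref_median` may be supplied). Chips whose post-subtraction median is 0
#' are left unscaled.
#'
#' @param signals data frame with columns `probe_id`, `stage`, `replicate`,
#'   `signal` (raw).
#' @param background data frame with columns `stage`, `replicate`,
#'   `bg_mean`, `bg_sd` covering every chip in `signals`.
#' @param method `"median"` (default) or `"quantile"` (all chips forced to
#'   the reference chip's empirical distribution).
#' @param ref_median optional reference median intensity.
#' @return `signals` with `signal` replaced by the normalised value.
#' @export
normalize_chip <- function(signals, background, method = c("median",
                                                           "quantile"),
                           ref_median = NULL) {
  method <- match.arg(method)
  chip_id <- function(df) paste(df$stage, df$replicate, sep = ":")
  sig_chip <- chip_id(signals)
  bg_chip <- chip_id(background)
  if (any(!sig_chip %in% bg_chip)) stop("missing background for some chips")
  bsub <- pmax(signals$signal -
                 background$bg_mean[match(sig_chip, bg_chip)], 0)
  chips <- unique(sig_chip)
  med <- vapply(chips, function(cid) median(bsub[sig_chip == cid]),
                numeric(1))
  if (method == "median") {
    if (is.null(ref_median)) ref_median <- med[1]
    fac <- ifelse(med > 0, ref_median / med, 1)
    out <- bsub * fac[match(sig_chip, chips)]
  } else {
    ref <- sort(bsub[sig_chip == chips[1]])
    out <- bsub
    for (cid in chips) {
      idx <- which(sig_chip == cid)
      r <- rank(bsub[idx], ties.method = "average")
      q <- stats::quantile(ref, probs = (r - 0.5) / length(idx),
                           names = FALSE, type = 4)
      out[idx] <- q
    }
  }
  signals$signal <- out
  signals
}

#' Detection call for one probe at one stage
#'
#' Detected iff mean > 3 x background SD, replicate CV < `max_cv`, at least
#' `repeat_fraction_ok` of repeat spots individually pass, and mean >= the
#' absolute floor.
#'
#' @param replicate_signals numeric vector of normalised replicate signals.
#' @param background_sd chip background standard deviation.
#' @param repeat_pass_fraction fraction of repeat spots individually above
#'   detection level (default 1 when no repeat-probe info exists).
#' @param max_cv CV ceiling (default 0.5).
#' @param floor absolute intensity floor (default 32).
#' @param repeat_fraction_ok required repeat-spot pass fraction (default
#'   0.5).
#' @return list with `detected` (flag), `reasons` (character vector, empty
#'   when detected), `mean`, `cv`.
#' @export
detect_call <- function(replicate_signals, background_sd,
                        repeat_pass_fraction = 1, max_cv = 0.5, floor = 32,
                        repeat_fraction_ok = 0.5) {
  m <- mean(replicate_signals)
  cv <- if (m > 0) sd(replicate_signals) / m else Inf
  reasons <- character(0)
  if (!(m > 3 * background_sd)) reasons <- c(reasons, "below_3sd")
  if (!(cv < max_cv)) reasons <- c(reasons, "cv_fail")
  if (repeat_pass_fraction < repeat_fraction_ok) {
    reasons <- c(reasons, "repeat_probe_fail")
  }
  if (m < floor) reasons <- c(reasons, "below_floor")
  list(detected = length(reasons) == 0, reasons = reasons, mean = m, cv = cv)
}

#' Fold change between two stage means
#'
#' @param mean_a denominator stage mean (must be positive).
#' @param mean_b numerator stage mean.
#' @return `mean_b / mean_a`, rounded half-up to 2 decimals.
#' @examples
#' fold_change(53, 293)   # 5.53
#' fold_change(349, 1140) # 3.27
#' @export
fold_change <- function(mean_a, mean_b) {
  if (any(mean_a <= 0)) stop("zero_denominator")
  round_half_up(mean_b / mean_a, 2)
}

#' Two-sample Student's t-test between stages
#'
#' @param x,y replicate signal vectors (>= 2 each).
#' @param log2 test on `log2(signal + 1)` (default TRUE, the clustering
#'   scale).
#' @return two-sided p-value; 1 when both groups are constant and equal.
#' @export
differential_test <- function(x, y, log2 = TRUE) {
  if (length(x) < 2 || length(y) < 2) stop("insufficient_replicates")
  if (log2) {
    x <- base::log2(x + 1)
    y <- base::log2(y + 1)
  }
  if (sd(x) == 0 && sd(y) == 0) {
    return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
  }
  t.test(x, y, var.equal = TRUE)$p.value
}

#' Classify a probe's regulation across the three stages
#'
#' The operative rule is a 2-fold intensity change between consecutive
#' stages: `up` when G2/G1 >= 2 or G3/G2 >= 2 (and neither ratio <= 0.5),
#' `down` for the mirror case, `unchanged` otherwise; probes whose largest
#' stage mean is below `min_abundance` are `low_abundance`. Conflicting
#' directions give `unchanged` with a warning.
#'
#' @param means numeric length-3 vector of stage means (G1, G2, G3).
#' @param min_abundance low-abundance cutoff (default 100).
#' @return one of `"up"`, `"down"`, `"unchanged"`, `"low_abundance"`.
#' @export
classify_regulation <- function(means, min_abundance = 100) {
  stopifnot(length(means) == 3)
  if (max(means) < min_abundance) return("low_abundance")
  fc21 <- fold_change(means[1], means[2])
  fc32 <- fold_change(means[2], means[3])
  up <- fc21 >= 2 || fc32 >= 2
  down <- fc21 <= 0.5 || fc32 <= 0.5
  if (up && down) {
    warning("conflicting regulation directions; classifying as unchanged")
    return("unchanged")
  }
  if (up) return("up")
  if (down) return("down")
  "unchanged"
}

#' Full chip expression analysis
#'
#' Normalises, computes per-probe per-stage means/CVs, detection calls,
#' consecutive-stage fold changes, t-tests (G3 replicates vs G1 replicates)
#' and regulation classes.
#'
#' @param signals raw signal table (`probe_id`, `stage`, `replicate`,
#'   `signal`).
#' @param background per-chip background table (see [normalize_chip()]).
#' @param normalize_method passed to [normalize_chip()].
#' @param min_abundance low-abundance cutoff for classification.
#' @param floor detection floor (default 32).
#' @param adjust_p apply Benjamini-Hochberg correction (default FALSE,
#'   matching raw p-value reporting).
#' @return list of class `chip_analysis` with `calls` (probe x stage
#'   detection calls), `de` (per-probe means, fold changes, p-value,
#'   regulation) and `normalized` (the normalised signal table).
#' @export
chip_analysis <- function(signals, background,
                          normalize_method = "median",
                          min_abundance = 100, floor = 32,
                          adjust_p = FALSE) {
  norm <- normalize_chip(signals, background, method = normalize_method)
  stages <- c("G1", "G2", "G3")
  probes <- unique(norm$probe_id)
  bg_sd <- mean(background$bg_sd)
  calls <- list()
  de <- list()
  for (pr in probes) {
    reps <- lapply(stages, function(st)
      norm$signal[norm$probe_id == pr & norm$stage == st])
    names(reps) <- stages
    st_calls <- lapply(stages, function(st)
      detect_call(reps[[st]], background_sd = bg_sd, floor = floor))
    names(st_calls) <- stages
    for (st in stages) {
      calls[[length(calls) + 1L]] <- data.frame(
        probe_id = pr, stage = st,
        detected = st_calls[[st]]$detected,
        reasons = paste(st_calls[[st]]$reasons, collapse = ","),
        mean = st_calls[[st]]$mean, cv = st_calls[[st]]$cv,
        stringsAsFactors = FALSE)
    }
    means <- vapply(st_calls, `[[`, numeric(1), "mean")
    p <- tryCatch(differential_test(reps$G1, reps$G3),
                  error = function(e) NA_real_)
    de[[length(de) + 1L]] <- data.frame(
      probe_id = pr, mean_g1 = means[["G1"]], mean_g2 = means[["G2"]],
      mean_g3 = means[["G3"]],
      fc_21 = if (means[["G1"]] > 0) fold_change(means[["G1"]],
                                                 means[["G2"]]) else NA,
      fc_32 = if (means[["G2"]] > 0) fold_change(means[["G2"]],
                                                 means[["G3"]]) else NA,
      p_value = p,
      regulation = suppressWarnings(
        classify_regulation(means, min_abundance = min_abundance)),
      stringsAsFactors = FALSE)
  }
  calls <- do.call(rbind, calls)
  de <- do.call(rbind, de)
  if (adjust_p) de$p_adj <- stats::p.adjust(de$p_value, method = "BH")
  structure(list(calls = calls, de = de, normalized = norm),
            class = "chip_analysis")
}

#' @export
print.chip_analysis <- function(x, ...) {
  n_det <- tapply(x$calls$detected, x$calls$stage, sum)
  cat("Chip expression analysis:",
      length(unique(x$calls$probe_id)), "probes\n")
  cat("  detected per stage:",
      paste(sprintf("%s=%d", names(n_det), n_det), collapse = " "), "\n")
  cat("  regulation classes:",
      paste(sprintf("%s=%d", names(table(x$de$regulation)),
                    table(x$de$regulation)), collapse = " "), "\n")
  invisible(x)
}

#' Stage-overlap (Venn) partition of detection calls
#'
#' @param calls detection-call data frame (`probe_id`, `stage`,
#'   `detected`) covering stages G1, G2, G3.
#' @return named integer vector over the 7 Venn regions (`G1`, `G2`, `G3`,
#'   `G1G2`, `G1G3`, `G2G3`, `G1G2G3`); the counts sum to the number of
#'   probes detected in at least one stage.
#' @export
stage_overlap <- function(calls) {
  det <- calls[calls$detected, ]
  sets <- lapply(c("G1", "G2", "G3"), function(st)
    unique(det$probe_id[det$stage == st]))
  names(sets) <- c("G1", "G2", "G3")
  all_probes <- unique(det$probe_id)
  region <- vapply(all_probes, function(p) {
    paste(names(sets)[vapply(sets, function(s) p %in% s, logical(1))],
          collapse = "")
  }, character(1))
  out <- setNames(integer(7),
                  c("G1", "G2", "G3", "G1G2", "G1G3", "G2G3", "G1G2G3"))
  tab <- table(region)
  out[names(tab)] <- as.integer(tab)
  out
}

#' Relative expression by the 2^-ddCt method
#'
#' @param ct_target length-2 vector `c(treated, calibrator)` of target-gene
#'   threshold cycles.
#' @param ct_reference length-2 vector `c(treated, calibrator)` of
#'   reference-gene threshold cycles.
#' @return relative fold = `2^-((target_treated - reference_treated) -
#'   (target_calibrator - reference_calibrator))`.
#' @examples
#' ddct(c(20, 20), c(15, 15))  # 1: no change
#' @export
ddct <- function(ct_target, ct_reference) {
  stopifnot(length(ct_target) == 2, length(ct_reference) == 2,
            all(is.finite(c(ct_target, ct_reference))))
  d <- (ct_target[1] - ct_reference[1]) - (ct_target[2] - ct_reference[2])
  2^(-d)
}

#' Export the log2 expression matrix for clustering
#'
#' @param de DE table from [chip_analysis()].
#' @return matrix of `log2(mean + 1)` with probes as rows, stages as
#'   columns.
#' @export
log2_matrix <- function(de) {
  m <- as.matrix(de[, c("mean_g1", "mean_g2", "mean_g3")])
  rownames(m) <- de$probe_id
  colnames(m) <- c("G1", "G2", "G3")
  base::log2(m + 1)
}
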