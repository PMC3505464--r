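# Internal sequence and numeric helpers shared across modules.

#' Reverse-complement DNA strings
#'
#' Vectorised reverse complement in DNA space (A/C/G/T, with N preserved).
#'
#' @param x character vector of DNA sequences.
#' @return character vector of the same length.
#' @examples
#' revcomp(c("ACGT", "GGAA"))
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x))
  out <- chartr("ACGTUacgtu", "TGCAAtgcaa", x)
  vapply(strsplit(out, "", fixed = TRUE),
         function(s) paste(rev(s), collapse = ""), character(1))
}

# U->T canonicalisation: all internal sequence space is DNA.
canon_dna <- function(x) chartr("u", "T", chartr("U", "T", toupper(x)))

# DNA -> RNA for display/output of miRNA sequences.
as_rna <- function(x) chartr("T", "U", toupper(x))

# Round half-up at `digits` decimals (R's round() is round-half-even).
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Derive a deterministic per-operation substream seed from one global seed.
# Keeps results below 2^31 so set.seed() always accepts them.
substream_seed <- function(seed, label) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}

# Random DNA of given lengths (vectorised).
random_dna <- function(lengths) {
  vapply(lengths, function(L) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, character(1))
}

# Hamming distance between two equal-length strings.
hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  if (nchar(a) == 0L) return(0L)
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}
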