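# Independent oracles used by the test suite. These deliberately avoid the
# package's own algorithms: folding is checked against a plain recursive
# enumeration of all nested structures, and target scanning against a naive
# score-everything sweep.

# Maximum number of base pairs over all nested structures (WC + optional
# G:U, minimum hairpin loop `min_loop`), by exhaustive recursion on the
# leftmost position: either it stays unpaired or it pairs with each
# admissible partner. No memoisation, no traceback -- pure enumeration.
oracle_max_pairs <- function(sequence, min_loop = 3, allow_gu = TRUE) {
  s <- strsplit(chartr("Tt", "Uu", toupper(sequence)), "")[[1]]
  ok <- function(a, b) {
    (a == "A" && b == "U") || (a == "U" && b == "A") ||
      (a == "C" && b == "G") || (a == "G" && b == "C") ||
      (allow_gu && ((a == "G" && b == "U") || (a == "U" && b == "G")))
  }
  rec <- function(i, j) {
    if (j - i < min_loop + 1) return(0L)
    best <- rec(i + 1L, j)
    for (k in (i + min_loop + 1L):j) {
      if (ok(s[i], s[k])) {
        v <- 1L + rec(i + 1L, k - 1L) + rec(k + 1L, j)
        if (v > best) best <- v
      }
    }
    best
  }
  if (length(s) < min_loop + 2) return(0L)
  rec(1L, length(s))
}

# Check a dot-bracket string is well formed (balanced pushdown) and respects
# the minimum loop length; returns TRUE/FALSE.
oracle_valid_dotbracket <- function(db, min_loop = 3) {
  stack <- integer(0)
  ch <- strsplit(db, "")[[1]]
  for (i in seq_along(ch)) {
    if (ch[i] == "(") stack <- c(stack, i)
    else if (ch[i] == ")") {
      if (length(stack) == 0) return(FALSE)
      j <- stack[length(stack)]
      if (i - j - 1 < min_loop) return(FALSE)
      stack <- stack[-length(stack)]
    } else if (ch[i] != ".") return(FALSE)
  }
  length(stack) == 0
}

# Naive target-scan oracle: for every transcript start score the gapless
# placement plus every single interior gap placement, and keep the minimum
# score per start. Works directly in miRNA-vs-target base space.
oracle_scan <- function(mirna, transcript, max_score = 5) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  m <- strsplit(chartr("Uu", "Tt", toupper(mirna)), "")[[1]]
  t <- strsplit(toupper(transcript), "")[[1]]
  L <- length(m)
  n <- length(t)
  pen <- function(mb, tb) {
    if (comp[[mb]] == tb) return(0)
    if ((mb == "G" && tb == "T") || (mb == "T" && tb == "G")) return(0.5)
    1
  }
  res <- list()
  if (n < L) return(data.frame(start = integer(), score = numeric()))
  for (p in 1:(n - L + 1L)) {
    # gapless: miRNA position k faces transcript position p + L - k
    sc <- sum(vapply(seq_len(L), function(k) pen(m[k], t[p + L - k]),
                     numeric(1)))
    best <- sc
    # one unopposed miRNA base (interior), window L - 1
    if (p + L - 2L <= n) {
      for (g in 2:(L - 1L)) {
        faced <- t[seq(p + L - 2L, p, by = -1L)]
        sc <- 2
        fi <- 0L
        for (k in seq_len(L)) {
          if (k == g) next
          fi <- fi + 1L
          sc <- sc + pen(m[k], faced[fi])
        }
        best <- min(best, sc)
      }
    }
    # one unopposed transcript base between miRNA positions, window L + 1
    if (p + L <= n) {
      for (g in 1:(L - 1L)) {
        faced <- t[seq(p + L, p, by = -1L)]
        sc <- 2
        fi <- 0L
        for (k in seq_len(L)) {
          fi <- fi + 1L
          sc <- sc + pen(m[k], faced[fi])
          if (k == g) fi <- fi + 1L   # skip the bulged transcript base
        }
        best <- min(best, sc)
      }
    }
    if (best <= max_score) {
      res[[length(res) + 1L]] <- data.frame(start = p - 1L, score = best)
    }
  }
  if (length(res) == 0) return(data.frame(start = integer(),
                                          score = numeric()))
  do.call(rbind, res)
}

# Random DNA string helper for tests.
rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Small known-miRNA catalog built from two synthetic hairpins.
make_test_catalog <- function(seed = 7) {
  set.seed(seed)
  h1 <- planted_hairpin("k1", "none", 0, "+", mature_seq = rand_dna(21),
                        mature_arm = "5p")
  h2 <- planted_hairpin("k2", "none", 0, "+", mature_seq = rand_dna(22),
                        mature_arm = "3p")
  mature <- c("osa-miR9101" = h1$mature_seq, "osa-miR9102" = h2$mature_seq)
  prec <- c("osa-MIR9101" = h1$precursor_seq,
            "osa-MIR9102" = h2$precursor_seq)
  links <- data.frame(name = names(mature), precursor_id = names(prec),
                      offset = c(h1$mature_off, h2$mature_off) - 1L,
                      arm = c("5p", "3p"), stringsAsFactors = FALSE)
  list(catalog = mirna_catalog(mature, prec, links), h1 = h1, h2 = h2)
}
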