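# RNA secondary structure by maximum base pairing. Deterministic and
# oracle-checkable; a thermodynamic folder can be swapped in through the
# `engine` argument without changing downstream duplex logic.

#' Fold an RNA sequence by maximum base pairing
#'
#' Computes a nested secondary structure maximising the number of base pairs
#' (Watson-Crick plus G:U wobble) with a minimum hairpin loop of
#' `min_loop` unpaired bases. Ties are broken deterministically: during
#' traceback the 5'-most base of each interval is paired with the leftmost
#' partner that achieves the optimal pair count.
#'
#' @param sequence RNA (or DNA; T is read as U) string, 1-2000 nt, ACGU/T
#'   alphabet only.
#' @param min_loop minimum hairpin loop length (default 3).
#' @param allow_gu allow G:U wobble pairs (default TRUE).
#' @param engine folding engine; `"maxpair"` is the built-in algorithm. A
#'   function `(sequence) -> list(dotbracket=, pair_count=)` may be supplied
#'   to plug in an external folder.
#' @return object of class `secondary_structure`: list with `sequence`
#'   (RNA), `dotbracket` and `pair_count`.
#' @examples
#' fold("GGGGAAAACCCC")$dotbracket  # "((((....))))"
#' @export
fold <- function(sequence, min_loop = 3, allow_gu = TRUE,
                 engine = "maxpair") {
  stopifnot(length(sequence) == 1)
  rna <- as_rna(canon_dna(sequence))
  if (nchar(rna) < 1 || nchar(rna) > 2000) {
    stop("sequence length must be in 1..2000 nt")
  }
  res <- if (is.function(engine)) {
    engine(rna)
  } else {
    .nussinov_fold(rna, min_loop = as.integer(min_loop),
                   allow_gu = allow_gu)
  }
  structure(list(sequence = rna, dotbracket = res$dotbracket,
                 pair_count = res$pair_count),
            class = "secondary_structure")
}

#' @export
print.secondary_structure <- function(x, ...) {
  cat(x$sequence, "\n", x$dotbracket, "  (", x$pair_count, " pairs)\n",
      sep = "")
  invisible(x)
}

#' Pairing-partner table of a dot-bracket string
#'
#' @param structure a `secondary_structure` or dot-bracket string.
#' @return integer vector: `partner[i]` is the 1-based partner of position
#'   `i`, or `NA` if unpaired. Errors on unbalanced brackets.
#' @export
pairing_partners <- function(structure) {
  db <- if (inherits(structure, "secondary_structure"))
    structure$dotbracket else structure
  ch <- strsplit(db, "")[[1]]
  partner <- rep(NA_integer_, length(ch))
  stack <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") {
      stack <- c(stack, i)
    } else if (ch[i] == ")") {
      if (length(stack) == 0) stop("unbalanced dot-bracket")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      partner[i] <- j
      partner[j] <- i
    } else if (ch[i] != ".") {
      stop("invalid dot-bracket character: ", ch[i])
    }
  }
  if (length(stack) > 0) stop("unbalanced dot-bracket")
  partner
}
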