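#' @importFrom rlang abort warn .data
#' @importFrom stats pchisq pt qnorm rbinom rnorm runif sd setNames var
NULL

# IUPAC degenerate nucleotide codes -> base sets. Degeneracy is honoured in
# primers only; an N in a target/reference sequence never matches.
IUPAC_CODES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

IUPAC_ALPHABET <- names(IUPAC_CODES)

# 15 x 4 logical lookup: does primer code (row) accept target base (col)?
iupac_accept_matrix <- local({
  m <- matrix(FALSE, nrow = length(IUPAC_CODES), ncol = 4,
              dimnames = list(names(IUPAC_CODES), c("A", "C", "G", "T")))
  for (code in names(IUPAC_CODES)) m[code, IUPAC_CODES[[code]]] <- TRUE
  m
})

check_iupac <- function(x, what = "sequence") {
  bad <- setdiff(unique(strsplit(x, "")[[1]]), IUPAC_ALPHABET)
  if (length(bad) > 0) {
    abort(sprintf("non-IUPAC character(s) %s in %s '%s'",
                  paste(bad, collapse = ", "), what, x))
  }
  invisible(x)
}

#' Match a degenerate primer against a concrete target subsequence
#'
#' Positionwise comparison of an IUPAC primer with an A/C/G/T target of the
#' same length. A position matches when the target base belongs to the
#' expansion of the primer's IUPAC code. Degeneracy is one-directional: it is
#' honoured in the primer only, and an `N` in the target never matches.
#'
#' @param primer IUPAC nucleotide string (the oligo, 5'->3').
#' @param target A/C/G/T string of the same length.
#' @return `TRUE` when every position matches, `FALSE` otherwise.
#' @examples
#' iupac_match("CTWACC", "CTAACC")  # W = {A,T}
#' iupac_match("CTWACC", "CTGACC")  # G not in W
#' @export
iupac_match <- function(primer, target) {
  if (nchar(primer) != nchar(target)) {
    abort(sprintf("length mismatch: primer %d nt, target %d nt",
                  nchar(primer), nchar(target)))
  }
  check_iupac(primer, "primer")
  iupac_n_mismatch(primer, target) == 0L
}

# Number of positions where the target base is outside the primer's code set.
# Target characters outside A/C/G/T (including N) count as mismatches, except
# that genuinely malformed targets raise an error via the alphabet check.
iupac_n_mismatch <- function(primer, target) {
  pc <- strsplit(primer, "")[[1]]
  tc <- strsplit(target, "")[[1]]
  bad <- !tc %in% c("A", "C", "G", "T", "N")
  if (any(bad)) {
    abort(sprintf("non-nucleotide character(s) %s in target",
                  paste(unique(tc[bad]), collapse = ", ")))
  }
  ok <- tc %in% c("A", "C", "G", "T")
  hit <- logical(length(pc))
  hit[ok] <- iupac_accept_matrix[cbind(pc[ok], tc[ok])]
  sum(!hit)
}

# Translate an IUPAC primer to an ERE character-class regex.
iupac_to_regex <- function(primer) {
  check_iupac(primer, "primer")
  chars <- strsplit(primer, "")[[1]]
  paste(vapply(chars, function(ch) {
    bases <- IUPAC_CODES[[ch]]
    if (length(bases) == 1) bases else paste0("[", paste(bases, collapse = ""), "]")
  }, character(1)), collapse = "")
}

# Replace each degenerate code by one uniformly drawn base from its expansion.
iupac_instantiate <- function(primer) {
  chars <- strsplit(primer, "")[[1]]
  paste(vapply(chars, function(ch) {
    bases <- IUPAC_CODES[[ch]]
    if (length(bases) == 1) bases else sample(bases, 1)
  }, character(1)), collapse = "")
}

reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
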