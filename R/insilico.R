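# In-silico PCR: degenerate primer site scanning and amplicon prediction.

# All start offsets (1-based) where `primer` matches `sequence` with at most
# max_mismatch IUPAC-aware mismatches.
scan_primer_sites <- function(primer, sequence, max_mismatch = 0L) {
  np <- nchar(primer)
  ns <- nchar(sequence)
  if (np > ns) return(integer(0))
  if (max_mismatch == 0L) {
    # Biostrings matchPattern honours IUPAC degeneracy with fixed = "subject"
    hits <- Biostrings::matchPattern(Biostrings::DNAString(primer),
                                     Biostrings::DNAString(sequence),
                                     fixed = "subject")
    return(Biostrings::start(hits))
  }
  pc <- strsplit(primer, "")[[1]]
  tc <- strsplit(sequence, "")[[1]]
  ok_target <- tc %in% c("A", "C", "G", "T")
  starts <- integer(0)
  for (i in seq_len(ns - np + 1L)) {
    idx <- i:(i + np - 1L)
    hit <- ok_target[idx]
    hit[hit] <- iupac_accept_matrix[cbind(pc[hit], tc[idx][hit])]
    if (sum(!hit) <= max_mismatch) starts <- c(starts, i)
  }
  starts
}

#' Predict amplicons of a primer set on a reference sequence
#'
#' Scans both orientations of the reference for the forward primer on the
#' given strand and each reverse primer as its reverse complement downstream,
#' reporting every (forward start, reverse end) pair. Coordinates are 1-based
#' inclusive in the frame of the supplied reference; `length_bp` is
#' `end - start + 1`. Degeneracy is honoured in the primer only.
#'
#' @param panel A `micropanel_panel`.
#' @param set_name Primer set to use.
#' @param reference A/C/G/T(/N) reference sequence (single string).
#' @param max_mismatch Maximum IUPAC-aware mismatches per binding site
#'   (default 0: exact degenerate match).
#' @param both_strands Also scan the reverse-complement orientation.
#' @return Tibble: `set_name`, `reverse_index`, `start`, `end`, `length_bp`,
#'   `strand`. Zero rows when no site pair is found.
#' @export
predict_amplicons <- function(panel, set_name, reference, max_mismatch = 0L,
                              both_strands = TRUE) {
  oligos <- panel$oligos[panel$oligos$set_name == set_name, ]
  if (nrow(oligos) == 0) abort(sprintf("unknown primer set '%s'", set_name))
  fwd <- oligos$sequence[oligos$orientation == "forward"]
  revs <- oligos$sequence[oligos$orientation == "reverse"]
  if (nchar(reference) < max(nchar(c(fwd, revs)))) {
    abort("reference shorter than the longest primer")
  }

  scan_strand <- function(seq, strand) {
    n <- nchar(seq)
    fstarts <- scan_primer_sites(fwd, seq, max_mismatch)
    out <- list()
    for (ri in seq_along(revs)) {
      rsite <- reverse_complement(revs[ri])
      rstarts <- scan_primer_sites(rsite, seq, max_mismatch)
      rends <- rstarts + nchar(rsite) - 1L
      for (fs in fstarts) {
        down <- rends[rstarts > fs + nchar(fwd) - 1L]
        for (re in down) {
          start <- fs
          end <- re
          if (strand == "-") {
            # map back to the input reference frame
            start2 <- n - end + 1L
            end2 <- n - fs + 1L
            start <- start2
            end <- end2
          }
          out[[length(out) + 1L]] <- tibble::tibble(
            set_name = set_name, reverse_index = ri,
            start = start, end = end,
            length_bp = end - start + 1L, strand = strand)
        }
      }
    }
    if (length(out) == 0) NULL else dplyr::bind_rows(out)
  }

  res <- scan_strand(reference, "+")
  if (both_strands) {
    res <- dplyr::bind_rows(res, scan_strand(reverse_complement(reference), "-"))
  }
  if (is.null(res) || nrow(res) == 0) {
    return(tibble::tibble(set_name = character(0), reverse_index = integer(0),
                          start = integer(0), end = integer(0),
                          length_bp = integer(0), strand = character(0)))
  }
  dplyr::arrange(res, .data$start, .data$reverse_index)
}
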