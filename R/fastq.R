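# FASTQ I/O (Sanger Phred+33) via Biostrings.

#' Read a FASTQ file into a read tibble
#' @param path FASTQ file (Phred+33 qualities).
#' @return Tibble: `id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  tibble::tibble(
    id = unname(names(x)),
    sequence = unname(as.character(x)),
    quality = unname(as.character(S4Vectors::mcols(x)$qualities))
  )
}

#' Write a read tibble to FASTQ
#' @param reads Tibble with `id`, `sequence`, `quality`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$sequence)
  names(x) <- reads$id
  Biostrings::writeXStringSet(
    x, path, format = "fastq",
    qualities = Biostrings::BStringSet(reads$quality))
  invisible(path)
}

# per-base Phred scores from a Phred+33 quality string
phred_scores <- function(quality) utf8ToInt(quality) - 33L

# mean per-base calling accuracy of a quality string
mean_accuracy <- function(quality) {
  if (nchar(quality) == 0) return(NA_real_)
  mean(1 - 10^(-phred_scores(quality) / 10))
}
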