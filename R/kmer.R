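# Quality-aware 8-mer set-overlap similarity and reference search.

# unique k-mers of a sequence; when a quality string is supplied, only
# windows whose every base reaches min_quality_base are used
usable_kmers <- function(sequence, quality = NULL, k = 8L,
                         min_quality_base = 15L) {
  n <- nchar(sequence)
  if (n < k) return(character(0))
  starts <- seq_len(n - k + 1L)
  if (!is.null(quality) && !is.na(quality)) {
    q <- phred_scores(quality)
    ok <- q >= min_quality_base
    # window usable iff all k bases pass
    run <- stats::filter(as.numeric(ok), rep(1, k), sides = 1)
    good <- which(run[starts + k - 1L] == k)
    starts <- starts[good]
  }
  if (length(starts) == 0) return(character(0))
  unique(substring(sequence, starts, starts + k - 1L))
}

#' Quality-aware k-mer set-overlap similarity
#'
#' Similarity of a query read to a reference sequence as the percentage of
#' the query's unique k-mers found among the reference's unique k-mers
#' (the query's k-mer count is the denominator). Query k-mers are produced
#' only from windows whose every base reaches `min_quality_base`; a query
#' with fewer than `min_kmers` usable k-mers is skipped (`NA`), which keeps
#' low-quality reads from generating spurious similarities.
#'
#' @param query Query sequence (insert or cluster centroid).
#' @param reference Reference sequence.
#' @param quality Optional Phred+33 quality string for the query.
#' @param k K-mer size (default 8).
#' @param min_quality_base Per-base Phred floor for k-mer extraction.
#' @param min_kmers Minimum usable query k-mers; below it the read is
#'   skipped.
#' @return Similarity percentage in \[0, 100\], or `NA` for skipped queries.
#' @export
kmer_similarity <- function(query, reference, quality = NULL, k = 8L,
                            min_quality_base = 15L, min_kmers = 20L) {
  qk <- usable_kmers(query, quality, k = k, min_quality_base = min_quality_base)
  if (length(qk) < min_kmers) return(NA_real_)
  rk <- usable_kmers(reference, NULL, k = k)
  100 * sum(qk %in% rk) / length(qk)
}

#' Pre-compute the unique k-mer sets of a reference database
#' @param reference_db Tibble `reference_id`, `sequence`.
#' @param k K-mer size (default 8).
#' @return A `micropanel_kmer_index` (list of k-mer character vectors).
#' @export
index_reference_kmers <- function(reference_db, k = 8L) {
  if (nrow(reference_db) == 0) abort("empty reference database")
  idx <- lapply(reference_db$sequence, usable_kmers, quality = NULL, k = k)
  names(idx) <- reference_db$reference_id
  structure(list(kmers = idx, k = k), class = "micropanel_kmer_index")
}

#' Search a reference database for the best k-mer similarities
#'
#' Computes the k-mer similarity of the query to every reference and returns
#' the hits within `best_fraction` of the top similarity (a relative band,
#' e.g. 1 percent below the best) that also reach the absolute `cutoff`.
#' Skipped queries (too few usable k-mers) return no hits.
#'
#' @param query Query sequence.
#' @param reference_db Tibble `reference_id`, `sequence`, or a pre-built
#'   [index_reference_kmers()] index.
#' @param quality Optional query quality string.
#' @param best_fraction Relative band below the best similarity
#'   (default 0.01).
#' @param cutoff Absolute similarity floor in percent (default 50).
#' @param k,min_quality_base,min_kmers Passed to the similarity computation.
#' @return Tibble `reference_id`, `similarity`, descending; zero rows when
#'   nothing passes (or the query is skipped, flagged in
#'   `attr(, "skipped")`).
#' @export
kmer_search <- function(query, reference_db, quality = NULL,
                        best_fraction = 0.01, cutoff = 50, k = 8L,
                        min_quality_base = 15L, min_kmers = 20L) {
  if (inherits(reference_db, "micropanel_kmer_index")) {
    idx <- reference_db$kmers
    k <- reference_db$k
  } else {
    if (nrow(reference_db) == 0) abort("empty reference database")
    idx <- index_reference_kmers(reference_db, k = k)$kmers
  }
  qk <- usable_kmers(query, quality, k = k, min_quality_base = min_quality_base)
  empty <- tibble::tibble(reference_id = character(0), similarity = numeric(0))
  if (length(qk) < min_kmers) {
    attr(empty, "skipped") <- TRUE
    return(empty)
  }
  sims <- vapply(idx, function(rk) 100 * sum(qk %in% rk) / length(qk),
                 numeric(1))
  best <- max(sims)
  keep <- sims >= max(cutoff, (1 - best_fraction) * best)
  if (!any(keep)) return(empty)
  out <- tibble::tibble(reference_id = names(sims)[keep],
                        similarity = unname(sims[keep]))
  dplyr::arrange(out, dplyr::desc(.data$similarity), .data$reference_id)
}
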