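# Greedy centroid clustering at high identity (OTU formation).

# fixed match/mismatch scoring: quality strings play no role in the
# identity computation, and it is several-fold faster than the default
# quality-aware scheme
cluster_submat <- function() {
  Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                           baseOnly = FALSE)
}

# percent identity of two sequences: matches / alignment columns, using
# global end-free alignment
alignment_identity <- function(a, b) {
  if (a == b) return(100)
  aln <- Biostrings::pairwiseAlignment(a, b, type = "overlap",
                                       substitutionMatrix = cluster_submat())
  Biostrings::pid(aln, type = "PID1")
}

greedy_cluster_one <- function(sequences, qualities, min_similarity) {
  if (is.null(qualities)) qualities <- rep(NA_character_, length(sequences))
  # dereplicate exact duplicates first; centroid quality = first occurrence
  first_idx <- !duplicated(sequences)
  counts <- table(factor(sequences, levels = sequences[first_idx]))
  uniq <- sequences[first_idx]
  uq <- qualities[first_idx]
  # deterministic processing order: longest first, then lexicographic
  ord <- order(-nchar(uniq), uniq)
  uniq <- uniq[ord]; uq <- uq[ord]
  ucount <- as.integer(counts[uniq])

  centroid <- character(0)
  centroid_q <- character(0)
  member <- integer(0)
  for (i in seq_along(uniq)) {
    k <- NA_integer_
    if (length(centroid) > 0) {
      # one vectorised alignment call against all centroids; the joined
      # cluster is the first (in founding order) at or above the threshold
      aln <- Biostrings::pairwiseAlignment(
        Biostrings::DNAStringSet(centroid), uniq[i], type = "overlap",
        substitutionMatrix = cluster_submat())
      ok <- Biostrings::pid(aln, type = "PID1") >= 100 * min_similarity
      if (any(ok)) k <- which(ok)[1]
    }
    if (!is.na(k)) {
      member[k] <- member[k] + ucount[i]
    } else {
      centroid <- c(centroid, uniq[i])
      centroid_q <- c(centroid_q, uq[i])
      member <- c(member, ucount[i])
    }
  }
  tibble::tibble(cluster_id = seq_along(centroid), centroid = centroid,
                 centroid_quality = centroid_q, member_count = member)
}

#' Greedy centroid clustering of inserts at a minimum identity
#'
#' Incremental greedy clustering: sequences are processed in a deterministic
#' order (descending length, then lexicographic); each joins the first
#' existing centroid with pairwise identity at or above `min_similarity`
#' (identity = matches / alignment columns under global end-free alignment),
#' otherwise it founds a new cluster. Member counts sum exactly to the input
#' count. When `records` carries `sample_id`/`primer_set` columns, clustering
#' runs within each such context.
#'
#' @param records Tibble with `insert` and `insert_quality` (and optionally
#'   `sample_id`, `primer_set`).
#' @param min_similarity Identity threshold as a fraction (default 0.995).
#' @return Tibble: context columns, `cluster_id`, `centroid`,
#'   `centroid_quality`, `member_count`.
#' @export
greedy_cluster <- function(records, min_similarity = 0.995) {
  ctx <- intersect(c("sample_id", "primer_set"), names(records))
  if (length(ctx) == 0) {
    return(greedy_cluster_one(records$insert, records$insert_quality,
                              min_similarity))
  }
  records |>
    dplyr::group_by(dplyr::across(dplyr::all_of(ctx))) |>
    dplyr::group_modify(~ greedy_cluster_one(.x$insert, .x$insert_quality,
                                             min_similarity)) |>
    dplyr::ungroup()
}
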