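# Demultiplexing of tagged/barcoded amplicon reads and read cleaning.

hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

check_barcodes <- function(barcodes, max_mismatch) {
  if (anyDuplicated(barcodes$sample_id)) abort("duplicate sample_id in barcode table")
  bl <- unique(nchar(barcodes$barcode))
  if (length(bl) != 1) abort("barcodes must share one length")
  bc <- barcodes$barcode
  if (anyDuplicated(bc)) abort("configuration error: duplicate barcodes")
  if (length(bc) > 1) {
    for (i in seq_len(length(bc) - 1)) {
      for (j in (i + 1):length(bc)) {
        if (hamming(bc[i], bc[j]) <= 2 * max_mismatch) {
          abort(sprintf("configuration error: barcodes %s and %s collide at max_mismatch = %d",
                        bc[i], bc[j], max_mismatch))
        }
      }
    }
  }
  bl
}

#' Split reads by sample barcode and tagged primer
#'
#' Recognizes the 5' read structure `barcode + forward tag + forward primer +
#' insert`: the barcode identifies the sample, the universal forward tag
#' confirms library structure, and the forward primer (matched with IUPAC
#' degeneracy) identifies the primer set. Matched components are trimmed off
#' in the same pass. Only tagged primer sets participate: the untagged
#' species-specific assays can never receive reads. Unmatched reads are
#' returned with a reason code.
#'
#' @param reads Read tibble (`id`, `sequence`, `quality`).
#' @param barcodes Tibble `sample_id`, `barcode` (equal lengths, pairwise
#'   Hamming distance > `2 * max_mismatch`).
#' @param panel A `micropanel_panel`.
#' @param tags Tag pair (default [tag_pair()]).
#' @param max_mismatch Mismatches tolerated per component (default 0).
#' @return List with `records` (tibble `read_id`, `sample_id`, `primer_set`,
#'   `insert`, `insert_quality`) and `rejects` (tibble `read_id`, `reason`
#'   in `barcode`/`tag`/`primer`).
#' @export
demultiplex <- function(reads, barcodes, panel, tags = tag_pair(),
                        max_mismatch = 0L) {
  bl <- check_barcodes(barcodes, max_mismatch)
  # candidate order: longest primer first, then least degenerate (so an exact
  # assay beats a degenerate superset binding the same position), then name
  n_degenerate <- function(s) {
    sum(!strsplit(s, "")[[1]] %in% c("A", "C", "G", "T"))
  }
  tagged_sets <- panel$oligos |>
    dplyr::filter(.data$orientation == "forward", .data$tagged) |>
    dplyr::select("set_name", primer = "sequence") |>
    dplyr::mutate(degen = vapply(.data$primer, n_degenerate, numeric(1))) |>
    dplyr::arrange(-nchar(.data$primer), .data$degen, .data$set_name)
  tag <- tags$forward_tag
  tl <- nchar(tag)

  n <- nrow(reads)
  sample_id <- rep(NA_character_, n)
  primer_set <- rep(NA_character_, n)
  reason <- rep(NA_character_, n)
  insert <- rep(NA_character_, n)
  insert_q <- rep(NA_character_, n)

  if (max_mismatch == 0L) {
    bc_obs <- substr(reads$sequence, 1L, bl)
    hit <- match(bc_obs, barcodes$barcode)
    sample_id <- barcodes$sample_id[hit]
    reason[is.na(hit)] <- "barcode"
    tag_obs <- substr(reads$sequence, bl + 1L, bl + tl)
    bad_tag <- is.na(reason) & tag_obs != tag
    reason[bad_tag] <- "tag"
    open <- which(is.na(reason))
    rest <- substr(reads$sequence, bl + tl + 1L, nchar(reads$sequence))
    for (k in seq_len(nrow(tagged_sets))) {
      if (length(open) == 0) break
      pat <- paste0("^", iupac_to_regex(tagged_sets$primer[k]))
      m <- grepl(pat, rest[open])
      idx <- open[m]
      primer_set[idx] <- tagged_sets$set_name[k]
      pl <- nchar(tagged_sets$primer[k])
      insert[idx] <- substr(rest[idx], pl + 1L, nchar(rest[idx]))
      insert_q[idx] <- substr(reads$quality[idx], bl + tl + pl + 1L,
                              nchar(reads$quality[idx]))
      open <- open[!m]
    }
    reason[open] <- "primer"
  } else {
    for (i in seq_len(n)) {
      seq_i <- reads$sequence[i]
      bc_obs <- substr(seq_i, 1L, bl)
      dists <- vapply(barcodes$barcode, hamming, integer(1), a = bc_obs)
      if (min(dists) > max_mismatch) { reason[i] <- "barcode"; next }
      sample_id[i] <- barcodes$sample_id[which.min(dists)]
      if (hamming(substr(seq_i, bl + 1L, bl + tl), tag) > max_mismatch) {
        reason[i] <- "tag"; next
      }
      rest <- substr(seq_i, bl + tl + 1L, nchar(seq_i))
      found <- FALSE
      for (k in seq_len(nrow(tagged_sets))) {
        prm <- tagged_sets$primer[k]
        pl <- nchar(prm)
        if (nchar(rest) < pl) next
        if (iupac_n_mismatch(prm, substr(rest, 1L, pl)) <= max_mismatch) {
          primer_set[i] <- tagged_sets$set_name[k]
          insert[i] <- substr(rest, pl + 1L, nchar(rest))
          insert_q[i] <- substr(reads$quality[i], bl + tl + pl + 1L,
                                nchar(reads$quality[i]))
          found <- TRUE
          break
        }
      }
      if (!found) reason[i] <- "primer"
    }
  }

  assigned <- is.na(reason)
  list(
    records = tibble::tibble(
      read_id = reads$id[assigned],
      sample_id = sample_id[assigned],
      primer_set = primer_set[assigned],
      insert = insert[assigned],
      insert_quality = insert_q[assigned]),
    rejects = tibble::tibble(
      read_id = reads$id[!assigned],
      reason = reason[!assigned])
  )
}

#' Quality and length cleaning of demultiplexed inserts
#'
#' Retains records whose mean per-base calling accuracy (averaged
#' `1 - 10^(-Q/10)`) reaches `min_quality` and whose insert is at least
#' `min_length` bases long.
#'
#' @param records Demultiplexed record tibble.
#' @param min_quality Minimum mean accuracy (default 0.96).
#' @param min_length Minimum insert length in bp (default 200).
#' @return The filtered record tibble.
#' @export
quality_filter <- function(records, min_quality = 0.96, min_length = 200L) {
  acc <- vapply(records$insert_quality, mean_accuracy, numeric(1),
                USE.NAMES = FALSE)
  keep <- !is.na(acc) & acc >= min_quality & nchar(records$insert) >= min_length
  records[keep, , drop = FALSE]
}
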