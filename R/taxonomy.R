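# Weighted read-density taxonomy and specificity summaries.

#' Weighted read-density taxonomy assignment
#'
#' Distributes each cluster's reads over its reference hits in proportion to
#' their similarities (hit i gets weight `sim_i / sum_j sim_j`), accumulating
#' the weighted read counts onto the hits' taxon paths. Clusters without hits
#' contribute to `"unclassified"`. Scores therefore sum exactly to the
#' clustered read count; densities are scores divided by that total and sum
#' to 1 per (sample, primer set).
#'
#' @param clusters Cluster tibble (context columns, `cluster_id`,
#'   `member_count`).
#' @param hits Tibble of per-cluster hits (`cluster_id`, `reference_id`,
#'   `similarity`, plus the same context columns).
#' @param taxonomy Tibble `reference_id`, `taxon_path` (semicolon-delimited).
#' @return Profile tibble: context columns, `taxon`, `score`, `density`,
#'   `total_reads`.
#' @export
assign_weighted_taxonomy <- function(clusters, hits, taxonomy) {
  ctx <- intersect(c("sample_id", "primer_set"), names(clusters))
  missing_tax <- setdiff(unique(hits$reference_id), taxonomy$reference_id)
  if (length(missing_tax) > 0) {
    abort(sprintf("reference(s) without taxonomy entry: %s",
                  paste(missing_tax, collapse = ", ")))
  }
  key_cols <- c(ctx, "cluster_id")
  hits <- hits |>
    dplyr::left_join(dplyr::select(taxonomy, "reference_id", "taxon_path"),
                     by = "reference_id")

  scores <- clusters |>
    dplyr::left_join(hits, by = key_cols) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(key_cols))) |>
    dplyr::mutate(
      weight = if (all(is.na(.data$similarity))) 1
               else .data$similarity / sum(.data$similarity),
      taxon = dplyr::coalesce(.data$taxon_path, "unclassified")
    ) |>
    dplyr::ungroup() |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(ctx, "taxon")))) |>
    dplyr::summarise(score = sum(.data$weight * .data$member_count),
                     .groups = "drop")

  totals <- clusters |>
    dplyr::group_by(dplyr::across(dplyr::all_of(ctx))) |>
    dplyr::summarise(total_reads = sum(.data$member_count), .groups = "drop")

  if (length(ctx) == 0) {
    scores$total_reads <- totals$total_reads
  } else {
    scores <- dplyr::left_join(scores, totals, by = ctx)
  }
  scores |>
    dplyr::mutate(density = .data$score / .data$total_reads) |>
    dplyr::arrange(dplyr::across(dplyr::all_of(ctx)), dplyr::desc(.data$score))
}

#' Drop low-density phylotypes while keeping totals auditable
#'
#' Taxa whose read density falls below `min_density` (default 1 percent) are
#' removed from the profile; their mass is retained under a `"filtered"`
#' remainder taxon so scores and densities still sum to the original totals.
#' A density exactly at the threshold is retained.
#'
#' @param profile Profile tibble from [assign_weighted_taxonomy()].
#' @param min_density Density threshold (default 0.01).
#' @return Filtered profile tibble.
#' @export
filter_density <- function(profile, min_density = 0.01) {
  if (nrow(profile) == 0) return(profile)
  ctx <- intersect(c("sample_id", "primer_set"), names(profile))
  profile |>
    dplyr::mutate(taxon = ifelse(.data$density >= min_density, .data$taxon,
                                 "filtered")) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(ctx, "taxon", "total_reads")))) |>
    dplyr::summarise(score = sum(.data$score), density = sum(.data$density),
                     .groups = "drop") |>
    dplyr::select(dplyr::all_of(ctx), "taxon", "score", "density", "total_reads")
}

# does a taxon path fall inside a primer set's target clade?
taxon_in_clade <- function(taxon_path, panel, set_name) {
  targets <- panel$sets$main_target[panel$sets$set_name %in%
                                      panel_clade(panel, set_name)]
  parts <- strsplit(taxon_path, ";", fixed = TRUE)
  vapply(parts, function(p) any(trimws(p) %in% targets), logical(1))
}

#' On-target versus off-target read densities per primer set
#'
#' Partitions each primer set's read densities into the set's own target
#' clade (the set and its lineage descendants) versus everything else,
#' pooling scores over samples. Assays targeting the 23S gene are excluded:
#' the taxonomy stage covers 16S references only.
#'
#' @param profiles Profile tibble (with `primer_set` context).
#' @param panel A `micropanel_panel`.
#' @return Tibble: `primer_set`, `on_target`, `off_target`, `unclassified`
#'   (density fractions summing to 1 per set).
#' @export
specificity_matrix <- function(profiles, panel) {
  sets16 <- panel$sets$set_name[panel$sets$gene == "16S" & panel$sets$tagged]
  profiles <- profiles[profiles$primer_set %in% sets16, , drop = FALSE]
  out <- profiles |>
    dplyr::group_by(.data$primer_set, .data$taxon) |>
    dplyr::summarise(score = sum(.data$score), .groups = "drop")
  out$class <- "off_target"
  for (s in unique(out$primer_set)) {
    rows <- which(out$primer_set == s)
    unc <- out$taxon[rows] %in% c("unclassified", "filtered")
    out$class[rows][unc] <- "unclassified"
    tgt <- taxon_in_clade(out$taxon[rows], panel, s) & !unc
    out$class[rows][tgt] <- "on_target"
  }
  out |>
    dplyr::group_by(.data$primer_set, .data$class) |>
    dplyr::summarise(score = sum(.data$score), .groups = "drop") |>
    dplyr::group_by(.data$primer_set) |>
    dplyr::mutate(density = .data$score / sum(.data$score)) |>
    dplyr::ungroup() |>
    dplyr::select(-"score") |>
    tidyr::pivot_wider(names_from = "class", values_from = "density",
                       values_fill = 0) |>
    (\(d) {
      for (col in c("on_target", "off_target", "unclassified")) {
        if (!col %in% names(d)) d[[col]] <- 0
      }
      d[, c("primer_set", "on_target", "off_target", "unclassified")]
    })()
}

#' Run the full amplicon pipeline on a read set
#'
#' Demultiplex, clean, cluster, search and assign: the complete sequence-side
#' chain from raw tagged reads to per-sample, per-primer-set read-density
#' taxonomy profiles.
#'
#' @param reads Read tibble.
#' @param barcodes Barcode tibble.
#' @param panel A `micropanel_panel`.
#' @param reference_db Tibble `reference_id`, `sequence`.
#' @param taxonomy Tibble `reference_id`, `taxon_path`.
#' @param min_quality,min_length Cleaning thresholds (see
#'   [quality_filter()]).
#' @param min_similarity Clustering identity threshold.
#' @param best_fraction,cutoff Search band parameters (see [kmer_search()]).
#' @param max_mismatch Demultiplexing mismatch tolerance.
#' @param min_density Density floor applied at the end; `NULL` skips the
#'   filter.
#' @return List: `profile`, `clusters`, `records`, `rejects`.
#' @export
run_amplicon_pipeline <- function(reads, barcodes, panel, reference_db,
                                  taxonomy, min_quality = 0.96,
                                  min_length = 200L, min_similarity = 0.995,
                                  best_fraction = 0.01, cutoff = 50,
                                  max_mismatch = 0L, min_density = NULL) {
  dm <- demultiplex(reads, barcodes, panel, max_mismatch = max_mismatch)
  clean <- quality_filter(dm$records, min_quality = min_quality,
                          min_length = min_length)
  clusters <- greedy_cluster(clean, min_similarity = min_similarity)
  idx <- index_reference_kmers(reference_db)
  hits <- clusters |>
    dplyr::group_by(.data$sample_id, .data$primer_set, .data$cluster_id) |>
    dplyr::group_modify(~ kmer_search(.x$centroid, idx,
                                      quality = .x$centroid_quality,
                                      best_fraction = best_fraction,
                                      cutoff = cutoff)) |>
    dplyr::ungroup()
  profile <- assign_weighted_taxonomy(clusters, hits, taxonomy)
  if (!is.null(min_density)) profile <- filter_density(profile, min_density)
  list(profile = profile, clusters = clusters, records = clean,
       rejects = dm$rejects)
}

#' Stacked read-density profile plot
#' @param profile Profile tibble.
#' @return A ggplot object.
#' @export
plot_taxonomy_profile <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$sample_id,
                                        y = .data$density,
                                        fill = .data$taxon)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(ggplot2::vars(.data$primer_set)) +
    ggplot2::labs(x = NULL, y = "read density") +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Primer-set specificity tile plot (target vs off-target densities)
#' @param spec Tibble from [specificity_matrix()].
#' @return A ggplot object.
#' @export
plot_specificity <- function(spec) {
  long <- tidyr::pivot_longer(spec, -"primer_set", names_to = "class",
                              values_to = "density")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$class, y = .data$primer_set,
                                     fill = .data$density)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "darkgreen") +
    ggplot2::labs(x = NULL, y = NULL, fill = "density") +
    ggplot2::theme_minimal(base_size = 9)
}
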