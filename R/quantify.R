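# Raw Cq -> relative abundance: IPC calibration, cut-offs, replicate
# collapsing, and the two Livak-form quantification formulas.

#' Calibrate Cq values across runs with the interplate calibrator
#'
#' Every run carries one common calibrator sample (IPC). Per run and primer
#' set, the offset is the run's IPC Cq minus the cross-run mean IPC Cq for
#' that primer set; subtracting it makes runs directly comparable and leaves
#' a single run unchanged. Where the IPC itself gave no call the run's values
#' for that primer set cannot be corrected and are flagged.
#'
#' @param cq Long Cq tibble covering one or more runs.
#' @param meta Sample metadata tibble with columns `run_id`, `sample_id`,
#'   `is_ipc` (exactly one IPC per run).
#' @return The Cq tibble with calibrated `cq` plus columns `ipc_offset` and
#'   `uncorrectable`.
#' @export
ipc_calibrate <- function(cq, meta) {
  ipc_counts <- meta |>
    dplyr::group_by(.data$run_id) |>
    dplyr::summarise(n_ipc = sum(.data$is_ipc), .groups = "drop")
  runs <- unique(cq$run_id)
  missing_meta <- setdiff(runs, ipc_counts$run_id)
  bad <- ipc_counts$run_id[ipc_counts$n_ipc != 1L]
  if (length(missing_meta) > 0 || length(intersect(bad, runs)) > 0) {
    abort(sprintf("calibration error: run(s) %s lack exactly one IPC sample",
                  paste(union(missing_meta, intersect(bad, runs)), collapse = ", ")))
  }
  ipc_ids <- meta |> dplyr::filter(.data$is_ipc) |>
    dplyr::select("run_id", ipc_sample = "sample_id")

  ipc_cq <- cq |>
    dplyr::inner_join(ipc_ids, by = "run_id") |>
    dplyr::filter(.data$sample_id == .data$ipc_sample) |>
    dplyr::group_by(.data$run_id, .data$primer_set) |>
    dplyr::summarise(ipc_cq = if (all(is.na(.data$cq))) NA_real_
                     else mean(.data$cq, na.rm = TRUE), .groups = "drop") |>
    dplyr::group_by(.data$primer_set) |>
    dplyr::mutate(ipc_mean = if (all(is.na(.data$ipc_cq))) NA_real_
                  else mean(.data$ipc_cq, na.rm = TRUE)) |>
    dplyr::ungroup() |>
    dplyr::mutate(ipc_offset = .data$ipc_cq - .data$ipc_mean) |>
    dplyr::select("run_id", "primer_set", "ipc_offset")

  cq |>
    dplyr::left_join(ipc_cq, by = c("run_id", "primer_set")) |>
    dplyr::mutate(
      uncorrectable = is.na(.data$ipc_offset),
      cq = ifelse(.data$uncorrectable, .data$cq, .data$cq - .data$ipc_offset)
    )
}

#' Exclude Cq values exceeding primer-specific cut-offs
#'
#' Values strictly above a primer set's cut-off (established from the highest
#' specific Cq seen in the assay verification step) are treated as unspecific
#' and replaced by no-calls; a value exactly at the cut-off is retained.
#' Primer sets without a supplied cut-off default to the total cycle count.
#'
#' @param cq Long Cq tibble.
#' @param cutoffs Tibble with columns `primer_set`, `max_cq`; may be `NULL`
#'   (all defaults).
#' @param default_cutoff Cut-off for sets absent from `cutoffs`.
#' @return The Cq tibble with exclusions applied and a logical `excluded`
#'   column; per-set exclusion counts are in `attr(, "exclusions")`.
#' @export
apply_cutoffs <- function(cq, cutoffs = NULL, default_cutoff = total_cycles()) {
  if (is.null(cutoffs)) {
    cutoffs <- tibble::tibble(primer_set = character(0), max_cq = numeric(0))
  }
  unknown <- setdiff(cutoffs$primer_set, unique(cq$primer_set))
  if (length(unknown) > 0) {
    warn(sprintf("cut-off table names unassayed primer set(s): %s",
                 paste(unknown, collapse = ", ")))
  }
  out <- cq |>
    dplyr::left_join(cutoffs, by = "primer_set") |>
    dplyr::mutate(
      max_cq = dplyr::coalesce(.data$max_cq, default_cutoff),
      excluded = !is.na(.data$cq) & .data$cq > .data$max_cq,
      cq = ifelse(.data$excluded, NA_real_, .data$cq)
    ) |>
    dplyr::select(-"max_cq")
  attr(out, "exclusions") <- out |>
    dplyr::group_by(.data$primer_set) |>
    dplyr::summarise(n_excluded = sum(.data$excluded), .groups = "drop")
  out
}

#' Collapse technical replicates to one Cq per sample and primer set
#'
#' Arithmetic mean of the called replicate values; with a single called
#' replicate that value is used, and with none the result is missing.
#' Discarding half-called duplicates would inflate missingness, so the
#' surviving call is kept.
#'
#' @param cq Long Cq tibble with a `replicate` column.
#' @return Tibble: `run_id` (if present), `sample_id`, `primer_set`, `cq`,
#'   `n_called`.
#' @export
collapse_replicates <- function(cq) {
  keys <- intersect(c("run_id", "sample_id", "primer_set"), names(cq))
  cq |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      n_called = sum(!is.na(.data$cq)),
      cq = if (all(is.na(.data$cq))) NA_real_ else mean(.data$cq, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::select(dplyr::all_of(keys), "cq", "n_called")
}

#' Livak relative quantification against a normalizer primer set
#'
#' Per sample, `R_X = 2^(Cq_N - Cq_X)` where N is the normalizer set assumed
#' to capture the whole community, so `R_X` is the fraction of total
#' template amplifiable by set X (under perfect per-cycle doubling). Samples
#' whose normalizer Cq is missing yield missing `R` throughout and are
#' flagged.
#'
#' @param cq_table Collapsed Cq tibble (`sample_id`, `primer_set`, `cq`).
#' @param normalizer Normalizer primer set name.
#' @return Tibble: `sample_id`, `primer_set`, `rel_abund`,
#'   `normalizer_missing`.
#' @export
livak_relative <- function(cq_table, normalizer = "bacteria_B") {
  if (!normalizer %in% cq_table$primer_set) {
    abort(sprintf("normalizer set '%s' absent from Cq table", normalizer))
  }
  norm <- cq_table |>
    dplyr::filter(.data$primer_set == normalizer) |>
    dplyr::select("sample_id", cq_norm = "cq")
  cq_table |>
    dplyr::left_join(norm, by = "sample_id") |>
    dplyr::mutate(
      rel_abund = 2^(.data$cq_norm - .data$cq),
      normalizer_missing = is.na(.data$cq_norm)
    ) |>
    dplyr::select("sample_id", "primer_set", "rel_abund", "normalizer_missing")
}

#' Total-bacteria quantity relative to the cycles run
#'
#' For the normalizer (general-bacteria) set itself the Livak ratio is
#' trivially 1, so its quantity is instead related to the total number of
#' amplification cycles: `R = 2^(total_cycles - Cq)`.
#'
#' @param cq_table Collapsed Cq tibble.
#' @param cycles Total amplification cycles (default 35, see
#'   [total_cycles()]).
#' @param normalizer Normalizer primer set name.
#' @return Tibble: `sample_id`, `rel_total`.
#' @export
total_bacteria_relative <- function(cq_table, cycles = total_cycles(),
                                    normalizer = "bacteria_B") {
  cq_table |>
    dplyr::filter(.data$primer_set == normalizer) |>
    dplyr::transmute(.data$sample_id, rel_total = 2^(cycles - .data$cq))
}

#' Normalize each sample's Cq values to its mean over all primer sets
#'
#' Alternative normalization: `R_X = 2^(mean_over_sets(Cq) - Cq_X)` per
#' sample, using the called values only.
#'
#' @param cq_table Collapsed Cq tibble.
#' @return Tibble: `sample_id`, `primer_set`, `rel_abund`.
#' @export
total_mean_normalize <- function(cq_table) {
  cq_table |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::mutate(rel_abund = 2^(mean(.data$cq, na.rm = TRUE) - .data$cq)) |>
    dplyr::ungroup() |>
    dplyr::select("sample_id", "primer_set", "rel_abund")
}

#' Cross-reaction fraction implied by a Cq separation
#'
#' Under ideal per-cycle doubling, an unspecific product first detected
#' `delta_cq` cycles after the specific one corresponds to a template
#' fraction of `2^-delta_cq`. A separation of 9 cycles therefore bounds
#' cross reaction below 1 percent.
#'
#' @param delta_cq Non-negative Cq difference(s) in cycles.
#' @return Fraction(s) in (0, 1].
#' @export
cross_reaction_fraction <- function(delta_cq) {
  if (any(delta_cq < 0)) abort("domain error: delta_cq must be >= 0")
  2^(-delta_cq)
}
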