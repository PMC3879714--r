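# 48.48 singleplex chip model: layout, thermal protocol, raw-Cq parsing.

#' Chip layout: detector inlets mapped to primer sets
#'
#' The microfluidic chip crosses `n_detector` assay inlets with `n_sample`
#' sample inlets into `n_detector * n_sample` singleplex chambers (2304 for
#' the 48.48 format). Primer sets occupy consecutive detector inlets in
#' technical duplicates by default.
#'
#' @param panel A `micropanel_panel`.
#' @param n_detector,n_sample Inlet counts (default 48 x 48).
#' @param replicates Technical replicates per primer set (default 2).
#' @return A `micropanel_layout`: tibble `assay_map` (detector, primer_set,
#'   replicate) plus dimensions.
#' @export
chip_layout <- function(panel, n_detector = 48L, n_sample = 48L, replicates = 2L) {
  sets <- panel$sets$set_name
  need <- length(sets) * replicates
  if (need != n_detector) {
    abort(sprintf("layout error: %d sets x %d replicates = %d detector inlets, chip has %d",
                  length(sets), replicates, need, n_detector))
  }
  assay_map <- tibble::tibble(
    detector = sprintf("D%02d", seq_len(n_detector)),
    primer_set = rep(sets, each = replicates),
    replicate = rep(seq_len(replicates), times = length(sets))
  )
  structure(list(assay_map = assay_map, n_detector = n_detector,
                 n_sample = n_sample, n_reactions = n_detector * n_sample),
            class = "micropanel_layout")
}

#' @export
print.micropanel_layout <- function(x, ...) {
  cat(sprintf("<micropanel_layout> %d detector x %d sample inlets = %d singleplex reactions\n",
              x$n_detector, x$n_sample, x$n_reactions))
  invisible(x)
}

#' The standard chip thermal protocol
#'
#' Stage list of the 48 x 48 standard amplification protocol: a hot-start
#' phase, interleaved PCR and C0t (re-annealing) cycling stages, and a final
#' extension. Only PCR and C0t stages count as amplification cycles; the
#' total (35) is the constant used when relating the general-bacteria Cq to
#' the number of cycles run.
#'
#' @return Tibble with columns `stage`, `kind`, `cycles`.
#' @export
thermal_protocol <- function() {
  tibble::tibble(
    stage = c("thermal mixing and hot start", "PCR cycle", "C0t cycle",
              "PCR cycle", "C0t cycle", "PCR cycle", "C0t cycle", "extension"),
    kind = c("hot_start", "pcr", "c0t", "pcr", "c0t", "pcr", "c0t", "extension"),
    cycles = c(1L, 10L, 2L, 8L, 2L, 8L, 5L, 1L)
  )
}

#' Total amplification cycles of a thermal protocol
#'
#' Sums the PCR and C0t stage cycle counts; hot start and final extension do
#' not amplify and are excluded.
#'
#' @param protocol A protocol tibble as returned by [thermal_protocol()].
#' @return Integer cycle count (35 for the standard protocol).
#' @export
total_cycles <- function(protocol = thermal_protocol()) {
  as.integer(sum(protocol$cycles[protocol$kind %in% c("pcr", "c0t")]))
}

parse_cq_cell <- function(x, decimal, no_call_tokens) {
  x <- trimws(x)
  if (x %in% no_call_tokens) return(NA_real_)
  if (decimal == "comma") x <- sub(",", ".", x, fixed = TRUE)
  suppressWarnings(as.numeric(x))
}

#' Load a raw Cq chip export
#'
#' Parses a grid CSV as exported from the chip's real-time analysis software:
#' first row detector labels, first column sample labels, one Cq per chamber.
#' Handles both point- and comma-decimal dialects (the vendor software emits
#' commas); designated no-call tokens map to `NA`.
#'
#' @param path CSV file.
#' @param layout A `micropanel_layout`; grid dimensions must match.
#' @param decimal `"auto"` (detect per file), `"point"` or `"comma"`.
#' @param no_call_tokens Cell values treated as no-calls (default empty and
#'   `"999"`).
#' @param run_id Run identifier attached to every parsed value (default: file
#'   name without extension).
#' @return Long tibble: `run_id`, `sample_id`, `detector`, `primer_set`,
#'   `replicate`, `cq`.
#' @export
load_cq <- function(path, layout, decimal = c("auto", "point", "comma"),
                    no_call_tokens = c("", "999"), run_id = NULL) {
  decimal <- match.arg(decimal)
  if (is.null(run_id)) run_id <- sub("\\.[^.]*$", "", basename(path))
  raw <- utils::read.csv(path, header = TRUE, check.names = FALSE,
                         colClasses = "character", row.names = NULL)
  sample_ids <- raw[[1]]
  detectors <- names(raw)[-1]
  grid <- raw[, -1, drop = FALSE]
  if (ncol(grid) != layout$n_detector) {
    abort(sprintf("dimension mismatch: %d detector columns, layout has %d",
                  ncol(grid), layout$n_detector))
  }
  if (nrow(grid) > layout$n_sample) {
    abort(sprintf("dimension mismatch: %d sample rows, layout allows %d",
                  nrow(grid), layout$n_sample))
  }
  if (decimal == "auto") {
    cells <- unlist(grid, use.names = FALSE)
    decimal <- if (any(grepl(",", cells, fixed = TRUE))) "comma" else "point"
  }
  long <- tidyr::expand_grid(sample_id = sample_ids, detector = detectors) |>
    dplyr::arrange(match(.data$sample_id, sample_ids))
  vals <- character(nrow(long))
  k <- 1L
  for (i in seq_along(sample_ids)) {
    vals[k:(k + length(detectors) - 1L)] <- as.character(unlist(grid[i, ]))
    k <- k + length(detectors)
  }
  cq <- vapply(vals, parse_cq_cell, numeric(1),
               decimal = decimal, no_call_tokens = no_call_tokens,
               USE.NAMES = FALSE)
  bad <- which(is.na(cq) & !trimws(vals) %in% no_call_tokens)
  if (length(bad) > 0) {
    abort(sprintf("unparseable Cq cell '%s' at sample '%s', detector '%s'",
                  vals[bad[1]], long$sample_id[bad[1]], long$detector[bad[1]]))
  }
  long |>
    dplyr::mutate(run_id = run_id, cq = cq) |>
    dplyr::left_join(layout$assay_map, by = "detector") |>
    dplyr::select("run_id", "sample_id", "detector", "primer_set", "replicate", "cq")
}

#' Export a Cq grid as CSV (and optionally a heatmap plot)
#'
#' Writes the chamber grid back to the chip's native CSV shape (samples in
#' rows, detector inlets in columns, no-calls as empty cells) so a run can be
#' archived or re-parsed; [plot_cq_heatmap()] renders the matching 48 x 48
#' heatmap.
#'
#' @param cq Long Cq tibble from [load_cq()] or [simulate_chip()].
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
export_heatmap <- function(cq, path) {
  wide <- cq |>
    dplyr::select("sample_id", "detector", "cq") |>
    tidyr::pivot_wider(names_from = "detector", values_from = "cq")
  utils::write.csv(wide, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Heatmap of a raw Cq chip run
#'
#' One tile per reaction chamber, coloured by Cq (low Cq = abundant target);
#' no-calls are drawn in a distinct colour.
#'
#' @param cq Long Cq tibble.
#' @return A ggplot object.
#' @export
plot_cq_heatmap <- function(cq) {
  ggplot2::ggplot(cq, ggplot2::aes(x = .data$detector, y = .data$sample_id,
                                   fill = .data$cq)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(na.value = "grey85", direction = -1) +
    ggplot2::labs(x = "detector inlet", y = "sample inlet", fill = "Cq") +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
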