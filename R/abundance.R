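# Log relative-abundance matrix assembly and variable selection.

#' Assemble the log relative-abundance matrix
#'
#' Combines per-sample Livak ratios (every set vs the normalizer) with the
#' normalizer's own cycles-relative quantity, takes the natural logarithm,
#' and joins the 2 x 2 design covariates (gut section, diarrhoeic status).
#' The calibrator sample is dropped.
#'
#' @param cq_table Collapsed Cq tibble (`sample_id`, `primer_set`, `cq`).
#' @param meta Metadata tibble: `sample_id`, `gut_section` (`"S"`/`"L"`),
#'   `status` (`"diarrhoea"`/`"healthy"`), `is_ipc`.
#' @param panel A `micropanel_panel` (supplies the normalizer name).
#' @param cycles Total amplification cycles for the normalizer's quantity.
#' @return Wide tibble: `sample_id`, `gut_section`, `status`, then one
#'   ln-abundance column per primer set (`NA` = missing).
#' @export
abundance_matrix <- function(cq_table, meta, panel, cycles = total_cycles()) {
  normalizer <- panel$normalizer
  keep <- meta |> dplyr::filter(!.data$is_ipc)
  cq_table <- cq_table |> dplyr::filter(.data$sample_id %in% keep$sample_id)

  rel <- livak_relative(cq_table, normalizer = normalizer) |>
    dplyr::filter(.data$primer_set != normalizer)
  tot <- total_bacteria_relative(cq_table, cycles = cycles,
                                 normalizer = normalizer) |>
    dplyr::transmute(.data$sample_id, primer_set = normalizer,
                     rel_abund = .data$rel_total,
                     normalizer_missing = FALSE)
  long <- dplyr::bind_rows(rel, tot) |>
    dplyr::mutate(ln_abund = log(.data$rel_abund))

  long |>
    dplyr::select("sample_id", "primer_set", "ln_abund") |>
    tidyr::pivot_wider(names_from = "primer_set", values_from = "ln_abund") |>
    dplyr::left_join(dplyr::select(keep, "sample_id", "gut_section", "status"),
                     by = "sample_id") |>
    dplyr::relocate("sample_id", "gut_section", "status")
}

abundance_vars <- function(abund) {
  setdiff(names(abund), c("sample_id", "gut_section", "status"))
}

#' Select primer-set variables for multivariate analysis
#'
#' Applies, in order: (1) drop variables with more than `max_missing` of the
#' data missing; (2) among surviving ancestor/descendant pairs of the panel
#' lineage whose ln-abundances correlate above `cor_threshold` (Pearson, on
#' pairwise-complete observations), retain only the highest-level variable —
#' conclusions for it then cover the collapsed sub-level sets; (3) among the
#' general-bacteria sets retain only the normalizer. The correlation rule
#' applies to lineage pairs only; unrelated variables are never collapsed.
#'
#' @param abund Abundance tibble from [abundance_matrix()].
#' @param panel A `micropanel_panel`.
#' @param max_missing Missing-fraction threshold (default 0.5).
#' @param cor_threshold Lineage-correlation threshold (default 0.99).
#' @return A `micropanel_selection`: list with `retained`, `dropped_missing`,
#'   `collapsed` (kept/dropped pairs with their correlation),
#'   `dropped_general`, and the per-variable `missing_fraction` table.
#' @export
select_variables <- function(abund, panel, max_missing = 0.5,
                             cor_threshold = 0.99) {
  vars <- abundance_vars(abund)
  unknown <- setdiff(vars, panel$sets$set_name)
  if (length(unknown) > 0) {
    abort(sprintf("variable(s) %s absent from panel",
                  paste(unknown, collapse = ", ")))
  }

  miss <- tibble::tibble(
    primer_set = vars,
    missing_fraction = vapply(vars, function(v) mean(is.na(abund[[v]])),
                              numeric(1))
  )
  dropped_missing <- miss$primer_set[miss$missing_fraction > max_missing]
  surviving <- setdiff(vars, dropped_missing)

  # lineage ancestor/descendant pairs among survivors
  ranks <- setNames(level_rank(panel$sets$level), panel$sets$set_name)
  pairs <- list()
  for (v in surviving) {
    anc <- intersect(panel_ancestors(panel, v), surviving)
    for (a in anc) pairs[[length(pairs) + 1L]] <- c(a, v)
  }
  collapsed <- tibble::tibble(kept = character(0), dropped = character(0),
                              correlation = numeric(0))
  drop_cor <- character(0)
  for (pr in pairs) {
    a <- pr[1]; d <- pr[2]
    r <- suppressWarnings(stats::cor(abund[[a]], abund[[d]],
                                     use = "pairwise.complete.obs"))
    if (!is.na(r) && r > cor_threshold) {
      collapsed <- dplyr::bind_rows(collapsed,
        tibble::tibble(kept = a, dropped = d, correlation = r))
      drop_cor <- union(drop_cor, d)
    }
  }
  surviving <- setdiff(surviving, drop_cor)

  general <- panel$sets$set_name[panel$sets$main_target == "Bacteria"]
  dropped_general <- setdiff(intersect(surviving, general), panel$normalizer)
  retained <- setdiff(surviving, dropped_general)

  structure(
    list(retained = retained,
         dropped_missing = dropped_missing,
         collapsed = collapsed,
         dropped_general = dropped_general,
         missing_fraction = miss),
    class = "micropanel_selection"
  )
}

#' @export
print.micropanel_selection <- function(x, ...) {
  cat(sprintf("<micropanel_selection> %d variables retained\n", length(x$retained)))
  cat(sprintf("  dropped for missingness: %s\n",
              if (length(x$dropped_missing)) paste(x$dropped_missing, collapse = ", ") else "none"))
  if (nrow(x$collapsed) > 0) {
    cat("  collapsed lineage pairs:\n")
    for (i in seq_len(nrow(x$collapsed))) {
      cat(sprintf("    %s -> kept %s (r = %.4f)\n", x$collapsed$dropped[i],
                  x$collapsed$kept[i], x$collapsed$correlation[i]))
    }
  }
  cat(sprintf("  general sets dropped: %s\n",
              if (length(x$dropped_general)) paste(x$dropped_general, collapse = ", ") else "none"))
  invisible(x)
}
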