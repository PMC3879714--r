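#' Universal amplicon-tagging tag pair
#'
#' The two 22-nt universal tails appended to the 5' end of every tagged panel
#' primer. They enable a barcode library to be incorporated during
#' amplification (4-primer amplicon tagging), so pooled amplicons can be
#' sequenced and demultiplexed afterwards.
#'
#' @return A list with elements `forward_tag` and `reverse_tag`.
#' @export
tag_pair <- function() {
  tags <- list(
    forward_tag = "ACACTGACGACATGGTTCTACA",
    reverse_tag = "TACGGTAGCAGAGACTTGGTCT"
  )
  stopifnot(nchar(tags$forward_tag) == 22L, nchar(tags$reverse_tag) == 22L)
  tags
}

TAXONOMIC_LEVELS <- c("domain", "phylum", "class", "family", "genus", "species")

level_rank <- function(level) match(level, TAXONOMIC_LEVELS)

#' Load the primer panel from a TSV file
#'
#' Reads a one-row-per-oligo primer table (set name, target, taxonomic level,
#' rRNA gene, orientation, IUPAC sequence, reference-genome position, expected
#' amplicon size, tag status, parent set) and assembles the panel object used
#' throughout the package. The shipped fixture
#' (`system.file("extdata", "primer_panel.tsv", package = "micropanel")`)
#' contains the full 24-set / 49-oligo gut panel.
#'
#' Positions follow the conventional numbering of the *E. coli* rRNA gene:
#' 1-based, with the forward position the 5'-most base of the forward primer's
#' binding site and the reverse position the 3'-most base of the reverse
#' site, so that amplicon length = reverse - forward + 1.
#'
#' @param path Path to the panel TSV.
#' @param normalizer Name of the primer set used as quantification
#'   denominator (the general-bacteria set covering the whole community).
#' @return A `micropanel_panel` object: a list with tibbles `oligos` and
#'   `sets`, plus `normalizer` and the universal `tags`.
#' @export
load_panel <- function(path, normalizer = "bacteria_B") {
  if (!file.exists(path)) abort(sprintf("panel file '%s' does not exist", path))
  raw <- tryCatch(
    utils::read.delim(path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE, na.strings = "NA",
                      colClasses = "character"),
    error = function(e) abort(sprintf("parse error in '%s': %s", path,
                                      conditionMessage(e))))
  if (nrow(raw) == 0) abort(sprintf("parse error: '%s' contains no oligo rows", path))
  required <- c("set_name", "main_target", "level", "gene", "orientation",
                "sequence", "ecoli_position", "size_bp", "tagged", "parent_set")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort(sprintf("parse error: missing column(s) %s",
                  paste(missing_cols, collapse = ", ")))
  }

  oligos <- tibble::as_tibble(raw)
  oligos$ecoli_position <- suppressWarnings(as.integer(oligos$ecoli_position))
  oligos$size_bp <- suppressWarnings(as.integer(oligos$size_bp))
  oligos$tagged <- toupper(oligos$tagged) == "TRUE"

  for (i in seq_len(nrow(oligos))) {
    row <- oligos[i, ]
    line <- i + 1L  # header is line 1
    if (is.na(row$set_name) || row$set_name == "" || is.na(row$sequence) ||
        row$sequence == "") {
      abort(sprintf("parse error at line %d: empty set name or sequence", line))
    }
    if (!row$orientation %in% c("forward", "reverse")) {
      abort(sprintf("parse error at line %d: orientation '%s'", line, row$orientation))
    }
    if (!row$level %in% TAXONOMIC_LEVELS) {
      abort(sprintf("parse error at line %d: unknown level '%s'", line, row$level))
    }
    if (!row$gene %in% c("16S", "23S")) {
      abort(sprintf("parse error at line %d: gene must be 16S or 23S", line))
    }
    bad <- setdiff(unique(strsplit(row$sequence, "")[[1]]), IUPAC_ALPHABET)
    if (length(bad) > 0) {
      abort(sprintf("parse error at line %d: non-IUPAC character(s) %s",
                    line, paste(bad, collapse = ", ")))
    }
    if (!is.na(row$ecoli_position) && row$ecoli_position < 1L) {
      abort(sprintf("parse error at line %d: position must be >= 1", line))
    }
  }

  dup <- duplicated(oligos[, c("set_name", "orientation", "sequence")])
  if (any(dup)) {
    abort(sprintf("validation error: duplicate (set, orientation, sequence) row(s): %s",
                  paste(unique(oligos$set_name[dup]), collapse = ", ")))
  }

  sets <- oligos |>
    dplyr::group_by(.data$set_name) |>
    dplyr::summarise(
      main_target = dplyr::first(.data$main_target),
      level = dplyr::first(.data$level),
      gene = dplyr::first(.data$gene),
      tagged = dplyr::first(.data$tagged),
      parent_set = dplyr::first(.data$parent_set),
      n_forward = sum(.data$orientation == "forward"),
      n_reverse = sum(.data$orientation == "reverse"),
      expected_sizes_bp = list(.data$size_bp[.data$orientation == "reverse"]),
      .groups = "drop"
    )

  bad_sets <- sets$set_name[sets$n_forward != 1L | sets$n_reverse < 1L]
  if (length(bad_sets) > 0) {
    abort(sprintf("validation error: set(s) %s need exactly 1 forward and >= 1 reverse oligo",
                  paste(bad_sets, collapse = ", ")))
  }

  # species-level assays are the only untagged ones
  sp <- sets$set_name[sets$level == "species"]
  if (any(oligos$tagged[oligos$set_name %in% sp])) {
    abort("validation error: species-level oligos must be untagged")
  }

  sizes <- oligos$size_bp[oligos$orientation == "reverse"]
  if (any(!is.na(sizes) & (sizes < 200L | sizes > 900L))) {
    abort("validation error: expected amplicon sizes must lie in [200, 900] bp")
  }

  # lineage must be acyclic and closed over set names
  parents <- setNames(sets$parent_set, sets$set_name)
  unknown <- setdiff(stats::na.omit(unique(sets$parent_set)), sets$set_name)
  if (length(unknown) > 0) {
    abort(sprintf("validation error: parent set(s) %s not in panel",
                  paste(unknown, collapse = ", ")))
  }
  for (s in sets$set_name) {
    seen <- character(0)
    cur <- s
    while (!is.na(parents[[cur]])) {
      if (cur %in% seen) abort("validation error: lineage contains a cycle")
      seen <- c(seen, cur)
      cur <- parents[[cur]]
    }
  }

  if (!normalizer %in% sets$set_name) {
    abort(sprintf("validation error: normalizer set '%s' not in panel", normalizer))
  }

  structure(
    list(oligos = oligos, sets = sets, normalizer = normalizer, tags = tag_pair()),
    class = "micropanel_panel"
  )
}

#' @export
print.micropanel_panel <- function(x, ...) {
  cat(sprintf("<micropanel_panel> %d primer sets, %d oligos (normalizer: %s)\n",
              nrow(x$sets), nrow(x$oligos), x$normalizer))
  print(dplyr::count(x$sets, .data$level, .data$gene))
  invisible(x)
}

#' Ancestor sets of a primer set in the panel lineage
#' @param panel A `micropanel_panel`.
#' @param set_name Primer set name.
#' @return Character vector of ancestor set names, nearest first.
#' @export
panel_ancestors <- function(panel, set_name) {
  parents <- setNames(panel$sets$parent_set, panel$sets$set_name)
  out <- character(0)
  cur <- set_name
  while (!is.na(parents[[cur]])) {
    cur <- parents[[cur]]
    out <- c(out, cur)
  }
  out
}

#' A primer set's clade: itself plus all descendant sets
#' @inheritParams panel_ancestors
#' @return Character vector of set names.
#' @export
panel_clade <- function(panel, set_name) {
  kids <- panel$sets$set_name
  out <- set_name
  repeat {
    more <- kids[!is.na(panel$sets$parent_set) & panel$sets$parent_set %in% out &
                   !kids %in% out]
    if (length(more) == 0) break
    out <- c(out, more)
  }
  out
}

#' Amplicon length from forward and reverse binding-site positions
#'
#' Inclusive 1-based convention: the forward position is the 5'-most
#' reference base of the forward site, the reverse position the 3'-most base
#' of the reverse site, so the product spans `rev_pos - fwd_pos + 1` bases.
#' This convention reproduces every printed size in the shipped panel table.
#'
#' @param fwd_pos,rev_pos 1-based reference positions (vectorised).
#' @return Integer amplicon length(s) in bp.
#' @export
amplicon_size_from_positions <- function(fwd_pos, rev_pos) {
  if (any(rev_pos < fwd_pos)) {
    abort("coordinate error: reverse position upstream of forward position")
  }
  as.integer(rev_pos - fwd_pos + 1L)
}

#' Check printed amplicon sizes against binding-site coordinates
#'
#' For every (set, reverse oligo) with both positions present, recomputes the
#' amplicon length from the coordinates and compares it with the printed
#' expected size. Rows lacking positions are marked not checkable.
#'
#' @param panel A `micropanel_panel`.
#' @return Tibble with one row per (set, reverse): positions, expected and
#'   computed size, and `consistent` (`TRUE`/`FALSE`, `NA` = not checkable).
#' @export
validate_panel <- function(panel) {
  fwd <- panel$oligos |>
    dplyr::filter(.data$orientation == "forward") |>
    dplyr::select("set_name", fwd_pos = "ecoli_position")
  rev <- panel$oligos |>
    dplyr::filter(.data$orientation == "reverse") |>
    dplyr::group_by(.data$set_name) |>
    dplyr::mutate(reverse_index = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::select("set_name", "reverse_index", rev_pos = "ecoli_position",
                  expected_size_bp = "size_bp")
  out <- dplyr::left_join(rev, fwd, by = "set_name") |>
    dplyr::mutate(
      computed_size_bp = ifelse(
        is.na(.data$fwd_pos) | is.na(.data$rev_pos), NA_integer_,
        as.integer(.data$rev_pos - .data$fwd_pos + 1L)),
      consistent = ifelse(
        is.na(.data$computed_size_bp) | is.na(.data$expected_size_bp), NA,
        .data$computed_size_bp == .data$expected_size_bp)
    ) |>
    dplyr::select("set_name", "reverse_index", "fwd_pos", "rev_pos",
                  "expected_size_bp", "computed_size_bp", "consistent")
  out
}

#' Prepend the universal tag to a tagged panel oligo
#'
#' Forward oligos receive the forward tag, reverse oligos the reverse tag, at
#' the 5' end (as synthesized). Species-specific oligos are untagged and
#' requesting a tagged sequence for one is an error.
#'
#' @param oligo One-row tibble (or list) with fields `sequence`,
#'   `orientation` and `tagged`.
#' @param tags A tag pair, see [tag_pair()].
#' @return The tagged 5'->3' sequence (length 22 + primer length).
#' @export
tagged_primer <- function(oligo, tags = tag_pair()) {
  if (!isTRUE(oligo$tagged)) {
    abort("contract violation: oligo is untagged (species-specific primers carry no tag)")
  }
  tag <- if (oligo$orientation == "forward") tags$forward_tag else tags$reverse_tag
  paste0(tag, oligo$sequence)
}
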