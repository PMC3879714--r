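# Seeded synthetic-data generator: reference taxonomy, community profiles,
# chip Cq matrices and tagged/barcoded amplicon reads with truth tables.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_dna <- function(sequence, rate) {
  chars <- strsplit(sequence, "")[[1]]
  hit <- runif(length(chars)) < rate
  if (any(hit)) {
    chars[hit] <- vapply(chars[hit], function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1)
    }, character(1))
  }
  paste(chars, collapse = "")
}

#' Generate sample barcodes with a minimum pairwise distance
#'
#' Synthetic stand-ins for a commercial barcode library: fixed-length
#' barcodes drawn by seeded rejection sampling so that every pair differs at
#' `min_dist` or more positions.
#'
#' @param sample_ids Character vector of sample names.
#' @param length Barcode length (default 10).
#' @param min_dist Minimum pairwise Hamming distance (default 5).
#' @param seed Integer seed.
#' @return Tibble `sample_id`, `barcode`.
#' @export
make_barcodes <- function(sample_ids, length = 10L, min_dist = 5L, seed = 1L) {
  withr::with_seed(seed, {
    out <- character(0)
    while (length(out) < base::length(sample_ids)) {
      cand <- random_dna(length)
      if (all(vapply(out, hamming, integer(1), b = cand) >= min_dist)) {
        out <- c(out, cand)
      }
    }
    tibble::tibble(sample_id = sample_ids, barcode = out)
  })
}

# representative community members: one per primer set (domain sets share the
# root member) plus a named Streptococcus species
panel_taxa <- function(panel) {
  target <- setNames(panel$sets$main_target, panel$sets$set_name)
  path_of <- function(set) {
    chain <- rev(c(set, panel_ancestors(panel, set)))
    root <- if (target[[set]] == "Archaea") character(0) else "Bacteria"
    paste(c(root, unname(target[chain])), collapse = ";")
  }
  sets <- setdiff(panel$sets$set_name, c("bacteria_A", "bacteria_B"))
  taxa <- tibble::tibble(
    taxon_id = c("bacteria_root", sets, "s_alactolyticus"),
    set_name = c("bacteria_B", sets, "streptococcus"),
    taxon_path = c("Bacteria", vapply(sets, path_of, character(1)),
                   paste0(path_of("streptococcus"), ";Streptococcus alactolyticus"))
  )
  taxa
}

# default healthy small-intestine community (fractions, normalized later):
# lactic-acid bacteria dominate a neonatal piglet gut, clostridia and
# enterobacteria are common, strict anaerobe specialists are rare
BASE_ABUNDANCE <- c(
  bacteria_root = 0.040, firmicutes = 0.060, bacilli = 0.030,
  enterococcus = 0.004, lactobacillus = 0.200, streptococcus = 0.100,
  s_alactolyticus = 0.060, clostridium_I = 0.050, c_perfringens = 0.030,
  clostridium_IV = 0.015, clostridium_XIV = 0.050, bacteroidetes = 0.040,
  bacteroides = 0.030, actinobacteria = 0.012, bifidobacteriaceae = 0.008,
  bg_proteobacteria = 0.020, enterobacteriaceae = 0.060, e_coli = 0.050,
  e_proteobacteria = 0.004, d_proteobacteria = 0.003, fusobacteria = 0.050,
  verrucomicrobia = 0.003, spirochaetes = 0.006, archaea = 0.004
)

#' Simulation configuration
#'
#' Bundles the generator's study conditions: group sizes (the study design's
#' 5/7/4/7 samples for S-, S+, L-, L+), planted multiplicative effects of
#' diarrhoea and of gut section on taxon abundances (the default plants the
#' 5-fold Streptococcus depletion under diarrhoea and a Gram-negative shift),
#' Cq noise levels in cycles, per-variable missingness, read counts and
#' per-base sequencing error.
#'
#' @param seed Integer seed (mandatory; all generator randomness derives
#'   from it).
#' @param group_sizes Named integer vector over `S-`, `S+`, `L-`, `L+`.
#' @param effects Named fold changes applied to taxa under diarrhoea.
#' @param section_effects Named fold changes applied in the large intestine.
#' @param cq_noise_sd Per-sample, per-primer-set biological Cq noise (cycles).
#' @param extra_set_noise_sd Small independent per-set noise added on top of
#'   (possibly shared) biological noise (cycles).
#' @param duplicate_sd Technical-duplicate Cq noise (cycles).
#' @param load_sd Per-sample total-load Cq noise (cycles).
#' @param missingness Scalar MCAR rate per (sample, primer set), at most
#'   0.35; or a named per-set vector (named rates may exceed 0.35 to emulate
#'   assay dropout of the kind that removes variables from analysis).
#' @param noise_groups Optional named map primer set -> noise-group label;
#'   sets sharing a label share their biological noise draw (used to emulate
#'   near-perfectly correlated lineage assays).
#' @param reads_per_sample Reads per sample and primer set.
#' @param error_rate Per-base substitution error rate of simulated reads.
#' @param read_length Maximum read length after the barcode/tag/primer head.
#' @return A `micropanel_sim_config` list.
#' @export
sim_config <- function(seed,
                       group_sizes = c("S-" = 5L, "S+" = 7L, "L-" = 4L, "L+" = 7L),
                       effects = c(streptococcus = 0.2, s_alactolyticus = 0.2,
                                   enterobacteriaceae = 2.5, e_coli = 2.5),
                       section_effects = c(bacteroidetes = 2, bacteroides = 2,
                                           clostridium_XIV = 1.8,
                                           lactobacillus = 0.5),
                       cq_noise_sd = 2, extra_set_noise_sd = 0.02,
                       duplicate_sd = 0.15, load_sd = 1,
                       missingness = 0.1, noise_groups = NULL,
                       reads_per_sample = 1000L, error_rate = 0.005,
                       read_length = 500L) {
  if (missing(seed)) abort("seed is mandatory")
  if (length(missingness) == 1 && is.null(names(missingness)) &&
      missingness > 0.35) {
    abort("config error: scalar missingness rate above 0.35")
  }
  if (any(missingness < 0 | missingness > 1) || error_rate < 0 || error_rate > 1) {
    abort("config error: rates must lie in [0, 1]")
  }
  structure(
    list(seed = as.integer(seed), group_sizes = group_sizes, effects = effects,
         section_effects = section_effects, cq_noise_sd = cq_noise_sd,
         extra_set_noise_sd = extra_set_noise_sd, duplicate_sd = duplicate_sd,
         load_sd = load_sd, missingness = missingness,
         noise_groups = noise_groups, reads_per_sample = reads_per_sample,
         error_rate = error_rate, read_length = read_length),
    class = "micropanel_sim_config"
  )
}

#' Per-group community profiles with planted effects
#'
#' Starts from the built-in base community, applies the configured
#' multiplicative diarrhoea effects in the `+` groups and section effects in
#' the `L` groups, and renormalizes each group to sum to 1.
#'
#' @param config A `micropanel_sim_config`.
#' @param taxa Taxa tibble (defaults to the panel representatives used by
#'   the built-in reference).
#' @return Tibble: `group`, `taxon_id`, `abundance` (fractions summing to 1
#'   within group).
#' @export
community_profiles <- function(config, taxa = NULL) {
  base <- BASE_ABUNDANCE
  if (!is.null(taxa)) base <- base[names(base) %in% taxa$taxon_id]
  groups <- names(config$group_sizes)
  out <- lapply(groups, function(gr) {
    ab <- base
    if (grepl("\\+", gr)) {
      for (tx in names(config$effects)) {
        if (tx %in% names(ab)) ab[tx] <- ab[tx] * config$effects[[tx]]
      }
    }
    if (startsWith(gr, "L")) {
      for (tx in names(config$section_effects)) {
        if (tx %in% names(ab)) ab[tx] <- ab[tx] * config$section_effects[[tx]]
      }
    }
    tibble::tibble(group = gr, taxon_id = names(ab),
                   abundance = unname(ab / sum(ab)))
  })
  dplyr::bind_rows(out)
}

#' Build the synthetic reference taxonomy and sequences
#'
#' Generates one pseudo-rRNA sequence per representative community member by
#' seeded mutation along the panel lineage (related taxa share recent
#' backbone), then plants every relevant primer binding site at its printed
#' reference coordinate, instantiating degenerate positions uniformly. Sites
#' are planted from the broadest to the most specific assay, so where two
#' binding sites physically overlap the more specific assay wins and the
#' broader one simply fails to amplify that member; the returned `amplicons`
#' truth table records every intact product (verified by in-silico PCR).
#'
#' @param panel A `micropanel_panel`.
#' @param seed Integer seed.
#' @param frame_length Length of the common coordinate frame (default 1300,
#'   covering all printed site coordinates).
#' @param mutation_rate Per-base substitution rate per lineage step.
#' @param n_decoys Additional site-free decoy sequences.
#' @return A `micropanel_refdb`: list with `taxa`, `sequences`
#'   (`reference_id`, `sequence`), `taxonomy` (`reference_id`,
#'   `taxon_path`) and the `amplicons` truth table.
#' @export
make_reference <- function(panel, seed, frame_length = 1300L,
                           mutation_rate = 0.02, n_decoys = 0L) {
  taxa <- panel_taxa(panel)
  withr::with_seed(seed, {
    root <- random_dna(frame_length)
    arch_root <- mutate_dna(root, 0.10)
    node_seq <- list()
    node_for <- function(set) {
      if (!is.null(node_seq[[set]])) return(node_seq[[set]])
      parent <- panel$sets$parent_set[panel$sets$set_name == set]
      base <- if (is.na(parent)) {
        if (panel$sets$main_target[panel$sets$set_name == set] == "Archaea")
          arch_root else root
      } else {
        node_for(parent)
      }
      node_seq[[set]] <<- mutate_dna(base, mutation_rate)
      node_seq[[set]]
    }

    other_forwards <- function(set) {
      o <- panel$oligos[panel$oligos$orientation == "forward" &
                          panel$oligos$tagged &
                          panel$oligos$set_name != set, ]
      o$sequence
    }
    plant <- function(sequence, set) {
      oligos <- panel$oligos[panel$oligos$set_name == set, ]
      fwd <- oligos[oligos$orientation == "forward", ]
      revs <- oligos[oligos$orientation == "reverse", ]
      sub_in <- function(s, at, piece) {
        paste0(substr(s, 1, at - 1L), piece,
               substr(s, at + nchar(piece), nchar(s)))
      }
      if (!is.na(fwd$ecoli_position)) {
        # keep the planted site assay-distinguishable: re-instantiate while
        # the instance is also an exact match of another tagged assay's
        # forward primer (e.g. the archaeal/general-bacteria pair binds the
        # same conserved position)
        others <- other_forwards(set)
        others <- others[nchar(others) == nchar(fwd$sequence)]
        for (try in 1:25) {
          inst <- iupac_instantiate(fwd$sequence)
          clash <- any(vapply(others, function(o) iupac_match(o, inst),
                              logical(1)))
          if (!clash || length(others) == 0) break
        }
        sequence <- sub_in(sequence, fwd$ecoli_position, inst)
      }
      for (i in seq_len(nrow(revs))) {
        if (is.na(revs$ecoli_position[i])) next
        site <- reverse_complement(iupac_instantiate(revs$sequence[i]))
        sequence <- sub_in(sequence,
                           revs$ecoli_position[i] - nchar(site) + 1L, site)
      }
      sequence
    }

    ranks <- setNames(level_rank(panel$sets$level), panel$sets$set_name)
    seqs <- character(nrow(taxa))
    for (i in seq_len(nrow(taxa))) {
      own <- taxa$set_name[i]
      s <- if (taxa$taxon_id[i] == "bacteria_root") root
           else if (taxa$taxon_id[i] == "s_alactolyticus")
             mutate_dna(node_for("streptococcus"), 0.01)
           else node_for(own)
      chain <- c(own, panel_ancestors(panel, own))
      domains <- if (grepl("^Archaea", taxa$taxon_path[i])) "archaea"
                 else c("bacteria_A", "bacteria_B")
      chain <- unique(c(chain, domains))
      chain <- chain[order(ranks[chain])]
      for (set in chain) s <- plant(s, set)
      seqs[i] <- s
    }

    sequences <- tibble::tibble(reference_id = taxa$taxon_id, sequence = seqs)
    if (n_decoys > 0) {
      dec <- tibble::tibble(
        reference_id = sprintf("decoy%02d", seq_len(n_decoys)),
        sequence = vapply(seq_len(n_decoys), function(i) random_dna(frame_length),
                          character(1)))
      sequences <- dplyr::bind_rows(sequences, dec)
    }

    amp <- list()
    for (i in seq_len(nrow(taxa))) {
      for (set in panel$sets$set_name) {
        hits <- predict_amplicons(panel, set, seqs[i], both_strands = FALSE)
        if (nrow(hits) > 0) {
          hits$taxon_id <- taxa$taxon_id[i]
          amp[[length(amp) + 1L]] <- hits
        }
      }
    }
    amplicons <- dplyr::bind_rows(amp) |>
      dplyr::select("set_name", "taxon_id", "reverse_index", "start", "end",
                    "length_bp")

    structure(
      list(taxa = taxa, sequences = sequences,
           taxonomy = tibble::tibble(reference_id = taxa$taxon_id,
                                     taxon_path = taxa$taxon_path),
           amplicons = amplicons),
      class = "micropanel_refdb"
    )
  })
}

#' @export
print.micropanel_refdb <- function(x, ...) {
  cat(sprintf("<micropanel_refdb> %d taxa, %d sequence(s), %d verified amplicon site pairs\n",
              nrow(x$taxa), nrow(x$sequences), nrow(x$amplicons)))
  invisible(x)
}

# expand group sizes into a per-sample metadata tibble
sample_sheet <- function(group_sizes) {
  rows <- lapply(names(group_sizes), function(gr) {
    n <- group_sizes[[gr]]
    if (n == 0) return(NULL)
    stem <- gsub("\\+", "p", gsub("-", "m", gr))
    tibble::tibble(
      group = gr,
      sample_id = sprintf("%s_%02d", stem, seq_len(n)),
      gut_section = substr(gr, 1, 1),
      status = if (grepl("\\+", gr)) "diarrhoea" else "healthy")
  })
  dplyr::bind_rows(rows)
}

# per-sample true relative abundance of each primer set: clade sum over the
# taxonomy, expressed relative to the total-bacteria clade
true_set_fractions <- function(panel, taxa, profile_group) {
  prof <- setNames(profile_group$abundance, profile_group$taxon_id)
  prof <- prof[taxa$taxon_id]
  clade_sum <- vapply(panel$sets$set_name, function(set) {
    sum(prof[taxon_in_clade(taxa$taxon_path, panel, set)])
  }, numeric(1))
  total_bact <- sum(prof[startsWith(taxa$taxon_path, "Bacteria")])
  clade_sum / total_bact
}

#' Simulate a chip run of the panel over the study design
#'
#' Inverts the Livak relation to generate raw Cq values: per sample the
#' total-bacteria Cq follows the gut section's typical load, each set's Cq is
#' offset by `-log2` of its true clade fraction, and noise is added at the
#' biological (per sample and set, optionally shared between sets of a
#' lineage) and technical-duplicate levels. Missingness is injected
#' completely at random per (sample, primer set); a calibrator (IPC) sample
#' with a fixed community and no missingness is appended to every run. The
#' truth table carries the planted fractions and noise-free Cq for recovery
#' tests.
#'
#' @param panel A `micropanel_panel`.
#' @param config A `micropanel_sim_config`.
#' @return List: `cq` (long tibble as from [load_cq()]), `meta`, `truth`,
#'   `layout`, `profiles`.
#' @export
simulate_chip <- function(panel, config) {
  layout <- chip_layout(panel)
  taxa <- panel_taxa(panel)
  profiles <- community_profiles(config, taxa)
  sheet <- sample_sheet(config$group_sizes)
  cycles <- total_cycles()
  sets <- panel$sets$set_name

  miss_rate <- function(set) {
    m <- config$missingness
    if (is.null(names(m))) m[[1]] else if (set %in% names(m)) m[[set]] else 0
  }
  group_of_set <- function(set) {
    ng <- config$noise_groups
    if (!is.null(ng) && set %in% names(ng)) ng[[set]] else set
  }
  noise_group <- vapply(sets, group_of_set, character(1))

  withr::with_seed(config$seed, {
    frac_by_group <- lapply(split(profiles, profiles$group),
                            function(pg) true_set_fractions(panel, taxa, pg))

    # total-bacteria Cq: more bacteria (lower Cq) in the large intestine
    base_cq_b <- c(S = cycles - 17, L = cycles - 20)

    cq_rows <- list()
    truth_rows <- list()
    for (i in seq_len(nrow(sheet))) {
      sm <- sheet[i, ]
      frac <- frac_by_group[[sm$group]]
      cq_b <- base_cq_b[[sm$gut_section]] + rnorm(1, 0, config$load_sd)
      eps <- setNames(rnorm(length(unique(noise_group)), 0, config$cq_noise_sd),
                      unique(noise_group))
      eta <- rnorm(length(sets), 0, config$extra_set_noise_sd)
      true_cq <- cq_b - log2(frac) + eps[noise_group] + eta
      miss <- runif(length(sets)) < vapply(sets, miss_rate, numeric(1))
      for (r in 1:2) {
        cq_rep <- true_cq + rnorm(length(sets), 0, config$duplicate_sd)
        cq_rep[miss] <- NA_real_
        cq_rep[!is.na(cq_rep) & cq_rep > cycles] <- NA_real_
        cq_rows[[length(cq_rows) + 1L]] <- tibble::tibble(
          sample_id = sm$sample_id, primer_set = sets, replicate = r,
          cq = unname(cq_rep))
      }
      truth_rows[[i]] <- tibble::tibble(
        sample_id = sm$sample_id, primer_set = sets,
        true_rel = unname(frac), true_cq = unname(true_cq))
    }

    # interplate calibrator: fixed healthy community, fixed load, no dropout
    ipc_frac <- true_set_fractions(panel, taxa,
                                   profiles[profiles$group == names(config$group_sizes)[1], ])
    ipc_cq <- (cycles - 20) - log2(ipc_frac)
    for (r in 1:2) {
      cq_rows[[length(cq_rows) + 1L]] <- tibble::tibble(
        sample_id = "IPC", primer_set = sets, replicate = r,
        cq = unname(ipc_cq + rnorm(length(sets), 0, config$duplicate_sd)))
    }

    cq <- dplyr::bind_rows(cq_rows) |>
      dplyr::left_join(layout$assay_map, by = c("primer_set", "replicate")) |>
      dplyr::mutate(run_id = "run1") |>
      dplyr::select("run_id", "sample_id", "detector", "primer_set",
                    "replicate", "cq")

    meta <- dplyr::bind_rows(
      sheet |>
        dplyr::transmute(run_id = "run1", .data$sample_id, .data$gut_section,
                         .data$status, is_ipc = FALSE, dna_conc = 50),
      tibble::tibble(run_id = "run1", sample_id = "IPC", gut_section = NA,
                     status = NA, is_ipc = TRUE, dna_conc = 50))

    list(cq = cq, meta = meta, truth = dplyr::bind_rows(truth_rows),
         layout = layout, profiles = profiles)
  })
}

#' Simulate tagged, barcoded amplicon reads with a truth table
#'
#' For each sample and tagged 16S primer set, draws `reads_per_sample` reads:
#' a taxon is chosen with probability proportional to its group abundance
#' among the set's amplifiable clade members, the read is assembled as
#' `barcode + forward tag + planted forward site + amplicon interior`
#' (truncated to the configured read length), substitution errors are applied
#' at the configured per-base rate, and qualities are set consistently with
#' that rate. Assays targeting the 23S gene are not simulated (the taxonomy
#' stage is 16S-only, and their products cannot pass the length filter).
#'
#' @param panel A `micropanel_panel`.
#' @param refdb A `micropanel_refdb` from [make_reference()].
#' @param config A `micropanel_sim_config`.
#' @param primer_sets Primer sets to simulate (default: all tagged 16S sets
#'   with at least one amplifiable taxon).
#' @param groups Study groups to include (default: all in the config).
#' @return List: `reads`, `barcodes`, `meta`, `truth` (read id -> sample,
#'   primer set, taxon).
#' @export
simulate_reads <- function(panel, refdb, config, primer_sets = NULL,
                           groups = NULL) {
  if (is.null(primer_sets)) {
    primer_sets <- panel$sets$set_name[panel$sets$tagged &
                                         panel$sets$gene == "16S"]
  }
  sheet <- sample_sheet(config$group_sizes)
  if (!is.null(groups)) sheet <- sheet[sheet$group %in% groups, , drop = FALSE]
  profiles <- community_profiles(config, refdb$taxa)
  barcodes <- make_barcodes(sheet$sample_id, seed = config$seed + 1L)
  tags <- panel$tags
  seq_of <- setNames(refdb$sequences$sequence, refdb$sequences$reference_id)

  # one product per (set, taxon): the first verified amplicon
  products <- refdb$amplicons |>
    dplyr::filter(.data$set_name %in% primer_sets) |>
    dplyr::group_by(.data$set_name, .data$taxon_id) |>
    dplyr::slice(1) |>
    dplyr::ungroup()

  q_char <- intToUtf8(33L + min(40L, as.integer(round(
    -10 * log10(max(config$error_rate, 1e-4))))))

  withr::with_seed(config$seed + 2L, {
    reads <- list()
    truth <- list()
    counter <- 0L
    for (i in seq_len(nrow(sheet))) {
      sm <- sheet[i, ]
      prof <- profiles[profiles$group == sm$group, ]
      ab <- setNames(prof$abundance, prof$taxon_id)
      bc <- barcodes$barcode[barcodes$sample_id == sm$sample_id]
      for (set in primer_sets) {
        pr <- products[products$set_name == set, ]
        pr <- pr[pr$taxon_id %in% names(ab), ]
        if (nrow(pr) == 0) next
        w <- ab[pr$taxon_id]
        if (sum(w) <= 0) next
        counts <- as.vector(stats::rmultinom(1, config$reads_per_sample,
                                             w / sum(w)))
        for (j in seq_len(nrow(pr))) {
          if (counts[j] == 0) next
          amp <- substr(seq_of[[pr$taxon_id[j]]], pr$start[j], pr$end[j])
          body <- paste0(bc, tags$forward_tag, amp)
          body <- substr(body, 1L,
                         nchar(bc) + 22L + config$read_length)
          for (r in seq_len(counts[j])) {
            counter <- counter + 1L
            s <- if (config$error_rate > 0) mutate_dna(body, config$error_rate)
                 else body
            reads[[counter]] <- s
            truth[[counter]] <- c(sm$sample_id, set, pr$taxon_id[j])
          }
        }
      }
    }
    read_tbl <- tibble::tibble(
      id = sprintf("read%07d", seq_along(reads)),
      sequence = unlist(reads),
      quality = strrep(q_char, nchar(unlist(reads))))
    truth_m <- do.call(rbind, truth)
    truth_tbl <- tibble::tibble(
      read_id = read_tbl$id, sample_id = truth_m[, 1],
      primer_set = truth_m[, 2], taxon_id = truth_m[, 3])
    meta <- sheet |>
      dplyr::transmute(.data$sample_id, .data$gut_section, .data$status,
                       is_ipc = FALSE)
    list(reads = read_tbl, barcodes = barcodes, meta = meta, truth = truth_tbl)
  })
}

#' The assay-dropout chip scenario used for variable selection
#'
#' Simulates the chip under the study's group sizes with the observed
#' missingness and correlation structure planted: five rare-clade assays
#' (Clostridium cluster IV, epsilon- and delta-proteobacteria,
#' Verrucomicrobia, Archaea) miss more than half their data, the two lineage
#' chains beta/gamma-proteobacteria ~ Enterobacteriaceae ~ E. coli and
#' Bacteroidetes ~ Bacteroides share their biological noise so their
#' log-abundances correlate above 0.99, and both general-bacteria assays are
#' run. Variable selection on this scenario retains 15 of the 24 sets.
#'
#' @param panel A `micropanel_panel`.
#' @param seed Integer seed.
#' @return As [simulate_chip()], plus the `config` used.
#' @export
scenario_paper_missingness <- function(panel, seed) {
  dropout_sets <- c("clostridium_IV", "e_proteobacteria", "d_proteobacteria",
                    "verrucomicrobia", "archaea")
  miss <- setNames(rep(0.05, nrow(panel$sets)), panel$sets$set_name)
  miss[dropout_sets] <- 0.8
  config <- sim_config(
    seed = seed,
    missingness = miss,
    noise_groups = c(bg_proteobacteria = "entero_chain",
                     enterobacteriaceae = "entero_chain",
                     e_coli = "entero_chain",
                     bacteroidetes = "bacteroides_chain",
                     bacteroides = "bacteroides_chain"))
  out <- simulate_chip(panel, config)
  out$config <- config
  out
}
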