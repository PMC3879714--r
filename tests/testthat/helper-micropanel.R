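# Shared fixtures and independent oracles for the test suite.

panel_fixture_path <- function() {
  system.file("extdata", "primer_panel.tsv", package = "micropanel")
}

the_panel <- load_panel(panel_fixture_path())

# --- small sequence helpers -------------------------------------------------

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

plant_site <- function(sequence, at, piece) {
  paste0(substr(sequence, 1, at - 1), piece,
         substr(sequence, at + nchar(piece), nchar(sequence)))
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# --- brute-force oracles ----------------------------------------------------

# exhaustive expansion of an IUPAC string into all concrete sequences
iupac_codes <- list(A = "A", C = "C", G = "G", T = "T",
                    R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                    W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                    B = c("C", "G", "T"), D = c("A", "G", "T"),
                    H = c("A", "C", "T"), V = c("A", "C", "G"),
                    N = c("A", "C", "G", "T"))

expand_iupac <- function(primer) {
  sets <- iupac_codes[strsplit(primer, "")[[1]]]
  grid <- do.call(expand.grid, c(sets, stringsAsFactors = FALSE))
  apply(grid, 1, paste, collapse = "")
}

oracle_iupac_match <- function(primer, target) {
  target %in% expand_iupac(primer)
}

# exact two-sided rank-sum p-value by full enumeration of group labelings
oracle_wilcoxon_p <- function(x1, x2) {
  pooled <- c(x1, x2)
  n1 <- length(x1)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n1)])
  combos <- utils::combn(length(pooled), n1)
  w_all <- apply(combos, 2, function(idx) sum(r[idx]))
  mu <- n1 * (length(pooled) + 1) / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

# k-mer set-overlap similarity by explicit set construction
oracle_kmer_similarity <- function(query, reference, k = 8) {
  kmers <- function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    unique(vapply(seq_len(n - k + 1),
                  function(i) substr(s, i, i + k - 1), character(1)))
  }
  qk <- kmers(query)
  if (length(qk) == 0) return(NA_real_)
  100 * length(intersect(qk, kmers(reference))) / length(qk)
}

# --- toy data builders ------------------------------------------------------

# abundance tibble over the 2x2 design with given per-cell mean vectors
make_abund <- function(n_per_cell, means, sigma, seed = 1) {
  p <- ncol(means)
  withr::with_seed(seed, {
    cells <- expand.grid(gut_section = c("S", "L"),
                         status = c("healthy", "diarrhoea"),
                         stringsAsFactors = FALSE)
    rows <- list()
    for (k in seq_len(nrow(cells))) {
      Z <- matrix(rnorm(n_per_cell * p), n_per_cell, p) %*% chol(sigma)
      X <- sweep(Z, 2, means[k, ], "+")
      d <- tibble::as_tibble(as.data.frame(X))
      names(d) <- paste0("v", seq_len(p))
      d$gut_section <- cells$gut_section[k]
      d$status <- cells$status[k]
      rows[[k]] <- d
    }
    out <- dplyr::bind_rows(rows)
    out$sample_id <- sprintf("s%03d", seq_len(nrow(out)))
    dplyr::relocate(out, "sample_id", "gut_section", "status")
  })
}

# closed-form ML fit on complete data (cell means + ML covariance)
closed_form_mle <- function(abund, variables) {
  X <- as.matrix(abund[, variables])
  cells <- paste(abund$gut_section,
                 ifelse(abund$status == "diarrhoea", "+", "-"), sep = "")
  lv <- unique(cells)
  means <- t(vapply(lv, function(cl) colMeans(X[cells == cl, , drop = FALSE]),
                    numeric(ncol(X))))
  R <- X - means[match(cells, lv), , drop = FALSE]
  list(means = means, sigma = crossprod(R) / nrow(X), levels = lv)
}

# long Cq tibble from a sample x set matrix of collapsed values
cq_long <- function(m) {
  tibble::as_tibble(as.data.frame(m)) |>
    dplyr::mutate(sample_id = rownames(m)) |>
    tidyr::pivot_longer(-"sample_id", names_to = "primer_set",
                        values_to = "cq")
}
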