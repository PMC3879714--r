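# Wilks likelihood-ratio tests for gut section and diarrhoeic status.

# reduced-model cell assignment for a contrast; returns list(cells, m)
# where m = number of mean vectors constrained equal
reduce_cells <- function(cells, contrast) {
  lab <- as.character(cells)
  merge_pairs <- switch(
    contrast,
    "S/L"   = list(c("S-", "L-"), c("S+", "L+")),
    "S+/S-" = list(c("S+", "S-")),
    "L+/L-" = list(c("L+", "L-")),
    abort(sprintf("unknown contrast '%s' (use \"S/L\", \"S+/S-\" or \"L+/L-\")",
                  contrast))
  )
  for (pr in merge_pairs) {
    if (!all(pr %in% lab)) {
      abort(sprintf("contrast %s needs groups %s in the data", contrast,
                    paste(pr, collapse = " and ")))
    }
    counts <- table(lab)[pr]
    if (any(counts < 2)) {
      abort(sprintf("group(s) %s have fewer than 2 samples",
                    paste(pr[counts < 2], collapse = ", ")))
    }
    lab[lab %in% pr] <- paste(pr, collapse = "=")
  }
  list(cells = factor(lab, levels = unique(lab)), m = length(merge_pairs))
}

# ML fit of the cell-means Gaussian on complete data; returns log|Sigma_hat|
fit_logdet <- function(X, cells, ridge = 0) {
  means <- matrix(0, nlevels(cells), ncol(X))
  for (k in seq_len(nlevels(cells))) {
    means[k, ] <- colMeans(X[as.integer(cells) == k, , drop = FALSE])
  }
  R <- X - means[as.integer(cells), , drop = FALSE]
  sigma <- crossprod(R) / nrow(X)
  p <- ncol(sigma)
  if (ridge > 0) sigma <- sigma + diag(ridge * sum(diag(sigma)) / p, p)
  determinant(sigma, logarithm = TRUE)$modulus[[1]]
}

#' Wilks likelihood-ratio test of group effects on the abundance profile
#'
#' Tests the effect of gut section (`"S/L"`) or of diarrhoeic status within
#' one section (`"S+/S-"`, `"L+/L-"`) on the joint vector of log
#' relative abundances. The full model gives every section-by-status cell its
#' own mean vector with a common unstructured covariance; the reduced model
#' equates the mean vectors of the contrasted groups (for `"S/L"`, within
#' each status, so status effects remain free to differ by section). The
#' statistic is the Bartlett-corrected `-2 log Lambda`, referred to a
#' chi-square with `p` degrees of freedom per constrained mean vector.
#'
#' @param abund Completed abundance tibble (no missing values in the tested
#'   variables; see [em_impute()]).
#' @param contrast `"S/L"`, `"S+/S-"` or `"L+/L-"`.
#' @param variables Variables to test (default: all abundance columns).
#' @param ridge Optional ridge factor applied to both covariance estimates.
#' @return A `micropanel_lrt` with the corrected and uncorrected statistics,
#'   degrees of freedom and p-value.
#' @export
wilks_lrt <- function(abund, contrast, variables = NULL, ridge = 0) {
  if (is.null(variables)) variables <- abundance_vars(abund)
  X <- as.matrix(abund[, variables, drop = FALSE])
  storage.mode(X) <- "double"
  if (anyNA(X)) abort("abundance matrix contains missing values; impute first")
  n <- nrow(X); p <- ncol(X)
  cells <- design_cells(abund)
  g <- nlevels(cells)
  red <- reduce_cells(cells, contrast)

  ld_full <- fit_logdet(X, cells, ridge = ridge)
  ld_red <- fit_logdet(X, red$cells, ridge = ridge)
  log_ratio <- max(ld_red - ld_full, 0)  # >= 0 up to round-off for nested fits

  m <- red$m
  df <- p * m
  bartlett <- (n - g) - (p - m + 1) / 2
  statistic <- bartlett * log_ratio
  p_value <- pchisq(statistic, df = df, lower.tail = FALSE)

  structure(
    list(contrast = contrast, statistic = statistic,
         statistic_uncorrected = n * log_ratio,
         df = df, p_value = p_value, n = n, p_vars = p,
         variables = variables),
    class = "micropanel_lrt"
  )
}

#' @export
print.micropanel_lrt <- function(x, ...) {
  cat(sprintf("<micropanel_lrt> contrast %s: -2 log Lambda = %.3f (Bartlett), df = %d, p = %.4g\n",
              x$contrast, x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Tidy a Wilks likelihood-ratio test
#' @param x A `micropanel_lrt`.
#' @param ... Unused.
#' @return One-row tibble: contrast, statistic, df, p.value, n, p_vars.
#' @method tidy micropanel_lrt
#' @export
tidy.micropanel_lrt <- function(x, ...) {
  tibble::tibble(contrast = x$contrast, statistic = x$statistic,
                 df = x$df, p.value = x$p_value, n = x$n, p_vars = x$p_vars)
}
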