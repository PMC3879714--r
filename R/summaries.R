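# Per-primer-set group summaries and the Wilcoxon stage for read densities.

#' Per-group estimated mean percentages with confidence intervals
#'
#' Back-transforms the fitted cell means of the log-abundance model to
#' estimated mean percentages relative to total bacteria
#' (`100 * exp(mean ln R)`), with Wald confidence limits computed on the log
#' scale and exponentiated — hence asymmetric about the estimate. Also
#' reports, per variable, the within-section status contrast p-value
#' (two-sided t on the fitted cell-mean difference).
#'
#' @param fit A `micropanel_em`.
#' @param conf_level Confidence level (default 0.95).
#' @return Tibble: `primer_set`, `group`, `n`, `estimate_pct`,
#'   `conf_low_pct`, `conf_high_pct`, `p_status` (the status p-value for the
#'   group's gut section; `NA` when that section lacks both status groups).
#' @export
primer_summaries <- function(fit, conf_level = 0.95) {
  m <- fit$model
  z <- qnorm(1 - (1 - conf_level) / 2)
  n_cell <- table(m$cells)
  # unbiased residual variance for standard errors (ML Sigma rescaled)
  s2 <- diag(m$sigma) * m$n / (m$n - m$g)
  df_resid <- m$n - m$g

  rows <- list()
  for (v in seq_along(m$variables)) {
    for (cl in levels(m$cells)) {
      mu <- m$means[cl, v]
      se <- sqrt(s2[v] / n_cell[[cl]])
      section <- substr(cl, 1, 1)
      other <- paste0(section, if (grepl("\\+", cl)) "-" else "+")
      p_status <- NA_real_
      if (other %in% levels(m$cells)) {
        d <- m$means[paste0(section, "+"), v] - m$means[paste0(section, "-"), v]
        se_d <- sqrt(s2[v] * (1 / n_cell[[paste0(section, "+")]] +
                                1 / n_cell[[paste0(section, "-")]]))
        p_status <- 2 * pt(abs(d / se_d), df = df_resid, lower.tail = FALSE)
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        primer_set = m$variables[v], group = cl, n = n_cell[[cl]],
        estimate_pct = 100 * exp(mu),
        conf_low_pct = 100 * exp(mu - z * se),
        conf_high_pct = 100 * exp(mu + z * se),
        p_status = p_status)
    }
  }
  dplyr::bind_rows(rows)
}

#' Wilcoxon rank-sum comparison of read densities between status groups
#'
#' Two-sided Wilcoxon rank-sum test of a per-sample quantity (typically a
#' taxon's read density) between two groups. With at most `exact_max_n`
#' samples per group and no ties the exact rank-sum distribution is used;
#' otherwise the normal approximation with continuity correction.
#'
#' @param data Data frame with one row per sample.
#' @param value Column holding the per-sample values (tidy-eval).
#' @param group Column holding the two-level grouping (tidy-eval).
#' @param exact_max_n Largest per-group size for the exact test.
#' @return One-row tibble: `statistic`, `p_value`, `method`, `n1`, `n2`.
#' @export
wilcoxon_by_status <- function(data, value, group, exact_max_n = 10L) {
  x <- dplyr::pull(data, {{ value }})
  g <- as.character(dplyr::pull(data, {{ group }}))
  lev <- unique(g)
  if (length(lev) != 2) {
    abort(sprintf("need exactly two groups, got %d", length(lev)))
  }
  x1 <- x[g == lev[1]]
  x2 <- x[g == lev[2]]
  if (length(x1) == 0 || length(x2) == 0) abort("empty group")
  ties <- any(duplicated(c(x1, x2)))
  exact <- length(x1) <= exact_max_n && length(x2) <= exact_max_n && !ties
  ht <- suppressWarnings(
    stats::wilcox.test(x1, x2, alternative = "two.sided", exact = exact,
                       correct = TRUE)
  )
  tibble::tibble(statistic = unname(ht$statistic), p_value = ht$p.value,
                 method = if (exact) "exact" else "normal approximation",
                 n1 = length(x1), n2 = length(x2))
}
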