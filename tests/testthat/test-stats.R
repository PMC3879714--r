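# Variable selection, EM imputation, Wilks tests and Wilcoxon stage.

test_that("selection drops only the redundant general assay on clean data", {
  means <- matrix(0, 4, 3)
  ab <- make_abund(6, means, diag(3), seed = 2)
  names(ab)[4:6] <- c("bacteria_B", "bacteria_A", "streptococcus")
  sel <- select_variables(ab, the_panel)
  expect_setequal(sel$retained, c("bacteria_B", "streptococcus"))
  expect_equal(sel$dropped_general, "bacteria_A")
  expect_equal(length(sel$dropped_missing), 0L)
  expect_equal(nrow(sel$collapsed), 0L)
})

test_that("perfect correlation collapses lineage pairs only", {
  withr::with_seed(4, {
    n <- 24
    ab <- tibble::tibble(
      sample_id = sprintf("s%02d", 1:n),
      gut_section = rep(c("S", "L"), each = n / 2),
      status = rep(rep(c("healthy", "diarrhoea"), each = n / 4), 2),
      bacteria_B = rnorm(n))
    base <- rnorm(n)
    ab$bacteroidetes <- base
    ab$bacteroides <- 2 * base + 1        # r = 1, lineage pair -> collapse
    ab$fusobacteria <- ab$spirochaetes <- rnorm(n)  # r = 1, NOT a lineage pair
    sel <- select_variables(ab, the_panel)
    expect_true("bacteroidetes" %in% sel$retained)
    expect_false("bacteroides" %in% sel$retained)
    # unrelated variables stay even at r = 1
    expect_true(all(c("fusobacteria", "spirochaetes") %in% sel$retained))
    expect_equal(sel$collapsed$kept, "bacteroidetes")
  })
})

test_that("selection is invariant to input column order", {
  sc <- scenario_paper_missingness(the_panel, seed = 31)
  ab <- abundance_matrix(collapse_replicates(sc$cq), sc$meta, the_panel)
  sel1 <- select_variables(ab, the_panel)
  vars <- abundance_vars(ab)
  ab2 <- ab[, c(names(ab)[1:3], rev(vars))]
  sel2 <- select_variables(ab2, the_panel)
  expect_setequal(sel1$retained, sel2$retained)
  expect_equal(length(sel1$retained), 15L)
})

test_that("EM with no missing data equals the closed-form fit exactly", {
  means <- matrix(rnorm(12), 4, 3)
  sigma <- diag(3) * 0.5 + 0.2
  ab <- make_abund(8, means, sigma, seed = 5)
  vars <- paste0("v", 1:3)
  fit <- em_impute(ab, vars)
  ref <- closed_form_mle(ab, vars)
  expect_equal(unname(fit$model$means[ref$levels, ]), unname(ref$means),
               tolerance = 1e-10)
  expect_equal(unname(fit$model$sigma), unname(ref$sigma), tolerance = 1e-10)
  expect_equal(as.matrix(fit$completed[, vars]), as.matrix(ab[, vars]),
               ignore_attr = TRUE)
  expect_equal(sum(fit$imputed), 0L)
  g <- glance(fit)
  expect_true(g$converged)
})

test_that("single-variable MCAR imputation returns the cell mean", {
  means <- matrix(c(1, 2, 3, 4), 4, 1)
  ab <- make_abund(10, means, matrix(0.4), seed = 6)
  withr::with_seed(7, {
    miss <- sample(nrow(ab), 8)
    ab$v1[miss] <- NA
  })
  fit <- em_impute(ab, "v1")
  cells <- paste(ab$gut_section,
                 ifelse(ab$status == "diarrhoea", "+", "-"), sep = "")
  for (i in miss) {
    cell_mean <- fit$model$means[cells[i], "v1"]
    expect_equal(fit$completed$v1[i], unname(cell_mean), tolerance = 1e-7)
  }
})

test_that("EM log-likelihood is monotone and recovery is calibrated", {
  mu <- c(0.5, -1)
  sigma <- matrix(c(1, 0.6, 0.6, 2), 2)
  n_rep <- 50
  mu_hat <- matrix(NA_real_, n_rep, 2)
  sig_hat <- array(NA_real_, c(n_rep, 2, 2))
  for (r in seq_len(n_rep)) {
    means <- rbind(mu, mu, mu, mu)
    ab <- make_abund(50, means, sigma, seed = 100 + r)  # n = 200
    withr::with_seed(200 + r, {
      for (v in c("v1", "v2")) {
        ab[[v]][runif(nrow(ab)) < 0.2] <- NA   # 20% MCAR
      }
    })
    fit <- em_impute(ab, c("v1", "v2"))
    # monotone trajectory, asserted on every run
    expect_true(all(diff(fit$model$trajectory) >=
                      -1e-8 * (abs(fit$model$loglik) + 1)))
    mu_hat[r, ] <- colMeans(fit$model$means)
    sig_hat[r, , ] <- fit$model$sigma
  }
  # grand means within 3 Monte-Carlo SE of the truth
  for (j in 1:2) {
    mc_se <- sd(mu_hat[, j]) / sqrt(n_rep)
    expect_lt(abs(mean(mu_hat[, j]) - mu[j]), 3 * mc_se)
  }
  # covariance entries within 15% relative error on average
  sig_bar <- apply(sig_hat, c(2, 3), mean)
  expect_true(all(abs(sig_bar - sigma) / abs(sigma) < 0.15))
})

test_that("imputation guards reject unusable inputs", {
  means <- matrix(0, 4, 2)
  ab <- make_abund(6, means, diag(2), seed = 8)
  ab$v1[ab$gut_section == "S" & ab$status == "healthy"] <- NA
  expect_error(em_impute(ab, c("v1", "v2")), "missing-fraction|no observed")
  ab2 <- make_abund(3, means, diag(2), seed = 9)
  ab2$v1[1:2] <- NA
  fit_ok <- em_impute(ab2, c("v1", "v2"), max_missing = 0.35)
  expect_s3_class(fit_ok, "micropanel_em")
})

test_that("standardized residuals whiten the fitted model", {
  means <- matrix(rnorm(8), 4, 2)
  sigma <- matrix(c(2, 1.2, 1.2, 1.5), 2)
  covs <- array(NA_real_, c(10, 2, 2))
  for (r in 1:10) {
    ab <- make_abund(250, means, sigma, seed = 300 + r)  # n = 1000
    fit <- em_impute(ab, c("v1", "v2"))
    Z <- standardized_residuals(fit)
    covs[r, , ] <- crossprod(Z) / nrow(Z)
  }
  avg <- apply(covs, c(2, 3), mean)
  expect_lt(norm(avg - diag(2), "F"), 0.1)

  # identity covariance leaves residuals unchanged
  ab <- make_abund(50, matrix(0, 4, 2), diag(2), seed = 42)
  fit <- em_impute(ab, c("v1", "v2"))
  fit$model$sigma <- diag(2)
  Z <- standardized_residuals(fit)
  R <- as.matrix(fit$completed[, c("v1", "v2")]) -
    fit$model$means[fit$model$cells, ]
  expect_equal(unname(Z), unname(R), ignore_attr = TRUE)

  # singular covariance is refused with a remediation hint
  fit$model$sigma <- matrix(1, 2, 2)
  expect_error(standardized_residuals(fit), "singular")
  expect_silent(standardized_residuals(fit, ridge = 1e-6))
})

test_that("Wilks test: null statistic vanishes for duplicated groups", {
  # identical group labels duplicated: the contrasted cells carry identical
  # data, so Lambda = 1 and the statistic is ~0
  means <- matrix(0, 4, 3)
  ab <- make_abund(6, means, diag(3), seed = 10)
  half <- ab[ab$gut_section == "S" & ab$status == "healthy", ]
  dup <- half
  dup$status <- "diarrhoea"
  dup$sample_id <- paste0(dup$sample_id, "dup")
  both <- dplyr::bind_rows(
    half, dup,
    ab[ab$gut_section == "L", ])
  res <- wilks_lrt(both, "S+/S-", variables = paste0("v", 1:3))
  expect_lt(res$statistic, 1e-8)
  expect_equal(res$p_value, 1, tolerance = 1e-6)
})

test_that("Wilks statistic is invariant under affine rescaling", {
  means <- matrix(rnorm(12, sd = 0.5), 4, 3)
  ab <- make_abund(10, means, diag(3) + 0.3, seed = 12)
  r1 <- wilks_lrt(ab, "S+/S-")
  ab2 <- ab
  ab2$v1 <- 100 * ab2$v1 - 7
  ab2$v3 <- -0.01 * ab2$v3
  r2 <- wilks_lrt(ab2, "S+/S-")
  expect_equal(r1$statistic, r2$statistic, tolerance = 1e-8)
  td <- tidy(r1)
  expect_equal(td$p.value, r1$p_value)
})

test_that("Wilks test has power against a planted shift", {
  # 2 SD shift in one of four variables at n = 40
  hits <- 0
  n_rep <- 100
  for (r in seq_len(n_rep)) {
    means <- matrix(0, 4, 4)
    ab <- make_abund(10, means, diag(4), seed = 500 + r)
    ab$v1[ab$gut_section == "S" & ab$status == "diarrhoea"] <-
      ab$v1[ab$gut_section == "S" & ab$status == "diarrhoea"] + 2
    if (wilks_lrt(ab, "S+/S-")$p_value < 0.05) hits <- hits + 1
  }
  expect_gt(hits / n_rep, 0.8)
})

test_that("Wilks test rejects undersized groups", {
  means <- matrix(0, 4, 2)
  ab <- make_abund(5, means, diag(2), seed = 13)
  idx <- which(ab$gut_section == "S" & ab$status == "diarrhoea")
  ab <- ab[-idx[-1], ]
  expect_error(wilks_lrt(ab, "S+/S-"), "fewer than 2")
})

test_that("summaries back-transform cell means with asymmetric intervals", {
  means <- matrix(c(0, 0, 0, 0,
                    -2, -2, -2, -2), 4, 2)
  ab <- make_abund(60, means, diag(2) * 0.3, seed = 14)
  fit <- em_impute(ab, c("v1", "v2"))
  sm <- primer_summaries(fit)
  expect_equal(nrow(sm), 8L)
  # zero mean on the log scale ~ 100%
  v1 <- sm[sm$primer_set == "v1", ]
  expect_true(all(abs(v1$estimate_pct - 100) < 40))
  expect_true(all(sm$conf_low_pct <= sm$estimate_pct &
                    sm$estimate_pct <= sm$conf_high_pct))
  expect_true(all(sm$conf_low_pct > 0))
  # convexity of exp: upper gap exceeds lower gap
  expect_true(all((sm$conf_high_pct - sm$estimate_pct) >
                    (sm$estimate_pct - sm$conf_low_pct)))
  # estimates track 100 * exp(true mean)
  v2 <- sm[sm$primer_set == "v2", ]
  expect_true(all(abs(log(v2$estimate_pct / 100) - (-2)) < 0.5))
})

test_that("rank-sum stage matches exact enumeration", {
  d <- tibble::tibble(dens = c(1, 2, 3, 4, 5, 6),
                      status = rep(c("healthy", "diarrhoea"), each = 3))
  out <- wilcoxon_by_status(d, dens, status)
  expect_equal(out$p_value, 0.1)
  expect_equal(out$method, "exact")

  # identical groups
  d2 <- tibble::tibble(dens = rep(c(5, 7, 9), 2),
                       status = rep(c("healthy", "diarrhoea"), each = 3))
  expect_equal(wilcoxon_by_status(d2, dens, status)$p_value, 1)

  expect_error(
    wilcoxon_by_status(tibble::tibble(dens = 1:3, status = "healthy"),
                       dens, status), "two groups")

  # brute-force enumeration oracle on random tie-free inputs
  withr::with_seed(15, {
    for (rep in 1:20) {
      n1 <- sample(2:7, 1); n2 <- sample(2:7, 1)
      x <- sample(1000, n1 + n2)  # distinct -> no ties
      d3 <- tibble::tibble(dens = x,
                           status = rep(c("a", "b"), c(n1, n2)))
      got <- wilcoxon_by_status(d3, dens, status)$p_value
      expect_equal(got, oracle_wilcoxon_p(x[1:n1], x[-(1:n1)]),
                   tolerance = 1e-12)
    }
  })
})
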