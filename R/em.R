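# EM imputation under a covariate-dependent multivariate Gaussian.

# cell label per sample: gut section x diarrhoeic status
design_cells <- function(abund) {
  lab <- paste(abund$gut_section,
               ifelse(abund$status == "diarrhoea", "+", "-"), sep = "")
  factor(lab, levels = unique(lab))
}

# observed-data log-likelihood: sum over samples of the marginal Gaussian
# density of the observed coordinates
obs_loglik <- function(X, cells, means, sigma) {
  ll <- 0
  for (i in seq_len(nrow(X))) {
    obs <- which(!is.na(X[i, ]))
    if (length(obs) == 0) next
    mu <- means[cells[i], obs]
    S <- sigma[obs, obs, drop = FALSE]
    ch <- chol(S)
    z <- backsolve(ch, X[i, obs] - mu, transpose = TRUE)
    ll <- ll - 0.5 * (length(obs) * log(2 * pi) + 2 * sum(log(diag(ch))) +
                        sum(z^2))
  }
  ll
}

#' EM imputation of missing log-abundances
#'
#' Fits a multivariate Gaussian in which every primer-set variable depends
#' freely on the others (unstructured covariance) and on gut section,
#' diarrhoeic status and their interaction (cell means over the 2 x 2
#' design), substituting missing entries by their conditional expectations.
#' The E-step computes conditional means and covariances of the missing
#' coordinates given the observed ones; the M-step updates cell means and
#' the pooled covariance (maximum-likelihood denominator `n`, so likelihood
#' ratios of nested fits are internally consistent). The observed-data
#' log-likelihood is non-decreasing across iterations and is checked.
#'
#' @param abund Abundance tibble from [abundance_matrix()] (typically after
#'   [select_variables()]).
#' @param variables Variables to model (default: all abundance columns).
#' @param tol Relative log-likelihood change declaring convergence.
#' @param max_iter Maximum EM iterations.
#' @param max_missing Largest tolerated per-variable missing fraction; the
#'   imputation model is trusted only for modest missingness.
#' @param ridge Optional stabilizer for near-singular covariances (when the
#'   variable count approaches the sample count): after each update the
#'   covariance becomes `sigma + ridge * tr(sigma)/p * I`. With a ridge the
#'   strict monotonicity guarantee of plain EM is only approximate, so the
#'   monotonicity check downgrades to a warning.
#' @return A `micropanel_em`: list with `completed` (abundance tibble with
#'   imputed entries), `imputed` (logical matrix), and `model` (cell means,
#'   covariance, log-likelihood trajectory, design bookkeeping).
#' @export
em_impute <- function(abund, variables = NULL, tol = 1e-8, max_iter = 500L,
                      max_missing = 0.35, ridge = 0) {
  if (is.null(variables)) variables <- abundance_vars(abund)
  X <- as.matrix(abund[, variables, drop = FALSE])
  storage.mode(X) <- "double"
  n <- nrow(X); p <- ncol(X)
  cells <- design_cells(abund)
  g <- nlevels(cells)
  if (n <= g) abort(sprintf("need more samples (%d) than design cells (%d)", n, g))

  mf <- colMeans(is.na(X))
  if (any(mf > max_missing)) {
    abort(sprintf("variable(s) %s exceed the %.2f missing-fraction bound; run select_variables() first",
                  paste(variables[mf > max_missing], collapse = ", "), max_missing))
  }
  for (cl in levels(cells)) {
    sub <- X[cells == cl, , drop = FALSE]
    dead <- colSums(!is.na(sub)) == 0
    if (any(dead)) {
      abort(sprintf("variable(s) %s have no observed value in cell %s",
                    paste(variables[dead], collapse = ", "), cl))
    }
  }

  # initialization: observed cell means; complete-case ML covariance
  means <- matrix(0, g, p, dimnames = list(levels(cells), variables))
  for (cl in levels(cells)) {
    means[cl, ] <- colMeans(X[cells == cl, , drop = FALSE], na.rm = TRUE)
  }
  cc <- stats::complete.cases(X)
  if (sum(cc) > p) {
    R0 <- X[cc, , drop = FALSE] - means[cells[cc], , drop = FALSE]
    sigma <- crossprod(R0) / sum(cc)
  } else {
    sigma <- diag(apply(X, 2, var, na.rm = TRUE), p)
  }
  diag(sigma) <- pmax(diag(sigma), 1e-10)
  if (ridge > 0) sigma <- sigma + diag(ridge * sum(diag(sigma)) / p, p)

  trajectory <- numeric(0)
  ll_prev <- -Inf
  converged <- FALSE
  warned <- FALSE
  Xhat <- X
  for (iter in seq_len(max_iter)) {
    # E-step
    Csum <- matrix(0, p, p)
    for (i in seq_len(n)) {
      mis <- which(is.na(X[i, ]))
      if (length(mis) == 0) next
      obs <- which(!is.na(X[i, ]))
      mu <- means[cells[i], ]
      if (length(obs) == 0) {
        Xhat[i, ] <- mu
        Csum <- Csum + sigma
        next
      }
      Soo <- sigma[obs, obs, drop = FALSE]
      Smo <- sigma[mis, obs, drop = FALSE]
      W <- Smo %*% solve(Soo)
      Xhat[i, mis] <- mu[mis] + W %*% (X[i, obs] - mu[obs])
      Csum[mis, mis] <- Csum[mis, mis] +
        sigma[mis, mis, drop = FALSE] - W %*% t(Smo)
    }
    # M-step
    for (cl in levels(cells)) {
      means[cl, ] <- colMeans(Xhat[cells == cl, , drop = FALSE])
    }
    R <- Xhat - means[cells, , drop = FALSE]
    sigma <- (crossprod(R) + Csum) / n
    sigma <- (sigma + t(sigma)) / 2
    if (ridge > 0) sigma <- sigma + diag(ridge * sum(diag(sigma)) / p, p)

    ll <- obs_loglik(X, cells, means, sigma)
    trajectory <- c(trajectory, ll)
    if (is.finite(ll_prev)) {
      if (ll < ll_prev - 1e-8 * (abs(ll_prev) + 1)) {
        msg <- sprintf("EM log-likelihood decreased at iteration %d (%.8f -> %.8f)",
                       iter, ll_prev, ll)
        if (ridge > 0) {
          if (!warned) warn(paste(msg, "(expected with a ridge; reported once)"))
          warned <- TRUE
        } else {
          abort(msg)
        }
      }
      if (abs(ll - ll_prev) < tol * (abs(ll_prev) + 1)) {
        converged <- TRUE
        break
      }
    }
    ll_prev <- ll
  }
  if (!converged && any(is.na(X))) {
    abort(
      sprintf("EM did not converge within %d iterations", max_iter),
      class = "micropanel_em_nonconvergence",
      trajectory = trajectory
    )
  }

  completed <- abund
  completed[, variables] <- as.data.frame(Xhat)

  structure(
    list(
      completed = completed,
      imputed = is.na(X),
      model = list(
        means = means, sigma = sigma,
        loglik = trajectory[length(trajectory)],
        trajectory = trajectory, n_iter = length(trajectory),
        converged = converged, cells = cells, variables = variables,
        n = n, p = p, g = g
      )
    ),
    class = "micropanel_em"
  )
}

#' @export
print.micropanel_em <- function(x, ...) {
  m <- x$model
  cat(sprintf("<micropanel_em> %d samples x %d variables, %d design cells\n",
              m$n, m$p, m$g))
  cat(sprintf("  imputed entries: %d; log-likelihood %.3f after %d iteration(s)\n",
              sum(x$imputed), m$loglik, m$n_iter))
  invisible(x)
}

#' Tidy the fitted Gaussian cell means
#' @param x A `micropanel_em`.
#' @param ... Unused.
#' @return Tibble: `primer_set`, `group`, `mean_ln`.
#' @method tidy micropanel_em
#' @export
tidy.micropanel_em <- function(x, ...) {
  m <- x$model
  tibble::as_tibble(m$means, rownames = "group") |>
    tidyr::pivot_longer(-"group", names_to = "primer_set",
                        values_to = "mean_ln") |>
    dplyr::select("primer_set", "group", "mean_ln") |>
    dplyr::arrange(.data$primer_set, .data$group)
}

#' One-row model summary of an EM fit
#' @param x A `micropanel_em`.
#' @param ... Unused.
#' @return Tibble with `n`, `p`, `n_imputed`, `loglik`, `n_iter`, `converged`.
#' @method glance micropanel_em
#' @export
glance.micropanel_em <- function(x, ...) {
  m <- x$model
  tibble::tibble(n = m$n, p = m$p, n_imputed = sum(x$imputed),
                 loglik = m$loglik, n_iter = m$n_iter, converged = m$converged)
}

# symmetric inverse square root, optionally ridge-stabilized
sigma_inv_sqrt <- function(sigma, ridge = 0) {
  p <- ncol(sigma)
  if (ridge > 0) sigma <- sigma + diag(ridge * sum(diag(sigma)) / p, p)
  e <- eigen(sigma, symmetric = TRUE)
  if (min(e$values) <= 1e-12 * max(e$values)) {
    abort("covariance is singular; pass a small ridge (e.g. ridge = 1e-6) to stabilize")
  }
  e$vectors %*% diag(1 / sqrt(e$values), p) %*% t(e$vectors)
}

#' Standardized model residuals
#'
#' Residuals from the fitted cell means, right-multiplied by the symmetric
#' inverse square root of the estimated covariance. At the fitted model the
#' standardized residuals have identity covariance up to sampling error, so
#' standard univariate model control applies to each column.
#'
#' @param fit A `micropanel_em`.
#' @param ridge Optional ridge factor: the covariance is stabilized as
#'   `sigma + ridge * tr(sigma)/p * I` before inversion (default 0).
#' @return Matrix of standardized residuals (samples x variables).
#' @export
standardized_residuals <- function(fit, ridge = 0) {
  m <- fit$model
  X <- as.matrix(fit$completed[, m$variables, drop = FALSE])
  R <- X - m$means[m$cells, , drop = FALSE]
  Z <- R %*% sigma_inv_sqrt(m$sigma, ridge = ridge)
  dimnames(Z) <- list(fit$completed$sample_id, m$variables)
  Z
}
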