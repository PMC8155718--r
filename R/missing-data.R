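#' Summarise missing data and run Little's MCAR test
#'
#' Reports per-item and overall missing-cell proportions, the number of
#' distinct missingness patterns, and Little's test of the
#' missing-completely-at-random hypothesis (treating codes as continuous).
#'
#' @param x An [item_response_matrix()].
#' @param items Item subset (default: all items).
#' @return A `missing_report` list with elements `per_item`, `overall`,
#'   `n_patterns` and `little` (`d2`, `df`, `p`; all `NA` when the test is
#'   undefined, e.g. all cells missing).
#' @export
missing_report <- function(x, items = x$item_ids) {
  stopifnot(inherits(x, "item_response_matrix"))
  v <- x$values[, items, drop = FALSE]
  if (nrow(v) < 2L) stop("need at least 2 subjects")
  miss <- is.na(v)
  per_item <- colMeans(miss)
  overall <- mean(miss)
  pat <- apply(miss, 1L, function(r) paste(as.integer(r), collapse = ""))
  little <- if (overall >= 1) {
    list(d2 = NA_real_, df = NA_integer_, p = NA_real_,
         note = "all cells missing; test undefined")
  } else {
    littles_mcar_test(x, items)
  }
  structure(
    list(per_item = per_item, overall = overall,
         n_patterns = length(unique(pat)), little = little),
    class = "missing_report"
  )
}

#' @export
print.missing_report <- function(x, ...) {
  cat(sprintf("<missing_report> overall %.2f%% missing, %d pattern(s)\n",
              100 * x$overall, x$n_patterns))
  if (!is.na(x$little$d2)) {
    cat(sprintf("  Little's MCAR test: d2 = %.3f, df = %d, p = %.4f\n",
                x$little$d2, x$little$df, x$little$p))
  }
  invisible(x)
}

#' @rdname missing_report
#' @details `as_json.missing_report` serialises a report to a JSON string.
#' @export
missing_report_json <- function(x) {
  stopifnot(inherits(x, "missing_report"))
  jsonlite::toJSON(unclass(x), auto_unbox = TRUE, digits = NA, na = "null")
}

#' Little's test of missing completely at random
#'
#' Estimates the grand mean vector and covariance matrix by EM under
#' multivariate normality, groups subjects by missingness pattern, and
#' compares each pattern's observed means with the EM means:
#' \deqn{d^2 = \sum_j n_j (\bar y_{j,obs} - \hat\mu_{obs})' \hat\Sigma_{obs}^{-1}
#'       (\bar y_{j,obs} - \hat\mu_{obs}),}
#' referred to a chi-square with \eqn{df = \sum_j p_j - p}.  Large values
#' indicate pattern means that drift with the pattern, i.e. evidence
#' against MCAR.
#'
#' @inheritParams missing_report
#' @param tol EM stopping tolerance on the maximum absolute parameter
#'   change.
#' @param max_iter Maximum EM iterations.
#' @param ridge Ridge added to the covariance diagonal for invertibility.
#' @return List with `d2`, `df`, `p`, `n_patterns`, `em_iterations`.
#'   Complete data yields `d2 = 0`, `df = 0`, `p = 1` (trivially passed).
#' @export
littles_mcar_test <- function(x, items = x$item_ids, tol = 1e-6,
                              max_iter = 500L, ridge = 1e-8) {
  stopifnot(inherits(x, "item_response_matrix"))
  Y <- x$values[, items, drop = FALSE]
  if (ncol(Y) < 2L) stop("need at least 2 items")
  # drop subjects with nothing observed: they carry no information
  some_obs <- rowSums(!is.na(Y)) > 0L
  Y <- Y[some_obs, , drop = FALSE]
  if (nrow(Y) < 2L) stop("need at least 2 subjects with observed values")
  p <- ncol(Y)
  n <- nrow(Y)

  em <- em_mvnorm(Y, tol = tol, max_iter = max_iter, ridge = ridge)
  mu <- em$mu
  Sigma <- em$Sigma

  miss <- is.na(Y)
  pat_id <- apply(miss, 1L, function(r) paste(as.integer(r), collapse = ""))
  pats <- split(seq_len(n), pat_id)

  d2 <- 0
  df <- 0L
  for (rows in pats) {
    obs <- which(!miss[rows[1], ])
    ybar <- colMeans(Y[rows, obs, drop = FALSE])
    S_oo <- Sigma[obs, obs, drop = FALSE]
    inv <- tryCatch(solve(S_oo), error = function(e) {
      stop("singular covariance for missingness pattern '",
           pat_id[rows[1]], "'")
    })
    diff <- ybar - mu[obs]
    d2 <- d2 + length(rows) * drop(t(diff) %*% inv %*% diff)
    df <- df + length(obs)
  }
  df <- df - p
  pval <- if (df <= 0L) 1 else stats::pchisq(d2, df, lower.tail = FALSE)
  list(d2 = d2, df = as.integer(df), p = pval,
       n_patterns = length(pats), em_iterations = em$iterations)
}

# EM estimation of a multivariate-normal mean and covariance with
# missing data (ML, denominator n).
em_mvnorm <- function(Y, tol = 1e-6, max_iter = 500L, ridge = 1e-8) {
  n <- nrow(Y)
  p <- ncol(Y)
  miss <- is.na(Y)
  mu <- colMeans(Y, na.rm = TRUE)
  v <- apply(Y, 2L, stats::var, na.rm = TRUE)
  v[!is.finite(v) | v <= 0] <- 1
  Sigma <- diag(v, p)
  pat_id <- apply(miss, 1L, function(r) paste(as.integer(r), collapse = ""))
  pats <- split(seq_len(n), pat_id)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    S1 <- numeric(p)
    S2 <- matrix(0, p, p)
    for (rows in pats) {
      m <- miss[rows[1], ]
      obs <- which(!m)
      mis <- which(m)
      Yo <- Y[rows, obs, drop = FALSE]
      if (length(mis) == 0L) {
        S1 <- S1 + colSums(Yo)
        S2 <- S2 + crossprod(Yo)
        next
      }
      S_oo_inv <- solve(Sigma[obs, obs, drop = FALSE])
      B <- Sigma[mis, obs, drop = FALSE] %*% S_oo_inv        # regression coefs
      C <- Sigma[mis, mis, drop = FALSE] -
        B %*% Sigma[obs, mis, drop = FALSE]                  # cond. covariance
      Em <- matrix(mu[mis], nrow(Yo), length(mis), byrow = TRUE) +
        sweep(Yo, 2L, mu[obs]) %*% t(B)
      S1[obs] <- S1[obs] + colSums(Yo)
      S1[mis] <- S1[mis] + colSums(Em)
      S2[obs, obs] <- S2[obs, obs] + crossprod(Yo)
      S2[obs, mis] <- S2[obs, mis] + crossprod(Yo, Em)
      S2[mis, obs] <- S2[mis, obs] + crossprod(Em, Yo)
      S2[mis, mis] <- S2[mis, mis] + crossprod(Em) + nrow(Yo) * C
    }
    mu_new <- S1 / n
    Sigma_new <- S2 / n - tcrossprod(mu_new)
    diag(Sigma_new) <- diag(Sigma_new) + ridge
    delta <- max(abs(c(mu_new - mu, Sigma_new - Sigma)))
    mu <- mu_new
    Sigma <- Sigma_new
    if (delta < tol || iter >= max_iter) break
  }
  list(mu = mu, Sigma = Sigma, iterations = iter)
}
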