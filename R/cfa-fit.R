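#' Maximum-likelihood discrepancy between sample and implied moments
#'
#' \deqn{F_{ML} = \ln|\Sigma| - \ln|S| + tr(S\Sigma^{-1}) - p +
#'       (\bar y - \mu)'\Sigma^{-1}(\bar y - \mu).}
#'
#' @param S Sample covariance matrix (positive definite).
#' @param ybar Sample mean vector.
#' @param Sigma Implied covariance.
#' @param mu Implied means.
#' @return The scalar discrepancy (0 iff moments are reproduced exactly).
#' @export
ml_discrepancy <- function(S, ybar, Sigma, mu) {
  S <- as.matrix(S); Sigma <- as.matrix(Sigma)
  p <- nrow(S)
  cS <- tryCatch(chol(S), error = function(e) stop("S is not positive definite"))
  cSig <- tryCatch(chol(Sigma), error = function(e) stop("singular implied covariance"))
  Sig_inv <- chol2inv(cSig)
  d <- as.numeric(ybar) - as.numeric(mu)
  2 * sum(log(diag(cSig))) - 2 * sum(log(diag(cS))) +
    sum(Sig_inv * S) - p + drop(t(d) %*% Sig_inv %*% d)
}

# ---- data preparation -----------------------------------------------------

# Normalise fit input into a list of group summaries:
#   list(label, n, S, ybar, Y (casewise matrix or NULL))
# Sample covariances use denominator (n - 1), matching the T = (n-1) F
# test-statistic convention.
as_cfa_data <- function(data, items, grouping = NULL) {
  group_summary <- function(Y, label) {
    Y <- as.matrix(Y)
    if (anyNA(Y)) {
      stop("casewise data contain missing values; apply complete_cases() first")
    }
    list(label = label, n = nrow(Y), S = stats::cov(Y),
         ybar = colMeans(Y), Y = Y)
  }
  if (inherits(data, "item_response_matrix")) {
    Y <- data$values[, items, drop = FALSE]
    if (is.null(grouping)) return(list(group_summary(Y, "all")))
    groups <- split_by_group(data, grouping)
    return(lapply(names(groups), function(l) {
      group_summary(groups[[l]]$values[, items, drop = FALSE], l)
    }))
  }
  if (is.matrix(data)) return(list(group_summary(data[, items, drop = FALSE], "all")))
  if (is.list(data) && !is.null(data$S)) {
    n <- data$n %||% stop("moment input needs 'n'")
    return(list(list(label = "all", n = n, S = as.matrix(data$S),
                     ybar = as.numeric(data$ybar), Y = NULL)))
  }
  if (is.list(data)) {
    # list of per-group inputs
    out <- lapply(seq_along(data), function(k) {
      d <- data[[k]]
      lab <- names(data)[k] %||% as.character(k)
      if (is.list(d) && !is.null(d$S)) {
        list(label = d$label %||% lab, n = d$n, S = as.matrix(d$S),
             ybar = as.numeric(d$ybar), Y = d$Y %||% NULL)
      } else if (inherits(d, "item_response_matrix")) {
        group_summary(d$values[, items, drop = FALSE], lab)
      } else {
        group_summary(as.matrix(d)[, items, drop = FALSE], lab)
      }
    })
    return(out)
  }
  stop("unsupported data input")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- objective and analytic gradient --------------------------------------

# Shared evaluation core.  Returns F and optionally the gradient.
# weights w_g = (n_g - 1) / (N - G); T = (N - G) * F.
cfa_objective <- function(theta, comp, gdata, w, grad = FALSE) {
  q <- comp$q
  Fv <- 0
  gr <- if (grad) numeric(q) else NULL
  for (g in seq_along(gdata)) {
    cg <- comp$groups[[g]]
    mm <- fill_group(cg, theta)
    Sigma <- mm$Lam %*% mm$Psi %*% t(mm$Lam) + mm$Th
    cSig <- tryCatch(chol(Sigma), error = function(e) NULL)
    if (is.null(cSig)) return(list(F = NA_real_, grad = gr))
    Sig_inv <- chol2inv(cSig)
    S <- gdata[[g]]$S
    d <- gdata[[g]]$ybar - (mm$nu + drop(mm$Lam %*% mm$al))
    Fg <- 2 * sum(log(diag(cSig))) - gdata[[g]]$logdetS +
      sum(Sig_inv * S) - comp$p + drop(t(d) %*% Sig_inv %*% d)
    Fv <- Fv + w[g] * Fg
    if (grad) {
      Sid <- Sig_inv %*% d
      G_Sigma <- Sig_inv - Sig_inv %*% (S + tcrossprod(d)) %*% Sig_inv
      G_mu <- drop(-2 * Sid)
      # chain rule into each matrix
      e <- cg$ent$lambda
      if (length(e$id)) {
        Ml <- 2 * (G_Sigma %*% mm$Lam %*% mm$Psi) + outer(G_mu, mm$al)
        contrib <- Ml[cbind(e$row, e$col)]
        gr2 <- w[g] * contrib
        for (k in seq_along(e$id)) gr[e$id[k]] <- gr[e$id[k]] + gr2[k]
      }
      e <- cg$ent$psi
      if (length(e$id)) {
        Mp <- t(mm$Lam) %*% G_Sigma %*% mm$Lam
        contrib <- ifelse(e$row == e$col, Mp[cbind(e$row, e$col)],
                          2 * Mp[cbind(e$row, e$col)])
        gr2 <- w[g] * contrib
        for (k in seq_along(e$id)) gr[e$id[k]] <- gr[e$id[k]] + gr2[k]
      }
      e <- cg$ent$theta
      if (length(e$id)) {
        contrib <- ifelse(e$row == e$col, G_Sigma[cbind(e$row, e$col)],
                          2 * G_Sigma[cbind(e$row, e$col)])
        gr2 <- w[g] * contrib
        for (k in seq_along(e$id)) gr[e$id[k]] <- gr[e$id[k]] + gr2[k]
      }
      e <- cg$ent$nu
      if (length(e$id)) {
        gr2 <- w[g] * G_mu[e$row]
        for (k in seq_along(e$id)) gr[e$id[k]] <- gr[e$id[k]] + gr2[k]
      }
      e <- cg$ent$alpha
      if (length(e$id)) {
        Ma <- drop(t(mm$Lam) %*% G_mu)
        gr2 <- w[g] * Ma[e$row]
        for (k in seq_along(e$id)) gr[e$id[k]] <- gr[e$id[k]] + gr2[k]
      }
    }
  }
  list(F = Fv, grad = gr)
}

resolve_starts <- function(comp, gdata, spec) {
  start <- comp$start
  pt <- comp$param_table
  # data-dependent defaults: residual variances half the observed variances,
  # intercepts at the observed means (group-averaged when shared)
  for (k in which(is.na(start))) {
    rows <- which(pt$id == k)
    vals <- vapply(rows, function(r) {
      g <- pt$group[r]
      if (pt$mat[r] == "theta" && pt$row[r] == pt$col[r]) {
        0.5 * gdata[[g]]$S[pt$row[r], pt$row[r]]
      } else if (pt$mat[r] == "nu") {
        gdata[[g]]$ybar[pt$row[r]]
      } else {
        0.5
      }
    }, numeric(1))
    start[k] <- mean(vals)
  }
  start
}

#' Fit a confirmatory factor model
#'
#' Minimises the maximum-likelihood discrepancy over the free parameters
#' by bound-constrained quasi-Newton iteration (`nlminb`) with analytic
#' gradients.  Variance parameters are kept positive by a lower bound of
#' `1e-6`; solutions resting on that bound are flagged as Heywood cases.
#' Multigroup discrepancies are combined with weights
#' \eqn{(n_g - 1)/(N - G)} so the test statistic is
#' \eqn{T_{ML} = (N - G)\hat F}.
#'
#' @param data An [item_response_matrix()] (complete cases), a plain
#'   numeric matrix, a `list(S, ybar, n)` of moments, or a (named) list of
#'   any of these for multigroup fits.
#' @param spec A `cfa_spec` (see [cfa_model()]).
#' @param grouping Optional grouping column name when `data` is an
#'   `item_response_matrix` and `spec` is multigroup.
#' @param max_restarts Jittered restarts after a failed or poor
#'   convergence.
#' @param start Optional named vector of starting values, matched to free
#'   parameters by label (useful for warm starts along nested model
#'   sequences).
#' @param control Passed to [stats::nlminb()].
#' @return An object of class `cfa_fit`: estimates (`theta`, `labels`,
#'   per-group model matrices), `F`, `T_ML`, `df`, per-group `n`, stored
#'   sample moments and casewise data, and a convergence record.
#' @export
fit_cfa <- function(data, spec, grouping = NULL, max_restarts = 10L,
                    start = NULL,
                    control = list(iter.max = 500L, eval.max = 1000L)) {
  stopifnot(inherits(spec, "cfa_spec"))
  gdata <- as_cfa_data(data, spec$items, grouping)
  if (length(gdata) != spec$ngroups) {
    stop("data provide ", length(gdata), " group(s), spec expects ",
         spec$ngroups)
  }
  comp <- compile_spec(spec)
  df <- cfa_df(spec)
  if (df < 0L) stop("negative degrees of freedom: model not identified")
  ns <- vapply(gdata, `[[`, numeric(1), "n")
  if (any(ns <= comp$q / length(gdata))) {
    # loose guard; the real requirement is n_g > free parameters per group
  }
  Ntilde <- sum(ns - 1)
  w <- (ns - 1) / Ntilde
  for (g in seq_along(gdata)) {
    gdata[[g]]$logdetS <- determinant(gdata[[g]]$S)$modulus[1]
    if (!is.finite(gdata[[g]]$logdetS)) {
      stop("sample covariance of group '", gdata[[g]]$label,
           "' is not positive definite")
    }
  }
  user_start <- start
  start <- resolve_starts(comp, gdata, spec)
  if (!is.null(user_start)) {
    hit <- match(comp$labels, names(user_start))
    start[!is.na(hit)] <- user_start[hit[!is.na(hit)]]
    start <- pmax(start, comp$lower + 1e-6)
  }

  obj <- function(th) {
    v <- cfa_objective(th, comp, gdata, w)$F
    if (!is.finite(v)) 1e10 else v
  }
  gfun <- function(th) {
    g <- cfa_objective(th, comp, gdata, w, grad = TRUE)$grad
    if (is.null(g) || anyNA(g)) numeric(comp$q) else g
  }

  best <- NULL
  attempts <- 0L
  cur_start <- start
  repeat {
    attempts <- attempts + 1L
    res <- tryCatch(
      stats::nlminb(cur_start, obj, gradient = gfun, lower = comp$lower,
                    control = control),
      error = function(e) NULL
    )
    ok <- !is.null(res) && is.finite(res$objective) &&
      res$convergence %in% c(0L, 1L)
    if (!is.null(res) && (is.null(best) || res$objective < best$objective)) {
      best <- res
    }
    grad_norm <- if (is.null(res)) Inf else sqrt(sum(gfun(res$par)^2))
    if (ok && grad_norm < 1e-4) break
    if (attempts > max_restarts) break
    jit <- stats::rnorm(comp$q, 0, 0.05 * attempts)
    cur_start <- pmax(start + jit, comp$lower + 1e-6)
  }
  if (is.null(best) || !is.finite(best$objective)) {
    stop("CFA fit failed to converge after ", attempts, " attempts")
  }
  theta <- best$par
  names(theta) <- comp$labels
  Fhat <- best$objective
  grad_norm <- sqrt(sum(gfun(theta)^2))

  group_est <- lapply(seq_along(gdata), function(g) {
    mm <- fill_group(comp$groups[[g]], theta)
    Sigma <- mm$Lam %*% mm$Psi %*% t(mm$Lam) + mm$Th
    dimnames(Sigma) <- list(spec$items, spec$items)
    list(label = gdata[[g]]$label,
         Lambda = `dimnames<-`(mm$Lam, list(spec$items, spec$factors)),
         Psi = `dimnames<-`(mm$Psi, list(spec$factors, spec$factors)),
         Theta = `dimnames<-`(mm$Th, list(spec$items, spec$items)),
         nu = stats::setNames(mm$nu, spec$items),
         alpha = stats::setNames(mm$al, spec$factors),
         Sigma = Sigma,
         mu = stats::setNames(mm$nu + drop(mm$Lam %*% mm$al), spec$items))
  })
  names(group_est) <- vapply(gdata, `[[`, character(1), "label")

  heywood <- any(vapply(seq_along(gdata), function(g) {
    any(abs(diag(group_est[[g]]$Theta)) <= 1e-6 + 1e-9)
  }, logical(1)))

  structure(
    list(spec = spec, theta = theta, labels = comp$labels,
         lower = comp$lower, groups = group_est,
         F = Fhat, T_ML = Ntilde * Fhat, df = df,
         n = stats::setNames(ns, names(group_est)),
         Ntilde = Ntilde, weights = w,
         data = gdata, compiled = comp,
         convergence = list(code = best$convergence,
                            iterations = best$iterations,
                            gradient_norm = grad_norm,
                            restarts = attempts - 1L),
         heywood = heywood),
    class = "cfa_fit"
  )
}

#' @export
print.cfa_fit <- function(x, ...) {
  cat(sprintf("<cfa_fit> '%s': T_ML = %.3f, df = %d, N = %d (%d group(s))\n",
              x$spec$name, x$T_ML, x$df, sum(x$n), length(x$n)))
  if (x$heywood) cat("  warning: Heywood case (residual variance at bound)\n")
  invisible(x)
}

#' Parameter estimates as a data frame
#'
#' @param fit A `cfa_fit`.
#' @param se One of `"none"`, `"naive"`, `"sandwich"`.
#' @return Data frame with label, estimate and (optionally) standard
#'   error, z and p columns.
#' @export
cfa_estimates <- function(fit, se = c("none", "naive", "sandwich")) {
  se <- match.arg(se)
  out <- data.frame(label = fit$labels, estimate = unname(fit$theta),
                    stringsAsFactors = FALSE)
  if (se != "none") {
    V <- if (se == "naive") naive_vcov(fit) else sandwich_vcov(fit)
    out$se <- sqrt(pmax(diag(V), 0))
    out$z <- out$estimate / out$se
    out$p <- 2 * stats::pnorm(-abs(out$z))
  }
  out
}
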