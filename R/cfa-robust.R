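# Robust (sandwich) covariance and mean-scaled test statistics.
#
# All quantities are built from the moment-structure representation: per
# group the model maps theta to the moment vector (mu, vech Sigma); the
# normal-theory weight matrix V is evaluated at the fitted moments and the
# fourth-moment matrix Gamma is estimated from the casewise data.

# duplication matrix: vec(S) = D %*% vech(S), vech in column-major
# lower-triangular order
dup_matrix <- function(p) {
  tmp <- matrix(0L, p, p)
  pos <- which(lower.tri(tmp, diag = TRUE))
  tmp[pos] <- seq_along(pos)
  idx <- tmp + t(tmp)
  diag(idx) <- diag(tmp)
  D <- matrix(0, p * p, p * (p + 1) / 2)
  D[cbind(seq_len(p * p), as.vector(idx))] <- 1
  D
}

vech <- function(M) M[lower.tri(M, diag = TRUE)]

# normal-theory weight matrix for the (mu, vech Sigma) moment vector
normal_weight <- function(Sigma) {
  p <- nrow(Sigma)
  Sig_inv <- chol2inv(chol(Sigma))
  D <- dup_matrix(p)
  Vs <- 0.5 * t(D) %*% (Sig_inv %x% Sig_inv) %*% D
  V <- matrix(0, p + p * (p + 1) / 2, p + p * (p + 1) / 2)
  V[seq_len(p), seq_len(p)] <- Sig_inv
  V[-seq_len(p), -seq_len(p)] <- Vs
  V
}

# empirical asymptotic covariance of (ybar, vech S): the covariance of the
# casewise moment contributions (y_i, vech((y_i - ybar)(y_i - ybar)'))
gamma_matrix <- function(Y) {
  n <- nrow(Y)
  p <- ncol(Y)
  Yc <- sweep(Y, 2L, colMeans(Y))
  idx <- which(lower.tri(diag(p), diag = TRUE), arr.ind = TRUE)
  Z2 <- Yc[, idx[, 1], drop = FALSE] * Yc[, idx[, 2], drop = FALSE]
  Z <- cbind(Y, Z2)
  Zc <- sweep(Z, 2L, colMeans(Z))
  crossprod(Zc) / n
}

# analytic Jacobian d(mu, vech Sigma)/d(theta) for group g
moment_jacobian_group <- function(comp, theta, g) {
  cg <- comp$groups[[g]]
  mm <- fill_group(cg, theta)
  p <- comp$p
  nv <- p * (p + 1) / 2
  J <- matrix(0, p + nv, comp$q)
  low <- lower.tri(matrix(0, p, p), diag = TRUE)
  LP <- mm$Lam %*% mm$Psi

  add_sigma <- function(col, dS) J[p + seq_len(nv), col] <<-
    J[p + seq_len(nv), col] + dS[low]
  add_mu <- function(col, dmu) J[seq_len(p), col] <<-
    J[seq_len(p), col] + dmu

  e <- cg$ent$lambda
  for (k in seq_along(e$id)) {
    i <- e$row[k]; j <- e$col[k]
    dS <- matrix(0, p, p)
    dS[i, ] <- dS[i, ] + LP[, j]
    dS[, i] <- dS[, i] + LP[, j]
    add_sigma(e$id[k], dS)
    dmu <- numeric(p); dmu[i] <- mm$al[j]
    add_mu(e$id[k], dmu)
  }
  e <- cg$ent$psi
  for (k in seq_along(e$id)) {
    j <- e$row[k]; l <- e$col[k]
    dS <- if (j == l) tcrossprod(mm$Lam[, j]) else
      tcrossprod(mm$Lam[, j], mm$Lam[, l]) +
      tcrossprod(mm$Lam[, l], mm$Lam[, j])
    add_sigma(e$id[k], dS)
  }
  e <- cg$ent$theta
  for (k in seq_along(e$id)) {
    i <- e$row[k]; l <- e$col[k]
    dS <- matrix(0, p, p)
    dS[i, l] <- dS[i, l] + 1
    dS[l, i] <- dS[l, i] + 1
    if (i == l) dS[i, i] <- 1
    add_sigma(e$id[k], dS)
  }
  e <- cg$ent$nu
  for (k in seq_along(e$id)) {
    dmu <- numeric(p); dmu[e$row[k]] <- 1
    add_mu(e$id[k], dmu)
  }
  e <- cg$ent$alpha
  for (k in seq_along(e$id)) {
    add_mu(e$id[k], mm$Lam[, e$row[k]])
  }
  J
}

# assemble A = J' V_w J, plus per-group pieces needed downstream
robust_pieces <- function(fit) {
  comp <- fit$compiled
  G <- length(fit$data)
  per <- lapply(seq_len(G), function(g) {
    Y <- fit$data[[g]]$Y
    if (is.null(Y)) {
      stop("casewise data unavailable: robust statistics need raw responses")
    }
    list(J = moment_jacobian_group(comp, fit$theta, g),
         V = normal_weight(fit$groups[[g]]$Sigma),
         Gam = gamma_matrix(Y))
  })
  w <- fit$weights
  q <- comp$q
  A <- matrix(0, q, q)      # J' V_w J
  B <- matrix(0, q, q)      # J' V_w Gamma* V_w J, Gamma* = Gamma_g / w_g
  for (g in seq_len(G)) {
    VJ <- per[[g]]$V %*% per[[g]]$J
    A <- A + w[g] * crossprod(per[[g]]$J, VJ)
    B <- B + w[g] * crossprod(VJ, per[[g]]$Gam %*% VJ)
  }
  list(per = per, A = A, B = B, w = w)
}

#' Naive (normal-theory) covariance of the estimates
#'
#' @param fit A `cfa_fit`.
#' @return Symmetric covariance matrix of the free parameters.
#' @export
naive_vcov <- function(fit) {
  rp <- robust_pieces(fit)
  Ainv <- tryCatch(solve(rp$A), error = function(e) {
    stop("information matrix is singular; consider re-specifying the model")
  })
  V <- Ainv / fit$Ntilde
  dimnames(V) <- list(fit$labels, fit$labels)
  (V + t(V)) / 2
}

#' Sandwich (Huber-White) covariance of the estimates
#'
#' Robust covariance \eqn{A^{-1} B A^{-1}} with \eqn{A} the expected
#' information of the moment structure and \eqn{B} built from the
#' empirical fourth-moment matrix of the casewise data, so standard
#' errors remain consistent when the discretized responses violate
#' multivariate normality.
#'
#' @param fit A `cfa_fit` fitted to casewise data.
#' @return Symmetric positive semi-definite covariance matrix.
#' @export
sandwich_vcov <- function(fit) {
  rp <- robust_pieces(fit)
  Ainv <- tryCatch(solve(rp$A), error = function(e) {
    stop("information matrix is singular; consider re-specifying the model")
  })
  V <- Ainv %*% rp$B %*% Ainv / fit$Ntilde
  dimnames(V) <- list(fit$labels, fit$labels)
  (V + t(V)) / 2
}

#' Mean-scaled (Satorra-Bentler-type) test statistic
#'
#' Computes the scaling correction \eqn{\hat c = tr(U\Gamma)/df} from the
#' residual weight matrix \eqn{U} and the fourth-moment matrix
#' \eqn{\Gamma} of the data, and returns \eqn{T_{scaled} = T_{ML}/\hat c}.
#' For multivariate-normal data \eqn{\hat c \to 1}; excess kurtosis (as
#' induced by discretizing) inflates \eqn{\hat c} and deflates the
#' statistic, which is asymptotically equivalent to the Yuan-Bentler
#' mean-corrected statistic.
#'
#' @param fit A `cfa_fit` fitted to casewise data.
#' @return List with `T_scaled`, `c_hat`, `df`, `p_scaled`.
#' @export
scaled_statistic <- function(fit) {
  if (fit$df == 0L) {
    return(list(T_scaled = 0, c_hat = 1, df = 0L, p_scaled = 1))
  }
  rp <- robust_pieces(fit)
  Ainv <- solve(rp$A)
  # tr(U Gamma*) with U = V_w - V_w J A^{-1} J' V_w assembled blockwise;
  # within block g the w_g and 1/w_g factors cancel:
  tr_UG <- 0
  for (g in seq_along(rp$per)) {
    Vg <- rp$per[[g]]$V
    Jg <- rp$per[[g]]$J
    Gg <- rp$per[[g]]$Gam
    tr_UG <- tr_UG + sum(diag(Vg %*% Gg)) -
      rp$w[g] * sum(diag((crossprod(Jg, Vg %*% Gg %*% Vg) %*% Jg) %*% Ainv))
  }
  c_hat <- tr_UG / fit$df
  if (!is.finite(c_hat) || c_hat <= 0) {
    stop("non-positive scaling factor; scaled statistic undefined")
  }
  T_scaled <- fit$T_ML / c_hat
  list(T_scaled = T_scaled, c_hat = c_hat, df = fit$df,
       p_scaled = stats::pchisq(T_scaled, fit$df, lower.tail = FALSE))
}

#' Scaled chi-square difference test for nested fits
#'
#' Uses the standard difference-scaling correction
#' \eqn{\hat c_d = (df_r \hat c_r - df_f \hat c_f)/(df_r - df_f)} and
#' refers \eqn{(T_{ML,r} - T_{ML,f})/\hat c_d} to a chi-square with
#' \eqn{df_r - df_f} degrees of freedom.
#'
#' @param restricted,full Nested `cfa_fit` objects on identical data
#'   (restricted has the larger df).
#' @return List with `delta_T`, `delta_df`, `p`, `c_d` and a `scaled`
#'   flag (`FALSE` when a non-positive \eqn{\hat c_d} forced fallback to
#'   the unscaled difference, with a warning).
#' @export
scaled_chisq_difference <- function(restricted, full) {
  if (restricted$df < full$df) {
    stop("'restricted' must have more degrees of freedom than 'full'")
  }
  delta_df <- restricted$df - full$df
  if (delta_df == 0L) {
    return(list(delta_T = 0, delta_df = 0L, p = 1, c_d = 1, scaled = TRUE))
  }
  if (sum(restricted$n) != sum(full$n)) {
    stop("models were not fitted to identical data")
  }
  c_r <- scaled_statistic(restricted)$c_hat
  c_f <- if (full$df > 0L) scaled_statistic(full)$c_hat else c_r
  c_d <- (restricted$df * c_r - full$df * c_f) / delta_df
  raw <- restricted$T_ML - full$T_ML
  scaled <- TRUE
  if (!is.finite(c_d) || c_d <= 0) {
    warning("non-positive difference scaling factor; ",
            "falling back to the unscaled chi-square difference")
    c_d <- 1
    scaled <- FALSE
  }
  delta_T <- max(raw, 0) / c_d
  list(delta_T = delta_T, delta_df = as.integer(delta_df),
       p = stats::pchisq(delta_T, delta_df, lower.tail = FALSE),
       c_d = c_d, scaled = scaled)
}
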