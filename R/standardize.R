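#' Standardized solution of a fitted CFA model
#'
#' Rescales the solution so factors and items have unit variance:
#' \eqn{\Lambda^* = D_y^{-1}\Lambda D_f}, \eqn{\Psi^*} the factor
#' correlation matrix, \eqn{\Theta^* = D_y^{-1}\Theta D_y^{-1}} with
#' \eqn{D_y = diag(\sqrt{\sigma_{ii}})}, \eqn{D_f = diag(\sqrt{\psi_{jj}})}.
#' For orthogonal-factor models the standardized residual variance of an
#' item equals one minus its summed squared standardized loadings.
#'
#' @param fit A converged `cfa_fit`.
#' @return Per group (named as the groups), a list with `loadings`,
#'   `factor_cor`, `residual_prop` (standardized residual variances) and
#'   `residual_cor`.  Single-group fits return the inner list directly.
#' @export
standardized_solution <- function(fit) {
  out <- lapply(fit$groups, function(g) {
    item_var <- diag(g$Sigma)
    if (any(item_var <= 0)) stop("non-positive implied item variance")
    Dy <- 1 / sqrt(item_var)
    fvar <- diag(g$Psi)
    Df <- sqrt(fvar)
    Lam_s <- sweep(sweep(g$Lambda, 1L, Dy, "*"), 2L, Df, "*")
    Psi_s <- stats::cov2cor(g$Psi)
    Theta_s <- g$Theta * tcrossprod(Dy)
    list(loadings = Lam_s, factor_cor = Psi_s,
         residual_prop = stats::setNames(diag(Theta_s), rownames(g$Theta)),
         residual_cor = Theta_s)
  })
  if (length(out) == 1L) out[[1]] else out
}
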