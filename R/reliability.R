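#' Fit a bifactor-(S-1) model to item responses
#'
#' Builds the specification via [bifactor_s_minus_1_spec()] (general
#' factor on all items, one orthogonal group factor on the non-reference
#' subscale) and fits it with [fit_cfa()].
#'
#' @param data Complete-case [item_response_matrix()] (or any input
#'   accepted by [fit_cfa()]).
#' @param scale_def A [scale_definition()] with exactly two subscales.
#' @param reference_subscale Subscale whose group factor is discarded
#'   (its items anchor the general factor).
#' @return A `cfa_fit` carrying the spec's `reference_subscale`.
#' @export
fit_bifactor_s_minus_1 <- function(data, scale_def,
                                   reference_subscale = "somatic") {
  spec <- bifactor_s_minus_1_spec(scale_def, reference_subscale)
  fit_cfa(data, spec)
}

#' Model-based reliability of unit-weighted scores (omega family)
#'
#' For an orthogonal bifactor solution with general loadings
#' \eqn{\lambda_g}, group loadings \eqn{\lambda_s} and residual variances
#' \eqn{\theta}, the variance of the unit-weighted total decomposes as
#' \eqn{V = (\Sigma\lambda_g)^2 + \Sigma_s(\Sigma_{i\in s}\lambda_{s,i})^2
#' + \Sigma\theta_i}.  Total omega is the proportion of \eqn{V} due to all
#' common factors, hierarchical omega the proportion due to the general
#' factor alone, and subscale hierarchical omega the proportion of a
#' subscale score's variance due to its own group factor net of the
#' general factor.
#'
#' The reference subscale of a bifactor-(S-1) solution has no modeled
#' group factor, so its omegaHS is not computed by default; with
#' `include_reference = TRUE` it is emitted under the zero-group-variance
#' convention (numerator 0).
#'
#' @param fit A `cfa_fit` of a bifactor-(S-1) model (orthogonal factors).
#' @param scale_def The [scale_definition()] the model was built from.
#' @param standardized Use the standardized solution instead of the raw
#'   one (differences are negligible for unit-variance items).
#' @param include_reference Emit the reference subscale's omegaHS under
#'   the zero-variance convention.
#' @param omega_h_min,omega_hs_min Recommended minima used for flags.
#' @return A `reliability_report`: `omega_t`, `omega_h`, `omega_hs`
#'   (named per subscale), `flags`, and the source model name.
#' @export
omega_indices <- function(fit, scale_def, standardized = FALSE,
                          include_reference = FALSE,
                          omega_h_min = 0.70, omega_hs_min = 0.50) {
  stopifnot(inherits(fit, "cfa_fit"))
  if (length(fit$groups) != 1L) stop("omega indices expect a single-group fit")
  g <- fit$groups[[1]]
  m <- ncol(g$Psi)
  if (m < 1L) stop("no factors in model")
  off <- g$Psi[upper.tri(g$Psi)]
  if (any(abs(off) > 1e-8)) {
    stop("omega formulas require orthogonal factors")
  }
  sol <- if (standardized) {
    s <- standardized_solution(fit)
    list(Lambda = s$loadings, Theta = s$residual_cor)
  } else {
    # rescale loadings by factor SDs so factors are unit-variance
    list(Lambda = sweep(g$Lambda, 2L, sqrt(diag(g$Psi)), "*"),
         Theta = g$Theta)
  }
  Lam <- sol$Lambda
  th <- diag(sol$Theta)
  items <- fit$spec$items
  general <- "general"
  if (!general %in% colnames(Lam)) general <- colnames(Lam)[1]
  group_factors <- setdiff(colnames(Lam), general)

  lam_g <- Lam[, general]
  sum_g2 <- sum(lam_g)^2
  group_sums2 <- vapply(group_factors, function(f) sum(Lam[, f])^2,
                        numeric(1))
  V <- sum_g2 + sum(group_sums2) + sum(th)
  omega_t <- (sum_g2 + sum(group_sums2)) / V
  omega_h <- sum_g2 / V

  # map group factors to subscales by their loaded items
  sub_of_factor <- vapply(group_factors, function(f) {
    loaded <- items[Lam[, f] != 0]
    hit <- vapply(scale_def$subscales, function(s) all(loaded %in% s),
                  logical(1))
    if (!any(hit)) f else names(scale_def$subscales)[which(hit)[1]]
  }, character(1))

  omega_hs <- vapply(group_factors, function(f) {
    sname <- sub_of_factor[f]
    idx <- match(scale_def$subscales[[sname]], items)
    num <- sum(Lam[idx, f])^2
    den <- sum(lam_g[idx])^2 + num + sum(th[idx])
    num / den
  }, numeric(1))
  names(omega_hs) <- sub_of_factor

  if (include_reference) {
    ref <- fit$spec$reference_subscale
    if (!is.null(ref)) {
      idx <- match(scale_def$subscales[[ref]], items)
      den <- sum(lam_g[idx])^2 + sum(th[idx])
      omega_hs <- c(omega_hs, stats::setNames(0 / den * 0, ref))
      omega_hs[ref] <- 0
    }
  }

  structure(
    list(omega_t = omega_t, omega_h = omega_h, omega_hs = omega_hs,
         flags = list(
           omega_h_ok = omega_h >= omega_h_min,
           omega_hs_ok = omega_hs >= omega_hs_min),
         model = fit$spec$name,
         thresholds = c(omega_h_min = omega_h_min,
                        omega_hs_min = omega_hs_min)),
    class = "reliability_report"
  )
}

#' @export
print.reliability_report <- function(x, ...) {
  cat(sprintf("<reliability_report> omegaT = %.3f, omegaH = %.3f%s\n",
              x$omega_t, x$omega_h,
              if (x$flags$omega_h_ok) " (>= minimum)" else " (below minimum)"))
  for (s in names(x$omega_hs)) {
    cat(sprintf("  omegaHS[%s] = %.3f\n", s, x$omega_hs[s]))
  }
  invisible(x)
}

#' Omega indices from explicit loading vectors
#'
#' Convenience for analytic work: the same formulas as [omega_indices()]
#' applied directly to numeric inputs.
#'
#' @param lambda_general General-factor loadings.
#' @param lambda_group Group-factor loadings (0 off the subscale).
#' @param theta Residual variances.
#' @param subscale_idx Indices of the group factor's subscale items.
#' @return List `omega_t`, `omega_h`, `omega_hs`.
#' @export
omega_from_loadings <- function(lambda_general, lambda_group, theta,
                                subscale_idx = which(lambda_group != 0)) {
  sum_g2 <- sum(lambda_general)^2
  sum_s2 <- sum(lambda_group)^2
  V <- sum_g2 + sum_s2 + sum(theta)
  i <- subscale_idx
  list(
    omega_t = (sum_g2 + sum_s2) / V,
    omega_h = sum_g2 / V,
    omega_hs = sum(lambda_group[i])^2 /
      (sum(lambda_general[i])^2 + sum(lambda_group[i])^2 + sum(theta[i]))
  )
}

#' Coefficient alpha
#'
#' \eqn{\alpha = k/(k-1)\,(1 - \Sigma_i s_i^2 / s_X^2)} over complete
#' cases on the selected items.
#'
#' @param x An [item_response_matrix()] or numeric matrix.
#' @param items Item subset (default all).
#' @return Scalar alpha.
#' @export
coefficient_alpha <- function(x, items = NULL) {
  Y <- if (inherits(x, "item_response_matrix")) x$values else as.matrix(x)
  if (!is.null(items)) Y <- Y[, items, drop = FALSE]
  Y <- Y[stats::complete.cases(Y), , drop = FALSE]
  k <- ncol(Y)
  if (k < 2L) stop("alpha needs at least 2 items")
  tot_var <- stats::var(rowSums(Y))
  if (tot_var <= 0) stop("zero total-score variance")
  k / (k - 1) * (1 - sum(apply(Y, 2L, stats::var)) / tot_var)
}

#' Leave-one-item-out reliability sensitivity
#'
#' Recomputes the omega indices of a bifactor-(S-1) fit after dropping
#' each non-reference item in turn, to check that no single item drives
#' the reliability conclusions.
#'
#' @inheritParams fit_bifactor_s_minus_1
#' @return Data frame: dropped item, omega_t, omega_h.
#' @export
leave_one_item_out_omega <- function(data, scale_def,
                                     reference_subscale = "somatic") {
  other <- setdiff(names(scale_def$subscales), reference_subscale)
  droppable <- scale_def$subscales[[other]]
  rows <- lapply(droppable, function(it) {
    subs <- scale_def$subscales
    subs[[other]] <- setdiff(subs[[other]], it)
    if (length(subs[[other]]) < 2L) return(NULL)
    sd2 <- scale_definition(scale_def$name, setdiff(scale_def$items, it),
                            subs)
    datc <- complete_cases(data, sd2$items)
    fit <- fit_bifactor_s_minus_1(datc, sd2, reference_subscale)
    om <- omega_indices(fit, sd2)
    data.frame(dropped = it, omega_t = om$omega_t, omega_h = om$omega_h,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
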