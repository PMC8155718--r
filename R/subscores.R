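#' Haberman's PRMSE for a subscale
#'
#' Quantifies how well the observed subscore S and the observed total X
#' each predict the subscale's true score.  With remainder R = X - S:
#' PRMSE_sub is the subscore's reliability (coefficient alpha here);
#' var(S_true) = PRMSE_sub * var(S); cov(X, S_true) = var(S_true) +
#' cov(S, R); and PRMSE_total = cov(X, S_true)^2 / (var(X) var(S_true)).
#' A subscore can only be worth reporting when PRMSE_sub exceeds
#' PRMSE_total.
#'
#' @param x An [item_response_matrix()].
#' @param scale_def A [scale_definition()].
#' @param subscale Subscale name.
#' @return List: `prmse_sub`, `prmse_total`, `r_sub`, `r_total`, `r_sx`
#'   (observed subscore-total correlation), `n`.
#' @export
haberman_prmse <- function(x, scale_def, subscale) {
  stopifnot(inherits(x, "item_response_matrix"),
            inherits(scale_def, "scale_definition"))
  if (!subscale %in% names(scale_def$subscales)) {
    stop("unknown subscale '", subscale, "'")
  }
  xc <- complete_cases(x, scale_def$items)
  sub_items <- scale_def$subscales[[subscale]]
  S <- unit_weighted_score(xc, sub_items)
  X <- unit_weighted_score(xc, scale_def$items)
  R <- X - S
  var_S <- stats::var(S)
  var_X <- stats::var(X)
  if (var_S <= 0 || var_X <= 0) stop("degenerate score variance")
  prmse_sub <- coefficient_alpha(xc, sub_items)
  var_St <- prmse_sub * var_S
  if (var_St <= 0) stop("non-positive true-score variance")
  cov_X_St <- var_St + stats::cov(S, R)
  prmse_total <- cov_X_St^2 / (var_X * var_St)
  list(prmse_sub = prmse_sub, prmse_total = prmse_total,
       r_sub = sqrt(max(prmse_sub, 0)),
       r_total = sqrt(max(min(prmse_total, 1), 0)),
       r_sx = stats::cor(S, X), n = length(S))
}

#' Olkin's Z for two dependent correlations
#'
#' Compares the correlation of the true subscore with the observed
#' subscore (`r_sub`) against its correlation with the observed total
#' (`r_total`), which share the true subscore as common variable.  The
#' asymptotic variance of the difference uses the Olkin-Siotani
#' covariance of dependent correlations:
#' \deqn{Var(r_{12}-r_{13}) = [(1-r_{12}^2)^2 + (1-r_{13}^2)^2 -
#'   2\psi]/n}
#' with \eqn{\psi = r_{23}(1-r_{12}^2-r_{13}^2) -
#'   \tfrac12 r_{12}r_{13}(1-r_{12}^2-r_{13}^2-r_{23}^2)}.
#' Positive Z favours the subscore.
#'
#' @param r_sub Correlation of subscore with true subscore
#'   (\eqn{\sqrt{PRMSE_{sub}}}).
#' @param r_total Correlation of total with true subscore
#'   (\eqn{\sqrt{PRMSE_{total}}}).
#' @param r_sx Observed correlation between subscore and total.
#' @param n Sample size (>= 30).
#' @return List `z`, `se`.
#' @export
olkin_z <- function(r_sub, r_total, r_sx, n) {
  if (n < 30) stop("Olkin's Z requires n >= 30")
  if (any(abs(c(r_sub, r_total, r_sx)) >= 1)) {
    stop("correlations must be strictly inside (-1, 1)")
  }
  r12 <- r_sub; r13 <- r_total; r23 <- r_sx
  psi <- r23 * (1 - r12^2 - r13^2) -
    0.5 * r12 * r13 * (1 - r12^2 - r13^2 - r23^2)
  v <- ((1 - r12^2)^2 + (1 - r13^2)^2 - 2 * psi) / n
  if (v <= 0) stop("non-positive variance in Olkin's Z")
  se <- sqrt(v)
  list(z = (r12 - r13) / se, se = se)
}

#' Subscore value-added verdict
#'
#' A subscale has added value iff its PRMSE strictly exceeds the total
#' score's PRMSE *and* Olkin's Z exceeds the threshold (1.64, a one-sided
#' 5% test).
#'
#' @param prmse_sub,prmse_total PRMSE values.
#' @param z Olkin's Z.
#' @param z_threshold Decision threshold.
#' @return `"added_value"` or `"no_added_value"`.
#' @export
subscore_verdict <- function(prmse_sub, prmse_total, z,
                             z_threshold = 1.64) {
  if (prmse_sub > prmse_total && z > z_threshold) "added_value"
  else "no_added_value"
}

#' Full subscore value-added report for a scale
#'
#' Runs [haberman_prmse()] and [olkin_z()] for every subscale and applies
#' [subscore_verdict()].
#'
#' @inheritParams haberman_prmse
#' @param z_threshold Passed to [subscore_verdict()].
#' @return A `subscore_report` data frame: subscale, prmse_sub,
#'   prmse_total, olkin_z, verdict.
#' @export
subscore_report <- function(x, scale_def, z_threshold = 1.64) {
  rows <- lapply(names(scale_def$subscales), function(s) {
    if (length(scale_def$subscales[[s]]) < 2L) {
      return(data.frame(subscale = s, prmse_sub = NA, prmse_total = NA,
                        olkin_z = NA, verdict = "degenerate",
                        stringsAsFactors = FALSE))
    }
    h <- haberman_prmse(x, scale_def, s)
    z <- olkin_z(h$r_sub, h$r_total, h$r_sx, h$n)$z
    data.frame(subscale = s, prmse_sub = h$prmse_sub,
               prmse_total = h$prmse_total, olkin_z = z,
               verdict = subscore_verdict(h$prmse_sub, h$prmse_total, z,
                                          z_threshold),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("subscore_report", class(out))
  out
}
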