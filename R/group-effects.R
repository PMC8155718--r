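#' Robust MM-regression
#'
#' High-breakdown robust linear regression: an S-estimate of scale with
#' bisquare loss (50% breakdown) followed by an efficient bisquare
#' M-step (approximately 95% Gaussian efficiency), as provided by
#' [MASS::rlm()] with `method = "MM"`.
#'
#' @param y Numeric response.
#' @param X Design matrix (including the intercept column).
#' @param maxit Maximum IWLS iterations.
#' @return List: `coefficients`, `se` (asymptotic), `scale` (robust
#'   residual scale), `iterations`, `converged`.
#' @export
mm_regression <- function(y, X, maxit = 100L) {
  X <- as.matrix(X)
  if (length(y) != nrow(X)) stop("y/X dimension mismatch")
  if (nrow(X) <= ncol(X)) stop("need n > number of design columns")
  if (qr(X)$rank < ncol(X)) stop("collinear design matrix")
  fit <- MASS::rlm(X, y, method = "MM", maxit = maxit)
  if (!fit$converged) {
    stop("MM-regression failed to converge after ", maxit, " iterations")
  }
  sm <- summary(fit)
  list(coefficients = stats::coef(fit),
       se = sm$coefficients[, "Std. Error"],
       scale = fit$s,
       iterations = length(fit$conv),
       converged = fit$converged)
}

group_design <- function(labels, baseline) {
  lv <- unique(labels)
  if (!baseline %in% lv) stop("unknown baseline level '", baseline, "'")
  lv <- c(baseline, setdiff(lv, baseline))
  X <- matrix(0, length(labels), length(lv))
  X[, 1] <- 1
  for (k in seq_along(lv)[-1]) X[, k] <- as.numeric(labels == lv[k])
  colnames(X) <- c("(intercept)", lv[-1])
  list(X = X, levels = lv)
}

#' Observed (unit-weighted) standardized effect sizes
#'
#' Regresses unit-weighted scores on group indicators by MM-estimation
#' and standardizes each contrast coefficient by the robust residual
#' scale of the same regression.  Signs follow contrast minus baseline.
#'
#' @param scores Numeric vector of unit-weighted scores.
#' @param labels Group labels (same length).
#' @param baseline Baseline level (default: first level in appearance
#'   order).
#' @return Data frame: subgroup, n, mean, sd, ses, p (baseline row has
#'   `NA` effect columns).
#' @export
observed_ses <- function(scores, labels, baseline = NULL) {
  keep <- !is.na(scores)
  scores <- scores[keep]
  labels <- as.character(labels)[keep]
  lv <- unique(labels)
  if (length(lv) < 2L) stop("need at least 2 groups")
  if (is.null(baseline)) baseline <- lv[1]
  cnt <- table(labels)
  if (any(cnt < 10)) {
    warning("group(s) with n < 10: ",
            paste(names(cnt)[cnt < 10], collapse = ", "))
  }
  d <- group_design(labels, baseline)
  fit <- mm_regression(scores, d$X)
  rows <- lapply(d$levels, function(l) {
    s <- scores[labels == l]
    if (l == baseline) {
      data.frame(subgroup = l, n = length(s), mean = mean(s),
                 sd = stats::sd(s), ses = NA_real_, p = NA_real_,
                 stringsAsFactors = FALSE)
    } else {
      b <- fit$coefficients[l]
      z <- b / fit$se[l]
      data.frame(subgroup = l, n = length(s), mean = mean(s),
                 sd = stats::sd(s), ses = unname(b / fit$scale),
                 p = unname(2 * stats::pnorm(-abs(z))),
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Latent-mean standardized effect sizes
#'
#' Fits the scalar-invariant multigroup model (baseline latent means
#' fixed at 0, non-baseline means free) and standardizes each group's
#' latent mean by the pooled (sample-size-weighted) factor variance
#' across groups; p-values use the sandwich standard error of the latent
#' mean.
#'
#' @param data An [item_response_matrix()] with a grouping column (or a
#'   named list of per-group inputs).
#' @param spec Single-group template `cfa_spec` (typically one factor:
#'   the general severity construct).
#' @param grouping Grouping column name.
#' @param ladder Optional [run_ladder()] result used to verify that
#'   scalar invariance was attained; an error directs the caller to the
#'   partial-invariance output otherwise.
#' @param freed Freed parameter sets (e.g. from a partial ladder) passed
#'   to [constrain_invariance()].
#' @return Data frame: subgroup, factor, n, ses, p (baseline rows `NA`).
#' @export
latent_ses <- function(data, spec, grouping = NULL, ladder = NULL,
                       freed = list()) {
  if (!is.null(ladder)) {
    if (level_rank(ladder$attained) < level_rank("scalar")) {
      stop("scalar invariance not attained (ladder stopped at '",
           ladder$attained, "'); inspect the partial-invariance output")
    }
    freed <- ladder$records$scalar$fit$spec$freed %||% freed
  }
  if (inherits(data, "item_response_matrix")) {
    if (anyNA(data$values)) data <- complete_cases(data, spec$items)
    gdata <- as_cfa_data(data, spec$items, grouping)
  } else {
    gdata <- as_cfa_data(data, spec$items)
  }
  groups <- vapply(gdata, `[[`, character(1), "label")
  sp <- constrain_invariance(spec, groups, "scalar", freed)
  fit <- fit_cfa(gdata, sp)
  Vr <- sandwich_vcov(fit)
  # pooled factor variance, weighting groups by sample size
  wn <- fit$n / sum(fit$n)
  rows <- list()
  for (f in spec$factors) {
    pooled <- sum(vapply(seq_along(fit$groups), function(g) {
      wn[g] * fit$groups[[g]]$Psi[f, f]
    }, numeric(1)))
    for (g in seq_along(fit$groups)) {
      lab <- groups[g]
      if (g == 1L) {
        rows[[length(rows) + 1L]] <- data.frame(
          subgroup = lab, factor = f, n = unname(fit$n[g]),
          ses = NA_real_, p = NA_real_, stringsAsFactors = FALSE)
      } else {
        par <- sprintf("al.%s.g%d", f, g)
        kap <- fit$theta[par]
        se <- sqrt(Vr[par, par])
        rows[[length(rows) + 1L]] <- data.frame(
          subgroup = lab, factor = f, n = unname(fit$n[g]),
          ses = unname(kap / sqrt(pooled)),
          p = unname(2 * stats::pnorm(-abs(kap / se))),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Compare unit-weighted and latent-mean effect sizes
#'
#' For each grouping, computes descriptive statistics and both
#' standardized effect-size variants for every contrast against the
#' baseline (first) level, in the layout of a published effect-size
#' comparison table.
#'
#' @param data An [item_response_matrix()] with grouping columns.
#' @param scale_def A [scale_definition()].
#' @param groupings Character vector of grouping column names.
#' @param spec Single-group `cfa_spec` for the latent model (default: a
#'   one-factor model of the full scale, the common severity construct).
#' @return An `effect_report` data frame: category, subgroup, n, mean,
#'   sd, observed_ses, observed_p, latent_ses, latent_p.
#' @export
effect_comparison <- function(data, scale_def, groupings, spec = NULL) {
  stopifnot(inherits(data, "item_response_matrix"))
  if (is.null(spec)) {
    spec <- cfa_model(scale_def$items,
                      stats::setNames(list(scale_def$items), "severity"),
                      name = "one_factor")
  }
  datc <- complete_cases(data, scale_def$items)
  out <- list()
  for (gname in groupings) {
    scores <- unit_weighted_score(datc, scale_def$items)
    labels <- datc$grouping[[gname]]
    if (is.null(labels)) stop("unknown grouping column '", gname, "'")
    obs <- observed_ses(scores, labels)
    lat <- latent_ses(datc, spec, gname)
    lat1 <- lat[lat$factor == spec$factors[1], ]
    merged <- merge(obs, lat1[, c("subgroup", "ses", "p")],
                    by = "subgroup", all.x = TRUE, sort = FALSE,
                    suffixes = c("", "_latent"))
    merged <- merged[match(obs$subgroup, merged$subgroup), ]
    out[[gname]] <- data.frame(
      category = gname, subgroup = merged$subgroup, n = merged$n,
      mean = merged$mean, sd = merged$sd,
      observed_ses = merged$ses, observed_p = merged$p,
      latent_ses = merged$ses_latent, latent_p = merged$p_latent,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("effect_report", class(res))
  res
}
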