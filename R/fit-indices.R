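# Goodness-of-fit indices: CFI, TLI, RMSEA (with 90% CI), SRMR, and their
# mean-scaled variants.

# independence (baseline) spec: diagonal covariance, free means, no
# cross-group constraints; same group structure as `spec`
baseline_spec <- function(spec) {
  p <- length(spec$items)
  rows <- list()
  for (g in seq_len(spec$ngroups)) {
    for (i in seq_len(p)) {
      rows[[length(rows) + 1L]] <- data.frame(
        mat = "theta", row = i, col = i, free = TRUE, value = NA,
        label = sprintf("th.%s.g%d", spec$items[i], g), group = g,
        stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        mat = "nu", row = i, col = 1L, free = TRUE, value = NA,
        label = sprintf("nu.%s.g%d", spec$items[i], g), group = g,
        stringsAsFactors = FALSE)
    }
  }
  structure(
    list(name = paste0(spec$name, "_baseline"), items = spec$items,
         factors = character(0), ptable = do.call(rbind, rows),
         ngroups = spec$ngroups, group_labels = spec$group_labels,
         identification = spec$identification),
    class = "cfa_spec"
  )
}

#' Fit the independence baseline model
#'
#' Diagonal covariance with free means per group, fitted to the same data
#' as `fit`; the reference point of incremental fit indices.
#'
#' @param fit A `cfa_fit`.
#' @return A `cfa_fit` for the baseline model.
#' @export
baseline_fit <- function(fit) {
  fit_cfa(fit$data, baseline_spec(fit$spec))
}

rmsea_point <- function(T, df, Ntilde, G) {
  if (df <= 0L) return(0)
  sqrt(G) * sqrt(max(T - df, 0) / (df * Ntilde))
}

# 90% CI by inversion of the noncentral chi-square distribution
rmsea_ci <- function(T, df, Ntilde, G, level = 0.90) {
  if (df <= 0L || !is.finite(T)) return(c(0, 0))
  lo_tail <- (1 + level) / 2   # 0.95
  hi_tail <- (1 - level) / 2   # 0.05
  ncp_root <- function(target) {
    f <- function(l) stats::pchisq(T, df, ncp = l) - target
    if (f(0) < 0) return(0)
    upper <- max(T * 2, df * 2, 10)
    while (f(upper) > 0 && upper < 1e8) upper <- upper * 2
    if (f(upper) > 0) return(upper)
    stats::uniroot(f, c(0, upper), tol = 1e-8)$root
  }
  lam_lo <- ncp_root(lo_tail)
  lam_hi <- ncp_root(hi_tail)
  c(sqrt(G) * sqrt(lam_lo / (df * Ntilde)),
    sqrt(G) * sqrt(lam_hi / (df * Ntilde)))
}

# standardized root mean squared residual, n-weighted across groups.
# Mean residuals enter only when the mean structure is restricted
# (cross-group intercept constraints or free latent means), mirroring the
# saturated-mean convention.
srmr_value <- function(fit) {
  pt <- fit$spec$ptable
  nu_rows <- pt[pt$mat == "nu", , drop = FALSE]
  structured_means <- length(unique(nu_rows$label[nu_rows$free])) <
    length(fit$spec$items) * fit$spec$ngroups ||
    any(pt$free[pt$mat == "alpha"])
  w <- fit$n / sum(fit$n)
  total <- 0
  for (g in seq_along(fit$groups)) {
    S <- fit$data[[g]]$S
    ybar <- fit$data[[g]]$ybar
    Sig <- fit$groups[[g]]$Sigma
    mu <- fit$groups[[g]]$mu
    sd <- sqrt(diag(S))
    Rcov <- (S - Sig) / tcrossprod(sd)
    resid2 <- Rcov[lower.tri(Rcov, diag = TRUE)]^2
    if (structured_means) {
      resid2 <- c(resid2, ((ybar - mu) / sd)^2)
    }
    total <- total + w[g] * sqrt(mean(resid2))
  }
  total
}

#' Fit indices for a fitted CFA model
#'
#' Computes chi-square, CFI, TLI, RMSEA with 90% confidence interval, and
#' SRMR, in both the plain maximum-likelihood and the mean-scaled
#' (sample-corrected) versions.  Scaled indices substitute the scaled
#' statistics of both the target and the baseline model.
#'
#' @param fit A `cfa_fit`.
#' @param baseline Optional `cfa_fit` of the independence model on the
#'   same data (computed via [baseline_fit()] when omitted).
#' @param scaled Compute scaled variants (requires casewise data).
#' @return A `fit_index_set` list: `chi2`, `df`, `p`, `CFI`, `TLI`,
#'   `RMSEA`, `RMSEA_ci`, `SRMR`, and under `$scaled` the same fields
#'   computed from the scaled statistics plus `c_hat`.
#' @export
fit_indices <- function(fit, baseline = NULL, scaled = TRUE) {
  if (is.null(baseline)) baseline <- baseline_fit(fit)
  G <- length(fit$groups)
  Ntilde <- fit$Ntilde

  index_block <- function(T_m, df_m, T_b, df_b) {
    if (df_m == 0L) {
      return(list(
        chi2 = T_m, df = 0L, p = 1, CFI = 1, TLI = 1, RMSEA = 0,
        RMSEA_ci = c(0, 0), SRMR = srmr_value(fit)))
    }
    num <- max(T_m - df_m, 0)
    den <- max(T_b - df_b, T_m - df_m, 0)
    CFI <- if (den == 0) 1 else 1 - num / den
    TLI <- if (T_b / df_b - 1 == 0) 1 else
      ((T_b / df_b) - (T_m / df_m)) / ((T_b / df_b) - 1)
    list(
      chi2 = T_m, df = as.integer(df_m),
      p = stats::pchisq(T_m, df_m, lower.tail = FALSE),
      CFI = CFI, TLI = TLI,
      RMSEA = rmsea_point(T_m, df_m, Ntilde, G),
      RMSEA_ci = rmsea_ci(T_m, df_m, Ntilde, G),
      SRMR = srmr_value(fit)
    )
  }

  out <- index_block(fit$T_ML, fit$df, baseline$T_ML, baseline$df)
  if (scaled) {
    have_casewise <- !is.null(fit$data[[1]]$Y)
    if (have_casewise) {
      sc_m <- scaled_statistic(fit)
      sc_b <- scaled_statistic(baseline)
      out$scaled <- index_block(sc_m$T_scaled, fit$df,
                                sc_b$T_scaled, baseline$df)
      out$scaled$c_hat <- sc_m$c_hat
    } else {
      out$scaled <- NULL
    }
  }
  structure(out, class = "fit_index_set")
}

#' @export
print.fit_index_set <- function(x, ...) {
  fmt <- function(b, tag) {
    cat(sprintf(
      "  %schi2(%d) = %.3f, p = %.4g, CFI = %.3f, TLI = %.3f, RMSEA = %.3f [%.3f, %.3f], SRMR = %.3f\n",
      tag, b$df, b$chi2, b$p, b$CFI, b$TLI, b$RMSEA,
      b$RMSEA_ci[1], b$RMSEA_ci[2], b$SRMR))
  }
  cat("<fit_index_set>\n")
  fmt(x, "")
  if (!is.null(x$scaled)) fmt(x$scaled, "scaled ")
  invisible(x)
}

#' Model comparison table in the layout of a published fit table
#'
#' One row per fitted model with scaled chi-square, df, p, CFI, TLI,
#' RMSEA and its 90% CI, and SRMR.
#'
#' @param fits Named list of `cfa_fit` objects on the same data.
#' @param scaled Use the scaled index block when available.
#' @return A data frame.
#' @export
model_fit_table <- function(fits, scaled = TRUE) {
  rows <- lapply(names(fits), function(nm) {
    fi <- fit_indices(fits[[nm]], scaled = scaled)
    b <- if (scaled && !is.null(fi$scaled)) fi$scaled else fi
    data.frame(
      model = nm, chi2 = b$chi2, df = b$df, p = b$p, CFI = b$CFI,
      TLI = b$TLI, RMSEA = b$RMSEA,
      RMSEA_lo = b$RMSEA_ci[1], RMSEA_hi = b$RMSEA_ci[2],
      SRMR = b$SRMR, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
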