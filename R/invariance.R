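# Multigroup measurement-invariance ladder:
# configural -> metric -> scalar -> {factor_variance (side branch), residual}.
# Residual invariance nests on scalar, matching the published df
# arithmetic; the factor-variance step is reported as a side branch that
# qualifies the reliability interpretation of residual invariance.

invariance_level_names <- c("configural", "metric", "scalar",
                            "factor_variance", "residual")

level_rank <- function(level) {
  match(level, invariance_level_names)
}

#' Build a multigroup specification at an invariance level
#'
#' Expands a single-group `cfa_spec` to `length(groups)` groups and
#' applies the cumulative equality constraints of the requested level:
#' configural shares only the pattern; metric equates loadings (freeing
#' non-reference-group factor variances); scalar additionally equates
#' intercepts (freeing non-reference latent means); factor_variance
#' equates factor variances on top of scalar; residual equates residual
#' variances on top of scalar.  Parameters listed in `freed` are exempted
#' from their level's equalities (partial invariance).
#'
#' The first group is the reference: its factor variances stay fixed at 1
#' and latent means at 0 throughout.
#'
#' @param spec A single-group `cfa_spec` with unit-factor-variance
#'   identification.
#' @param groups Character vector of group labels (>= 2).
#' @param level One of `"configural"`, `"metric"`, `"scalar"`,
#'   `"factor_variance"`, `"residual"`.
#' @param freed Named list of item ids (or factor ids for
#'   `factor_variance`) exempted per level, e.g.
#'   `list(scalar = "phq2", residual = c("phq6", "phq7"))`.
#' @return A multigroup `cfa_spec`.
#' @export
constrain_invariance <- function(spec, groups, level,
                                 freed = list()) {
  stopifnot(inherits(spec, "cfa_spec"))
  if (spec$ngroups != 1L) stop("'spec' must be a single-group template")
  level <- match.arg(level, invariance_level_names)
  if (length(groups) < 2L) stop("need at least 2 groups")
  if (anyDuplicated(groups)) stop("group labels must be unique")
  bad_freed <- setdiff(names(freed), invariance_level_names)
  if (length(bad_freed)) {
    stop("freed parameters for unknown level(s): ",
         paste(bad_freed, collapse = ", "))
  }
  for (lv in names(freed)) {
    if (level_rank(lv) > level_rank(level) ||
        (lv == "factor_variance" && level != "factor_variance") ||
        (lv == "residual" && level != "residual")) {
      stop("cannot free '", lv, "' parameters at the ", level, " level")
    }
  }
  rk <- level_rank(level)
  items <- spec$items
  G <- length(groups)
  pt0 <- spec$ptable
  out <- vector("list", G)
  for (g in seq_len(G)) {
    pt <- pt0
    pt$group <- g
    sfx <- paste0(".g", g)
    for (r in seq_len(nrow(pt))) {
      mt <- pt$mat[r]
      if (mt == "lambda" && pt$free[r]) {
        item <- items[pt$row[r]]
        shared <- rk >= 2L && !item %in% freed$metric
        if (!shared) pt$label[r] <- paste0(pt$label[r], sfx)
      } else if (mt == "psi" && pt$row[r] == pt$col[r]) {
        fac <- spec$factors[pt$row[r]]
        if (!pt$free[r]) {
          # unit-variance identification: fixed 1 in the template
          if (level == "factor_variance" && !fac %in% freed$factor_variance) {
            # equal variances: keep fixed at 1 in every group
          } else if (rk >= 2L && g > 1L) {
            pt$free[r] <- TRUE
            pt$value[r] <- 1
            pt$label[r] <- paste0("psi.", fac, sfx)
          }
        } else {
          # marker identification: free variances
          if (level == "factor_variance" && !fac %in% freed$factor_variance) {
            # shared label across groups
          } else {
            pt$label[r] <- paste0(pt$label[r], sfx)
          }
        }
      } else if (mt == "psi") {
        if (pt$free[r]) pt$label[r] <- paste0(pt$label[r], sfx)
      } else if (mt == "theta") {
        if (pt$free[r]) {
          diag_row <- pt$row[r] == pt$col[r]
          item <- items[pt$row[r]]
          shared <- diag_row && level == "residual" &&
            !item %in% freed$residual
          if (!shared) pt$label[r] <- paste0(pt$label[r], sfx)
        }
      } else if (mt == "nu") {
        item <- items[pt$row[r]]
        shared <- rk >= 3L && !item %in% freed$scalar
        if (!shared) pt$label[r] <- paste0(pt$label[r], sfx)
      } else if (mt == "alpha") {
        if (rk >= 3L && g > 1L) {
          pt$free[r] <- TRUE
          pt$value[r] <- 0
          pt$label[r] <- paste0(pt$label[r], sfx)
        }
      }
    }
    out[[g]] <- pt
  }
  structure(
    list(name = sprintf("%s_%s", spec$name, level), items = items,
         factors = spec$factors, ptable = do.call(rbind, out),
         ngroups = G, group_labels = groups,
         identification = spec$identification,
         level = level, freed = freed,
         reference_subscale = spec$reference_subscale),
    class = "cfa_spec"
  )
}

#' Invariance decision rule
#'
#' A step up the ladder passes when the fit deterioration is negligible
#' (CFI drop smaller than `cfi_drop` *and* RMSEA increase at most
#' `rmsea_increase`) or the scaled chi-square difference test is
#' non-significant at `alpha`.
#'
#' @param delta_cfi CFI(current) - CFI(previous); negative = worse.
#' @param delta_rmsea RMSEA(current) - RMSEA(previous); positive = worse.
#' @param p P-value of the scaled chi-square difference test (`NA` to
#'   rely on the index rule alone).
#' @param alpha Significance level.
#' @param cfi_drop,rmsea_increase Index thresholds.
#' @return Logical: `TRUE` = invariance retained at this step.
#' @export
invariance_decision <- function(delta_cfi, delta_rmsea, p, alpha = 0.05,
                                cfi_drop = 0.01, rmsea_increase = 0.015) {
  index_ok <- (delta_cfi >= -cfi_drop) && (delta_rmsea <= rmsea_increase)
  test_ok <- !is.na(p) && p >= alpha
  isTRUE(index_ok || test_ok)
}

# ---- modification indices for partial-invariance search -------------------

# Univariate score (Lagrange multiplier) statistic for releasing one
# equality set: evaluate the gradient of the expanded parameterisation at
# the restricted optimum and form MI = (Ntilde/4) g' A^{-1} g with A the
# expected information of the moment structure.
modification_index <- function(fit, expanded_spec) {
  comp_e <- compile_spec(expanded_spec)
  # embed restricted estimates into the expanded parameter vector
  th_r <- fit$theta
  th_e <- numeric(comp_e$q)
  for (k in seq_len(comp_e$q)) {
    lab <- comp_e$labels[k]
    hit <- match(lab, names(th_r))
    if (is.na(hit)) hit <- match(sub("\\.g[0-9]+$", "", lab), names(th_r))
    if (is.na(hit)) {
      # parameter fixed in the restricted model (e.g. factor variance 1)
      base <- sub("\\.g[0-9]+$", "", lab)
      th_e[k] <- if (grepl("^psi\\.", base)) 1 else 0
    } else {
      th_e[k] <- th_r[hit]
    }
  }
  gdata <- fit$data
  w <- fit$weights
  g <- cfa_objective(th_e, comp_e, gdata, w, grad = TRUE)$grad
  A <- matrix(0, comp_e$q, comp_e$q)
  for (gg in seq_along(gdata)) {
    J <- moment_jacobian_group(comp_e, th_e, gg)
    V <- normal_weight(fit$groups[[gg]]$Sigma)
    A <- A + w[gg] * crossprod(J, V %*% J)
  }
  Ainv_g <- tryCatch(solve(A, g), error = function(e) {
    solve(A + diag(1e-8, nrow(A)), g)
  })
  as.numeric(fit$Ntilde / 4 * crossprod(g, Ainv_g))
}

releasable_targets <- function(spec, level, freed) {
  if (level == "metric") setdiff(spec$items, freed$metric)
  else if (level == "scalar") setdiff(spec$items, freed$scalar)
  else if (level == "residual") setdiff(spec$items, freed$residual)
  else if (level == "factor_variance") {
    setdiff(spec$factors, freed$factor_variance)
  } else character(0)
}

#' Partial-invariance search at a failed level
#'
#' Iteratively frees the constrained parameter with the largest
#' univariate score-test (modification) contribution, refits, and
#' re-applies the invariance decision against the comparison fit.  Stops
#' at a pass or once `max_freed` parameters are freed, after which the
#' verdict is non-invariant.  Ties are broken toward the lowest item
#' index, making the search deterministic.
#'
#' @param base_spec Single-group template `cfa_spec`.
#' @param gdata Internal per-group data list (as stored in a `cfa_fit`).
#' @param groups Group labels.
#' @param level Failing level.
#' @param freed Freed sets already accumulated at lower levels.
#' @param comparison_fit The retained fit the level is compared against.
#' @param comparison_indices Its `fit_index_set`.
#' @param failed_fit The full-constraint fit at this level.
#' @param max_freed Maximum number of freed parameters (default: half
#'   the items, rounded down).
#' @param alpha,cfi_drop,rmsea_increase Decision-rule settings.
#' @return List: `pass`, `freed` (character vector at this level), `fit`,
#'   `indices`, `delta`.
#' @keywords internal
partial_search <- function(base_spec, gdata, groups, level, freed,
                           comparison_fit, comparison_indices, failed_fit,
                           max_freed = floor(length(base_spec$items) / 2),
                           alpha = 0.05, cfi_drop = 0.01,
                           rmsea_increase = 0.015) {
  freed_here <- character(0)
  current_fit <- failed_fit
  repeat {
    candidates <- setdiff(releasable_targets(base_spec, level, freed),
                          freed_here)
    if (length(candidates) == 0L || length(freed_here) >= max_freed) {
      ind <- fit_indices(current_fit)
      delta <- ladder_delta(current_fit, ind, comparison_fit,
                            comparison_indices)
      return(list(pass = FALSE, freed = freed_here, fit = current_fit,
                  indices = ind, delta = delta))
    }
    mi <- vapply(candidates, function(tg) {
      fr <- freed
      fr[[level]] <- c(fr[[level]], freed_here, tg)
      sp <- constrain_invariance(base_spec, groups, level, fr)
      modification_index(current_fit, sp)
    }, numeric(1))
    # largest contribution; ties -> lowest item index
    ord <- order(-mi, match(candidates, base_spec$items))
    pick <- candidates[ord[1]]
    freed_here <- c(freed_here, pick)
    fr <- freed
    fr[[level]] <- c(fr[[level]], freed_here)
    sp <- constrain_invariance(base_spec, groups, level, fr)
    current_fit <- fit_cfa(gdata, sp, start = current_fit$theta)
    ind <- fit_indices(current_fit)
    delta <- ladder_delta(current_fit, ind, comparison_fit,
                          comparison_indices)
    if (invariance_decision(delta$delta_cfi, delta$delta_rmsea,
                            delta$p, alpha, cfi_drop, rmsea_increase)) {
      return(list(pass = TRUE, freed = freed_here, fit = current_fit,
                  indices = ind, delta = delta))
    }
  }
}

ladder_delta <- function(fit, indices, prev_fit, prev_indices) {
  use_scaled <- !is.null(indices$scaled) && !is.null(prev_indices$scaled)
  cur <- if (use_scaled) indices$scaled else indices
  prv <- if (use_scaled) prev_indices$scaled else prev_indices
  diff <- tryCatch(scaled_chisq_difference(fit, prev_fit),
                   error = function(e) {
                     list(delta_T = NA_real_,
                          delta_df = fit$df - prev_fit$df, p = NA_real_)
                   })
  list(delta_chi2 = diff$delta_T, delta_df = diff$delta_df, p = diff$p,
       delta_cfi = cur$CFI - prv$CFI,
       delta_rmsea = cur$RMSEA - prv$RMSEA,
       delta_srmr = cur$SRMR - prv$SRMR)
}

#' Run the measurement-invariance ladder
#'
#' Fits the requested levels in order on data split by a grouping column,
#' compares each level to the previously retained one (the
#' factor-variance side branch and the residual level are both compared
#' to the retained scalar fit), applies [invariance_decision()], and
#' invokes the partial-invariance search on failure.
#'
#' @param data An [item_response_matrix()] with a grouping column, or a
#'   named list of per-group inputs accepted by [fit_cfa()].
#' @param spec Single-group template `cfa_spec`.
#' @param grouping Grouping column name (when `data` is an
#'   `item_response_matrix`).
#' @param levels Ordered subset of
#'   `configural, metric, scalar, factor_variance, residual` (must
#'   respect the canonical order and start at `configural`).
#' @param alpha,cfi_drop,rmsea_increase Decision-rule settings.
#' @param max_freed Cap on freed parameters per level in the partial
#'   search.
#' @param min_invariant_items If not `NULL`, a partial solution retaining
#'   fewer than this many invariant items is downgraded to
#'   non-invariant; the default (`NULL`) only reports the count.
#' @return A `ladder_result`: per level a record with the fit, indices,
#'   deltas, decision and freed parameters, plus `attained` (the highest
#'   retained main-branch level) and `factor_variance_invariant`.
#' @export
run_ladder <- function(data, spec, grouping = NULL,
                       levels = invariance_level_names,
                       alpha = 0.05, cfi_drop = 0.01,
                       rmsea_increase = 0.015,
                       max_freed = NULL,
                       min_invariant_items = NULL) {
  stopifnot(inherits(spec, "cfa_spec"))
  levels <- match.arg(levels, invariance_level_names, several.ok = TRUE)
  if (!identical(levels,
                 invariance_level_names[sort(level_rank(levels))]) ||
      is.unsorted(level_rank(levels))) {
    stop("levels must follow the ladder order")
  }
  if (levels[1] != "configural") stop("the ladder starts at 'configural'")
  if (inherits(data, "item_response_matrix")) {
    if (is.null(grouping)) stop("'grouping' required for matrix input")
    if (anyNA(data$values)) {
      data <- complete_cases(data, spec$items)
    }
    gdata <- as_cfa_data(data, spec$items, grouping)
  } else {
    gdata <- as_cfa_data(data, spec$items)
  }
  if (length(gdata) < 2L) stop("invariance testing needs >= 2 groups")
  groups <- vapply(gdata, `[[`, character(1), "label")
  if (is.null(max_freed)) max_freed <- floor(length(spec$items) / 2)

  records <- list()
  freed <- list()
  attained <- NULL
  fv_invariant <- NA

  conf_spec <- constrain_invariance(spec, groups, "configural")
  fit_prev <- fit_cfa(gdata, conf_spec)
  ind_prev <- fit_indices(fit_prev)
  records$configural <- list(
    level = "configural", fit = fit_prev, indices = ind_prev,
    delta = NULL, decision = TRUE, freed = character(0))
  attained <- "configural"

  scalar_anchor <- NULL   # retained fit at the scalar level
  for (lv in setdiff(levels, "configural")) {
    side_branch <- lv == "factor_variance"
    if (lv %in% c("factor_variance", "residual")) {
      if (is.null(scalar_anchor)) {
        records[[lv]] <- list(level = lv, fit = NULL, indices = NULL,
                              delta = NULL, decision = FALSE,
                              freed = character(0),
                              note = "scalar level not retained")
        next
      }
      base_fit <- scalar_anchor$fit
      base_ind <- scalar_anchor$indices
    } else {
      base_fit <- fit_prev
      base_ind <- ind_prev
    }
    sp <- constrain_invariance(spec, groups, lv, freed)
    fit_lv <- fit_cfa(gdata, sp, start = base_fit$theta)
    ind_lv <- fit_indices(fit_lv)
    delta <- ladder_delta(fit_lv, ind_lv, base_fit, base_ind)
    pass <- invariance_decision(delta$delta_cfi, delta$delta_rmsea,
                                delta$p, alpha, cfi_drop, rmsea_increase)
    freed_lv <- character(0)
    if (!pass) {
      ps <- partial_search(spec, gdata, groups, lv, freed, base_fit,
                           base_ind, fit_lv, max_freed = max_freed,
                           alpha = alpha, cfi_drop = cfi_drop,
                           rmsea_increase = rmsea_increase)
      pass <- ps$pass
      freed_lv <- ps$freed
      fit_lv <- ps$fit
      ind_lv <- ps$indices
      delta <- ps$delta
      if (pass && !is.null(min_invariant_items) &&
          lv %in% c("metric", "scalar", "residual")) {
        if (length(spec$items) - length(freed_lv) < min_invariant_items) {
          pass <- FALSE
        }
      }
    }
    if (pass && length(freed_lv)) freed[[lv]] <- freed_lv
    records[[lv]] <- list(level = lv, fit = fit_lv, indices = ind_lv,
                          delta = delta, decision = pass,
                          freed = freed_lv)
    if (side_branch) {
      fv_invariant <- pass
    } else if (pass) {
      attained <- lv
      fit_prev <- fit_lv
      ind_prev <- ind_lv
      if (lv == "scalar") {
        scalar_anchor <- list(fit = fit_lv, indices = ind_lv)
      }
    } else if (lv %in% c("metric", "scalar")) {
      break   # higher main-branch levels are not identified without this one
    }
  }

  structure(
    list(records = records, attained = attained,
         factor_variance_invariant = fv_invariant,
         groups = groups,
         settings = list(alpha = alpha, cfi_drop = cfi_drop,
                         rmsea_increase = rmsea_increase,
                         max_freed = max_freed,
                         min_invariant_items = min_invariant_items)),
    class = "ladder_result"
  )
}

#' @export
print.ladder_result <- function(x, ...) {
  cat("<ladder_result> attained level:", x$attained, "\n")
  print(as.data.frame(x), digits = 4)
  invisible(x)
}

#' Invariance ladder as a table
#'
#' @param x A `ladder_result`.
#' @param ... Unused.
#' @return Data frame with chi2, df, p, CFI, RMSEA, SRMR, the deltas, the
#'   decision and the freed parameters per level.
#' @export
as.data.frame.ladder_result <- function(x, ...) {
  rows <- lapply(x$records, function(r) {
    if (is.null(r$fit)) {
      return(data.frame(level = r$level, chi2 = NA, df = NA, p = NA,
                        CFI = NA, RMSEA = NA, SRMR = NA,
                        delta_chi2 = NA, delta_df = NA, delta_p = NA,
                        delta_CFI = NA, delta_RMSEA = NA, delta_SRMR = NA,
                        decision = r$decision,
                        freed = "", stringsAsFactors = FALSE))
    }
    b <- if (!is.null(r$indices$scaled)) r$indices$scaled else r$indices
    d <- r$delta
    data.frame(
      level = r$level, chi2 = b$chi2, df = b$df, p = b$p, CFI = b$CFI,
      RMSEA = b$RMSEA, SRMR = b$SRMR,
      delta_chi2 = if (is.null(d)) NA else d$delta_chi2,
      delta_df = if (is.null(d)) NA else d$delta_df,
      delta_p = if (is.null(d)) NA else d$p,
      delta_CFI = if (is.null(d)) NA else d$delta_cfi,
      delta_RMSEA = if (is.null(d)) NA else d$delta_rmsea,
      delta_SRMR = if (is.null(d)) NA else d$delta_srmr,
      decision = r$decision,
      freed = paste(r$freed, collapse = ","),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
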