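#' Specify a confirmatory factor model
#'
#' Builds a single-group CFA specification over a covariance-plus-mean
#' structure \eqn{\Sigma = \Lambda\Psi\Lambda' + \Theta},
#' \eqn{\mu = \nu + \Lambda\kappa}.  The specification is stored as a
#' parameter table (one row per non-trivial matrix entry) in which free
#' rows carry labels; rows sharing a label share one parameter, which is
#' how cross-group equality constraints are expressed by
#' [constrain_invariance()].
#'
#' Mean structure is always present and saturated by default (free
#' intercepts, latent means fixed at 0), so single-group degrees of
#' freedom coincide with a covariance-only analysis.
#'
#' @param items Character vector of item (indicator) ids.
#' @param factors Named list mapping each factor name to the item ids it
#'   loads on (an item may load on several factors, as in bifactor
#'   models).
#' @param factor_cov `"correlated"` (free factor covariances) or
#'   `"orthogonal"` (fixed to zero).
#' @param residual_pairs Optional 2-column matrix / data frame of item-id
#'   pairs given free residual covariances.
#' @param identification `"unit_factor_variance"` (factor variances fixed
#'   at 1) or `"marker_item"` (first loading of each factor fixed at 1,
#'   factor variances free).
#' @param name Model name.
#' @return An object of class `cfa_spec`.
#' @examples
#' sdef <- phq9_scale()
#' spec <- cfa_model(sdef$items, list(dep = sdef$items))
#' cfa_df(spec)  # 27
#' @export
cfa_model <- function(items, factors,
                      factor_cov = c("correlated", "orthogonal"),
                      residual_pairs = NULL,
                      identification = c("unit_factor_variance",
                                         "marker_item"),
                      name = "cfa_model") {
  factor_cov <- match.arg(factor_cov)
  identification <- match.arg(identification)
  items <- as.character(items)
  if (anyDuplicated(items)) stop("item ids must be unique")
  if (!is.list(factors) || is.null(names(factors))) {
    stop("'factors' must be a named list of item vectors")
  }
  for (f in names(factors)) {
    if (length(factors[[f]]) < 2L) {
      stop("factor '", f, "' has fewer than 2 indicators")
    }
    unknown <- setdiff(factors[[f]], items)
    if (length(unknown)) {
      stop("unknown item(s) on factor '", f, "': ",
           paste(unknown, collapse = ", "))
    }
  }
  fnames <- names(factors)
  rows <- list()
  add <- function(mat, row, col, free, value, label) {
    rows[[length(rows) + 1L]] <<- data.frame(
      mat = mat, row = row, col = col, free = free, value = value,
      label = label, stringsAsFactors = FALSE
    )
  }
  for (j in seq_along(fnames)) {
    f_items <- factors[[fnames[j]]]
    for (k in seq_along(f_items)) {
      i <- match(f_items[k], items)
      if (identification == "marker_item" && k == 1L) {
        add("lambda", i, j, FALSE, 1, "")
      } else {
        add("lambda", i, j, TRUE, 0.5,
            sprintf("lam.%s.%s", f_items[k], fnames[j]))
      }
    }
  }
  for (j in seq_along(fnames)) {
    if (identification == "unit_factor_variance") {
      add("psi", j, j, FALSE, 1, "")
    } else {
      add("psi", j, j, TRUE, 1, sprintf("psi.%s", fnames[j]))
    }
  }
  if (length(fnames) > 1L) {
    for (j in 2:length(fnames)) {
      for (k in 1:(j - 1L)) {
        if (factor_cov == "correlated") {
          add("psi", j, k, TRUE, 0.3,
              sprintf("psi.%s.%s", fnames[k], fnames[j]))
        }  # orthogonal: omit row, template zero
      }
    }
  }
  for (i in seq_along(items)) {
    add("theta", i, i, TRUE, NA, sprintf("th.%s", items[i]))
  }
  if (!is.null(residual_pairs)) {
    rp <- as.matrix(residual_pairs)
    for (k in seq_len(nrow(rp))) {
      i1 <- match(rp[k, 1], items)
      i2 <- match(rp[k, 2], items)
      if (anyNA(c(i1, i2))) stop("unknown item in residual_pairs")
      add("theta", max(i1, i2), min(i1, i2), TRUE, 0,
          sprintf("th.%s.%s", items[min(i1, i2)], items[max(i1, i2)]))
    }
  }
  for (i in seq_along(items)) {
    add("nu", i, 1L, TRUE, NA, sprintf("nu.%s", items[i]))
  }
  for (j in seq_along(fnames)) {
    add("alpha", j, 1L, FALSE, 0, sprintf("al.%s", fnames[j]))
  }
  pt <- do.call(rbind, rows)
  pt$group <- 1L
  structure(
    list(name = name, items = items, factors = fnames,
         ptable = pt, ngroups = 1L, group_labels = "all",
         identification = identification),
    class = "cfa_spec"
  )
}

#' @export
print.cfa_spec <- function(x, ...) {
  cat(sprintf(
    "<cfa_spec> '%s': %d items, %d factor(s), %d group(s), %d free parameters, df = %d\n",
    x$name, length(x$items), length(x$factors), x$ngroups,
    n_free_params(x), cfa_df(x)))
  invisible(x)
}

n_free_params <- function(spec) {
  pt <- spec$ptable
  length(unique(pt$label[pt$free]))
}

#' Degrees of freedom of a specification
#'
#' Number of unique sample moments (per-group means plus non-redundant
#' covariances) minus the number of unique free parameters.
#'
#' @param spec A `cfa_spec`.
#' @return Integer df.
#' @export
cfa_df <- function(spec) {
  p <- length(spec$items)
  as.integer(spec$ngroups * (p + p * (p + 1) / 2) - n_free_params(spec))
}

#' Catalog of candidate measurement models for a two-facet scale
#'
#' Returns the four structures compared throughout the package for scales
#' with a somatic and a cognitive/affective facet: a one-factor model, a
#' correlated two-factor model following the subscale partition, a
#' one-factor model with free residual covariances among all
#' within-somatic item pairs, and the bifactor-(S-1) model with the
#' somatic facet as reference.
#'
#' @param scale_def A [scale_definition()] whose subscales include one
#'   named `"somatic"`.
#' @param identification Passed to [cfa_model()].
#' @return Named list of `cfa_spec` objects: `one_factor`,
#'   `two_factor_correlated`, `one_factor_correlated_residuals`,
#'   `bifactor_s_minus_1`.
#' @export
model_catalog <- function(scale_def,
                          identification = "unit_factor_variance") {
  stopifnot(inherits(scale_def, "scale_definition"))
  if (!"somatic" %in% names(scale_def$subscales)) {
    stop("scale definition must name a 'somatic' subscale")
  }
  if (any(lengths(scale_def$subscales) < 2L)) {
    stop("every subscale needs >= 2 items to support a factor")
  }
  items <- scale_def$items
  general <- sub("-.*$", "", tolower(scale_def$name))
  if (!nzchar(general)) general <- "general"
  som <- scale_def$subscales$somatic
  som_pairs <- t(utils::combn(som, 2L))
  list(
    one_factor = cfa_model(
      items, stats::setNames(list(items), general),
      identification = identification, name = "one_factor"),
    two_factor_correlated = cfa_model(
      items, scale_def$subscales, factor_cov = "correlated",
      identification = identification, name = "two_factor_correlated"),
    one_factor_correlated_residuals = cfa_model(
      items, stats::setNames(list(items), general),
      residual_pairs = som_pairs,
      identification = identification,
      name = "one_factor_correlated_residuals"),
    bifactor_s_minus_1 = bifactor_s_minus_1_spec(
      scale_def, reference_subscale = "somatic")
  )
}

#' Bifactor-(S-1) specification
#'
#' A general factor loads on every item; one group factor loads only on
#' the non-reference subscale's items; all factors are orthogonal with
#' unit variance.  Discarding the reference subscale's group factor makes
#' that facet the reference for the general factor and resolves the
#' identification problem of a two-facet bifactor model.
#'
#' @param scale_def A [scale_definition()] with exactly two subscales.
#' @param reference_subscale Name of the subscale whose group factor is
#'   discarded.
#' @return A `cfa_spec`.
#' @export
bifactor_s_minus_1_spec <- function(scale_def, reference_subscale) {
  stopifnot(inherits(scale_def, "scale_definition"))
  if (length(scale_def$subscales) != 2L) {
    stop("bifactor-(S-1) modeling here requires exactly 2 subscales")
  }
  if (!reference_subscale %in% names(scale_def$subscales)) {
    stop("unknown reference subscale '", reference_subscale, "'")
  }
  other <- setdiff(names(scale_def$subscales), reference_subscale)
  if (length(scale_def$subscales[[other]]) < 2L) {
    stop("non-reference subscale needs >= 2 items")
  }
  facs <- stats::setNames(
    list(scale_def$items, scale_def$subscales[[other]]),
    c("general", other)
  )
  spec <- cfa_model(scale_def$items, facs, factor_cov = "orthogonal",
                    identification = "unit_factor_variance",
                    name = "bifactor_s_minus_1")
  spec$reference_subscale <- reference_subscale
  spec
}

#' Saturated (just-identified) specification
#'
#' Free means and a fully free covariance matrix (all variances and all
#' pairwise covariances as residual parameters, no factors): zero degrees
#' of freedom, reproducing any sample moments exactly.  Useful as a
#' degenerate reference and for testing.
#'
#' @param items Item ids.
#' @return A `cfa_spec` with `cfa_df() == 0`.
#' @export
saturated_spec <- function(items) {
  items <- as.character(items)
  p <- length(items)
  rows <- list()
  for (i in seq_len(p)) {
    rows[[length(rows) + 1L]] <- data.frame(
      mat = "theta", row = i, col = i, free = TRUE, value = NA,
      label = sprintf("th.%s", items[i]), stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      mat = "nu", row = i, col = 1L, free = TRUE, value = NA,
      label = sprintf("nu.%s", items[i]), stringsAsFactors = FALSE)
  }
  if (p > 1L) {
    for (i in 2:p) for (j in 1:(i - 1L)) {
      rows[[length(rows) + 1L]] <- data.frame(
        mat = "theta", row = i, col = j, free = TRUE, value = 0,
        label = sprintf("th.%s.%s", items[j], items[i]),
        stringsAsFactors = FALSE)
    }
  }
  pt <- do.call(rbind, rows)
  pt$group <- 1L
  structure(
    list(name = "saturated", items = items, factors = character(0),
         ptable = pt, ngroups = 1L, group_labels = "all",
         identification = "unit_factor_variance"),
    class = "cfa_spec"
  )
}

# ---- compilation: parameter table -> fast index structure -----------------

compile_spec <- function(spec) {
  pt <- spec$ptable
  p <- length(spec$items)
  m <- length(spec$factors)
  free_rows <- which(pt$free)
  labels <- pt$label[free_rows]
  ulab <- unique(labels)
  q <- length(ulab)
  id <- integer(nrow(pt))
  id[free_rows] <- match(labels, ulab)

  start <- vapply(ulab, function(l) {
    pt$value[free_rows[match(l, labels)]]
  }, numeric(1))
  lower <- rep(-Inf, q)
  var_rows <- pt$free & pt$mat %in% c("psi", "theta") & pt$row == pt$col
  lower[unique(id[var_rows])] <- 1e-6

  groups <- lapply(seq_len(spec$ngroups), function(g) {
    sel <- pt$group == g
    gp <- pt[sel, , drop = FALSE]
    gid <- id[sel]
    tmpl <- list(
      Lam = matrix(0, p, m), Psi = matrix(0, m, m),
      Th = matrix(0, p, p), nu = numeric(p), al = numeric(m)
    )
    ent <- list()
    for (mt in c("lambda", "psi", "theta", "nu", "alpha")) {
      k <- which(gp$mat == mt)
      fixed <- k[gid[k] == 0L]
      free <- k[gid[k] > 0L]
      # fixed values into templates
      for (kk in fixed) {
        r <- gp$row[kk]; cc <- gp$col[kk]; v <- gp$value[kk]
        switch(mt,
          lambda = { tmpl$Lam[r, cc] <- v },
          psi = { tmpl$Psi[r, cc] <- v; tmpl$Psi[cc, r] <- v },
          theta = { tmpl$Th[r, cc] <- v; tmpl$Th[cc, r] <- v },
          nu = { tmpl$nu[r] <- v },
          alpha = { tmpl$al[r] <- v })
      }
      ent[[mt]] <- list(row = gp$row[free], col = gp$col[free],
                        id = gid[free])
    }
    c(tmpl, list(ent = ent))
  })

  # data-dependent starts resolved at fit time (NA markers)
  list(q = q, labels = ulab, start = start, lower = lower,
       groups = groups, p = p, m = m, param_table = cbind(pt, id = id))
}

# fill model matrices for group g given parameter vector th
fill_group <- function(cg, th) {
  Lam <- cg$Lam; Psi <- cg$Psi; Th <- cg$Th; nu <- cg$nu; al <- cg$al
  e <- cg$ent$lambda
  if (length(e$id)) Lam[cbind(e$row, e$col)] <- th[e$id]
  e <- cg$ent$psi
  if (length(e$id)) {
    Psi[cbind(e$row, e$col)] <- th[e$id]
    Psi[cbind(e$col, e$row)] <- th[e$id]
  }
  e <- cg$ent$theta
  if (length(e$id)) {
    Th[cbind(e$row, e$col)] <- th[e$id]
    Th[cbind(e$col, e$row)] <- th[e$id]
  }
  e <- cg$ent$nu
  if (length(e$id)) nu[e$row] <- th[e$id]
  e <- cg$ent$alpha
  if (length(e$id)) al[e$row] <- th[e$id]
  list(Lam = Lam, Psi = Psi, Th = Th, nu = nu, al = al)
}

#' Model-implied moments for a parameter vector
#'
#' @param spec A `cfa_spec`.
#' @param theta Free-parameter vector in the order of
#'   `compile_spec(spec)$labels` (internal order; see `cfa_fit$labels`).
#' @return For a single-group spec, a list `Sigma`, `mu`; for multigroup,
#'   a list of such lists.
#' @export
implied_moments <- function(spec, theta) {
  comp <- compile_spec(spec)
  if (length(theta) != comp$q) {
    stop("parameter vector has length ", length(theta),
         ", expected ", comp$q)
  }
  out <- lapply(comp$groups, function(cg) {
    mm <- fill_group(cg, theta)
    Sigma <- mm$Lam %*% mm$Psi %*% t(mm$Lam) + mm$Th
    dimnames(Sigma) <- list(spec$items, spec$items)
    mu <- stats::setNames(mm$nu + drop(mm$Lam %*% mm$al), spec$items)
    list(Sigma = Sigma, mu = mu)
  })
  if (spec$ngroups == 1L) out[[1]] else out
}
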