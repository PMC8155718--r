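#' Specify a population factor model for Likert data generation
#'
#' Fully specifies the data-generating process used by the simulator:
#' continuous item responses follow the common-factor model
#' \eqn{y = \nu + \Lambda(\kappa + \xi) + \epsilon} with
#' \eqn{\xi \sim N(0, \Psi)}, \eqn{\epsilon \sim N(0, \Theta)}; 4-point
#' Likert codes arise by cutting each continuous response at three strictly
#' increasing thresholds.
#'
#' @param loadings Items x factors loading matrix \eqn{\Lambda}.
#' @param factor_cov Factor covariance matrix \eqn{\Psi} (PSD).
#' @param residual_cov Residual covariance \eqn{\Theta} (PSD; diagonal plus
#'   optional off-diagonal entries), or a vector of residual variances.
#' @param intercepts Item intercepts \eqn{\nu} (default 0).
#' @param latent_means Factor means \eqn{\kappa} (default 0).
#' @param thresholds Items x 3 matrix of strictly increasing cut points, or
#'   `NULL` to use [default_thresholds()] at simulation time.
#' @param missing_rate MCAR cell-missingness probability in `[0, 1)`.
#' @param item_ids,factor_ids Optional identifier vectors.
#' @return An object of class `population_model`.
#' @examples
#' m <- population_model(matrix(0.6, 9, 1), 1, rep(0.64, 9))
#' implied_population_moments(m)$Sigma[1, 2]  # 0.36
#' @export
population_model <- function(loadings, factor_cov, residual_cov,
                             intercepts = NULL, latent_means = NULL,
                             thresholds = NULL, missing_rate = 0,
                             item_ids = NULL, factor_ids = NULL) {
  L <- as.matrix(loadings)
  p <- nrow(L)
  m <- ncol(L)
  Psi <- as.matrix(factor_cov)
  if (!isTRUE(all.equal(Psi, t(Psi)))) stop("factor_cov must be symmetric")
  if (length(residual_cov) == p && is.null(dim(residual_cov))) {
    Theta <- diag(as.numeric(residual_cov), p)
  } else {
    Theta <- as.matrix(residual_cov)
  }
  if (!isTRUE(all.equal(Theta, t(Theta)))) stop("residual_cov must be symmetric")
  if (nrow(Psi) != m) stop("factor_cov dimension mismatch")
  if (nrow(Theta) != p) stop("residual_cov dimension mismatch")
  if (is.null(intercepts)) intercepts <- numeric(p)
  if (is.null(latent_means)) latent_means <- numeric(m)
  if (length(intercepts) != p) stop("intercepts length mismatch")
  if (length(latent_means) != m) stop("latent_means length mismatch")
  if (min(eigen(Psi, symmetric = TRUE, only.values = TRUE)$values) < -1e-10) {
    stop("factor_cov is not positive semi-definite")
  }
  Sigma <- L %*% Psi %*% t(L) + Theta
  if (min(eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values) <= 1e-10) {
    stop("implied covariance is not positive definite")
  }
  if (!is.null(thresholds)) {
    thresholds <- as.matrix(thresholds)
    if (nrow(thresholds) != p || ncol(thresholds) != 3L) {
      stop("thresholds must be an items x 3 matrix")
    }
    if (any(apply(thresholds, 1L, function(t) any(diff(t) <= 0)))) {
      stop("thresholds must be strictly increasing per item")
    }
  }
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must be in [0,1)")
  if (is.null(item_ids)) item_ids <- paste0("item", seq_len(p))
  if (is.null(factor_ids)) factor_ids <- paste0("f", seq_len(m))
  structure(
    list(loadings = L, factor_cov = Psi, residual_cov = Theta,
         intercepts = as.numeric(intercepts),
         latent_means = as.numeric(latent_means),
         thresholds = thresholds, missing_rate = missing_rate,
         item_ids = as.character(item_ids),
         factor_ids = as.character(factor_ids)),
    class = "population_model"
  )
}

#' @export
print.population_model <- function(x, ...) {
  cat(sprintf("<population_model> %d items, %d factor(s), missing rate %.3f\n",
              nrow(x$loadings), ncol(x$loadings), x$missing_rate))
  invisible(x)
}

#' Model-implied moments of the continuous responses
#'
#' @param model A [population_model()].
#' @return List with `Sigma` (\eqn{\Lambda\Psi\Lambda' + \Theta}) and `mu`
#'   (\eqn{\nu + \Lambda\kappa}).
#' @export
implied_population_moments <- function(model) {
  stopifnot(inherits(model, "population_model"))
  Sigma <- model$loadings %*% model$factor_cov %*% t(model$loadings) +
    model$residual_cov
  mu <- model$intercepts + drop(model$loadings %*% model$latent_means)
  dimnames(Sigma) <- list(model$item_ids, model$item_ids)
  names(mu) <- model$item_ids
  list(Sigma = Sigma, mu = mu)
}

#' Default right-skewed thresholds
#'
#' Mild symptom-severity items are strongly right-skewed: most respondents
#' endorse the lowest category.  The default cut points sit at the 60th,
#' 80th and 93rd percentiles of each item's implied continuous
#' distribution, giving marginal category proportions of roughly
#' 0.60/0.20/0.13/0.07.
#'
#' @param model A [population_model()].
#' @param probs Percentile positions of the three cut points.
#' @return Items x 3 threshold matrix on the items' own scales.
#' @export
default_thresholds <- function(model, probs = c(0.60, 0.80, 0.93)) {
  mom <- implied_population_moments(model)
  sds <- sqrt(diag(mom$Sigma))
  t(vapply(seq_along(sds), function(i) {
    mom$mu[i] + sds[i] * stats::qnorm(probs)
  }, numeric(3)))
}

#' Discretize continuous responses into Likert codes
#'
#' A value's code is the number of thresholds strictly below it, yielding
#' integer codes 0--3 for three cut points.
#'
#' @param values Numeric matrix of continuous responses (items in columns)
#'   or a vector for a single item.
#' @param thresholds Items x 3 matrix (or length-3 vector) of strictly
#'   increasing cut points.
#' @return Integer matrix (or vector) of codes.
#' @export
discretize <- function(values, thresholds) {
  vec_in <- is.null(dim(values))
  v <- if (vec_in) matrix(values, ncol = 1L) else as.matrix(values)
  th <- if (is.null(dim(thresholds))) {
    matrix(thresholds, nrow = ncol(v), ncol = length(thresholds), byrow = TRUE)
  } else {
    as.matrix(thresholds)
  }
  if (nrow(th) != ncol(v)) stop("thresholds/value dimension mismatch")
  if (any(apply(th, 1L, function(t) any(diff(t) <= 0)))) {
    stop("thresholds must be strictly increasing per item")
  }
  out <- v
  for (j in seq_len(ncol(v))) {
    out[, j] <- (v[, j] > th[j, 1]) + (v[, j] > th[j, 2]) + (v[, j] > th[j, 3])
  }
  if (vec_in) drop(out) else out
}

#' Simulate item responses from a population model
#'
#' Draws factors and residuals from multivariate normal distributions with
#' the model's moments, optionally discretizes through the model's
#' thresholds, and applies MCAR missingness at the model's `missing_rate`.
#' Reproducible for a given `seed`.
#'
#' @param model A [population_model()].
#' @param n Sample size (>= 2).
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @param discretize Logical; if `FALSE`, returns the continuous responses.
#' @param grouping Optional data frame of grouping labels to attach.
#' @return An [item_response_matrix()]; continuous values carry
#'   `code_range = c(-Inf, Inf)` semantics via a plain matrix in
#'   `$values` with validation disabled.
#' @export
simulate_responses <- function(model, n, seed = NULL, discretize = TRUE,
                               grouping = NULL) {
  stopifnot(inherits(model, "population_model"), n >= 2)
  if (!is.null(seed)) set.seed(as.integer(seed) %% .Machine$integer.max)
  mom <- implied_population_moments(model)
  p <- length(mom$mu)
  Lch <- chol(mom$Sigma)
  Y <- matrix(stats::rnorm(n * p), n, p) %*% Lch
  Y <- sweep(Y, 2L, mom$mu, "+")
  colnames(Y) <- model$item_ids
  if (discretize) {
    th <- model$thresholds
    if (is.null(th)) th <- default_thresholds(model)
    Y <- discretize(Y, th)
  }
  if (model$missing_rate > 0) {
    drop_mask <- matrix(stats::runif(n * p) < model$missing_rate, n, p)
    Y[drop_mask] <- NA
  }
  item_response_matrix(
    Y, item_ids = model$item_ids, grouping = grouping,
    code_range = if (discretize) c(0L, 3L) else c(-Inf, Inf)
  )
}

#' Plant an invariance violation into a population model
#'
#' @param kind One of `"loading"`, `"intercept"`, `"residual_variance"`,
#'   `"factor_variance"`.
#' @param target Item id (or factor id for `"factor_variance"`).
#' @param shift Numeric shift; additive unless `multiplicative = TRUE`.
#' @param group Group label the violation applies to.
#' @param multiplicative Logical.
#' @param factor For `"loading"`: which factor's loading to shift
#'   (default: the first factor the item loads on).
#' @return A `violation_spec` object.
#' @export
violation_spec <- function(kind, target, shift, group,
                           multiplicative = FALSE, factor = NULL) {
  kind <- match.arg(kind, c("loading", "intercept", "residual_variance",
                            "factor_variance"))
  structure(list(kind = kind, target = target, shift = shift,
                 group = group, multiplicative = multiplicative,
                 factor = factor),
            class = "violation_spec")
}

apply_violation <- function(model, v) {
  stopifnot(inherits(v, "violation_spec"))
  if (v$kind == "factor_variance") {
    j <- match(v$target, model$factor_ids)
    if (is.na(j)) stop("unknown factor id '", v$target, "'")
    model$factor_cov[j, j] <- if (v$multiplicative) {
      model$factor_cov[j, j] * v$shift
    } else {
      model$factor_cov[j, j] + v$shift
    }
  } else {
    i <- match(v$target, model$item_ids)
    if (is.na(i)) stop("unknown item id '", v$target, "'")
    if (v$kind == "loading") {
      j <- if (is.null(v$factor)) which(model$loadings[i, ] != 0)[1] else
        match(v$factor, model$factor_ids)
      if (is.na(j) || length(j) == 0L) stop("no loading to shift for '", v$target, "'")
      model$loadings[i, j] <- if (v$multiplicative) {
        model$loadings[i, j] * v$shift
      } else {
        model$loadings[i, j] + v$shift
      }
    } else if (v$kind == "intercept") {
      model$intercepts[i] <- if (v$multiplicative) {
        model$intercepts[i] * v$shift
      } else {
        model$intercepts[i] + v$shift
      }
    } else {
      model$residual_cov[i, i] <- if (v$multiplicative) {
        model$residual_cov[i, i] * v$shift
      } else {
        model$residual_cov[i, i] + v$shift
      }
    }
  }
  # re-validate through the constructor
  population_model(model$loadings, model$factor_cov, model$residual_cov,
                   model$intercepts, model$latent_means, model$thresholds,
                   model$missing_rate, model$item_ids, model$factor_ids)
}

#' Build a multigroup invariance scenario
#'
#' Unviolated groups share the base model; each violation is applied to
#' the model of its target group.  The returned manifest records exactly
#' which parameters differ from the base model, so planted effects can be
#' audited downstream.
#'
#' @param base A [population_model()].
#' @param violations List of [violation_spec()] objects (may be empty).
#' @param group_labels Unique group labels.
#' @param group_ns Per-group sample sizes.
#' @return List with `groups` (named list of `list(model, n)`) and
#'   `manifest` (data frame: group, kind, target, parameter).
#' @export
make_invariance_scenario <- function(base, violations, group_labels,
                                     group_ns) {
  stopifnot(inherits(base, "population_model"))
  if (anyDuplicated(group_labels)) stop("group labels must be unique")
  # pin thresholds before any shift: cut points are a measurement property
  # shared across groups, otherwise planted violations would be absorbed
  if (is.null(base$thresholds)) base$thresholds <- default_thresholds(base)
  if (length(group_ns) != length(group_labels)) {
    stop("group_ns must match group_labels")
  }
  models <- stats::setNames(rep(list(base), length(group_labels)),
                            group_labels)
  manifest <- data.frame(group = character(), kind = character(),
                         target = character(), parameter = character(),
                         stringsAsFactors = FALSE)
  for (v in violations) {
    if (!v$group %in% group_labels) stop("unknown group '", v$group, "'")
    models[[v$group]] <- apply_violation(models[[v$group]], v)
    par_name <- switch(v$kind,
      loading = sprintf("lambda[%s]", v$target),
      intercept = sprintf("nu[%s]", v$target),
      residual_variance = sprintf("theta[%s]", v$target),
      factor_variance = sprintf("psi[%s]", v$target)
    )
    manifest <- rbind(manifest, data.frame(
      group = v$group, kind = v$kind, target = v$target,
      parameter = par_name, stringsAsFactors = FALSE
    ))
  }
  list(
    groups = Map(function(m, n) list(model = m, n = n),
                 models, as.list(group_ns)),
    manifest = manifest
  )
}

#' Simulate a full multigroup dataset from a scenario
#'
#' Draws each group's sample with a deterministic child seed derived from
#' `seed`, stacks them, and attaches the group label as a grouping column.
#'
#' @param scenario Output of [make_invariance_scenario()].
#' @param seed Root integer seed.
#' @param grouping_name Name for the grouping column.
#' @param discretize Logical, as in [simulate_responses()].
#' @return An [item_response_matrix()] with one grouping column.
#' @export
simulate_scenario <- function(scenario, seed = 1L, grouping_name = "group",
                              discretize = TRUE) {
  labels <- names(scenario$groups)
  mats <- vector("list", length(labels))
  for (k in seq_along(labels)) {
    g <- scenario$groups[[k]]
    child <- (as.integer(seed) + 7919L * k) %% .Machine$integer.max
    grp <- stats::setNames(
      data.frame(rep(labels[k], g$n), stringsAsFactors = FALSE),
      grouping_name
    )
    mats[[k]] <- simulate_responses(g$model, g$n, seed = child,
                                    discretize = discretize, grouping = grp)
  }
  values <- do.call(rbind, lapply(mats, `[[`, "values"))
  grouping <- do.call(rbind, lapply(mats, `[[`, "grouping"))
  rownames(values) <- NULL
  rownames(grouping) <- NULL
  item_response_matrix(
    values, item_ids = mats[[1]]$item_ids, grouping = grouping,
    code_range = if (discretize) c(0L, 3L) else c(-Inf, Inf)
  )
}

#' PHQ-9-shaped default population model
#'
#' A two-factor population with a cognitive/affective factor (six items)
#' and a somatic factor (three items) correlated 0.77, standardized
#' loadings around 0.45--0.73, and right-skewed default thresholds.  This
#' emulates the structure of rural-community depression screening data; it
#' is a generic stand-in, not a reproduction of any fitted solution.
#'
#' @param factor_cor Correlation between the two factors.
#' @param missing_rate MCAR cell probability.
#' @return A [population_model()] whose items follow [phq9_scale()].
#' @export
phq9_population <- function(factor_cor = 0.77, missing_rate = 0) {
  sdef <- phq9_scale()
  items <- sdef$items
  lam <- c(0.65, 0.70, 0.55, 0.73, 0.50, 0.68, 0.60, 0.58, 0.45)
  L <- matrix(0, 9, 2, dimnames = list(items, c("cognitive", "somatic")))
  L[match(sdef$subscales$cognitive, items), 1] <-
    lam[match(sdef$subscales$cognitive, items)]
  L[match(sdef$subscales$somatic, items), 2] <-
    lam[match(sdef$subscales$somatic, items)]
  Psi <- matrix(c(1, factor_cor, factor_cor, 1), 2, 2)
  communal <- rowSums((L %*% Psi) * L)
  model <- population_model(L, Psi, 1 - communal, item_ids = items,
                            factor_ids = c("cognitive", "somatic"),
                            missing_rate = missing_rate)
  model$thresholds <- default_thresholds(model)
  model
}

#' GAD-7-shaped default population model
#'
#' One general anxiety factor with loadings 0.27--0.88 (item 6 weak, as
#' commonly reported) and correlated residuals among items 3, 5 and 6.
#'
#' @inheritParams phq9_population
#' @return A [population_model()] whose items follow [gad7_scale()].
#' @export
gad7_population <- function(missing_rate = 0) {
  sdef <- gad7_scale()
  items <- sdef$items
  lam <- c(0.75, 0.88, 0.70, 0.62, 0.58, 0.27, 0.66)
  L <- matrix(lam, 7, 1, dimnames = list(items, "anxiety"))
  Theta <- diag(1 - lam^2)
  pairs <- rbind(c(3, 5), c(3, 6), c(5, 6))
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    Theta[i, j] <- Theta[j, i] <- 0.15 * sqrt(Theta[i, i] * Theta[j, j])
  }
  model <- population_model(L, matrix(1), Theta, item_ids = items,
                            factor_ids = "anxiety",
                            missing_rate = missing_rate)
  model$thresholds <- default_thresholds(model)
  model
}
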