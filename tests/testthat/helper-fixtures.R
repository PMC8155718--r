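# Shared fixtures: small population models and data builders.
# All randomness is seeded per call site for reproducibility.

toy_items <- function(k = 6) paste0("i", seq_len(k))

# one-factor population with equal loadings, unit item variances
one_factor_population <- function(lambda = 0.6, k = 6,
                                  missing_rate = 0) {
  items <- toy_items(k)
  L <- matrix(lambda, k, 1, dimnames = list(items, "f"))
  m <- population_model(L, matrix(1), rep(1 - lambda^2, k),
                        item_ids = items, factor_ids = "f",
                        missing_rate = missing_rate)
  m$thresholds <- default_thresholds(m)
  m
}

# bifactor population with a dominant general factor and a weak group
# factor on `group_items` (orthogonal, unit item variances); defaults to
# the PHQ-9 cognitive facet so it aligns with bifactor_s_minus_1_spec
bifactor_population <- function(k = 9, group_items = c(1, 2, 6, 7, 8, 9),
                                general = 0.7, group = 0.35,
                                items = phq9_scale()$items) {
  L <- matrix(0, k, 2, dimnames = list(items, c("general", "grp")))
  L[, 1] <- general
  L[group_items, 2] <- group
  th <- 1 - rowSums(L^2)
  m <- population_model(L, diag(2), th, item_ids = items,
                        factor_ids = c("general", "grp"))
  m$thresholds <- default_thresholds(m)
  m
}

# two-group scenario builder around the PHQ-9-shaped population
two_group_scenario <- function(violations = list(), n = 600) {
  make_invariance_scenario(phq9_population(), violations,
                           c("A", "B"), c(n, n))
}

# continuous multivariate-normal item_response_matrix
continuous_irm <- function(n, Sigma, mu = rep(0, ncol(Sigma)),
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  Y <- MASS::mvrnorm(n, mu, Sigma)
  colnames(Y) <- paste0("i", seq_len(ncol(Sigma)))
  item_response_matrix(Y, code_range = c(-Inf, Inf))
}

# brute-force ML discrepancy evaluated without the package's algebra
brute_force_fml <- function(S, ybar, Sigma, mu) {
  p <- nrow(S)
  log(det(Sigma)) - log(det(S)) + sum(diag(S %*% solve(Sigma))) - p +
    t(ybar - mu) %*% solve(Sigma) %*% (ybar - mu)
}

random_spd <- function(p, seed) {
  set.seed(seed)
  A <- matrix(rnorm(p * p), p)
  crossprod(A) / p + diag(0.5, p)
}
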