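#' Configuration for the end-to-end validation pipeline
#'
#' Collects the decision-rule constants used across the pipeline.  The
#' defaults are the conventional thresholds for these procedures: a CFI
#' drop of 0.01 with an RMSEA increase of 0.015 for invariance steps at
#' alpha 0.05, Olkin's Z above 1.64 for subscore added value, and
#' recommended minima of 0.70 for hierarchical omega and 0.50 for
#' subscale hierarchical omega.
#'
#' @param alpha Significance level for difference tests.
#' @param cfi_drop,rmsea_increase Invariance index thresholds.
#' @param olkin_z Subscore decision threshold.
#' @param omega_h_min,omega_hs_min Reliability flag minima.
#' @param reference_subscale Subscale discarded in the bifactor-(S-1)
#'   model.
#' @param seed Root seed recorded with every simulated operation.
#' @return A `validation_config` list.
#' @export
validation_config <- function(alpha = 0.05, cfi_drop = 0.01,
                              rmsea_increase = 0.015, olkin_z = 1.64,
                              omega_h_min = 0.70, omega_hs_min = 0.50,
                              reference_subscale = "somatic",
                              seed = 1L) {
  stopifnot(alpha > 0, cfi_drop > 0, rmsea_increase > 0, olkin_z > 0)
  structure(
    list(alpha = alpha, cfi_drop = cfi_drop,
         rmsea_increase = rmsea_increase, olkin_z = olkin_z,
         omega_h_min = omega_h_min, omega_hs_min = omega_hs_min,
         reference_subscale = reference_subscale, seed = as.integer(seed)),
    class = "validation_config"
  )
}

#' Simulate a complete synthetic validation study
#'
#' Generates a multigroup PHQ-9-shaped dataset (gender-like two-group
#' structure by default, optionally with planted violations), writes the
#' responses as CSV together with a JSON manifest of the scenario, and
#' returns the data invisibly.
#'
#' @param out_dir Output directory (created if missing); `NULL` skips
#'   writing.
#' @param seed Root seed.
#' @param n_per_group Named or unnamed vector of group sizes.
#' @param violations List of [violation_spec()] objects.
#' @param missing_rate MCAR cell probability.
#' @return The simulated [item_response_matrix()] (invisibly when
#'   writing).
#' @export
simulate_study <- function(out_dir = NULL, seed = 1L,
                           n_per_group = c(female = 600, male = 600),
                           violations = list(), missing_rate = 0.01) {
  labels <- names(n_per_group) %||% paste0("g", seq_along(n_per_group))
  pop <- phq9_population(missing_rate = missing_rate)
  scen <- make_invariance_scenario(pop, violations, labels,
                                   unname(n_per_group))
  dat <- simulate_scenario(scen, seed = seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_responses(dat, file.path(out_dir, "responses.csv"))
    manifest <- list(
      seed = as.integer(seed),
      groups = lapply(seq_along(labels), function(k) {
        list(label = labels[k], n = unname(n_per_group[k]),
             child_seed = (as.integer(seed) + 7919L * k) %%
               .Machine$integer.max)
      }),
      planted_violations = if (nrow(scen$manifest)) scen$manifest else
        list()
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(dat))
  }
  dat
}

#' Run the full validation pipeline on one scale
#'
#' Executes the stages of a psychometric validation in order: missing
#' data summary and complete-case filtering, competing-model comparison,
#' bifactor-(S-1) reliability, Haberman subscore analysis, the
#' measurement-invariance ladder per grouping, and unit-weighted versus
#' latent-mean effect sizes.
#'
#' @param data An [item_response_matrix()].
#' @param scale_def A [scale_definition()].
#' @param groupings Character vector of grouping columns for invariance
#'   and effect sizes (may be empty).
#' @param config A [validation_config()].
#' @return A `validation_result` list with sections `missing`,
#'   `model_comparison`, `reliability`, `subscores`, `invariance` (one
#'   `ladder_result` per grouping), `effects`, and `meta`.
#' @export
validate_scale <- function(data, scale_def, groupings = character(0),
                           config = validation_config()) {
  stopifnot(inherits(data, "item_response_matrix"),
            inherits(scale_def, "scale_definition"))
  if (nrow(data$values) == 0L) stop("empty dataset")
  miss <- missing_report(data, scale_def$items)
  datc <- complete_cases(data, scale_def$items)

  catalog <- model_catalog(scale_def)
  fits <- lapply(catalog, function(sp) fit_cfa(datc, sp))
  comparison <- model_fit_table(fits)

  bf <- fits$bifactor_s_minus_1
  rel <- omega_indices(bf, scale_def,
                       omega_h_min = config$omega_h_min,
                       omega_hs_min = config$omega_hs_min)
  subsc <- subscore_report(datc, scale_def, z_threshold = config$olkin_z)

  invariance <- list()
  base_spec <- catalog$two_factor_correlated
  for (g in groupings) {
    invariance[[g]] <- run_ladder(
      datc, base_spec, g,
      alpha = config$alpha, cfi_drop = config$cfi_drop,
      rmsea_increase = config$rmsea_increase)
  }

  effects <- if (length(groupings)) {
    effect_comparison(datc, scale_def, groupings)
  } else {
    NULL
  }

  structure(
    list(missing = miss, model_comparison = comparison,
         reliability = rel, subscores = subsc,
         invariance = invariance, effects = effects,
         meta = list(scale = scale_def$name,
                     n_input = nrow(data$values),
                     n_complete = nrow(datc$values),
                     config = unclass(config),
                     scaling = "mean-scaled (Yuan-Bentler-type) statistics",
                     timestamp = NULL)),
    class = "validation_result"
  )
}

#' @export
print.validation_result <- function(x, ...) {
  cat(render_report(x))
  invisible(x)
}

#' Serialize a validation result to JSON
#'
#' Every number later rendered in text reports is traceable to a field
#' of this JSON document; the renderer performs no recomputation.
#'
#' @param result A `validation_result`.
#' @param path Optional output path; when `NULL` the JSON string is
#'   returned.
#' @return JSON string (invisibly when writing to `path`).
#' @export
validation_json <- function(result, path = NULL) {
  stopifnot(inherits(result, "validation_result"))
  obj <- list(
    meta = result$meta,
    missing = unclass(result$missing),
    model_comparison = result$model_comparison,
    reliability = list(omega_t = result$reliability$omega_t,
                       omega_h = result$reliability$omega_h,
                       omega_hs = as.list(result$reliability$omega_hs),
                       flags = result$reliability$flags),
    subscores = as.data.frame(unclass(result$subscores)),
    invariance = lapply(result$invariance, function(l) {
      list(attained = l$attained,
           factor_variance_invariant = l$factor_variance_invariant,
           table = as.data.frame(l))
    }),
    effects = if (is.null(result$effects)) NULL else
      as.data.frame(unclass(result$effects))
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

fmt_num <- function(x, d = 3) {
  ifelse(is.na(x), "-", formatC(x, digits = d, format = "f"))
}

#' Render a validation result as a markdown report
#'
#' Produces a deterministic human-readable summary with the five
#' standard sections (factor structure, subscores, reliability,
#' invariance, group differences); absent sections are marked as such.
#'
#' @param result A `validation_result`.
#' @return A single markdown string.
#' @export
render_report <- function(result) {
  stopifnot(inherits(result, "validation_result"))
  out <- character(0)
  add <- function(...) out <<- c(out, paste0(...))
  add("# Validation report: ", result$meta$scale, "\n")
  add(sprintf("Subjects: %d (%d complete cases)\n",
              result$meta$n_input, result$meta$n_complete))
  add(sprintf("Missing cells: %.2f%% across %d pattern(s)",
              100 * result$missing$overall, result$missing$n_patterns))
  if (!is.na(result$missing$little$d2)) {
    add(sprintf("; Little's MCAR test d2 = %.2f (df %d, p = %.3f)",
                result$missing$little$d2, result$missing$little$df,
                result$missing$little$p))
  }
  add("\n\n## Factor structure\n")
  mc <- result$model_comparison
  add(paste(utils::capture.output(print(mc, digits = 3, row.names = FALSE)),
            collapse = "\n"), "\n")
  add("\n## Subscore value added (Haberman)\n")
  sc <- as.data.frame(unclass(result$subscores))
  add(paste(utils::capture.output(print(sc, digits = 3, row.names = FALSE)),
            collapse = "\n"), "\n")
  add("\n## Model-based reliability (bifactor-(S-1))\n")
  rel <- result$reliability
  add(sprintf("omegaT = %.3f; omegaH = %.3f (minimum %.2f: %s)\n",
              rel$omega_t, rel$omega_h, rel$thresholds["omega_h_min"],
              if (rel$flags$omega_h_ok) "met" else "not met"))
  for (s in names(rel$omega_hs)) {
    add(sprintf("omegaHS[%s] = %.3f (minimum %.2f: %s)\n", s,
                rel$omega_hs[s], rel$thresholds["omega_hs_min"],
                if (rel$flags$omega_hs_ok[s]) "met" else "not met"))
  }
  add("\n## Measurement invariance\n")
  if (length(result$invariance) == 0L) {
    add("section absent: no groupings requested\n")
  } else {
    for (g in names(result$invariance)) {
      l <- result$invariance[[g]]
      add(sprintf("\n### Grouping: %s (attained: %s%s)\n", g, l$attained,
                  if (isTRUE(l$factor_variance_invariant))
                    "; factor variances invariant"
                  else if (isFALSE(l$factor_variance_invariant))
                    "; factor variances non-invariant" else ""))
      add(paste(utils::capture.output(
        print(as.data.frame(l), digits = 3, row.names = FALSE)),
        collapse = "\n"), "\n")
    }
  }
  add("\n## Group differences\n")
  if (is.null(result$effects)) {
    add("section absent: no groupings requested\n")
  } else {
    ef <- as.data.frame(unclass(result$effects))
    add(paste(utils::capture.output(print(ef, digits = 3,
                                          row.names = FALSE)),
              collapse = "\n"), "\n")
  }
  paste(out, collapse = "")
}
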