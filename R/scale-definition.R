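#' Define a scale and its subscale partition
#'
#' A scale definition names the ordered item identifiers of a questionnaire
#' and partitions them into named subscales (for the scales handled here,
#' typically a somatic and a cognitive/affective facet).  The partition must
#' be disjoint and exhaustive; subscales with fewer than two items are
#' allowed but flagged as degenerate since they cannot support a group
#' factor.
#'
#' @param name Scale name, e.g. `"PHQ-9"`.
#' @param items Character vector of ordered, unique item identifiers.
#' @param subscales Named list of character vectors partitioning `items`.
#' @return An object of class `scale_definition`.
#' @examples
#' phq9_scale()
#' scale_definition("TOY", paste0("i", 1:4),
#'                  list(a = c("i1", "i2"), b = c("i3", "i4")))
#' @export
scale_definition <- function(name, items, subscales) {
  stopifnot(is.character(name), length(name) == 1L)
  items <- as.character(items)
  if (anyDuplicated(items)) stop("item ids must be unique")
  if (!is.list(subscales) || is.null(names(subscales)) ||
      any(names(subscales) == "")) {
    stop("'subscales' must be a named list of item vectors")
  }
  all_sub <- unlist(subscales, use.names = FALSE)
  if (anyDuplicated(all_sub)) stop("subscales must be disjoint")
  if (!setequal(all_sub, items)) {
    stop("subscales must partition the item set exactly")
  }
  if (any(lengths(subscales) == 0L)) stop("empty subscale")
  degenerate <- names(subscales)[lengths(subscales) < 2L]
  structure(
    list(name = name, items = items,
         subscales = lapply(subscales, as.character),
         degenerate = degenerate),
    class = "scale_definition"
  )
}

#' @export
print.scale_definition <- function(x, ...) {
  cat(sprintf("<scale_definition> %s: %d items\n", x$name, length(x$items)))
  for (s in names(x$subscales)) {
    cat(sprintf("  %s: %s\n", s, paste(x$subscales[[s]], collapse = ", ")))
  }
  if (length(x$degenerate)) {
    cat("  degenerate subscales:", paste(x$degenerate, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Built-in PHQ-9 scale definition
#'
#' Nine depression items scored 0--3, partitioned into the somatic facet
#' (items 3, 4, 5: sleep, fatigue, appetite) and the cognitive/affective
#' facet (the remaining six items).
#'
#' @return A [scale_definition()].
#' @export
phq9_scale <- function() {
  items <- paste0("phq", 1:9)
  scale_definition(
    "PHQ-9", items,
    list(cognitive = items[c(1, 2, 6, 7, 8, 9)],
         somatic   = items[c(3, 4, 5)])
  )
}

#' Built-in GAD-7 scale definition
#'
#' Seven anxiety items scored 0--3, with the somatic facet on items 4, 5
#' and 6 and the cognitive/worry facet on the remainder.
#'
#' @return A [scale_definition()].
#' @export
gad7_scale <- function() {
  items <- paste0("gad", 1:7)
  scale_definition(
    "GAD-7", items,
    list(cognitive = items[c(1, 2, 3, 7)],
         somatic   = items[c(4, 5, 6)])
  )
}

#' Read or write scale definitions as structured config
#'
#' Scale definitions round-trip through YAML (or JSON via [jsonlite]) with
#' fields `name`, `items` and `subscales`.
#'
#' @param path File path.
#' @return `read_scale_definition()` returns a [scale_definition()];
#'   `write_scale_definition()` returns `path` invisibly.
#' @export
read_scale_definition <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$name) || is.null(cfg$items) || is.null(cfg$subscales)) {
    stop("config must contain fields 'name', 'items', 'subscales'")
  }
  scale_definition(cfg$name, unlist(cfg$items), cfg$subscales)
}

#' @rdname read_scale_definition
#' @param x A `scale_definition`.
#' @export
write_scale_definition <- function(x, path) {
  stopifnot(inherits(x, "scale_definition"))
  yaml::write_yaml(list(name = x$name, items = x$items,
                        subscales = x$subscales), path)
  invisible(path)
}
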