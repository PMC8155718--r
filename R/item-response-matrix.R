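#' Construct an item response matrix
#'
#' The universal input container of the package: an n_subjects x n_items
#' matrix of integer Likert codes (default range 0--3) with optional
#' missing cells, plus per-subject categorical grouping labels.
#'
#' @param values Numeric matrix (or data frame) of item codes; `NA` marks a
#'   missing response.
#' @param item_ids Ordered unique item identifiers (defaults to column
#'   names).
#' @param subject_ids Ordered unique subject identifiers (defaults to row
#'   names or `s1..sn`).
#' @param grouping Optional data frame of per-subject categorical labels
#'   (one row per subject, no missing labels).
#' @param code_range Vector `c(min, max)` of admissible codes; an
#'   infinite bound disables the integer-code check, allowing continuous
#'   responses (as produced by the simulator with discretization off).
#' @return An object of class `item_response_matrix`.
#' @export
item_response_matrix <- function(values, item_ids = colnames(values),
                                 subject_ids = rownames(values),
                                 grouping = NULL,
                                 code_range = c(0L, 3L)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(item_ids)) {
    item_ids <- sprintf("item%d", seq_len(ncol(values)))
  }
  if (is.null(subject_ids)) {
    subject_ids <- sprintf("s%d", seq_len(nrow(values)))
  }
  item_ids <- as.character(item_ids)
  subject_ids <- as.character(subject_ids)
  if (anyDuplicated(item_ids)) stop("item ids must be unique")
  if (anyDuplicated(subject_ids)) stop("subject ids must be unique")
  if (length(item_ids) != ncol(values)) stop("item_ids/value dimension mismatch")
  if (length(subject_ids) != nrow(values)) {
    stop("subject_ids/value dimension mismatch")
  }
  integer_codes <- all(is.finite(code_range))
  bad <- which(!is.na(values) &
                 (values < code_range[1] | values > code_range[2] |
                    (integer_codes & values != round(values))),
               arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "out-of-range code %s at subject '%s', item '%s'",
      format(values[bad[1, , drop = FALSE]]),
      subject_ids[bad[1, 1]], item_ids[bad[1, 2]]
    ))
  }
  if (!is.null(grouping)) {
    grouping <- as.data.frame(grouping, stringsAsFactors = FALSE)
    if (nrow(grouping) != nrow(values)) {
      stop("grouping must have one row per subject")
    }
    for (g in names(grouping)) {
      if (anyNA(grouping[[g]])) stop("grouping column '", g, "' has missing labels")
      grouping[[g]] <- as.character(grouping[[g]])
    }
  }
  dimnames(values) <- list(subject_ids, item_ids)
  structure(
    list(values = values, item_ids = item_ids, subject_ids = subject_ids,
         grouping = grouping, code_range = code_range),
    class = "item_response_matrix"
  )
}

#' @export
print.item_response_matrix <- function(x, ...) {
  miss <- mean(is.na(x$values))
  cat(sprintf("<item_response_matrix> %d subjects x %d items, %.1f%% missing\n",
              nrow(x$values), ncol(x$values), 100 * miss))
  if (!is.null(x$grouping)) {
    cat("  grouping:", paste(names(x$grouping), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.item_response_matrix <- function(x) dim(x$values)

#' Read item responses from a delimited text file
#'
#' Parses a CSV (or TSV, auto-detected from the header line) with one row
#' per subject.  All item ids of `scale_def` must appear as columns; any
#' further columns are treated as grouping labels.  Cells matching
#' `missing_codes` become missing.
#'
#' @param path File path to a delimited text file with a header row.
#' @param scale_def A [scale_definition()]; item columns are reordered to
#'   follow it.
#' @param missing_codes Character values to read as missing.
#' @param grouping_cols Optional character vector restricting which
#'   non-item columns are kept as grouping labels (default: all).
#' @inheritParams item_response_matrix
#' @return An [item_response_matrix()].
#' @export
read_responses <- function(path, scale_def, missing_codes = c("", "NA"),
                           grouping_cols = NULL, code_range = c(0L, 3L)) {
  stopifnot(inherits(scale_def, "scale_definition"))
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          na.strings = missing_codes,
                          colClasses = "character",
                          check.names = FALSE, stringsAsFactors = FALSE)
  missing_items <- setdiff(scale_def$items, names(df))
  if (length(missing_items)) {
    stop("missing item column(s): ", paste(missing_items, collapse = ", "))
  }
  vals <- sapply(scale_def$items, function(it) {
    v <- df[[it]]
    out <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(out))
    if (length(bad)) {
      stop(sprintf("non-numeric code '%s' at row %d, item '%s'",
                   v[bad[1]], bad[1], it))
    }
    out
  })
  vals <- matrix(vals, nrow = nrow(df),
                 dimnames = list(NULL, scale_def$items))
  extra <- setdiff(names(df), scale_def$items)
  if (!is.null(grouping_cols)) {
    unknown <- setdiff(grouping_cols, extra)
    if (length(unknown)) {
      stop("grouping column(s) not in file: ", paste(unknown, collapse = ", "))
    }
    extra <- grouping_cols
  }
  grouping <- if (length(extra)) df[extra] else NULL
  subj <- if ("subject_id" %in% extra) df[["subject_id"]] else NULL
  if (!is.null(subj) && !anyDuplicated(subj)) {
    grouping <- grouping[setdiff(extra, "subject_id")]
    if (ncol(grouping) == 0L) grouping <- NULL
  } else {
    subj <- NULL
  }
  item_response_matrix(vals, item_ids = scale_def$items,
                       subject_ids = subj, grouping = grouping,
                       code_range = code_range)
}

#' Write item responses to CSV
#'
#' Inverse of [read_responses()]: writes `subject_id`, grouping columns and
#' one column per item, with empty cells for missing responses.
#'
#' @param x An [item_response_matrix()].
#' @param path Output path.
#' @export
write_responses <- function(x, path) {
  stopifnot(inherits(x, "item_response_matrix"))
  df <- data.frame(subject_id = x$subject_ids, stringsAsFactors = FALSE)
  if (!is.null(x$grouping)) df <- cbind(df, x$grouping)
  df <- cbind(df, as.data.frame(x$values))
  utils::write.table(df, path, sep = ",", na = "", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Unit-weighted (sum) scores
#'
#' The plain sum of a subject's item codes over a set of items.  Following
#' the complete-case convention, the score is missing whenever any selected
#' item is missing; no proration is applied.
#'
#' @param x An [item_response_matrix()].
#' @param items Item subset (default: all items).
#' @return Numeric vector of per-subject scores (with `NA` where any item
#'   is missing), named by subject id.
#' @export
unit_weighted_score <- function(x, items = x$item_ids) {
  stopifnot(inherits(x, "item_response_matrix"))
  if (length(items) == 0L) stop("empty item set")
  unknown <- setdiff(items, x$item_ids)
  if (length(unknown)) stop("unknown item(s): ", paste(unknown, collapse = ", "))
  rowSums(x$values[, items, drop = FALSE])
}

#' Retain complete cases on a set of items
#'
#' Drops every subject with at least one missing value among `items`;
#' grouping labels are carried along.
#'
#' @inheritParams unit_weighted_score
#' @return An [item_response_matrix()] containing the surviving subjects.
#' @export
complete_cases <- function(x, items = x$item_ids) {
  stopifnot(inherits(x, "item_response_matrix"))
  unknown <- setdiff(items, x$item_ids)
  if (length(unknown)) stop("unknown item(s): ", paste(unknown, collapse = ", "))
  keep <- !apply(is.na(x$values[, items, drop = FALSE]), 1L, any)
  if (!any(keep)) stop("no complete cases remain")
  item_response_matrix(
    x$values[keep, , drop = FALSE],
    item_ids = x$item_ids,
    subject_ids = x$subject_ids[keep],
    grouping = if (is.null(x$grouping)) NULL else
      x$grouping[keep, , drop = FALSE],
    code_range = x$code_range
  )
}

#' Split an item response matrix by a grouping column
#'
#' @param x An [item_response_matrix()].
#' @param grouping Name of a grouping column.
#' @return Named list of `item_response_matrix` objects, one per level, in
#'   order of first appearance (the first level acts as reference group
#'   downstream).
#' @export
split_by_group <- function(x, grouping) {
  stopifnot(inherits(x, "item_response_matrix"))
  if (is.null(x$grouping) || !grouping %in% names(x$grouping)) {
    stop("unknown grouping column '", grouping, "'")
  }
  labels <- x$grouping[[grouping]]
  lv <- unique(labels)
  out <- lapply(lv, function(l) {
    keep <- labels == l
    item_response_matrix(
      x$values[keep, , drop = FALSE], item_ids = x$item_ids,
      subject_ids = x$subject_ids[keep],
      grouping = x$grouping[keep, , drop = FALSE],
      code_range = x$code_range
    )
  })
  names(out) <- lv
  out
}
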