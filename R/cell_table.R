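#' Construct an annotated cell table
#'
#' The central data container: one row per segmented cell, with planar
#' coordinates, a region identifier, a cell-type label, one or more discrete
#' hierarchical organization labels (e.g. cellular neighborhood, community,
#' tissue unit), and optional context columns (disease state, patient, ...).
#' Coordinates are treated as already-registered planar positions in a shared
#' length unit per region; no unit conversion is attempted.
#'
#' @param df data.frame holding at least `cell_id`, `x`, `y`, `region_id`,
#'   `cell_type` plus one column per label level and context.
#' @param label_levels character vector of column names holding hierarchical
#'   organization labels.
#' @param contexts character vector of column names holding context labels
#'   (may be empty).
#' @return A `cell_table`: a data.frame with attributes `label_levels` and
#'   `contexts`.
#' @export
cell_table <- function(df, label_levels, contexts = character()) {
  req <- c("cell_id", "x", "y", "region_id", "cell_type")
  missing_cols <- setdiff(c(req, label_levels, contexts), names(df))
  if (length(missing_cols) > 0L) {
    stop("cell_table: missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!is.finite(df$x) | !is.finite(df$y))
  if (length(bad) > 0L) {
    stop("cell_table: non-finite coordinate at row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  df$cell_id <- as.character(df$cell_id)
  if (anyDuplicated(df$cell_id)) {
    stop("cell_table: duplicated cell_id values", call. = FALSE)
  }
  for (col in c("region_id", "cell_type", label_levels, contexts)) {
    df[[col]] <- normalize_label(df[[col]])
  }
  structure(
    as.data.frame(df, stringsAsFactors = FALSE),
    label_levels = label_levels,
    contexts = contexts,
    class = c("cell_table", "data.frame")
  )
}

# Categorical normalization: integer-coded labels are stringified, whitespace
# trimmed, case preserved.
normalize_label <- function(v) {
  if (is.factor(v)) v <- as.character(v)
  if (is.numeric(v)) v <- as.character(v)
  trimws(as.character(v))
}

#' @export
print.cell_table <- function(x, ...) {
  cat(sprintf("<cell_table> %d cells, %d region(s), %d cell type(s)\n",
              nrow(x), length(unique(x$region_id)),
              length(unique(x$cell_type))))
  cat("  label levels:", paste(label_levels(x), collapse = ", "), "\n")
  if (length(context_cols(x)) > 0L)
    cat("  contexts:", paste(context_cols(x), collapse = ", "), "\n")
  invisible(x)
}

#' Label-level and context column names of a cell table
#' @param table a `cell_table`
#' @return character vector of column names
#' @export
label_levels <- function(table) attr(table, "label_levels")

#' @rdname label_levels
#' @export
context_cols <- function(table) attr(table, "contexts")

#' Read a per-cell table from delimited text
#'
#' Loads a CSV/TSV of per-cell annotations into a [cell_table()]. A `schema`
#' maps the file's column names onto the canonical roles; file columns named
#' in the schema are renamed, everything the schema does not mention is
#' ignored. Cells missing a label at a requested level are dropped with a
#' message (annotation in deposited tables is not always total).
#'
#' @param path path to a delimited text file; the delimiter is inferred from
#'   the extension (`.tsv`/`.txt` = tab, otherwise comma).
#' @param schema named list/vector mapping canonical names (`cell_id`, `x`,
#'   `y`, `region_id`, `cell_type`, plus level and context names) to file
#'   column names. Canonical columns already present in the file need not be
#'   listed. A missing `cell_id` entry autogenerates sequential ids.
#' @param label_levels character: which (canonical) columns are hierarchical
#'   label levels. Default `"neighborhood"` if present.
#' @param contexts character: canonical context column names present.
#' @return a [cell_table()]
#' @export
load_cell_table <- function(path, schema = list(), label_levels = NULL,
                            contexts = character()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "", quote = "\"")
  schema <- unlist(schema)
  for (canonical in names(schema)) {
    src <- schema[[canonical]]
    if (!src %in% names(raw)) {
      stop("schema error: column '", src, "' (for '", canonical,
           "') not found in ", path, call. = FALSE)
    }
    names(raw)[names(raw) == src] <- canonical
  }
  if (!"cell_id" %in% names(raw)) raw$cell_id <- sprintf("cell_%06d", seq_len(nrow(raw)))
  for (col in c("x", "y")) {
    if (!col %in% names(raw)) {
      stop("schema error: required column '", col, "' missing", call. = FALSE)
    }
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]))
    if (length(bad) > 0L) {
      stop("parse error: non-numeric ", col, " at row ", bad[1L], call. = FALSE)
    }
    raw[[col]] <- v
  }
  for (col in c("region_id", "cell_type")) {
    if (!col %in% names(raw)) {
      stop("schema error: required column '", col, "' missing", call. = FALSE)
    }
  }
  if (is.null(label_levels)) {
    label_levels <- intersect(c("neighborhood", "community", "tissue_unit"),
                              names(raw))
    if (length(label_levels) == 0L) {
      stop("schema error: no hierarchical label level column found; ",
           "map one via `schema` or name it in `label_levels`", call. = FALSE)
    }
  }
  miss <- setdiff(label_levels, names(raw))
  if (length(miss) > 0L) {
    stop("schema error: label level column(s) missing: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  # drop-and-log cells unannotated at a requested level
  keep <- rep(TRUE, nrow(raw))
  for (lv in label_levels) {
    v <- raw[[lv]]
    keep <- keep & !is.na(v) & trimws(as.character(v)) != ""
  }
  if (any(!keep)) {
    message(sum(!keep), " cell(s) dropped: missing label at a requested level")
    raw <- raw[keep, , drop = FALSE]
  }
  cell_table(raw, label_levels = label_levels, contexts = contexts)
}

#' Write a cell table back to delimited text
#'
#' Inverse of [load_cell_table()]: a load-write-load round trip preserves the
#' cell count, labels and coordinates.
#'
#' @param table a [cell_table()]
#' @param path output path; `.tsv` writes tab-separated, anything else comma.
#' @return `path`, invisibly
#' @export
write_cell_table <- function(table, path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(as.data.frame(table), path, sep = sep, row.names = FALSE,
                     quote = TRUE)
  invisible(path)
}

#' Validate a cell table
#'
#' Pure structural checks: duplicate ids, missing labels at required levels,
#' regions too small for a requested window size (warning), and degenerate
#' coordinates (all cells of a region co-located). All findings go into the
#' report; nothing throws.
#'
#' @param table a [cell_table()]
#' @param required_levels label levels that must be fully annotated.
#' @param k_min minimum region size for downstream window construction;
#'   smaller regions trigger a warning-severity issue.
#' @return a `validation_report`: list with `n_cells`, `n_regions`,
#'   `labels_per_level` and an `issues` data.frame (`severity`, `message`).
#'   `issues` has zero rows iff the table passes every check.
#' @export
validate_cells <- function(table, required_levels = label_levels(table),
                           k_min = 10L) {
  issues <- list()
  add <- function(severity, message) {
    issues[[length(issues) + 1L]] <<- data.frame(severity = severity,
                                                 message = message)
  }
  dup <- unique(table$cell_id[duplicated(table$cell_id)])
  if (length(dup) > 0L) {
    add("error", paste0("duplicated cell_id: ",
                        paste(utils::head(dup, 5L), collapse = ", ")))
  }
  if (any(!is.finite(table$x) | !is.finite(table$y))) {
    add("error", "non-finite coordinates present")
  }
  for (lv in required_levels) {
    if (!lv %in% names(table)) {
      add("error", paste0("label level '", lv, "' absent"))
      next
    }
    n_missing <- sum(is.na(table[[lv]]) | table[[lv]] == "")
    if (n_missing > 0L) {
      add("error", paste0(n_missing, " cell(s) missing label at level '", lv, "'"))
    }
  }
  reg_n <- table(table$region_id)
  small <- names(reg_n)[reg_n < k_min + 1L]
  for (r in small) {
    add("warning", paste0("region '", r, "' has ", reg_n[[r]],
                          " cells; fewer than k_min + 1 = ", k_min + 1L,
                          " needed for k = ", k_min, " windows"))
  }
  for (r in names(reg_n)) {
    sub <- table[table$region_id == r, c("x", "y")]
    if (nrow(sub) > 1L && length(unique(sub$x)) == 1L &&
        length(unique(sub$y)) == 1L) {
      add("warning", paste0("region '", r, "' has degenerate coordinates ",
                            "(all cells co-located)"))
    }
  }
  issues_df <- if (length(issues) > 0L) {
    do.call(rbind, issues)
  } else {
    data.frame(severity = character(), message = character())
  }
  lv <- label_levels(table)
  structure(list(
    n_cells = nrow(table),
    n_regions = length(reg_n),
    labels_per_level = vapply(lv, function(l) length(unique(table[[l]])),
                              integer(1)),
    issues = issues_df
  ), class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> %d cells, %d regions\n",
              x$n_cells, x$n_regions))
  if (nrow(x$issues) == 0L) {
    cat("  no issues\n")
  } else {
    for (i in seq_len(nrow(x$issues))) {
      cat(sprintf("  [%s] %s\n", x$issues$severity[i], x$issues$message[i]))
    }
  }
  invisible(x)
}
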