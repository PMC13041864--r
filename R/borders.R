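#' Classify border cells from thresholded multi-membership
#'
#' A cell is positive for a unit when its membership probability is at or
#' above `threshold` (inclusive comparison; switchable). The positive count
#' \eqn{C_i} is the number of positive units; cells with \eqn{C_i > 1} are
#' border cells. For every border cell each unordered pair of co-positive
#' units is recorded for network construction.
#'
#' @param M a `membership_matrix`
#' @param threshold positive-membership probability threshold in (0, 1];
#'   default 0.25.
#' @param inclusive use `>=` (default) rather than `>` for positivity.
#' @return a `border_set`: list with `threshold`, `positive` (cells x units
#'   logical), `C` (per-cell positive count), `is_border`,
#'   `positive_units` (list of unit-name vectors) and `pair_records`
#'   (data.frame `cell`, `unit_a`, `unit_b`; `C(C-1)/2` rows per border
#'   cell).
#' @export
classify_borders <- function(M, threshold = 0.25, inclusive = TRUE) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 1) {
    stop("threshold must lie in (0, 1]", call. = FALSE)
  }
  pos <- if (inclusive) M$prob >= threshold else M$prob > threshold
  C <- rowSums(pos)
  is_border <- C > 1L
  cells <- M$cells
  if (is.null(cells)) cells <- as.character(seq_len(nrow(M$prob)))
  positive_units <- apply(pos, 1L, function(p) M$units[p], simplify = FALSE)
  names(positive_units) <- cells
  recs <- lapply(which(is_border), function(i) {
    u <- M$units[pos[i, ]]
    pr <- utils::combn(u, 2L)
    data.frame(cell = cells[i], unit_a = pr[1L, ], unit_b = pr[2L, ])
  })
  pair_records <- if (length(recs) > 0L) {
    do.call(rbind, recs)
  } else {
    data.frame(cell = character(), unit_a = character(), unit_b = character())
  }
  structure(list(
    threshold = threshold,
    units = M$units,
    cells = cells,
    positive = pos,
    C = as.integer(C),
    is_border = is_border,
    positive_units = positive_units,
    pair_records = pair_records
  ), class = "border_set")
}

#' @export
print.border_set <- function(x, ...) {
  cat(sprintf("<border_set> threshold %.3g: %d / %d cells are border cells\n",
              x$threshold, sum(x$is_border), length(x$C)))
  invisible(x)
}

#' Border robustness across probability thresholds
#'
#' Re-runs border classification at each threshold and records the border
#' count and fraction, plus (when a table is supplied) the cell-type
#' composition of the border population. With inclusive positivity the
#' positive sets shrink as the threshold rises, so the border fraction is
#' non-increasing; this is asserted.
#'
#' @param M a `membership_matrix`
#' @param thresholds ascending thresholds within (0, 1]
#' @param table optional [cell_table()] aligned to `M` for compositions
#' @return a `threshold_sweep`: list with `summary` (data.frame `threshold`,
#'   `n_border`, `border_fraction`) and `composition` (thresholds x cell
#'   types proportion matrix, or NULL).
#' @export
threshold_sweep <- function(M, thresholds = c(0.05, 0.1, 0.15, 0.2, 0.25),
                            table = NULL) {
  if (length(thresholds) == 0L) stop("empty threshold list", call. = FALSE)
  if (any(thresholds <= 0 | thresholds > 1)) {
    stop("thresholds must lie in (0, 1]", call. = FALSE)
  }
  thresholds <- sort(thresholds)
  n <- nrow(M$prob)
  n_border <- integer(length(thresholds))
  comp <- NULL
  if (!is.null(table)) {
    types <- sort(unique(table$cell_type))
    comp <- matrix(NA_real_, length(thresholds), length(types),
                   dimnames = list(format(thresholds), types))
  }
  for (j in seq_along(thresholds)) {
    b <- classify_borders(M, thresholds[j])
    n_border[j] <- sum(b$is_border)
    if (!is.null(comp) && n_border[j] > 0L) {
      tb <- base::table(factor(table$cell_type[b$is_border], levels = types))
      comp[j, ] <- as.numeric(tb) / sum(tb)
    }
  }
  frac <- n_border / n
  stopifnot("border fraction must be non-increasing in threshold" =
              all(diff(frac) <= 1e-12))
  structure(list(
    summary = data.frame(threshold = thresholds, n_border = n_border,
                         border_fraction = frac),
    composition = comp
  ), class = "threshold_sweep")
}

#' Interface cell-type enrichment for a unit pair
#'
#' Compares the cell-type composition of cells positive for both units of a
#' pair (the border group) against cells positive for exactly one
#' (single-unit groups):
#' \deqn{E_t(\mathrm{A}) = \log_2 \frac{p_{t,\mathrm{border}}}{p_{t,\mathrm{A\ only}}}}
#' and symmetrically for B. A pseudocount is added to both proportions so
#' types absent from a group stay finite (flagged). A type is
#' interface-enriched when both enrichment values are positive.
#'
#' @param borders a `border_set`
#' @param table the [cell_table()] aligned to the border set
#' @param unit_pair character vector of two unit names
#' @param pseudocount small positive value added to both proportions
#' @return a `border_enrichment` list with `status` (`"ok"` or `"empty"`) and,
#'   when ok, `enrichment`: data.frame with per-type proportions,
#'   `E_a`, `E_b`, `interface_enriched`, and absent-in-denominator flags.
#' @export
border_enrichment <- function(borders, table, unit_pair,
                              pseudocount = 1e-4) {
  stopifnot(length(unit_pair) == 2L)
  miss <- setdiff(unit_pair, borders$units)
  if (length(miss) > 0L) {
    stop("unknown unit(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  a <- unit_pair[1L]; b <- unit_pair[2L]
  pos <- borders$positive
  in_border <- pos[, a] & pos[, b]
  only_a <- pos[, a] & borders$C == 1L
  only_b <- pos[, b] & borders$C == 1L
  if (!any(in_border)) {
    return(structure(list(status = "empty", pair = unit_pair,
                          enrichment = NULL),
                     class = "border_enrichment"))
  }
  types <- sort(unique(table$cell_type))
  prop <- function(sel) {
    if (!any(sel)) return(stats::setNames(rep(0, length(types)), types))
    tb <- base::table(factor(table$cell_type[sel], levels = types))
    as.numeric(tb) / sum(tb)
  }
  p_border <- prop(in_border)
  p_a <- prop(only_a)
  p_b <- prop(only_b)
  E_a <- log2((p_border + pseudocount) / (p_a + pseudocount))
  E_b <- log2((p_border + pseudocount) / (p_b + pseudocount))
  structure(list(
    status = "ok",
    pair = unit_pair,
    n_border = sum(in_border),
    n_only = c(sum(only_a), sum(only_b)),
    enrichment = data.frame(
      cell_type = types,
      p_border = p_border,
      p_only_a = p_a,
      p_only_b = p_b,
      E_a = E_a,
      E_b = E_b,
      interface_enriched = E_a > 0 & E_b > 0,
      absent_only_a = p_a == 0,
      absent_only_b = p_b == 0
    )
  ), class = "border_enrichment")
}

#' Organization-unit interaction graph from co-membership
#'
#' Nodes are organization units; an edge connects two units whenever border
#' cells are co-positive for both. The count weight is the number of such
#' cells. The geometric-mean weight combines the two directional conditional
#' co-occurrence probabilities, computed among border cells:
#' \deqn{w_{AB} = \sqrt{P(B \mid A)\, P(A \mid B)}}
#' with \eqn{P(B \mid A)} the fraction of border cells positive for A that
#' are also positive for B. The weight is symmetric by construction.
#'
#' @param borders a `border_set`
#' @return an `interaction_graph`: list with `nodes` and `edges`
#'   (data.frame `node_a`, `node_b`, `count_weight`, `geomean_weight`).
#' @export
build_graph <- function(borders) {
  pr <- borders$pair_records
  if (nrow(pr) == 0L) {
    return(structure(list(nodes = borders$units,
                          edges = data.frame(node_a = character(),
                                             node_b = character(),
                                             count_weight = integer(),
                                             geomean_weight = numeric())),
                     class = "interaction_graph"))
  }
  # canonical unordered pair by unit order
  ui <- match(pr$unit_a, borders$units)
  vi <- match(pr$unit_b, borders$units)
  a <- ifelse(ui <= vi, pr$unit_a, pr$unit_b)
  b <- ifelse(ui <= vi, pr$unit_b, pr$unit_a)
  key <- paste(a, b, sep = "\r")
  tab <- table(key)
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  node_a <- vapply(parts, `[`, character(1), 1L)
  node_b <- vapply(parts, `[`, character(1), 2L)
  # per-unit border-cell positivity counts (denominators of the conditionals)
  bpos <- borders$positive[borders$is_border, , drop = FALSE]
  n_pos <- colSums(bpos)
  cw <- as.integer(tab)
  p_b_given_a <- cw / n_pos[node_a]
  p_a_given_b <- cw / n_pos[node_b]
  edges <- data.frame(
    node_a = node_a,
    node_b = node_b,
    count_weight = cw,
    geomean_weight = sqrt(p_b_given_a * p_a_given_b)
  )
  edges <- edges[order(edges$node_a, edges$node_b), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = borders$units, edges = edges),
            class = "interaction_graph")
}

#' @export
print.interaction_graph <- function(x, ...) {
  cat(sprintf("<interaction_graph> %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Convert an interaction graph to an igraph object
#'
#' @param graph an `interaction_graph`
#' @param weight which weight becomes the igraph `weight` attribute
#' @return an undirected `igraph` graph
#' @export
as_igraph <- function(graph, weight = c("geomean", "count")) {
  if (!requireNamespace("igraph", quietly = TRUE)) {
    stop("as_igraph requires the 'igraph' package", call. = FALSE)
  }
  weight <- match.arg(weight)
  g <- igraph::graph_from_data_frame(graph$edges, directed = FALSE,
                                     vertices = data.frame(name = graph$nodes))
  igraph::E(g)$weight <- if (weight == "geomean") {
    graph$edges$geomean_weight
  } else {
    graph$edges$count_weight
  }
  g
}
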