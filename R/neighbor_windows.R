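# Exact k-nearest-neighbor search within one region, deterministic under
# distance ties. Returns an n x k integer matrix of indices into `coords`
# rows (NA-padded when fewer than k neighbors exist) plus the matching
# distances. Ties at rank k are resolved by ascending `order_key` (the rank
# of a cell's id), so window membership never depends on input order.
region_knn <- function(coords, k, order_key, max_radius = Inf) {
  n <- nrow(coords)
  if (n < 2L) stop("kNN search needs >= 2 cells", call. = FALSE)
  k_eff <- min(k, n - 1L)
  k_query <- min(k_eff + 1L, n - 1L)
  res <- BiocNeighbors::findKNN(coords, k = k_query, get.index = TRUE,
                                get.distance = TRUE, warn.ties = FALSE)
  idx <- res$index[, seq_len(k_eff), drop = FALSE]
  dst <- res$distance[, seq_len(k_eff), drop = FALSE]
  if (k_query > k_eff) {
    # a tie across the rank-k boundary makes the returned set arbitrary;
    # re-resolve those rows exhaustively with the deterministic key
    d_k  <- res$distance[, k_eff]
    d_k1 <- res$distance[, k_eff + 1L]
    tol <- 1e-9 * (1 + abs(d_k))
    tied <- which(d_k1 - d_k <= tol)
    for (i in tied) {
      d_all <- sqrt((coords[, 1L] - coords[i, 1L])^2 +
                    (coords[, 2L] - coords[i, 2L])^2)
      ord <- order(d_all, order_key)
      ord <- ord[ord != i][seq_len(k_eff)]
      idx[i, ] <- ord
      dst[i, ] <- d_all[ord]
    }
  }
  if (is.finite(max_radius)) {
    drop <- dst > max_radius
    idx[drop] <- NA_integer_
    dst[drop] <- NA_real_
  }
  list(index = idx, distance = dst)
}

#' k-nearest-neighbor composition windows
#'
#' For every cell, finds its `k` nearest neighbors by Euclidean distance
#' within the same region (the index cell is excluded) and counts the
#' occurrences of each label at `count_level` among them. The resulting
#' counts are the compositional features the membership model is fit on:
#' cell-type counts at the neighborhood scale (k = 10), neighborhood-label
#' counts at the community scale (k = 100), community-label counts at the
#' tissue-unit scale (k = 300).
#'
#' Distance ties at rank `k` are broken by ascending `cell_id`, so windows
#' are deterministic and independent of row order. Cells with fewer than `k`
#' in-radius neighbors keep their reduced-count row and are flagged in
#' `short_rows`; downstream normalization uses row sums, never `k`.
#'
#' @param table a [cell_table()]
#' @param k number of neighbors per window (positive integer)
#' @param count_level column whose labels are counted: `"cell_type"` or a
#'   label level of `table`.
#' @param max_radius exclude neighbors farther than this distance
#'   (default `Inf` = no radius cutoff).
#' @return a `feature_matrix`: list with `counts` (cells x labels integer
#'   matrix, rownames = cell ids), `cells`, `features`, `k`, `level`,
#'   `max_radius`, `short_rows` (logical).
#' @export
knn_window_features <- function(table, k, count_level = "cell_type",
                                max_radius = Inf) {
  if (!is.numeric(k) || length(k) != 1L || k <= 0 || k != round(k)) {
    stop("k must be a positive integer", call. = FALSE)
  }
  k <- as.integer(k)
  if (!count_level %in% names(table)) {
    stop("count_level '", count_level, "' is not a column of the table",
         call. = FALSE)
  }
  labels <- as.character(table[[count_level]])
  feats <- sort(unique(labels))
  lab_code <- match(labels, feats)
  n <- nrow(table)
  order_key <- xtfrm(table$cell_id)
  counts <- matrix(0L, n, length(feats), dimnames = list(table$cell_id, feats))
  for (r in unique(table$region_id)) {
    rows <- which(table$region_id == r)
    if (length(rows) < 2L) {
      stop("region '", r, "' has ", length(rows),
           " cell(s); >= 2 required for windows", call. = FALSE)
    }
    coords <- cbind(table$x[rows], table$y[rows])
    nn <- region_knn(coords, k, order_key[rows], max_radius)
    idx <- nn$index
    keep <- !is.na(idx)
    i_rep <- rep(seq_along(rows), ncol(idx))[keep]
    j_lab <- lab_code[rows[idx[keep]]]
    acc <- Matrix::sparseMatrix(i = i_rep, j = j_lab, x = 1,
                                dims = c(length(rows), length(feats)))
    counts[rows, ] <- counts[rows, , drop = FALSE] + as.matrix(acc)
  }
  storage.mode(counts) <- "integer"
  structure(list(
    counts = counts,
    cells = table$cell_id,
    features = feats,
    k = k,
    level = count_level,
    max_radius = max_radius,
    short_rows = rowSums(counts) < k
  ), class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d cells x %d features (level '%s', k = %d)\n",
              length(x$cells), length(x$features), x$level, x$k))
  if (any(x$short_rows))
    cat("  ", sum(x$short_rows), "row(s) with fewer than k neighbors\n")
  invisible(x)
}

#' Mean nearest-neighbor distance of a region
#'
#' The mean, over the region's cells, of each cell's distance to its single
#' nearest neighbor. This characteristic spacing (d_NN) normalizes local
#' gradient magnitudes to per-intercellular-step units.
#'
#' @param table a [cell_table()]
#' @param region_id region to measure; if `NULL`, all regions (named vector).
#' @return numeric length-1 (or named vector over regions)
#' @export
mean_nn_distance <- function(table, region_id = NULL) {
  regions <- unique(table$region_id)
  if (is.null(region_id)) {
    out <- vapply(regions, function(r) mean_nn_distance(table, r), numeric(1))
    names(out) <- regions
    return(out)
  }
  if (!region_id %in% regions) {
    stop("unknown region: ", region_id, call. = FALSE)
  }
  rows <- which(table$region_id == region_id)
  if (length(rows) < 2L) {
    stop("region '", region_id, "' has fewer than 2 cells", call. = FALSE)
  }
  coords <- cbind(table$x[rows], table$y[rows])
  res <- BiocNeighbors::findKNN(coords, k = 1L, get.index = FALSE,
                                get.distance = TRUE, warn.ties = FALSE)
  mean(res$distance[, 1L])
}
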