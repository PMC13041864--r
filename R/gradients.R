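#' Probability-weighted log-ratio score for a unit pair
#'
#' For two organization units CN1, CN2 the per-cell score is
#' \deqn{S_i = \log\frac{P_i(CN1)+\varepsilon}{P_i(CN2)+\varepsilon}\cdot
#'   \max(P_i(CN1), P_i(CN2))}
#' (natural log). Zero marks the mixed-state crossover; the sign gives the
#' direction of the transition and the max-probability factor weights it by
#' assignment confidence. Swapping the pair negates the score.
#'
#' @param M a `membership_matrix`
#' @param pair character vector of two unit names (CN1, CN2)
#' @param eps numerical floor inside the ratio (default `1e-9`)
#' @return per-cell numeric vector (named by cell id), for every cell in `M`
#' @export
log_ratio_score <- function(M, pair, eps = 1e-9) {
  stopifnot(length(pair) == 2L)
  miss <- setdiff(pair, M$units)
  if (length(miss) > 0L) {
    stop("unknown unit(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  p1 <- M$prob[, pair[1L]]
  p2 <- M$prob[, pair[2L]]
  s <- log((p1 + eps) / (p2 + eps)) * pmax(p1, p2)
  names(s) <- M$cells
  s
}

#' Equal-width score bins
#'
#' Partitions scores into `K` equal-width intervals
#' \eqn{e_j = S_{min} + (j/K)(S_{max} - S_{min})}, half-open
#' \eqn{[e_j, e_{j+1})} except the last, which is closed so the maximum
#' lands in the top bin. Bin widths are equal; bin occupancy need not be.
#'
#' @param scores numeric vector (NAs allowed; they stay unbinned)
#' @param K number of bins (>= 2; default 5)
#' @param restrict optional logical/index subset of cells to bin; others get
#'   `NA`.
#' @return list with `edges` (length K + 1) and `bin` (per-cell integer in
#'   1..K or NA)
#' @export
equal_width_bins <- function(scores, K = 5L, restrict = NULL) {
  if (K < 2L) stop("K must be >= 2", call. = FALSE)
  use <- !is.na(scores)
  if (!is.null(restrict)) {
    sel <- rep(FALSE, length(scores))
    sel[restrict] <- TRUE
    use <- use & sel
  }
  s <- scores[use]
  if (length(unique(s)) < 2L) {
    stop("degenerate score range: need >= 2 distinct values", call. = FALSE)
  }
  edges <- min(s) + (0:K) / K * (max(s) - min(s))
  bin <- rep(NA_integer_, length(scores))
  bin[use] <- findInterval(s, edges, rightmost.closed = TRUE)
  list(edges = edges, bin = bin)
}

#' Neighbor bin-count vectors
#'
#' For each binned cell, counts how its `N` nearest binned neighbors (same
#' region, Euclidean distance, self excluded) distribute over the K score
#' bins. Each vector sums to `min(N, available neighbors)`. These vectors
#' are the clustering substrate for ordering the transition.
#'
#' @param table a [cell_table()]
#' @param bin_of_cell per-cell bin index aligned to `table` rows (NA =
#'   outside the transition subset)
#' @param N neighbors per vector (default 20)
#' @return binned-cells x K integer matrix, rownames = cell ids
#' @export
neighbor_bin_vectors <- function(table, bin_of_cell, N = 20L) {
  if (N < 1L) stop("N must be >= 1", call. = FALSE)
  stopifnot(length(bin_of_cell) == nrow(table))
  K <- max(bin_of_cell, na.rm = TRUE)
  sub <- which(!is.na(bin_of_cell))
  out <- matrix(0L, length(sub), K,
                dimnames = list(table$cell_id[sub], paste0("bin", seq_len(K))))
  order_key <- xtfrm(table$cell_id)
  pos_in_sub <- match(seq_len(nrow(table)), sub)
  for (r in unique(table$region_id[sub])) {
    rows <- sub[table$region_id[sub] == r]
    if (length(rows) < 2L) {
      stop("region '", r, "' has a single cell in the transition subset",
           call. = FALSE)
    }
    coords <- cbind(table$x[rows], table$y[rows])
    nn <- region_knn(coords, N, order_key[rows])
    idx <- nn$index
    keep <- !is.na(idx)
    i_rep <- rep(seq_along(rows), ncol(idx))[keep]
    j_bin <- bin_of_cell[rows[idx[keep]]]
    acc <- Matrix::sparseMatrix(i = i_rep, j = j_bin, x = 1,
                                dims = c(length(rows), K))
    out[pos_in_sub[rows], ] <- as.matrix(acc)
  }
  storage.mode(out) <- "integer"
  out
}

#' Cluster bin vectors and order by weighted percentile score
#'
#' Partitions the neighbor bin-count vectors with seeded k-means, then
#' orders the clusters by the size-normalized weighted percentile score
#' \deqn{W_c = \sum_b \frac{N_{c,b}}{N_c}\, 2^{\mathrm{rank}(b)}}
#' where \eqn{N_{c,b}} counts cluster-c cells whose own score falls in bin
#' b, \eqn{N_c} is the cluster size, and bins are ranked 1..K ascending so
#' the top-score bin has the highest rank. Clusters are relabeled 0, 1, ...
#' by decreasing \eqn{W_c} (cluster 0 = most CN1-like); the weighting makes
#' the ordering invariant to cluster size.
#'
#' @param bin_vectors cells x K matrix from [neighbor_bin_vectors()]
#' @param bin_of_cell per-vector own-bin index (1..K), aligned to
#'   `bin_vectors` rows
#' @param n_clusters number of transition clusters (default 5)
#' @param seed RNG seed for k-means
#' @param n_init k-means restarts
#' @param weighting `"power"` uses \eqn{2^{\mathrm{rank}}} (default);
#'   `"linear"` uses \eqn{2\,\mathrm{rank}}. Both give identical orderings
#'   on monotone bin profiles.
#' @return list with `cluster` (per-cell ordered id, 0-based),
#'   `order` (data.frame `cluster`, `W`, `n`), `raw_cluster` (unordered
#'   k-means labels).
#' @export
cluster_and_order <- function(bin_vectors, bin_of_cell, n_clusters = 5L,
                              seed = 0L, n_init = 10L,
                              weighting = c("power", "linear")) {
  weighting <- match.arg(weighting)
  if (n_clusters < 2L) stop("n_clusters must be >= 2", call. = FALSE)
  n_distinct <- nrow(unique(bin_vectors))
  if (n_distinct < n_clusters) {
    stop("fewer distinct bin vectors (", n_distinct, ") than clusters (",
         n_clusters, ")", call. = FALSE)
  }
  stopifnot(length(bin_of_cell) == nrow(bin_vectors))
  km <- with_seed(seed, stats::kmeans(bin_vectors, centers = n_clusters,
                                      nstart = n_init, iter.max = 100L))
  raw <- km$cluster
  K <- ncol(bin_vectors)
  w_of_rank <- if (weighting == "power") 2^(seq_len(K)) else 2 * seq_len(K)
  W <- vapply(seq_len(n_clusters), function(c) {
    own_bins <- bin_of_cell[raw == c]
    N_c <- length(own_bins)
    N_cb <- tabulate(own_bins, nbins = K)
    sum(N_cb / N_c * w_of_rank)
  }, numeric(1))
  ord <- order(-W)
  relabel <- match(raw, ord) - 1L
  list(
    cluster = stats::setNames(relabel, rownames(bin_vectors)),
    order = data.frame(cluster = seq_len(n_clusters) - 1L, W = W[ord],
                       n = as.integer(base::table(factor(raw, levels = ord)))),
    raw_cluster = raw
  )
}

#' Discrete transition derivatives and steepness
#'
#' Given the mean log-ratio score of each ordered transition cluster, the
#' first discrete derivative is \eqn{D^{(1)}_k = S_{k+1} - S_k} and the
#' second \eqn{D^{(2)}_k = D^{(1)}_{k+1} - D^{(1)}_k}. Steepness is the mean
#' absolute second derivative (curvature magnitude averaged along the
#' ordered sequence) and max-curvature its maximum; larger values mean a
#' sharper transition. The signed mean is available for diagnostics, but it
#' telescopes to \eqn{(D^{(1)}_{last} - D^{(1)}_{first})/(K-2)} and so is
#' not a curvature summary.
#'
#' @param cluster_mean_scores mean scores of the ordered clusters (length
#'   K >= 3)
#' @param signed if TRUE, also telescoped signed mean in `steepness_signed`
#' @return a `steepness_result`: list with `first_derivs`, `second_derivs`,
#'   `steepness`, `max_curvature` (and `steepness_signed` when requested)
#' @export
transition_derivatives <- function(cluster_mean_scores, signed = FALSE) {
  s <- as.numeric(cluster_mean_scores)
  if (length(s) < 3L) {
    stop("need >=3 ordered clusters for curvature", call. = FALSE)
  }
  d1 <- diff(s)
  d2 <- diff(d1)
  out <- list(
    first_derivs = d1,
    second_derivs = d2,
    steepness = mean(abs(d2)),
    max_curvature = max(abs(d2))
  )
  if (signed) out$steepness_signed <- mean(d2)
  structure(out, class = "steepness_result")
}

#' @export
print.steepness_result <- function(x, ...) {
  cat(sprintf("<steepness_result> steepness %.4g, max curvature %.4g (K = %d)\n",
              x$steepness, x$max_curvature, length(x$first_derivs) + 1L))
  invisible(x)
}

#' Local spatial gradient of a score field
#'
#' For each scored cell, fits the least-squares local plane
#' \eqn{\Delta S = \beta_x \Delta x + \beta_y \Delta y} over its `k`
#' nearest scored neighbors in the same region, with all deltas taken
#' relative to the focal cell (no intercept: \eqn{\Delta S = 0} at the
#' origin by construction). The gradient magnitude is
#' \eqn{|\nabla S_i| = \sqrt{\beta_x^2+\beta_y^2}}. Rank-deficient neighbor
#' geometry (collinear through the focal cell) falls back to the
#' minimum-norm solution and is flagged.
#'
#' @param table a [cell_table()]
#' @param scores per-cell scores aligned to `table` rows; NA = cell outside
#'   the scored subset (excluded from fits and neighborhoods)
#' @param k neighbors per fit (default 20); reduced per cell when a region
#'   holds fewer scored cells
#' @return a `gradient_field`: list with `cell_id`, `region_id`, `beta_x`,
#'   `beta_y`, `magnitude`, `rank_deficient` for every scored cell
#' @export
local_gradient <- function(table, scores, k = 20L) {
  stopifnot(length(scores) == nrow(table))
  sub <- which(!is.na(scores))
  if (length(sub) == 0L) stop("no scored cells", call. = FALSE)
  bx <- by <- rep(NA_real_, length(sub))
  flag <- rep(FALSE, length(sub))
  order_key <- xtfrm(table$cell_id)
  pos_in_sub <- match(seq_len(nrow(table)), sub)
  for (r in unique(table$region_id[sub])) {
    rows <- sub[table$region_id[sub] == r]
    if (length(rows) < 3L) {
      stop("region '", r, "' has fewer than 3 scored cells", call. = FALSE)
    }
    coords <- cbind(table$x[rows], table$y[rows])
    nn <- region_knn(coords, min(k, length(rows) - 1L), order_key[rows])
    idx <- nn$index
    s_r <- scores[rows]
    for (i in seq_along(rows)) {
      nb <- idx[i, !is.na(idx[i, ])]
      dx <- coords[nb, 1L] - coords[i, 1L]
      dy <- coords[nb, 2L] - coords[i, 2L]
      ds <- s_r[nb] - s_r[i]
      sxx <- sum(dx * dx); sxy <- sum(dx * dy); syy <- sum(dy * dy)
      sxs <- sum(dx * ds); sys <- sum(dy * ds)
      det <- sxx * syy - sxy * sxy
      j <- pos_in_sub[rows[i]]
      if (det > 1e-12 * (sxx + syy)^2) {
        bx[j] <- (syy * sxs - sxy * sys) / det
        by[j] <- (sxx * sys - sxy * sxs) / det
      } else {
        # minimum-norm least squares via pseudoinverse
        A <- cbind(dx, dy)
        sv <- svd(A)
        pos_sv <- sv$d > max(sv$d) * 1e-12
        beta <- sv$v[, pos_sv, drop = FALSE] %*%
          ((crossprod(sv$u[, pos_sv, drop = FALSE], ds)) / sv$d[pos_sv])
        bx[j] <- beta[1L]; by[j] <- beta[2L]
        flag[j] <- TRUE
      }
    }
  }
  structure(list(
    cell_id = table$cell_id[sub],
    region_id = table$region_id[sub],
    beta_x = bx,
    beta_y = by,
    magnitude = sqrt(bx^2 + by^2),
    rank_deficient = flag,
    k = k
  ), class = "gradient_field")
}

#' Spatially normalized gradient magnitude
#'
#' Multiplies each cell's gradient magnitude by its region's mean
#' nearest-neighbor distance: \eqn{G_i = |\nabla S_i| \cdot d_{NN}}. G is
#' the expected score change across one typical intercellular step, so it is
#' invariant to rescaling coordinates and comparable across regions with
#' different cell densities.
#'
#' @param field a `gradient_field` from [local_gradient()]
#' @param table the [cell_table()] the field was computed on
#' @return list with `G` (per scored cell, named), `d_nn` (per region) and
#'   `region_summary` (data.frame `region_id`, `mean_G`, `median_G`)
#' @export
normalize_gradient <- function(field, table) {
  d_nn <- mean_nn_distance(table)
  G <- field$magnitude * d_nn[field$region_id]
  names(G) <- field$cell_id
  regs <- unique(field$region_id)
  region_summary <- data.frame(
    region_id = regs,
    d_nn = as.numeric(d_nn[regs]),
    mean_G = vapply(regs, function(r) mean(G[field$region_id == r]), numeric(1)),
    median_G = vapply(regs, function(r) stats::median(G[field$region_id == r]),
                      numeric(1))
  )
  list(G = G, d_nn = d_nn, region_summary = region_summary)
}

#' Full transition profile between two organization units
#'
#' Orchestrates the gradient workflow for a unit pair: cells assigned
#' (argmax) to either unit are scored with [log_ratio_score()], binned with
#' [equal_width_bins()], given neighbor bin vectors, clustered and ordered
#' by \eqn{W_c}, and summarized by ordered-cluster mean scores, discrete
#' derivatives and steepness, plus the local gradient field and its
#' normalized magnitudes.
#'
#' @param table a [cell_table()] aligned to `M`
#' @param M a `membership_matrix`
#' @param pair two unit names (CN1, CN2)
#' @param eps score floor (default 1e-9)
#' @param bins K equal-width score bins (default 5)
#' @param neighbors N for bin vectors (default 20)
#' @param clusters transition clusters (default 5)
#' @param gradient_k neighbors per local gradient fit (default 20)
#' @param seed k-means seed
#' @return a `transition_profile`: list with `pair`, `scores`, `bin_edges`,
#'   `bin_of_cell`, `bin_vectors`, `cluster_of_cell`, `cluster_order`,
#'   `cluster_mean_scores`, `derivatives` (a `steepness_result`),
#'   `gradient` (a `gradient_field`), `G` (normalized magnitudes),
#'   `mean_G_transition` (mean G over cells in the interior score bins,
#'   i.e. the transition zone between the two saturated plateaus) and
#'   `region_summary`
#' @export
transition_profile <- function(table, M, pair, eps = 1e-9, bins = 5L,
                               neighbors = 20L, clusters = 5L,
                               gradient_k = 20L, seed = 0L) {
  stopifnot(nrow(table) == nrow(M$prob))
  in_pair <- M$assigned_unit %in% pair
  s_all <- log_ratio_score(M, pair, eps)
  s <- ifelse(in_pair, s_all, NA_real_)
  eb <- equal_width_bins(s, K = bins)
  bv <- neighbor_bin_vectors(table, eb$bin, N = neighbors)
  sub <- which(!is.na(eb$bin))
  co <- cluster_and_order(bv, eb$bin[sub], n_clusters = clusters, seed = seed)
  mean_scores <- vapply(sort(unique(co$cluster)), function(cl) {
    mean(s[sub][co$cluster == cl])
  }, numeric(1))
  der <- transition_derivatives(mean_scores)
  gf <- local_gradient(table, s, k = gradient_k)
  ng <- normalize_gradient(gf, table)
  # transition-zone gradient summary: cells in the interior score bins.
  # The extreme bins hold the saturated plateaus of each unit, where the
  # spatial mean of |grad S| is width-invariant (total variation / area),
  # so only the interior-bin mean discriminates sharp from gradual
  # interfaces.
  interior <- eb$bin[sub] > 1L & eb$bin[sub] < bins
  mean_G_transition <- if (any(interior)) mean(ng$G[interior]) else NA_real_
  structure(list(
    pair = pair,
    scores = s,
    bin_edges = eb$edges,
    bin_of_cell = eb$bin,
    bin_vectors = bv,
    cluster_of_cell = co$cluster,
    cluster_order = co$order,
    cluster_mean_scores = mean_scores,
    derivatives = der,
    gradient = gf,
    G = ng$G,
    mean_G_transition = mean_G_transition,
    region_summary = ng$region_summary
  ), class = "transition_profile")
}

#' @export
print.transition_profile <- function(x, ...) {
  cat(sprintf("<transition_profile> %s vs %s: %d cells in transition\n",
              x$pair[1L], x$pair[2L], sum(!is.na(x$bin_of_cell))))
  cat(sprintf("  steepness %.4g, max curvature %.4g, mean G %.4g\n",
              x$derivatives$steepness, x$derivatives$max_curvature,
              mean(x$G)))
  invisible(x)
}
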