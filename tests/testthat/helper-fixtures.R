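# Small in-code fixtures shared across test files.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Seeded evaluation without disturbing the session RNG (tests may run
# against the installed package, so don't rely on internals).
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

# Hand-built membership matrix from a probability matrix.
mm_of <- function(prob) {
  ll <- log(prob + 1e-300)
  idx <- max.col(prob, ties.method = "first")
  structure(list(cells = rownames(prob) %||%
                   sprintf("c%02d", seq_len(nrow(prob))),
                 units = colnames(prob),
                 loglik = ll, prob = prob,
                 assigned_unit = colnames(prob)[idx],
                 assigned_prob = prob[cbind(seq_len(nrow(prob)), idx)]),
            class = "membership_matrix")
}

# Minimal hand-built cell table: n cells on given coordinates, one region.
toy_table <- function(x, y, type, nbhd = type, region = "R1",
                      ids = sprintf("c%03d", seq_along(x))) {
  cell_table(data.frame(cell_id = ids, x = x, y = y, region_id = region,
                        cell_type = type, neighborhood = nbhd,
                        stringsAsFactors = FALSE),
             label_levels = "neighborhood")
}

# Brute-force O(n^2) window counts: the independent oracle for
# knn_window_features. Ties at rank k broken by ascending cell_id.
brute_window_counts <- function(table, k, count_level = "cell_type",
                                max_radius = Inf) {
  labs <- as.character(table[[count_level]])
  feats <- sort(unique(labs))
  n <- nrow(table)
  counts <- matrix(0L, n, length(feats),
                   dimnames = list(table$cell_id, feats))
  for (i in seq_len(n)) {
    same <- which(table$region_id == table$region_id[i])
    same <- setdiff(same, i)
    d <- sqrt((table$x[same] - table$x[i])^2 + (table$y[same] - table$y[i])^2)
    ord <- same[order(d, xtfrm(table$cell_id[same]))]
    dd <- sort(d)[seq_len(min(k, length(same)))]
    sel <- ord[seq_len(min(k, length(same)))]
    sel <- sel[dd <= max_radius]
    for (j in sel) {
      f <- match(labs[j], feats)
      counts[i, f] <- counts[i, f] + 1L
    }
  }
  counts
}

# Naive per-feature Gaussian density product membership: the independent
# oracle for the membership core. Works in plain probability space on
# deliberately small instances.
naive_membership <- function(counts, labels, sigma_floor = 1e-6) {
  units <- sort(unique(labels))
  dens <- sapply(units, function(u) {
    rows <- which(labels == u)
    mu <- colMeans(counts[rows, , drop = FALSE])
    sd_u <- apply(counts[rows, , drop = FALSE], 2, stats::sd)
    sd_u[is.na(sd_u) | sd_u < sigma_floor] <- sigma_floor
    apply(counts, 1, function(xi) prod(stats::dnorm(xi, mu, sd_u)))
  })
  dens / rowSums(dens)
}
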