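test_that("the full-dataset context has exactly zero deltas", {
  tb <- generate_tissue(tissue_spec("striped", n_cells = 800, contrast = 2,
                                    seed = 2))
  fm <- knn_window_features(tb, k = 10)
  cd <- context_delta(tb, fm, tb$neighborhood, "region_id", NULL)
  expect_true(all(cd$delta == 0))
  expect_equal(heterogeneity_index(cd), 0)
})

test_that("per-cell deltas sum to zero across units", {
  base <- tissue_spec("striped", n_cells = 600, contrast = 2, seed = 3)
  tb <- generate_context_cohort(base, contexts = c("a", "b"))
  fm <- knn_window_features(tb, k = 10)
  cd <- context_delta(tb, fm, tb$neighborhood, "condition", "a")
  expect_lt(max(abs(rowSums(cd$delta))), 1e-9)
  expect_equal(cd$n_cells, 600L)
})

test_that("a composition-shifted context ranks highest in heterogeneity", {
  # 4 contexts so the perturbation stays dilute in the global model; with
  # only 2 equal contexts the global centroids sit halfway and both
  # contexts deviate comparably
  base <- tissue_spec("striped", n_cells = 2500, contrast = 2, seed = 11)
  tb <- generate_context_cohort(
    base, contexts = paste0("c", 1:4),
    shifts = list(list(context = "c2", domain = "N1", type = "T7",
                       delta = 0.2)))
  fm <- knn_window_features(tb, k = 10)
  H <- vapply(paste0("c", 1:4), function(cx) {
    heterogeneity_index(context_delta(tb, fm, tb$neighborhood,
                                      "condition", cx))
  }, numeric(1))
  expect_equal(names(which.max(H)), "c2")
  # the shifted unit carries the largest absolute mean delta in its context
  cd <- context_delta(tb, fm, tb$neighborhood, "condition", "c2")
  expect_equal(names(which.max(abs(cd$mean_delta))), "N1")
})

test_that("units absent from a context are dropped with a warning and NA deltas", {
  tb <- generate_tissue(tissue_spec("striped", n_cells = 600, n_domains = 2,
                                    contrast = 2, seed = 5))
  # a pseudo-context that only covers the left stripe
  df <- as.data.frame(tb)
  df$side <- ifelse(df$x < sqrt(600) / 2 - 3, "left", "rest")
  tb2 <- cell_table(df, label_levels = "neighborhood", contexts = "side")
  fm <- knn_window_features(tb2, k = 10)
  expect_warning(
    cd <- context_delta(tb2, fm, tb2$neighborhood, "side", "left"),
    "absent")
  expect_true("N2" %in% cd$dropped_units)
  expect_true(all(is.na(cd$delta[, "N2"])))
  expect_true(is.finite(heterogeneity_index(cd)))
})

test_that("heterogeneity index and patient aggregation follow the formulas", {
  cd <- structure(list(mean_delta = c(a = 0.10, b = -0.05, c = -0.05)),
                  class = "context_delta")
  expect_equal(heterogeneity_index(cd), 0.2)
  # invariant to unit order
  cd2 <- structure(list(mean_delta = c(b = -0.05, c = -0.05, a = 0.10)),
                   class = "context_delta")
  expect_equal(heterogeneity_index(cd2), 0.2)

  h <- c(r1 = 0.2, r2 = 0.3, r3 = 0.4)
  map <- data.frame(region_id = c("r1", "r2", "r3"),
                    patient = c("p1", "p1", "p2"))
  agg <- aggregate_patients(h, map)
  expect_equal(agg$H_patient[agg$patient == "p1"], 0.5)
  expect_equal(agg$H_normalized[agg$patient == "p1"], 0.25)
  expect_equal(agg$H_patient[agg$patient == "p2"], 0.4)
  # partition identity
  expect_equal(sum(agg$H_patient), sum(h))
  expect_error(aggregate_patients(c(h, r9 = 1), map), "unmapped")
  expect_error(aggregate_patients(h, rbind(map, map[1, ])),
               "more than one patient")
})

test_that("context enrichment applies the exact ratio and the annotation filters", {
  # unit cells: global 200, context 100; type X: 4/100 context, 8/200+... build:
  n <- 300
  types <- rep("bulk", n)
  labels <- rep(c("u1", "u2"), c(200, 100))
  ctx <- rep("g", n); ctx[1:100] <- "c"
  # within u1: context cells 1:100; make X 4% of context, 2% globally
  types[1:4] <- "X"                      # 4 of 100 context cells
  # u1 has 200 cells; X global count must be 4 of 200 -> no more X
  tb <- cell_table(data.frame(cell_id = sprintf("c%03d", 1:n),
                              x = seq_len(n), y = 0, region_id = "R1",
                              cell_type = types, neighborhood = labels,
                              condition = ctx),
                   label_levels = "neighborhood", contexts = "condition")
  enr <- context_enrichment(tb, "u1", tb$neighborhood, "condition", "c")
  row_x <- enr$enrichment[enr$enrichment$cell_type == "X", ]
  expect_equal(row_x$E, 1)              # log2(0.04 / 0.02), exact
  expect_true(row_x$annotated)          # abundance 4% > 1%, |E| >= 1
  expect_false(row_x$zero_handled)

  # a rare type below 1% abundance is not annotated even with large |E|
  types2 <- types; types2[5] <- "rare"  # 1/100 = 1% context, 1/200 global
  tb2 <- cell_table(data.frame(cell_id = sprintf("c%03d", 1:n),
                               x = seq_len(n), y = 0, region_id = "R1",
                               cell_type = types2, neighborhood = labels,
                               condition = ctx),
                    label_levels = "neighborhood", contexts = "condition")
  enr2 <- context_enrichment(tb2, "u1", tb2$neighborhood, "condition", "c")
  row_r <- enr2$enrichment[enr2$enrichment$cell_type == "rare", ]
  expect_equal(row_r$E, 1)
  expect_false(row_r$annotated)         # fails the > 1% filter

  # equal proportions -> E = 0, no annotation
  row_b <- enr$enrichment[enr$enrichment$cell_type == "bulk", ]
  expect_lt(abs(row_b$E), 0.1)
  expect_false(row_b$annotated)

  # empty context for the unit -> status, not exception
  expect_equal(context_enrichment(tb, "u2", tb$neighborhood,
                                  "condition", "c")$status, "empty")
})

test_that("entropy follows the closed form with 0 log 0 = 0 and the Jensen bound", {
  expect_equal(neighborhood_entropy(c(1, 0, 0)), 0)
  expect_equal(neighborhood_entropy(rep(0.25, 4)), log(4), tolerance = 1e-12)
  expect_equal(neighborhood_entropy(rep(0.25, 4), base = "2"), 2)
  for (seed in 1:5) {
    p <- with_seed(seed, {v <- stats::runif(6); v / sum(v)})
    expect_lte(neighborhood_entropy(p), log(6) + 1e-12)
  }
  expect_error(neighborhood_entropy(c(0.9, 0.2)), "sum to 1")
  expect_error(neighborhood_entropy(c(1.2, -0.2)), "negative")
})
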