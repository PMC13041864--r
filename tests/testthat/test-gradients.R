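test_that("log-ratio score is zero at equality, antisymmetric, exact on hand case", {
  prob <- rbind(c(0.5, 0.5), c(0.8, 0.2), c(0.2, 0.8))
  colnames(prob) <- c("A", "B")
  M <- mm_of(prob)
  s <- log_ratio_score(M, c("A", "B"))
  expect_equal(unname(s[1]), 0, tolerance = 1e-8)
  expect_equal(unname(s[2]), log(4) * 0.8, tolerance = 1e-6)
  # swapping the pair negates the score exactly
  expect_equal(unname(log_ratio_score(M, c("B", "A"))), unname(-s))
  expect_error(log_ratio_score(M, c("A", "nope")), "unknown unit")
})

test_that("equal-width bins follow the edge formula with a closed top bin", {
  s <- c(0, 3.9, 10, 2, 9.9999)
  eb <- equal_width_bins(s, K = 5)
  expect_equal(eb$edges, c(0, 2, 4, 6, 8, 10))
  expect_equal(eb$bin[1], 1L)
  expect_equal(eb$bin[2], 2L)   # 3.9 in [2, 4)
  expect_equal(eb$bin[3], 5L)   # max lands in the top bin
  expect_equal(eb$bin[4], 2L)   # left edge inclusive
  expect_error(equal_width_bins(rep(1, 5), K = 5), "degenerate")
  expect_error(equal_width_bins(s, K = 1), ">= 2")
})

test_that("neighbor bin vectors match brute-force enumeration", {
  # 6 collinear cells, known bins, N = 2
  tb <- toy_table(x = 0:5, y = rep(0, 6), type = rep("A", 6))
  bins <- c(1L, 1L, 2L, 2L, 3L, 3L)
  bv <- neighbor_bin_vectors(tb, bins, N = 2)
  expect_equal(unname(bv[1, ]), c(1, 1, 0))  # neighbors x=1 (bin1), x=2 (bin2)
  expect_equal(unname(bv[3, ]), c(1, 1, 0))  # x=1 and x=3 (tie broken low id)
  expect_true(all(rowSums(bv) == 2))
  # all neighbors in one bin
  bins2 <- c(1L, 2L, 2L, 2L, 2L, NA)
  bv2 <- neighbor_bin_vectors(tb, bins2, N = 3)
  expect_equal(unname(bv2[1, ]), c(0, 3))
})

test_that("cluster ordering by weighted percentile score is size-invariant", {
  # two clearly separated vector populations: top-heavy and bottom-heavy
  top <- matrix(rep(c(0, 0, 0, 2, 18), 12), 12, byrow = TRUE)
  bot <- matrix(rep(c(18, 2, 0, 0, 0), 30), 30, byrow = TRUE)
  bv <- with_seed(9, rbind(top + matrix(rpois(60, 1), 12),
                           bot + matrix(rpois(150, 1), 30)))
  own_bin <- c(rep(5L, 12), rep(1L, 30))
  co <- cluster_and_order(bv, own_bin, n_clusters = 2, seed = 1)
  # the top-heavy cluster is ordered first (cluster 0) despite being smaller
  expect_equal(unname(co$cluster[1]), 0L)
  expect_equal(unname(co$cluster[20]), 1L)
  expect_true(all(diff(co$order$W) < 0))

  # a cluster entirely in the top of K = 5 bins has W = 2^5 = 32
  pure <- matrix(rep(c(0, 0, 0, 0, 20), 10), 10, byrow = TRUE)
  pure_mix <- rbind(pure, matrix(rep(c(20, 0, 0, 0, 0), 10), 10, byrow = TRUE))
  co2 <- cluster_and_order(pure_mix, c(rep(5L, 10), rep(1L, 10)),
                           n_clusters = 2, seed = 1)
  expect_equal(co2$order$W[1], 32)
  expect_equal(co2$order$W[2], 2)
  # W is invariant to duplicating every cell of a cluster
  co3 <- cluster_and_order(rbind(pure_mix, pure_mix),
                           rep(c(rep(5L, 10), rep(1L, 10)), 2),
                           n_clusters = 2, seed = 1)
  expect_equal(co3$order$W, co2$order$W)

  expect_error(cluster_and_order(pure, rep(5L, 10), n_clusters = 3),
               "distinct bin vectors")
})

test_that("transition derivatives follow the discrete formulas", {
  r <- transition_derivatives(c(10, 8, 2, 0))
  expect_equal(r$first_derivs, c(-2, -6, -2))
  expect_equal(r$second_derivs, c(-4, 4))
  expect_equal(r$steepness, 4)
  expect_equal(r$max_curvature, 4)
  # linear sequence -> zero curvature
  expect_equal(transition_derivatives(c(9, 6, 3, 0))$steepness, 0)
  expect_error(transition_derivatives(c(9, 0)), ">=3 ordered clusters")
  # signed variant telescopes
  rs <- transition_derivatives(c(10, 8, 2, 0), signed = TRUE)
  expect_equal(rs$steepness_signed, ((-2) - (-2)) / 2)
})

test_that("local gradients reproduce analytic gradients of affine fields", {
  g <- expand.grid(x = 0:9, y = 0:9)
  tb <- toy_table(x = g$x + 0.01 * sin(seq_len(100)),
                  y = g$y + 0.01 * cos(seq_len(100)),
                  type = rep("A", 100))
  s1 <- 2 * tb$x
  f1 <- local_gradient(tb, s1, k = 8)
  expect_lt(max(abs(f1$beta_x - 2)), 1e-8)
  expect_lt(max(abs(f1$beta_y)), 1e-8)
  expect_lt(max(abs(f1$magnitude - 2)), 1e-8)

  s2 <- tb$x + tb$y
  f2 <- local_gradient(tb, s2, k = 8)
  expect_lt(max(abs(f2$magnitude - sqrt(2))), 1e-8)

  f0 <- local_gradient(tb, rep(3, 100), k = 8)
  expect_lt(max(f0$magnitude), 1e-10)
})

test_that("collinear neighbor geometry falls back to a flagged minimum-norm fit", {
  tb <- toy_table(x = 0:9, y = rep(0, 10), type = rep("A", 10))
  f <- local_gradient(tb, 3 * tb$x, k = 4)
  expect_true(all(f$rank_deficient))
  expect_equal(f$beta_x, rep(3, 10), tolerance = 1e-8)
  expect_equal(f$beta_y, rep(0, 10), tolerance = 1e-8)
})

test_that("normalized gradient is the magnitude times regional spacing and scale-free", {
  g <- expand.grid(x = 0:9, y = 0:9)
  tb <- toy_table(x = g$x, y = g$y, type = rep("A", 100))
  s <- 2 * tb$x
  f <- local_gradient(tb, s, k = 8)
  ng <- normalize_gradient(f, tb)
  expect_equal(unname(ng$d_nn["R1"]), 1)
  expect_equal(max(abs(ng$G - 2)), 0, tolerance = 1e-8)

  # rescaling coordinates leaves G unchanged (score field fixed per cell)
  tb_c <- toy_table(x = 3 * g$x, y = 3 * g$y, type = rep("A", 100))
  f_c <- local_gradient(tb_c, s, k = 8)
  ng_c <- normalize_gradient(f_c, tb_c)
  expect_equal(unname(ng_c$G), unname(ng$G), tolerance = 1e-8)
})

test_that("the full transition profile orders clusters monotonically on a gradient", {
  tb <- generate_tissue(tissue_spec("striped", n_cells = 4000,
                                    interface_width = 4, aspect = 0.25,
                                    seed = 5))
  M <- soft_membership(tb, "neighborhood", k = 20)
  tp <- transition_profile(tb, M, c("N1", "N2"), seed = 0)
  # ordered cluster mean scores are non-increasing (W_c ordering works)
  expect_true(all(diff(tp$cluster_mean_scores) <= 1e-9))
  expect_equal(length(tp$derivatives$first_derivs), 4L)
  expect_gte(tp$derivatives$steepness, 0)
  expect_true(all(tp$bin_edges == sort(tp$bin_edges)))
  # scores restricted to pair-assigned cells only
  expect_true(all(is.na(tp$scores[!(M$assigned_unit %in% c("N1", "N2"))])))
})
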