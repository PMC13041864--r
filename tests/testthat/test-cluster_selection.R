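# Small synthetic feature matrix of three well-separated Gaussian blobs in
# feature space, used to exercise the sweep without spatial machinery.
blob_fm <- function(n_per = 40, seed = 1) {
  m <- with_seed(seed, {
    centers <- rbind(c(0, 0, 10), c(10, 0, 0), c(0, 10, 0))
    m <- centers[rep(1:3, each = n_per), ] +
      matrix(rnorm(3 * n_per * 3, sd = 0.5), 3 * n_per)
    colnames(m) <- paste0("f", 1:3)
    m
  })
  structure(list(counts = m, cells = as.character(seq_len(nrow(m))),
                 features = colnames(m), k = NA_integer_,
                 level = "synthetic", max_radius = Inf,
                 short_rows = rep(FALSE, nrow(m))),
            class = "feature_matrix")
}

test_that("sweep curves behave as expected on separable blobs", {
  fm <- blob_fm()
  sw <- suppressWarnings(sweep_resolutions(fm, n_range = 1:6, seed = 0,
                                           n_init = 5))
  s <- sw$summary
  expect_equal(s$avg_prob[s$n == 1], 1)       # degenerate softmax
  # average fit improves from 1 to the generative number 3
  expect_true(all(diff(s$avg_loglik[s$n <= 3]) > 0))
  # normalized curves live in [0, 1]
  expect_true(all(s$L_n >= 0 & s$L_n <= 1 & s$P_n >= 0 & s$P_n <= 1))
  expect_true(all(s$composite >= 0 & s$composite <= 1))
  # seeded determinism: identical rerun, bit for bit
  sw2 <- suppressWarnings(sweep_resolutions(fm, n_range = 1:6, seed = 0,
                                            n_init = 5))
  expect_identical(sw$summary, sw2$summary)
  # infeasible n values are skipped with a warning
  expect_warning(sweep_resolutions(fm, n_range = c(2, 1e5), seed = 0),
                 "skipping")
})

test_that("composite score is the harmonic mean with zero guard", {
  expect_equal(composite_score(1, 1), 1)
  expect_equal(composite_score(0.5, 1), 2 * 0.5 / 1.5)
  expect_equal(composite_score(0, 0.7), 0)
  expect_equal(composite_score(0, 0), 0)
})

test_that("elbow detection matches a brute-force geometric oracle", {
  # piecewise-linear curve with a single kink at n = 6
  n <- 1:20
  y <- ifelse(n <= 6, 10 - (n - 1), 5 - 0.05 * (n - 6))
  expect_equal(find_elbow(n, y)$n, 6)

  # brute-force oracle: normalized perpendicular distances
  oracle_elbow <- function(n, y) {
    xs <- (n - min(n)) / diff(range(n))
    ys <- (y - min(y)) / diff(range(y))
    vx <- xs[length(xs)] - xs[1]; vy <- ys[length(ys)] - ys[1]
    d <- abs(vx * (ys - ys[1]) - vy * (xs - xs[1])) / sqrt(vx^2 + vy^2)
    n[which.max(d)]
  }
  # exponential decay y = exp(-n/3) over 1:50: the max-chord-distance point,
  # computed by the oracle, is n = 9 (note the argmax is invariant to
  # per-axis rescaling, so normalization cannot move it)
  y2 <- exp(-(1:50) / 3)
  e2 <- find_elbow(1:50, y2)
  expect_equal(e2$n, oracle_elbow(1:50, y2))
  expect_equal(e2$n, 9)

  # exactly linear curve: no elbow, not a crash
  expect_equal(find_elbow(1:10, 2 * (1:10) + 1)$status, "no_elbow")
  expect_error(find_elbow(1:2, c(1, 2)), ">= 3 points")
})

test_that("resolution selection applies the plateau rule on constructed curves", {
  # composite flat at 0.9 from n = 15 on; elbows forced at 6 and 28 by
  # constructing the raw curves as piecewise linear with kinks there
  n <- 1:40
  avg_prob <- ifelse(n <= 6, 1 - 0.08 * (n - 1), 0.6 - 0.002 * (n - 6))
  avg_loglik <- ifelse(n <= 28, -40 + 1.2 * n, -6.4 + 0.01 * (n - 28))
  composite <- ifelse(n < 15, 0.2 + 0.7 * (n - 1) / 14, 0.9)
  slope <- c(diff(composite)[1], (composite[3:40] - composite[1:38]) / 2,
             diff(composite)[39])
  sweep <- structure(list(summary = data.frame(
    n = n, avg_loglik = avg_loglik, avg_prob = avg_prob,
    L_n = NA, P_n = NA, composite = composite, slope = slope)),
    class = "resolution_sweep")
  ch <- select_resolution(sweep)
  expect_equal(ch$elbow_prob, 6)
  expect_equal(ch$elbow_loglik, 28)
  # the plateau starts at 15, but the central-difference slope at 15 still
  # sees the rise at 14, so the first point whose neighborhood is flat is 16
  expect_equal(ch$selected, 16)
  expect_false(ch$fallback)

  # strictly rising composite with no flat plateau: argmax fallback, flagged
  sweep2 <- sweep
  sweep2$summary$composite <- seq(0, 1, length.out = 40)
  sweep2$summary$slope <- rep(1 / 39, 40)
  ch2 <- select_resolution(sweep2)
  expect_true(ch2$fallback)
  expect_equal(ch2$selected, 28)  # in-range argmax of a rising curve
})

test_that("selection recovers the generative cluster number on blob tissue", {
  spec <- tissue_spec("blobs", n_cells = 3000, n_domains = 5,
                      interface_width = 1, seed = 3)
  tb <- generate_tissue(spec)
  fm <- knn_window_features(tb, k = 20)
  sw <- suppressWarnings(sweep_resolutions(fm, n_range = c(1:12, 14, 17, 20),
                                           seed = 3, n_init = 2))
  ch <- select_resolution(sw)
  expect_gte(ch$selected, 3)
  expect_lte(ch$selected, 8)
  lo <- min(ch$elbow_prob, ch$elbow_loglik)
  hi <- max(ch$elbow_prob, ch$elbow_loglik)
  expect_true(ch$selected >= lo && ch$selected <= hi)
})
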