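# A feature_matrix wrapper around an arbitrary numeric matrix, for testing
# the membership math independently of the window machinery.
fm_of <- function(m) {
  structure(list(counts = m,
                 cells = rownames(m) %||% as.character(seq_len(nrow(m))),
                 features = colnames(m),
                 k = NA_integer_, level = "synthetic", max_radius = Inf,
                 short_rows = rep(FALSE, nrow(m))),
            class = "feature_matrix")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("centroid fit reproduces hand-computed means and sample sds", {
  m <- matrix(c(1, 3,
                1, 3,
                5, 5), nrow = 3, byrow = FALSE,
              dimnames = list(NULL, c("f1", "f2")))
  # unit u1 holds rows 1-2: f1 values {1, 1} -> sd 0 -> floored;
  # f2 values {1, 5} wait, build explicitly instead:
  m <- rbind(c(1, 2), c(3, 2), c(0, 9))
  colnames(m) <- c("f1", "f2")
  model <- fit_centroids(fm_of(m), c("u1", "u1", "u2"))
  expect_equal(model$mean["u1", "f1"], 2)          # mean of {1, 3}
  expect_equal(model$std["u1", "f1"], sqrt(2))      # n-1 denominator
  expect_equal(model$std["u1", "f2"], 1e-6)         # zero spread -> floor
  # singleton unit: all sds floored, mean = the vector itself
  expect_equal(model$mean["u2", ], c(f1 = 0, f2 = 9))
  expect_equal(unname(model$std["u2", ]), c(1e-6, 1e-6))
})

test_that("log-likelihood matches the closed-form normal density", {
  m <- matrix(c(0, 1), ncol = 1, dimnames = list(NULL, "f"))
  model <- list(units = "u", features = "f",
                mean = matrix(0, 1, 1, dimnames = list("u", "f")),
                std = matrix(1, 1, 1, dimnames = list("u", "f")),
                n_cells_per_unit = c(u = 5L), sigma_floor = 1e-6)
  class(model) <- "centroid_model"
  ll <- log_likelihoods(fm_of(m), model)
  expect_equal(ll[1, "u"], -0.5 * log(2 * pi), tolerance = 1e-12)
  expect_equal(ll[2, "u"], -0.5 * log(2 * pi) - 0.5, tolerance = 1e-12)

  # duplicating a feature column (and its centroid column) doubles every entry
  m2 <- cbind(f = m[, 1], f2 = m[, 1])
  model2 <- model
  model2$features <- c("f", "f2")
  model2$mean <- cbind(f = 0, f2 = 0); rownames(model2$mean) <- "u"
  model2$std <- cbind(f = 1, f2 = 1); rownames(model2$std) <- "u"
  expect_equal(log_likelihoods(fm_of(m2), model2), 2 * ll)

  bad <- model; bad$features <- "other"
  colnames(bad$mean) <- colnames(bad$std) <- "other"
  expect_error(log_likelihoods(fm_of(m), bad), "feature mismatch")
})

test_that("softmax probabilities are exact on hand cases and shift-invariant", {
  ll <- matrix(c(2, 0), 1, 2, dimnames = list("c1", c("u1", "u2")))
  M <- membership_probabilities(ll)
  expect_equal(M$prob[1, ], c(u1 = exp(2) / (exp(2) + 1),
                              u2 = 1 / (exp(2) + 1)), tolerance = 1e-12)
  expect_equal(M$assigned_unit, "u1")

  # single unit -> probability 1; equal logliks -> uniform
  one <- membership_probabilities(matrix(-5, 3, 1,
                                         dimnames = list(NULL, "u")))
  expect_equal(unname(one$prob[, 1]), rep(1, 3))
  four <- membership_probabilities(matrix(7, 2, 4,
    dimnames = list(NULL, paste0("u", 1:4))))
  expect_equal(unname(four$prob), matrix(0.25, 2, 4))
  expect_equal(four$assigned_unit, c("u1", "u1"))  # ties by unit order

  # adding a constant to a loglik row leaves its probability row unchanged
  llr <- matrix(rnorm(8), 2, 4, dimnames = list(NULL, paste0("u", 1:4)))
  expect_equal(membership_probabilities(llr + 100)$prob,
               membership_probabilities(llr)$prob, tolerance = 1e-12)

  # extreme magnitudes do not overflow thanks to max-subtraction
  big <- matrix(c(1e4, 9.99e3), 1, 2, dimnames = list(NULL, c("a", "b")))
  expect_equal(sum(membership_probabilities(big)$prob), 1)
})

test_that("membership matches the naive density-product oracle on random instances", {
  for (seed in 1:20) {
    inst <- with_seed(seed, {
      n <- sample(10:50, 1)
      n_units <- sample(2:4, 1)
      n_feat <- sample(2:6, 1)
      labels <- sample(paste0("u", seq_len(n_units)), n, replace = TRUE)
      # ensure every unit has >= 2 cells so no sd is floored
      labels[seq_len(2 * n_units)] <- rep(paste0("u", seq_len(n_units)), 2)
      centers <- matrix(rnorm(n_units * n_feat, sd = 2), n_units)
      m <- centers[match(labels, paste0("u", seq_len(n_units))), ,
                   drop = FALSE] + matrix(rnorm(n * n_feat), n)
      colnames(m) <- paste0("f", seq_len(n_feat))
      list(m = m, labels = labels)
    })
    fm <- fm_of(inst$m)
    model <- fit_centroids(fm, inst$labels)
    M <- membership_probabilities(log_likelihoods(fm, model))
    oracle <- naive_membership(inst$m, inst$labels)
    expect_lt(max(abs(M$prob - oracle) / pmax(oracle, 1e-12)), 1e-6)
    expect_lt(max(abs(rowSums(M$prob) - 1)), 1e-9)
    expect_true(all(M$assigned_prob >= 1 / length(M$units) - 1e-12))
  }
})

test_that("well-separated synthetic mixtures are recovered almost perfectly", {
  # feature-space mixture with unit means >= 6 sigma apart
  inst <- with_seed(7, {
    labels <- sample(c("u1", "u2", "u3"), 600, replace = TRUE)
    centers <- rbind(u1 = c(0, 0), u2 = c(8, 0), u3 = c(0, 8))
    m <- centers[labels, ] + matrix(rnorm(1200), 600)
    colnames(m) <- c("f1", "f2")
    list(m = m, labels = labels)
  })
  fm <- fm_of(inst$m)
  M <- membership_probabilities(
    log_likelihoods(fm, fit_centroids(fm, inst$labels)))
  expect_gt(mean(M$assigned_unit == inst$labels), 0.99)
})
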