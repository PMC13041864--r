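#' Fit organization-unit centroids from annotations
#'
#' Each annotated organization unit (neighborhood, community, tissue unit) is
#' summarized by the per-feature sample mean and sample standard deviation of
#' the window-composition features of the cells annotated to it. Each
#' (unit, feature) pair thus defines a univariate Gaussian; together the
#' features form a diagonal-covariance Gaussian per unit. Standard deviations
#' below `sigma_floor`, or undefined ones (singleton units), are replaced by
#' `sigma_floor` so densities stay finite.
#'
#' @param fm a `feature_matrix` from [knn_window_features()]
#' @param labels per-cell unit labels aligned to `fm` rows
#' @param sigma_floor minimum standard deviation (default `1e-6`)
#' @param population use the population (n) instead of the sample (n - 1)
#'   standard deviation; kept for sensitivity checks.
#' @return a `centroid_model`: list with `units`, `features`, `mean` and
#'   `std` (units x features matrices), `n_cells_per_unit`, `sigma_floor`.
#' @export
fit_centroids <- function(fm, labels, sigma_floor = 1e-6,
                          population = FALSE) {
  x <- fm$counts
  labels <- as.character(labels)
  if (length(labels) != nrow(x)) {
    stop("labels (", length(labels), ") not aligned to feature rows (",
         nrow(x), ")", call. = FALSE)
  }
  if (anyNA(labels)) stop("NA labels not allowed", call. = FALSE)
  units <- sort(unique(labels))
  n_u <- as.integer(table(factor(labels, levels = units)))
  if (any(n_u == 0L)) {
    stop("unit with 0 cells: ", units[which(n_u == 0L)[1L]], call. = FALSE)
  }
  f <- factor(labels, levels = units)
  sums  <- rowsum(x, f)
  sums2 <- rowsum(x^2, f)
  mu <- sums / n_u
  denom <- if (population) n_u else n_u - 1L
  ss <- sums2 - n_u * mu^2
  ss[ss < 0] <- 0  # numerical guard
  sd_mat <- sqrt(ss / ifelse(denom > 0L, denom, NA_real_))
  sd_mat[is.na(sd_mat) | sd_mat < sigma_floor] <- sigma_floor
  dimnames(mu) <- dimnames(sd_mat) <- list(units, fm$features)
  structure(list(
    units = units,
    features = fm$features,
    mean = mu,
    std = sd_mat,
    n_cells_per_unit = stats::setNames(n_u, units),
    sigma_floor = sigma_floor
  ), class = "centroid_model")
}

#' @export
print.centroid_model <- function(x, ...) {
  cat(sprintf("<centroid_model> %d units x %d features (sigma floor %g)\n",
              length(x$units), length(x$features), x$sigma_floor))
  invisible(x)
}

#' Per-cell log-likelihood under each centroid
#'
#' Entry (i, n) is the log of the product of per-feature univariate normal
#' densities of cell i's window features under unit n's centroid:
#' \deqn{\sum_t \log \phi(x_{i,t};\, \mu_{n,t},\, \sigma_{n,t}).}
#' Evaluated in log space; finite for all inputs given the sigma floor.
#'
#' @param fm a `feature_matrix`
#' @param model a `centroid_model`; features must match `fm`'s by name
#'   (order is aligned automatically).
#' @return cells x units numeric matrix with dimnames
#' @export
log_likelihoods <- function(fm, model) {
  unmatched <- c(setdiff(fm$features, model$features),
                 setdiff(model$features, fm$features))
  if (length(unmatched) > 0L) {
    stop("feature mismatch between windows and centroids: ",
         paste(unique(unmatched), collapse = ", "), call. = FALSE)
  }
  x <- fm$counts[, model$features, drop = FALSE]
  n <- nrow(x)
  ll <- matrix(0, n, length(model$units),
               dimnames = list(fm$cells, model$units))
  const <- -0.5 * log(2 * pi)
  for (u in seq_along(model$units)) {
    mu <- model$mean[u, ]
    sd_u <- model$std[u, ]
    z <- sweep(x, 2L, mu, "-")
    z <- sweep(z, 2L, sd_u, "/")
    ll[, u] <- ncol(x) * const - sum(log(sd_u)) - 0.5 * rowSums(z^2)
  }
  ll
}

#' Softmax membership probabilities
#'
#' Converts per-cell, per-unit log-likelihoods into a normalized probability
#' vector via a row-wise softmax, computed with max-subtraction
#' (log-sum-exp) so no overflow occurs. Uniform mixture weights are implied:
#' no unit-abundance prior enters the normalization. The argmax unit and its
#' probability are recorded per cell, ties broken by unit order.
#'
#' @param loglik cells x units matrix, e.g. from [log_likelihoods()]
#' @return a `membership_matrix`: list with `cells`, `units`, `loglik`,
#'   `prob` (rows sum to 1), `assigned_unit`, `assigned_prob`.
#' @export
membership_probabilities <- function(loglik) {
  if (is.null(dim(loglik)) || ncol(loglik) < 1L) {
    stop("loglik must be a cells x units matrix with >= 1 unit",
         call. = FALSE)
  }
  if (any(!is.finite(loglik))) stop("non-finite log-likelihoods", call. = FALSE)
  m <- apply(loglik, 1L, max)
  e <- exp(loglik - m)
  prob <- e / rowSums(e)
  assigned_idx <- max.col(prob, ties.method = "first")
  units <- colnames(loglik)
  if (is.null(units)) units <- as.character(seq_len(ncol(loglik)))
  structure(list(
    cells = rownames(loglik),
    units = units,
    loglik = loglik,
    prob = prob,
    assigned_unit = units[assigned_idx],
    assigned_prob = prob[cbind(seq_len(nrow(prob)), assigned_idx)]
  ), class = "membership_matrix")
}

#' @export
print.membership_matrix <- function(x, ...) {
  cat(sprintf("<membership_matrix> %d cells x %d units\n",
              nrow(x$prob), length(x$units)))
  cat(sprintf("  mean assigned probability %.3f\n", mean(x$assigned_prob)))
  invisible(x)
}

#' One-call soft membership from an annotated table
#'
#' Convenience wrapper chaining [knn_window_features()], [fit_centroids()]
#' (on the annotations at `level`), [log_likelihoods()] and
#' [membership_probabilities()].
#'
#' @param table a [cell_table()]
#' @param level label level supplying the unit annotations
#' @param count_level labels counted in the windows (default `"cell_type"`)
#' @param k window size (default 10, the cellular-neighborhood scale)
#' @param max_radius optional window radius cutoff
#' @param sigma_floor minimum centroid standard deviation
#' @return a `membership_matrix`; the `feature_matrix` and `centroid_model`
#'   are attached as attributes `features` and `model`.
#' @export
soft_membership <- function(table, level, count_level = "cell_type", k = 10,
                            max_radius = Inf, sigma_floor = 1e-6) {
  if (!level %in% names(table)) {
    stop("level '", level, "' is not a column of the table", call. = FALSE)
  }
  fm <- knn_window_features(table, k = k, count_level = count_level,
                            max_radius = max_radius)
  model <- fit_centroids(fm, table[[level]], sigma_floor = sigma_floor)
  M <- membership_probabilities(log_likelihoods(fm, model))
  attr(M, "features") <- fm
  attr(M, "model") <- model
  M
}
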