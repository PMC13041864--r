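#' Sweep unsupervised cluster numbers
#'
#' For each candidate cluster number n, runs seeded k-means on the window
#' features, treats the k-means labels as annotations, fits centroids and
#' membership probabilities, and records the fit/confidence trade-off:
#' \eqn{\bar L(n)} = mean over cells of the assigned cluster's
#' log-likelihood (fit) and \eqn{\bar P(n)} = mean assigned probability
#' (confidence). Both curves are min-max normalized over the swept range
#' (so they depend on that range) and combined into the harmonic composite
#' \eqn{S(n) = 2 L_n P_n / (L_n + P_n)}. The slope of S(n) is a central
#' finite difference (one-sided at the endpoints). At n = 1 the softmax is
#' degenerate, so \eqn{\bar P(1) = 1} exactly.
#'
#' @param fm a `feature_matrix`
#' @param n_range cluster numbers to sweep (default 1:50); values exceeding
#'   the number of cells (or of distinct feature rows) are skipped with a
#'   warning
#' @param seed base RNG seed; repetition r of cluster number n uses
#'   `seed + 1000 * r`
#' @param reps independent k-means repetitions averaged per n (default 1)
#' @param n_init k-means restarts per repetition (default 10)
#' @param sigma_floor centroid floor
#' @return a `resolution_sweep`: list with `summary` (data.frame `n`,
#'   `avg_loglik`, `avg_prob`, `L_n`, `P_n`, `composite`, `slope`),
#'   `per_cluster` (per-n list of per-cluster mean prob/loglik,
#'   diagnostic), `seed`, `reps`
#' @export
sweep_resolutions <- function(fm, n_range = 1:50, seed = 0L, reps = 1L,
                              n_init = 10L, sigma_floor = 1e-6) {
  x <- fm$counts
  n_cells <- nrow(x)
  n_distinct <- nrow(unique(x))
  usable <- n_range[n_range >= 1L & n_range <= min(n_cells, n_distinct)]
  skipped <- setdiff(n_range, usable)
  if (length(skipped) > 0L) {
    warning("skipping n = ", paste(skipped, collapse = ", "),
            " (more clusters than distinct cells)", call. = FALSE)
  }
  usable <- sort(usable)
  avg_ll <- avg_p <- numeric(length(usable))
  per_cluster <- vector("list", length(usable))
  for (j in seq_along(usable)) {
    n <- usable[j]
    ll_r <- p_r <- numeric(reps)
    pc <- NULL
    for (r in seq_len(reps)) {
      lab <- with_seed(seed + 1000L * r, {
        km <- stats::kmeans(x, centers = n, nstart = n_init, iter.max = 100L)
        km$cluster
      })
      model <- fit_centroids(fm, lab, sigma_floor = sigma_floor)
      M <- membership_probabilities(log_likelihoods(fm, model))
      idx <- match(M$assigned_unit, M$units)
      ll_assigned <- M$loglik[cbind(seq_len(n_cells), idx)]
      ll_r[r] <- mean(ll_assigned)
      p_r[r] <- mean(M$assigned_prob)
      if (r == 1L) {
        pc <- data.frame(
          cluster = M$units,
          mean_prob = vapply(M$units, function(u)
            mean(M$assigned_prob[M$assigned_unit == u]), numeric(1)),
          mean_loglik = vapply(M$units, function(u)
            mean(ll_assigned[M$assigned_unit == u]), numeric(1)),
          row.names = NULL
        )
      }
    }
    avg_ll[j] <- mean(ll_r)
    avg_p[j] <- mean(p_r)
    per_cluster[[j]] <- pc
  }
  minmax <- function(v) {
    rng <- range(v)
    if (diff(rng) == 0) return(rep(0, length(v)))
    (v - rng[1L]) / diff(rng)
  }
  L_n <- minmax(avg_ll)
  P_n <- minmax(avg_p)
  S <- composite_score(L_n, P_n)
  slope <- finite_diff_slope(usable, S)
  names(per_cluster) <- usable
  structure(list(
    summary = data.frame(n = usable, avg_loglik = avg_ll, avg_prob = avg_p,
                         L_n = L_n, P_n = P_n, composite = S, slope = slope),
    per_cluster = per_cluster,
    seed = seed,
    reps = reps
  ), class = "resolution_sweep")
}

# central finite difference, one-sided at the endpoints
finite_diff_slope <- function(n, y) {
  m <- length(y)
  if (m < 2L) return(rep(NA_real_, m))
  slope <- numeric(m)
  slope[1L] <- (y[2L] - y[1L]) / (n[2L] - n[1L])
  slope[m] <- (y[m] - y[m - 1L]) / (n[m] - n[m - 1L])
  if (m > 2L) {
    i <- 2:(m - 1L)
    slope[i] <- (y[i + 1L] - y[i - 1L]) / (n[i + 1L] - n[i - 1L])
  }
  slope
}

#' Harmonic composite of normalized fit and confidence
#'
#' \eqn{S(n) = 2 L_n P_n / (L_n + P_n)}, with S = 0 when
#' \eqn{L_n + P_n = 0}. Both inputs are expected min-max normalized to
#' [0, 1] over the swept range.
#'
#' @param L_n,P_n normalized curves of equal length
#' @return numeric vector in [0, 1]
#' @export
composite_score <- function(L_n, P_n) {
  stopifnot(length(L_n) == length(P_n))
  s <- L_n + P_n
  ifelse(s == 0, 0, 2 * L_n * P_n / s)
}

#' Elbow point of a monotone-trending curve
#'
#' Kneedle-style geometry: both axes are min-max normalized to [0, 1], and
#' the elbow is the point with maximum perpendicular distance from the chord
#' joining the curve's endpoints. Ties break toward smaller n. An exactly
#' linear curve has zero distance everywhere and returns a no-elbow status.
#'
#' @param n x-coordinates (e.g. cluster numbers)
#' @param values curve values over `n` (length >= 3)
#' @return list with `n` (elbow location, NA when absent), `distance`
#'   (max normalized chord distance), `status` (`"ok"` or `"no_elbow"`)
#' @export
find_elbow <- function(n, values) {
  stopifnot(length(n) == length(values))
  if (length(n) < 3L) stop("need >= 3 points", call. = FALSE)
  xr <- range(n); yr <- range(values)
  if (diff(yr) == 0) return(list(n = NA_integer_, distance = 0,
                                 status = "no_elbow"))
  x <- (n - xr[1L]) / diff(xr)
  y <- (values - yr[1L]) / diff(yr)
  m <- length(x)
  vx <- x[m] - x[1L]; vy <- y[m] - y[1L]
  # perpendicular distance of each point to the endpoint chord
  d <- abs(vx * (y - y[1L]) - vy * (x - x[1L])) / sqrt(vx^2 + vy^2)
  if (max(d) < 1e-12) return(list(n = NA_integer_, distance = 0,
                                  status = "no_elbow"))
  list(n = n[which.max(d)], distance = max(d), status = "ok")
}

#' Select a stable cluster-number resolution
#'
#' Elbows are located on the raw confidence curve \eqn{\bar P(n)} and the
#' raw fit curve \eqn{\bar L(n)}. Within the interval they bracket, the
#' selected resolution is the smallest n whose composite slope magnitude is
#' at most `slope_tolerance` and whose composite is at least
#' `high_fraction` of the interval's maximum — the earliest stable
#' high-score plateau. When no n qualifies the interval's composite argmax
#' is returned with a fallback flag; when an elbow is missing the global
#' composite argmax is returned, flagged.
#'
#' @param sweep a `resolution_sweep`
#' @param slope_tolerance plateau slope bound on S(n) (default 0.005)
#' @param high_fraction plateau height bound relative to the in-range
#'   maximum composite (default 0.9)
#' @return a `resolution_choice`: list with `elbow_prob`, `elbow_loglik`,
#'   `selected`, `fallback` (logical), `rationale`
#' @export
select_resolution <- function(sweep, slope_tolerance = 0.005,
                              high_fraction = 0.9) {
  s <- sweep$summary
  e_p <- find_elbow(s$n, s$avg_prob)
  e_l <- find_elbow(s$n, s$avg_loglik)
  if (e_p$status != "ok" || e_l$status != "ok") {
    sel <- s$n[which.max(s$composite)]
    return(structure(list(
      elbow_prob = e_p$n, elbow_loglik = e_l$n, selected = sel,
      fallback = TRUE,
      rationale = "missing elbow; global composite maximum"
    ), class = "resolution_choice"))
  }
  lo <- min(e_p$n, e_l$n); hi <- max(e_p$n, e_l$n)
  in_range <- s$n >= lo & s$n <= hi
  s_max <- max(s$composite[in_range])
  ok <- in_range & abs(s$slope) <= slope_tolerance &
    s$composite >= high_fraction * s_max
  if (any(ok)) {
    sel <- min(s$n[ok])
    fb <- FALSE
    why <- sprintf(
      "earliest n in [%d, %d] with |slope| <= %g and composite >= %g of range max",
      lo, hi, slope_tolerance, high_fraction)
  } else {
    in_idx <- which(in_range)
    sel <- s$n[in_idx[which.max(s$composite[in_idx])]]
    fb <- TRUE
    why <- sprintf("no sub-tolerance plateau in [%d, %d]; composite argmax",
                   lo, hi)
  }
  structure(list(
    elbow_prob = e_p$n, elbow_loglik = e_l$n, selected = sel,
    fallback = fb, rationale = why
  ), class = "resolution_choice")
}

#' @export
print.resolution_choice <- function(x, ...) {
  cat(sprintf("<resolution_choice> selected n = %d (elbows: prob %s, loglik %s)%s\n",
              x$selected, format(x$elbow_prob), format(x$elbow_loglik),
              if (isTRUE(x$fallback)) " [fallback]" else ""))
  cat("  ", x$rationale, "\n")
  invisible(x)
}

#' @export
print.resolution_sweep <- function(x, ...) {
  cat(sprintf("<resolution_sweep> n in [%d, %d], %d points (seed %d)\n",
              min(x$summary$n), max(x$summary$n), nrow(x$summary), x$seed))
  invisible(x)
}
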