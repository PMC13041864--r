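#' Context-specific delta probabilities
#'
#' Measures how spatial organization within one context (a disease state, a
#' patient, a single region, ...) deviates from the cohort-wide model.
#' Global membership probabilities come from centroids fit on all cells;
#' context probabilities come from centroids refit on the context's cells
#' only (windows are NOT recomputed — they describe each cell's actual
#' spatial surroundings regardless of context). For each context cell and
#' unit,
#' \deqn{\Delta P_{i,n}(c) = P_c(n \mid i) - P_{global}(n \mid i).}
#' Since both probability vectors are normalized over the same units, each
#' cell's deltas sum to zero. Units with no annotated cell inside the
#' context are dropped from the context model with a warning (the context
#' softmax renormalizes over the present units) and their deltas are
#' reported as `NA`.
#'
#' @param table a [cell_table()]
#' @param fm a `feature_matrix` over all cells of `table`
#' @param labels per-cell unit labels aligned to `fm` rows (typically
#'   `table[[level]]`)
#' @param context_col context column name in `table`
#' @param context_level context value defining the subset; `NULL` means the
#'   full dataset (all deltas are exactly zero — a useful null)
#' @param sigma_floor centroid floor, as in [fit_centroids()]
#' @return a `context_delta`: list with `context` (name=level), `n_cells`,
#'   `units`, `delta` (context cells x units; NA for dropped units),
#'   `mean_delta` (per unit), `dropped_units`
#' @export
context_delta <- function(table, fm, labels, context_col,
                          context_level = NULL, sigma_floor = 1e-6) {
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(fm$counts))
  global_model <- fit_centroids(fm, labels, sigma_floor = sigma_floor)
  P_global <- membership_probabilities(log_likelihoods(fm, global_model))$prob
  if (is.null(context_level)) {
    sel <- rep(TRUE, nrow(table))
    ctx_name <- paste0(context_col, "=<all>")
  } else {
    if (!context_col %in% names(table)) {
      stop("context column '", context_col, "' absent", call. = FALSE)
    }
    sel <- table[[context_col]] == context_level
    ctx_name <- paste0(context_col, "=", context_level)
  }
  if (!any(sel)) stop("empty context subset: ", ctx_name, call. = FALSE)
  sub_fm <- fm
  sub_fm$counts <- fm$counts[sel, , drop = FALSE]
  sub_fm$cells <- fm$cells[sel]
  sub_fm$short_rows <- fm$short_rows[sel]
  sub_labels <- labels[sel]
  present <- sort(unique(sub_labels))
  dropped <- setdiff(global_model$units, present)
  if (length(dropped) > 0L) {
    warning("unit(s) absent from context ", ctx_name, ": ",
            paste(dropped, collapse = ", "),
            "; dropped from the context model", call. = FALSE)
  }
  ctx_model <- fit_centroids(sub_fm, sub_labels, sigma_floor = sigma_floor)
  P_ctx <- membership_probabilities(log_likelihoods(sub_fm, ctx_model))$prob
  units <- global_model$units
  delta <- matrix(NA_real_, sum(sel), length(units),
                  dimnames = list(sub_fm$cells, units))
  delta[, present] <- P_ctx[, present, drop = FALSE] -
    P_global[sel, present, drop = FALSE]
  structure(list(
    context = ctx_name,
    n_cells = sum(sel),
    units = units,
    delta = delta,
    mean_delta = colMeans(delta),
    dropped_units = dropped
  ), class = "context_delta")
}

#' @export
print.context_delta <- function(x, ...) {
  cat(sprintf("<context_delta> %s: %d cells, %d units\n",
              x$context, x$n_cells, length(x$units)))
  invisible(x)
}

#' Heterogeneity index of a context
#'
#' The total structural deviation of a context from the global spatial
#' model: the sum of absolute per-unit mean delta probabilities,
#' \eqn{H_c = \sum_n |\bar{\Delta P}_n(c)|}. Zero iff every mean delta is
#' zero; larger values mean stronger reorganization. Units with undefined
#' deltas (absent from the context) are excluded.
#'
#' @param cd a `context_delta`
#' @return non-negative scalar
#' @export
heterogeneity_index <- function(cd) {
  sum(abs(cd$mean_delta), na.rm = TRUE)
}

#' Aggregate per-region heterogeneity to patients
#'
#' Sums regional heterogeneity indices per patient,
#' \eqn{H_{patient} = \sum_{r \in patient} H_r}, and also reports the
#' per-region-normalized mean, which separates widespread from localized
#' divergence.
#'
#' @param h_region named numeric vector of per-region heterogeneity indices
#' @param region_to_patient data.frame with columns `region_id`,
#'   `patient`; every region must map to exactly one patient
#' @return data.frame `patient`, `n_regions`, `H_patient`, `H_normalized`
#' @export
aggregate_patients <- function(h_region, region_to_patient) {
  stopifnot(all(c("region_id", "patient") %in% names(region_to_patient)))
  if (anyDuplicated(region_to_patient$region_id)) {
    stop("a region maps to more than one patient", call. = FALSE)
  }
  unmapped <- setdiff(names(h_region), region_to_patient$region_id)
  if (length(unmapped) > 0L) {
    stop("unmapped region(s): ", paste(unmapped, collapse = ", "),
         call. = FALSE)
  }
  pat <- region_to_patient$patient[match(names(h_region),
                                         region_to_patient$region_id)]
  agg <- rowsum(as.numeric(h_region), pat)
  n_reg <- as.integer(base::table(pat)[rownames(agg)])
  data.frame(
    patient = rownames(agg),
    n_regions = n_reg,
    H_patient = as.numeric(agg),
    H_normalized = as.numeric(agg) / n_reg,
    row.names = NULL
  )
}

#' Context-specific compositional enrichment within a unit
#'
#' Within one organization unit, compares the cell-type composition of the
#' unit's cells inside a context against its global composition:
#' \deqn{E_{t,n}(c) = \log_2 \frac{p_{t,n}(c)}{p_{t,n}(global)}.}
#' When a type is absent from one of the groups the ratio is evaluated with
#' a pseudocount added to both proportions and flagged; otherwise the
#' ratio is exact. Types are annotated when they exceed 1% abundance in the
#' context AND change at least two-fold (`|E| >= 1`); `dot_size` carries the
#' context abundance for plotting.
#'
#' @param table a [cell_table()]
#' @param unit organization-unit name
#' @param labels per-cell unit labels aligned to `table` rows
#' @param context_col,context_level context defining the subset
#' @param pseudocount used only when a proportion is zero (default 1e-4)
#' @param min_abundance annotation abundance filter (default 0.01)
#' @param min_fold annotation |E| filter (default 1 = two-fold)
#' @return a `context_enrichment` list with `status` and, when ok,
#'   `enrichment`: data.frame `cell_type`, `p_context`, `p_global`, `E`,
#'   `annotated`, `zero_handled`, `dot_size`
#' @export
context_enrichment <- function(table, unit, labels, context_col,
                               context_level, pseudocount = 1e-4,
                               min_abundance = 0.01, min_fold = 1) {
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(table))
  in_unit <- labels == unit
  if (!any(in_unit)) stop("unit '", unit, "' has no cells", call. = FALSE)
  in_ctx <- in_unit & table[[context_col]] == context_level
  if (!any(in_ctx)) {
    return(structure(list(status = "empty", unit = unit,
                          context = paste0(context_col, "=", context_level),
                          enrichment = NULL),
                     class = "context_enrichment"))
  }
  types <- sort(unique(table$cell_type))
  prop <- function(sel) {
    tb <- base::table(factor(table$cell_type[sel], levels = types))
    as.numeric(tb) / sum(tb)
  }
  p_ctx <- prop(in_ctx)
  p_glob <- prop(in_unit)
  zero <- p_ctx == 0 | p_glob == 0
  E <- ifelse(zero,
              log2((p_ctx + pseudocount) / (p_glob + pseudocount)),
              log2(p_ctx / p_glob))
  structure(list(
    status = "ok",
    unit = unit,
    context = paste0(context_col, "=", context_level),
    n_context = sum(in_ctx),
    n_global = sum(in_unit),
    enrichment = data.frame(
      cell_type = types,
      p_context = p_ctx,
      p_global = p_glob,
      E = E,
      annotated = p_ctx > min_abundance & abs(E) >= min_fold,
      zero_handled = zero,
      dot_size = p_ctx
    )
  ), class = "context_enrichment")
}

#' Shannon entropy of a composition
#'
#' Compositional diversity of a unit's cell-type proportions,
#' \eqn{-\sum_t p_t \log p_t} with \eqn{0 \log 0 = 0}. Natural log by
#' default (maximum \eqn{\ln T} for T types, attained at the uniform
#' composition); base 2 available.
#'
#' @param composition non-negative proportions summing to 1 (within 1e-9)
#' @param base log base: `"e"` (default) or `"2"`
#' @return non-negative scalar
#' @export
neighborhood_entropy <- function(composition, base = c("e", "2")) {
  base <- match.arg(base)
  p <- as.numeric(composition)
  if (any(p < 0)) stop("negative proportion", call. = FALSE)
  if (abs(sum(p) - 1) > 1e-9) {
    stop("proportions must sum to 1 (got ", format(sum(p)), ")",
         call. = FALSE)
  }
  p <- p[p > 0]
  h <- -sum(p * log(p))
  if (base == "2") h <- h / log(2)
  h
}
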