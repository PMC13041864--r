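#' Run the analysis pipeline end to end
#'
#' Orchestrates the standard stage chain on a cell table: window features,
#' centroid fit, membership probabilities, then any requested analysis arm
#' (borders, interaction graph, transition gradient, heterogeneity,
#' resolution sweep). Stage outputs are plain CSV/JSON files in `out_dir`;
#' a JSON manifest records the fully resolved configuration, the seed and
#' the package version, so rerunning from the same manifest reproduces all
#' deterministic artifacts byte-for-byte. Stages are run in dependency
#' order; requesting a stage whose prerequisite artifact is neither
#' requested nor already on disk is an error naming the missing artifact.
#'
#' @param config list (or path to a JSON file) with entries:
#'   `input` (CSV path; ignored when `simulate` is requested), `schema`,
#'   `level` (default `"neighborhood"`), `count_level` (default
#'   `"cell_type"`), `k` (default 10), `max_radius` (default unbounded),
#'   `threshold` (default 0.25), `pair` (two unit names, for `gradient`),
#'   `bins` (5), `neighbors` (20), `clusters` (5), `gradient_k` (20),
#'   `context_col`, `n_min`/`n_max` (sweep range, default 1-50), `seed`
#'   (default 0), and `simulate` (a list of [tissue_spec()] arguments).
#' @param stages character subset of `c("simulate", "windows", "fit",
#'   "probs", "borders", "graph", "gradient", "heterogeneity", "resolve")`
#' @param out_dir output directory (created if absent)
#' @return invisibly, a list of written artifact paths (plus the manifest)
#' @export
run_pipeline <- function(config, stages, out_dir) {
  if (is.character(config) && length(config) == 1L) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
    # a run manifest wraps the resolved config; accept it directly so a run
    # can be reproduced from its own manifest
    if (!is.null(config$package) && !is.null(config$config)) {
      config <- config$config
    }
  }
  defaults <- list(level = "neighborhood", count_level = "cell_type",
                   k = 10L, max_radius = Inf, threshold = 0.25,
                   bins = 5L, neighbors = 20L, clusters = 5L,
                   gradient_k = 20L, n_min = 1L, n_max = 50L, seed = 0L)
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  if (identical(config$max_radius, "unbounded")) config$max_radius <- Inf
  all_stages <- c("simulate", "windows", "fit", "probs", "borders", "graph",
                  "gradient", "heterogeneity", "resolve")
  bad <- setdiff(stages, all_stages)
  if (length(bad) > 0L) {
    stop("unknown stage(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  stages <- all_stages[all_stages %in% stages]
  deps <- list(
    windows = character(), fit = "windows", probs = "fit",
    borders = "probs", graph = "borders", gradient = "probs",
    heterogeneity = "windows", resolve = "windows"
  )
  artifact <- function(stage) file.path(out_dir, paste0(stage, ".csv"))
  for (st in setdiff(stages, "simulate")) {
    for (dep in deps[[st]]) {
      if (!dep %in% stages && !file.exists(artifact(dep))) {
        stop("stage '", st, "' needs artifact '", basename(artifact(dep)),
             "' from stage '", dep, "', which was neither requested nor found",
             call. = FALSE)
      }
    }
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  note <- function(p) written <<- c(written, p)

  if ("simulate" %in% stages) {
    spec <- do.call(tissue_spec, c(config$simulate,
                                   list(seed = config$seed)))
    tb <- generate_tissue(spec)
    config$input <- file.path(out_dir, "cells.csv")
    write_cell_table(tb, config$input)
    note(config$input)
  }
  if (is.null(config$input) || !file.exists(config$input)) {
    stop("input cell table not found: ", config$input, call. = FALSE)
  }
  tb <- load_cell_table(config$input, schema = config$schema %||% list(),
                        label_levels = config$level,
                        contexts = config$context_col %||% character())

  state <- new.env(parent = emptyenv())
  get_fm <- function() {
    if (is.null(state$fm)) {
      state$fm <- knn_window_features(tb, k = config$k,
                                      count_level = config$count_level,
                                      max_radius = config$max_radius)
    }
    state$fm
  }
  get_M <- function() {
    if (is.null(state$M)) {
      model <- fit_centroids(get_fm(), tb[[config$level]])
      state$M <- membership_probabilities(log_likelihoods(get_fm(), model))
    }
    state$M
  }
  if ("windows" %in% stages) {
    fm <- get_fm()
    utils::write.csv(data.frame(cell_id = fm$cells, fm$counts,
                                check.names = FALSE),
                     artifact("windows"), row.names = FALSE)
    note(artifact("windows"))
  }
  if ("fit" %in% stages) {
    model <- fit_centroids(get_fm(), tb[[config$level]])
    utils::write.csv(data.frame(unit = model$units,
                                n_cells = model$n_cells_per_unit,
                                mean = model$mean, std = model$std,
                                check.names = FALSE),
                     artifact("fit"), row.names = FALSE)
    note(artifact("fit"))
  }
  if ("probs" %in% stages) {
    M <- get_M()
    utils::write.csv(data.frame(cell_id = M$cells, M$prob,
                                assigned_unit = M$assigned_unit,
                                assigned_prob = M$assigned_prob,
                                check.names = FALSE),
                     artifact("probs"), row.names = FALSE)
    note(artifact("probs"))
  }
  if ("borders" %in% stages) {
    b <- classify_borders(get_M(), config$threshold)
    utils::write.csv(data.frame(cell_id = b$cells, C = b$C,
                                is_border = b$is_border),
                     artifact("borders"), row.names = FALSE)
    state$borders <- b
    note(artifact("borders"))
  }
  if ("graph" %in% stages) {
    if (is.null(state$borders)) state$borders <- classify_borders(get_M(), config$threshold)
    g <- build_graph(state$borders)
    utils::write.csv(g$edges, artifact("graph"), row.names = FALSE)
    note(artifact("graph"))
  }
  if ("gradient" %in% stages) {
    if (is.null(config$pair) || length(config$pair) != 2L) {
      stop("stage 'gradient' needs config$pair = two unit names",
           call. = FALSE)
    }
    tp <- transition_profile(tb, get_M(), config$pair, bins = config$bins,
                             neighbors = config$neighbors,
                             clusters = config$clusters,
                             gradient_k = config$gradient_k,
                             seed = config$seed)
    sub <- which(!is.na(tp$bin_of_cell))
    percell <- data.frame(cell_id = tb$cell_id[sub],
                          score = tp$scores[sub],
                          bin = tp$bin_of_cell[sub],
                          cluster = as.integer(tp$cluster_of_cell),
                          G = as.numeric(tp$G))
    utils::write.csv(percell, artifact("gradient"), row.names = FALSE)
    jsonlite::write_json(
      list(pair = tp$pair, W = tp$cluster_order$W,
           cluster_mean_scores = tp$cluster_mean_scores,
           first_derivs = tp$derivatives$first_derivs,
           second_derivs = tp$derivatives$second_derivs,
           steepness = tp$derivatives$steepness,
           max_curvature = tp$derivatives$max_curvature),
      file.path(out_dir, "gradient_summary.json"),
      auto_unbox = TRUE, digits = NA)
    note(artifact("gradient")); note(file.path(out_dir, "gradient_summary.json"))
  }
  if ("heterogeneity" %in% stages) {
    if (is.null(config$context_col)) {
      stop("stage 'heterogeneity' needs config$context_col", call. = FALSE)
    }
    fm <- get_fm()
    levels_ <- sort(unique(tb[[config$context_col]]))
    rows <- lapply(levels_, function(lv) {
      cd <- context_delta(tb, fm, tb[[config$level]], config$context_col, lv)
      data.frame(context = lv, unit = cd$units, mean_delta = cd$mean_delta,
                 H = heterogeneity_index(cd), row.names = NULL)
    })
    utils::write.csv(do.call(rbind, rows), artifact("heterogeneity"),
                     row.names = FALSE)
    note(artifact("heterogeneity"))
  }
  if ("resolve" %in% stages) {
    sw <- sweep_resolutions(get_fm(), n_range = config$n_min:config$n_max,
                            seed = config$seed)
    choice <- select_resolution(sw)
    utils::write.csv(sw$summary, artifact("resolve"), row.names = FALSE)
    jsonlite::write_json(
      list(elbow_prob = choice$elbow_prob,
           elbow_loglik = choice$elbow_loglik,
           selected = choice$selected, fallback = choice$fallback,
           rationale = choice$rationale),
      file.path(out_dir, "resolve_choice.json"), auto_unbox = TRUE,
      digits = NA)
    note(artifact("resolve")); note(file.path(out_dir, "resolve_choice.json"))
  }
  manifest <- list(
    package = "nichemix",
    version = as.character(utils::packageVersion("nichemix")),
    stages = stages,
    config = config[!vapply(config, is.function, logical(1))],
    artifacts = basename(written)
  )
  manifest$config$max_radius <-
    if (is.finite(config$max_radius)) config$max_radius else "unbounded"
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  note(manifest_path)
  invisible(written)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
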