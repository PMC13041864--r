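#' Specify a synthetic annotated tissue
#'
#' Defines a seeded generative model of an annotated tissue with known
#' ground truth, emulating the structure of segmented spatial-omics cell
#' tables: one or more regions, spatially compact organization-unit domains
#' (parallel stripes, concentric rings, or Voronoi patches around scattered
#' centers), per-domain cell-type composition simplices, and logistic
#' mixing of compositions across domain interfaces. The region is a square
#' of side `sqrt(n_cells)` so the mean cell density is one cell per unit
#' area and the nearest-neighbor spacing d_NN is close to 1; cells sit on a
#' jittered grid, which avoids pathological co-located cells.
#'
#' @param geometry `"striped"` (vertical stripes), `"concentric"` (rings
#'   around the region center) or `"blobs"` (Voronoi domains of scattered
#'   centers)
#' @param n_cells cells per region
#' @param n_regions number of regions (independent placements, shared
#'   layout)
#' @param n_domains number of ground-truth organization units
#' @param compositions optional domains x types probability matrix (rows sum
#'   to 1). Default: signature-block compositions — the cell types are split
#'   evenly into one signature block per domain, and domain d up-weights its
#'   own block by `contrast` relative to the shared background, mirroring
#'   niches enriched for a set of marker types over a common background.
#' @param n_types number of cell types when `compositions` is NULL
#'   (default `max(12, 3 * n_domains)`, within the 10-50 range typical of
#'   multiplexed-imaging annotations)
#' @param contrast signature-block relative weight of the default
#'   compositions (default 8); a vector is recycled over domains, giving
#'   units of heterogeneous compositional distinctness
#' @param interface_width logistic mixing scale across domain interfaces,
#'   in the same length unit as the coordinates (d_NN is about 1);
#'   `interface_width -> 0` recovers hard interfaces.
#' @param aspect region width / height ratio (area stays `n_cells`);
#'   values below 1 elongate the region perpendicular to the stripes,
#'   lengthening the interfaces at constant density.
#' @param seed RNG seed; the same spec generates bit-identical tissue
#' @return a `tissue_spec` list
#' @export
tissue_spec <- function(geometry = c("striped", "concentric", "blobs"),
                        n_cells = 10000L, n_regions = 1L, n_domains = 2L,
                        compositions = NULL, n_types = NULL, contrast = 8,
                        interface_width = 1, aspect = 1, seed = 0L) {
  geometry <- match.arg(geometry)
  if (interface_width <= 0) stop("interface_width must be > 0", call. = FALSE)
  if (is.null(compositions)) {
    if (is.null(n_types)) n_types <- max(12L, 3L * n_domains)
    compositions <- default_compositions(n_domains, n_types, contrast)
  } else {
    compositions <- as.matrix(compositions)
    if (nrow(compositions) != n_domains) {
      stop("compositions must have one row per domain", call. = FALSE)
    }
    if (any(compositions < 0) ||
        any(abs(rowSums(compositions) - 1) > 1e-9)) {
      stop("composition rows must be probability simplices (sum 1 within 1e-9)",
           call. = FALSE)
    }
  }
  if (is.null(rownames(compositions))) {
    rownames(compositions) <- paste0("N", seq_len(n_domains))
  }
  if (is.null(colnames(compositions))) {
    colnames(compositions) <- paste0("T", seq_len(ncol(compositions)))
  }
  structure(list(
    geometry = geometry,
    n_cells = as.integer(n_cells),
    n_regions = as.integer(n_regions),
    n_domains = as.integer(n_domains),
    compositions = compositions,
    interface_width = interface_width,
    aspect = aspect,
    seed = as.integer(seed)
  ), class = "tissue_spec")
}

# Signature-block compositions: types are split evenly into one block per
# domain; domain d weights its own block `contrast`, all other types 1.
# `contrast` may be a vector (recycled over domains) to emulate tissues
# whose units differ in compositional distinctness.
default_compositions <- function(n_domains, n_types, contrast = 8) {
  stopifnot(n_types >= n_domains, all(contrast >= 1))
  contrast <- rep_len(contrast, n_domains)
  blocks <- split(seq_len(n_types), rep(seq_len(n_domains),
                                        length.out = n_types))
  comp <- matrix(1, n_domains, n_types)
  for (d in seq_len(n_domains)) comp[d, blocks[[d]]] <- contrast[d]
  comp <- comp / rowSums(comp)
  rownames(comp) <- paste0("N", seq_len(n_domains))
  colnames(comp) <- paste0("T", seq_len(n_types))
  comp
}

#' Generate a synthetic annotated tissue
#'
#' Realizes a [tissue_spec()]: cells are placed on a jittered grid within
#' each region, each cell's ground-truth domain follows from the geometry,
#' and its cell type is drawn from the mixture of domain compositions with
#' logistic weights of signed interface distance over `interface_width`.
#' The ground-truth domain is stored as the `"neighborhood"` label level —
#' it plays the role of the expert annotation the membership model
#' conditions on. Interface locations (for striped and concentric
#' geometries) are stored in the `interfaces` attribute;
#' [distance_to_interface()] reads them back.
#'
#' @param spec a [tissue_spec()]
#' @return a [cell_table()] with columns `cell_id`, `x`, `y`, `region_id`,
#'   `cell_type`, `neighborhood`, attribute `interfaces`, and the realized
#'   spec in attribute `tissue_spec`
#' @export
generate_tissue <- function(spec) {
  stopifnot(inherits(spec, "tissue_spec"))
  with_seed(spec$seed, {
    parts <- lapply(seq_len(spec$n_regions), function(rg) {
      generate_region(spec, sprintf("R%d", rg))
    })
  })
  df <- do.call(rbind, lapply(parts, `[[`, "cells"))
  interfaces <- do.call(rbind, lapply(parts, `[[`, "interfaces"))
  tb <- cell_table(df, label_levels = "neighborhood")
  attr(tb, "interfaces") <- interfaces
  attr(tb, "tissue_spec") <- spec
  tb
}

generate_region <- function(spec, region_id) {
  n <- spec$n_cells
  W <- sqrt(n * spec$aspect)
  H <- sqrt(n / spec$aspect)
  gx_n <- max(1L, round(W))
  gy_n <- ceiling(n / gx_n)
  sx <- W / gx_n
  sy <- H / gy_n
  slot <- sample.int(gx_n * gy_n, n)
  gx <- (slot - 1L) %% gx_n
  gy <- (slot - 1L) %/% gx_n
  x <- (gx + 0.5) * sx + stats::runif(n, -0.45, 0.45) * sx
  y <- (gy + 0.5) * sy + stats::runif(n, -0.45, 0.45) * sy
  D <- spec$n_domains
  w <- spec$interface_width
  comp <- spec$compositions
  if (spec$geometry == "striped") {
    bounds <- W * (0:D) / D
    domain_idx <- pmin(pmax(findInterval(x, bounds, rightmost.closed = TRUE),
                            1L), D)
    weights <- sapply(seq_len(D), function(d) {
      lo <- if (d == 1L) -Inf else bounds[d]
      hi <- if (d == D) Inf else bounds[d + 1L]
      stats::plogis((x - lo) / w) * stats::plogis((hi - x) / w)
    })
    interfaces <- data.frame(region_id = region_id, kind = "x",
                             position = bounds[2:D],
                             center_x = NA_real_, center_y = NA_real_)
  } else if (spec$geometry == "concentric") {
    cx <- W / 2; cy <- H / 2
    r <- sqrt((x - cx)^2 + (y - cy)^2)
    rmax <- min(W, H) / 2
    bounds <- rmax * (0:D) / D
    domain_idx <- pmin(pmax(findInterval(r, bounds, rightmost.closed = TRUE),
                            1L), D)
    weights <- sapply(seq_len(D), function(d) {
      lo <- if (d == 1L) -Inf else bounds[d]
      hi <- if (d == D) Inf else bounds[d + 1L]
      stats::plogis((r - lo) / w) * stats::plogis((hi - r) / w)
    })
    interfaces <- data.frame(region_id = region_id, kind = "r",
                             position = bounds[2:D],
                             center_x = cx, center_y = cy)
  } else { # blobs: Voronoi domains of jittered-grid centers
    cgx <- ceiling(sqrt(D))
    cgy <- ceiling(D / cgx)
    csx <- W / cgx
    csy <- H / cgy
    csel <- sample.int(cgx * cgy, D)
    ccx <- ((csel - 1L) %% cgx + 0.5) * csx + stats::runif(D, -0.2, 0.2) * csx
    ccy <- ((csel - 1L) %/% cgx + 0.5) * csy + stats::runif(D, -0.2, 0.2) * csy
    dmat <- sqrt(outer(x, ccx, "-")^2 + outer(y, ccy, "-")^2)
    domain_idx <- max.col(-dmat, ties.method = "first")
    dmin <- dmat[cbind(seq_len(n), domain_idx)]
    weights <- exp(-(dmat - dmin) / w)
    interfaces <- data.frame(region_id = character(), kind = character(),
                             position = numeric(), center_x = numeric(),
                             center_y = numeric())
  }
  weights <- weights / rowSums(weights)
  type_prob <- weights %*% comp
  cum <- type_prob %*% upper.tri(diag(ncol(comp)), diag = TRUE)
  cum <- cum / cum[, ncol(cum)]
  u <- stats::runif(n)
  type_idx <- 1L + rowSums(cum < u)
  cells <- data.frame(
    cell_id = sprintf("%s_%06d", region_id, seq_len(n)),
    x = x, y = y,
    region_id = region_id,
    cell_type = colnames(comp)[type_idx],
    neighborhood = rownames(comp)[domain_idx],
    stringsAsFactors = FALSE
  )
  list(cells = cells, interfaces = interfaces)
}

#' Distance of each cell to the nearest true domain interface
#'
#' Reads the `interfaces` attribute written by [generate_tissue()]
#' (striped: vertical lines; concentric: circles) and returns each cell's
#' Euclidean distance to the nearest one. Used to check that detected
#' border cells concentrate at true boundaries.
#'
#' @param table a generated [cell_table()]
#' @return per-cell numeric vector
#' @export
distance_to_interface <- function(table) {
  itf <- attr(table, "interfaces")
  if (is.null(itf) || nrow(itf) == 0L) {
    stop("table carries no interface ground truth", call. = FALSE)
  }
  out <- rep(Inf, nrow(table))
  for (r in unique(itf$region_id)) {
    rows <- which(table$region_id == r)
    sub <- itf[itf$region_id == r, , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      d <- if (sub$kind[i] == "x") {
        abs(table$x[rows] - sub$position[i])
      } else {
        abs(sqrt((table$x[rows] - sub$center_x[i])^2 +
                 (table$y[rows] - sub$center_y[i])^2) - sub$position[i])
      }
      out[rows] <- pmin(out[rows], d)
    }
  }
  out
}

#' Generate a multi-context cohort with targeted composition shifts
#'
#' Builds one tissue per context from a shared base spec (context-specific
#' seeds derived from the base seed), optionally perturbing the composition
#' of one named domain in chosen contexts: `delta` is added to the named
#' type's proportion and the other types are scaled down proportionally.
#' Regions and cell ids are prefixed by context so the bound table passes
#' validation.
#'
#' @param base a [tissue_spec()]
#' @param contexts character vector of context names (e.g. disease states)
#' @param shifts list of perturbations, each a list with `context`,
#'   `domain`, `type`, `delta` (absolute proportion shift)
#' @param context_col name of the context column (default `"condition"`)
#' @return a [cell_table()] with the context column registered as a context
#' @export
generate_context_cohort <- function(base, contexts, shifts = list(),
                                    context_col = "condition") {
  stopifnot(inherits(base, "tissue_spec"))
  for (sh in shifts) {
    if (!sh$context %in% contexts) {
      stop("shift targets unknown context: ", sh$context, call. = FALSE)
    }
    if (!sh$domain %in% rownames(base$compositions)) {
      stop("shift targets unknown domain: ", sh$domain, call. = FALSE)
    }
    if (!sh$type %in% colnames(base$compositions)) {
      stop("shift targets unknown cell type: ", sh$type, call. = FALSE)
    }
  }
  tables <- lapply(seq_along(contexts), function(i) {
    ctx <- contexts[i]
    spec_i <- base
    spec_i$seed <- base$seed + 7919L * i
    for (sh in shifts) {
      if (sh$context != ctx) next
      comp <- spec_i$compositions
      p0 <- comp[sh$domain, sh$type]
      p1 <- p0 + sh$delta
      if (p1 < 0 || p1 > 1) {
        stop("shift drives proportion outside [0, 1]", call. = FALSE)
      }
      others <- setdiff(colnames(comp), sh$type)
      comp[sh$domain, others] <- comp[sh$domain, others] *
        (1 - p1) / (1 - p0)
      comp[sh$domain, sh$type] <- p1
      spec_i$compositions <- comp
    }
    tb <- generate_tissue(spec_i)
    df <- as.data.frame(tb)
    df$cell_id <- paste0(ctx, "_", df$cell_id)
    df$region_id <- paste0(ctx, "_", df$region_id)
    df[[context_col]] <- ctx
    itf <- attr(tb, "interfaces")
    if (nrow(itf) > 0L) itf$region_id <- paste0(ctx, "_", itf$region_id)
    list(df = df, itf = itf)
  })
  df <- do.call(rbind, lapply(tables, `[[`, "df"))
  out <- cell_table(df, label_levels = "neighborhood", contexts = context_col)
  attr(out, "interfaces") <- do.call(rbind, lapply(tables, `[[`, "itf"))
  attr(out, "tissue_spec") <- base
  out
}
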