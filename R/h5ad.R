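#' Read a per-cell table from an annotated-matrix (h5ad) container
#'
#' Minimal reader for the standard anndata on-disk layout: per-cell
#' annotations are taken from `/obs` (plain and categorical columns are
#' decoded; the expression matrix `X` is ignored) and coordinates from a
#' 2-column spatial matrix in `/obsm`. Requires the `rhdf5` package.
#'
#' @param path path to an `.h5ad` file
#' @param spatial_key name of the `obsm` entry holding the n-cells x 2
#'   coordinate matrix (default `"spatial"`).
#' @param schema named mapping from canonical column roles (`region_id`,
#'   `cell_type`, level and context names) to `obs` column names, as in
#'   [load_cell_table()].
#' @param label_levels,contexts as in [load_cell_table()]
#' @return a [cell_table()]
#' @export
read_h5ad_cell_table <- function(path, spatial_key = "spatial",
                                 schema = list(), label_levels = NULL,
                                 contexts = character()) {
  if (!requireNamespace("rhdf5", quietly = TRUE)) {
    stop("read_h5ad_cell_table requires the 'rhdf5' package", call. = FALSE)
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  contents <- rhdf5::h5ls(path)
  obs_attrs <- rhdf5::h5readAttributes(path, "obs")
  index_name <- if (!is.null(obs_attrs[["_index"]])) obs_attrs[["_index"]] else "_index"
  obs_members <- contents$name[contents$group == "/obs"]
  obs_members <- setdiff(obs_members, "__categories")
  df <- list()
  for (m in obs_members) {
    obj_path <- paste0("obs/", m)
    is_group <- any(contents$group == paste0("/obs/", m))
    if (is_group) {
      members <- contents$name[contents$group == paste0("/obs/", m)]
      if (all(c("categories", "codes") %in% members)) {
        cats <- as.character(rhdf5::h5read(path, paste0(obj_path, "/categories")))
        codes <- as.integer(rhdf5::h5read(path, paste0(obj_path, "/codes")))
        v <- ifelse(codes < 0L, NA_character_, cats[codes + 1L])
        df[[m]] <- v
      }
    } else {
      v <- rhdf5::h5read(path, obj_path)
      if (is.array(v) && length(dim(v)) == 1L) v <- as.vector(v)
      if (is.raw(v)) v <- as.integer(v)
      df[[m]] <- v
    }
  }
  rhdf5::h5closeAll()
  n <- unique(vapply(df, length, integer(1)))
  if (length(n) != 1L) stop("inconsistent obs column lengths", call. = FALSE)
  out <- as.data.frame(df, stringsAsFactors = FALSE, check.names = FALSE)
  if (index_name %in% names(out) && !"cell_id" %in% names(out)) {
    names(out)[names(out) == index_name] <- "cell_id"
  }
  sp <- rhdf5::h5read(path, paste0("obsm/", spatial_key))
  rhdf5::h5closeAll()
  # HDF5 is row-major: a numpy (n, 2) array arrives as a 2 x n R matrix
  if (nrow(sp) == 2L && ncol(sp) == n) sp <- t(sp)
  if (ncol(sp) < 2L || nrow(sp) != n) {
    stop("obsm/", spatial_key, " is not an n x 2 coordinate matrix",
         call. = FALSE)
  }
  out$x <- as.numeric(sp[, 1L])
  out$y <- as.numeric(sp[, 2L])
  schema <- unlist(schema)
  for (canonical in names(schema)) {
    src <- schema[[canonical]]
    if (!src %in% names(out)) {
      stop("schema error: obs column '", src, "' (for '", canonical,
           "') not found", call. = FALSE)
    }
    names(out)[names(out) == src] <- canonical
  }
  if (is.null(label_levels)) {
    label_levels <- intersect(c("neighborhood", "community", "tissue_unit"),
                              names(out))
  }
  cell_table(out, label_levels = label_levels, contexts = contexts)
}
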