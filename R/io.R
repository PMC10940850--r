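# File formats: TSV/CSV view matrices (first column = entity id, header of
# feature names), edge-list TSV or MatrixMarket relationship files, YAML run
# configurations, and deterministic result writers. Entity order in the
# files defines the index order used by the relationship matrices.

file_sep <- function(path) if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"

#' Read a view matrix from TSV/CSV
#'
#' Expects a header row of feature names and a first column of entity ids.
#' Duplicate ids and non-numeric cells are rejected with the offending
#' location named in the error.
#'
#' @param path file path (`.tsv`/`.txt` tab-separated, `.csv` comma-separated).
#' @return a list with `ids` and the numeric matrix `X` (ids as row names).
#' @export
read_view_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = file_sep(path), header = TRUE,
                          colClasses = "character", check.names = FALSE)
  if (ncol(df) < 2) stop("view matrix needs an id column and at least one feature: ", path)
  ids <- df[[1]]
  if (anyDuplicated(ids))
    stop(sprintf("duplicate entity id '%s' in %s", ids[duplicated(ids)][1], path))
  feat <- as.matrix(df[, -1, drop = FALSE])
  X <- suppressWarnings(apply(feat, 2, as.numeric))
  if (!is.matrix(X)) X <- matrix(X, nrow = nrow(feat), dimnames = dimnames(feat))
  bad <- which(is.na(X) & !is.na(feat), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-numeric cell '%s' at row %d, column %d of %s",
                 feat[bad[1, 1], bad[1, 2]], bad[1, 1], bad[1, 2], path))
  }
  if (any(is.na(X)))
    stop(sprintf("missing value at row %d, column %d of %s",
                 which(is.na(X), arr.ind = TRUE)[1, 1],
                 which(is.na(X), arr.ind = TRUE)[1, 2], path))
  rownames(X) <- ids
  list(ids = ids, X = X)
}

#' Write a view matrix to TSV
#'
#' @param X numeric matrix with entity row names.
#' @param path output path.
#' @param id_col name of the id column.
#' @return `path`, invisibly.
#' @export
write_view_matrix <- function(X, path, id_col = "entity_id") {
  df <- data.frame(rownames(X), X, check.names = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a cross-view relationship block
#'
#' Two formats are supported. An edge-list TSV with header columns
#' `id_a`, `id_b` and optional `weight` (default 1): ids are resolved
#' against the supplied entity orders, unknown ids are an error, duplicate
#' edges are summed with a warning, negative weights are rejected. Or a
#' MatrixMarket coordinate file (`.mtx`), whose dimensions must match the
#' two views; the supplied id vectors act as the sidecar naming of rows and
#' columns.
#'
#' @param path edge-list TSV or `.mtx` file.
#' @param view_a_ids,view_b_ids entity ids of the two views, in matrix order.
#' @return a sparse `dgCMatrix` (rows = view a, columns = view b).
#' @export
read_relationships <- function(path, view_a_ids, view_b_ids) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    R <- methods::as(methods::as(Matrix::readMM(path), "generalMatrix"),
                     "CsparseMatrix")
    if (nrow(R) != length(view_a_ids) || ncol(R) != length(view_b_ids))
      stop(sprintf("relationship matrix is %d x %d but the views have %d and %d entities",
                   nrow(R), ncol(R), length(view_a_ids), length(view_b_ids)))
    if (any(R@x < 0)) stop("negative relationship weight in ", path)
    dimnames(R) <- list(view_a_ids, view_b_ids)
    return(Matrix::drop0(R))
  }
  df <- utils::read.delim(path, sep = file_sep(path), header = TRUE,
                          colClasses = "character", check.names = FALSE)
  if (ncol(df) < 2) stop("edge list needs columns id_a, id_b[, weight]: ", path)
  i <- match(df[[1]], view_a_ids)
  j <- match(df[[2]], view_b_ids)
  if (anyNA(i)) stop("unknown entity id '", df[[1]][which(is.na(i))[1]],
                     "' (first view) in ", path)
  if (anyNA(j)) stop("unknown entity id '", df[[2]][which(is.na(j))[1]],
                     "' (second view) in ", path)
  w <- if (ncol(df) >= 3) suppressWarnings(as.numeric(df[[3]])) else rep(1, nrow(df))
  if (anyNA(w)) stop("non-numeric weight in ", path)
  if (any(w < 0)) stop("negative relationship weight in ", path)
  if (anyDuplicated(cbind(i, j)))
    warning("duplicate edges in ", path, "; their weights were summed")
  R <- Matrix::sparseMatrix(i = i, j = j, x = w,
                            dims = c(length(view_a_ids), length(view_b_ids)),
                            dimnames = list(view_a_ids, view_b_ids))
  Matrix::drop0(R)
}

#' Write relationships as an edge-list TSV
#'
#' @param R sparse relationship matrix with dimnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_relationships <- function(R, path) {
  tr <- Matrix::mat2triplet(methods::as(methods::as(Matrix::Matrix(R, sparse = TRUE),
                                                    "generalMatrix"), "CsparseMatrix"))
  df <- data.frame(id_a = rownames(R)[tr$i], id_b = colnames(R)[tr$j],
                   weight = tr$x)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the results of a fit to a directory
#'
#' Emits, deterministically given the fit: one `assignments_<view>.tsv` per
#' view (entity_id, cluster), `phi.tsv`, `matchings.tsv`, one affinity-map
#' TSV per coupled pair when `data`/`relations` are supplied, and
#' `run_summary.json` holding the configuration, seeds, objective trace and
#' per-restart objectives.
#'
#' @param fit a `bmvc_fit`.
#' @param outdir output directory (created if needed).
#' @param data,relations optional originals used to compute affinity maps.
#' @return invisibly, the vector of files written.
#' @export
write_results <- function(fit, outdir, data = NULL, relations = NULL) {
  stopifnot(inherits(fit, "bmvc_fit"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (v in seq_along(fit$state$z)) {
    f <- file.path(outdir, sprintf("assignments_%s.tsv", fit$view_names[v]))
    utils::write.table(data.frame(entity_id = fit$entity_ids[[v]],
                                  cluster = fit$state$z[[v]]),
                       f, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, f)
  }
  f <- file.path(outdir, "phi.tsv")
  utils::write.table(data.frame(pair = fit$pair_names %||% character(0),
                                phi = as.numeric(fit$state$phi)),
                     f, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, f)
  if (length(fit$state$C)) {
    md <- do.call(rbind, lapply(seq_along(fit$state$C), function(p)
      data.frame(pair = fit$pair_names[p],
                 cluster = seq_along(fit$state$C[[p]]),
                 matched_cluster = fit$state$C[[p]])))
    f <- file.path(outdir, "matchings.tsv")
    utils::write.table(md, f, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, f)
  }
  if (!is.null(data) && !is.null(relations)) {
    pairs <- compile_relations(relations, view_sizes(data), view_names(data))
    for (p in seq_along(pairs)) {
      pr <- pairs[[p]]
      R <- Matrix::sparseMatrix(i = pr$ti, j = pr$tj, x = pr$tw,
                                dims = c(pr$Nv, pr$Nu))
      am <- affinity_map(fit$state$z[[pr$v]], fit$state$z[[pr$u]], R,
                         K_v = length(fit$state$pi[[pr$v]]),
                         K_u = length(fit$state$pi[[pr$u]]),
                         matching = fit$state$C[[p]])
      f <- file.path(outdir, sprintf("affinity_%s.tsv", gsub(":", "_", pr$name)))
      utils::write.table(am$scores, f, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
      files <- c(files, f)
    }
  }
  summary <- list(
    package_version = as.character(utils::packageVersion("bmvc")),
    mode = fit$mode,
    objective = fit$objective,
    best_restart = fit$best_restart,
    seeds = fit$seeds,
    restart_objectives = fit$restarts$objective,
    converged = fit$converged,
    trace = fit$trace,
    phi = as.list(fit$state$phi),
    config = fit$config[setdiff(names(fit$config), c("priors", "init_labels"))],
    priors = unclass(fit$config$priors))
  f <- file.path(outdir, "run_summary.json")
  jsonlite::write_json(summary, f, auto_unbox = TRUE, digits = NA, null = "null")
  files <- c(files, f)
  invisible(files)
}

#' Read a YAML run configuration
#'
#' The configuration lists the view matrix files, the relationship files and
#' the fitting options:
#' ```yaml
#' views: {expr: expr.tsv, meth: meth.tsv}
#' relations:
#'   - {a: expr, b: meth, file: edges.tsv}
#' fit: {K: 4, seed: 1, restarts: 10, mode: pseudo}
#' ```
#'
#' @param path YAML file.
#' @return a list with `data` ([mv_dataset]), `relations` ([mv_relations])
#'   and `fit` (a [bmvc_config]).
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$views) || length(cfg$views) < 1)
    stop("run configuration must list at least one view")
  base <- dirname(path)
  resolve <- function(f) if (file.exists(f)) f else file.path(base, f)
  views <- lapply(cfg$views, function(f) read_view_matrix(resolve(f))$X)
  data <- mv_dataset(views)
  blocks <- lapply(cfg$relations %||% list(), function(r) {
    stopifnot(!is.null(r$a), !is.null(r$b), !is.null(r$file))
    R <- read_relationships(resolve(r$file),
                            data$views[[r$a]]$ids, data$views[[r$b]]$ids)
    relation_block(r$a, r$b, R)
  })
  fit_args <- cfg$fit %||% list(K = 2)
  list(data = data, relations = mv_relations(blocks),
       fit = do.call(bmvc_config, fit_args))
}
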