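#' Read omics views from delimited files onto one patient ordering
#'
#' Each file holds one view as a delimited matrix: a header row of feature
#' IDs, a first column of patient IDs, rows = patients, columns = features.
#' Patients are aligned across views: the canonical ordering is the first
#' view's patient order restricted to the IDs present in every view.
#' Patients absent from any view are dropped with a warning
#' (complete-case integration).
#'
#' @param paths Character vector of file paths, one per view.
#' @param delimiter Field delimiter, default tab.
#' @param names Optional view names; defaults to file base names.
#' @return A named list of view tibbles (`patient_id` + numeric feature
#'   columns), all with identical patient ordering.
#' @export
read_views <- function(paths, delimiter = "\t", names = NULL) {
  stopifnot(length(paths) >= 1L)
  if (is.null(names)) {
    names <- tools::file_path_sans_ext(basename(paths))
  }
  stopifnot(length(names) == length(paths))
  mats <- lapply(seq_along(paths), function(i) read_view_matrix(paths[i], delimiter))
  id_sets <- lapply(mats, rownames)
  shared <- Reduce(intersect, id_sets)
  canonical <- id_sets[[1L]][id_sets[[1L]] %in% shared]
  if (length(canonical) == 0L) {
    stop("no patient IDs shared by all views", call. = FALSE)
  }
  n_drop <- sum(vapply(id_sets, function(s) sum(!s %in% shared), integer(1)))
  if (n_drop > 0L) {
    warning(n_drop, " patient record(s) absent from some view(s) were dropped; ",
            length(canonical), " shared patients retained", call. = FALSE)
  }
  views <- lapply(mats, function(m) {
    m <- m[canonical, , drop = FALSE]
    check_view(m)
    view_tibble(m)
  })
  stats::setNames(views, names)
}

# Strict numeric reader: any cell that does not parse as a finite number is
# fatal and named by file, patient row and feature column.
read_view_matrix <- function(path, delimiter) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, sep = delimiter, header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop(path, ": expected an ID column plus feature columns", call. = FALSE)
  ids <- raw[[1L]]
  feat_names <- colnames(raw)[-1L]
  vals <- suppressWarnings(
    vapply(raw[-1L], function(col) as.numeric(col), numeric(nrow(raw)))
  )
  if (nrow(raw) == 1L) vals <- matrix(vals, nrow = 1L)
  bad <- which(!is.finite(vals), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    r <- bad[1L, 1L]; c <- bad[1L, 2L]
    stop("non-numeric cell in ", path, ": row '", ids[r], "', column '",
         feat_names[c], "' (value '", raw[r, c + 1L], "')", call. = FALSE)
  }
  dimnames(vals) <- list(ids, feat_names)
  if (anyDuplicated(ids)) stop(path, ": duplicated patient IDs", call. = FALSE)
  vals
}

#' Write omics views as delimited files
#'
#' Inverse of [read_views()]: one file per view, header of feature IDs,
#' first column `patient_id`. Values are written at full precision so that
#' a read/write round trip is exact.
#'
#' @param views Named list of view tibbles (or matrices with row names).
#' @param dir Output directory (created if missing).
#' @param delimiter Field delimiter, default tab.
#' @return Invisibly, the paths written.
#' @export
write_views <- function(views, dir, delimiter = "\t") {
  stopifnot(is.list(views), length(views) >= 1L, !is.null(names(views)))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(names(views), function(nm) {
    m <- as_view_matrix(views[[nm]], nm)
    path <- file.path(dir, paste0(nm, ".tsv"))
    # 17 significant digits: doubles survive the text round trip exactly
    chr <- matrix(sprintf("%.17g", m), nrow(m), ncol(m),
                  dimnames = dimnames(m))
    df <- data.frame(patient_id = rownames(m), chr, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = delimiter, quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    path
  }, character(1))
  invisible(paths)
}

#' Read a survival table
#'
#' Three-column delimited file: `patient_id`, `time_days` (non-negative
#' follow-up time), `event` (1 = death/event observed, 0 = censored).
#'
#' @param path File path.
#' @param delimiter Field delimiter, default tab.
#' @return A tibble with columns `patient_id`, `time_days`, `event`.
#' @export
read_survival <- function(path, delimiter = "\t") {
  df <- utils::read.delim(path, sep = delimiter, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop(path, ": expected columns patient_id, time_days, event", call. = FALSE)
  out <- tibble::tibble(
    patient_id = as.character(df[[1L]]),
    time_days = as.numeric(df[[2L]]),
    event = as.integer(df[[3L]])
  )
  validate_survival(out)
  out
}

#' @keywords internal
validate_survival <- function(surv) {
  stopifnot(all(c("patient_id", "time_days", "event") %in% names(surv)))
  if (anyDuplicated(surv$patient_id)) stop("survival table: duplicated patient IDs", call. = FALSE)
  if (anyNA(surv$time_days) || any(surv$time_days < 0)) {
    stop("survival table: times must be non-negative", call. = FALSE)
  }
  if (!all(surv$event %in% c(0L, 1L))) stop("survival table: event must be 0 or 1", call. = FALSE)
  invisible(surv)
}

#' Write subgroup assignments (plus a metrics sidecar)
#'
#' Writes a delimited file with columns `patient_id` and `subgroup`
#' (1-based integers). Any scalar diagnostics attached to the result
#' (subgroup count, within-cluster sum of squares, mean silhouette) go to a
#' key-value sidecar file next to it.
#'
#' @param result A `subgroup_result` (from [kmeans_cluster()] or a pipeline
#'   fit's `$result`), or a data frame with `patient_id` and `subgroup`.
#' @param path Output path for the assignment table.
#' @param metrics_path Sidecar path; default `<path>.metrics.tsv`. `NULL`
#'   suppresses the sidecar.
#' @param delimiter Field delimiter, default tab.
#' @return Invisibly, `path`.
#' @export
write_subgroups <- function(result, path,
                            metrics_path = paste0(path, ".metrics.tsv"),
                            delimiter = "\t") {
  tbl <- if (inherits(result, "subgroup_result")) result$subgroups else tibble::as_tibble(result)
  stopifnot(all(c("patient_id", "subgroup") %in% names(tbl)))
  if (nrow(tbl) == 0L) stop("empty result: no patients to write", call. = FALSE)
  utils::write.table(tbl[, c("patient_id", "subgroup")], path, sep = delimiter,
                     quote = FALSE, row.names = FALSE, col.names = TRUE)
  if (!is.null(metrics_path) && inherits(result, "subgroup_result")) {
    kv <- data.frame(
      key = c("n_clusters", "inertia", "silhouette"),
      value = c(result$n_clusters, result$inertia, result$silhouette)
    )
    utils::write.table(kv, metrics_path, sep = delimiter, quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  }
  invisible(path)
}

#' Read subgroup assignments written by [write_subgroups()]
#' @param path File path.
#' @param delimiter Field delimiter, default tab.
#' @return Tibble with `patient_id` (character) and `subgroup` (integer).
#' @export
read_subgroups <- function(path, delimiter = "\t") {
  df <- utils::read.delim(path, sep = delimiter, header = TRUE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop(path, ": expected an ID column and a label column", call. = FALSE)
  # accept any label column name (e.g. `subgroup`, `cluster`)
  tibble::tibble(patient_id = as.character(df[[1L]]),
                 subgroup = as.integer(df[[2L]]))
}

#' Read a flat YAML configuration file
#'
#' Keys mirror the pipeline arguments (`variance_threshold`, `n_neighbors`,
#' `kernel_bandwidth`, `n_clusters`, `embed_dim`, `kmeans_restarts`,
#' `random_seed`). Unknown keys are rejected so typos fail loudly.
#'
#' @param path YAML file path.
#' @return Named list of configuration values.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  allowed <- c("variance_threshold", "n_neighbors", "kernel_bandwidth",
               "n_clusters", "embed_dim", "kmeans_restarts", "random_seed")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown) > 0L) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  cfg
}
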