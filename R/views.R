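#' Coerce an omics view to a numeric patient-by-feature matrix
#'
#' Views travel through the package as tibbles whose first column (named
#' `patient_id`) holds patient identifiers and whose remaining columns are
#' numeric features, one row per patient. This helper accepts that layout or
#' an already-built numeric matrix with patient IDs as row names.
#'
#' @param x A data frame with a `patient_id` first column, or a numeric
#'   matrix with row names.
#' @param what Label used in error messages.
#' @return A numeric matrix, patients in rows (row names = patient IDs),
#'   features in columns.
#' @keywords internal
as_view_matrix <- function(x, what = "view") {
  if (is.matrix(x)) {
    if (!is.numeric(x)) stop(what, " matrix must be numeric", call. = FALSE)
    if (is.null(rownames(x))) stop(what, " matrix must have patient IDs as row names", call. = FALSE)
    return(x)
  }
  if (!is.data.frame(x)) {
    stop(what, " must be a data frame or a numeric matrix", call. = FALSE)
  }
  id_col <- if ("patient_id" %in% names(x)) "patient_id" else names(x)[1L]
  ids <- as.character(x[[id_col]])
  feat <- x[setdiff(names(x), id_col)]
  if (ncol(feat) < 1L) stop(what, " has no feature columns", call. = FALSE)
  bad <- names(feat)[!vapply(feat, is.numeric, logical(1))]
  if (length(bad) > 0L) {
    stop(what, " has non-numeric feature column(s): ",
         paste(utils::head(bad, 3L), collapse = ", "), call. = FALSE)
  }
  m <- as.matrix(feat)
  rownames(m) <- ids
  m
}

#' @keywords internal
view_tibble <- function(m) {
  tibble::as_tibble(as.data.frame(m), .name_repair = "minimal") |>
    tibble::add_column(patient_id = rownames(m), .before = 1L)
}

#' @keywords internal
check_view <- function(m, what = "view") {
  ids <- rownames(m)
  if (anyNA(ids) || any(ids == "")) stop(what, ": missing patient IDs", call. = FALSE)
  if (anyDuplicated(ids)) stop(what, ": duplicated patient IDs", call. = FALSE)
  if (nrow(m) < 2L) stop(what, ": need at least 2 patients", call. = FALSE)
  if (!all(is.finite(m))) {
    idx <- which(!is.finite(m), arr.ind = TRUE)[1L, ]
    stop(what, ": non-finite value at patient '", rownames(m)[idx[1L]],
         "', feature '", colnames(m)[idx[2L]], "'", call. = FALSE)
  }
  invisible(m)
}

#' Extract the shared patient IDs of a set of objects
#' @keywords internal
patient_ids_of <- function(x) {
  if (is.matrix(x)) return(rownames(x))
  if (is.data.frame(x)) {
    id_col <- if ("patient_id" %in% names(x)) "patient_id" else names(x)[1L]
    return(as.character(x[[id_col]]))
  }
  if (!is.null(x$patient_ids)) return(x$patient_ids)
  stop("cannot determine patient IDs", call. = FALSE)
}
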