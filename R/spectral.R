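#' Symmetric normalized graph Laplacian
#'
#' \eqn{L = D^{-1/2} (D - \tilde W) D^{-1/2}} for a symmetric non-negative
#' adjacency \eqn{\tilde W} with zero diagonal, where D is the diagonal
#' degree matrix of row sums. L is symmetric positive-semidefinite with
#' eigenvalues in [0, 2]; the number of zero eigenvalues equals the number
#' of connected components.
#'
#' @param w A `patient_graph` or a symmetric non-negative matrix with zero
#'   diagonal (the kNN-sparsified similarity).
#' @return N x N symmetric Laplacian matrix.
#' @export
normalized_laplacian <- function(w) {
  if (inherits(w, "patient_graph")) w <- w$knn_similarity
  stopifnot(is.matrix(w), nrow(w) == ncol(w))
  if (any(w < 0)) stop("adjacency must be non-negative", call. = FALSE)
  if (max(abs(w - t(w))) > 1e-10) stop("adjacency must be symmetric", call. = FALSE)
  wd <- w
  diag(wd) <- 0
  deg <- rowSums(wd)
  if (any(deg <= 0)) {
    iso <- rownames(wd)[deg <= 0]
    if (is.null(iso)) iso <- as.character(which(deg <= 0))
    stop("isolated patient(s) with zero graph degree: ",
         paste(utils::head(iso, 5L), collapse = ", "),
         "; increase n_neighbors or the kernel bandwidth", call. = FALSE)
  }
  dhalf <- 1 / sqrt(deg)
  l <- -wd * tcrossprod(dhalf)
  diag(l) <- 1
  l <- (l + t(l)) / 2
  dimnames(l) <- dimnames(w)
  l
}

#' Spectral embedding: smallest-k eigenvectors of the Laplacian
#'
#' Solves \eqn{\min_U tr(U^T L U)} subject to \eqn{U^T U = I}; by
#' Rayleigh-Ritz the optimum is the orthonormal basis of eigenvectors
#' belonging to the k smallest eigenvalues, and the attained objective is
#' their sum. The embedding is a point on the Grassmann manifold G(k, N):
#' only the column span matters downstream, but for reproducibility each
#' eigenvector's largest-magnitude entry is made positive. A tie between
#' the k-th and (k+1)-th eigenvalue makes the subspace non-unique; this is
#' reported with a warning.
#'
#' @param l Laplacian matrix (from [normalized_laplacian()]), or a
#'   `patient_graph` (the Laplacian is computed first).
#' @param k Embedding dimension, in `[1, N-1]`. The standard choice is the
#'   number of clusters sought.
#' @param source Label for the originating view (default `"view"`).
#' @return An object of class `subspace_embedding`: `patient_ids`, `basis`
#'   (N x k, orthonormal columns), `eigenvalues` (the k smallest),
#'   `source`.
#' @export
spectral_embed <- function(l, k, source = "view") {
  if (inherits(l, "patient_graph")) {
    if (is.null(source) || identical(source, "view")) source <- l$name %||% "view"
    l <- normalized_laplacian(l)
  }
  stopifnot(is.matrix(l), nrow(l) == ncol(l))
  n <- nrow(l)
  stopifnot(k >= 1L, k <= n - 1L)
  e <- tryCatch(eigen(l, symmetric = TRUE),
                error = function(err) {
                  stop("eigendecomposition failed (N = ", n,
                       ", |L|_max = ", signif(max(abs(l)), 3), "): ",
                       conditionMessage(err), call. = FALSE)
                })
  # eigen() returns decreasing order; the k smallest are the last k columns
  ord <- seq(n, n - k + 1L)
  vals <- e$values[ord]
  vecs <- e$vectors[, ord, drop = FALSE]
  if (k < n && abs(e$values[n - k] - vals[k]) < 1e-10) {
    warning("eigenvalue tie at the embedding cut-off (k = ", k,
            "); the spectral subspace is not unique", call. = FALSE)
  }
  new_subspace_embedding(fix_signs(vecs), rownames(l), vals, source)
}

#' @keywords internal
new_subspace_embedding <- function(basis, patient_ids, eigenvalues = NULL,
                                   source = "view") {
  rownames(basis) <- patient_ids
  colnames(basis) <- paste0("dim", seq_len(ncol(basis)))
  structure(
    list(patient_ids = patient_ids, basis = basis,
         eigenvalues = eigenvalues, source = source),
    class = "subspace_embedding"
  )
}

#' @keywords internal
fix_signs <- function(u) {
  for (j in seq_len(ncol(u))) {
    i_max <- which.max(abs(u[, j]))
    if (u[i_max, j] < 0) u[, j] <- -u[, j]
  }
  u
}

#' @export
print.subspace_embedding <- function(x, ...) {
  cat("<subspace_embedding '", x$source, "'> ", nrow(x$basis), " patients, k = ",
      ncol(x$basis), "\n", sep = "")
  invisible(x)
}

#' @describeIn spectral_embed Embedding coordinates as a tibble
#'   (`patient_id` + one column per dimension).
#' @param x A `subspace_embedding`.
#' @param ... Unused.
#' @export
tidy.subspace_embedding <- function(x, ...) {
  view_tibble(x$basis)
}

#' @keywords internal
embedding_basis <- function(x, what = "embedding") {
  if (inherits(x, "subspace_embedding")) return(x$basis)
  if (is.matrix(x)) return(x)
  stop(what, " must be a subspace_embedding or a matrix", call. = FALSE)
}
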