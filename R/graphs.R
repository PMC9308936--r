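#' Gaussian-kernel patient similarity matrix
#'
#' Dense similarity between patients i and j in the reduced (PCA) space:
#' \eqn{W_{ij} = \exp(-\|H_i - H_j\|^2 / (2 t^2))}, a value in (0, 1] with
#' unit diagonal. The bandwidth t sets how fast similarity decays with
#' distance; `"auto"` uses the median off-diagonal pairwise Euclidean
#' distance, a scale-equivariant self-tuning choice.
#'
#' @param rep A `pca_view`, or a numeric patient-by-coordinate matrix with
#'   patient IDs as row names.
#' @param bandwidth Positive numeric, or `"auto"` (default).
#' @return N x N symmetric similarity matrix with unit diagonal; the chosen
#'   bandwidth is attached as attribute `"bandwidth"`.
#' @export
gaussian_similarity <- function(rep, bandwidth = "auto") {
  h <- if (inherits(rep, "pca_view")) rep$scores else as_view_matrix(rep, "representation")
  if (nrow(h) < 2L) stop("need at least 2 patients", call. = FALSE)
  d <- as.matrix(stats::dist(h))
  if (identical(bandwidth, "auto")) {
    bandwidth <- stats::median(d[upper.tri(d)])
    if (!is.finite(bandwidth) || bandwidth <= 0) {
      stop("automatic bandwidth failed: median pairwise distance is 0 ",
           "(all patients identical); supply a positive numeric bandwidth",
           call. = FALSE)
    }
  }
  stopifnot(is.numeric(bandwidth), length(bandwidth) == 1L, bandwidth > 0)
  w <- exp(-d^2 / (2 * bandwidth^2))
  w <- (w + t(w)) / 2
  diag(w) <- 1
  dimnames(w) <- list(rownames(h), rownames(h))
  attr(w, "bandwidth") <- bandwidth
  w
}

#' Sparsify a similarity matrix to a k-nearest-neighbour graph
#'
#' For each patient the `n_neighbors` most similar other patients are
#' retained (self excluded); everything else is zeroed. Ties at the k-th
#' rank are all kept, so the result does not depend on how equal
#' similarities happen to be ordered. The matrix is then symmetrized by the
#' union rule \eqn{\tilde W \leftarrow \max(\tilde W, \tilde W^T)}, which
#' keeps the graph connected at small k. Retained entries equal the
#' original similarities; the diagonal is set to 0 (degrees count
#' neighbours only).
#'
#' @param w Symmetric similarity matrix (e.g. from
#'   [gaussian_similarity()]).
#' @param n_neighbors Number of neighbours per patient, in `[1, N-1]`, or
#'   `"auto"` for `round(sqrt(N))` clipped to `[2, N-1]`.
#' @return Sparsified symmetric matrix with zero diagonal.
#' @export
knn_sparsify <- function(w, n_neighbors = "auto") {
  stopifnot(is.matrix(w), nrow(w) == ncol(w))
  n <- nrow(w)
  if (identical(n_neighbors, "auto")) n_neighbors <- auto_neighbors(n)
  stopifnot(is.numeric(n_neighbors), length(n_neighbors) == 1L)
  n_neighbors <- as.integer(n_neighbors)
  if (n_neighbors < 1L || n_neighbors > n - 1L) {
    stop("n_neighbors must be between 1 and N-1 (= ", n - 1L, ")", call. = FALSE)
  }
  keep <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    s <- w[i, ]
    s[i] <- -Inf
    kth <- sort(s, decreasing = TRUE)[n_neighbors]
    keep[i, ] <- s >= kth   # ties at the k-th rank all retained
  }
  keep <- keep | t(keep)    # union symmetrization
  wt <- ifelse(keep, w, 0)
  diag(wt) <- 0
  dimnames(wt) <- dimnames(w)
  attr(wt, "n_neighbors") <- n_neighbors
  wt
}

#' @keywords internal
auto_neighbors <- function(n) {
  max(2L, min(n - 1L, as.integer(round(sqrt(n)))))
}

#' Build the per-view patient graph (dense + kNN-sparsified similarity)
#'
#' Convenience wrapper chaining [gaussian_similarity()] and
#' [knn_sparsify()].
#'
#' @inheritParams gaussian_similarity
#' @inheritParams knn_sparsify
#' @param name Optional view name carried along for reporting.
#' @return An object of class `patient_graph` with elements `patient_ids`,
#'   `dense_similarity`, `knn_similarity`, `bandwidth`, `n_neighbors`,
#'   `name`.
#' @export
patient_graph <- function(rep, bandwidth = "auto", n_neighbors = "auto",
                          name = NULL) {
  w <- gaussian_similarity(rep, bandwidth)
  wt <- knn_sparsify(w, n_neighbors)
  structure(
    list(patient_ids = rownames(w), dense_similarity = w,
         knn_similarity = wt, bandwidth = attr(w, "bandwidth"),
         n_neighbors = attr(wt, "n_neighbors"), name = name),
    class = "patient_graph"
  )
}

#' @export
print.patient_graph <- function(x, ...) {
  cat("<patient_graph", if (!is.null(x$name)) paste0(" '", x$name, "'"), "> ",
      length(x$patient_ids), " patients, k = ", x$n_neighbors,
      ", bandwidth = ", signif(x$bandwidth, 4), "\n", sep = "")
  invisible(x)
}

#' Weighted edge list of a patient graph
#'
#' One row per undirected edge of the kNN-sparsified graph, for export to
#' external network viewers.
#'
#' @param graph A `patient_graph`, or a symmetric similarity matrix.
#' @return Tibble with columns `patient_a`, `patient_b`, `weight`.
#' @export
graph_edges <- function(graph) {
  w <- if (inherits(graph, "patient_graph")) graph$knn_similarity else graph
  stopifnot(is.matrix(w))
  ids <- rownames(w)
  idx <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  tibble::tibble(
    patient_a = ids[idx[, 1L]],
    patient_b = ids[idx[, 2L]],
    weight = w[idx]
  )
}
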