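#' Squared projection distance between two subspaces
#'
#' Grassmann projection distance between the column spans of two N x k
#' orthonormal bases Y and \eqn{\tilde Y}:
#' \deqn{d^2_{proj}(Y, \tilde Y) = \sum_{i=1}^k \sin^2 \Theta_i
#'   = k - tr(Y Y^T \tilde Y \tilde Y^T),}
#' where \eqn{\Theta_i} are the principal angles between the subspaces. It
#' is symmetric, lies in [0, k], vanishes iff the subspaces coincide, and
#' equals k when they are orthogonal. Basis choice within each subspace is
#' irrelevant.
#'
#' @param y,ytilde `subspace_embedding` objects or N x k matrices with
#'   orthonormal columns.
#' @return Non-negative scalar in [0, k].
#' @export
projection_distance <- function(y, ytilde) {
  a <- embedding_basis(y, "y")
  b <- embedding_basis(ytilde, "ytilde")
  if (!all(dim(a) == dim(b))) {
    stop("subspaces must have the same N and k (got ",
         paste(dim(a), collapse = "x"), " vs ",
         paste(dim(b), collapse = "x"), ")", call. = FALSE)
  }
  k <- ncol(a)
  # tr(YY' ỸỸ') = ||Y'Ỹ||_F^2
  d2 <- k - sum(crossprod(a, b)^2)
  max(d2, 0)
}

#' Fuse per-view spectral embeddings on the Grassmann manifold
#'
#' Finds the single k-dimensional subspace U closest to all M per-view
#' subspaces in summed squared projection distance:
#' \deqn{\min_{U^T U = I} -\sum_m tr(U U^T U^{(m)} U^{(m)T}).}
#' The closed-form solution is the k leading eigenvectors of the modified
#' Laplacian \eqn{L_{mod} = \sum_m w_m U^{(m)} U^{(m)T}}, a sum of per-view
#' projection matrices (Ky Fan theorem). All views are weighted equally by
#' default.
#'
#' @param embeddings List of `subspace_embedding` objects (or N x k
#'   orthonormal matrices) sharing patient IDs and k.
#' @param weights Optional non-negative per-view weights, default all 1.
#' @return An object of class `grassmann_fusion`: `fused` (a
#'   `subspace_embedding` with source `"fused"`), `l_mod`,
#'   `per_view_distance` (named vector of \eqn{d^2_{proj}} from the fused
#'   subspace to each view), `eigenvalues` (all eigenvalues of `l_mod`),
#'   `objective` (\eqn{\sum_m tr(UU^T U^{(m)}U^{(m)T})}).
#' @export
fuse_subspaces <- function(embeddings, weights = NULL) {
  stopifnot(is.list(embeddings), length(embeddings) >= 1L)
  m_views <- length(embeddings)
  bases <- lapply(embeddings, embedding_basis)
  n <- nrow(bases[[1L]])
  k <- ncol(bases[[1L]])
  ids <- rownames(bases[[1L]])
  for (i in seq_along(bases)) {
    if (!all(dim(bases[[i]]) == c(n, k))) {
      stop("all embeddings must share N and k", call. = FALSE)
    }
    ids_i <- rownames(bases[[i]])
    if (!is.null(ids) && !is.null(ids_i) && !identical(ids, ids_i)) {
      stop("embeddings have inconsistent patient orderings", call. = FALSE)
    }
  }
  if (is.null(weights)) weights <- rep(1, m_views)
  stopifnot(length(weights) == m_views, all(weights >= 0))

  l_mod <- matrix(0, n, n)
  for (i in seq_along(bases)) {
    l_mod <- l_mod + weights[i] * tcrossprod(bases[[i]])
  }
  l_mod <- (l_mod + t(l_mod)) / 2
  dimnames(l_mod) <- list(ids, ids)

  e <- eigen(l_mod, symmetric = TRUE)
  if (k < n && abs(e$values[k] - e$values[k + 1L]) < 1e-10) {
    warning("eigenvalue tie at the fusion cut-off (k = ", k,
            "); the fused subspace is not unique", call. = FALSE)
  }
  fused_basis <- fix_signs(e$vectors[, seq_len(k), drop = FALSE])
  fused <- new_subspace_embedding(fused_basis, ids,
                                  eigenvalues = e$values[seq_len(k)],
                                  source = "fused")
  dists <- vapply(bases, function(b) projection_distance(fused_basis, b),
                  numeric(1))
  names(dists) <- vapply(seq_along(embeddings), function(i) {
    src <- if (inherits(embeddings[[i]], "subspace_embedding")) {
      embeddings[[i]]$source
    } else NULL
    src %||% paste0("view", i)
  }, character(1))
  structure(
    list(fused = fused, l_mod = l_mod, per_view_distance = dists,
         eigenvalues = e$values, objective = sum(e$values[seq_len(k)]),
         n_views = m_views, k = k, weights = weights),
    class = "grassmann_fusion"
  )
}

#' @export
print.grassmann_fusion <- function(x, ...) {
  cat("<grassmann_fusion> ", x$n_views, " views fused into a ", x$k,
      "-dimensional subspace over ", nrow(x$fused$basis), " patients\n",
      "  summed d2_proj to views: ",
      signif(sum(x$per_view_distance), 4), "\n", sep = "")
  invisible(x)
}

#' @describeIn fuse_subspaces One row per view with its squared projection
#'   distance from the fused subspace.
#' @param x A `grassmann_fusion`.
#' @param ... Unused.
#' @export
tidy.grassmann_fusion <- function(x, ...) {
  tibble::tibble(
    view = names(x$per_view_distance),
    projection_distance2 = unname(x$per_view_distance)
  )
}

#' @describeIn fuse_subspaces One-row summary of the fusion fit.
#' @export
glance.grassmann_fusion <- function(x, ...) {
  tibble::tibble(
    n_views = x$n_views,
    k = x$k,
    n_patients = nrow(x$fused$basis),
    objective = x$objective,
    total_distance2 = sum(x$per_view_distance)
  )
}

#' Write a fused (or per-view) embedding as TSV
#' @param embedding A `subspace_embedding` (e.g. `fusion$fused`).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_embedding <- function(embedding, path) {
  stopifnot(inherits(embedding, "subspace_embedding"))
  utils::write.table(tidy.subspace_embedding(embedding), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
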