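#' Feature-wise z-score standardization of an omics view
#'
#' Centers and scales every feature across patients:
#' \eqn{z_{pf} = (x_{pf} - \bar x_f) / \sigma_f}. The scale \eqn{\sigma_f}
#' is the population standard deviation (divide by N) by default, the usual
#' convention for standardized scores; set `sd = "sample"` for the
#' N-1 denominator. Features with zero variance carry no information and
#' cannot be scaled; they are dropped with a warning (constant probes are
#' common in real methylation matrices).
#'
#' @param view A view tibble (`patient_id` + numeric feature columns) or a
#'   numeric patient-by-feature matrix with row names.
#' @param sd `"population"` (default) or `"sample"`.
#' @return A tibble of the same layout with standardized (dimensionless)
#'   feature columns; constant features removed.
#' @export
zscore_view <- function(view, sd = c("population", "sample")) {
  sd <- match.arg(sd)
  m <- as_view_matrix(view)
  check_view(m)
  n <- nrow(m)
  mu <- colMeans(m)
  centered <- sweep(m, 2L, mu, "-")
  ss <- colSums(centered^2)
  denom <- if (sd == "population") n else n - 1L
  sigma <- sqrt(ss / denom)
  keep <- sigma > 0
  if (!any(keep)) stop("all features have zero variance", call. = FALSE)
  if (any(!keep)) {
    warning(sum(!keep), " zero-variance feature(s) dropped: ",
            paste(utils::head(colnames(m)[!keep], 3L), collapse = ", "),
            if (sum(!keep) > 3L) ", ..." else "", call. = FALSE)
  }
  z <- sweep(centered[, keep, drop = FALSE], 2L, sigma[keep], "/")
  view_tibble(z)
}

#' Principal component reduction of a standardized view
#'
#' Computes the principal components of a standardized patient-by-feature
#' matrix via singular value decomposition (numerically stabler than the
#' equivalent eigendecomposition of the patient Gram matrix \eqn{ZZ^T} when
#' features vastly outnumber patients, and spanning the same score space).
#' The number of retained components is the smallest count whose cumulative
#' explained-variance ratio reaches `variance_threshold`; components whose
#' eigenvalue ties the last retained one are also kept, so the choice does
#' not depend on an arbitrary ordering of equal eigenvalues.
#'
#' Component signs are fixed by making the largest-magnitude loading entry
#' of each component positive, so results are reproducible.
#'
#' @param z A standardized view (tibble or matrix), e.g. from
#'   [zscore_view()].
#' @param variance_threshold Fraction of total variance to retain, in
#'   (0, 1]; default 0.95.
#' @return An object of class `pca_view` with elements `patient_ids`,
#'   `scores` (N x k patient coordinates), `loadings` (D x k, orthonormal
#'   columns), `explained_variance_ratio`, `eigenvalues`, and
#'   `n_components`.
#' @export
pca_reduce <- function(z, variance_threshold = 0.95) {
  stopifnot(is.numeric(variance_threshold), length(variance_threshold) == 1L,
            variance_threshold > 0, variance_threshold <= 1)
  m <- as_view_matrix(z)
  if (nrow(m) < 2L) stop("need at least 2 patients for PCA", call. = FALSE)
  # re-center defensively; a z-scored input is already centered
  m <- sweep(m, 2L, colMeans(m), "-")
  sv <- svd(m)
  ev <- sv$d^2
  total <- sum(ev)
  if (total <= 0) stop("input has no variance", call. = FALSE)
  evr <- ev / total
  cum <- cumsum(evr)
  k <- which(cum >= variance_threshold - 1e-12)[1L]
  if (is.na(k)) k <- length(evr)
  # include components tied (to numerical precision) with the k-th eigenvalue
  tol <- max(ev[1L], 1) * 1e-10
  while (k < length(ev) && abs(ev[k + 1L] - ev[k]) <= tol && ev[k] > tol) {
    k <- k + 1L
  }
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k, k)
  loadings <- sv$v[, seq_len(k), drop = FALSE]
  # deterministic sign: largest-|loading| entry positive per component
  for (j in seq_len(k)) {
    i_max <- which.max(abs(loadings[, j]))
    if (loadings[i_max, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  rownames(scores) <- rownames(m)
  rownames(loadings) <- colnames(m)
  colnames(scores) <- colnames(loadings) <- paste0("PC", seq_len(k))
  structure(
    list(patient_ids = rownames(m), scores = scores, loadings = loadings,
         explained_variance_ratio = evr[seq_len(k)],
         eigenvalues = ev[seq_len(k)],
         cumulative_variance = cum[seq_len(k)],
         n_components = k, total_variance = total,
         all_explained_variance_ratio = evr),
    class = "pca_view"
  )
}

#' @export
print.pca_view <- function(x, ...) {
  cat("<pca_view> ", length(x$patient_ids), " patients, ",
      x$n_components, " components (",
      sprintf("%.1f%%", 100 * x$cumulative_variance[x$n_components]),
      " of variance)\n", sep = "")
  invisible(x)
}

#' @describeIn pca_reduce Scree table: one row per retained component with
#'   its eigenvalue, explained-variance ratio and cumulative ratio.
#' @param x A `pca_view`.
#' @param ... Unused.
#' @export
tidy.pca_view <- function(x, ...) {
  tibble::tibble(
    component = seq_len(x$n_components),
    eigenvalue = x$eigenvalues,
    variance_ratio = x$explained_variance_ratio,
    cumulative_ratio = x$cumulative_variance
  )
}

#' Write a per-view scree table as TSV
#' @param pca A `pca_view`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_scree <- function(pca, path) {
  stopifnot(inherits(pca, "pca_view"))
  utils::write.table(tidy.pca_view(pca), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
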