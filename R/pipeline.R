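#' Full multi-omics subgrouping pipeline
#'
#' Runs the complete intermediate-integration pipeline on a list of omics
#' views sharing one patient cohort:
#' 1. feature-wise z-score standardization per view ([zscore_view()]);
#' 2. PCA retaining `variance_threshold` of the variance ([pca_reduce()]);
#' 3. Gaussian-kernel similarity + kNN sparsification per view
#'    ([patient_graph()]);
#' 4. normalized-Laplacian spectral embedding per view
#'    ([spectral_embed()]);
#' 5. fusion of the per-view subspaces on the Grassmann manifold
#'    ([fuse_subspaces()]);
#' 6. k-means subgrouping on the fused embedding ([kmeans_cluster()]),
#'    with the subgroup count chosen by silhouette scan when
#'    `n_clusters = "auto"` ([select_k_silhouette()]).
#'
#' @param views Named list of view tibbles (`patient_id` + numeric feature
#'   columns) or matrices with patient row names, all with identical
#'   patient ordering (as returned by [read_views()] or
#'   [simulate_multiomics()]`$views`).
#' @param n_clusters Number of subgroups K, or `"auto"` to select by mean
#'   silhouette over `k_range`.
#' @param variance_threshold PCA variance fraction to retain (default
#'   0.95).
#' @param bandwidth Gaussian kernel bandwidth per view: positive numeric or
#'   `"auto"` (median pairwise distance; default).
#' @param n_neighbors kNN graph degree: positive integer or `"auto"`
#'   (`round(sqrt(N))`; default).
#' @param embed_dim Spectral embedding dimension; default = `n_clusters`.
#'   In auto mode the scan re-embeds at each candidate K, keeping the
#'   embedding dimension coupled to the cluster count throughout.
#' @param kmeans_restarts k-means restarts (default 50).
#' @param k_range Candidate K values for `n_clusters = "auto"` (default
#'   `2:8`).
#' @param row_normalize Normalize fused-embedding rows before k-means
#'   (default `FALSE`).
#' @param seed Integer seed controlling k-means restarts (default 1).
#' @return An object of class `subgroup_fit`: `result` (a
#'   `subgroup_result`), `fusion` (a `grassmann_fusion`), `embeddings`,
#'   `graphs`, `pca` (per-view lists), `k_selection` (`NULL` unless
#'   auto-selected), and `config`.
#' @examples
#' sim <- simulate_multiomics(n_samples = 60, n_clusters = 3,
#'                            view_feature_counts = c(40, 60, 50),
#'                            latent_dim = 6, separation = 6, seed = 7)
#' fit <- fuse_pipeline(sim$views, n_clusters = 3, seed = 7)
#' tidy(fit)
#' glance(fit)
#' clustering_metrics(tidy(fit)$subgroup, sim$true_labels$cluster)
#' @export
fuse_pipeline <- function(views,
                          n_clusters = "auto",
                          variance_threshold = 0.95,
                          bandwidth = "auto",
                          n_neighbors = "auto",
                          embed_dim = NULL,
                          kmeans_restarts = 50L,
                          k_range = 2:8,
                          row_normalize = FALSE,
                          seed = 1L) {
  stopifnot(is.list(views), length(views) >= 1L)
  if (is.null(names(views))) names(views) <- paste0("view", seq_along(views))
  mats <- lapply(names(views), function(nm) {
    m <- as_view_matrix(views[[nm]], nm)
    check_view(m, nm)
    m
  })
  names(mats) <- names(views)
  ids <- rownames(mats[[1L]])
  for (nm in names(mats)) {
    if (!identical(rownames(mats[[nm]]), ids)) {
      stop("view '", nm, "' has a different patient ordering; ",
           "align views with read_views() first", call. = FALSE)
    }
  }
  n <- length(ids)

  pca <- lapply(names(mats), function(nm) {
    pca_reduce(zscore_view(mats[[nm]]), variance_threshold)
  })
  names(pca) <- names(mats)
  graphs <- lapply(names(pca), function(nm) {
    patient_graph(pca[[nm]], bandwidth = bandwidth,
                  n_neighbors = n_neighbors, name = nm)
  })
  names(graphs) <- names(pca)

  auto_k <- identical(n_clusters, "auto")
  k_sel <- NULL
  if (auto_k) {
    # scan: re-embed and re-fuse at each candidate K (embedding dimension =
    # cluster count, the standard spectral-clustering coupling), then score
    # each K by mean silhouette on its own fused embedding
    k_range <- sort(unique(as.integer(k_range)))
    stopifnot(all(k_range >= 2L), all(k_range <= n - 1L))
    rows <- purrr::map(k_range, function(kk) {
      emb <- lapply(graphs, spectral_embed, k = kk)
      res <- kmeans_cluster(fuse_subspaces(emb), kk,
                            restarts = kmeans_restarts, seed = seed,
                            row_normalize = row_normalize)
      tibble::tibble(n_clusters = kk, silhouette = res$silhouette,
                     inertia = res$inertia)
    })
    tab <- dplyr::bind_rows(rows)
    k_sel <- structure(
      list(best_k = tab$n_clusters[which.max(tab$silhouette)], table = tab),
      class = "k_selection"
    )
    n_clusters <- k_sel$best_k
  }
  n_clusters <- as.integer(n_clusters)
  if (is.null(embed_dim)) embed_dim <- n_clusters
  stopifnot(embed_dim >= 1L, embed_dim <= n - 1L, n_clusters <= n)

  embeddings <- lapply(graphs, spectral_embed, k = embed_dim)
  fusion <- fuse_subspaces(embeddings)
  result <- kmeans_cluster(fusion, n_clusters, restarts = kmeans_restarts,
                           seed = seed, row_normalize = row_normalize)

  structure(
    list(result = result, fusion = fusion, embeddings = embeddings,
         graphs = graphs, pca = pca, k_selection = k_sel,
         patient_ids = ids,
         config = list(n_clusters = n_clusters,
                       variance_threshold = variance_threshold,
                       bandwidth = bandwidth, n_neighbors = n_neighbors,
                       embed_dim = embed_dim,
                       kmeans_restarts = kmeans_restarts,
                       row_normalize = row_normalize,
                       seed = as.integer(seed))),
    class = "subgroup_fit"
  )
}

#' @export
print.subgroup_fit <- function(x, ...) {
  cat("<subgroup_fit> ", length(x$patient_ids), " patients, ",
      length(x$embeddings), " views fused; K = ",
      x$result$n_clusters,
      if (!is.null(x$k_selection)) " (silhouette-selected)",
      "\n", sep = "")
  print(x$result)
  invisible(x)
}

#' @describeIn fuse_pipeline Per-patient subgroup assignments with the
#'   fused embedding coordinates.
#' @param x A `subgroup_fit`.
#' @param ... Unused.
#' @export
tidy.subgroup_fit <- function(x, ...) {
  dplyr::left_join(x$result$subgroups,
                   tidy.subspace_embedding(x$fusion$fused),
                   by = "patient_id")
}

#' @describeIn fuse_pipeline One-row fit summary.
#' @export
glance.subgroup_fit <- function(x, ...) {
  tibble::tibble(
    n_patients = length(x$patient_ids),
    n_views = length(x$embeddings),
    n_clusters = x$result$n_clusters,
    embed_dim = x$config$embed_dim,
    inertia = x$result$inertia,
    silhouette = x$result$silhouette,
    fusion_objective = x$fusion$objective,
    pca_components = sum(vapply(x$pca, function(p) p$n_components, integer(1)))
  )
}

#' Evaluate a subgrouping against reference labels and/or survival
#'
#' Convenience wrapper combining [clustering_metrics()] and
#' [logrank_test()] for whichever references are available.
#'
#' @param labels A `subgroup_fit`, `subgroup_result`, or data frame with
#'   `patient_id` and `subgroup`.
#' @param truth Optional reference labels (vector or data frame).
#' @param survival Optional survival table.
#' @param nmi_norm Passed to [clustering_metrics()].
#' @return A list with elements `metrics` (tibble or `NULL`) and
#'   `survival` (`survival_comparison` or `NULL`).
#' @export
evaluate_subgroups <- function(labels, truth = NULL, survival = NULL,
                               nmi_norm = "geometric") {
  if (inherits(labels, "subgroup_fit")) labels <- labels$result
  out <- list(metrics = NULL, survival = NULL)
  if (!is.null(truth)) {
    out$metrics <- clustering_metrics(labels, truth, nmi_norm = nmi_norm)
  }
  if (!is.null(survival)) {
    out$survival <- logrank_test(labels, survival)
  }
  out
}
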