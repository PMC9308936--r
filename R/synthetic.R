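#' Simulate multi-view omics data with shared latent cluster structure
#'
#' Generates M patient-by-feature views measured on one cohort, all driven
#' by the same latent clustering — the situation multi-omics integration
#' assumes. Cluster centers are mutually orthogonal directions on a sphere
#' of radius `separation` in latent space (so every pair of centers is
#' `separation * sqrt(2)` apart); each patient is their cluster center plus
#' unit Gaussian latent noise. Each view observes the latent coordinates
#' through its own random linear map with orthonormalized columns, scaled
#' by `sqrt(n_features / latent_dim)` so that a typical feature carries
#' O(1) signal variance regardless of how many features the view has —
#' per-feature signal-to-noise is then governed by `separation / noise_sd`
#' alone — plus independent Gaussian measurement noise of sd `noise_sd`.
#'
#' The default shape (200 patients; three views of 503, 2541 and 936
#' features, mimicking miRNA, mRNA expression and DNA methylation panels;
#' 4 balanced clusters; `separation = 4`; `noise_sd = 1`; `latent_dim =
#' 10`) is this package's benchmark preset.
#'
#' @param n_samples Number of patients (default 200).
#' @param n_clusters Number of latent clusters (default 4); must not
#'   exceed `n_samples`. Orthogonal center placement needs
#'   `n_clusters <= latent_dim`; beyond that, centers fall back to
#'   independent random directions (with a warning).
#' @param cluster_proportions Simplex vector of cluster sizes; default
#'   balanced.
#' @param view_feature_counts Features per view (default
#'   `c(503, 2541, 936)`).
#' @param view_names Names for the views; default
#'   `c("mirna", "mrna", "methylation")` when three views are requested,
#'   else `view1..M`.
#' @param latent_dim Dimension of the shared latent space (default 10).
#' @param separation Radius of the sphere holding the cluster centers, in
#'   latent units (the within-cluster latent spread is 1 per dimension).
#' @param noise_sd Per-feature measurement noise sd added in each view.
#' @param seed Integer seed; the whole draw is deterministic given it.
#' @return An object of class `multiomics_sim`: `views` (named list of
#'   view tibbles), `true_labels` (tibble `patient_id`, `cluster`),
#'   `latent` (N x latent_dim matrix), `spec` (the generating parameters).
#' @export
simulate_multiomics <- function(n_samples = 200L,
                                n_clusters = 4L,
                                cluster_proportions = NULL,
                                view_feature_counts = c(503L, 2541L, 936L),
                                view_names = NULL,
                                latent_dim = 10L,
                                separation = 4,
                                noise_sd = 1,
                                seed = 1L) {
  stopifnot(n_samples >= 2L, n_clusters >= 1L,
            all(view_feature_counts >= 1L),
            latent_dim >= 1L, separation >= 0, noise_sd > 0)
  if (n_clusters > n_samples) {
    stop("n_clusters cannot exceed n_samples", call. = FALSE)
  }
  if (is.null(cluster_proportions)) {
    cluster_proportions <- rep(1 / n_clusters, n_clusters)
  }
  stopifnot(length(cluster_proportions) == n_clusters,
            all(cluster_proportions > 0),
            abs(sum(cluster_proportions) - 1) < 1e-8)
  if (is.null(view_names)) {
    view_names <- if (length(view_feature_counts) == 3L) {
      c("mirna", "mrna", "methylation")
    } else {
      paste0("view", seq_along(view_feature_counts))
    }
  }
  stopifnot(length(view_names) == length(view_feature_counts))

  set.seed(as.integer(seed))
  # cluster sizes from proportions (largest-remainder rounding)
  sizes <- floor(cluster_proportions * n_samples)
  rem <- n_samples - sum(sizes)
  if (rem > 0) {
    frac <- cluster_proportions * n_samples - sizes
    sizes[order(frac, decreasing = TRUE)[seq_len(rem)]] <- sizes[order(frac, decreasing = TRUE)[seq_len(rem)]] + 1
  }
  labels <- rep(seq_len(n_clusters), times = sizes)

  centers <- cluster_centers(n_clusters, latent_dim, separation)
  latent <- centers[labels, , drop = FALSE] +
    matrix(stats::rnorm(n_samples * latent_dim), n_samples, latent_dim)

  ids <- sprintf("P%03d", seq_len(n_samples))
  rownames(latent) <- ids

  views <- stats::setNames(vector("list", length(view_feature_counts)), view_names)
  for (v in seq_along(view_feature_counts)) {
    d <- view_feature_counts[v]
    if (d < latent_dim) {
      stop("view '", view_names[v], "' has fewer features (", d,
           ") than latent_dim (", latent_dim, ")", call. = FALSE)
    }
    q <- qr.Q(qr(matrix(stats::rnorm(d * latent_dim), d, latent_dim)))
    map <- q * sqrt(d / latent_dim)               # D x L, scaled orthonormal columns
    x <- latent %*% t(map) +
      matrix(stats::rnorm(n_samples * d, sd = noise_sd), n_samples, d)
    dimnames(x) <- list(ids, paste0(view_names[v], "_f", seq_len(d)))
    views[[v]] <- view_tibble(x)
  }

  structure(
    list(views = views,
         true_labels = tibble::tibble(patient_id = ids, cluster = labels),
         latent = latent,
         spec = list(n_samples = n_samples, n_clusters = n_clusters,
                     cluster_proportions = cluster_proportions,
                     view_feature_counts = view_feature_counts,
                     view_names = view_names, latent_dim = latent_dim,
                     separation = separation, noise_sd = noise_sd,
                     seed = as.integer(seed))),
    class = "multiomics_sim"
  )
}

#' @keywords internal
cluster_centers <- function(n_clusters, latent_dim, separation) {
  if (separation == 0 || n_clusters == 1L) {
    return(matrix(0, n_clusters, latent_dim))
  }
  if (n_clusters <= latent_dim) {
    q <- qr.Q(qr(matrix(stats::rnorm(latent_dim * n_clusters),
                        latent_dim, n_clusters)))
    centers <- separation * t(q)                  # orthogonal, radius = separation
  } else {
    warning("n_clusters > latent_dim: centers are random (not orthogonal) ",
            "directions; separation is only approximate", call. = FALSE)
    dirs <- matrix(stats::rnorm(n_clusters * latent_dim), n_clusters, latent_dim)
    centers <- separation * dirs / sqrt(rowSums(dirs^2))
  }
  centers
}

#' @export
print.multiomics_sim <- function(x, ...) {
  s <- x$spec
  cat("<multiomics_sim> ", s$n_samples, " patients, ",
      length(x$views), " views (",
      paste(s$view_feature_counts, collapse = "/"), " features), ",
      s$n_clusters, " latent clusters, separation = ", s$separation,
      ", noise_sd = ", s$noise_sd, "\n", sep = "")
  invisible(x)
}

#' Corrupt one view of a simulated dataset
#'
#' Permutes a fraction of the chosen view's rows among themselves, breaking
#' that view's link to the latent clustering while leaving its marginal
#' feature distributions intact — a controlled way to study how fusion
#' degrades when one view is uninformative.
#'
#' @param dataset A `multiomics_sim`.
#' @param view_index View to corrupt (index or name).
#' @param shuffle_fraction Fraction of rows to permute, in `[0, 1]`.
#' @param seed Integer seed for the permutation (default: the dataset's own
#'   seed plus 1).
#' @return A modified copy of `dataset`; the applied corruption is recorded
#'   in `spec$corruption`.
#' @export
corrupt_view <- function(dataset, view_index, shuffle_fraction,
                         seed = NULL) {
  stopifnot(inherits(dataset, "multiomics_sim"),
            shuffle_fraction >= 0, shuffle_fraction <= 1)
  if (is.character(view_index)) {
    view_index <- match(view_index, names(dataset$views))
  }
  if (is.na(view_index) || view_index < 1L ||
      view_index > length(dataset$views)) {
    stop("invalid view index", call. = FALSE)
  }
  if (shuffle_fraction == 0) return(dataset)
  if (is.null(seed)) seed <- dataset$spec$seed + 1L
  set.seed(as.integer(seed))
  v <- dataset$views[[view_index]]
  n <- nrow(v)
  n_shuffle <- round(shuffle_fraction * n)
  rows <- sample.int(n, n_shuffle)
  perm <- sample(rows)
  feat_cols <- setdiff(names(v), "patient_id")
  v[rows, feat_cols] <- v[perm, feat_cols]
  dataset$views[[view_index]] <- v
  dataset$spec$corruption <- list(view_index = view_index,
                                  shuffle_fraction = shuffle_fraction,
                                  seed = as.integer(seed))
  dataset
}

#' Write a simulated dataset to disk
#'
#' One TSV per view (via [write_views()]), a `truth.tsv` with the latent
#' cluster labels, and a `spec.json` sidecar recording every generator
#' parameter for provenance.
#'
#' @param dataset A `multiomics_sim`.
#' @param dir Output directory.
#' @return Invisibly, `dir`.
#' @export
write_simulation <- function(dataset, dir) {
  stopifnot(inherits(dataset, "multiomics_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_views(dataset$views, dir)
  utils::write.table(dataset$true_labels, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(dataset$spec, file.path(dir, "spec.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
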