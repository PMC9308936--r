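#' k-means subgrouping of patients on a fused embedding
#'
#' Runs k-means with multiple random restarts on the rows of the (fused)
#' spectral embedding and keeps the solution with minimal within-cluster
#' sum of squares. Labels are reported 1-based and renumbered in order of
#' first appearance, so the same seed always yields bitwise-identical
#' output.
#'
#' @param u A `subspace_embedding`, a `grassmann_fusion` (its fused
#'   embedding is used), or a numeric matrix of patient coordinates with
#'   row names.
#' @param n_clusters Number of subgroups K, `2 <= K <= N`.
#' @param restarts Number of random restarts (default 50).
#' @param seed Integer seed making the restarts reproducible.
#' @param row_normalize Normalize embedding rows to unit length before
#'   clustering (off by default).
#' @return An object of class `subgroup_result`: `subgroups` (tibble with
#'   `patient_id`, `subgroup`), `n_clusters`, `inertia` (within-cluster sum
#'   of squares), `silhouette` (mean silhouette width, `NA` for K = N),
#'   `centers`.
#' @export
kmeans_cluster <- function(u, n_clusters, restarts = 50L, seed = 1L,
                           row_normalize = FALSE) {
  x <- clustering_input(u, row_normalize)
  n <- nrow(x)
  stopifnot(n_clusters >= 1L, n_clusters <= n, restarts >= 1L)
  set.seed(as.integer(seed))
  if (n_clusters == n) {
    # every patient its own subgroup; no optimization needed
    fit <- list(cluster = seq_len(n), tot.withinss = 0, centers = x)
  } else {
    fit <- stats::kmeans(x, centers = n_clusters,
                         nstart = as.integer(restarts), iter.max = 100L)
  }
  labels <- canonical_labels(fit$cluster)
  sil <- if (n_clusters >= 2L && n_clusters < n) {
    mean(cluster::silhouette(labels, stats::dist(x))[, "sil_width"])
  } else NA_real_
  structure(
    list(subgroups = tibble::tibble(patient_id = rownames(x),
                                    subgroup = labels),
         n_clusters = as.integer(n_clusters),
         inertia = fit$tot.withinss,
         silhouette = sil,
         centers = fit$centers),
    class = "subgroup_result"
  )
}

#' @keywords internal
clustering_input <- function(u, row_normalize = FALSE) {
  if (inherits(u, "grassmann_fusion")) u <- u$fused
  x <- embedding_basis(u, "embedding")
  if (is.null(rownames(x))) rownames(x) <- paste0("P", seq_len(nrow(x)))
  if (row_normalize) {
    nrm <- sqrt(rowSums(x^2))
    nrm[nrm == 0] <- 1
    x <- x / nrm
  }
  x
}

# renumber labels 1..K in order of first appearance
#' @keywords internal
canonical_labels <- function(labels) {
  as.integer(match(labels, unique(labels)))
}

#' @export
print.subgroup_result <- function(x, ...) {
  cat("<subgroup_result> ", nrow(x$subgroups), " patients in ",
      x$n_clusters, " subgroups; inertia = ", signif(x$inertia, 5),
      if (!is.na(x$silhouette)) paste0(", mean silhouette = ",
                                       signif(x$silhouette, 4)),
      "\n", sep = "")
  invisible(x)
}

#' @describeIn kmeans_cluster Per-patient subgroup assignments.
#' @param x A `subgroup_result`.
#' @param ... Unused.
#' @export
tidy.subgroup_result <- function(x, ...) {
  x$subgroups
}

#' @describeIn kmeans_cluster One-row summary (K, inertia, silhouette).
#' @export
glance.subgroup_result <- function(x, ...) {
  tibble::tibble(
    n_patients = nrow(x$subgroups),
    n_clusters = x$n_clusters,
    inertia = x$inertia,
    silhouette = x$silhouette
  )
}

#' Choose the number of subgroups by mean silhouette width
#'
#' Clusters the embedding for each candidate K and returns the K with the
#' largest mean silhouette width (cohesion within subgroups versus
#' separation from the nearest other subgroup). Ties go to the smallest K.
#'
#' @inheritParams kmeans_cluster
#' @param k_range Candidate subgroup counts, each in `[2, N-1]`
#'   (default `2:8`).
#' @return An object of class `k_selection`: `best_k` and `table`, a
#'   tibble of (`n_clusters`, `silhouette`, `inertia`).
#' @export
select_k_silhouette <- function(u, k_range = 2:8, restarts = 50L, seed = 1L,
                                row_normalize = FALSE) {
  x <- clustering_input(u, row_normalize)
  n <- nrow(x)
  k_range <- sort(unique(as.integer(k_range)))
  stopifnot(all(k_range >= 2L), all(k_range <= n - 1L))
  if (max(stats::dist(x)) == 0) {
    stop("degenerate embedding: all patients identical", call. = FALSE)
  }
  rows <- purrr::map(k_range, function(k) {
    res <- kmeans_cluster(x, k, restarts = restarts, seed = seed)
    tibble::tibble(n_clusters = k, silhouette = res$silhouette,
                   inertia = res$inertia)
  })
  tab <- dplyr::bind_rows(rows)
  best <- tab$n_clusters[which.max(tab$silhouette)]  # which.max takes first = smallest K on ties
  structure(list(best_k = as.integer(best), table = tab),
            class = "k_selection")
}

#' @export
print.k_selection <- function(x, ...) {
  cat("<k_selection> best K = ", x$best_k, " by mean silhouette\n", sep = "")
  print(x$table)
  invisible(x)
}

#' @describeIn select_k_silhouette The per-K silhouette table.
#' @param x A `k_selection`.
#' @param ... Unused.
#' @export
tidy.k_selection <- function(x, ...) {
  x$table
}

#' Clustering agreement metrics against reference labels
#'
#' Compares a predicted partition with a reference partition of the same
#' patients:
#' * `nmi` — mutual information normalized by the geometric mean of the
#'   two label entropies (set `nmi_norm = "arithmetic"` for the mean);
#' * `acc` — accuracy under the best one-to-one matching of predicted
#'   subgroups to reference classes (optimal assignment);
#' * `precision`, `recall`, `f_score` — pairwise co-membership decisions:
#'   of all patient pairs placed together by the prediction, how many
#'   belong together (precision); of all pairs truly together, how many
#'   the prediction joins (recall); their harmonic mean (F);
#' * `purity` — each predicted subgroup votes for its majority class.
#'
#' All metrics lie in [0, 1] and are invariant to relabeling either
#' partition.
#'
#' @param pred,truth Label vectors of equal length (integers, characters or
#'   factors), or data frames with `patient_id` and a label column (aligned
#'   by patient ID).
#' @param nmi_norm `"geometric"` (default) or `"arithmetic"` entropy
#'   normalization for NMI.
#' @return One-row tibble with columns `nmi`, `acc`, `f_score`,
#'   `precision`, `recall`, `purity`.
#' @export
clustering_metrics <- function(pred, truth,
                               nmi_norm = c("geometric", "arithmetic")) {
  nmi_norm <- match.arg(nmi_norm)
  al <- align_labels(pred, truth)
  p <- al$pred
  t_ <- al$truth
  n <- length(p)
  if (n < 2L) stop("need at least 2 patients", call. = FALSE)
  ct <- table(p, t_)
  pf <- pairwise_f(ct)
  tibble::tibble(
    nmi = nmi_from_table(ct, nmi_norm),
    acc = acc_from_table(ct),
    f_score = unname(pf["f"]),
    precision = unname(pf["precision"]),
    recall = unname(pf["recall"]),
    purity = sum(apply(ct, 1L, max)) / n
  )
}

#' @keywords internal
align_labels <- function(pred, truth) {
  get_lab <- function(x, what) {
    if (is.data.frame(x)) {
      id_col <- if ("patient_id" %in% names(x)) "patient_id" else names(x)[1L]
      lab_col <- setdiff(names(x), id_col)[1L]
      list(ids = as.character(x[[id_col]]), lab = x[[lab_col]])
    } else if (inherits(x, "subgroup_result")) {
      list(ids = x$subgroups$patient_id, lab = x$subgroups$subgroup)
    } else {
      list(ids = NULL, lab = x)
    }
  }
  a <- get_lab(pred, "pred")
  b <- get_lab(truth, "truth")
  if (!is.null(a$ids) && !is.null(b$ids)) {
    idx <- match(a$ids, b$ids)
    if (anyNA(idx)) stop("pred and truth cover different patients", call. = FALSE)
    b$lab <- b$lab[idx]
  }
  if (length(a$lab) != length(b$lab)) {
    stop("pred and truth must have equal length", call. = FALSE)
  }
  list(pred = as.integer(factor(a$lab)), truth = as.integer(factor(b$lab)))
}

#' @keywords internal
nmi_from_table <- function(ct, norm = "geometric") {
  n <- sum(ct)
  pij <- ct / n
  pi_ <- rowSums(pij)
  pj_ <- colSums(pij)
  nz <- pij > 0
  mi <- sum(pij[nz] * log(pij[nz] / outer(pi_, pj_)[nz]))
  h <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  hp <- h(pi_); ht <- h(pj_)
  denom <- if (norm == "geometric") sqrt(hp * ht) else (hp + ht) / 2
  if (denom <= 0) return(0)
  max(0, min(1, mi / denom))
}

#' @keywords internal
acc_from_table <- function(ct) {
  # best one-to-one matching of predicted clusters to classes: maximum-weight
  # assignment on the (square-padded) contingency table
  n <- sum(ct)
  m <- max(dim(ct))
  cost <- matrix(0, m, m)
  cost[seq_len(nrow(ct)), seq_len(ncol(ct))] <- ct
  assignment_max(cost) / n
}

# exact maximum-weight assignment by dynamic programming over column
# subsets: f(i, S) = best matching of rows 1..i to columns in S.
# O(n^2 2^n) — fine for the subgroup counts met in practice (n <= 16).
#' @keywords internal
assignment_max <- function(w) {
  n <- nrow(w)
  stopifnot(ncol(w) == n)
  if (n > 16L) stop("assignment supports at most 16 clusters", call. = FALSE)
  nmask <- bitwShiftL(1L, n)
  f <- rep(-Inf, nmask)
  f[1L] <- 0
  bitcounts <- vapply(0:(nmask - 1L), function(m) sum(bitwAnd(m, bitwShiftL(1L, 0:(n - 1L))) > 0), numeric(1))
  for (mask in 1:(nmask - 1L)) {
    i <- bitcounts[mask + 1L]        # row index to place next (1-based)
    for (j in seq_len(n)) {
      bit <- bitwShiftL(1L, j - 1L)
      if (bitwAnd(mask, bit) > 0L) {
        prev <- f[bitwXor(mask, bit) + 1L]
        cand <- prev + w[i, j]
        if (cand > f[mask + 1L]) f[mask + 1L] <- cand
      }
    }
  }
  f[nmask]
}

#' @keywords internal
pairwise_f <- function(ct) {
  pairs <- function(x) sum(x * (x - 1) / 2)
  tp <- pairs(ct)
  pred_pairs <- pairs(rowSums(ct))
  truth_pairs <- pairs(colSums(ct))
  precision <- if (pred_pairs > 0) tp / pred_pairs else 0
  recall <- if (truth_pairs > 0) tp / truth_pairs else 0
  f <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  c(precision = precision, recall = recall, f = f)
}
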