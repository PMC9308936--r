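test_that("k-means recovers separable clouds and is deterministic given the seed", {
  set.seed(51)
  x <- rbind(matrix(rnorm(20, mean = 0, sd = 0.1), 10, 2),
             matrix(rnorm(20, mean = 5, sd = 0.1), 10, 2))
  rownames(x) <- sprintf("P%02d", 1:20)
  res <- kmeans_cluster(x, 2, restarts = 10, seed = 5)
  expect_equal(res$subgroups$subgroup, rep(1:2, each = 10))

  res2 <- kmeans_cluster(x, 2, restarts = 10, seed = 5)
  expect_identical(res$subgroups$subgroup, res2$subgroups$subgroup)
  expect_identical(res$inertia, res2$inertia)
})

test_that("K = N gives singleton subgroups with zero inertia", {
  set.seed(52)
  x <- matrix(rnorm(12), 6, 2, dimnames = list(paste0("P", 1:6), NULL))
  res <- kmeans_cluster(x, 6, restarts = 5, seed = 1)
  expect_equal(sort(res$subgroups$subgroup), 1:6)
  expect_equal(res$inertia, 0, tolerance = 1e-12)
})

test_that("k-means inertia matches the exhaustive two-partition minimum", {
  set.seed(53)
  x <- matrix(rnorm(12, sd = 2), 6, 2, dimnames = list(paste0("P", 1:6), NULL))
  res <- kmeans_cluster(x, 2, restarts = 50, seed = 3)
  wss <- function(lab) {
    sum(vapply(unique(lab), function(g) {
      pts <- x[lab == g, , drop = FALSE]
      sum(sweep(pts, 2, colMeans(pts), "-")^2)
    }, numeric(1)))
  }
  best <- Inf
  for (code in 1:(2^5)) {            # fix point 1 in group 1; others free
    lab <- c(1L, as.integer(intToBits(code)[1:5]) + 1L)
    if (length(unique(lab)) == 2L) best <- min(best, wss(lab))
  }
  expect_equal(res$inertia, best, tolerance = 1e-8)
})

test_that("silhouette scan selects the true number of blobs", {
  set.seed(54)
  centers <- rbind(c(0, 0), c(8, 0), c(0, 8))
  x <- do.call(rbind, lapply(1:3, function(i) {
    sweep(matrix(rnorm(24, sd = 0.5), 12, 2), 2, centers[i, ], "+")
  }))
  rownames(x) <- sprintf("P%02d", 1:36)
  sel <- select_k_silhouette(x, k_range = 2:6, restarts = 20, seed = 2)
  expect_equal(sel$best_k, 3L)
  expect_equal(nrow(sel$table), 5L)
  # silhouette agrees with the cluster package's definition at the optimum
  res <- kmeans_cluster(x, 3, restarts = 20, seed = 2)
  sil <- cluster::silhouette(res$subgroups$subgroup, dist(x))
  expect_equal(res$silhouette, mean(sil[, "sil_width"]), tolerance = 1e-12)
})

test_that("silhouette scan handles minimal clusters and degenerate input", {
  x <- rbind(c(0, 0), c(0.1, 0), c(10, 10), c(10.1, 10))
  rownames(x) <- paste0("P", 1:4)
  sel <- select_k_silhouette(x, k_range = 2:3, restarts = 5, seed = 1)
  expect_equal(sel$best_k, 2L)

  flat <- matrix(1, 5, 2, dimnames = list(paste0("P", 1:5), NULL))
  expect_error(select_k_silhouette(flat, k_range = 2:3), "degenerate")
})

test_that("perfect and label-permuted clusterings score 1 on every metric", {
  truth <- rep(1:3, times = c(5, 7, 4))
  m <- clustering_metrics(truth, truth)
  expect_equal(unlist(m), c(nmi = 1, acc = 1, f_score = 1, precision = 1,
                            recall = 1, purity = 1), tolerance = 1e-12)
  renamed <- c("c", "a", "b")[truth]
  m2 <- clustering_metrics(renamed, truth)
  expect_equal(unlist(m2), unlist(m), tolerance = 1e-12)
})

test_that("the hand-enumerated 4-point counterexample scores as computed by hand", {
  # pred = (1,1,2,2), truth = (1,2,1,2): all 6 pairs disagree on co-membership
  # -> pairwise TP = 0 so precision = recall = F = 0; each predicted group is
  # half right -> purity 0.5; the contingency table is uniform -> NMI 0;
  # the best 1-1 matching gets 2 of 4 right -> ACC 0.5
  m <- clustering_metrics(c(1, 1, 2, 2), c(1, 2, 1, 2))
  expect_equal(m$precision, 0)
  expect_equal(m$recall, 0)
  expect_equal(m$f_score, 0)
  expect_equal(m$purity, 0.5)
  expect_equal(m$nmi, 0, tolerance = 1e-12)
  expect_equal(m$acc, 0.5)
})

test_that("accuracy uses the exact optimal assignment (brute-force cross-check)", {
  set.seed(55)
  perm_max <- function(w) {
    n <- nrow(w)
    max(vapply(asplit(gtools_permutations(n), 1),
               function(p) sum(w[cbind(1:n, p)]), numeric(1)))
  }
  # all permutations of 1..n, no external dependency
  gtools_permutations <- function(n) {
    if (n == 1) return(matrix(1L, 1, 1))
    sub <- gtools_permutations(n - 1)
    do.call(rbind, lapply(1:n, function(i) {
      cbind(i, matrix((1:n)[-i][sub], nrow(sub), n - 1))
    }))
  }
  for (rep in 1:20) {
    n <- sample(2:6, 1)
    w <- matrix(sample(0:20, n * n, replace = TRUE), n, n)
    expect_equal(grassmannfuse:::assignment_max(w), perm_max(w))
  }
})

test_that("metrics are invariant to relabeling and reject length mismatches", {
  set.seed(56)
  truth <- sample(1:4, 40, replace = TRUE)
  pred <- sample(1:3, 40, replace = TRUE)
  m <- clustering_metrics(pred, truth)
  m_relab <- clustering_metrics(c(30, 10, 20)[pred], truth * 7)
  expect_equal(m, m_relab, tolerance = 1e-12)
  expect_true(all(unlist(m) >= 0 & unlist(m) <= 1))
  expect_error(clustering_metrics(1:5, 1:4), "equal length")

  # arithmetic-mean NMI normalization stays in [0, 1] too
  m_ar <- clustering_metrics(pred, truth, nmi_norm = "arithmetic")
  expect_true(m_ar$nmi >= 0 && m_ar$nmi <= 1)
})
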