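test_that("the generator is deterministic given the seed", {
  s1 <- small_sim(seed = 9)
  s2 <- small_sim(seed = 9)
  expect_identical(s1$views, s2$views)
  expect_identical(s1$true_labels, s2$true_labels)
  s3 <- small_sim(seed = 10)
  expect_false(identical(s1$views, s3$views))
})

test_that("shapes, labels and proportions follow the spec", {
  sim <- simulate_multiomics(n_samples = 50, n_clusters = 3,
                             cluster_proportions = c(0.5, 0.3, 0.2),
                             view_feature_counts = c(20, 35),
                             latent_dim = 5, separation = 3, seed = 4)
  expect_length(sim$views, 2L)
  expect_equal(nrow(sim$views[[1]]), 50L)
  expect_equal(ncol(sim$views[[1]]) - 1L, 20L)
  expect_equal(as.integer(table(sim$true_labels$cluster)), c(25L, 15L, 10L))
  expect_identical(sim$views[[1]]$patient_id, sim$views[[2]]$patient_id)

  expect_error(simulate_multiomics(n_samples = 5, n_clusters = 6),
               "cannot exceed")
  expect_error(simulate_multiomics(n_samples = 20, view_feature_counts = c(4),
                                   latent_dim = 8),
               "fewer features")
})

test_that("latent centers sit on the separation sphere, mutually orthogonal", {
  set.seed(5)
  centers <- grassmannfuse:::cluster_centers(4, 10, 6)
  expect_equal(sqrt(rowSums(centers^2)), rep(6, 4), tolerance = 1e-10)
  gram <- tcrossprod(centers)
  expect_equal(unname(gram), diag(36, 4), tolerance = 1e-8)
})

test_that("zero separation carries no signal but the pipeline still runs", {
  sim <- simulate_multiomics(n_samples = 60, n_clusters = 3,
                             view_feature_counts = c(25, 40, 30),
                             latent_dim = 6, separation = 0, seed = 12)
  fit <- fuse_pipeline(sim$views, n_clusters = 3, seed = 12)
  m <- clustering_metrics(fit$result, sim$true_labels$cluster)
  expect_lt(m$nmi, 0.3)
})

test_that("well-separated clusters are recovered exactly", {
  hits <- vapply(1:3, function(s) {
    sim <- small_sim(seed = s, separation = 10)
    fit <- fuse_pipeline(sim$views, n_clusters = 3, seed = s)
    clustering_metrics(fit$result, sim$true_labels$cluster)$nmi
  }, numeric(1))
  expect_true(all(hits == 1))
})

test_that("mean recovery is nondecreasing in the separation", {
  seps <- c(0, 1, 2, 4, 8)
  mean_nmi <- vapply(seps, function(sep) {
    mean(vapply(1:10, function(s) {
      sim <- simulate_multiomics(n_samples = 60, n_clusters = 3,
                                 view_feature_counts = c(25, 40, 30),
                                 latent_dim = 6, separation = sep,
                                 seed = s)
      fit <- fuse_pipeline(sim$views, n_clusters = 3, seed = s)
      clustering_metrics(fit$result, sim$true_labels$cluster)$nmi
    }, numeric(1)))
  }, numeric(1))
  # nondecreasing up to Monte Carlo noise; strong overall rise
  expect_true(all(diff(mean_nmi) > -0.05))
  expect_lt(mean_nmi[1], 0.3)
  expect_gt(mean_nmi[5], 0.95)
})

test_that("corrupting a view permutes only the requested rows", {
  sim <- small_sim(seed = 14, n = 40)
  same <- corrupt_view(sim, 1, 0)
  expect_identical(same$views, sim$views)

  full <- corrupt_view(sim, "mirna", 1)
  expect_identical(full$views[[1]]$patient_id, sim$views[[1]]$patient_id)
  expect_false(identical(full$views[[1]], sim$views[[1]]))
  expect_identical(full$views[[2]], sim$views[[2]])
  # marginals preserved: same multiset of rows
  a <- apply(as.matrix(full$views[[1]][-1]), 1, sum)
  b <- apply(as.matrix(sim$views[[1]][-1]), 1, sum)
  expect_equal(sort(a), sort(b), tolerance = 1e-12)

  expect_error(corrupt_view(sim, 9, 0.5), "invalid view index")
})

test_that("fusion withstands one fully corrupted view", {
  deltas <- vapply(1:5, function(s) {
    sim <- small_sim(seed = s, n = 60, separation = 6)
    bad <- corrupt_view(sim, 1, 1)
    fit_all <- fuse_pipeline(bad$views, n_clusters = 3, seed = s)
    nmi_fused <- clustering_metrics(fit_all$result,
                                    sim$true_labels$cluster)$nmi
    fit_bad <- fuse_pipeline(bad$views[1], n_clusters = 3, seed = s)
    nmi_bad <- clustering_metrics(fit_bad$result,
                                  sim$true_labels$cluster)$nmi
    nmi_fused - nmi_bad
  }, numeric(1))
  expect_gt(mean(deltas), 0.3)

  # corrupting every view leaves nothing to recover
  sim <- small_sim(seed = 20, n = 60, separation = 6)
  allbad <- sim
  for (v in 1:3) allbad <- corrupt_view(allbad, v, 1, seed = 100 + v)
  fit <- fuse_pipeline(allbad$views, n_clusters = 3, seed = 20)
  expect_lt(clustering_metrics(fit$result, sim$true_labels$cluster)$nmi, 0.3)
})

test_that("fusing partial-signal views beats the best single view", {
  # eight clusters at the corners of a cube in 3-D latent space; each of
  # three views observes only two of the three axes, so alone it can
  # separate at most four corner pairs -- integration is required. The
  # informative fused subspace is spanned by the constant direction plus
  # the three axis indicators, hence embed_dim = 4.
  run_one <- function(seed) {
    set.seed(seed)
    n_per <- 12
    grid <- as.matrix(expand.grid(a = c(-4, 4), b = c(-4, 4), c = c(-4, 4)))
    n <- 8 * n_per
    latent <- grid[rep(1:8, each = n_per), ] + matrix(rnorm(n * 3), n, 3)
    truth <- rep(1:8, each = n_per)
    ids <- sprintf("P%03d", seq_len(n))
    make_view <- function(axes, d) {
      la <- latent[, axes, drop = FALSE]
      q <- qr.Q(qr(matrix(rnorm(d * length(axes)), d, length(axes)))) *
        sqrt(d / length(axes))
      x <- la %*% t(q) + matrix(rnorm(n * d), n, d)
      rownames(x) <- ids
      colnames(x) <- paste0("f", 1:d)
      x
    }
    views <- list(vab = make_view(c(1, 2), 30), vbc = make_view(c(2, 3), 40),
                  vac = make_view(c(1, 3), 35))
    nmi_single <- vapply(views, function(v) {
      fit <- fuse_pipeline(list(v = v), n_clusters = 8, embed_dim = 4,
                           seed = 1)
      clustering_metrics(fit$result, truth)$nmi
    }, numeric(1))
    fit_fused <- fuse_pipeline(views, n_clusters = 8, embed_dim = 4, seed = 1)
    c(best_single = max(nmi_single),
      fused = clustering_metrics(fit_fused$result, truth)$nmi)
  }
  out <- vapply(1:3, run_one, numeric(2))
  expect_gte(mean(out["fused", ]), mean(out["best_single", ]))
  expect_gt(mean(out["fused", ]), 0.9)
  expect_lt(mean(out["best_single", ]), 0.8)
})

test_that("simulations round-trip through disk with full provenance", {
  sim <- simulate_multiomics(n_samples = 20, n_clusters = 2,
                             view_feature_counts = c(12, 15),
                             latent_dim = 4, separation = 5, seed = 3)
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  views <- read_views(file.path(dir, c("view1.tsv", "view2.tsv")))
  expect_equal(as.matrix(views[[1]][-1]), as.matrix(sim$views[[1]][-1]),
               tolerance = 1e-12, ignore_attr = TRUE)
  spec <- jsonlite::read_json(file.path(dir, "spec.json"), simplifyVector = TRUE)
  expect_equal(spec$seed, 3L)
  expect_equal(spec$n_samples, 20L)
})
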