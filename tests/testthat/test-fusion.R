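test_that("projection distance has the right extremes", {
  set.seed(41)
  y <- random_orthonormal(8, 3)
  expect_equal(projection_distance(y, y), 0, tolerance = 1e-12)
  # rotated basis spans the same subspace
  q <- random_orthonormal(3, 3)
  expect_equal(projection_distance(y, y %*% q), 0, tolerance = 1e-10)
  # orthogonal complements: all principal angles are pi/2
  eye <- diag(8)
  expect_equal(projection_distance(eye[, 1:3], eye[, 4:6]), 3)
  expect_error(projection_distance(eye[, 1:3], eye[, 1:2]), "same N and k")
})

test_that("projection distance equals the principal-angle definition on random pairs", {
  set.seed(42)
  for (i in 1:100) {
    n <- sample(6:20, 1)
    k <- sample(1:min(4, n - 1), 1)
    y <- random_orthonormal(n, k)
    yt <- random_orthonormal(n, k)
    expect_equal(projection_distance(y, yt), principal_angle_distance(y, yt),
                 tolerance = 1e-8)
    expect_equal(projection_distance(y, yt), projection_distance(yt, y),
                 tolerance = 1e-12)
    expect_true(projection_distance(y, yt) >= 0 &&
                  projection_distance(y, yt) <= k + 1e-12)
  }
})

test_that("fusing a single view or identical views returns that subspace", {
  set.seed(43)
  u <- random_orthonormal(10, 2)
  f1 <- fuse_subspaces(list(u))
  expect_equal(projection_distance(f1$fused$basis, u), 0, tolerance = 1e-10)
  expect_equal(unname(f1$per_view_distance), 0, tolerance = 1e-10)

  f3 <- suppressWarnings(fuse_subspaces(list(u, u, u)))
  expect_equal(unname(f3$per_view_distance), rep(0, 3), tolerance = 1e-10)
  expect_equal(f3$eigenvalues[1:2], c(3, 3), tolerance = 1e-10)
})

test_that("the fused subspace attains the Ky Fan optimum and beats random candidates", {
  set.seed(44)
  bases <- lapply(1:3, function(i) random_orthonormal(10, 2))
  fus <- fuse_subspaces(bases)
  # Ky Fan certificate: objective = sum of the 2 largest eigenvalues of L_mod
  ev <- eigen(fus$l_mod, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(fus$objective, sum(ev[1:2]), tolerance = 1e-10)
  # summed distance identity: sum d2 = kM - objective
  expect_equal(sum(fus$per_view_distance), 2 * 3 - fus$objective,
               tolerance = 1e-8)
  # no random orthonormal candidate does better
  obj <- function(u) sum(vapply(bases, function(b) sum(crossprod(u, b)^2),
                                numeric(1)))
  rand_best <- max(vapply(1:5000, function(i) obj(random_orthonormal(10, 2)),
                          numeric(1)))
  expect_gte(fus$objective + 1e-10, rand_best)
})

test_that("fusion is invariant to per-view rotation and to view order", {
  set.seed(45)
  bases <- lapply(1:3, function(i) random_orthonormal(12, 3))
  fus <- fuse_subspaces(bases)
  rotated <- bases
  rotated[[2]] <- rotated[[2]] %*% random_orthonormal(3, 3)
  fus_rot <- fuse_subspaces(rotated)
  expect_equal(fus$l_mod, fus_rot$l_mod, tolerance = 1e-8)
  expect_lt(projection_distance(fus$fused$basis, fus_rot$fused$basis), 1e-8)
  expect_equal(fus$per_view_distance, fus_rot$per_view_distance,
               tolerance = 1e-8)

  fus_perm <- fuse_subspaces(bases[c(3, 1, 2)])
  expect_lt(projection_distance(fus$fused$basis, fus_perm$fused$basis), 1e-8)
})

test_that("the Euclidean average of bases is not closer than the Grassmann solution", {
  # contrast with the rejected plain-averaging formulation: orthonormalize
  # the elementwise mean of the bases and compare summed projection distances
  set.seed(46)
  bases <- lapply(1:3, function(i) random_orthonormal(12, 2))
  fus <- fuse_subspaces(bases)
  avg <- qr.Q(qr(Reduce(`+`, bases) / 3))
  d_avg <- sum(vapply(bases, function(b) projection_distance(avg, b), numeric(1)))
  expect_lte(sum(fus$per_view_distance), d_avg + 1e-10)
})

test_that("mismatched patient orderings are fatal", {
  set.seed(47)
  u1 <- random_orthonormal(6, 2)
  u2 <- random_orthonormal(6, 2)
  rownames(u1) <- paste0("P", 1:6)
  rownames(u2) <- paste0("P", 6:1)
  e1 <- grassmannfuse:::new_subspace_embedding(u1, rownames(u1))
  e2 <- grassmannfuse:::new_subspace_embedding(u2, rownames(u2))
  expect_error(fuse_subspaces(list(e1, e2)), "inconsistent patient orderings")
})
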