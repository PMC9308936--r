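# Shared fixtures and independent oracles used across the suite.

# random N x k matrix with orthonormal columns
random_orthonormal <- function(n, k) {
  qr.Q(qr(matrix(rnorm(n * k), n, k)))
}

# Grassmann projection distance computed from first principles: principal
# angles are acos of the singular values of Y' Ỹ, and the distance is the
# sum of their squared sines. Independent of the trace shortcut used by
# the package.
principal_angle_distance <- function(y, ytilde) {
  s <- svd(crossprod(y, ytilde))$d
  theta <- acos(pmin(pmax(s, -1), 1))
  sum(sin(theta)^2)
}

# Two-group log-rank statistic computed directly from the observed-minus-
# expected table over event times, with the hypergeometric variance.
logrank_oracle <- function(time, event, group) {
  g <- as.integer(factor(group))
  stopifnot(max(g) == 2L)
  ev_times <- sort(unique(time[event == 1]))
  o1 <- e1 <- v <- 0
  for (tt in ev_times) {
    at_risk <- time >= tt
    n <- sum(at_risk)
    n1 <- sum(at_risk & g == 1L)
    d <- sum(time == tt & event == 1)
    d1 <- sum(time == tt & event == 1 & g == 1L)
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (o1 - e1)^2 / v
}

# small three-view simulation used by several end-to-end tests
small_sim <- function(seed = 1, n = 90, k = 3, separation = 8) {
  simulate_multiomics(n_samples = n, n_clusters = k,
                      view_feature_counts = c(30, 60, 45),
                      latent_dim = 6, separation = separation,
                      noise_sd = 1, seed = seed)
}

# a connected random kNN-style weighted graph adjacency for spectral tests
random_graph <- function(n, k = 3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  h <- matrix(rnorm(n * 3), n, 3)
  rownames(h) <- sprintf("P%02d", seq_len(n))
  knn_sparsify(gaussian_similarity(h), n_neighbors = k)
}
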