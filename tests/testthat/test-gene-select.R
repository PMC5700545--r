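test_that("PAM solves small worked examples exactly", {
  # two tight pairs on the line: optimum picks one medoid per pair
  X <- matrix(c(0, 1, 10, 11), ncol = 1)
  sol <- pam_cluster(X, 2, "euclidean", seed = 4)
  expect_equal(sol$cost, 2.0)
  expect_equal(sort(sol$labels), c(1L, 1L, 2L, 2L))
  # K = n: every point its own medoid, zero cost
  soln <- pam_cluster(X, 4, "euclidean", seed = 1)
  expect_equal(soln$cost, 0)
  # {0,1,2}, K = 1: middle point is the medoid
  sol1 <- pam_cluster(matrix(c(0, 1, 2), ncol = 1), 1, seed = 1)
  expect_equal(sol1$medoids, 2L)
  expect_equal(sol1$cost, 2.0)
  expect_error(pam_cluster(X, 5), "invalid K")
  expect_error(pam_cluster(matrix(c(0, 0, 0, 1), ncol = 1), 3),
               "degenerate data")
})

test_that("PAM is deterministic under a fixed seed and local-optimal", {
  set.seed(8)
  X <- matrix(rnorm(40), 20, 2)
  a <- pam_cluster(X, 3, "euclidean", seed = 5)
  b <- pam_cluster(X, 3, "euclidean", seed = 5)
  expect_identical(a$medoids, b$medoids)
  expect_identical(a$labels, b$labels)
  # no single (medoid, non-medoid) swap improves the final cost
  D <- annotation_dist_matrix(X, "euclidean")
  for (mi in seq_along(a$medoids)) {
    for (o in setdiff(seq_len(nrow(X)), a$medoids)) {
      cand <- a$medoids; cand[mi] <- o
      cc <- sum(apply(D[, cand, drop = FALSE], 1, min))
      expect_gte(cc, a$cost - 1e-12)
    }
  }
})

test_that("PAM never beats and usually matches exhaustive search", {
  for (s in 1:40) {
    set.seed(s)
    n <- sample(4:8, 1); K <- sample(1:min(3L, n), 1)
    X <- matrix(rnorm(2 * n), n, 2)
    D <- as.matrix(dist(X))
    opt <- pam_exhaustive(D, K)$cost
    expect_gte(pam_cluster(X, K, seed = s)$cost, opt - 1e-9)
    # multi-start reaches the global optimum on these tiny instances
    expect_equal(pam_cluster(X, K, seed = s, restarts = 10)$cost, opt,
                 tolerance = 1e-9)
  }
})

test_that("PAM finds planted well-separated groups from any seed", {
  set.seed(2)
  X <- rbind(matrix(rnorm(10, 0, 0.05), 5, 2),
             matrix(rnorm(10, 20, 0.05), 5, 2))
  D <- as.matrix(dist(X))
  opt <- pam_exhaustive(D, 2)$cost
  for (s in 1:10) {
    expect_equal(pam_cluster(X, 2, seed = s)$cost, opt, tolerance = 1e-9)
  }
})

test_that("silhouette matches hand evaluation and conventions", {
  X <- matrix(c(0, 1, 10, 11), ncol = 1)
  D <- as.matrix(dist(X))
  lab <- c(1, 1, 2, 2)
  # a = 1 everywhere; b = 10.5, 9.5, 9.5, 10.5
  expect_equal(silhouette_index(D, lab),
               mean(c(9.5 / 10.5, 8.5 / 9.5, 8.5 / 9.5, 9.5 / 10.5)),
               tolerance = 1e-12)
  expect_equal(silhouette_index(D, lab), 0.899749, tolerance = 1e-6)
  # all-singleton partition scores 0 by convention
  expect_equal(silhouette_index(D, 1:4), 0)
  # coincident-point clusters far apart approach the (b - 0)/b = 1 limit
  Y <- matrix(c(0, 0, 50, 50), ncol = 1)
  expect_equal(silhouette_index(as.matrix(dist(Y)), lab), 1.0)
  expect_error(silhouette_index(D, rep(1, 4)), "single cluster")
})

test_that("silhouette agrees with the reference implementation", {
  skip_if_not_installed("cluster")
  set.seed(77)
  X <- matrix(rnorm(60), 30, 2)
  lab <- sample(1:3, 30, replace = TRUE)
  D <- as.matrix(dist(X))
  ours <- silhouette_index(D, lab)
  ref <- mean(cluster::silhouette(lab, dmatrix = D)[, "sil_width"])
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("sqrt-n heuristic and default grids match the known regimes", {
  expect_equal(max_k_heuristic(2260), 48L)
  expect_equal(max_k_heuristic(4673), 68L)
  expect_equal(max_k_heuristic(100), 10L)
  expect_error(max_k_heuristic(3), "too few")
  expect_equal(default_k_grid(2260), c(5L, 10L, 20L, 30L, 40L, 50L))
  expect_equal(default_k_grid(4673), c(5L, 10L, 20L, 30L, 40L, 50L, 60L, 70L))
})

test_that("sweep_k scores every (kind, K) and returns the argmax", {
  set.seed(6)
  M <- rbind(matrix(rnorm(24, 0, 0.1), 12, 2),
             matrix(rnorm(24, 5, 0.1), 12, 2))
  rownames(M) <- sprintf("g%02d", 1:24)
  sw <- sweep_k(M, k_grid = c(2, 3), kinds = c("euclidean", "cityblock"),
                seed = 1, allow_large_k = TRUE)
  expect_equal(nrow(sw$table), 4L)
  expect_equal(sw$best$silhouette, max(sw$table$silhouette))
  expect_equal(sw$best$K, 2L)  # two planted row groups
  # singleton grid returns that solution
  sw1 <- sweep_k(M, k_grid = 4, kinds = "euclidean", allow_large_k = TRUE)
  expect_equal(sw1$best$K, 4L)
  expect_error(sweep_k(M, k_grid = integer(0)), "no K candidates")
  expect_error(sweep_k(M, k_grid = 11), "allow_large_k")
})

test_that("medoid extraction and expression slicing are consistent", {
  set.seed(10)
  M <- matrix(rnorm(40), 10, 4)
  rownames(M) <- sprintf("g%02d", 1:10)
  sol <- pam_cluster(M, 3, seed = 2)
  red <- extract_medoids(sol, M)
  expect_equal(red$gene_ids, rownames(M)[sol$medoids])
  expect_equal(length(red$gene_ids), sol$K)

  expr <- matrix(rnorm(17 * 10), 17, 10,
                 dimnames = list(NULL, rownames(M)))
  sliced <- reduce_expression(expr, red)
  expect_equal(dim(sliced), c(17L, 3L))
  expect_equal(sliced, expr[, red$gene_ids])
  # identity slice
  expect_equal(reduce_expression(expr, colnames(expr)), expr)
  expect_error(reduce_expression(expr, c(red$gene_ids, "gXX")), "gXX")
})
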