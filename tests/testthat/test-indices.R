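test_that("XB index matches hand expansion and is scale-invariant", {
  tp <- toy_partition()
  expect_equal(xb_index(tp$points4, tp$centers, tp$labels), 0.01)
  # points on centers score 0
  expect_equal(xb_index(tp$centers[tp$labels, , drop = FALSE], tp$centers,
                        tp$labels), 0)
  expect_equal(xb_index(tp$points4 * 7, tp$centers * 7, tp$labels), 0.01,
               tolerance = 1e-12)
  expect_error(xb_index(tp$points4, rbind(c(1), c(1)), tp$labels),
               "zero separation")
})

test_that("PBM index matches hand expansion and is translation-invariant", {
  tp <- toy_partition()
  # E1 = 20 about grand centroid 6, EK = 4, DK = 10
  expect_equal(pbm_index(tp$points4, tp$centers, tp$labels), 625)
  expect_equal(pbm_index(tp$points4 + 3, tp$centers + 3, tp$labels), 625,
               tolerance = 1e-9)
  expect_error(pbm_index(tp$points4, tp$centers[1, , drop = FALSE],
                         rep(1, 4)), "at least 2")
})

test_that("fuzzy c-means objective matches its closed form", {
  tp <- toy_partition()
  # m = 2: each point contributes 1 / sum_k d_k^-2
  oracle <- 2 / (1 / 1 + 1 / 121) + 2 / (1 / 1 + 1 / 81)
  expect_equal(fcm_index(tp$points4, tp$centers), oracle, tolerance = 1e-12)
  expect_equal(fcm_index(tp$points4, tp$centers), 3.9592163,
               tolerance = 1e-6)
  # single point at distances (1, 11)
  expect_equal(fcm_index(matrix(0, 1, 1), tp$centers), 1 / (1 + 1 / 121),
               tolerance = 1e-12)
  expect_equal(fcm_index(matrix(0, 1, 1), tp$centers), 0.99180,
               tolerance = 1e-4)
  # points on centers -> 0; K = 1 -> plain SSE
  expect_equal(fcm_index(tp$centers, tp$centers), 0)
  expect_equal(fcm_index(tp$points4, matrix(6, 1, 1)),
               sum((tp$points4 - 6)^2))
  # translation invariance
  expect_equal(fcm_index(tp$points4 - 5, tp$centers - 5), oracle,
               tolerance = 1e-9)
})

test_that("J_m never exceeds the hard-assignment SSE for m > 1", {
  set.seed(33)
  for (i in 1:20) {
    X <- matrix(rnorm(40), 20, 2)
    C <- X[sample(20, 3), ]
    expect_lte(fcm_index(X, C, m = 2),
               fcm_index(X, C, crisp = TRUE) + 1e-12)
  }
})

test_that("DB and Dunn match hand expansion on tight pairs", {
  tp <- toy_partition()
  expect_equal(db_index(tp$tight4, tp$labels), 0.1)
  expect_equal(dunn_index(tp$tight4, tp$labels), 9)
  # coincident-point clusters far apart: DB 0, Dunn degenerate
  Y <- matrix(c(0, 0, 50, 50), ncol = 1)
  expect_equal(db_index(Y, tp$labels), 0)
  expect_warning(d <- dunn_index(Y, tp$labels), "degenerate")
  expect_equal(d, Inf)
  expect_error(db_index(tp$tight4, rep(1, 4)), "at least 2")
  # merging the true pairs lowers Dunn below the true partition
  expect_lt(dunn_index(tp$tight4, c(1, 2, 1, 2)),
            dunn_index(tp$tight4, tp$labels))
})

test_that("indices are invariant to cluster relabelling", {
  set.seed(11)
  X <- rbind(matrix(rnorm(20, 0, 0.3), 10, 2),
             matrix(rnorm(20, 4, 0.3), 10, 2))
  C <- rbind(c(0, 0), c(4, 4))
  lab <- rep(1:2, each = 10)
  swap <- 3L - lab  # relabel 1<->2
  expect_equal(xb_index(X, C, lab), xb_index(X, C[2:1, ], swap),
               tolerance = 1e-12)
  expect_equal(pbm_index(X, C, lab), pbm_index(X, C[2:1, ], swap),
               tolerance = 1e-12)
  expect_equal(db_index(X, lab), db_index(X, swap), tolerance = 1e-12)
  expect_equal(dunn_index(X, lab), dunn_index(X, swap), tolerance = 1e-12)
})

test_that("the true partition of separated blobs beats random ones", {
  set.seed(21)
  X <- rbind(matrix(rnorm(30, 0, 0.5), 15, 2),
             matrix(rnorm(30, 8, 0.5), 15, 2))
  truth <- rep(1:2, each = 15)
  ctr <- rbind(colMeans(X[1:15, ]), colMeans(X[16:30, ]))
  D <- as.matrix(dist(X))
  for (i in 1:100) {
    rnd <- sample(rep(1:2, each = 15))
    rctr <- rbind(colMeans(X[rnd == 1, , drop = FALSE]),
                  colMeans(X[rnd == 2, , drop = FALSE]))
    expect_lt(xb_index(X, ctr, truth), xb_index(X, rctr, rnd))
    expect_gt(pbm_index(X, ctr, truth), pbm_index(X, rctr, rnd))
    expect_lt(db_index(X, truth), db_index(X, rnd))
    expect_gt(dunn_index(X, truth), dunn_index(X, rnd))
    expect_gt(silhouette_index(D, truth), silhouette_index(D, rnd))
  }
})

test_that("%CoA uses the optimal cluster-to-class mapping", {
  # identical up to renaming
  expect_equal(classification_accuracy(c(2, 2, 1, 1), c("A", "A", "B", "B")),
               100)
  # worked 2x2 example: best bijection gets 3 of 4
  expect_equal(classification_accuracy(c(1, 1, 1, 2), c("A", "A", "B", "B")),
               75)
  # one cluster over two balanced classes
  expect_equal(classification_accuracy(rep(1, 4), c("A", "A", "B", "B")), 50)
  expect_error(classification_accuracy(1:3, 1:4), "same length")
})

test_that("%CoA matches brute force and is relabel-invariant", {
  set.seed(19)
  for (i in 1:25) {
    n <- 30
    truth <- sample(letters[1:3], n, replace = TRUE)
    pred <- sample.int(sample(2:5, 1), n, replace = TRUE)
    ours <- classification_accuracy(pred, truth)
    expect_equal(ours, coa_brute(pred, truth))
    # bijective relabelling of pred leaves %CoA unchanged
    perm <- sample(max(pred))
    expect_equal(classification_accuracy(perm[pred], truth), ours)
  }
})
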