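# Cluster validity indices. XB/PBM/FCM serve as the annealer's
# objectives; DB, Dunn, silhouette and %CoA are evaluation metrics.
# All of them use Euclidean distance in expression space.

.as_points <- function(x) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  x
}

# squared Euclidean distances points (n x m) -> centers (k x m)
.sqdist_to_centers <- function(X, C) {
  d2 <- outer(rowSums(X^2), rowSums(C^2), "+") - 2 * tcrossprod(X, C)
  d2[d2 < 0] <- 0
  d2
}

.rowMins <- function(m) m[cbind(seq_len(nrow(m)), max.col(-m, ties.method = "first"))]

.check_partition <- function(n_points, labels, k_min = 2L) {
  labels <- as.integer(labels)
  if (length(labels) != n_points) stop("labels length does not match points")
  k <- max(labels)
  if (length(unique(labels)) < k_min) {
    stop("need at least ", k_min, " non-empty clusters")
  }
  labels
}

#' Xie-Beni index
#'
#' Within-cluster scatter over minimal center separation:
#' `sum_k sum_{x in C_k} ||x - c_k||^2 / (n * min_{i != j} ||c_i - c_j||^2)`.
#' Smaller is better; the index is invariant to uniform scaling of all
#' coordinates.
#'
#' @param points Numeric matrix, points in rows.
#' @param centers Numeric matrix of cluster centers (K >= 2 rows,
#'   pairwise distinct).
#' @param labels Integer assignment of points to center rows.
#' @return Non-negative scalar.
#' @export
xb_index <- function(points, centers, labels) {
  X <- .as_points(points); C <- .as_points(centers)
  if (nrow(C) < 2) stop("XB index needs at least 2 centers")
  labels <- .check_partition(nrow(X), labels, 1L)
  d2 <- .sqdist_to_centers(X, C)
  sep <- .sqdist_to_centers(C, C)
  min_sep <- min(sep[upper.tri(sep)])
  if (min_sep == 0) stop("zero separation: coincident centers")
  sum(d2[cbind(seq_len(nrow(X)), labels)]) / (nrow(X) * min_sep)
}

#' PBM index
#'
#' `((1/K) * (E_1 / E_K) * D_K)^2` with `E_1` the sum of distances to
#' the grand centroid, `E_K` the sum of distances of points to their
#' assigned centers, and `D_K` the maximum inter-center distance.
#' Larger is better; the index is invariant to rigid translation.
#'
#' @inheritParams xb_index
#' @return Non-negative scalar.
#' @export
pbm_index <- function(points, centers, labels) {
  X <- .as_points(points); C <- .as_points(centers)
  K <- nrow(C)
  if (K < 2) stop("PBM index needs at least 2 centers")
  labels <- .check_partition(nrow(X), labels, 1L)
  grand <- colMeans(X)
  e1 <- sum(sqrt(rowSums((X - rep(grand, each = nrow(X)))^2)))
  d <- sqrt(.sqdist_to_centers(X, C))
  ek <- sum(d[cbind(seq_len(nrow(X)), labels)])
  dk <- sqrt(max(.sqdist_to_centers(C, C)))
  if (ek == 0) {
    if (e1 == 0) return(0)
    stop("degenerate partition: every point sits on its center")
  }
  ((1 / K) * (e1 / ek) * dk)^2
}

#' Fuzzy c-means objective J_m
#'
#' `J_m = sum_i sum_k u_ik^m ||x_i - c_k||^2` with memberships derived
#' from the center distances, `u_ik = 1 / sum_j (d_ik / d_ij)^(2/(m-1))`.
#' A point lying exactly on a center takes membership 1 there. Smaller
#' is better. For m = 2 each point contributes `1 / sum_k d_ik^-2`.
#'
#' @inheritParams xb_index
#' @param m Fuzzifier, `> 1` (default 2). With `crisp = TRUE` the
#'   hard-assignment sum of squared errors is returned instead.
#' @param crisp Use hard nearest-center assignment instead of fuzzy
#'   memberships.
#' @return Non-negative scalar.
#' @export
fcm_index <- function(points, centers, m = 2, crisp = FALSE) {
  X <- .as_points(points); C <- .as_points(centers)
  d2 <- .sqdist_to_centers(X, C)
  if (crisp) return(sum(.rowMins(d2)))
  if (nrow(C) == 1) return(sum(d2))
  if (m <= 1) stop("fuzzifier m must exceed 1")
  on_center <- .rowMins(d2) == 0   # membership 1 there, contribution 0
  if (all(on_center)) return(0)
  d2 <- d2[!on_center, , drop = FALSE]
  W <- (1 / d2)^(1 / (m - 1))      # proportional memberships
  U <- W / rowSums(W)
  sum(U^m * d2)
}

#' Davies-Bouldin index
#'
#' `(1/K) * sum_i max_{j != i} (S_i + S_j) / M_ij` with `S` the mean
#' distance of cluster members to their centroid and `M` the centroid
#' separation. Smaller is better.
#'
#' @param points Numeric matrix, points in rows.
#' @param labels Integer cluster assignment (K >= 2 non-empty
#'   clusters).
#' @return Non-negative scalar.
#' @export
db_index <- function(points, labels) {
  X <- .as_points(points)
  labels <- .check_partition(nrow(X), labels)
  labels <- as.integer(factor(labels))
  k <- max(labels)
  centroids <- matrix(0, k, ncol(X))
  for (cl in seq_len(k)) {
    centroids[cl, ] <- colMeans(X[labels == cl, , drop = FALSE])
  }
  s <- vapply(seq_len(k), function(cl) {
    mean(sqrt(rowSums((X[labels == cl, , drop = FALSE] -
                         rep(centroids[cl, ], each = sum(labels == cl)))^2)))
  }, numeric(1))
  M <- sqrt(.sqdist_to_centers(centroids, centroids))
  if (any(M[upper.tri(M)] == 0)) stop("zero separation: coincident centroids")
  r <- vapply(seq_len(k), function(i) {
    max((s[i] + s[-i]) / M[i, -i])
  }, numeric(1))
  mean(r)
}

#' Dunn index
#'
#' Minimum single-linkage inter-cluster distance divided by the
#' maximum intra-cluster diameter. Larger is better. When every
#' cluster collapses to a single point (zero diameter) the partition
#' is degenerate and `Inf` is returned.
#'
#' @inheritParams db_index
#' @return Positive scalar, possibly `Inf` for degenerate partitions.
#' @export
dunn_index <- function(points, labels) {
  X <- .as_points(points)
  labels <- .check_partition(nrow(X), labels)
  labels <- as.integer(factor(labels))
  D <- as.matrix(stats::dist(X))
  same <- outer(labels, labels, "==")
  diam <- max(D[same])
  min_link <- min(D[!same])
  if (diam == 0) {
    warning("degenerate partition: zero intra-cluster diameter")
    return(Inf)
  }
  min_link / diam
}

#' Classification accuracy (%CoA)
#'
#' Percentage of samples whose cluster label matches the true class
#' under the best cluster-to-class mapping. The mapping is injective
#' where possible (distinct clusters claim distinct classes); when
#' there are more clusters than classes the surplus clusters fall back
#' to their majority class. The optimum over all such mappings is
#' found by exact enumeration on the confusion matrix, so the measure
#' is invariant under any relabelling of the predicted clusters.
#'
#' @param pred Predicted cluster labels.
#' @param truth True class labels (same length).
#' @return Accuracy as a percentage in `[0, 100]`.
#' @export
classification_accuracy <- function(pred, truth) {
  if (length(pred) != length(truth)) {
    stop("pred and truth must have the same length")
  }
  conf <- unclass(table(pred, truth))
  K <- nrow(conf); C <- ncol(conf)
  surplus <- max(0L, K - C)
  row_max <- apply(conf, 1, max)

  best <- -Inf
  # each cluster row claims an unused class, or (surplus rows only)
  # falls back to its majority class; dead ends prune themselves
  dfs <- function(row, used, slack, acc) {
    if (row > K) { best <<- max(best, acc); return() }
    for (cl in seq_len(C)) {
      if (!used[cl]) {
        used[cl] <- TRUE
        dfs(row + 1L, used, slack, acc + conf[row, cl])
        used[cl] <- FALSE
      }
    }
    if (slack > 0L) dfs(row + 1L, used, slack - 1L, acc + row_max[row])
  }
  dfs(1L, rep(FALSE, C), surplus, 0)
  100 * best / length(pred)
}
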