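#' Partitioning Around Medoids with steepest-descent swaps
#'
#' K-medoids clustering of annotation-matrix rows. Starting from a
#' seeded random medoid set, every (medoid, non-medoid) swap is
#' evaluated and the best strictly-improving swap is applied until no
#' swap lowers the cost (sum of point-to-medoid distances). Each point
#' is assigned to its nearest medoid; ties go to the lowest medoid
#' index, and equal-cost swaps keep the incumbent configuration, so the
#' run is fully deterministic given the seed.
#'
#' @param M An `annotation_matrix` / numeric matrix of points (rows),
#'   or a precomputed symmetric distance matrix (set
#'   `is_dist = TRUE`).
#' @param K Number of medoids, `1 <= K <= n`.
#' @param kind Distance used when `M` is a point matrix; see
#'   [annotation_dist_matrix()].
#' @param seed Integer seed driving medoid initialisation.
#' @param is_dist Set TRUE when `M` is already a distance matrix.
#' @param restarts Number of independent seeded initialisations
#'   (seeds `seed, seed + 1, ...`); the lowest-cost local optimum is
#'   returned. Default 1. Steepest-descent swaps can stall in a local
#'   optimum from an unlucky start, so small instances reach the
#'   global optimum reliably with a handful of restarts.
#' @return Object of class `pam_solution`: list with `K`, `medoids`
#'   (row indices), `labels` (cluster of each point, 1..K), `cost`,
#'   `kind`, `silhouette` (same distance as the clustering; NA when
#'   K < 2), `seed`.
#' @export
pam_cluster <- function(M, K, kind = c("euclidean", "cityblock", "cosine"),
                        seed = 1L, is_dist = FALSE, restarts = 1L) {
  kind <- match.arg(kind)
  if (restarts > 1L) {
    sols <- lapply(seq_len(restarts) - 1L, function(r) {
      pam_cluster(M, K, kind, seed = seed + r, is_dist = is_dist)
    })
    return(sols[[which.min(vapply(sols, `[[`, numeric(1), "cost"))]])
  }
  if (is_dist) {
    D <- as.matrix(M)
  } else {
    if (K <= nrow(M)) {
      n_unique <- nrow(unique(as.matrix(unclass(M))))
      if (n_unique < K) {
        stop("degenerate data: only ", n_unique,
             " distinct rows, cannot place ", K, " distinct medoids")
      }
    }
    D <- annotation_dist_matrix(M, kind)
  }
  n <- nrow(D)
  if (K < 1 || K > n) stop("invalid K: need 1 <= K <= ", n)

  set.seed(seed)
  medoids <- sort(sample.int(n, K))
  cost <- .pam_cost(D, medoids)

  repeat {
    best <- list(cost = cost)
    non_medoids <- setdiff(seq_len(n), medoids)
    for (mi in seq_len(K)) {
      for (o in non_medoids) {
        cand <- medoids
        cand[mi] <- o
        cc <- .pam_cost(D, cand)
        if (cc < best$cost) best <- list(cost = cc, medoids = cand)
      }
    }
    if (best$cost < cost) {
      medoids <- best$medoids
      cost <- best$cost
    } else break
  }

  medoids <- sort(medoids)
  A <- D[, medoids, drop = FALSE]
  labels <- max.col(-A, ties.method = "first")
  sil <- if (K >= 2) silhouette_index(D, labels) else NA_real_
  structure(list(K = K, medoids = medoids, labels = labels,
                 cost = sum(A[cbind(seq_len(n), labels)]),
                 kind = kind, silhouette = sil, seed = seed),
            class = "pam_solution")
}

.pam_cost <- function(D, medoids) {
  A <- D[, medoids, drop = FALSE]
  sum(A[cbind(seq_len(nrow(D)), max.col(-A, ties.method = "first"))])
}

#' @export
print.pam_solution <- function(x, ...) {
  cat("pam_solution: K =", x$K, "| kind =", x$kind,
      "| cost =", format(x$cost), "| silhouette =",
      format(x$silhouette), "\n")
  invisible(x)
}

#' Silhouette index of a partition
#'
#' Mean over points of `(b - a) / max(a, b)`, where `a` is the mean
#' distance to the point's own cluster (excluding itself) and `b` the
#' smallest mean distance to any other cluster. Members of singleton
#' clusters contribute 0. Values lie in `[-1, 1]`; larger is better.
#'
#' @param D Symmetric pairwise distance matrix (or `dist`).
#' @param labels Integer cluster assignment, at least 2 distinct
#'   clusters, all non-empty.
#' @return The mean silhouette width.
#' @export
silhouette_index <- function(D, labels) {
  D <- as.matrix(D)
  labels <- as.integer(factor(labels))
  k <- max(labels)
  if (k < 2) stop("silhouette undefined for a single cluster")
  n <- length(labels)
  sizes <- tabulate(labels, k)
  # mean distance from every point to every cluster
  G <- vapply(seq_len(k), function(cl) {
    rowSums(D[, labels == cl, drop = FALSE])
  }, numeric(n))
  s <- numeric(n)
  for (i in seq_len(n)) {
    cl <- labels[i]
    if (sizes[cl] == 1L) { s[i] <- 0; next }
    a <- G[i, cl] / (sizes[cl] - 1L)
    b <- min(G[i, -cl] / sizes[-cl])
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

#' Upper bound on the number of clusters
#'
#' The standard rule of thumb for an unknown cluster count: the
#' nearest integer to the square root of the number of points.
#'
#' @param n Number of points, `n >= 4`.
#' @return Integer, `round(sqrt(n))`.
#' @examples
#' max_k_heuristic(2260) # 48
#' max_k_heuristic(4673) # 68
#' @export
max_k_heuristic <- function(n) {
  if (n < 4) stop("too few points for the sqrt(n) heuristic (need n >= 4)")
  as.integer(round(sqrt(n)))
}

#' Default K grid for the PAM sweep
#'
#' Candidate cluster counts 5, 10, 20, 30, ... kept up to the
#' `sqrt(n)` bound rounded up to the next ten (so 2260 genes give
#' 5,10,20,30,40,50 and 4673 give 5,...,70), and always below `n`.
#'
#' @param n Number of genes (rows of the annotation matrix).
#' @return Integer vector of K values.
#' @export
default_k_grid <- function(n) {
  cap <- 10L * as.integer(ceiling(max_k_heuristic(n) / 10))
  grid <- c(5L, seq(10L, max(cap, 10L), by = 10L))
  grid <- grid[grid <= cap & grid < n]
  if (length(grid) == 0L) grid <- max(2L, min(5L, n - 1L))
  grid
}

#' Sweep PAM over a K grid and distance kinds
#'
#' Runs [pam_cluster()] for every (distance kind, K) combination,
#' scores each solution with the silhouette index computed under the
#' same distance, and returns the solution with the maximum silhouette
#' together with the full score table. Sweep runs are independently
#' seeded `seed + run_index - 1`.
#'
#' @param M Annotation matrix (rows clustered).
#' @param k_grid Integer vector of K values; defaults to
#'   [default_k_grid()].
#' @param kinds Distance kinds to try.
#' @param seed Base seed.
#' @param allow_large_k Permit K beyond the default-grid cap
#'   (`sqrt(n)` rounded up to the next ten).
#' @param restarts Independent initialisations per (kind, K) run; see
#'   [pam_cluster()].
#' @return List of class `pam_sweep`: `best` (a `pam_solution`),
#'   `table` (data.frame kind, K, silhouette, cost).
#' @export
sweep_k <- function(M, k_grid = NULL,
                    kinds = c("euclidean", "cityblock", "cosine"),
                    seed = 1L, allow_large_k = FALSE, restarts = 1L) {
  n <- nrow(M)
  if (is.null(k_grid)) k_grid <- default_k_grid(n)
  if (length(k_grid) == 0L) stop("no K candidates supplied")
  if (!allow_large_k) {
    cap <- 10L * as.integer(ceiling(max_k_heuristic(n) / 10))
    if (any(k_grid > cap)) {
      stop("K value(s) ", paste(k_grid[k_grid > cap], collapse = ", "),
           " exceed the sqrt(n) cap ", cap,
           "; use allow_large_k = TRUE to override")
    }
  }
  kinds <- match.arg(kinds, several.ok = TRUE)

  runs <- expand.grid(kind = kinds, K = k_grid, stringsAsFactors = FALSE)
  best <- NULL
  tab <- vector("list", nrow(runs))
  for (r in seq_len(nrow(runs))) {
    sol <- pam_cluster(M, runs$K[r], runs$kind[r], seed = seed + r - 1L,
                       restarts = restarts)
    tab[[r]] <- data.frame(kind = runs$kind[r], K = runs$K[r],
                           silhouette = sol$silhouette, cost = sol$cost,
                           stringsAsFactors = FALSE)
    if (is.null(best) || isTRUE(sol$silhouette > best$silhouette)) best <- sol
  }
  structure(list(best = best, table = do.call(rbind, tab)),
            class = "pam_sweep")
}

#' @export
print.pam_sweep <- function(x, ...) {
  cat("pam_sweep over", nrow(x$table), "runs; winner:\n")
  print(x$best)
  invisible(x)
}

#' Extract medoid genes as the reduced feature set
#'
#' @param sol A `pam_solution` produced from `M`.
#' @param M The annotation matrix the solution was fitted on.
#' @return Object of class `reduced_gene_set`: list with `gene_ids`
#'   (the `n_m = K` medoid gene ids, in medoid order) and `provenance`
#'   (distance kind, K, silhouette).
#' @export
extract_medoids <- function(sol, M) {
  ids <- rownames(M)[sol$medoids]
  structure(list(gene_ids = ids,
                 provenance = list(kind = sol$kind, K = sol$K,
                                   silhouette = sol$silhouette)),
            class = "reduced_gene_set")
}

#' @export
print.reduced_gene_set <- function(x, ...) {
  cat("reduced_gene_set:", length(x$gene_ids), "medoid genes (kind =",
      x$provenance$kind, ", K =", x$provenance$K, ")\n")
  cat(" ", paste(x$gene_ids, collapse = ", "), "\n")
  invisible(x)
}

#' Slice an expression matrix down to the reduced gene space
#'
#' @param expr Numeric matrix, samples x genes, with gene ids as
#'   column names.
#' @param genes A `reduced_gene_set` or character vector of gene ids.
#' @return The column-sliced `d x n_m` matrix, sample order preserved.
#' @export
reduce_expression <- function(expr, genes) {
  ids <- if (inherits(genes, "reduced_gene_set")) genes$gene_ids else genes
  missing <- setdiff(ids, colnames(expr))
  if (length(missing)) {
    stop("gene id(s) absent from expression matrix: ",
         paste(missing, collapse = ", "))
  }
  expr[, ids, drop = FALSE]
}
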