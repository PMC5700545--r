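# Archived multi-objective simulated annealing for sample clustering.
# Solutions are variable-length strings of cluster centers in the
# (reduced) gene space; objectives are (XB, PBM, FCM), internally
# minimised as (xb, -pbm, fcm). The archive holds mutually
# non-dominating solutions, capped at SL during the run and clustered
# down to HL on return.

#' AMOSA configuration
#'
#' @param t_min,t_max Annealing temperature bounds (defaults 1e-4 and
#'   100).
#' @param alpha Geometric cooling factor in (0, 1), default 0.9.
#' @param hl Hard archive limit (size on return), default 50.
#' @param sl Soft archive limit (size during the run), default 100.
#' @param iter Perturbations per temperature, default 100.
#' @param kmin Minimum encoded cluster count, default 2.
#' @param kmax Maximum encoded cluster count; `NULL` (default) means
#'   `round(sqrt(d))` for `d` samples.
#' @param laplace_scale Scale of the Laplace center-move noise;
#'   `NULL` (default) uses 1 percent of each gene's expression range.
#' @param fuzzifier Fuzzifier for the FCM objective, default 2.
#' @param objectives Which of "xb", "pbm", "fcm" the annealer
#'   optimises (all three by default).
#' @param seed Integer seed.
#' @return List of class `amosa_config`.
#' @export
amosa_config <- function(t_min = 1e-4, t_max = 100, alpha = 0.9,
                         hl = 50L, sl = 100L, iter = 100L,
                         kmin = 2L, kmax = NULL, laplace_scale = NULL,
                         fuzzifier = 2,
                         objectives = c("xb", "pbm", "fcm"),
                         seed = 1L) {
  if (t_min >= t_max) stop("need t_min < t_max")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (kmin < 2) stop("kmin must be at least 2")
  if (!is.null(kmax) && kmax < kmin) stop("need kmin <= kmax")
  objectives <- match.arg(objectives, several.ok = TRUE)
  structure(list(t_min = t_min, t_max = t_max, alpha = alpha,
                 hl = as.integer(hl), sl = as.integer(sl),
                 iter = as.integer(iter), kmin = as.integer(kmin),
                 kmax = if (is.null(kmax)) NULL else as.integer(kmax),
                 laplace_scale = laplace_scale, fuzzifier = fuzzifier,
                 objectives = objectives, seed = as.integer(seed)),
            class = "amosa_config")
}

# fill in data-dependent defaults
.resolve_config <- function(cfg, X) {
  d <- nrow(X)
  if (is.null(cfg$kmax)) cfg$kmax <- max(cfg$kmin, max_k_heuristic(d))
  if (cfg$kmax > d) cfg$kmax <- d
  if (is.null(cfg$laplace_scale)) {
    rng <- apply(X, 2, function(v) diff(range(v)))
    rng[rng == 0] <- 1
    cfg$laplace_scale <- 0.01 * rng
  }
  cfg
}

.rlaplace <- function(n, scale) {
  u <- stats::runif(n) - 0.5
  -scale * sign(u) * log(1 - 2 * abs(u))
}

#' Assign samples to centers and evaluate the objective triple
#'
#' Each sample goes to its Euclidean-nearest center (ties to the
#' lowest center index). A center left with no samples is re-seeded to
#' the sample farthest from its nearest center, and assignment is
#' repeated. The XB, PBM and FCM indices are then computed from the
#' encoded centers.
#'
#' @param sol A solution list with a `centers` matrix (k x genes), or
#'   a bare centers matrix.
#' @param expr Expression matrix, samples x genes.
#' @param fuzzifier Fuzzifier for the FCM objective.
#' @return Solution list of class `amosa_solution`: `centers`,
#'   `labels`, `objectives` (named c(xb, pbm, fcm)).
#' @export
assign_and_evaluate <- function(sol, expr, fuzzifier = 2) {
  centers <- if (is.list(sol)) sol$centers else sol
  X <- .as_points(expr)
  k <- nrow(centers)
  for (attempt in 1:(k + 1L)) {
    d2 <- .sqdist_to_centers(X, centers)
    labels <- max.col(-d2, ties.method = "first")
    empty <- setdiff(seq_len(k), unique(labels))
    if (length(empty) == 0L) break
    # re-seed one empty center to the worst-served sample
    nearest <- d2[cbind(seq_len(nrow(X)), labels)]
    centers[empty[1L], ] <- X[which.max(nearest), ]
  }
  sep <- .sqdist_to_centers(centers, centers)
  infeasible <- c(xb = Inf, pbm = 0, fcm = Inf)
  obj <- if (min(sep[upper.tri(sep)]) == 0) {
    infeasible   # coincident centers: worthless
  } else {
    # degenerate partitions (e.g. every point on a center) are treated
    # as infeasible rather than aborting the annealing walk
    tryCatch(c(xb = xb_index(X, centers, labels),
               pbm = pbm_index(X, centers, labels),
               fcm = fcm_index(X, centers, m = fuzzifier)),
             error = function(e) infeasible)
  }
  structure(list(centers = centers, labels = labels, objectives = obj),
            class = "amosa_solution")
}

# internal minimisation vector restricted to the active objectives
.min_obj <- function(sol, objectives) {
  o <- sol$objectives
  v <- c(xb = o[["xb"]], pbm = -o[["pbm"]], fcm = o[["fcm"]])
  v[objectives]
}

#' Pareto domination on the objective triple
#'
#' `a` dominates `b` when it is no worse in every objective (lower XB,
#' higher PBM, lower FCM) and strictly better in at least one.
#'
#' @param a,b Named numeric triples `c(xb, pbm, fcm)` or
#'   `amosa_solution` objects.
#' @param objectives Objectives compared (all three by default).
#' @return Logical scalar.
#' @export
dominates <- function(a, b, objectives = c("xb", "pbm", "fcm")) {
  if (!is.list(a)) a <- list(objectives = a)
  if (!is.list(b)) b <- list(objectives = b)
  va <- .min_obj(a, objectives)
  vb <- .min_obj(b, objectives)
  all(va <= vb) && any(va < vb)
}


.obj_matrix <- function(sols, objectives) {
  p <- length(objectives)
  v <- vapply(sols, .min_obj, numeric(p), objectives)
  if (p == 1L) matrix(v, ncol = 1L) else t(v)
}

# drop dominated members from a list of solutions
.pareto_filter <- function(sols, objectives) {
  if (length(sols) <= 1L) return(sols)
  V <- .obj_matrix(sols, objectives)
  keep <- rep(TRUE, length(sols))
  for (i in seq_along(sols)) {
    if (!keep[i]) next
    for (j in seq_along(sols)) {
      if (i == j || !keep[j]) next
      if (all(V[j, ] <= V[i, ]) && any(V[j, ] < V[i, ])) {
        keep[i] <- FALSE
        break
      }
    }
  }
  sols[keep]
}

#' Initialise the AMOSA archive with random solutions
#'
#' Each of `hl` initial solutions draws a cluster count k uniformly in
#' `[kmin, kmax]` and k distinct samples as its centers; dominated
#' members are pruned.
#'
#' @param expr Expression matrix, samples x genes.
#' @param cfg An `amosa_config`. When `cfg$seed` is not `NULL` the RNG
#'   is seeded first.
#' @return List of mutually non-dominating `amosa_solution`s.
#' @export
init_archive <- function(expr, cfg = amosa_config()) {
  X <- .as_points(expr)
  cfg <- .resolve_config(cfg, X)
  if (nrow(X) < cfg$kmin) stop("too few samples: need at least kmin = ",
                               cfg$kmin)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  sols <- lapply(seq_len(cfg$hl), function(i) {
    k <- if (cfg$kmin == cfg$kmax) cfg$kmin else
      sample(cfg$kmin:cfg$kmax, 1L)
    centers <- X[sample.int(nrow(X), k), , drop = FALSE]
    assign_and_evaluate(centers, X, cfg$fuzzifier)
  })
  .pareto_filter(sols, cfg$objectives)
}

#' Perturb a clustering solution
#'
#' Applies exactly one of three operators, drawn uniformly among those
#' currently legal: (1) move one randomly chosen center by
#' coordinate-wise Laplace noise; (2) delete a random center (only
#' when k > kmin); (3) insert a random data point as a new center
#' (only when k < kmax). The perturbed solution is re-evaluated.
#'
#' @param sol An `amosa_solution`.
#' @param expr Expression matrix.
#' @param cfg A resolved `amosa_config` (kmax and laplace_scale set).
#' @return A new evaluated `amosa_solution`.
#' @export
perturb_solution <- function(sol, expr, cfg) {
  X <- .as_points(expr)
  cfg <- .resolve_config(cfg, X)
  k <- nrow(sol$centers)
  ops <- c("move",
           if (k > cfg$kmin) "delete",
           if (k < cfg$kmax) "insert")
  op <- ops[sample.int(length(ops), 1L)]
  centers <- sol$centers
  if (op == "move") {
    i <- sample.int(k, 1L)
    centers[i, ] <- centers[i, ] + .rlaplace(ncol(centers), cfg$laplace_scale)
  } else if (op == "delete") {
    centers <- centers[-sample.int(k, 1L), , drop = FALSE]
  } else {
    centers <- rbind(centers, X[sample.int(nrow(X), 1L), ])
  }
  assign_and_evaluate(centers, X, cfg$fuzzifier)
}

# amount of domination between minimisation vectors, normalised by the
# per-objective range over the reference set
.dom_amount <- function(va, vb, ranges) {
  diff <- abs(va - vb) / ranges
  prod(diff[va != vb])
}

# single-linkage clustering of the archive in (normalised) objective
# space down to `target` members; keeps the member nearest each
# cluster mean
.shrink_archive <- function(archive, objectives, target) {
  if (length(archive) <= target) return(archive)
  V <- .obj_matrix(archive, objectives)
  Vn <- apply(V, 2, function(v) {
    r <- diff(range(v))
    if (r == 0) rep(0, length(v)) else (v - min(v)) / r
  })
  cl <- stats::cutree(stats::hclust(stats::dist(Vn), method = "single"),
                      k = target)
  keep <- vapply(seq_len(target), function(g) {
    idx <- which(cl == g)
    if (length(idx) == 1L) return(idx)
    mu <- colMeans(Vn[idx, , drop = FALSE])
    idx[which.min(rowSums((Vn[idx, , drop = FALSE] -
                             rep(mu, each = length(idx)))^2))]
  }, integer(1))
  archive[keep]
}

# insert a solution known to be non-dominated; purge members it dominates
.archive_insert <- function(archive, sol, cfg) {
  dominated <- vapply(archive, function(m) {
    dominates(sol, m, cfg$objectives)
  }, logical(1))
  archive <- c(archive[!dominated], list(sol))
  if (length(archive) > cfg$sl) {
    archive <- .shrink_archive(archive, cfg$objectives, cfg$hl)
  }
  archive
}

#' Run archived multi-objective simulated annealing
#'
#' Anneals from `t_max` down by factor `alpha` until `t_min`, applying
#' `iter` perturbations per temperature. A perturbed solution that is
#' dominated (by the current solution or archive members) is accepted
#' as the new current solution with probability
#' `1 / (1 + exp(dom_avg / T))`, where `dom_avg` is the mean amount of
#' domination normalised by the objective ranges; non-dominated
#' solutions are accepted and inserted into the archive, evicting any
#' members they dominate. The archive never exceeds `sl` during the
#' run (overflow triggers single-linkage clustering in objective space
#' down to `hl`) and is clipped to `hl` on return.
#'
#' @param expr Expression matrix, samples x genes (the reduced space
#'   for the full method).
#' @param cfg An `amosa_config`.
#' @param trace Record the archive size and non-domination audit per
#'   temperature (attribute `trace` of the result).
#' @return List of mutually non-dominating `amosa_solution`s (length
#'   <= hl).
#' @export
amosa_run <- function(expr, cfg = amosa_config(), trace = FALSE) {
  X <- .as_points(expr)
  cfg <- .resolve_config(cfg, X)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  cfg_noseed <- cfg
  cfg_noseed$seed <- NULL
  archive <- init_archive(X, cfg_noseed)
  current <- archive[[sample.int(length(archive), 1L)]]
  p <- length(cfg$objectives)
  arch_V <- .obj_matrix(archive, cfg$objectives)
  cur_v <- .min_obj(current, cfg$objectives)
  tr <- list()

  temp <- cfg$t_max
  while (temp >= cfg$t_min) {
    for (it in seq_len(cfg$iter)) {
      new <- perturb_solution(current, X, cfg_noseed)
      vn <- .min_obj(new, cfg$objectives)
      if (any(!is.finite(vn))) next
      Vref <- rbind(cur_v, arch_V)
      vn_rep <- rep(vn, each = nrow(Vref))
      dom_rows <- rowSums(Vref <= vn_rep) == p & rowSums(Vref < vn_rep) > 0
      if (any(dom_rows)) {
        # dominated: probabilistic acceptance as current only
        D <- Vref[dom_rows, , drop = FALSE]
        pool <- rbind(D, vn)
        ranges <- pmax(apply(pool, 2, max) - apply(pool, 2, min),
                       .Machine$double.eps)
        davg <- mean(apply(D, 1, .dom_amount, vb = vn, ranges = ranges))
        if (stats::runif(1) < 1 / (1 + exp(davg / temp))) {
          current <- new
          cur_v <- vn
        }
      } else {
        # non-dominated (or dominating): accept and archive
        current <- new
        cur_v <- vn
        beaten <- rowSums(arch_V >= rep(vn, each = nrow(arch_V))) == p &
          rowSums(arch_V > rep(vn, each = nrow(arch_V))) > 0
        archive <- c(archive[!beaten], list(new))
        arch_V <- rbind(arch_V[!beaten, , drop = FALSE], vn)
        if (length(archive) > cfg$sl) {
          archive <- .shrink_archive(archive, cfg$objectives, cfg$hl)
          arch_V <- .obj_matrix(archive, cfg$objectives)
        }
      }
    }
    if (trace) {
      tr[[length(tr) + 1L]] <- list(temp = temp, size = length(archive))
    }
    temp <- temp * cfg$alpha
  }
  archive <- .shrink_archive(archive, cfg$objectives, cfg$hl)
  if (trace) attr(archive, "trace") <- tr
  archive
}

#' Pick the best archive member by silhouette
#'
#' Computes the Euclidean silhouette of every archive member's sample
#' partition and returns the argmax; ties go to the solution with
#' fewer clusters, then to the lower XB index.
#'
#' @param archive List of `amosa_solution`s (from [amosa_run()]).
#' @param expr The expression matrix the archive was built on.
#' @return The winning `amosa_solution`, with its silhouette stored in
#'   `$silhouette`.
#' @export
select_best <- function(archive, expr) {
  if (length(archive) == 0L) stop("empty archive")
  D <- as.matrix(stats::dist(.as_points(expr)))
  sil <- vapply(archive, function(m) {
    if (length(unique(m$labels)) < 2L) return(-1)
    silhouette_index(D, m$labels)
  }, numeric(1))
  k <- vapply(archive, function(m) nrow(m$centers), integer(1))
  xb <- vapply(archive, function(m) m$objectives[["xb"]], numeric(1))
  ord <- order(-sil, k, xb)
  best <- archive[[ord[1L]]]
  best$silhouette <- sil[ord[1L]]
  best
}
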