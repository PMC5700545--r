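# Shared fixtures and independent oracles, all built in code.

# Small multi-namespace ontology: BP is a 4-term diamond (D reachable
# from the root by paths of length 1 and 3), MF a 2-term chain, CC a
# 3-term fan.
toy_obo <- function() {
  c("[Term]", "id: A", "name: bp root", "namespace: biological_process",
    "",
    "[Term]", "id: B", "namespace: biological_process", "is_a: A",
    "[Term]", "id: C", "namespace: biological_process", "is_a: B",
    "[Term]", "id: D", "namespace: biological_process", "is_a: C",
    "is_a: A",
    "[Term]", "id: M1", "namespace: molecular_function",
    "[Term]", "id: M2", "namespace: molecular_function", "is_a: M1",
    "[Term]", "id: C1", "namespace: cellular_component",
    "[Term]", "id: C2", "namespace: cellular_component", "is_a: C1",
    "[Term]", "id: C3", "namespace: cellular_component", "is_a: C1")
}

# 10-term BP namespace where term "t" has depth 2 and 3 distinct
# descendants (d1, d2, d3), for the coverage worked example.
ten_term_obo <- function() {
  c("[Term]", "id: r", "namespace: biological_process",
    "[Term]", "id: a", "namespace: biological_process", "is_a: r",
    "[Term]", "id: t", "namespace: biological_process", "is_a: a",
    "[Term]", "id: d1", "namespace: biological_process", "is_a: t",
    "[Term]", "id: d2", "namespace: biological_process", "is_a: t",
    "[Term]", "id: d3", "namespace: biological_process", "is_a: d1",
    "[Term]", "id: f1", "namespace: biological_process", "is_a: r",
    "[Term]", "id: f2", "namespace: biological_process", "is_a: r",
    "[Term]", "id: f3", "namespace: biological_process", "is_a: r",
    "[Term]", "id: f4", "namespace: biological_process", "is_a: r")
}

# exhaustive k-medoids oracle: global optimum over all medoid sets
pam_exhaustive <- function(D, K) {
  combos <- utils::combn(nrow(D), K)
  costs <- apply(combos, 2, function(m) {
    sum(apply(D[, m, drop = FALSE], 1, min))
  })
  list(cost = min(costs), medoids = sort(combos[, which.min(costs)]))
}

# exact hypergeometric upper tail by combinatorial enumeration
hyper_upper_exact <- function(q, study_size, pop_count, pop_size) {
  ks <- q:min(study_size, pop_count)
  ks <- ks[ks >= max(0, study_size - (pop_size - pop_count))]
  if (length(ks) == 0) return(0)
  sum(choose(pop_count, ks) * choose(pop_size - pop_count, study_size - ks)) /
    choose(pop_size, study_size)
}

# %CoA oracle by brute force over all cluster->class maps that use
# distinct classes where possible (small K and C only)
coa_brute <- function(pred, truth) {
  conf <- unclass(table(pred, truth))
  K <- nrow(conf); C <- ncol(conf)
  m <- min(K, C)
  best <- 0
  carriers <- utils::combn(K, m)
  class_perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in class_perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  for (ci in seq_len(ncol(carriers))) {
    rows <- carriers[, ci]
    surplus <- setdiff(seq_len(K), rows)
    for (perm in class_perms(seq_len(C))) {
      acc <- sum(conf[cbind(rows, perm[seq_len(m)])]) +
        sum(apply(conf[surplus, , drop = FALSE], 1, max))
      best <- max(best, acc)
    }
  }
  100 * best / length(pred)
}

# fixed reference partitions on the line used by several index tests
toy_partition <- function() {
  list(points4 = matrix(c(0, 2, 10, 12), ncol = 1),
       centers = matrix(c(1, 11), ncol = 1),
       tight4 = matrix(c(0, 1, 10, 11), ncol = 1),
       labels = c(1L, 1L, 2L, 2L))
}

quick_amosa_config <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(t_min = 0.5, t_max = 100, alpha = 0.9, hl = 10L, sl = 20L,
         iter = 20L, seed = seed),
    list(...))
  do.call(amosa_config, args)
}
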