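# Deterministic generators for toy ontologies, block-structured
# annotation tables and expression matrices with planted sample
# clusters, so every pipeline stage is testable offline.

#' Specification for the synthetic generators
#'
#' The defaults describe the reference study conditions used
#' throughout the test suite: a three-namespace toy ontology, 60 genes
#' in 5 annotation groups of which 3 are informative, and 60 samples
#' in 3 planted clusters whose informative-gene means are 6 noise
#' standard deviations apart.
#'
#' @param n_terms_per_namespace Terms per namespace (>= 4), default 30.
#' @param n_genes Number of genes, default 60.
#' @param n_gene_groups Annotation groups of genes, default 5.
#' @param terms_per_group Size of each group's shared term block,
#'   default 4.
#' @param d_samples Number of samples, default 60.
#' @param k_sample_clusters Planted sample clusters, default 3.
#' @param informative_fraction Fraction of gene groups whose genes
#'   separate the sample clusters, default 0.6.
#' @param noise_sd Expression noise standard deviation, default 1.
#' @param separation Spacing of cluster means on informative genes, in
#'   units of `noise_sd`, default 6.
#' @param seed Integer seed; every generator is a pure function of the
#'   spec (including its seed).
#' @return List of class `synth_spec`.
#' @export
synth_spec <- function(n_terms_per_namespace = 30L, n_genes = 60L,
                       n_gene_groups = 5L, terms_per_group = 4L,
                       d_samples = 60L, k_sample_clusters = 3L,
                       informative_fraction = 0.6, noise_sd = 1,
                       separation = 6, seed = 1L) {
  if (n_terms_per_namespace < 4) stop("need at least 4 terms per namespace")
  if (n_gene_groups > n_genes) stop("more gene groups than genes")
  if (k_sample_clusters > d_samples) stop("more sample clusters than samples")
  if (informative_fraction <= 0 || informative_fraction > 1) {
    stop("informative_fraction must lie in (0, 1]")
  }
  structure(as.list(environment()), class = "synth_spec")
}

#' Generate a toy multi-namespace ontology as OBO text
#'
#' Builds, per namespace (BP, MF, CC), a rooted random DAG: each new
#' term attaches to one or two already-existing parents. Output is
#' valid OBO 1.2 and byte-identical for a fixed spec.
#'
#' @param spec A [synth_spec()].
#' @return A single character string of OBO text (feed to
#'   [parse_obo()]).
#' @export
synth_ontology <- function(spec) {
  set.seed(spec$seed)
  ns_long <- c(BP = "biological_process", MF = "molecular_function",
               CC = "cellular_component")
  counter <- 0L
  out <- c("format-version: 1.2", "")
  for (ns in names(ns_long)) {
    ids <- sprintf("GO:%07d", counter + seq_len(spec$n_terms_per_namespace))
    counter <- counter + spec$n_terms_per_namespace
    for (i in seq_along(ids)) {
      stanza <- c("[Term]",
                  paste0("id: ", ids[i]),
                  paste0("name: synthetic ", tolower(ns), " term ", i),
                  paste0("namespace: ", ns_long[[ns]]))
      if (i > 1L) {
        n_par <- if (i == 2L) 1L else sample(1:2, 1L)
        parents <- sample(ids[seq_len(i - 1L)], min(n_par, i - 1L))
        stanza <- c(stanza, paste0("is_a: ", parents))
      }
      out <- c(out, stanza, "")
    }
  }
  paste(out, collapse = "\n")
}

#' Generate a block-structured gene annotation table
#'
#' Genes are partitioned into `n_gene_groups` groups of near-equal
#' size; each group receives a disjoint block of `terms_per_group`
#' non-root terms that every member gene is annotated with, plus
#' Poisson(1) random off-block terms per gene. Genes of the same group
#' therefore share at least their whole term block, emulating
#' annotation-coherent gene modules.
#'
#' @param spec A [synth_spec()].
#' @param dag The `ontology_dag` parsed from [synth_ontology()].
#' @param off_block_rate Poisson rate of random extra terms per gene,
#'   default 1.
#' @return An `annotation_table` with attribute `gene_groups` (named
#'   integer vector: group of each gene).
#' @export
synth_annotations <- function(spec, dag, off_block_rate = 1) {
  set.seed(spec$seed + 1L)
  genes <- sprintf("gene%03d", seq_len(spec$n_genes))
  groups <- sort(rep_len(seq_len(spec$n_gene_groups), spec$n_genes))
  names(groups) <- genes

  pool <- setdiff(dag$terms$id, dag$roots)
  need <- spec$n_gene_groups * spec$terms_per_group
  if (length(pool) < need) {
    stop("ontology too small: need ", need, " non-root terms, have ",
         length(pool))
  }
  block_terms <- sample(pool, need)
  blocks <- split(block_terms,
                  rep(seq_len(spec$n_gene_groups), each = spec$terms_per_group))

  pairs <- lapply(genes, function(g) {
    own <- blocks[[groups[[g]]]]
    n_extra <- stats::rpois(1L, off_block_rate)
    extra <- if (n_extra > 0) {
      sample(setdiff(pool, own), min(n_extra, length(pool) - length(own)))
    } else character(0)
    data.frame(gene_id = g, term_id = c(own, extra),
               stringsAsFactors = FALSE)
  })
  tab <- unique(do.call(rbind, pairs))
  rownames(tab) <- NULL
  structure(tab, gene_groups = groups,
            class = c("annotation_table", "data.frame"))
}

#' Generate a genome-style background annotation table
#'
#' The study table plus `n_background_genes` extra genes annotated to
#' `1 + Poisson(1)` terms drawn uniformly from the non-root term pool.
#' Against this background the study groups' shared term blocks are
#' over-represented, so hypergeometric enrichment behaves as it would
#' against a real genome.
#'
#' @param spec A [synth_spec()].
#' @param dag The parsed synthetic ontology.
#' @param study The study `annotation_table` from
#'   [synth_annotations()].
#' @param n_background_genes Extra genome genes, default
#'   `4 * n_genes`.
#' @return An `annotation_table` covering study plus background genes.
#' @export
synth_background <- function(spec, dag, study,
                             n_background_genes = 4L * spec$n_genes) {
  set.seed(spec$seed + 3L)
  pool <- setdiff(dag$terms$id, dag$roots)
  extra <- lapply(seq_len(n_background_genes), function(i) {
    n_t <- 1L + stats::rpois(1L, 1)
    data.frame(gene_id = sprintf("bg%04d", i),
               term_id = sample(pool, min(n_t, length(pool))),
               stringsAsFactors = FALSE)
  })
  tab <- unique(rbind(as.data.frame(study)[, c("gene_id", "term_id")],
                      do.call(rbind, extra)))
  rownames(tab) <- NULL
  class(tab) <- c("annotation_table", "data.frame")
  tab
}

#' Generate an expression matrix with planted sample clusters
#'
#' Samples are split evenly over `k_sample_clusters` clusters. Genes
#' of the first `ceiling(informative_fraction * n_gene_groups)` gene
#' groups are informative: for each such gene the cluster means sit on
#' a randomly permuted grid with spacing `separation * noise_sd`, so
#' any two clusters differ by at least one grid step on every
#' informative gene. Non-informative genes are i.i.d. Gaussian noise
#' identical across clusters. Observations add N(0, noise_sd) noise.
#'
#' @param spec A [synth_spec()].
#' @param gene_groups Named integer vector (gene -> group), e.g. the
#'   `gene_groups` attribute of [synth_annotations()]; `NULL` derives
#'   the same partition from the spec.
#' @return List with `expr` (`d_samples x n_genes` matrix, dimnames
#'   set), `labels` (true sample clusters), `informative_genes`
#'   (character vector) and `informative_groups`.
#' @export
synth_expression <- function(spec, gene_groups = NULL) {
  set.seed(spec$seed + 2L)
  if (is.null(gene_groups)) {
    genes <- sprintf("gene%03d", seq_len(spec$n_genes))
    gene_groups <- stats::setNames(
      sort(rep_len(seq_len(spec$n_gene_groups), spec$n_genes)), genes)
  }
  genes <- names(gene_groups)
  d <- spec$d_samples
  k <- spec$k_sample_clusters
  labels <- sort(rep_len(seq_len(k), d))

  n_inf_groups <- ceiling(spec$informative_fraction * spec$n_gene_groups)
  inf_groups <- seq_len(n_inf_groups)
  informative <- genes[gene_groups %in% inf_groups]

  delta <- spec$separation * spec$noise_sd
  mu <- matrix(0, nrow = k, ncol = length(genes),
               dimnames = list(NULL, genes))
  for (g in informative) {
    mu[, g] <- delta * (sample.int(k) - 1L)
  }
  expr <- mu[labels, , drop = FALSE] +
    matrix(stats::rnorm(d * length(genes), 0, spec$noise_sd),
           nrow = d)
  dimnames(expr) <- list(sprintf("sample%03d", seq_len(d)), genes)
  list(expr = expr, labels = labels, informative_genes = informative,
       informative_groups = inf_groups)
}
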