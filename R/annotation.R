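#' Read gene-to-GO-term annotations
#'
#' Accepts either a two-column TSV (`gene_id<TAB>term_id`, no header)
#' or GAF 2.x lines (gene from column 2, term from column 5; `!`
#' comment lines skipped). Duplicate (gene, term) pairs are collapsed.
#' When an `ontology_dag` is supplied, pairs whose term is absent from
#' the DAG are dropped with a warning that reports the count.
#'
#' @param x File path, character vector of lines, or a two-column
#'   data.frame of (gene_id, term_id).
#' @param dialect "tsv" or "gaf".
#' @param dag Optional `ontology_dag` used to validate term ids.
#' @return Data.frame of class `annotation_table` with columns
#'   `gene_id`, `term_id`.
#' @export
parse_annotations <- function(x, dialect = c("tsv", "gaf"), dag = NULL) {
  dialect <- match.arg(dialect)
  if (is.data.frame(x)) {
    tab <- data.frame(gene_id = as.character(x[[1]]),
                      term_id = as.character(x[[2]]),
                      stringsAsFactors = FALSE)
  } else {
    lines <- as.character(.obo_lines(x))
    lines <- lines[nzchar(lines) & !startsWith(lines, "!")]
    if (length(lines) == 0L) stop("no annotations found in input")
    fields <- strsplit(lines, "\t", fixed = TRUE)
    want <- if (dialect == "tsv") c(1L, 2L) else c(2L, 5L)
    bad <- vapply(fields, length, integer(1)) < max(want)
    if (any(bad)) stop("annotation line(s) with too few columns: ",
                       paste(which(bad)[seq_len(min(3, sum(bad)))],
                             collapse = ", "))
    tab <- data.frame(
      gene_id = vapply(fields, `[[`, character(1), want[1]),
      term_id = vapply(fields, `[[`, character(1), want[2]),
      stringsAsFactors = FALSE
    )
  }
  tab <- unique(tab)
  if (nrow(tab) == 0L) stop("no annotations found in input")
  if (!is.null(dag)) {
    known <- tab$term_id %in% dag$terms$id
    if (any(!known)) {
      warning(sum(!known), " annotation(s) with term ids absent from ",
              "the ontology were skipped")
      tab <- tab[known, , drop = FALSE]
    }
    if (nrow(tab) == 0L) stop("no annotations found in input")
  }
  rownames(tab) <- NULL
  class(tab) <- c("annotation_table", "data.frame")
  tab
}

#' One-sided hypergeometric over-representation p-value
#'
#' Upper-tail probability `P(X >= study_count)` for
#' `X ~ Hypergeometric(pop_size, pop_count, study_size)`: the chance of
#' drawing at least `study_count` annotated genes in a study set of
#' `study_size` genes from a population of `pop_size` genes of which
#' `pop_count` carry the annotation.
#'
#' @param study_count,study_size,pop_count,pop_size Non-negative
#'   integers with `study_count <= study_size <= pop_size` and
#'   `study_count <= pop_count <= pop_size`.
#' @return P-value in `[0, 1]` (vectorised).
#' @export
enrichment_pvalue <- function(study_count, study_size, pop_count, pop_size) {
  ok <- study_count >= 0 & study_count <= study_size &
    study_size <= pop_size & study_count <= pop_count & pop_count <= pop_size
  if (any(!ok)) stop("invalid counts: require 0 <= study_count <= ",
                     "study_size <= pop_size and study_count <= pop_count ",
                     "<= pop_size")
  stats::phyper(study_count - 1, pop_count, pop_size - pop_count,
                study_size, lower.tail = FALSE)
}

#' Select significant GO terms for a gene set
#'
#' Scores every term annotated to the study genes with the one-sided
#' hypergeometric over-representation test against a background gene
#' set and keeps terms with raw p-value below `threshold` (default
#' 0.5). Results are grouped BP, then MF, then CC, lexicographic
#' within each namespace. No multiple-testing correction is applied by
#' default; `adjust = "BH"` switches on Benjamini-Hochberg.
#'
#' @param table An `annotation_table` for the study genes.
#' @param dag An `ontology_dag` resolving the term ids.
#' @param threshold Raw p-value cut, default 0.5.
#' @param background Optional `annotation_table` (or plain two-column
#'   data.frame) for the genome-wide background. When absent the study
#'   table itself is used and a warning flags that enrichment is
#'   degenerate (every p-value is 1).
#' @param adjust "none" (default) or "BH".
#' @return Data.frame of class `term_selection` with columns `term_id`,
#'   `namespace`, `study_count`, `pop_count`, `pvalue`; attribute
#'   `counts` holds the per-namespace totals `c(x = BP, y = MF, z = CC)`.
#' @export
select_significant_terms <- function(table, dag, threshold = 0.5,
                                     background = NULL,
                                     adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (is.null(background)) {
    warning("no background supplied; using the study set as its own ",
            "background makes enrichment degenerate (all p-values 1)")
    background <- table
  }
  .check_term(dag, unique(table$term_id))
  study_genes <- unique(table$gene_id)
  pop_genes <- unique(background$gene_id)
  study_size <- length(study_genes)
  pop_size <- length(pop_genes)

  terms <- sort(unique(table$term_id))
  study_count <- vapply(terms, function(tm) {
    length(unique(table$gene_id[table$term_id == tm]))
  }, integer(1))
  pop_count <- vapply(terms, function(tm) {
    max(length(unique(background$gene_id[background$term_id == tm])),
        study_count[[tm]])
  }, integer(1))
  p <- enrichment_pvalue(study_count, study_size, pop_count, pop_size)
  if (adjust == "BH") p <- stats::p.adjust(p, method = "BH")

  keep <- p < threshold
  if (!any(keep)) stop("no significant terms at threshold ", threshold)
  out <- data.frame(
    term_id = terms[keep],
    namespace = dag$terms$namespace[match(terms[keep], dag$terms$id)],
    study_count = unname(study_count[keep]),
    pop_count = unname(pop_count[keep]),
    pvalue = unname(p[keep]),
    stringsAsFactors = FALSE
  )
  out$namespace <- factor(out$namespace, levels = c("BP", "MF", "CC"))
  out <- out[order(out$namespace, out$term_id), , drop = FALSE]
  out$namespace <- as.character(out$namespace)
  rownames(out) <- NULL
  counts <- c(x = sum(out$namespace == "BP"),
              y = sum(out$namespace == "MF"),
              z = sum(out$namespace == "CC"))
  structure(out, counts = counts,
            class = c("term_selection", "data.frame"))
}

#' Build the Struct_IC-weighted gene-GO-term annotation matrix
#'
#' Rows are genes, columns are the selected terms grouped BP, MF, CC.
#' Entry `M[i, p]` is `struct_ic(term_p)` when gene i is annotated with
#' term p and 0 otherwise, so every nonzero entry of a column equals
#' that column's term IC. Genes annotated to none of the selected
#' terms yield all-zero rows and are dropped (their ids are kept in the
#' `dropped_genes` attribute).
#'
#' @param genes Character vector of gene ids (row order of the result
#'   before dropping unmapped genes).
#' @param terms A `term_selection` (or a data.frame with `term_id` and
#'   `namespace` columns, already grouped BP/MF/CC).
#' @param table An `annotation_table`.
#' @param dag An `ontology_dag`.
#' @param total_scope Passed to [struct_ic()].
#' @return Numeric matrix of class `annotation_matrix`, `n x (x+y+z)`,
#'   with attributes `ns_counts` (x, y, z), `term_ns` and
#'   `dropped_genes`.
#' @export
build_annotation_matrix <- function(genes, terms, table, dag,
                                    total_scope = "namespace") {
  term_ids <- terms$term_id
  term_ns <- terms$namespace
  ic <- struct_ic(dag, term_ids, total_scope)
  M <- matrix(0, nrow = length(genes), ncol = length(term_ids),
              dimnames = list(genes, term_ids))
  hits <- table[table$gene_id %in% genes & table$term_id %in% term_ids, ,
                drop = FALSE]
  if (nrow(hits)) {
    idx <- cbind(match(hits$gene_id, genes), match(hits$term_id, term_ids))
    M[idx] <- ic[idx[, 2]]
  }
  mapped <- rowSums(M != 0) > 0
  dropped <- genes[!mapped]
  if (!any(mapped)) stop("empty matrix: no gene maps to a selected term")
  if (length(dropped)) {
    message(length(dropped), " of ", length(genes),
            " genes map to no selected term and were dropped")
  }
  M <- M[mapped, , drop = FALSE]
  structure(M,
            ns_counts = c(x = sum(term_ns == "BP"),
                          y = sum(term_ns == "MF"),
                          z = sum(term_ns == "CC")),
            term_ns = term_ns,
            dropped_genes = dropped,
            class = c("annotation_matrix", "matrix", "array"))
}

#' Distance between two gene annotation vectors
#'
#' Euclidean (root of summed squared differences), city-block (summed
#' absolute differences) or cosine (1 minus the normalised dot
#' product) distance between rows `i` and `j` of the annotation
#' matrix. Because matrix entries are non-negative, cosine distance
#' lies in `[0, 1]`.
#'
#' @param M An `annotation_matrix` (or any numeric matrix).
#' @param i,j Row indices.
#' @param kind One of "euclidean", "cityblock", "cosine".
#' @return A single non-negative distance.
#' @export
annotation_distance <- function(M, i, j,
                                kind = c("euclidean", "cityblock", "cosine")) {
  kind <- match.arg(kind)
  a <- M[i, ]
  b <- M[j, ]
  switch(kind,
    euclidean = sqrt(sum((a - b)^2)),
    cityblock = sum(abs(a - b)),
    cosine = {
      na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
      if (na == 0 || nb == 0) stop("cosine distance undefined for a zero row")
      # clamp tiny negative round-off for identical rows
      max(0, 1 - sum(a * b) / (na * nb))
    }
  )
}

#' Full pairwise distance matrix for annotation (or expression) rows
#'
#' @inheritParams annotation_distance
#' @return Symmetric `n x n` matrix of distances.
#' @export
annotation_dist_matrix <- function(M,
                                   kind = c("euclidean", "cityblock",
                                            "cosine")) {
  kind <- match.arg(kind)
  M <- unclass(M)
  if (kind == "cosine") {
    nrm <- sqrt(rowSums(M^2))
    if (any(nrm == 0)) stop("cosine distance undefined for a zero row")
    S <- tcrossprod(M / nrm)
    D <- 1 - S
    D[D < 0] <- 0
    diag(D) <- 0
    D
  } else {
    method <- if (kind == "euclidean") "euclidean" else "manhattan"
    as.matrix(stats::dist(M, method = method))
  }
}
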