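# End-to-end orchestration: ontology -> significant terms -> weighted
# annotation matrix -> PAM gene selection -> AMOSA sample clustering
# -> evaluation, with a machine-readable report.

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage [", name, "] failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

.read_expression <- function(x, transpose = FALSE) {
  if (is.matrix(x)) {
    m <- x
  } else {
    sep <- if (grepl("\\.csv$", x)) "," else "\t"
    df <- utils::read.table(x, header = TRUE, sep = sep, row.names = 1,
                            check.names = FALSE)
    m <- as.matrix(df)
  }
  if (transpose) m <- t(m)
  m
}

#' Run the full gene-selection and sample-clustering pipeline
#'
#' Module 1: parse the ontology, select significant terms by
#' hypergeometric enrichment, build the Struct_IC-weighted annotation
#' matrix, sweep PAM over the K grid and distance kinds, and extract
#' the winning medoid genes. Module 2: slice the expression matrix to
#' the reduced gene space, run the multi-objective annealer on the
#' samples and pick the best archive member by silhouette. When true
#' sample classes are supplied, %CoA is reported.
#'
#' @param config A named list (or path to a JSON/YAML file) with
#'   entries:
#'   \describe{
#'     \item{obo}{OBO path or text.}
#'     \item{annotations}{Annotation TSV/GAF path, lines, or
#'       data.frame.}
#'     \item{annotation_dialect}{"tsv" (default) or "gaf".}
#'     \item{background}{Optional background annotations (same
#'       formats).}
#'     \item{expression}{Expression path or samples x genes matrix.}
#'     \item{transpose}{Set TRUE for gene-major expression files.}
#'     \item{truth}{Optional true sample class labels.}
#'     \item{pcut}{Enrichment threshold, default 0.5.}
#'     \item{kinds, k_grid, allow_large_k}{Passed to [sweep_k()].}
#'     \item{amosa}{List of [amosa_config()] arguments.}
#'     \item{seed}{Base seed, default 1.}
#'   }
#' @return List of class `pipeline_report` with sections
#'   `matrix_shape`, `selection`, `clustering`, `evaluation`,
#'   `provenance`.
#' @export
run_pipeline <- function(config) {
  config <- .load_config(config)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)

  dag <- .stage("ontology", parse_obo(config$obo))
  tab <- .stage("annotations", parse_annotations(
    config$annotations,
    dialect = if (is.null(config$annotation_dialect)) "tsv"
              else config$annotation_dialect,
    dag = dag))
  background <- if (!is.null(config$background)) {
    .stage("background", parse_annotations(
      config$background,
      dialect = if (is.null(config$annotation_dialect)) "tsv"
                else config$annotation_dialect,
      dag = dag))
  } else NULL

  pcut <- if (is.null(config$pcut)) 0.5 else config$pcut
  sel_terms <- .stage("term-selection", suppressWarnings(
    select_significant_terms(tab, dag, threshold = pcut,
                             background = background)))

  expr <- .stage("expression",
                 .read_expression(config$expression,
                                  isTRUE(config$transpose)))
  genes <- intersect(colnames(expr), unique(tab$gene_id))
  if (length(genes) == 0L) {
    stop("pipeline stage [expression] failed: no expression gene ids ",
         "match the annotation table", call. = FALSE)
  }
  M <- .stage("annotation-matrix",
              build_annotation_matrix(genes, sel_terms, tab, dag))

  kinds <- if (is.null(config$kinds)) {
    c("euclidean", "cityblock", "cosine")
  } else config$kinds
  sweep <- .stage("gene-selection", sweep_k(
    M, k_grid = config$k_grid, kinds = kinds, seed = seed,
    allow_large_k = isTRUE(config$allow_large_k)))
  reduced <- extract_medoids(sweep$best, M)
  expr_red <- .stage("reduce", reduce_expression(expr, reduced))

  acfg <- do.call(amosa_config, c(config$amosa, list(seed = seed)))
  archive <- .stage("sample-clustering", amosa_run(expr_red, acfg))
  best <- select_best(archive, expr_red)

  Dred <- as.matrix(stats::dist(expr_red))
  evaluation <- list(
    silhouette = silhouette_index(Dred, best$labels),
    db = db_index(expr_red, best$labels),
    dunn = dunn_index(expr_red, best$labels)
  )
  if (!is.null(config$truth)) {
    truth <- if (length(config$truth) == 1L && is.character(config$truth) &&
                 file.exists(config$truth)) {
      utils::read.table(config$truth, header = FALSE)[[1]]
    } else config$truth
    evaluation$coa <- classification_accuracy(best$labels, truth)
  }

  ns <- attr(M, "ns_counts")
  structure(list(
    matrix_shape = list(n = nrow(M), x = unname(ns[["x"]]),
                        y = unname(ns[["y"]]), z = unname(ns[["z"]]),
                        dropped_genes = attr(M, "dropped_genes")),
    selection = list(kind = sweep$best$kind, K = sweep$best$K,
                     silhouette = sweep$best$silhouette,
                     table = sweep$table, medoid_genes = reduced$gene_ids),
    clustering = list(
      k = nrow(best$centers),
      labels = best$labels,
      objectives = as.list(best$objectives),
      archive_objectives = lapply(archive, function(s) {
        as.list(s$objectives)
      })),
    evaluation = evaluation,
    provenance = list(seed = seed, pcut = pcut,
                      amosa = acfg[setdiff(names(acfg), "laplace_scale")],
                      package_version = as.character(
                        utils::packageVersion("goMedSel")))
  ), class = "pipeline_report")
}

.load_config <- function(config) {
  if (is.character(config) && length(config) == 1L && file.exists(config)) {
    if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE)) {
        stop("yaml package required for YAML configs")
      }
      config <- yaml::read_yaml(config)
    } else {
      config <- jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  if (!is.list(config)) stop("config must be a list or a JSON/YAML path")
  required <- c("obo", "annotations", "expression")
  missing <- setdiff(required, names(config))
  if (length(missing)) {
    stop("config lacks required entries: ", paste(missing, collapse = ", "))
  }
  config
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline_report\n")
  cat("  annotation matrix:", x$matrix_shape$n, "genes x",
      x$matrix_shape$x + x$matrix_shape$y + x$matrix_shape$z,
      "terms (x =", x$matrix_shape$x, ", y =", x$matrix_shape$y,
      ", z =", x$matrix_shape$z, ")\n")
  cat("  gene selection:", x$selection$kind, "PAM, K =", x$selection$K,
      ", silhouette =", format(x$selection$silhouette), "\n")
  cat("  sample clustering: k =", x$clustering$k,
      ", silhouette =", format(x$evaluation$silhouette),
      ", DB =", format(x$evaluation$db),
      ", Dunn =", format(x$evaluation$dunn), "\n")
  if (!is.null(x$evaluation$coa)) {
    cat("  %CoA =", format(x$evaluation$coa), "\n")
  }
  invisible(x)
}

#' Compare sample clustering over the full and reduced gene spaces
#'
#' Runs the annealer twice with identical configuration and seed: once
#' on the full samples x genes matrix and once on the reduced
#' (medoid-gene) matrix; reports silhouette, DB, Dunn and (when truth
#' labels are given) %CoA for each space.
#'
#' @param expr Expression matrix, samples x genes.
#' @param reduced_genes A `reduced_gene_set` or character vector of
#'   gene ids.
#' @param cfg An [amosa_config()].
#' @param truth Optional true sample classes.
#' @return Data.frame with one row per space (`full`, `reduced`).
#' @export
compare_spaces <- function(expr, reduced_genes, cfg = amosa_config(),
                           truth = NULL) {
  spaces <- list(full = expr,
                 reduced = reduce_expression(expr, reduced_genes))
  rows <- lapply(names(spaces), function(nm) {
    X <- spaces[[nm]]
    best <- select_best(amosa_run(X, cfg), X)
    D <- as.matrix(stats::dist(X))
    data.frame(
      space = nm, n_genes = ncol(X), k = nrow(best$centers),
      silhouette = silhouette_index(D, best$labels),
      db = db_index(X, best$labels),
      dunn = dunn_index(X, best$labels),
      coa = if (is.null(truth)) NA_real_ else
        classification_accuracy(best$labels, truth),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
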