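#' Parse an OBO 1.2 ontology into a namespace-partitioned DAG
#'
#' Reads `[Term]` stanzas (keys `id:`, `name:`, `namespace:`, `is_a:`,
#' `is_obsolete:`) and builds a directed acyclic graph of `is_a`
#' relations per namespace. Obsolete terms are dropped at parse time;
#' only `is_a` edges are used (other relationship types are ignored).
#' Each namespace must form a DAG with exactly one root (a term with no
#' `is_a` parent inside its namespace).
#'
#' Term depth (longest `is_a` path from the namespace root, root = 0)
#' and distinct-descendant counts are precomputed for every term.
#'
#' @param x Path to an OBO file, or the OBO text itself (a single
#'   string or a character vector of lines).
#' @return An object of class `ontology_dag`: a list with `terms` (a
#'   data.frame with columns `id`, `name`, `namespace`, `depth`,
#'   `desc`), `edges` (child/parent pairs), `roots` (named by
#'   namespace) and `ns_total` (term counts per namespace).
#' @examples
#' obo <- c("[Term]", "id: A", "namespace: biological_process",
#'          "[Term]", "id: B", "namespace: biological_process",
#'          "is_a: A")
#' dag <- parse_obo(obo)
#' term_depth(dag, "B")
#' @export
parse_obo <- function(x) {
  lines <- .obo_lines(x)
  stanzas <- .obo_stanzas(lines)
  if (length(stanzas) == 0L) stop("no [Term] stanzas found in OBO input")

  recs <- lapply(stanzas, .obo_parse_term)
  recs <- recs[!vapply(recs, is.null, logical(1))]
  if (length(recs) == 0L) stop("no non-obsolete [Term] stanzas in OBO input")

  ids <- vapply(recs, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    stop("duplicate term ids in OBO input: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  terms <- data.frame(
    id = ids,
    name = vapply(recs, `[[`, character(1), "name"),
    namespace = vapply(recs, `[[`, character(1), "namespace"),
    stringsAsFactors = FALSE
  )
  ns_of <- stats::setNames(terms$namespace, terms$id)

  edges <- do.call(rbind, lapply(recs, function(r) {
    if (length(r$parents) == 0L) return(NULL)
    data.frame(child = r$id, parent = r$parents, stringsAsFactors = FALSE)
  }))
  if (is.null(edges)) {
    edges <- data.frame(child = character(), parent = character(),
                        stringsAsFactors = FALSE)
  }
  # drop edges to unknown parents (e.g. obsolete or outside the file)
  known <- edges$parent %in% terms$id
  if (any(!known)) {
    warning(sum(!known), " is_a edge(s) point to unknown terms; dropped")
    edges <- edges[known, , drop = FALSE]
  }
  # is_a never crosses namespaces in GO; enforce
  cross <- ns_of[edges$child] != ns_of[edges$parent]
  if (any(cross)) {
    warning(sum(cross), " cross-namespace is_a edge(s) dropped")
    edges <- edges[!cross, , drop = FALSE]
  }
  rownames(edges) <- NULL

  depth <- stats::setNames(rep(NA_integer_, nrow(terms)), terms$id)
  desc <- stats::setNames(rep(NA_integer_, nrow(terms)), terms$id)
  roots <- character(0)

  for (ns in unique(terms$namespace)) {
    tids <- terms$id[terms$namespace == ns]
    e <- edges[ns_of[edges$child] == ns, , drop = FALSE]
    g <- igraph::graph_from_data_frame(
      e[, c("child", "parent")], directed = TRUE,
      vertices = data.frame(name = tids)
    )
    if (!igraph::is_dag(g)) {
      cyc <- .find_cycle(e)
      stop("is_a cycle detected in namespace ", ns, ": ",
           paste(cyc, collapse = " -> "))
    }
    has_parent <- tids %in% e$child
    r <- tids[!has_parent]
    if (length(r) != 1L) {
      stop("namespace ", ns, " must have exactly one root, found ",
           length(r), if (length(r)) paste0(": ", paste(r, collapse = ", ")))
    }
    roots[ns] <- r
    depth[tids] <- .dag_depths(g, tids, e)
    desc[tids] <- .dag_descendant_counts(g, tids)
  }

  terms$depth <- unname(depth[terms$id])
  terms$desc <- unname(desc[terms$id])
  structure(
    list(terms = terms, edges = edges, roots = roots,
         ns_total = table(terms$namespace)),
    class = "ontology_dag"
  )
}

#' @export
print.ontology_dag <- function(x, ...) {
  cat("ontology_dag:", nrow(x$terms), "terms,", nrow(x$edges),
      "is_a edges\n")
  for (ns in names(x$roots)) {
    cat("  ", ns, ": ", x$ns_total[[ns]], " terms, root ",
        x$roots[[ns]], "\n", sep = "")
  }
  invisible(x)
}

.obo_lines <- function(x) {
  if (length(x) == 1L && !grepl("\n", x, fixed = TRUE) && file.exists(x)) {
    readLines(x, warn = FALSE)
  } else {
    unlist(strsplit(x, "\n", fixed = TRUE), use.names = FALSE)
  }
}

.obo_stanzas <- function(lines) {
  lines <- sub("\\s+$", "", lines)
  heads <- grep("^\\[", lines)
  if (length(heads) == 0L) return(list())
  ends <- c(heads[-1] - 1L, length(lines))
  out <- list()
  for (i in seq_along(heads)) {
    if (lines[heads[i]] == "[Term]") {
      body <- lines[seq(heads[i] + 1L, length.out = ends[i] - heads[i])]
      out[[length(out) + 1L]] <- body[nzchar(body)]
    }
  }
  out
}

.obo_namespace_map <- c(
  biological_process = "BP", molecular_function = "MF",
  cellular_component = "CC", BP = "BP", MF = "MF", CC = "CC"
)

.obo_parse_term <- function(body) {
  val <- function(key) {
    m <- grep(paste0("^", key, ":"), body, value = TRUE)
    trimws(sub(paste0("^", key, ":\\s*"), "", m))
  }
  obs <- val("is_obsolete")
  if (length(obs) && tolower(obs[1]) == "true") return(NULL)
  id <- val("id")
  if (length(id) == 0L) stop("[Term] stanza without id")
  ns_raw <- val("namespace")
  if (length(ns_raw) == 0L) stop("term ", id[1], " has no namespace")
  ns <- .obo_namespace_map[ns_raw[1]]
  if (is.na(ns)) stop("term ", id[1], " has unknown namespace ", ns_raw[1])
  nm <- val("name")
  parents <- val("is_a")
  # strip trailing "! comment" and optional modifiers
  parents <- trimws(sub("\\s*!.*$", "", parents))
  parents <- vapply(strsplit(parents, "\\s+"), `[[`, character(1), 1,
                    USE.NAMES = FALSE)
  list(id = id[1], name = if (length(nm)) nm[1] else id[1],
       namespace = unname(ns), parents = unique(parents))
}

# longest root-to-term path, computed parent-first along a topological order
.dag_depths <- function(g, tids, e) {
  ord <- igraph::V(g)$name[as.integer(igraph::topo_sort(g, mode = "in"))]
  dep <- stats::setNames(integer(length(tids)), tids)
  parents_of <- split(e$parent, e$child)
  for (v in ord) {
    p <- parents_of[[v]]
    dep[v] <- if (is.null(p)) 0L else max(dep[p]) + 1L
  }
  dep[tids]
}

.dag_descendant_counts <- function(g, tids) {
  vapply(tids, function(v) {
    length(igraph::subcomponent(g, v, mode = "in")) - 1L
  }, integer(1))
}

# DFS cycle extraction on child->parent edges (small graphs only)
.find_cycle <- function(e) {
  adj <- split(e$parent, e$child)
  state <- new.env(parent = emptyenv())
  path <- character(0)
  found <- NULL
  visit <- function(v) {
    if (!is.null(found)) return()
    st <- mget(v, envir = state, ifnotfound = NA)[[1]]
    if (identical(st, 1L)) {
      i <- match(v, path)
      found <<- c(path[i:length(path)], v)
      return()
    }
    if (identical(st, 2L)) return()
    assign(v, 1L, envir = state)
    path <<- c(path, v)
    for (w in adj[[v]]) visit(w)
    path <<- path[-length(path)]
    assign(v, 2L, envir = state)
  }
  for (v in unique(e$child)) {
    visit(v)
    if (!is.null(found)) break
  }
  if (is.null(found)) "<cycle not localised>" else found
}

.check_term <- function(dag, t) {
  miss <- setdiff(t, dag$terms$id)
  if (length(miss)) {
    stop("term(s) not in ontology: ", paste(miss, collapse = ", "))
  }
}

#' Depth of a term
#'
#' Edge count of the longest `is_a` path from the namespace root to the
#' term; the root itself has depth 0. When several paths exist the
#' maximum depth is used.
#'
#' @param dag An `ontology_dag`.
#' @param t Term id(s).
#' @return Integer vector of depths.
#' @export
term_depth <- function(dag, t) {
  .check_term(dag, t)
  dag$terms$depth[match(t, dag$terms$id)]
}

#' Number of distinct descendants of a term
#'
#' Count of distinct terms reachable from `t` by following `is_a`
#' edges downward (the term itself is excluded); shared descendants in
#' diamond topologies are counted once.
#'
#' @inheritParams term_depth
#' @return Integer vector of descendant counts.
#' @export
descendant_count <- function(dag, t) {
  .check_term(dag, t)
  dag$terms$desc[match(t, dag$terms$id)]
}

#' Semantic coverage of a term
#'
#' `1 - log(desc(t) + 1) / log(total_terms)`, where `total_terms` is by
#' default the number of terms in the term's own namespace (each GO
#' namespace is a complete ontology). The value is 1 for leaves and 0
#' for a root that subsumes its whole namespace; it is independent of
#' the logarithm base.
#'
#' @inheritParams term_depth
#' @param total_scope Either "namespace" (default) or "ontology":
#'   whether `total_terms` counts the term's namespace or the whole
#'   parsed ontology.
#' @return Numeric vector in `[0, 1]`.
#' @export
semantic_coverage <- function(dag, t, total_scope = c("namespace", "ontology")) {
  .check_term(dag, t)
  total_scope <- match.arg(total_scope)
  i <- match(t, dag$terms$id)
  total <- if (total_scope == "ontology") {
    rep(nrow(dag$terms), length(i))
  } else {
    as.integer(dag$ns_total[dag$terms$namespace[i]])
  }
  if (any(total < 2L)) {
    stop("degenerate namespace: fewer than 2 terms, coverage undefined")
  }
  1 - log(dag$terms$desc[i] + 1) / log(total)
}

#' Structure-based information content of a term
#'
#' The product of the term's depth and its semantic coverage. Deep,
#' specific terms (few descendants) score high; a namespace root scores
#' 0. Only the ontology topology is used, so the measure is free of
#' annotation-corpus bias.
#'
#' @inheritParams semantic_coverage
#' @return Non-negative numeric vector.
#' @export
struct_ic <- function(dag, t, total_scope = c("namespace", "ontology")) {
  term_depth(dag, t) * semantic_coverage(dag, t, total_scope)
}

#' Per-term information-content table
#'
#' @inheritParams semantic_coverage
#' @return A data.frame with columns `term_id`, `namespace`, `depth`,
#'   `desc`, `coverage`, `struct_ic` for every term in the ontology.
#' @export
term_ic_table <- function(dag, total_scope = c("namespace", "ontology")) {
  cov <- semantic_coverage(dag, dag$terms$id, total_scope)
  data.frame(
    term_id = dag$terms$id,
    namespace = dag$terms$namespace,
    depth = dag$terms$depth,
    desc = dag$terms$desc,
    coverage = cov,
    struct_ic = dag$terms$depth * cov,
    stringsAsFactors = FALSE
  )
}
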