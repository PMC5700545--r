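make_dag <- function() parse_obo(toy_obo())

test_that("parse_annotations deduplicates and validates terms", {
  tab <- parse_annotations(c("g1\tB", "g1\tC", "g2\tB", "g1\tB"))
  expect_equal(nrow(tab), 3L)
  # unresolvable terms are skipped with a warning carrying the count
  dag <- make_dag()
  expect_warning(
    tab2 <- parse_annotations(c("g1\tB", "g1\tZZ"), dag = dag),
    "1 annotation")
  expect_equal(tab2$term_id, "B")
  expect_error(parse_annotations(character(0)), "no annotations")
})

test_that("GAF dialect extracts columns 2 and 5 past the qualifier", {
  gaf <- paste(c("DB", "g1", "sym", "NOT", "B", "ref", "IEA",
                 "", "P", "", "", "", "", "", ""), collapse = "\t")
  tab <- parse_annotations(c("!gaf-version: 2.1", gaf), dialect = "gaf")
  expect_equal(tab$gene_id, "g1")
  expect_equal(tab$term_id, "B")
})

test_that("enrichment p-values match exact combinatorial enumeration", {
  expect_equal(enrichment_pvalue(0, 5, 5, 20), 1.0)
  expect_equal(enrichment_pvalue(5, 5, 5, 20), 1 / choose(20, 5),
               tolerance = 1e-12)
  expect_equal(enrichment_pvalue(5, 5, 5, 20), 6.4499e-5, tolerance = 1e-4)
  expect_equal(enrichment_pvalue(3, 5, 5, 20),
               hyper_upper_exact(3, 5, 5, 20), tolerance = 1e-12)
  expect_equal(enrichment_pvalue(3, 5, 5, 20), 0.07262, tolerance = 1e-4)
  expect_error(enrichment_pvalue(6, 5, 5, 20), "invalid counts")
  # monotone non-increasing in study_count
  p <- enrichment_pvalue(0:5, 5, 8, 20)
  expect_true(all(diff(p) <= 1e-12))
})

test_that("significant-term selection filters, groups and orders", {
  dag <- make_dag()
  study <- parse_annotations(c("g1\tB", "g2\tB", "g3\tB", "g1\tM2",
                               "g2\tC2"))
  bg <- parse_annotations(c("g1\tB", "g2\tB", "g3\tB", "g1\tM2", "g2\tC2",
                            paste0("h", 1:17, "\tC3")))
  sel <- select_significant_terms(study, dag, threshold = 1.0,
                                  background = bg)
  # all annotated terms pass at threshold 1, grouped BP -> MF -> CC
  expect_equal(sel$term_id, c("B", "M2", "C2"))
  expect_equal(attr(sel, "counts"), c(x = 1L, y = 1L, z = 1L))
  # B: 3 of 3 study genes vs 3 of 20 background genes
  expect_equal(sel$pvalue[sel$term_id == "B"],
               hyper_upper_exact(3, 3, 3, 20), tolerance = 1e-12)
  # the p ~ 0.0088 term survives 0.5 but not a strict cut
  sel2 <- select_significant_terms(study, dag, threshold = 0.5,
                                   background = bg)
  expect_true("B" %in% sel2$term_id)
  expect_error(select_significant_terms(study, dag, threshold = 1e-6,
                                        background = bg),
               "no significant terms")
  # degenerate self-background warns
  expect_warning(try(select_significant_terms(study, dag), silent = TRUE),
                 "degenerate")
})

test_that("annotation matrix follows the 0-or-IC rule and drops unmapped", {
  dag <- make_dag()
  tab <- parse_annotations(c("g1\tC", "g1\tC2", "g2\tM2", "g3\tB"))
  terms <- data.frame(term_id = c("C", "M2", "C2"),
                      namespace = c("BP", "MF", "CC"))
  ic <- struct_ic(dag, terms$term_id)
  M <- suppressMessages(
    build_annotation_matrix(c("g1", "g2", "g3", "g4"), terms, tab, dag))
  # g3 (only term B, unselected) and g4 (unannotated) are dropped
  expect_equal(rownames(M), c("g1", "g2"))
  expect_equal(attr(M, "dropped_genes"), c("g3", "g4"))
  expect_equal(dim(M), c(2L, 3L))
  expect_equal(unname(M["g1", ]), c(ic[1], 0, ic[3]))
  expect_equal(unname(M["g2", ]), c(0, ic[2], 0))
  expect_equal(attr(M, "ns_counts"), c(x = 1L, y = 1L, z = 1L))
  # every nonzero entry of a column equals that column's Struct_IC
  for (p in seq_len(ncol(M))) {
    nz <- M[, p][M[, p] != 0]
    expect_true(all(nz == ic[p]))
  }
  expect_error(
    build_annotation_matrix("gX", terms, tab, dag), "empty matrix")
})

test_that("row distances match hand-expanded formulas", {
  M <- rbind(a = c(0.5, 0), b = c(0, 0.5), c = c(0.2, 0.4), d = c(0.1, 0.2))
  for (kind in c("euclidean", "cityblock", "cosine")) {
    expect_equal(annotation_distance(rbind(M[1, ], M[1, ]), 1, 2, kind), 0)
  }
  expect_equal(annotation_distance(M, 1, 2, "euclidean"), sqrt(0.5),
               tolerance = 1e-12)
  expect_equal(annotation_distance(M, 1, 2, "cityblock"), 1.0)
  expect_equal(annotation_distance(M, 1, 2, "cosine"), 1.0)
  expect_equal(annotation_distance(M, 3, 4, "cosine"), 0, tolerance = 1e-12)
  expect_error(annotation_distance(rbind(M, e = c(0, 0)), 1, 5, "cosine"),
               "zero row")
})

test_that("distance-matrix metric properties hold on random rows", {
  set.seed(42)
  n <- 30
  M <- matrix(rexp(n * 6), n) * matrix(rbinom(n * 6, 1, 0.6), n)
  M[rowSums(M) == 0, 1] <- 0.5
  trips <- matrix(sample.int(n, 3000, replace = TRUE), ncol = 3)
  trips <- trips[trips[, 1] != trips[, 2] & trips[, 2] != trips[, 3] &
                   trips[, 1] != trips[, 3], ]
  for (kind in c("euclidean", "cityblock")) {
    D <- annotation_dist_matrix(M, kind)
    expect_equal(D, t(D), tolerance = 1e-12)
    expect_true(all(diag(D) == 0))
    ij <- D[trips[, 1:2]]; jk <- D[trips[, 2:3]]; ik <- D[trips[, c(1, 3)]]
    expect_true(all(ik <= ij + jk + 1e-9))
  }
  Dc <- annotation_dist_matrix(M, "cosine")
  expect_true(all(Dc >= 0 & Dc <= 1 + 1e-12))
})
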