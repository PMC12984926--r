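screen_fixture <- function() {
  m <- toy_matrix(list(
    "PKN1:S916"  = c("U", "U", "D", "D", "U", "D", "N", "N", "N", "U", "D", "N"),
    "PDPK1:S241" = c("U", "U", "D", "D", "U", "D", "N", "N", "N", "N", "D", "N"),
    "GFPT1:S261" = c("U", "U", "D", "D", "N", "D", "N", "N", "N", "U", "D", "N"),
    "HSPB1:S78"  = c("D", "D", "U", "U", "D", "U", "U", "D", "N", "N", "U", "N")
  ), conditions_per_study = 2)
  coregulation_screen(m, "PKN1:S916",
                      confidence_criteria(min_pmids = 3, min_conditions = 3))
}

test_that("annotation overlay tags partners without dropping any call", {
  sc <- screen_fixture()
  edges <- tibble::tibble(
    source = c("PDPK1", "PDPK1", "GFPT1"),
    target = c("PKN1", "PKN1", "PKN1"),
    edge_type = c("binary_interactor", "kinase_of", "substrate_of"),
    evidence = c("curated_ppi", "kinase_pred", "substrate_pred"),
    site = NA_character_
  )
  out <- overlay_annotations(sc, edges)
  expect_equal(nrow(out), nrow(sc))
  pdpk1 <- out$edge_types[out$protein == "PDPK1"]
  # two edge types, both attached, canonically ordered
  expect_equal(pdpk1, "binary_interactor;kinase_of")
  expect_equal(out$edge_types[out$protein == "GFPT1"], "substrate_of")
  expect_equal(out$edge_types[out$protein == "HSPB1"], "")

  # empty edge table leaves calls unchanged apart from empty tag columns
  plain <- overlay_annotations(sc, edges[0, ])
  expect_equal(nrow(plain), nrow(sc))
  expect_true(all(plain$edge_types == ""))
})

test_that("hypergeometric ORA matches direct mass summation and its edge cases", {
  # k = 0: P(X >= 0) = 1 exactly
  r0 <- hypergeometric_ora("A", list(s = c("B", "C")), LETTERS[1:10])
  expect_identical(r0$p, 1)
  # forced overlap: query equal to the set, set equal to the universe
  rf <- hypergeometric_ora(LETTERS[1:4], list(s = LETTERS[1:4]), LETTERS[1:4])
  expect_identical(rf$p, 1)

  # N=20, K=5, n=5, k=3 against the brute-force sum (frozen from it)
  uni <- sprintf("G%02d", 1:20)
  res <- hypergeometric_ora(uni[1:5], list(s = uni[c(1:3, 6, 7)]), uni)
  expect_equal(res$overlap, 3)
  expect_equal(res$p, 0.0726264189886479, tolerance = 1e-12)
  expect_equal(res$p, oracle_hyper_upper(3, 5, 5, 20), tolerance = 1e-12)

  expect_error(hypergeometric_ora("A", list(s = "A"), character(0)), "universe")
  expect_error(hypergeometric_ora("ZZ", list(s = "A"), LETTERS), "subset|members")
})

test_that("ORA agrees with the lgamma oracle across random configurations", {
  withr::local_seed(31)
  for (i in 1:50) {
    N <- sample(10:200, 1)
    uni <- sprintf("G%03d", 1:N)
    K <- sample(1:N, 1); n <- sample(1:N, 1)
    set <- sample(uni, K); query <- sample(uni, n)
    res <- hypergeometric_ora(query, list(s = set), uni, adjust = FALSE)
    expect_equal(res$p,
                 oracle_hyper_upper(res$overlap, K, n, N),
                 tolerance = 1e-12)
  }
})

test_that("GMT files parse into named member lists", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("insulin_signaling\tdesc\tPDPK1\tIRS2\tPRKAA1",
               "cytoskeleton\tdesc\tMAPT\tMARCKS"), path)
  sets <- read_gmt(path)
  expect_named(sets, c("insulin_signaling", "cytoskeleton"))
  expect_setequal(sets$insulin_signaling, c("PDPK1", "IRS2", "PRKAA1"))
  bad <- withr::local_tempfile(fileext = ".gmt")
  writeLines("only_two\tfields", bad)
  expect_error(read_gmt(bad), "GMT")
})

test_that("the network carries signed co-regulation edges and label attributes", {
  sc <- screen_fixture()
  labels <- tibble::tibble(
    protein = c("PDPK1", "HSPB1"),
    direction = c("up", "up"),
    context = "HCC",
    activity_sites = c("S241", NA)
  )
  g <- build_network(sc, labels = labels)
  expect_equal(igraph::vcount(g),
               1 + dplyr::n_distinct(sc$partner[sc$passes_filters]))
  # anchor is the first node
  expect_equal(igraph::V(g)$name[1], "PKN1:S916")
  expect_true(igraph::V(g)$is_anchor[1])

  types <- igraph::E(g)$type
  expect_setequal(unique(types), c("pos_coreg", "neg_coreg"))
  expect_equal(igraph::E(g)$type[igraph::get_edge_ids(
    g, c("PKN1:S916", "HSPB1:S78"))], "neg_coreg")

  v <- igraph::V(g)
  expect_equal(v$expression[v$name == "PDPK1:S241"], "up")
  expect_true(v$activity_associated[v$name == "PDPK1:S241"])
  expect_false(v$activity_associated[v$name == "HSPB1:S78"])

  # with no passing calls the network is the anchor alone
  empty <- sc[0, ]
  attr(empty, "anchor") <- attr(sc, "anchor")
  g0 <- build_network(empty, anchor = "PKN1:S916")
  expect_equal(igraph::vcount(g0), 1)
  expect_equal(igraph::ecount(g0), 0)
})

test_that("network exports write SIF, round-trip edge TSV, and valid GraphML", {
  sc <- screen_fixture()
  edges <- tibble::tibble(source = "PDPK1", target = "PKN1",
                          edge_type = "binary_interactor",
                          evidence = "curated_ppi", site = "S241")
  g <- build_network(sc, edges = edges)

  sif <- withr::local_tempfile(fileext = ".sif")
  export_network(g, sif, "sif")
  lines <- readLines(sif)
  expect_equal(length(lines), igraph::ecount(g))
  expect_true(all(lengths(strsplit(lines, "\t")) == 3))
  expect_true(any(grepl("\tbinary_interactor\t", lines)))

  tsv <- withr::local_tempfile(fileext = ".tsv")
  export_network(g, tsv, "edge_tsv")
  g2 <- import_edge_tsv(tsv)
  tsv2 <- withr::local_tempfile(fileext = ".tsv")
  export_network(g2, tsv2, "edge_tsv")
  expect_identical(readLines(tsv), readLines(tsv2))

  gml <- withr::local_tempfile(fileext = ".graphml")
  export_network(g, gml, "graphml")
  doc <- xml2::read_xml(gml)  # independent parser accepts the output
  expect_equal(xml2::xml_name(doc), "graphml")
  expect_equal(length(xml2::xml_find_all(doc, ".//d1:edge", xml2::xml_ns(doc))),
               igraph::ecount(g))

  expect_error(export_network(g, tsv, "dot"), "arg")
})
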