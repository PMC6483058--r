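test_that("edge-list reading transcribes rows, merges duplicates, drops self-loops", {
  f <- withr::local_tempfile(lines = c("# comment", "A\tB", "B\tC"))
  net <- read_edge_list(f)
  expect_equal(n_nodes(net), 3)
  expect_equal(n_edges(net), 2)
  expect_setequal(net$nodes, c("A", "B", "C"))

  f2 <- withr::local_tempfile(lines = c("A\tB", "A\tB\t2.0"))
  net2 <- read_edge_list(f2)
  expect_equal(n_edges(net2), 1)
  expect_equal(net2$edges$weight, 2.0)

  f3 <- withr::local_tempfile(lines = c("A\tA", "A\tB"))
  expect_warning(net3 <- read_edge_list(f3), "self-loop")
  expect_equal(n_edges(net3), 1)
  expect_equal(net3$edges$tail, "A")
  expect_equal(net3$edges$head, "B")
})

test_that("malformed rows and negative weights are rejected with line numbers", {
  f <- withr::local_tempfile(lines = c("A\tB", "oops"))
  expect_error(read_edge_list(f), "line 2")
  f2 <- withr::local_tempfile(lines = c("A\tB\t-1"))
  expect_error(read_edge_list(f2), "negative weight")
  f3 <- withr::local_tempfile(lines = c("A\tB\tC\tD"))
  expect_error(read_edge_list(f3), "malformed")
})

test_that("sif dialect records the relation as subtype", {
  f <- withr::local_tempfile(lines = c("A\tactivates\tB"))
  net <- read_edge_list(f, dialect = "sif")
  expect_equal(net$edges$tail, "A")
  expect_equal(net$edges$head, "B")
  expect_equal(net$edges$subtype, "activates")
})

test_that("networks have set semantics: row order never matters", {
  rows <- c("A\tB", "B\tC", "C\tD", "A\tD\t3")
  for (perm in list(c(2, 1, 4, 3), c(4, 3, 2, 1), c(3, 1, 4, 2))) {
    f1 <- withr::local_tempfile(lines = rows)
    f2 <- withr::local_tempfile(lines = rows[perm])
    expect_identical(read_edge_list(f1, name = "x")$edges,
                     read_edge_list(f2, name = "x")$edges)
  }
})

test_that("edge-list write/read round-trips node, edge and weight content", {
  net <- edge_net(c("s", "s", "a", "b"), c("a", "b", "t", "t"))
  f <- withr::local_tempfile()
  write_edge_list(net, f)
  back <- read_edge_list(f)
  expect_identical(back$nodes, net$nodes)
  expect_identical(back$edges[, c("tail", "head", "weight")],
                   net$edges[, c("tail", "head", "weight")])
})

test_that("stored edges always satisfy the simple-digraph contract", {
  expect_warning(
    net <- pathway_network(data.frame(
      tail = c("a", "b", "b", "c", "c"), head = c("b", "b", "c", "a", "a"),
      weight = c(1, 1, 2, 1, 5))),
    "self-loop")
  expect_true(all(net$edges$tail != net$edges$head))
  expect_true(all(net$edges$weight > 0))
  expect_false(anyDuplicated(paste(net$edges$tail, net$edges$head)) > 0)
  expect_equal(net$edges$weight[net$edges$tail == "c"], 5)  # max kept
  expect_error(pathway_network(data.frame(tail = "a", head = "b", weight = 0)),
               "positive")
})

test_that("minimal KGML documents parse as specified", {
  two_gene <- withr::local_tempfile(lines = c(
    '<?xml version="1.0"?>',
    '<pathway name="path:test">',
    '<entry id="1" name="GENE1" type="gene"/>',
    '<entry id="2" name="GENE2" type="gene"/>',
    '<relation entry1="1" entry2="2" type="PPrel">',
    '<subtype name="activation" value="--&gt;"/></relation>',
    '</pathway>'), fileext = ".kgml")
  net <- read_kgml(two_gene)
  expect_equal(n_nodes(net), 2)
  expect_equal(n_edges(net), 1)
  expect_equal(net$edges$subtype, "activation")
  expect_equal(net$edges$provenance, "pathway")

  # compound between two genes: skipped, indirect link NOT collapsed
  via_compound <- withr::local_tempfile(lines = c(
    '<?xml version="1.0"?>', '<pathway name="path:test2">',
    '<entry id="1" name="GENE1" type="gene"/>',
    '<entry id="2" name="GENE2" type="gene"/>',
    '<entry id="3" name="cpd:C00001" type="compound"/>',
    '<relation entry1="1" entry2="3" type="PCrel"/>',
    '<relation entry1="3" entry2="2" type="PCrel"/>',
    '</pathway>'), fileext = ".kgml")
  expect_message(net2 <- read_kgml(via_compound), "compound")
  expect_equal(n_nodes(net2), 2)
  expect_equal(n_edges(net2), 0)
})

test_that("multi-gene KGML entries expand with the relation duplicated", {
  f <- withr::local_tempfile(lines = c(
    '<?xml version="1.0"?>', '<pathway name="path:test3">',
    '<entry id="1" name="GENE1 GENE1B" type="gene"/>',
    '<entry id="2" name="GENE2" type="gene"/>',
    '<relation entry1="1" entry2="2" type="PPrel"/>',
    '</pathway>'), fileext = ".kgml")
  net <- read_kgml(f)
  expect_equal(n_nodes(net), 3)
  expect_equal(n_edges(net), 2)
  expect_setequal(net$edges$tail, c("GENE1", "GENE1B"))
  expect_equal(unique(net$edges$head), "GENE2")
})

test_that("KGML relations to undeclared entries and broken XML are errors", {
  f <- withr::local_tempfile(lines = c(
    '<?xml version="1.0"?>', '<pathway name="p">',
    '<entry id="1" name="GENE1" type="gene"/>',
    '<relation entry1="1" entry2="99" type="PPrel"/>',
    '</pathway>'), fileext = ".kgml")
  expect_error(read_kgml(f), "unknown entry id")
  f2 <- withr::local_tempfile(lines = "<pathway><entry", fileext = ".kgml")
  expect_error(read_kgml(f2), "parse failure")
})

test_that("the packaged pathway fixture parses to the expected sparse map", {
  net <- suppressMessages(read_kgml(extdata("synthetic_ad_pathway.kgml")))
  expect_equal(n_edges(net), 24)
  stats <- subgraph_stats(net, ad_universe())
  expect_equal(stats$connected_nodes, 31)
  expect_equal(stats$universe_size, 171)
  expect_equal(round(stats$connected_fraction, 2), 0.18)
})

test_that("a KGML relation-type filter keeps only the requested types", {
  f <- withr::local_tempfile(lines = c(
    '<?xml version="1.0"?>', '<pathway name="p">',
    '<entry id="1" name="G1" type="gene"/>',
    '<entry id="2" name="G2" type="gene"/>',
    '<entry id="3" name="G3" type="gene"/>',
    '<relation entry1="1" entry2="2" type="PPrel"/>',
    '<relation entry1="2" entry2="3" type="GErel"/>',
    '</pathway>'), fileext = ".kgml")
  expect_equal(n_edges(read_kgml(f)), 2)
  net <- read_kgml(f, relation_types = "PPrel")
  expect_equal(n_edges(net), 1)
  expect_equal(net$edges$head, "G2")
})

test_that("GraphML round-trips networks losslessly including provenance", {
  net <- pathway_network(data.frame(
    tail = c("a", "b", "c"), head = c("b", "c", "a"),
    weight = c(1, 2.5, 1), provenance = c("pathway", "ppi", "pathway")),
    nodes = c("a", "b", "c", "isolated"), name = "rt")
  f <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(net, f)
  back <- read_graphml(f, name = "rt")
  expect_identical(back$nodes, net$nodes)
  expect_identical(back$edges, net$edges)

  empty <- pathway_network(NULL, name = "empty")
  f2 <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(empty, f2)
  expect_equal(n_nodes(read_graphml(f2)), 0)
})

test_that("subgraph_stats validates and degrades gracefully", {
  net <- edge_net(c("a", "b"), c("b", "c"))
  expect_error(subgraph_stats(net, universe = c("a", "b")), "superset")
  s <- subgraph_stats(net)
  expect_null(s$connected_fraction)
  expect_equal(subgraph_stats(net, c("a", "b", "c"))$connected_fraction, 1.0)
})
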