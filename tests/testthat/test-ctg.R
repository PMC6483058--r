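test_that("source/sink specifications enforce their contract", {
  expect_error(source_sink_spec("d", character(), "t"), "non-empty")
  expect_error(source_sink_spec("d", "x", c("x", "y")), "disjoint")
  expect_error(source_sink_spec("d", c("a", "a"), "t"), "duplicated")
  sp <- source_sink_spec("d", c(" s1", "s2 "), "t1")
  expect_identical(sp$sources, c("s1", "s2"))
})

test_that("pair enumeration is the ordered cartesian product", {
  sp <- source_sink_spec("AD", c("APP", "CAPN1"), c("CASP3", "APBB1", "MAPT"))
  pairs <- enumerate_pairs(sp)
  expect_equal(nrow(pairs), 6)
  expect_equal(pairs$source, rep(c("APP", "CAPN1"), each = 3))
  expect_equal(pairs$sink[1:3], c("CASP3", "APBB1", "MAPT"))
  expect_equal(nrow(enumerate_pairs(source_sink_spec("x", "a", "b"))), 1)
})

test_that("the packaged disease table enumerates the documented pair counts", {
  specs <- read_source_sink_specs(extdata("table2_specs.tsv"))
  counts <- vapply(specs, function(sp) nrow(enumerate_pairs(sp)), 1L)
  expect_identical(counts[c("AD", "T2DM", "MEL", "PC", "ALS",
                            "HD", "PRION", "CVID", "RCC", "NAFLD")],
                   c(AD = 6L, T2DM = 2L, MEL = 6L, PC = 28L, ALS = 5L,
                     HD = 4L, PRION = 1L, CVID = 2L, RCC = 15L, NAFLD = 18L))
})

test_that("spec files with duplicate diseases are rejected; YAML specs parse", {
  f <- withr::local_tempfile(lines = c("disease_id\tsources\tsinks",
                                       "d1\ta\tb", "d1\tc\td"))
  expect_error(read_source_sink_specs(f), "duplicate disease ids")
  y <- withr::local_tempfile(lines = c("- disease_id: d1", "  sources: [a, b]",
                                       "  sinks: [c]"), fileext = ".yaml")
  specs <- read_source_sink_specs(y)
  expect_equal(nrow(enumerate_pairs(specs$d1)), 2)
})

test_that("CTGs are the cut-edge endpoints minus sources and sinks", {
  spec <- source_sink_spec("d", "s", "t")
  cut <- structure(
    list(source = "s", sink = "t", capacity = 2,
         cut_edges = data.frame(tail = c("s", "b"), head = c("a", "t"),
                                weight = c(1, 1)),
         source_side = c("b", "s"), connected = TRUE),
    class = "cut_result")
  expect_identical(extract_ctgs(cut, spec), c("a", "b"))

  empty <- st_min_cut(edge_net("x", "s", nodes = c("s", "t", "x")), "s", "t")
  expect_identical(extract_ctgs(empty, spec), character())
})

test_that("the packaged augmented pathway yields the five relay CTGs", {
  initial <- suppressMessages(read_kgml(extdata("synthetic_ad_pathway.kgml")))
  ppi <- read_edge_list(extdata("synthetic_ad_ppi.tsv"), provenance = "ppi")
  aug <- augment(initial, ppi, ad_universe())$network
  spec <- read_source_sink_specs(extdata("table2_specs.tsv"))[["AD"]]
  cut <- st_min_cut(aug, "APP", "CASP3")
  expect_equal(nrow(cut$cut_edges), 5)
  expect_identical(extract_ctgs(cut, spec),
                   c("APAF1", "CASP8", "PSEN1", "PSEN2", "SNCA"))
})

test_that("occurrence proportions use attempted pairs as denominator", {
  # x mediates 2 of the 6 pairs, y mediates 1; the other 3 are disconnected
  net <- edge_net(c("s1", "x", "x", "s2", "y"),
                  c("x", "t1", "t2", "y", "t3"))
  spec <- source_sink_spec("toy", c("s1", "s2"), c("t1", "t2", "t3"))
  rep <- run_disease(net, spec)
  expect_equal(rep$n_runs, 6)
  expect_equal(rep$n_connected_runs, 3)
  expect_equal(rep$occurrences[["x"]], 2)
  expect_equal(sprintf("%.1f", rep$proportions[["x"]]), "33.3")
  expect_equal(sprintf("%.1f", rep$proportions[["y"]]), "16.7")
  expect_false(any(c(spec$sources, spec$sinks) %in% names(rep$occurrences)))
})

test_that("a gene mediating every run scores 100 percent", {
  net <- edge_net(c("s1", "s2", "m", "m"), c("m", "m", "t1", "t2"))
  spec <- source_sink_spec("toy", c("s1", "s2"), c("t1", "t2"))
  rep <- run_disease(net, spec)
  expect_equal(unname(rep$proportions["m"]), 100.0)
})

test_that("unresolved genes count as attempted-but-disconnected runs", {
  net <- edge_net("s1", "t1")
  spec <- source_sink_spec("toy", c("s1", "ghost"), "t1")
  expect_warning(rep <- run_disease(net, spec), "ghost")
  expect_equal(rep$n_runs, 2)
  expect_equal(rep$n_connected_runs, 1)
})

test_that("run_all aggregates, sorts deterministically and flags failures", {
  suite <- load_fixture_suite(suite_dir())
  expect_warning(
    res <- run_all(suite$augmented[-1], suite$specs),
    "no network")
  expect_equal(res$failures, "synth01")
  expect_equal(length(res$reports), 9)

  res2 <- run_all(suite$augmented, suite$specs)
  tab <- res2$table
  expect_equal(length(res2$reports), 10)
  ord <- order(tab$disease, -tab$occurrences, tab$gene, method = "radix")
  expect_identical(tab, tab[ord, ])
  # every connected run across the suite passes the disconnection check
  for (rep in res2$reports) {
    for (r in rep$results) {
      if (!is.null(r)) {
        expect_true(verify_cut(suite$augmented[[rep$disease_id]], r))
      }
    }
  }
  # counting consistency: no gene occurs more often than there are runs
  for (rep in res2$reports) {
    expect_true(all(rep$occurrences <= rep$n_runs))
    expect_equal(unname(rep$proportions),
                 unname(rep$occurrences / rep$n_runs * 100))
  }
})

test_that("rewriting identical results is byte-identical", {
  suite <- load_fixture_suite(suite_dir())
  res <- run_all(suite$augmented, suite$specs)
  f1 <- withr::local_tempfile()
  f2 <- withr::local_tempfile()
  write_ctg_table(res, f1)
  write_ctg_table(run_all(suite$augmented, suite$specs), f2)
  expect_identical(readBin(f1, "raw", 1e6), readBin(f2, "raw", 1e6))
  j1 <- withr::local_tempfile()
  write_ctg_report_json(res$reports[[1]], j1)
  expect_true(jsonlite::validate(paste(readLines(j1), collapse = "\n")))
})
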