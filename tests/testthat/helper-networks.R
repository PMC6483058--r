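# small graph builders shared across tests

edge_net <- function(tail, head, weight = 1, provenance = "pathway",
                     nodes = NULL, name = "") {
  pathway_network(data.frame(tail = tail, head = head, weight = weight,
                             provenance = provenance,
                             stringsAsFactors = FALSE),
                  nodes = nodes, name = name)
}

# s -> {a, b} -> t, unit weights: max flow 2, canonical cut {(s,a),(s,b)}
diamond_net <- function() {
  edge_net(c("s", "s", "a", "b"), c("a", "b", "t", "t"))
}

# star hub a -> {b, c, d}
star_net <- function() edge_net(c("a", "a", "a"), c("b", "c", "d"))

# uniform random simple digraph on n nodes with edge probability p
random_digraph <- function(n, p, seed) {
  ids <- sprintf("v%02d", seq_len(n))
  pairs <- expand.grid(tail = ids, head = ids, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$tail != pairs$head, ]
  withr::with_seed(seed, {
    kept <- pairs[stats::runif(nrow(pairs)) < p, , drop = FALSE]
    if (nrow(kept) == 0) return(pathway_network(NULL, nodes = ids))
    kept$weight <- 1
    kept$provenance <- "pathway"
    pathway_network(kept, nodes = ids)
  })
}

# fixture suite cached once per test run (deterministic in its seed)
suite_dir <- function() {
  dir <- file.path(tempdir(), "pathmincut_suite_seed7")
  if (!file.exists(file.path(dir, "manifest.json"))) {
    make_fixture_suite(dir, seed = 7)
  }
  dir
}

extdata <- function(...) {
  system.file("extdata", ..., package = "pathmincut", mustWork = TRUE)
}

ad_universe <- function() {
  lines <- readLines(extdata("synthetic_ad_universe.txt"), warn = FALSE)
  lines[!grepl("^#", lines)]
}
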