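# run code under a local RNG state so callers' streams are untouched
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Generate a directed scale-free gene network
#'
#' Directed preferential attachment in two phases. Growth phase: nodes
#' join one at a time, each attaching by a single edge to an existing
#' node chosen with probability proportional to its total degree (plus
#' `attractiveness`), with the edge direction drawn uniformly — so
#' whenever the edge budget allows (n_edges >= n_nodes - 1) every node
#' ends with degree >= 1, as in a drawn pathway map. Densification
#' phase: the remaining edges draw their tail proportional to out-degree
#' and head proportional to in-degree (each plus `attractiveness`),
#' rejecting self-loops and duplicate pairs. High-degree
#' nodes accumulate further edges, producing the heavy-tailed
#' (power-law-like) degree distributions characteristic of biological
#' networks, while peripheral nodes commonly have only outgoing (or only
#' incoming) edges — the natural sources and sinks of the benchmark. The
#' same seed always yields the identical network.
#'
#' `attractiveness` is the additive initial attractiveness of the linear
#' attachment kernel (probability proportional to degree +
#' `attractiveness`): small values strengthen the rich-get-richer effect
#' and hence the tail; the default 0.25 gives pooled degree tails that a
#' discrete power law fits better than an exponential at this scale.
#'
#' @param n_nodes number of nodes (>= 3); node ids are `"n01"`, `"n02"`, ...
#' @param n_edges number of directed edges; must not exceed
#'   n_nodes x (n_nodes - 1).
#' @param seed integer RNG seed.
#' @param attractiveness additive smoothing of the attachment kernel (> 0).
#' @param name network name.
#' @return a [pathway_network] with exactly `n_nodes` nodes (isolated
#'   ones included only when n_edges < n_nodes - 1) and `n_edges`
#'   unit-weight edges.
#' @export
generate_scale_free <- function(n_nodes, n_edges, seed, attractiveness = 0.25,
                                name = "simulated") {
  n_nodes <- as.integer(n_nodes)
  n_edges <- as.integer(n_edges)
  if (is.na(n_nodes) || n_nodes < 3) stop("n_nodes must be >= 3")
  if (is.na(n_edges) || n_edges < 0) stop("n_edges must be >= 0")
  if (!is.numeric(attractiveness) || attractiveness <= 0) {
    stop("attractiveness must be > 0")
  }
  if (n_edges > n_nodes * (n_nodes - 1)) {
    stop("infeasible edge budget: a simple digraph on ", n_nodes,
         " nodes holds at most ", n_nodes * (n_nodes - 1), " edges")
  }
  width <- max(2, nchar(n_nodes))
  ids <- sprintf(paste0("n%0", width, "d"), seq_len(n_nodes))
  with_seed(seed, {
    outd <- integer(n_nodes)
    ind <- integer(n_nodes)
    seen <- new.env(hash = TRUE, parent = emptyenv())
    tails <- integer(n_edges)
    heads <- integer(n_edges)
    m <- 0L
    add_edge <- function(u, v) {
      m <<- m + 1L
      tails[m] <<- u
      heads[m] <<- v
      outd[u] <<- outd[u] + 1L
      ind[v] <<- ind[v] + 1L
      seen[[paste0(u, "_", v)]] <- TRUE
    }
    # growth: node i attaches to one earlier node, PA on total degree
    for (i in seq_len(n_nodes)[-1]) {
      if (m >= n_edges) break
      j <- if (i == 2L) 1L else
        sample.int(i - 1L, 1,
                   prob = (outd + ind)[seq_len(i - 1L)] + attractiveness)
      if (stats::runif(1) < 0.5) add_edge(j, i) else add_edge(i, j)
    }
    # densification: remaining edges by degree-preferential sampling
    guard <- 0L
    while (m < n_edges) {
      guard <- guard + 1L
      if (guard > 1000L * (n_edges + 1L)) {
        stop("edge sampling failed to meet the budget; lower n_edges")
      }
      u <- sample.int(n_nodes, 1, prob = outd + attractiveness)
      v <- sample.int(n_nodes, 1, prob = ind + attractiveness)
      if (u == v || !is.null(seen[[paste0(u, "_", v)]])) next
      add_edge(u, v)
    }
    pathway_network(if (n_edges > 0)
      data.frame(tail = ids[tails], head = ids[heads], weight = 1,
                 provenance = "pathway", stringsAsFactors = FALSE),
      nodes = ids, name = name)
  })
}

#' Designate source and sink genes by degree
#'
#' The benchmark convention: sources are the nodes with no incoming
#' edges, sinks the nodes with no outgoing edges, each in ascending id
#' order. A node qualifying on both sides (an isolated node) violates
#' the disjointness contract, and a network lacking either kind cannot
#' host an s-t run; both raise a designation error — regenerate with a
#' different seed.
#'
#' @param net a [pathway_network].
#' @param disease_id id recorded in the returned spec.
#' @return a [source_sink_spec].
#' @export
designate_sources_sinks <- function(net, disease_id = net$name) {
  stopifnot_network(net)
  ind <- in_degree(net)
  outd <- out_degree(net)
  sources <- sort(names(ind)[ind == 0], method = "radix")
  sinks <- sort(names(outd)[outd == 0], method = "radix")
  isolated <- intersect(sources, sinks)
  if (length(isolated)) {
    stop("designation error: isolated node(s) qualify as both source and ",
         "sink: ", paste(isolated, collapse = ", "),
         "; regenerate with a different seed")
  }
  if (!length(sources) || !length(sinks)) {
    stop("designation error: need >= 1 in-degree-0 node and >= 1 ",
         "out-degree-0 node; regenerate with a different seed")
  }
  source_sink_spec(disease_id, sources, sinks)
}

#' Build a synthetic multi-disease fixture suite
#'
#' Writes a self-contained stand-in for a multi-disease study: 10
#' synthetic disease pathways with their gene universes, one shared
#' directed-PPI edge list, and a per-disease source/sink specification
#' table. Eight diseases have every (source, sink) pair connected through
#' a common relay after PPI augmentation; two (`synth09`, `synth10`) are
#' engineered with no source-to-sink path at all, emulating pathways
#' whose onset and apoptotic genes live in separate components. Overlay
#' densities are calibrated so that across the suite the mean augmented/
#' initial connected-node percentage is close to 207 and the mean added-
#' edge percentage close to 454, the densification level PPI augmentation
#' achieves on real disease pathways. Per-disease gene namespaces keep
#' the shared PPI file unambiguous.
#'
#' @param out_dir output directory (created if needed).
#' @param seed integer seed; identical seeds give byte-identical files.
#' @return the manifest, invisibly: a list recording the seed, file
#'   names, and per-disease expected properties (counts, connectivity).
#'   Also written as `manifest.json`.
#' @export
make_fixture_suite <- function(out_dir, seed = 7) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ids <- sprintf("synth%02d", 1:10)
  disconnected <- c("synth09", "synth10")
  ppi_rows <- list()
  diseases <- list()
  spec_rows <- list()

  with_seed(seed, {
    for (d in ids) {
      g <- function(k) sprintf("%s_g%03d", d, k)
      n_src <- sample(1:3, 1)
      n_snk <- sample(1:3, 1)
      srcs <- g(seq_len(n_src))
      snks <- g(10 + seq_len(n_snk))
      m1 <- g(20); m2 <- g(21)
      core <- data.frame(tail = c(srcs, if (!(d %in% disconnected)) m1,
                                  rep(m2, n_snk)),
                         head = c(rep(m1, n_src), if (!(d %in% disconnected)) m2,
                                  snks),
                         stringsAsFactors = FALSE)
      # filler: disjoint directed paths, sized to a sampled edge budget
      e_init <- sample(18:30, 1)
      ef <- e_init - nrow(core)
      comp_sizes <- c()
      left <- ef
      while (left > 0) {
        s <- min(left, sample(1:3, 1))
        comp_sizes <- c(comp_sizes, s)
        left <- left - s
      }
      base <- 100
      filler <- NULL
      filler_nodes <- character()
      for (cs in comp_sizes) {
        nodes <- g(base + 0:cs)
        filler <- rbind(filler, data.frame(tail = nodes[-(cs + 1)],
                                           head = nodes[-1],
                                           stringsAsFactors = FALSE))
        filler_nodes <- c(filler_nodes, nodes)
        base <- base + cs + 1
      }
      init_edges <- rbind(core, filler)
      init <- pathway_network(cbind(init_edges, weight = 1,
                                    provenance = "pathway"), name = d)
      n_init <- sum(total_degree(init) >= 1)

      # overlay: chain all new genes off a filler anchor, then densify
      # among filler nodes; core genes are never touched, so source-sink
      # connectivity is decided by the initial topology alone
      n_new <- round(1.07 * n_init)
      new_genes <- g(500 + seq_len(n_new))
      a_target <- round(4.54 * n_edges(init))
      anchor <- filler_nodes[1]
      ov <- data.frame(tail = c(anchor, new_genes[-n_new]),
                       head = new_genes, stringsAsFactors = FALSE)
      need <- a_target - nrow(ov)
      have <- paste(init_edges$tail, init_edges$head)
      pool <- expand.grid(tail = filler_nodes, head = filler_nodes,
                          stringsAsFactors = FALSE)
      pool <- pool[pool$tail != pool$head &
                   !(paste(pool$tail, pool$head) %in% have), , drop = FALSE]
      if (need > nrow(pool)) stop("internal: overlay pool too small for ", d)
      pool <- pool[sample.int(nrow(pool)), , drop = FALSE]
      ov <- rbind(ov, pool[seq_len(need), , drop = FALSE])

      universe <- c(init$nodes, new_genes, g(900 + 1:5))  # 5 never-connected
      pw_file <- file.path(out_dir, paste0("pathway_", d, ".tsv"))
      un_file <- file.path(out_dir, paste0("universe_", d, ".txt"))
      write_edge_list(init, pw_file)
      writeLines(sort(universe, method = "radix"),
                 con <- file(un_file, open = "wb"))
      close(con)
      ppi_rows[[d]] <- ov
      spec_rows[[d]] <- data.frame(disease_id = d,
                                   sources = paste(srcs, collapse = ";"),
                                   sinks = paste(snks, collapse = ";"),
                                   stringsAsFactors = FALSE)
      diseases[[d]] <- list(
        id = d, connected = !(d %in% disconnected),
        n_pairs = n_src * n_snk,
        initial_connected_nodes = n_init, initial_edges = n_edges(init),
        overlay_edges = nrow(ov), new_genes = n_new,
        pathway_file = basename(pw_file), universe_file = basename(un_file))
    }
  })

  ppi <- do.call(rbind, unname(ppi_rows))
  ppi_net <- pathway_network(cbind(ppi, weight = 1, provenance = "ppi"),
                             name = "synthetic_ppi")
  ppi_file <- file.path(out_dir, "ppi.tsv")
  write_edge_list(ppi_net, ppi_file)
  spec_file <- file.path(out_dir, "specs.tsv")
  spec_tab <- do.call(rbind, unname(spec_rows))
  con <- file(spec_file, open = "wb")
  writeLines(c("disease_id\tsources\tsinks",
               do.call(paste, c(unname(spec_tab), sep = "\t"))), con)
  close(con)

  manifest <- list(seed = seed, ppi_file = basename(ppi_file),
                   spec_file = basename(spec_file), diseases = diseases)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Load a fixture suite into pipeline-ready objects
#'
#' Reads the files written by [make_fixture_suite()], augments each
#' pathway with the shared PPI overlay, and returns everything
#' [run_all()] and [batch_augment()] need.
#'
#' @param dir the suite directory.
#' @return list with `pathways` (named list of `network` + `universe`),
#'   `ppi`, `specs`, `augmented` (named list of augmented networks),
#'   `stats` (the [batch_augment()] table) and `manifest`.
#' @export
load_fixture_suite <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  ppi <- read_edge_list(file.path(dir, manifest$ppi_file), provenance = "ppi")
  specs <- read_source_sink_specs(file.path(dir, manifest$spec_file))
  pathways <- lapply(manifest$diseases, function(m) {
    list(network = read_edge_list(file.path(dir, m$pathway_file)),
         universe = readLines(file.path(dir, m$universe_file)))
  })
  names(pathways) <- vapply(manifest$diseases, `[[`, "", "id")
  stats <- batch_augment(pathways, ppi)
  list(pathways = pathways, ppi = ppi, specs = specs,
       augmented = attr(stats, "networks"), stats = stats,
       manifest = manifest)
}
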