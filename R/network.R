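#' Construct a directed gene-pathway network
#'
#' A `pathway_network` is a simple directed graph of genes: at most one
#' stored edge per ordered (tail, head) pair, no self-loops, and every
#' stored edge has positive weight (an absent edge has implicit weight 0).
#' Edges carry a provenance tag distinguishing pathway-derived relations
#' from PPI-derived ones, so augmented networks remain auditable.
#'
#' Gene identifiers are compared by exact string match after whitespace
#' trimming; no case folding and no symbol/Entrez alias resolution is
#' performed.
#'
#' @param edges data.frame with columns `tail`, `head` and optionally
#'   `weight` (default 1), `provenance` (`"pathway"` or `"ppi"`, default
#'   `"pathway"`) and `subtype` (free-text relation subtype, recorded but
#'   never used in computation).
#' @param nodes optional character vector of gene ids; edge endpoints are
#'   always included, so this only adds isolated nodes.
#' @param name network name.
#' @param merge_duplicates how to treat repeated (tail, head) rows:
#'   `TRUE` (default) merges them keeping the maximum weight, `FALSE`
#'   raises an error.
#'
#' @return An object of class `pathway_network` with elements `nodes`
#'   (sorted character vector), `edges` (data.frame sorted by tail then
#'   head, columns tail/head/weight/provenance/subtype) and `name`.
#' @export
#' @examples
#' net <- pathway_network(data.frame(tail = c("A", "B"), head = c("B", "C")))
#' n_nodes(net)
#' n_edges(net)
pathway_network <- function(edges = NULL, nodes = NULL, name = "",
                            merge_duplicates = TRUE) {
  if (is.null(edges) || nrow(edges) == 0) {
    edges <- data.frame(tail = character(), head = character(),
                        weight = numeric(), provenance = character(),
                        subtype = character(), stringsAsFactors = FALSE)
  } else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    if (!all(c("tail", "head") %in% names(edges))) {
      stop("edges must have 'tail' and 'head' columns")
    }
    edges$tail <- trimws(as.character(edges$tail))
    edges$head <- trimws(as.character(edges$head))
    if (any(edges$tail == "") || any(edges$head == "")) {
      stop("empty gene identifier in edge table")
    }
    if (is.null(edges$weight)) edges$weight <- 1
    edges$weight <- as.numeric(edges$weight)
    if (anyNA(edges$weight) || any(edges$weight <= 0)) {
      stop("edge weights must be positive (absent edges have implicit weight 0)")
    }
    if (is.null(edges$provenance)) edges$provenance <- "pathway"
    edges$provenance <- as.character(edges$provenance)
    bad <- setdiff(unique(edges$provenance), c("pathway", "ppi"))
    if (length(bad)) stop("unknown provenance value(s): ", paste(bad, collapse = ", "))
    if (is.null(edges$subtype)) edges$subtype <- NA_character_
    edges$subtype <- as.character(edges$subtype)
    edges <- edges[, c("tail", "head", "weight", "provenance", "subtype")]

    loops <- edges$tail == edges$head
    if (any(loops)) {
      warning(sum(loops), " self-loop edge(s) dropped (a self-loop can never lie on an s-t cut)")
      edges <- edges[!loops, , drop = FALSE]
    }
    key <- paste(edges$tail, edges$head, sep = "\r")
    if (anyDuplicated(key)) {
      if (!merge_duplicates) stop("duplicate (tail, head) edge rows")
      # keep max weight; pathway provenance wins over ppi for the same pair
      ord <- order(key, edges$provenance != "pathway", -edges$weight)
      edges <- edges[ord, , drop = FALSE]
      key <- key[ord]
      w <- tapply(edges$weight, key, max)
      edges <- edges[!duplicated(key), , drop = FALSE]
      edges$weight <- as.numeric(w[paste(edges$tail, edges$head, sep = "\r")])
    }
  }

  nodes <- unique(c(trimws(as.character(nodes %||% character())),
                    edges$tail, edges$head))
  nodes <- sort(nodes[nodes != ""], method = "radix")
  edges <- edges[order(edges$tail, edges$head, method = "radix"), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, name = as.character(name)[1]),
            class = "pathway_network")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pathway_network <- function(x, ...) {
  cat("pathway_network", if (nzchar(x$name)) sQuote(x$name) else "",
      "\n  nodes:", length(x$nodes), "  edges:", nrow(x$edges), "\n")
  if (nrow(x$edges)) {
    tab <- table(x$edges$provenance)
    cat("  provenance:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Node and edge counts
#' @param net a `pathway_network`.
#' @return integer count.
#' @export
n_nodes <- function(net) length(net$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(net) nrow(net$edges)

stopifnot_network <- function(net) {
  if (!inherits(net, "pathway_network")) stop("not a pathway_network")
  invisible(net)
}

assert_genes_present <- function(net, genes, what = "gene") {
  missing <- setdiff(genes, net$nodes)
  if (length(missing)) {
    stop("unknown ", what, "(s): ", paste(missing, collapse = ", "))
  }
  invisible(TRUE)
}

#' Degree vectors of a network
#'
#' @param net a `pathway_network`.
#' @return named integer vector over all nodes (isolated nodes get 0).
#' @export
out_degree <- function(net) {
  stopifnot_network(net)
  d <- integer(length(net$nodes))
  names(d) <- net$nodes
  t <- table(net$edges$tail)
  d[names(t)] <- as.integer(t)
  d
}

#' @rdname out_degree
#' @export
in_degree <- function(net) {
  stopifnot_network(net)
  d <- integer(length(net$nodes))
  names(d) <- net$nodes
  t <- table(net$edges$head)
  d[names(t)] <- as.integer(t)
  d
}

#' @rdname out_degree
#' @export
total_degree <- function(net) in_degree(net) + out_degree(net)

#' Convert to / from igraph
#'
#' Used for GraphML serialization and for cross-checking against igraph's
#' graph algorithms; the package's own algorithms operate on the
#' `pathway_network` representation directly.
#'
#' @param net a `pathway_network`.
#' @return an `igraph` directed graph with edge attributes `weight`,
#'   `provenance` and `subtype`.
#' @export
as_igraph <- function(net) {
  stopifnot_network(net)
  if (n_edges(net) == 0) {
    g <- igraph::make_empty_graph(n = 0, directed = TRUE)
    g <- igraph::add_vertices(g, length(net$nodes), name = net$nodes)
    return(g)
  }
  igraph::graph_from_data_frame(
    d = data.frame(from = net$edges$tail, to = net$edges$head,
                   weight = net$edges$weight,
                   provenance = net$edges$provenance,
                   subtype = ifelse(is.na(net$edges$subtype), "",
                                    net$edges$subtype),
                   stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(name = net$nodes, stringsAsFactors = FALSE))
}

from_igraph <- function(g, name = "") {
  vn <- igraph::vertex_attr(g, "name")
  if (is.null(vn)) vn <- as.character(seq_len(igraph::vcount(g)))
  if (igraph::ecount(g) == 0) {
    return(pathway_network(NULL, nodes = vn, name = name))
  }
  el <- igraph::as_edgelist(g, names = TRUE)
  w <- igraph::edge_attr(g, "weight") %||% rep(1, nrow(el))
  prov <- igraph::edge_attr(g, "provenance") %||% rep("pathway", nrow(el))
  st <- igraph::edge_attr(g, "subtype") %||% rep(NA_character_, nrow(el))
  st[!is.na(st) & st == ""] <- NA_character_
  pathway_network(data.frame(tail = el[, 1], head = el[, 2], weight = w,
                             provenance = prov, subtype = st,
                             stringsAsFactors = FALSE),
                  nodes = vn, name = name)
}

#' Summary statistics of a network against a gene universe
#'
#' Reports node/edge counts and, when a reference universe (the full gene
#' list of the disease pathway, connected or not) is supplied, the count
#' and fraction of universe genes that are connected (degree >= 1). For a
#' sparse initial pathway like the Alzheimer's map this fraction is the
#' "31 of 171 (18\%) connected" style figure.
#'
#' @param net a `pathway_network`.
#' @param universe optional character vector of gene ids; must be a
#'   superset of the network's nodes.
#' @return list with `node_count`, `edge_count`, `connected_nodes`, and
#'   (when `universe` is given) `universe_size` and `connected_fraction`.
#' @export
subgraph_stats <- function(net, universe = NULL) {
  stopifnot_network(net)
  connected <- sum(total_degree(net) >= 1)
  out <- list(node_count = n_nodes(net), edge_count = n_edges(net),
              connected_nodes = connected)
  if (!is.null(universe) && length(universe)) {
    universe <- unique(trimws(as.character(universe)))
    extra <- setdiff(net$nodes, universe)
    if (length(extra)) {
      stop("universe is not a superset of network nodes; missing: ",
           paste(utils::head(extra, 5), collapse = ", "))
    }
    out$universe_size <- length(universe)
    out$connected_fraction <- connected / length(universe)
  }
  out
}
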