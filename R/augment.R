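#' Augment a pathway network with directed PPI edges
#'
#' Initial disease-pathway networks parsed from KEGG maps are typically
#' too sparse for s-t min-cut to be informative. Augmentation adds every
#' directed PPI edge whose tail AND head both belong to the pathway's gene
#' universe (the full disease gene list, connected or not); genes newly
#' touched by such an edge become network nodes. Initial edges are never
#' removed or reweighted, and a PPI edge duplicating an initial edge is
#' kept once with provenance `"pathway"`.
#'
#' By default PPI edges between already-connected genes are added too
#' (`strict = FALSE`); `strict = TRUE` restricts additions to edges that
#' touch at least one gene that is isolated in the initial network.
#'
#' The returned statistics report both percentage conventions, because
#' "increased to X\%" figures are ambiguous: `*_pct_of_initial` is
#' augmented/initial x 100 and `*_added_pct` is (augmented - initial) /
#' initial x 100. Node counts are counts of connected (degree >= 1) genes.
#'
#' @param initial [pathway_network] from the disease pathway.
#' @param ppi [pathway_network] of directed PPI edges (provenance `"ppi"`).
#' @param universe character vector: the disease pathway's full gene list.
#' @param strict only add PPI edges touching an initially-isolated gene.
#' @return list with `network` (the augmented [pathway_network]) and
#'   `stats` (one-row data.frame: `initial_nodes`, `initial_edges`,
#'   `augmented_nodes`, `augmented_edges`, `node_pct_of_initial`,
#'   `edge_pct_of_initial`, `node_added_pct`, `edge_added_pct`).
#' @export
augment <- function(initial, ppi, universe, strict = FALSE) {
  stopifnot_network(initial)
  stopifnot_network(ppi)
  universe <- unique(trimws(as.character(universe)))
  universe <- universe[universe != ""]
  if (!length(universe)) stop("empty gene universe")

  init_connected <- sum(total_degree(initial) >= 1)
  init_edges <- n_edges(initial)

  if (n_edges(ppi) == 0) {
    warning("empty PPI network: returning the initial network unchanged")
    stats <- augmentation_stats(init_connected, init_edges,
                                init_connected, init_edges)
    return(list(network = initial, stats = stats))
  }

  cand <- ppi$edges[ppi$edges$tail %in% universe &
                    ppi$edges$head %in% universe, , drop = FALSE]
  if (strict && nrow(cand)) {
    isolated <- setdiff(universe, names(which(total_degree(initial) >= 1)))
    cand <- cand[cand$tail %in% isolated | cand$head %in% isolated, ,
                 drop = FALSE]
  }
  if (nrow(cand) == 0) {
    warning("no PPI edge falls inside the gene universe; ",
            "check that pathway and PPI share one identifier namespace")
  }
  cand$provenance <- rep("ppi", nrow(cand))
  aug <- pathway_network(rbind(initial$edges, cand),
                         nodes = initial$nodes, name = initial$name)

  stats <- augmentation_stats(init_connected, init_edges,
                              sum(total_degree(aug) >= 1), n_edges(aug))
  list(network = aug, stats = stats)
}

augmentation_stats <- function(n0, e0, n1, e1) {
  pct <- function(a, b) if (!is.na(b) && b > 0) a / b * 100 else NA_real_
  data.frame(initial_nodes = n0, initial_edges = e0,
             augmented_nodes = n1, augmented_edges = e1,
             node_pct_of_initial = pct(n1, n0),
             edge_pct_of_initial = pct(e1, e0),
             node_added_pct = pct(n1 - n0, n0),
             edge_added_pct = pct(e1 - e0, e0))
}

#' Augment a batch of pathways against one PPI network
#'
#' Runs [augment()] for each pathway and appends an arithmetic-mean
#' summary row over the percentage columns. Per-pathway failures are
#' recorded (`ok = FALSE`, NA statistics) and remaining pathways continue.
#'
#' @param pathways named list; each element a list with components
#'   `network` (a [pathway_network]) and `universe` (character vector).
#' @param ppi [pathway_network] of directed PPI edges.
#' @param strict passed to [augment()].
#' @return data.frame with one row per pathway plus a `"mean"` row;
#'   columns `pathway`, `ok`, and the [augment()] stats columns. The
#'   augmented networks are attached as attribute `"networks"`.
#' @export
batch_augment <- function(pathways, ppi, strict = FALSE) {
  if (!length(pathways)) stop("need at least one pathway")
  ids <- names(pathways) %||% as.character(seq_along(pathways))
  nets <- vector("list", length(pathways))
  names(nets) <- ids
  rows <- lapply(seq_along(pathways), function(i) {
    p <- pathways[[i]]
    res <- tryCatch(augment(p$network, ppi, p$universe, strict = strict),
                    error = function(e) e)
    if (inherits(res, "error")) {
      warning("pathway ", ids[i], " failed: ", conditionMessage(res))
      cbind(data.frame(pathway = ids[i], ok = FALSE),
            augmentation_stats(NA_real_, NA_real_, NA_real_, NA_real_))
    } else {
      nets[[i]] <<- res$network
      cbind(data.frame(pathway = ids[i], ok = TRUE), res$stats)
    }
  })
  tab <- do.call(rbind, rows)
  pc <- c("node_pct_of_initial", "edge_pct_of_initial",
          "node_added_pct", "edge_added_pct")
  mean_row <- tab[1, , drop = FALSE]
  mean_row$pathway <- "mean"
  mean_row$ok <- all(tab$ok)
  for (col in setdiff(names(tab), c("pathway", "ok"))) {
    mean_row[[col]] <- if (col %in% pc) mean(tab[[col]][tab$ok]) else NA_real_
  }
  out <- rbind(tab, mean_row)
  rownames(out) <- NULL
  attr(out, "networks") <- nets
  out
}
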