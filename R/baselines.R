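new_centrality_ranking <- function(method, scores, k) {
  ord <- order(-scores, names(scores), method = "radix")
  top_k <- names(scores)[ord][seq_len(min(k, length(scores)))]
  structure(list(method = method, scores = scores, top_k = top_k,
                 k = as.integer(k)),
            class = "centrality_ranking")
}

#' @export
print.centrality_ranking <- function(x, ...) {
  cat(x$method, " centrality, top ", length(x$top_k), ": ",
      paste(x$top_k, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Degree centrality baselines
#'
#' Directed degree centrality (DC) scores a gene by its number of
#' outgoing links; the undirected variant (U_DC) counts incoming and
#' outgoing links. Ties in the top-k ranking are broken by ascending
#' gene id.
#'
#' @param net a non-empty [pathway_network].
#' @param undirected if `TRUE` compute U_DC, else DC.
#' @param k size of the top-k selection (capped at the node count).
#' @return a `centrality_ranking` with fields `method`, `scores`,
#'   `top_k`, `k`.
#' @export
degree_centrality <- function(net, undirected = FALSE, k = 6) {
  stopifnot_network(net)
  if (n_nodes(net) == 0) stop("empty network")
  scores <- if (undirected) total_degree(net) else out_degree(net)
  new_centrality_ranking(if (undirected) "U_DC" else "DC",
                         stats::setNames(as.numeric(scores), names(scores)), k)
}

#' HITS hub centrality
#'
#' Hub scores of the hyperlink-induced topic search scheme: the dominant
#' eigenvector direction of A %*% t(A) (equivalently the left singular
#' vectors of the adjacency matrix A), computed by power iteration from a
#' deterministic uniform start and L1-normalized so scores sum to 1.
#'
#' @param net a non-empty [pathway_network] with at least one edge (a
#'   network with no edges yields all-zero scores with a warning).
#' @param k size of the top-k selection.
#' @param tol convergence threshold on the maximum absolute score change
#'   between successive iterations.
#' @param max_iter iteration cap; non-convergence returns the best
#'   iterate with a warning.
#' @return a `centrality_ranking`.
#' @export
hub_centrality <- function(net, k = 6, tol = 1e-10, max_iter = 1000) {
  stopifnot_network(net)
  n <- n_nodes(net)
  if (n == 0) stop("empty network")
  if (n_edges(net) == 0) {
    warning("network has no edges; all hub scores are zero")
    return(new_centrality_ranking("HC", stats::setNames(numeric(n), net$nodes), k))
  }
  idx <- stats::setNames(seq_len(n), net$nodes)
  A <- matrix(0, n, n)
  A[cbind(idx[net$edges$tail], idx[net$edges$head])] <- 1
  h <- rep(1 / n, n)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    a <- crossprod(A, h)          # authority update
    h_new <- as.numeric(A %*% a)  # hub update: A A^T h
    s <- sum(h_new)
    if (s == 0) break
    h_new <- h_new / s
    if (max(abs(h_new - h)) < tol) {
      h <- h_new
      converged <- TRUE
      break
    }
    h <- h_new
  }
  if (!converged) {
    warning("hub centrality did not converge in ", max_iter,
            " iterations; returning the last iterate")
  }
  new_centrality_ranking("HC", stats::setNames(h, net$nodes), k)
}

#' Edge disruption caused by removing a node set
#'
#' The fraction of all network edges incident to (touching) at least one
#' of the given nodes — the damage a centrality-guided intervention at
#' those genes inflicts on the network's connections.
#'
#' @param net a [pathway_network].
#' @param nodes character vector of gene ids, a subset of the network's nodes.
#' @return data.frame row: `method`, `affected_edges`, `total_edges`, `ratio`.
#' @export
node_removal_disruption <- function(net, nodes, method = "node_removal") {
  stopifnot_network(net)
  assert_genes_present(net, nodes, "node")
  affected <- sum(net$edges$tail %in% nodes | net$edges$head %in% nodes)
  disruption_row(method, affected, n_edges(net))
}

#' @param method label for the output row.
#' @rdname node_removal_disruption
#' @export
cut_disruption <- function(net, result, method = "Min-cut") {
  stopifnot_network(net)
  if (!inherits(result, "cut_result")) stop("not a cut_result")
  disruption_row(method, nrow(result$cut_edges), n_edges(net))
}

disruption_row <- function(method, affected, total) {
  data.frame(method = method, affected_edges = as.integer(affected),
             total_edges = as.integer(total),
             ratio = if (total > 0) affected / total else NA_real_,
             stringsAsFactors = FALSE)
}

#' Compare min-cut against centrality baselines on one disease
#'
#' The performance measure is the cut-edge ratio: the fraction of all
#' edges a method disrupts (lower is better, since a good multi-target
#' intervention blocks disease progression with minimal collateral edge
#' damage). The min-cut row reports the smallest ratio over the disease's
#' (source, sink) pairs; each centrality row reports the incident-edge
#' ratio of its top-k gene set, with sources and sinks excluded from
#' selection.
#'
#' @param net the disease's (augmented) [pathway_network].
#' @param spec the disease's [source_sink_spec].
#' @param k number of top-centrality genes to select (required; the
#'   benchmark uses 6 for simulated networks, 7 for the Alzheimer map).
#' @return data.frame with rows Min-cut, U_DC, DC, HC and columns
#'   `method`, `affected_edges`, `total_edges`, `ratio`.
#' @export
compare_methods <- function(net, spec, k) {
  stopifnot_network(net)
  if (!inherits(spec, "source_sink_spec")) stop("not a source_sink_spec")
  if (missing(k) || k < 1) stop("k must be >= 1")

  pairs <- enumerate_pairs(spec)
  best <- NULL
  for (i in seq_len(nrow(pairs))) {
    res <- st_min_cut(net, pairs$source[i], pairs$sink[i])
    row <- cut_disruption(net, res)
    if (is.null(best) || row$ratio < best$ratio) best <- row
  }

  excl <- c(spec$sources, spec$sinks)
  top_excl <- function(ranking) {
    keep <- setdiff(names(ranking$scores), excl)
    sc <- ranking$scores[keep]
    names(sc)[order(-sc, names(sc), method = "radix")][seq_len(min(k, length(sc)))]
  }
  rows <- rbind(
    best,
    node_removal_disruption(net, top_excl(degree_centrality(net, TRUE, k)), "U_DC"),
    node_removal_disruption(net, top_excl(degree_centrality(net, FALSE, k)), "DC"),
    node_removal_disruption(net, top_excl(hub_centrality(net, k)), "HC"))
  rownames(rows) <- NULL
  rows
}
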