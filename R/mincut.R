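#' Maximum s-t flow by shortest augmenting paths
#'
#' Edmonds-Karp: repeatedly push flow along a breadth-first-shortest
#' augmenting path in the residual graph until none remains. Edge weights
#' are the capacities; on the unit-weight networks used for pathway
#' analysis all arithmetic is exact integer arithmetic. Also returns the
#' set of nodes reachable from `s` in the final residual graph, which
#' identifies the canonical source-minimal minimum cut by max-flow/min-cut
#' duality.
#'
#' @param net a [pathway_network].
#' @param s,t source and sink gene ids; must be distinct nodes of `net`.
#' @return list with `value` (the max-flow value) and `reachable`
#'   (character vector of residual-reachable node ids, always containing
#'   `s` and never `t`).
#' @export
st_max_flow <- function(net, s, t) {
  stopifnot_network(net)
  s <- trimws(s); t <- trimws(t)
  if (identical(s, t)) stop("source and sink must differ")
  assert_genes_present(net, c(s, t), "source/sink gene")

  n <- length(net$nodes)
  idx <- stats::setNames(seq_len(n), net$nodes)
  si <- idx[[s]]; ti <- idx[[t]]
  # dense residual-capacity matrix; pathway-scale networks are small
  R <- matrix(0, n, n)
  ei <- cbind(idx[net$edges$tail], idx[net$edges$head])
  R[ei] <- R[ei] + net$edges$weight

  value <- 0
  repeat {
    parent <- bfs_parent(R, si, ti)
    if (is.na(parent[ti])) break
    # bottleneck along the s->t path
    path <- integer(0)
    v <- ti
    while (v != si) {
      path <- c(parent[v], path)
      v <- parent[v]
    }
    vs <- c(path, ti)
    bott <- min(R[cbind(vs[-length(vs)], vs[-1])])
    for (k in seq_len(length(vs) - 1)) {
      u <- vs[k]; w <- vs[k + 1]
      R[u, w] <- R[u, w] - bott
      R[w, u] <- R[w, u] + bott
    }
    value <- value + bott
  }
  reach <- residual_reachable(R, si)
  list(value = value, reachable = net$nodes[reach])
}

# BFS over positive residual capacities; returns parent vector (NA = unreached)
bfs_parent <- function(R, si, ti) {
  n <- nrow(R)
  parent <- rep(NA_integer_, n)
  seen <- logical(n)
  seen[si] <- TRUE
  queue <- si
  while (length(queue)) {
    u <- queue[1]; queue <- queue[-1]
    nb <- which(R[u, ] > 0 & !seen)
    if (length(nb)) {
      parent[nb] <- u
      seen[nb] <- TRUE
      if (seen[ti]) return(parent)
      queue <- c(queue, nb)
    }
  }
  parent
}

residual_reachable <- function(R, si) {
  n <- nrow(R)
  seen <- logical(n)
  seen[si] <- TRUE
  queue <- si
  while (length(queue)) {
    u <- queue[1]; queue <- queue[-1]
    nb <- which(R[u, ] > 0 & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  which(seen)
}

new_cut_result <- function(source, sink, capacity, cut_edges, source_side,
                           connected) {
  cut_edges <- cut_edges[order(cut_edges$tail, cut_edges$head,
                               method = "radix"), , drop = FALSE]
  rownames(cut_edges) <- NULL
  structure(list(source = source, sink = sink, capacity = capacity,
                 cut_edges = cut_edges,
                 source_side = sort(source_side, method = "radix"),
                 connected = connected),
            class = "cut_result")
}

#' @export
print.cut_result <- function(x, ...) {
  cat("s-t min cut: ", x$source, " -> ", x$sink,
      "  capacity=", format(x$capacity), "  edges=", nrow(x$cut_edges),
      if (!x$connected) "  (source and sink not connected)", "\n", sep = "")
  if (nrow(x$cut_edges)) {
    cat(paste0("  ", x$cut_edges$tail, " -> ", x$cut_edges$head,
               " (w=", format(x$cut_edges$weight), ")", collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Minimum s-t cut of a directed gene network
#'
#' Computes the exact minimum-capacity set of edges whose removal leaves
#' no directed path from `s` to `t`, minimizing the cut capacity
#' c(S,T) = sum of the weights of edges crossing from the source side S to
#' the sink side T. The cut reported is the canonical source-minimal one:
#' S = nodes reachable from `s` in the final residual graph of
#' [st_max_flow()], which is unique, making results reproducible even when
#' several minimum cuts exist. Capacity equals the max-flow value by
#' duality (asserted). When no s-to-t path exists the cut is empty,
#' capacity 0, and `connected` is `FALSE`.
#'
#' @inheritParams st_max_flow
#' @return a `cut_result`: `source`, `sink`, `capacity`, `cut_edges`
#'   (data.frame sorted by tail then head), `source_side` (gene ids) and
#'   `connected`.
#' @export
st_min_cut <- function(net, s, t) {
  mf <- st_max_flow(net, s, t)
  side <- mf$reachable
  in_side <- net$edges$tail %in% side & !(net$edges$head %in% side)
  cut <- net$edges[in_side, c("tail", "head", "weight"), drop = FALSE]
  cap <- sum(cut$weight)
  if (abs(cap - mf$value) > 1e-9) {
    stop("internal error: cut capacity ", cap, " != max-flow value ", mf$value)
  }
  if (mf$value == 0) {
    return(new_cut_result(trimws(s), trimws(t), 0, cut[0, , drop = FALSE],
                          side, connected = FALSE))
  }
  new_cut_result(trimws(s), trimws(t), cap, cut, side, connected = TRUE)
}

#' Brute-force minimum s-t cut (test oracle)
#'
#' Enumerates every bipartition of the vertices with `s` on the source
#' side and `t` on the sink side, computes the crossing capacity, and
#' returns the minimum. Exponential in the node count, so guarded to
#' networks of at most 16 nodes; intended as an independent oracle for
#' [st_min_cut()]. Ties are broken by smallest source side, then
#' lexicographically by source-side membership.
#'
#' @inheritParams st_max_flow
#' @return a `cut_result` (note: the reported `source_side` is the
#'   tie-broken enumerated partition, which need not equal the canonical
#'   residual-reachability side of [st_min_cut()]; capacities always agree).
#' @export
brute_force_min_cut <- function(net, s, t) {
  stopifnot_network(net)
  s <- trimws(s); t <- trimws(t)
  if (identical(s, t)) stop("source and sink must differ")
  assert_genes_present(net, c(s, t), "source/sink gene")
  if (n_nodes(net) > 16) {
    stop("brute_force_min_cut is limited to networks with <= 16 nodes")
  }
  rest <- setdiff(net$nodes, c(s, t))
  k <- length(rest)
  # integer-indexed membership so the 2^k scan stays cheap
  node_pos <- stats::setNames(seq_len(k + 2L), c(s, t, rest))
  tail_i <- node_pos[net$edges$tail]
  head_i <- node_pos[net$edges$head]
  bits <- bitwShiftL(1L, seq_len(k) - 1L)
  best_cap <- Inf
  best_side <- NULL
  in_side <- logical(k + 2L)
  in_side[1L] <- TRUE  # s always on the source side, t never
  for (mask in 0:(2^k - 1)) {
    if (k > 0L) in_side[3:(k + 2L)] <- bitwAnd(mask, bits) != 0L
    cap <- sum(net$edges$weight[in_side[tail_i] & !in_side[head_i]])
    if (cap < best_cap - 1e-12) {
      best_cap <- cap; best_side <- c(s, rest[in_side[-(1:2)]])
    } else if (abs(cap - best_cap) <= 1e-12 && !is.null(best_side)) {
      side <- c(s, rest[in_side[-(1:2)]])
      if (length(side) < length(best_side) ||
          (length(side) == length(best_side) &&
           paste(sort(side), collapse = ",") <
           paste(sort(best_side), collapse = ","))) {
        best_side <- side
      }
    }
  }
  cross <- net$edges$tail %in% best_side & !(net$edges$head %in% best_side)
  cut <- net$edges[cross, c("tail", "head", "weight"), drop = FALSE]
  new_cut_result(s, t, best_cap, cut, best_side, connected = best_cap > 0)
}

#' Verify that a cut disconnects its source from its sink
#'
#' Pure check: breadth-first search from the cut's source in `net` with
#' the cut edges removed must not reach the sink.
#'
#' @param net the [pathway_network] the cut was computed on.
#' @param result a `cut_result`.
#' @return `TRUE` iff no directed source-to-sink path survives.
#' @export
verify_cut <- function(net, result) {
  stopifnot_network(net)
  if (!inherits(result, "cut_result")) stop("not a cut_result")
  key <- paste(net$edges$tail, net$edges$head, sep = "\r")
  cutkey <- paste(result$cut_edges$tail, result$cut_edges$head, sep = "\r")
  edges <- net$edges[!(key %in% cutkey), , drop = FALSE]
  !(result$sink %in% reachable_from(net$nodes, edges, result$source))
}

reachable_from <- function(nodes, edges, s) {
  seen <- s
  frontier <- s
  while (length(frontier)) {
    nb <- unique(edges$head[edges$tail %in% frontier])
    frontier <- setdiff(nb, seen)
    seen <- c(seen, frontier)
  }
  seen
}
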