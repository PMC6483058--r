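#' Read a directed edge list
#'
#' Tab/whitespace-separated rows `tail head [weight]`; lines starting with
#' `#` are comments. The SIF dialect (`tail relation head`) is accepted via
#' `dialect = "sif"`, recording the relation as the edge subtype.
#' Duplicate (tail, head) rows are merged keeping the maximum weight;
#' self-loop rows are dropped with a warning. The result is independent of
#' row order.
#'
#' @param path file path.
#' @param provenance `"pathway"` or `"ppi"` tag applied to every edge.
#' @param dialect `"tsv"` (default) or `"sif"`.
#' @param name network name (defaults to the file name).
#' @return a [pathway_network].
#' @export
read_edge_list <- function(path, provenance = c("pathway", "ppi"),
                           dialect = c("tsv", "sif"), name = NULL) {
  provenance <- match.arg(provenance)
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (!length(idx)) {
    return(pathway_network(NULL, name = name %||% basename(path)))
  }
  parts <- strsplit(trimws(lines[idx]), "[\t ]+")
  nfield <- lengths(parts)
  lo <- if (dialect == "sif") 3L else 2L
  hi <- 3L
  bad <- nfield < lo | nfield > hi
  if (any(bad)) {
    stop("malformed row at line ", idx[which(bad)[1]], " of ", path,
         " (expected ", lo, "-", hi, " columns, got ", nfield[which(bad)[1]], ")")
  }
  if (dialect == "sif") {
    tail <- vapply(parts, `[`, "", 1L)
    subtype <- vapply(parts, `[`, "", 2L)
    head <- vapply(parts, `[`, "", 3L)
    weight <- rep(1, length(parts))
  } else {
    tail <- vapply(parts, `[`, "", 1L)
    head <- vapply(parts, `[`, "", 2L)
    wchr <- vapply(parts, function(p) if (length(p) >= 3) p[3] else "1", "")
    weight <- suppressWarnings(as.numeric(wchr))
    if (anyNA(weight)) {
      stop("non-numeric weight at line ", idx[which(is.na(weight))[1]], " of ", path)
    }
    if (any(weight < 0)) {
      stop("negative weight at line ", idx[which(weight < 0)[1]], " of ", path)
    }
    subtype <- rep(NA_character_, length(parts))
  }
  pathway_network(data.frame(tail = tail, head = head, weight = weight,
                             provenance = provenance, subtype = subtype,
                             stringsAsFactors = FALSE),
                  name = name %||% basename(path))
}

#' Write a network as a tab-separated edge list
#'
#' Columns `tail<TAB>head<TAB>weight`; inverse of [read_edge_list()] on
#' the node/edge/weight content (provenance and subtype are not part of
#' the edge-list format).
#'
#' @param net a [pathway_network].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  stopifnot_network(net)
  con <- file(path, open = "wb")  # "wb": byte-identical output across platforms
  on.exit(close(con))
  writeLines(c("#tail\thead\tweight",
               sprintf("%s\t%s\t%s", net$edges$tail, net$edges$head,
                       format(net$edges$weight, trim = TRUE, scientific = FALSE))),
             con)
  invisible(path)
}

#' Read a KGML (KEGG pathway XML) file
#'
#' Gene-type `entry` elements become nodes (a multi-gene entry is expanded
#' to one node per gene id, with any relation duplicated to each);
#' `relation` elements become directed edges tail = entry1, head = entry2
#' with provenance `"pathway"` and the first subtype name recorded.
#' Group, compound and map entries are skipped (with counts reported via
#' message), and relations touching them are dropped rather than collapsed
#' into indirect gene-gene links.
#'
#' @param path KGML file path.
#' @param relation_types optional character vector of relation `type`
#'   attributes to keep (e.g. `"PPrel"`, `"GErel"`); default keeps all.
#' @return a [pathway_network].
#' @export
read_kgml <- function(path, relation_types = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("KGML parse failure in ", path, ": ",
                                           conditionMessage(e)))
  entries <- xml2::xml_find_all(doc, ".//entry")
  etype <- xml2::xml_attr(entries, "type")
  eid <- xml2::xml_attr(entries, "id")
  ename <- xml2::xml_attr(entries, "name")
  is_gene <- !is.na(etype) & etype == "gene"
  skipped <- table(etype[!is_gene])
  if (length(skipped)) {
    message("read_kgml: skipped non-gene entries: ",
            paste(names(skipped), skipped, sep = "=", collapse = ", "))
  }
  # entry id -> character vector of gene ids (multi-gene entries expand)
  genes_of <- stats::setNames(
    lapply(ename[is_gene], function(nm) trimws(strsplit(trimws(nm), "\\s+")[[1]])),
    eid[is_gene])
  known_ids <- eid

  rels <- xml2::xml_find_all(doc, ".//relation")
  edges <- NULL
  if (length(rels)) {
    e1 <- xml2::xml_attr(rels, "entry1")
    e2 <- xml2::xml_attr(rels, "entry2")
    rtype <- xml2::xml_attr(rels, "type")
    unknown <- !(e1 %in% known_ids) | !(e2 %in% known_ids)
    if (any(unknown)) {
      i <- which(unknown)[1]
      stop("relation references unknown entry id (entry1=", e1[i],
           ", entry2=", e2[i], ") in ", path)
    }
    sub <- vapply(rels, function(r) {
      s <- xml2::xml_find_first(r, "./subtype")
      if (inherits(s, "xml_missing")) NA_character_ else xml2::xml_attr(s, "name")
    }, "")
    keep <- e1 %in% names(genes_of) & e2 %in% names(genes_of)
    if (!is.null(relation_types)) keep <- keep & rtype %in% relation_types
    if (any(keep)) {
      edges <- do.call(rbind, lapply(which(keep), function(i) {
        expand.grid(tail = genes_of[[e1[i]]], head = genes_of[[e2[i]]],
                    stringsAsFactors = FALSE)
      }))
      edges$weight <- 1
      edges$provenance <- "pathway"
      edges$subtype <- rep(sub[keep],
                           vapply(which(keep), function(i)
                             length(genes_of[[e1[i]]]) * length(genes_of[[e2[i]]]),
                             1L))
    }
  }
  pname <- xml2::xml_attr(xml2::xml_root(doc), "name")
  pathway_network(edges, nodes = unlist(genes_of, use.names = FALSE),
                  name = if (is.na(pname)) basename(path) else pname)
}

#' GraphML serialization
#'
#' Writes/reads GraphML with directed edges and edge attributes `weight`
#' (double), `provenance` and `subtype` (strings); round-trips a network
#' losslessly. Serialization is delegated to igraph.
#'
#' @param net a [pathway_network].
#' @param path file path.
#' @return `write_graphml` returns `path` invisibly; `read_graphml`
#'   returns a [pathway_network].
#' @export
write_graphml <- function(net, path) {
  stopifnot_network(net)
  igraph::write_graph(as_igraph(net), path, format = "graphml")
  invisible(path)
}

#' @rdname write_graphml
#' @param name network name for the re-read object.
#' @export
read_graphml <- function(path, name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  from_igraph(igraph::read_graph(path, format = "graphml"),
              name = name %||% basename(path))
}
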