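#' Source/sink specification for one disease
#'
#' A disease run is defined by its onset (source) genes S and apoptotic
#' (sink) genes T; every (source, sink) pair is fed to the min cut
#' separately. Sources and sinks must be non-empty and disjoint.
#'
#' @param disease_id disease identifier string.
#' @param sources,sinks character vectors of gene ids (order preserved).
#' @return an object of class `source_sink_spec`.
#' @export
source_sink_spec <- function(disease_id, sources, sinks) {
  disease_id <- trimws(as.character(disease_id)[1])
  sources <- trimws(as.character(sources))
  sinks <- trimws(as.character(sinks))
  sources <- sources[sources != ""]
  sinks <- sinks[sinks != ""]
  if (!nzchar(disease_id)) stop("empty disease_id")
  if (!length(sources) || !length(sinks)) {
    stop(disease_id, ": sources and sinks must be non-empty")
  }
  if (anyDuplicated(sources) || anyDuplicated(sinks)) {
    stop(disease_id, ": duplicated gene in sources or sinks")
  }
  both <- intersect(sources, sinks)
  if (length(both)) {
    stop(disease_id, ": sources and sinks must be disjoint (",
         paste(both, collapse = ", "), ")")
  }
  structure(list(disease_id = disease_id, sources = sources, sinks = sinks),
            class = "source_sink_spec")
}

#' @export
print.source_sink_spec <- function(x, ...) {
  cat("disease ", x$disease_id, ": ", length(x$sources), " source(s) x ",
      length(x$sinks), " sink(s) = ", length(x$sources) * length(x$sinks),
      " pair(s)\n", sep = "")
  invisible(x)
}

#' Read per-disease source/sink specifications
#'
#' TSV format: header `disease_id<TAB>sources<TAB>sinks`, gene lists
#' semicolon-separated; `#` comment lines allowed. YAML format: a list of
#' records with fields `disease_id`, `sources`, `sinks`.
#'
#' @param path file path (`.yaml`/`.yml` parsed as YAML, anything else as TSV).
#' @return list of [source_sink_spec] objects, one per disease.
#' @export
read_source_sink_specs <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    recs <- yaml::read_yaml(path)
    specs <- lapply(recs, function(r)
      source_sink_spec(r$disease_id, unlist(r$sources), unlist(r$sinks)))
  } else {
    tab <- utils::read.delim(path, comment.char = "#",
                             stringsAsFactors = FALSE)
    need <- c("disease_id", "sources", "sinks")
    if (!all(need %in% names(tab))) {
      stop(path, ": expected columns ", paste(need, collapse = ", "))
    }
    specs <- lapply(seq_len(nrow(tab)), function(i)
      source_sink_spec(tab$disease_id[i],
                       strsplit(tab$sources[i], ";")[[1]],
                       strsplit(tab$sinks[i], ";")[[1]]))
  }
  ids <- vapply(specs, `[[`, "", "disease_id")
  if (anyDuplicated(ids)) {
    stop("duplicate disease ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  stats::setNames(specs, ids)
}

#' Enumerate (source, sink) pairs of a disease
#'
#' Cartesian product of sources and sinks in their listed order; each pair
#' is one min-cut run, so the row count is the disease's number of
#' (source, sink) combinations.
#'
#' @param spec a [source_sink_spec].
#' @return data.frame with columns `source`, `sink`; nrow = |S| x |T|.
#' @export
enumerate_pairs <- function(spec) {
  if (!inherits(spec, "source_sink_spec")) stop("not a source_sink_spec")
  out <- expand.grid(sink = spec$sinks, source = spec$sources,
                     stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  out <- out[, c("source", "sink")]
  rownames(out) <- NULL
  out
}

#' Extract candidate target genes from a cut
#'
#' The genes at the end points of the cut edges are the candidate target
#' genes (CTGs): the union of tails and heads of the cut edges, minus
#' every gene listed as a source or sink of the disease. A disconnected
#' pair (empty cut) yields no CTGs.
#'
#' @param result a `cut_result` from [st_min_cut()].
#' @param spec the disease's [source_sink_spec].
#' @return sorted character vector of gene ids.
#' @export
extract_ctgs <- function(result, spec) {
  if (!inherits(result, "cut_result")) stop("not a cut_result")
  if (!inherits(spec, "source_sink_spec")) stop("not a source_sink_spec")
  if (!result$connected) return(character())
  genes <- unique(c(result$cut_edges$tail, result$cut_edges$head))
  sort(setdiff(genes, c(spec$sources, spec$sinks)), method = "radix")
}

#' Run the min-cut CTG pipeline for one disease
#'
#' For every (source, sink) pair of the disease: compute the minimum cut
#' on the augmented network, verify that it disconnects the pair, extract
#' CTGs, and tally per-gene occurrence counts. Occurrence proportions use
#' the total number of attempted pairs as denominator (e.g. a gene seen in
#' 2 of 6 runs scores 33.3%). A source or sink gene absent from the
#' network makes its pairs count as attempted-but-disconnected runs, with
#' a warning, rather than aborting the disease.
#'
#' @param net the disease's augmented [pathway_network].
#' @param spec the disease's [source_sink_spec].
#' @return a `ctg_report`: `disease_id`, `n_runs`, `n_connected_runs`,
#'   `occurrences` (named integer vector, descending count then gene id),
#'   `proportions` (occurrences / n_runs x 100), `results` (list of
#'   `cut_result`, NULL for unresolved pairs).
#' @export
run_disease <- function(net, spec) {
  stopifnot_network(net)
  if (!inherits(spec, "source_sink_spec")) stop("not a source_sink_spec")
  missing <- setdiff(c(spec$sources, spec$sinks), net$nodes)
  if (length(missing)) {
    warning(spec$disease_id, ": gene(s) not in network, their pairs count ",
            "as disconnected runs: ", paste(missing, collapse = ", "))
  }
  pairs <- enumerate_pairs(spec)
  n_runs <- nrow(pairs)
  occ <- integer(0)
  n_connected <- 0L
  results <- vector("list", n_runs)
  for (i in seq_len(n_runs)) {
    s <- pairs$source[i]; t <- pairs$sink[i]
    if (s %in% missing || t %in% missing) next
    res <- st_min_cut(net, s, t)
    if (!verify_cut(net, res)) {
      stop(spec$disease_id, ": cut for (", s, ", ", t,
           ") failed the disconnection check")  # defensive; never expected
    }
    results[[i]] <- res
    if (res$connected) {
      n_connected <- n_connected + 1L
      for (g in extract_ctgs(res, spec)) {
        occ[g] <- (if (g %in% names(occ)) occ[[g]] else 0L) + 1L
      }
    }
  }
  if (length(occ)) occ <- occ[order(-occ, names(occ), method = "radix")]
  structure(list(disease_id = spec$disease_id, n_runs = n_runs,
                 n_connected_runs = n_connected,
                 occurrences = occ,
                 proportions = occ / n_runs * 100,
                 results = results),
            class = "ctg_report")
}

#' @export
print.ctg_report <- function(x, ...) {
  cat("CTG report for ", x$disease_id, ": ", x$n_connected_runs, "/",
      x$n_runs, " (source, sink) pairs connected\n", sep = "")
  if (length(x$occurrences)) {
    cat(sprintf("  %-12s %3d/%d  (%s%%)\n", names(x$occurrences),
                x$occurrences, x$n_runs,
                sprintf("%.1f", x$proportions)), sep = "")
  } else {
    cat("  no CTGs identified\n")
  }
  invisible(x)
}

#' Run the CTG pipeline across diseases
#'
#' One [run_disease()] per specification, against its matching network. A
#' spec without a network is recorded as a failure row and the remaining
#' diseases continue. The combined table lists one row per (disease, CTG)
#' sorted by disease, then descending proportion, then gene id, with
#' proportions formatted to one decimal.
#'
#' @param networks named list of augmented [pathway_network]s, names =
#'   disease ids.
#' @param specs list of [source_sink_spec]s (unique disease ids).
#' @return list with `reports` (named list of `ctg_report`), `table`
#'   (combined data.frame: disease, gene, occurrences, n_runs,
#'   proportion_pct) and `failures` (character vector of disease ids with
#'   no network).
#' @export
run_all <- function(networks, specs) {
  ids <- vapply(specs, `[[`, "", "disease_id")
  if (anyDuplicated(ids)) {
    stop("duplicate disease ids: ", paste(unique(ids[duplicated(ids)]),
                                          collapse = ", "))
  }
  reports <- list()
  failures <- character()
  rows <- list()
  for (spec in specs) {
    id <- spec$disease_id
    if (is.null(networks[[id]])) {
      warning("no network for disease ", id, "; skipped")
      failures <- c(failures, id)
      next
    }
    rep <- run_disease(networks[[id]], spec)
    reports[[id]] <- rep
    if (length(rep$occurrences)) {
      rows[[id]] <- data.frame(disease = id, gene = names(rep$occurrences),
                               occurrences = as.integer(rep$occurrences),
                               n_runs = rep$n_runs,
                               proportion_pct = sprintf("%.1f", rep$proportions),
                               stringsAsFactors = FALSE)
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(disease = character(), gene = character(),
               occurrences = integer(), n_runs = integer(),
               proportion_pct = character(), stringsAsFactors = FALSE)
  tab <- tab[order(tab$disease, -tab$occurrences, tab$gene,
                   method = "radix"), , drop = FALSE]
  rownames(tab) <- NULL
  list(reports = reports, table = tab, failures = failures)
}

#' Write the combined CTG table as TSV
#'
#' Fixed column order, sort order and one-decimal proportion formatting,
#' so identical inputs produce byte-identical files.
#'
#' @param result value of [run_all()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_ctg_table <- function(result, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  tab <- result$table
  writeLines(c(paste(names(tab), collapse = "\t"),
               if (nrow(tab)) do.call(paste, c(unname(tab), sep = "\t"))),
             con)
  invisible(path)
}

#' Serialize one disease's cut results as JSON
#'
#' @param report a `ctg_report`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_ctg_report_json <- function(report, path) {
  if (!inherits(report, "ctg_report")) stop("not a ctg_report")
  runs <- lapply(report$results, function(r) {
    if (is.null(r)) return(list(resolved = FALSE))
    list(resolved = TRUE, source = r$source, sink = r$sink,
         capacity = r$capacity, connected = r$connected,
         cut_edges = r$cut_edges[, c("tail", "head", "weight")],
         source_side = r$source_side)
  })
  obj <- list(disease_id = report$disease_id, n_runs = report$n_runs,
              n_connected_runs = report$n_connected_runs,
              occurrences = as.list(report$occurrences),
              proportions_pct = as.list(round(report$proportions, 1)),
              runs = runs)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
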