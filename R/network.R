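# Drug co-occurrence network over case reports (polypharmacy patterns).

#' Build the drug co-occurrence graph
#'
#' Nodes are normalized drugs reported on case reports (all roles by
#' default, since co-medication rather than suspicion drives
#' co-occurrence); the weight of edge (u, v) is the number of case reports
#' listing both u and v, counted once per pair per report. Edges below
#' `min_weight` are pruned; self-loops cannot arise.
#'
#' @param store deduplicated `faers_store`
#' @param case_ids PRIMARYIDs of the case reports (e.g.
#'   `extract_cases(...)$case_ids`)
#' @param roles drug roles included (default all of PS, SS, C, I)
#' @param min_weight minimum co-report count for an edge (default 3)
#' @param normalizer a [drug_normalizer()]
#' @return object of class `cooccurrence_graph`: `graph` (igraph),
#'   `edges` (drug_u, drug_v, weight), `nodes` (drug, n_reports),
#'   `min_weight`
#' @export
build_cooccurrence <- function(store, case_ids,
                               roles = c("PS", "SS", "C", "I"),
                               min_weight = 3,
                               normalizer = drug_normalizer()) {
  drug <- store$tables$drug
  sel <- drug$primaryid %in% case_ids & drug$role_cod %in% roles
  pairs <- unique(data.frame(
    primaryid = drug$primaryid[sel],
    drug = as.character(normalize_drug(drug$drugname[sel], normalizer)),
    stringsAsFactors = FALSE))
  nodes <- as.data.frame(table(pairs$drug), stringsAsFactors = FALSE)
  names(nodes) <- c("drug", "n_reports")

  by_report <- split(pairs$drug, pairs$primaryid)
  edge_keys <- unlist(lapply(by_report, function(ds) {
    if (length(ds) < 2) return(character(0))
    ds <- sort(ds)
    cmb <- utils::combn(ds, 2)
    paste(cmb[1, ], cmb[2, ], sep = "\r")
  }), use.names = FALSE)
  if (length(edge_keys)) {
    tab <- table(edge_keys)
    parts <- strsplit(names(tab), "\r", fixed = TRUE)
    edges <- data.frame(
      drug_u = vapply(parts, `[`, "", 1),
      drug_v = vapply(parts, `[`, "", 2),
      weight = as.integer(tab), stringsAsFactors = FALSE)
    edges <- edges[edges$weight >= min_weight, , drop = FALSE]
    edges <- edges[order(-edges$weight, edges$drug_u), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(drug_u = character(0), drug_v = character(0),
                        weight = integer(0), stringsAsFactors = FALSE)
  }
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = nodes[nodes$drug %in% c(edges$drug_u, edges$drug_v), ,
                     drop = FALSE])
  structure(list(graph = g, edges = edges, nodes = nodes,
                 min_weight = min_weight),
            class = "cooccurrence_graph")
}

#' @export
print.cooccurrence_graph <- function(x, ...) {
  cat(sprintf("Drug co-occurrence network: %d node(s), %d edge(s) at weight >= %d\n",
              igraph::vcount(x$graph), nrow(x$edges), x$min_weight))
  if (nrow(x$edges))
    print.data.frame(utils::head(x$edges, 5), row.names = FALSE)
  invisible(x)
}

#' Export a co-occurrence graph
#'
#' Writes the edge list as TSV and, optionally, the graph as GraphML.
#'
#' @param graph a `cooccurrence_graph`
#' @param edge_tsv path for the edge-list TSV
#' @param graphml optional path for a GraphML export
#' @return invisibly, the paths written
#' @export
export_cooccurrence <- function(graph, edge_tsv, graphml = NULL) {
  utils::write.table(graph$edges, edge_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(graphml))
    igraph::write_graph(graph$graph, graphml, format = "graphml")
  invisible(c(edge_tsv, graphml))
}
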