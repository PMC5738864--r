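# canonicalize an edge table: from < to lexicographically, self-loops
# dropped, duplicates collapsed (first occurrence's weight kept),
# deterministic row order
canonicalEdges <- function(edges) {
  if (nrow(edges) == 0)
    return(data.frame(from = character(), to = character(),
                      weight = numeric(), method = character(),
                      stringsAsFactors = FALSE))
  a <- pmin(edges$from, edges$to)
  b <- pmax(edges$from, edges$to)
  keep <- a != b
  out <- data.frame(from = a[keep], to = b[keep],
                    weight = if ("weight" %in% names(edges))
                      edges$weight[keep] else NA_real_,
                    method = if ("method" %in% names(edges))
                      edges$method[keep] else NA_character_,
                    stringsAsFactors = FALSE)
  out <- out[!duplicated(paste(out$from, out$to)), , drop = FALSE]
  out <- out[order(out$from, out$to), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a gene network from an edge table
#'
#' Edges are canonicalized (undirected, no self-loops, duplicates
#' collapsed, deterministic order); nodes are the engaged genes unless
#' \code{nodeIds} supplies the universe explicitly.
#'
#' @param edges data.frame with columns from, to and optionally weight,
#'   method.
#' @param nodeIds optional node universe (must cover all endpoints).
#' @param annotation optional [readAnnotation()] table.
#' @param method method tag.
#' @param provenance list of producing parameters.
#' @return a [GeneNetwork-class].
#' @export
makeGeneNetwork <- function(edges, nodeIds = NULL, annotation = NULL,
                            method = "glasso", provenance = list()) {
  ed <- canonicalEdges(edges)
  if (nrow(ed)) ed$method <- method
  ids <- if (is.null(nodeIds)) sort(unique(c(ed$from, ed$to)))
         else sort(unique(nodeIds))
  nodes <- data.frame(
    probe_id = ids,
    accession = if (!is.null(annotation) && nrow(annotation))
      ifelse(is.na(match(ids, annotation$probe_id)), "",
             annotation$accession[match(ids, annotation$probe_id)])
    else rep("", length(ids)),
    symbol = annotationSymbols(annotation, ids),
    stringsAsFactors = FALSE, row.names = NULL)
  new("GeneNetwork", nodes = nodes, edges = ed, method = method,
      provenance = provenance)
}

#' Read a doubly-listed pair table
#'
#' The published network tables list each undirected link twice (once per
#' direction) with four tab-separated columns: probe id and accession of
#' the first gene, probe id and accession of the second. This reads such
#' a table and returns the directed rows as-is.
#'
#' @param path TSV file with 4 columns and no header.
#' @return data.frame(from, to, from_accession, to_accession).
#' @export
readPairTable <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("from", "from_accession",
                                         "to", "to_accession"))
  tab[, c("from", "to", "from_accession", "to_accession")]
}

#' Collapse a doubly-listed pair table to undirected links
#'
#' @param pairs data.frame with columns from and to (e.g. from
#'   [readPairTable()]); a table of 2L directed rows collapses to L
#'   undirected links.
#' @return data.frame(from, to) with from < to, unique, sorted.
#' @export
collapsePairs <- function(pairs) {
  canonicalEdges(data.frame(from = pairs$from, to = pairs$to,
                            stringsAsFactors = FALSE))[, c("from", "to")]
}

#' Fan-out ("richness") filter
#'
#' Prunes a network to its well-connected core in a single pass on the
#' input degrees (degrees are never recomputed after removal). Two
#' published phrasings of the criterion coexist:
#' \describe{
#'   \item{\code{"reachable"} (default)}{keep gene v iff degree(v) > 1,
#'     \emph{or} v has at least one neighbour u with degree(u) > 1.}
#'   \item{\code{"strict"}}{keep gene v iff degree(v) > 1 \emph{and} v has
#'     at least one neighbour u with degree(u) > 1 — the reading that
#'     reproduces the published 14-gene (glasso) and 7-gene (Pearson)
#'     supraoptic nucleus networks from their printed edge lists.}
#' }
#' Edges are kept when both endpoints survive; nodes left isolated are
#' dropped.
#'
#' @param net a [GeneNetwork-class].
#' @param mode "reachable" or "strict".
#' @return the filtered [GeneNetwork-class].
#' @export
richnessFilter <- function(net, mode = c("reachable", "strict")) {
  mode <- match.arg(mode)
  stopifnot(is(net, "GeneNetwork"))
  ed <- net@edges
  ids <- net@nodes$probe_id
  deg <- stats::setNames(rep(0L, length(ids)), ids)
  if (nrow(ed)) {
    tab <- table(c(ed$from, ed$to))
    deg[names(tab)] <- as.integer(tab)
  }
  richNeighbor <- stats::setNames(rep(FALSE, length(ids)), ids)
  if (nrow(ed)) {
    fromRich <- deg[ed$from] > 1
    toRich <- deg[ed$to] > 1
    richNeighbor[unique(c(ed$to[fromRich], ed$from[toRich]))] <- TRUE
  }
  keep <- if (mode == "reachable") deg > 1 | richNeighbor
          else deg > 1 & richNeighbor
  kept <- ids[keep]
  ed2 <- ed[ed$from %in% kept & ed$to %in% kept, , drop = FALSE]
  engaged <- unique(c(ed2$from, ed2$to))
  nodes <- net@nodes[net@nodes$probe_id %in% engaged, , drop = FALSE]
  rownames(nodes) <- NULL
  rownames(ed2) <- NULL
  new("GeneNetwork", nodes = nodes, edges = ed2, method = net@method,
      provenance = c(net@provenance, list(richness_filter = mode)))
}

#' Intersect the node sets of two networks
#'
#' Node-set intersection keyed on probe id (symbols collide and are never
#' used as keys); edges are not required to match. Commutative and
#' idempotent.
#'
#' @param a,b [GeneNetwork-class] objects on the same probe-id namespace.
#' @return sorted character vector of shared probe ids.
#' @export
intersectNodes <- function(a, b) {
  stopifnot(is(a, "GeneNetwork"), is(b, "GeneNetwork"))
  sort(intersect(a@nodes$probe_id, b@nodes$probe_id))
}

#' Rank network genes by degree
#'
#' Nodes sorted by decreasing degree, ties broken by probe id; the top
#' node is the nominated hub.
#'
#' @param net a [GeneNetwork-class].
#' @return data.frame(probe_id, symbol, degree, rank); zero rows for an
#'   empty network.
#' @export
hubRank <- function(net) {
  stopifnot(is(net, "GeneNetwork"))
  ids <- net@nodes$probe_id
  if (length(ids) == 0)
    return(data.frame(probe_id = character(), symbol = character(),
                      degree = integer(), rank = integer(),
                      stringsAsFactors = FALSE))
  deg <- stats::setNames(rep(0L, length(ids)), ids)
  if (nrow(net@edges)) {
    tab <- table(c(net@edges$from, net@edges$to))
    deg[names(tab)] <- as.integer(tab)
  }
  ord <- order(-deg, ids)
  data.frame(probe_id = ids[ord], symbol = net@nodes$symbol[ord],
             degree = as.integer(deg[ord]),
             rank = seq_along(ids), stringsAsFactors = FALSE,
             row.names = NULL)
}

networkToIgraph <- function(net) {
  g <- igraph::graph_from_data_frame(
    net@edges[, c("from", "to", "weight", "method")],
    directed = FALSE, vertices = net@nodes)
  g
}

#' Export a network to TSV or GraphML
#'
#' TSV: one row per undirected link with columns probe_a, probe_b, weight,
#' method, deterministically ordered. GraphML: via igraph, with symbol and
#' accession vertex attributes and weight/method edge attributes.
#'
#' @param net a [GeneNetwork-class].
#' @param path output file.
#' @param format "tsv" or "graphml".
#' @return \code{path}, invisibly.
#' @export
exportNetwork <- function(net, path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  stopifnot(is(net, "GeneNetwork"))
  if (format == "tsv") {
    ed <- net@edges
    out <- data.frame(probe_a = ed$from, probe_b = ed$to,
                      weight = ed$weight, method = ed$method,
                      stringsAsFactors = FALSE)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    igraph::write_graph(networkToIgraph(net), path, format = "graphml")
  }
  invisible(path)
}

#' Read a network back from TSV or GraphML
#'
#' Inverse of [exportNetwork()].
#'
#' @param path file written by [exportNetwork()].
#' @param format "tsv" or "graphml".
#' @param method method tag for the reconstructed network (TSV carries it
#'   per edge; used when the file has no edges).
#' @return a [GeneNetwork-class].
#' @export
readNetwork <- function(path, format = c("tsv", "graphml"),
                        method = "glasso") {
  format <- match.arg(format)
  if (format == "tsv") {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (nrow(tab)) method <- tab$method[1]
    makeGeneNetwork(
      data.frame(from = tab$probe_a, to = tab$probe_b,
                 weight = tab$weight, stringsAsFactors = FALSE),
      method = method)
  } else {
    g <- igraph::read_graph(path, format = "graphml")
    vat <- igraph::vertex_attr(g)
    nodes <- data.frame(probe_id = vat$name,
                        accession = if (!is.null(vat$accession))
                          vat$accession else "",
                        symbol = if (!is.null(vat$symbol)) vat$symbol
                          else "EST",
                        stringsAsFactors = FALSE)
    ed <- igraph::as_data_frame(g, what = "edges")
    if (nrow(ed)) method <- ed$method[1]
    edges <- canonicalEdges(
      data.frame(from = ed$from, to = ed$to,
                 weight = if (nrow(ed)) ed$weight else numeric(),
                 method = if (nrow(ed)) ed$method else character(),
                 stringsAsFactors = FALSE))
    nodes <- nodes[order(nodes$probe_id), , drop = FALSE]
    rownames(nodes) <- NULL
    new("GeneNetwork", nodes = nodes, edges = edges, method = method,
        provenance = list(source = "graphml"))
  }
}

#' Published supraoptic nucleus reference networks
#'
#' Reconstructs the two networks published for the plastic supraoptic
#' nucleus transcriptome from the edge and annotation tables bundled with
#' the package: the graphical-lasso network (28 genes, 48 links, from the
#' doubly-listed 96-row pair table) and the Pearson network (47 genes, 32
#' links, from the 64-row table).
#'
#' @param method "glasso" or "pearson".
#' @return a [GeneNetwork-class].
#' @examples
#' net <- sonReferenceNetwork("glasso")
#' head(hubRank(net))
#' @export
sonReferenceNetwork <- function(method = c("glasso", "pearson")) {
  method <- match.arg(method)
  pairsPath <- system.file("extdata",
                           paste0(method, "_pairs.tsv"),
                           package = "plasticnet")
  genesPath <- system.file("extdata",
                           paste0(method, "_genes.tsv"),
                           package = "plasticnet")
  pairs <- readPairTable(pairsPath)
  ann <- readAnnotation(genesPath)
  edges <- collapsePairs(pairs)
  edges$weight <- NA_real_
  makeGeneNetwork(edges, annotation = ann, method = method,
                  provenance = list(source = paste0(method, "_pairs.tsv")))
}

#' Write a hub report as JSON
#' @param ranking output of [hubRank()].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeHubReport <- function(ranking, path) {
  jsonlite::write_json(ranking, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
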