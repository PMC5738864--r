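#' Construct a PlasticExpression object from a matrix
#'
#' @param values numeric genes x samples matrix with unique row (gene) and
#'   column (sample) names.
#' @param groups per-sample labels, "naive" or "plastic"; either unnamed in
#'   column order or named by sample id.
#' @param scale data-scale tag: "raw", "normalized" or "log2".
#' @return a validated [PlasticExpression-class].
#' @export
PlasticExpression <- function(values, groups,
                              scale = c("raw", "normalized", "log2")) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  if (!is.null(names(groups))) {
    miss <- setdiff(colnames(values), names(groups))
    if (length(miss))
      stop("no group label for sample(s): ", paste(miss, collapse = ", "))
    groups <- groups[colnames(values)]
  }
  se <- SummarizedExperiment(
    assays = list(exprs = values),
    colData = DataFrame(group = as.character(groups),
                        row.names = colnames(values)),
    metadata = list(scale = scale))
  new("PlasticExpression", se)
}

#' Read an expression matrix from TSV
#'
#' Expects genes in rows with the gene identifier in the first column and a
#' header row of sample identifiers. Duplicated gene or sample ids, missing
#' values and samples without a group label are rejected with the offending
#' identifier named.
#'
#' @param path TSV file.
#' @param groupMap named character vector (sample id -> "naive"/"plastic"),
#'   or a 2-column data.frame / TSV path readable by [readGroups()].
#' @param scale data-scale tag recorded in the object.
#' @return a [PlasticExpression-class].
#' @export
readExpression <- function(path, groupMap,
                           scale = c("raw", "normalized", "log2")) {
  scale <- match.arg(scale)
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("expression file needs a gene column and samples")
  ids <- as.character(tab[[1]])
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicated gene id(s): ", paste(unique(dup), collapse = ", "))
  sids <- colnames(tab)[-1]
  dup <- sids[duplicated(sids)]
  if (length(dup))
    stop("duplicated sample id(s): ", paste(unique(dup), collapse = ", "))
  x <- as.matrix(tab[, -1, drop = FALSE])
  if (anyNA(x)) {
    bad <- ids[rowSums(is.na(x)) > 0]
    stop("missing values in gene(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  mode(x) <- "numeric"
  rownames(x) <- ids
  if (is.character(groupMap) && length(groupMap) == 1 &&
      is.null(names(groupMap)) && file.exists(groupMap))
    groupMap <- readGroups(groupMap)
  if (is.data.frame(groupMap))
    groupMap <- stats::setNames(as.character(groupMap[[2]]),
                                as.character(groupMap[[1]]))
  PlasticExpression(x, groups = groupMap, scale = scale)
}

#' Write an expression matrix as TSV
#'
#' Inverse of [readExpression()]: first column \code{gene_id}, then one
#' column per sample.
#'
#' @param expr a [PlasticExpression-class].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeExpression <- function(expr, path) {
  stopifnot(is(expr, "PlasticExpression"))
  x <- assay(expr, "exprs")
  out <- data.frame(gene_id = rownames(x), x, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a 2-column sample-group table
#'
#' @param path TSV with columns sample id and group ("naive"/"plastic");
#'   a header line is detected and skipped.
#' @return named character vector sample id -> group.
#' @export
readGroups <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (nrow(tab) && !tab[1, 2] %in% GROUP_LEVELS) tab <- tab[-1, , drop = FALSE]
  stats::setNames(as.character(tab[[2]]), as.character(tab[[1]]))
}

#' Read a probe annotation table
#'
#' Three tab-separated columns: array probe id, GenBank accession, gene
#' symbol (no header). Empty or missing symbols become "EST", the
#' convention used for unannotated expressed sequence tags. Probe ids must
#' be unique; gene symbols may collide (e.g. two Hba1 probes), which is why
#' the whole pipeline keys genes on probe ids and treats symbols as
#' display-only.
#'
#' @param path TSV file; an empty file gives an empty table.
#' @return data.frame(probe_id, accession, symbol).
#' @export
readAnnotation <- function(path) {
  empty <- data.frame(probe_id = character(), accession = character(),
                      symbol = character(), stringsAsFactors = FALSE)
  if (!file.exists(path)) stop("no such annotation file: ", path)
  if (file.size(path) == 0) return(empty)
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           quote = "", fill = TRUE,
                           col.names = c("probe_id", "accession", "symbol"))
  if (nrow(tab) == 0) return(empty)
  dup <- tab$probe_id[duplicated(tab$probe_id)]
  if (length(dup))
    stop("duplicated probe id(s) in annotation: ",
         paste(unique(dup), collapse = ", "))
  tab$symbol[is.na(tab$symbol) | tab$symbol == ""] <- "EST"
  tab$accession[is.na(tab$accession)] <- ""
  tab
}

#' Look up gene symbols by probe id
#'
#' Probes absent from the table map to "EST" (the graceful fallback for
#' unannotated probes), so lookups against an empty table still return.
#'
#' @param annotation a table from [readAnnotation()] (or NULL).
#' @param probes character vector of probe ids.
#' @return character vector of symbols, same length/order as \code{probes}.
#' @export
annotationSymbols <- function(annotation, probes) {
  if (is.null(annotation) || nrow(annotation) == 0)
    return(rep("EST", length(probes)))
  i <- match(probes, annotation$probe_id)
  out <- annotation$symbol[i]
  out[is.na(out)] <- "EST"
  out
}

#' Log-transform an expression matrix
#'
#' Applies \code{log2(max(value, 1))} and retags the scale as "log2". The
#' floor at 1 keeps background-level raw intensities from exploding to
#' large negative logs.
#'
#' @param expr a [PlasticExpression-class].
#' @return the transformed [PlasticExpression-class].
#' @export
logTransform <- function(expr) {
  stopifnot(is(expr, "PlasticExpression"))
  x <- log2(pmax(assay(expr, "exprs"), 1))
  PlasticExpression(x, groups = sampleGroups(expr), scale = "log2")
}
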