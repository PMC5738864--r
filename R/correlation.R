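#' Pairwise Pearson correlation matrix over a gene subset
#'
#' Pearson r across all pooled samples (both groups), matching the
#' covariance convention. Zero-variance genes are flagged: their rows and
#' columns are set to NA and they never contribute edges.
#'
#' @param expr a [PlasticExpression-class] with >= 3 samples.
#' @param genes probe ids to include (default: all).
#' @return a [CorrelationMatrix-class].
#' @export
pearsonMatrix <- function(expr, genes = NULL) {
  stopifnot(is(expr, "PlasticExpression"))
  if (ncol(expr) < 3) stop("need at least 3 samples for correlations")
  if (is.null(genes)) genes <- rownames(expr)
  miss <- setdiff(genes, rownames(expr))
  if (length(miss))
    stop("gene(s) not found: ", paste(utils::head(miss, 5), collapse = ", "))
  x <- assay(expr, "exprs")[genes, , drop = FALSE]
  sds <- apply(x, 1, stats::sd)
  flagged <- genes[sds == 0]
  r <- suppressWarnings(stats::cor(t(x)))
  r <- (r + t(r)) / 2
  out <- which(!is.na(r) & abs(r) > 1)   # clamp floating-point overshoot
  r[out] <- sign(r[out])
  if (length(flagged)) {
    i <- match(flagged, genes)
    r[i, ] <- NA
    r[, i] <- NA
  }
  diag(r)[!(genes %in% flagged)] <- 1
  new("CorrelationMatrix", r = unname(r), geneIds = genes,
      flagged = flagged, nSamples = ncol(expr))
}

#' Threshold a correlation matrix into a co-expression network
#'
#' An undirected edge is created wherever \code{r_ij > cutoff}, strictly,
#' on the signed correlation by default (the published network counted
#' only positive correlations over the cutoff); set
#' \code{absolute = TRUE} to threshold |r| instead. Flagged (zero
#' variance) genes are excluded. Optionally each edge can additionally be
#' required to pass a two-sided correlation t test at \code{alpha}.
#'
#' @param cm a [CorrelationMatrix-class].
#' @param cutoff correlation cutoff (default 0.95).
#' @param annotation optional [readAnnotation()] table.
#' @param absolute threshold |r| instead of signed r.
#' @param pTest if TRUE, also require the per-edge correlation test
#'   p value (df = n - 2) to be below \code{alpha}.
#' @param alpha significance level for \code{pTest}.
#' @return a [GeneNetwork-class] with method tag "pearson".
#' @export
correlationEdges <- function(cm, cutoff = 0.95, annotation = NULL,
                             absolute = FALSE, pTest = FALSE,
                             alpha = 0.05) {
  stopifnot(is(cm, "CorrelationMatrix"))
  r <- cm@r
  ids <- cm@geneIds
  val <- if (absolute) abs(r) else r
  sel <- upper.tri(r) & !is.na(val) & val > cutoff
  if (pTest) {
    df <- cm@nSamples - 2
    tstat <- abs(r) * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
    pmatrix <- 2 * stats::pt(-tstat, df)
    pmatrix[abs(r) >= 1] <- 0
    sel <- sel & pmatrix < alpha
  }
  idx <- which(sel, arr.ind = TRUE)
  edges <- data.frame(from = ids[idx[, 1]], to = ids[idx[, 2]],
                      weight = r[idx],
                      method = rep("pearson", nrow(idx)),
                      stringsAsFactors = FALSE)
  makeGeneNetwork(edges, annotation = annotation, method = "pearson",
                  provenance = list(cutoff = cutoff, absolute = absolute,
                                    p_test = pTest))
}
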