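#' Gene identifiers of an object
#' @param x a plasticnet object.
#' @return character vector of probe ids in the object's row/node order.
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @describeIn geneIds row names of the expression matrix.
#' @export
setMethod("geneIds", "PlasticExpression", function(x) rownames(x))

#' @describeIn geneIds genes of the covariance model.
#' @export
setMethod("geneIds", "CovarianceModel", function(x) x@geneIds)

#' @describeIn geneIds genes of the precision estimate.
#' @export
setMethod("geneIds", "PrecisionEstimate", function(x) x@geneIds)

#' @describeIn geneIds genes of the correlation matrix.
#' @export
setMethod("geneIds", "CorrelationMatrix", function(x) x@geneIds)

#' @describeIn geneIds node probe ids of a network.
#' @export
setMethod("geneIds", "GeneNetwork", function(x) x@nodes$probe_id)

#' Per-sample group labels
#' @param x a [PlasticExpression-class] object.
#' @return character vector, "naive" or "plastic" per sample.
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))

#' @describeIn sampleGroups group labels from colData.
#' @export
setMethod("sampleGroups", "PlasticExpression",
          function(x) as.character(colData(x)$group))

#' Data-scale tag
#' @param x a [PlasticExpression-class] or [CovarianceModel-class] object.
#' @return "raw", "normalized" or "log2".
#' @export
setGeneric("scaleTag", function(x) standardGeneric("scaleTag"))

#' @describeIn scaleTag scale tag carried in the metadata.
#' @export
setMethod("scaleTag", "PlasticExpression", function(x) metadata(x)$scale)

#' @describeIn scaleTag scale tag inherited from the expression matrix.
#' @export
setMethod("scaleTag", "CovarianceModel", function(x) x@scale)

#' Estimated precision matrix
#' @param x a [PrecisionEstimate-class].
#' @return the symmetric matrix Gamma with gene ids as dimnames.
#' @export
setGeneric("precisionMatrix", function(x) standardGeneric("precisionMatrix"))

#' @export
#' @describeIn precisionMatrix the estimate.
setMethod("precisionMatrix", "PrecisionEstimate", function(x) {
  g <- x@gamma
  dimnames(g) <- list(x@geneIds, x@geneIds)
  g
})

#' Network nodes
#' @param x a [GeneNetwork-class].
#' @return data.frame(probe_id, accession, symbol).
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))

#' @export
#' @describeIn networkNodes the annotated node table.
setMethod("networkNodes", "GeneNetwork", function(x) x@nodes)

#' Network edges
#' @param x a [GeneNetwork-class].
#' @return data.frame(from, to, weight, method), one row per undirected
#'   link, \code{from < to}.
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @export
#' @describeIn networkEdges the undirected edge table.
setMethod("networkEdges", "GeneNetwork", function(x) x@edges)

setMethod("show", "PlasticExpression", function(object) {
  grp <- table(factor(sampleGroups(object), GROUP_LEVELS))
  cat(sprintf(
    "PlasticExpression: %d genes x %d samples (%d naive, %d plastic), scale=%s\n",
    nrow(object), ncol(object), grp[["naive"]], grp[["plastic"]],
    scaleTag(object)))
})

setMethod("show", "SyntheticSpec", function(object) {
  cat(sprintf(paste0(
    "SyntheticSpec: %d genes, %d naive + %d plastic samples\n",
    "  regulated fraction %.4g, effect size %.3g, noise sd %.3g, base scale %.3g\n",
    "  planted adjacency over %d genes (%d edges), partial-corr strength %.3g, seed %d\n"),
    object@nGenes, object@nNaive, object@nPlastic,
    object@regulatedFraction, object@effectSize, object@noiseSd,
    object@baseScale, nrow(object@plantedAdjacency),
    sum(object@plantedAdjacency) / 2, object@partialCorrStrength,
    object@seed))
})

setMethod("show", "CovarianceModel", function(object) {
  cat(sprintf("CovarianceModel: %d x %d, n=%d samples, scale=%s\n",
              nrow(object@S), ncol(object@S), object@nSamples, object@scale))
})

setMethod("show", "PrecisionEstimate", function(object) {
  p <- nrow(object@gamma)
  nz <- sum(abs(object@gamma[upper.tri(object@gamma)]) > 0)
  cat(sprintf(paste0(
    "PrecisionEstimate: %d x %d, rho=%.4g (diag penalty: %s)\n",
    "  %d non-zero off-diagonal pairs, objective %.6g, %d sweeps, converged: %s\n"),
    p, p, object@rho, object@penalizeDiagonal, nz, object@objective,
    object@nIter, object@converged))
})

setMethod("show", "CorrelationMatrix", function(object) {
  cat(sprintf("CorrelationMatrix: %d genes, n=%d samples, %d flagged\n",
              nrow(object@r), object@nSamples, length(object@flagged)))
})

setMethod("show", "GeneNetwork", function(object) {
  cat(sprintf("GeneNetwork (%s): %d genes engaged in %d links\n",
              object@method, nrow(object@nodes), nrow(object@edges)))
})

setMethod("show", "NullThresholdRecord", function(object) {
  cat(sprintf(paste0(
    "NullThresholdRecord: %d runs (mode=%s, seed=%d)\n",
    "  per-run min p in [%.3g, %.3g]; threshold %.3g\n"),
    object@nRuns, object@mode, object@seed,
    min(object@perRunMinP), max(object@perRunMinP), object@threshold))
})

setMethod("show", "ConditionReport", function(object) {
  cat(sprintf(
    "ConditionReport (%s): kappa_1 = %.3g (~%.1f digits lost)%s\n",
    object@matrixTag, object@kappa, object@digitsLost,
    if (object@singular) " [numerically singular]" else ""))
})

setMethod("show", "PipelineConfig", function(object) {
  src <- if (!is.null(object@syntheticSpec)) "synthetic" else
    object@expressionPath
  cat(sprintf(paste0(
    "PipelineConfig: input=%s, scale=%s\n",
    "  K=%d, null runs=%d, rho=%.4g (%s), link threshold=%.4g,",
    " cor cutoff=%.3g, filter=%s, seed=%d\n"),
    src, object@scale, object@K, object@nullRuns, object@rho,
    object@rhoMode, object@linkThreshold, object@corCutoff,
    object@filterMode, object@seed))
})
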