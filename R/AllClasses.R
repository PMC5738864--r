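#' @import methods
#' @import SummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

GROUP_LEVELS <- c("naive", "plastic")
SCALE_LEVELS <- c("raw", "normalized", "log2")

#' Two-state expression matrix
#'
#' A genes x samples expression container for a naive-versus-plastic design.
#' Extends \linkS4class{SummarizedExperiment} with a single assay
#' \code{"exprs"}, a per-sample \code{group} column restricted to
#' \code{"naive"}/\code{"plastic"}, and a data-scale tag
#' (\code{"raw"}, \code{"normalized"} or \code{"log2"}) carried in the
#' object metadata so downstream provenance records which version of the
#' data was analysed.
#'
#' @slot ... see \linkS4class{SummarizedExperiment}.
#' @seealso [PlasticExpression()] the constructor, [readExpression()],
#'   [generateDataset()].
#' @export
setClass("PlasticExpression", contains = "SummarizedExperiment")

setValidity("PlasticExpression", function(object) {
  msg <- character()
  if (!("exprs" %in% assayNames(object)))
    msg <- c(msg, "assay 'exprs' is required")
  else {
    x <- assay(object, "exprs")
    if (anyNA(x)) msg <- c(msg, "expression values must not contain NA")
    if (!is.numeric(x)) msg <- c(msg, "expression values must be numeric")
  }
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "gene ids must be present and unique")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids must be present and unique")
  grp <- colData(object)$group
  if (is.null(grp) || !all(as.character(grp) %in% GROUP_LEVELS))
    msg <- c(msg, "every sample needs a group label in {naive, plastic}")
  sc <- metadata(object)$scale
  if (is.null(sc) || !(sc %in% SCALE_LEVELS))
    msg <- c(msg, "metadata()$scale must be one of raw/normalized/log2")
  if (length(msg)) msg else TRUE
})

#' Synthetic dataset specification
#'
#' Parameters of the synthetic expression generator: a two-group design
#' (defaults 9 naive vs 20 plastic arrays, the design of the supraoptic
#' nucleus study this package emulates), a fraction of genes given a
#' standardized group mean shift, and a planted sparse precision-matrix
#' structure (typically a hub star) among the leading genes.
#'
#' @slot nGenes number of genes simulated.
#' @slot nNaive,nPlastic group sizes (default 9 and 20).
#' @slot regulatedFraction fraction of genes receiving the group mean shift;
#'   regulated genes are the first \code{round(regulatedFraction * nGenes)}.
#' @slot effectSize standardized mean difference (in units of
#'   \code{noiseSd}) added to the plastic-group mean of regulated genes.
#' @slot plantedAdjacency symmetric binary adjacency over the first
#'   \code{m} genes (zero diagonal); may be a 0 x 0 matrix for no planted
#'   structure.
#' @slot partialCorrStrength magnitude of off-diagonal precision entries
#'   placed on planted edges before diagonal-dominance rescaling.
#' @slot noiseSd residual standard deviation.
#' @slot baseScale multiplicative intensity scale emulating raw-intensity
#'   variances.
#' @slot seed integer RNG seed.
#' @seealso [syntheticSpec()], [generateDataset()], [hubAdjacency()].
#' @export
setClass("SyntheticSpec",
  representation(
    nGenes = "numeric", nNaive = "numeric", nPlastic = "numeric",
    regulatedFraction = "numeric", effectSize = "numeric",
    plantedAdjacency = "matrix", partialCorrStrength = "numeric",
    noiseSd = "numeric", baseScale = "numeric", seed = "numeric"
  ),
  prototype(
    nGenes = 2000, nNaive = 9, nPlastic = 20,
    regulatedFraction = 0.025, effectSize = 2,
    plantedAdjacency = matrix(0, 0, 0), partialCorrStrength = 0.3,
    noiseSd = 1, baseScale = 100, seed = 1
  )
)

setValidity("SyntheticSpec", function(object) {
  msg <- character()
  a <- object@plantedAdjacency
  if (nrow(a) != ncol(a)) msg <- c(msg, "plantedAdjacency must be square")
  else if (nrow(a) > 0) {
    if (!isTRUE(all.equal(a, t(a))))
      msg <- c(msg, "plantedAdjacency must be symmetric")
    if (any(diag(a) != 0))
      msg <- c(msg, "plantedAdjacency must have zero diagonal")
    if (!all(a %in% c(0, 1)))
      msg <- c(msg, "plantedAdjacency must be binary")
    if (nrow(a) > object@nGenes)
      msg <- c(msg, "plantedAdjacency larger than nGenes")
  }
  if (object@nNaive + object@nPlastic < 4)
    msg <- c(msg, "need nNaive + nPlastic >= 4")
  if (object@nGenes < 1) msg <- c(msg, "nGenes must be >= 1")
  if (object@regulatedFraction < 0 || object@regulatedFraction > 1)
    msg <- c(msg, "regulatedFraction must lie in [0, 1]")
  if (object@noiseSd <= 0) msg <- c(msg, "noiseSd must be > 0")
  if (object@baseScale <= 0) msg <- c(msg, "baseScale must be > 0")
  if (object@partialCorrStrength < 0)
    msg <- c(msg, "partialCorrStrength must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Sample covariance model over a gene subset
#'
#' The symmetric sample covariance matrix S (denominator n - 1, computed on
#' pooled samples from both groups) over a selected gene subset, together
#' with the gene identifiers, sample count and the data-scale tag inherited
#' from the expression matrix.
#'
#' @slot S symmetric covariance matrix (expression units squared).
#' @slot geneIds ordered gene identifiers (rows/cols of S).
#' @slot nSamples number of arrays used.
#' @slot scale data-scale tag.
#' @seealso [sampleCovariance()], [glassoFit()].
#' @export
setClass("CovarianceModel",
  representation(S = "matrix", geneIds = "character",
                 nSamples = "numeric", scale = "character"))

setValidity("CovarianceModel", function(object) {
  msg <- character()
  S <- object@S
  if (nrow(S) != ncol(S)) msg <- c(msg, "S must be square")
  else {
    if (max(abs(S - t(S))) > 1e-8 * max(1, max(abs(S))))
      msg <- c(msg, "S must be symmetric to machine tolerance")
    if (any(diag(S) < 0)) msg <- c(msg, "diagonal of S must be >= 0")
    if (length(object@geneIds) != nrow(S))
      msg <- c(msg, "geneIds length must equal dim(S)")
  }
  if (length(msg)) msg else TRUE
})

#' Penalized precision-matrix estimate
#'
#' The graphical-lasso output: an estimated precision matrix Gamma that
#' minimizes \code{-log det(Gamma) + tr(S Gamma) + rho * ||Gamma||_1}
#' (equivalent, up to additive constants, to a Kullback-Leibler fit of
#' N(0, Gamma) to N(0, S^-1) plus an L1 penalty), with convergence
#' metadata. Non-zero off-diagonal entries are candidate network links.
#'
#' @slot gamma estimated precision matrix.
#' @slot rho L1 penalty weight (>= 0), on the covariance scale of the data.
#' @slot objective final penalized negative log-likelihood.
#' @slot objectiveTrace per-sweep objective values.
#' @slot nIter outer sweeps used.
#' @slot converged logical convergence flag.
#' @slot penalizeDiagonal whether the diagonal was penalized.
#' @slot geneIds gene identifiers.
#' @seealso [glassoFit()], [extractEdges()].
#' @export
setClass("PrecisionEstimate",
  representation(gamma = "matrix", rho = "numeric", objective = "numeric",
                 objectiveTrace = "numeric", nIter = "numeric",
                 converged = "logical", penalizeDiagonal = "logical",
                 geneIds = "character"))

setValidity("PrecisionEstimate", function(object) {
  msg <- character()
  g <- object@gamma
  if (nrow(g) != ncol(g)) msg <- c(msg, "gamma must be square")
  else if (max(abs(g - t(g))) > 1e-8 * max(1, max(abs(g))))
    msg <- c(msg, "gamma must be symmetric")
  if (object@rho < 0) msg <- c(msg, "rho must be >= 0")
  if (length(object@geneIds) != nrow(g))
    msg <- c(msg, "geneIds length must equal dim(gamma)")
  if (length(msg)) msg else TRUE
})

#' Pearson correlation matrix over a gene subset
#'
#' @slot r symmetric matrix of Pearson correlation coefficients; rows of
#'   zero-variance genes are NA and those genes are listed in
#'   \code{flagged}.
#' @slot geneIds gene identifiers.
#' @slot flagged genes with zero variance (excluded from edges).
#' @slot nSamples number of arrays used.
#' @seealso [pearsonMatrix()], [correlationEdges()].
#' @export
setClass("CorrelationMatrix",
  representation(r = "matrix", geneIds = "character",
                 flagged = "character", nSamples = "numeric"))

setValidity("CorrelationMatrix", function(object) {
  msg <- character()
  r <- object@r
  if (nrow(r) != ncol(r)) msg <- c(msg, "r must be square")
  else {
    ok <- !is.na(r)
    if (any(abs(r[ok]) > 1 + 1e-12))
      msg <- c(msg, "correlations must lie in [-1, 1]")
    if (max(abs(r - t(r)), na.rm = TRUE) > 1e-12)
      msg <- c(msg, "r must be symmetric")
    d <- diag(r)
    if (any(abs(d[!is.na(d)] - 1) > 1e-12))
      msg <- c(msg, "diagonal must be 1 (or NA for flagged genes)")
  }
  if (length(object@geneIds) != nrow(r))
    msg <- c(msg, "geneIds length must equal dim(r)")
  if (length(msg)) msg else TRUE
})

#' Undirected weighted gene network
#'
#' Genes are nodes, inferred interactions are undirected weighted edges.
#' Edges are stored canonically with \code{from < to} (lexicographic), so
#' the doubly-listed symmetric tables published for such networks collapse
#' to one row per link.
#'
#' @slot nodes data.frame with columns \code{probe_id}, \code{accession},
#'   \code{symbol}.
#' @slot edges data.frame with columns \code{from}, \code{to},
#'   \code{weight}, \code{method}.
#' @slot method method tag, \code{"glasso"} or \code{"pearson"} (or
#'   \code{"mixed"} after set operations).
#' @slot provenance list of the parameters that produced the network.
#' @seealso [extractEdges()], [correlationEdges()], [richnessFilter()],
#'   [hubRank()], [exportNetwork()].
#' @export
setClass("GeneNetwork",
  representation(nodes = "data.frame", edges = "data.frame",
                 method = "character", provenance = "list"))

setValidity("GeneNetwork", function(object) {
  msg <- character()
  nd <- object@nodes; ed <- object@edges
  if (!all(c("probe_id", "accession", "symbol") %in% names(nd)))
    msg <- c(msg, "nodes need columns probe_id, accession, symbol")
  if (!all(c("from", "to", "weight", "method") %in% names(ed)))
    msg <- c(msg, "edges need columns from, to, weight, method")
  if (length(msg) == 0) {
    if (anyDuplicated(nd$probe_id)) msg <- c(msg, "duplicate node probe_id")
    if (nrow(ed)) {
      if (any(ed$from == ed$to)) msg <- c(msg, "self-loops are not allowed")
      if (any(ed$from > ed$to))
        msg <- c(msg, "edges must be stored with from < to")
      if (anyDuplicated(paste(ed$from, ed$to)))
        msg <- c(msg, "duplicate edges are not allowed")
      if (!all(c(ed$from, ed$to) %in% nd$probe_id))
        msg <- c(msg, "every edge endpoint must be a node")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Random-matrix null threshold record
#'
#' Per-comparison minimum p values from t tests on matrices of standard
#' Gaussian deviates of the same shape as the data, and the significance
#' cutoff derived from them (the smallest per-run minimum).
#'
#' @slot nRuns number of null comparisons (default 10).
#' @slot perRunMinP the per-comparison minimum p values.
#' @slot threshold chosen cutoff, \code{min(perRunMinP)}.
#' @slot seed master RNG seed.
#' @slot mode \code{"random_split"} (random vs random, the default) or
#'   \code{"data_vs_random"}.
#' @seealso [nullThreshold()], [selectTop()].
#' @export
setClass("NullThresholdRecord",
  representation(nRuns = "numeric", perRunMinP = "numeric",
                 threshold = "numeric", seed = "numeric", mode = "character"))

setValidity("NullThresholdRecord", function(object) {
  msg <- character()
  if (length(object@perRunMinP) != object@nRuns)
    msg <- c(msg, "perRunMinP must have nRuns entries")
  if (length(object@perRunMinP) &&
      object@threshold > min(object@perRunMinP) + 1e-15)
    msg <- c(msg, "threshold must not exceed min(perRunMinP)")
  if (length(msg)) msg else TRUE
})

#' Condition-number report
#'
#' One-norm condition number kappa = ||M||_1 * ||M^-1||_1 of a matrix, with
#' the rule of thumb that kappa of order 10^k costs about k digits of
#' numerical accuracy.
#'
#' @slot matrixTag which matrix was examined.
#' @slot kappa the condition number estimate (>= 1; +Inf when singular in
#'   floating point).
#' @slot digitsLost log10(kappa).
#' @slot singular TRUE when M is singular (or numerically singular) in
#'   floating point.
#' @seealso [conditionNumber()].
#' @export
setClass("ConditionReport",
  representation(matrixTag = "character", kappa = "numeric",
                 digitsLost = "numeric", singular = "logical"))

setValidity("ConditionReport", function(object) {
  if (!is.na(object@kappa) && object@kappa < 1 - 1e-9)
    "kappa must be >= 1" else TRUE
})

#' Pipeline configuration
#'
#' Parameters of the end-to-end run. Numeric defaults are the study's:
#' top K = 500 genes, 10 null comparisons, L1 penalty rho = 30 (absolute,
#' on the covariance scale of the data), link threshold 1e-4 on precision
#' entries, Pearson cutoff 0.95.
#'
#' @seealso [pipelineConfig()], [runPipeline()].
#' @export
setClass("PipelineConfig",
  representation(
    syntheticSpec = "ANY", expressionPath = "character",
    groupPath = "character", annotationPath = "character",
    scale = "character", K = "numeric", nullRuns = "numeric",
    rho = "numeric", rhoMode = "character", linkThreshold = "numeric",
    corCutoff = "numeric", corAbsolute = "logical", filterMode = "character",
    seed = "numeric", outDir = "character"
  ),
  prototype(
    syntheticSpec = NULL, expressionPath = NA_character_,
    groupPath = NA_character_, annotationPath = NA_character_,
    scale = "raw", K = 500, nullRuns = 10, rho = 30,
    rhoMode = "absolute", linkThreshold = 1e-4, corCutoff = 0.95,
    corAbsolute = FALSE, filterMode = "reachable", seed = 1,
    outDir = NA_character_
  )
)

setValidity("PipelineConfig", function(object) {
  msg <- character()
  if (object@K < 1) msg <- c(msg, "K must be >= 1")
  if (object@nullRuns < 1) msg <- c(msg, "nullRuns must be >= 1")
  if (object@rho < 0) msg <- c(msg, "rho must be >= 0")
  if (object@linkThreshold < 0) msg <- c(msg, "linkThreshold must be >= 0")
  if (object@corCutoff < 0) msg <- c(msg, "corCutoff must be >= 0")
  if (!object@rhoMode %in% c("absolute", "relative"))
    msg <- c(msg, "rhoMode must be 'absolute' or 'relative'")
  if (!object@filterMode %in% c("reachable", "strict"))
    msg <- c(msg, "filterMode must be 'reachable' or 'strict'")
  if (!object@scale %in% SCALE_LEVELS)
    msg <- c(msg, "scale must be one of raw/normalized/log2")
  if (is.null(object@syntheticSpec) && is.na(object@expressionPath))
    msg <- c(msg, "either a synthetic spec or an expression path is required")
  if (length(msg)) msg else TRUE
})
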