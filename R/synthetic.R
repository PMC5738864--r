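#' Construct a synthetic dataset specification
#'
#' Defaults emulate the 29-array supraoptic nucleus design (9 naive vs 20
#' plastic samples) at a desk-scale gene count of 2000 with a planted
#' 10-partner hub among the regulated genes; the study's full 31042-gene
#' scale is available by raising \code{nGenes}.
#'
#' @param nGenes number of genes.
#' @param nNaive,nPlastic group sizes.
#' @param regulatedFraction fraction of genes given a group mean shift
#'   (the first \code{round(regulatedFraction * nGenes)} genes).
#' @param effectSize standardized mean difference for regulated genes.
#' @param plantedAdjacency symmetric binary adjacency over the first
#'   \code{nrow(plantedAdjacency)} genes; defaults to [hubAdjacency()]
#'   with 10 partners.
#' @param partialCorrStrength magnitude of planted off-diagonal precision
#'   entries before rescaling.
#' @param noiseSd residual standard deviation.
#' @param baseScale multiplicative intensity scale.
#' @param seed RNG seed.
#' @return a validated [SyntheticSpec-class].
#' @examples
#' spec <- syntheticSpec(nGenes = 200, seed = 7)
#' spec
#' @export
syntheticSpec <- function(nGenes = 2000, nNaive = 9, nPlastic = 20,
                          regulatedFraction = 0.025, effectSize = 2,
                          plantedAdjacency = hubAdjacency(10),
                          partialCorrStrength = 0.3, noiseSd = 1,
                          baseScale = 100, seed = 1) {
  new("SyntheticSpec", nGenes = nGenes, nNaive = nNaive,
      nPlastic = nPlastic, regulatedFraction = regulatedFraction,
      effectSize = effectSize, plantedAdjacency = plantedAdjacency,
      partialCorrStrength = partialCorrStrength, noiseSd = noiseSd,
      baseScale = baseScale, seed = seed)
}

#' Star adjacency with a designated hub
#'
#' Binary adjacency of a star graph: node 1 is the hub, linked to
#' \code{nPartners} partner nodes.
#'
#' @param nPartners hub degree.
#' @return (nPartners + 1) square 0/1 matrix with zero diagonal.
#' @export
hubAdjacency <- function(nPartners = 10) {
  m <- nPartners + 1
  a <- matrix(0, m, m)
  if (nPartners > 0) {
    a[1, 2:m] <- 1
    a[2:m, 1] <- 1
  }
  a
}

#' Planted precision matrix of a synthetic spec
#'
#' Starts from the identity, adds \code{+-partialCorrStrength} on planted
#' edges (sign alternating over the upper-triangle edge index), then
#' symmetrically rescales off-diagonals so every row's off-diagonal
#' absolute sum is at most 0.9. The result is strictly diagonally dominant,
#' hence positive definite.
#'
#' @param spec a [SyntheticSpec-class].
#' @return the m x m precision matrix over the planted gene subset
#'   (m = \code{nrow(spec@plantedAdjacency)}).
#' @export
plantedPrecision <- function(spec) {
  stopifnot(is(spec, "SyntheticSpec"))
  validObject(spec)
  a <- spec@plantedAdjacency
  m <- nrow(a)
  P <- diag(m)
  if (m > 0 && sum(a) > 0) {
    ut <- which(upper.tri(a) & a == 1, arr.ind = TRUE)
    ut <- ut[order(ut[, 1], ut[, 2]), , drop = FALSE]
    sgn <- rep_len(c(1, -1), nrow(ut))
    for (k in seq_len(nrow(ut))) {
      i <- ut[k, 1]; j <- ut[k, 2]
      P[i, j] <- P[j, i] <- sgn[k] * spec@partialCorrStrength
    }
    # symmetric row rescale: entry (i, j) shrunk by the stricter of the two
    # row factors, keeping off-diagonal row sums <= 0.9
    off <- rowSums(abs(P)) - 1
    f <- ifelse(off > 0.9, 0.9 / off, 1)
    scl <- outer(f, f, pmin)
    diag(scl) <- 1
    P <- P * scl
  }
  if (m > 0) {
    ev <- tryCatch(chol(P), error = function(e) NULL)
    if (is.null(ev))
      stop("planted precision matrix is not positive definite; reject spec")
  }
  P
}

#' Generate a synthetic two-state expression dataset
#'
#' Samples are drawn from a zero-mean multivariate Gaussian whose precision
#' matrix is the identity, except over the planted gene subset where it is
#' [plantedPrecision()]. Regulated genes receive a
#' \code{+effectSize * noiseSd} shift of the plastic-group mean, and all
#' values are multiplied by \code{baseScale}. Identical specs (including
#' seed) give identical datasets.
#'
#' @param spec a [SyntheticSpec-class].
#' @return list with elements \code{expression}
#'   (a [PlasticExpression-class], scale tag "raw") and \code{truth}
#'   (planted adjacency edge list, hub probe id, regulated probe ids,
#'   planted precision matrix).
#' @examples
#' d <- generateDataset(syntheticSpec(nGenes = 100, seed = 3))
#' d$expression
#' d$truth$hub
#' @export
generateDataset <- function(spec) {
  stopifnot(is(spec, "SyntheticSpec"))
  validObject(spec)
  P <- plantedPrecision(spec)
  m <- nrow(P)
  G <- spec@nGenes
  n <- spec@nNaive + spec@nPlastic
  ids <- sprintf("g%0*d", max(4, nchar(G)), seq_len(G))
  samp <- c(sprintf("naive_%02d", seq_len(spec@nNaive)),
            sprintf("plastic_%02d", seq_len(spec@nPlastic)))
  groups <- rep(GROUP_LEVELS, c(spec@nNaive, spec@nPlastic))

  set.seed(spec@seed)
  z <- matrix(stats::rnorm(G * n), nrow = G, ncol = n)
  if (m > 0) {
    # precision P => covariance P^-1; X = t(chol(P^-1)) %*% z has cov P^-1.
    # Equivalent and stabler: solve the Cholesky system R x = z, R = chol(P).
    R <- chol(P)
    z[seq_len(m), ] <- backsolve(R, z[seq_len(m), , drop = FALSE])
  }
  x <- spec@noiseSd * z
  nReg <- round(spec@regulatedFraction * G)
  if (nReg > 0) {
    plastic <- which(groups == "plastic")
    x[seq_len(nReg), plastic] <-
      x[seq_len(nReg), plastic] + spec@effectSize * spec@noiseSd
  }
  x <- x * spec@baseScale
  dimnames(x) <- list(ids, samp)

  expr <- PlasticExpression(x, groups = groups, scale = "raw")
  edges <- which(upper.tri(spec@plantedAdjacency) &
                   spec@plantedAdjacency == 1, arr.ind = TRUE)
  truth <- list(
    adjacency = data.frame(from = ids[edges[, 1]], to = ids[edges[, 2]],
                           stringsAsFactors = FALSE),
    hub = if (m > 0) ids[1] else NA_character_,
    regulated = ids[seq_len(nReg)],
    planted = ids[seq_len(m)],
    precision = P
  )
  list(expression = expr, truth = truth)
}

#' Write the generator truth record as JSON
#'
#' @param truth the \code{truth} element of [generateDataset()] output.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeTruth <- function(truth, path) {
  out <- list(
    adjacency = truth$adjacency,
    hub = truth$hub,
    regulated = truth$regulated,
    planted = truth$planted
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
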