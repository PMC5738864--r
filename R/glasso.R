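#' Sample covariance over a gene subset
#'
#' Column-mean-centered covariance with denominator n - 1, computed across
#' all pooled samples (both groups). Pooling is deliberate: the two-state
#' design makes co-regulated genes co-vary through the naive-to-plastic
#' transition, which is the signal the network methods feed on.
#'
#' @param expr a [PlasticExpression-class] with >= 2 samples.
#' @param genes probe ids to include (default: all), e.g. a
#'   [selectTop()] subset; order is preserved.
#' @return a [CovarianceModel-class].
#' @export
sampleCovariance <- function(expr, genes = NULL) {
  stopifnot(is(expr, "PlasticExpression"))
  if (ncol(expr) < 2) stop("need at least 2 samples for a covariance")
  if (is.null(genes)) genes <- rownames(expr)
  miss <- setdiff(genes, rownames(expr))
  if (length(miss))
    stop("gene(s) not found: ", paste(utils::head(miss, 5), collapse = ", "))
  x <- assay(expr, "exprs")[genes, , drop = FALSE]
  S <- stats::cov(t(x))
  S <- (S + t(S)) / 2
  new("CovarianceModel", S = unname(S), geneIds = genes,
      nSamples = ncol(expr), scale = scaleTag(expr))
}

softThreshold <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

# penalized negative log-likelihood; NA when gamma is not PD
glassoObjective <- function(gamma, S, rho, penalizeDiagonal) {
  R <- tryCatch(chol(gamma), error = function(e) NULL)
  if (is.null(R)) return(NA_real_)
  pen <- sum(abs(gamma))
  if (!penalizeDiagonal) pen <- pen - sum(abs(diag(gamma)))
  -2 * sum(log(diag(R))) + sum(S * gamma) + rho * pen
}

# reconstruct the precision matrix from the working covariance W and the
# lasso coefficient matrix B (standard glasso recovery; exact zeros where
# the corresponding coefficients are zero)
reconstructGamma <- function(W, B) {
  p <- nrow(W)
  gamma <- matrix(0, p, p)
  for (j in seq_len(p)) {
    b <- B[-j, j]
    gjj <- 1 / (W[j, j] - sum(W[-j, j] * b))
    gamma[j, j] <- gjj
    gamma[-j, j] <- -b * gjj
  }
  (gamma + t(gamma)) / 2
}

#' Graphical lasso: L1-penalized sparse precision-matrix estimation
#'
#' From-scratch implementation of the graphical lasso. The estimate Gamma
#' minimizes the penalized negative Gaussian log-likelihood
#' \deqn{-\log\det\Gamma + \mathrm{tr}(S\Gamma) + \rho\|\Gamma\|_1,}
#' equivalent up to additive constants to minimizing the Kullback-Leibler
#' divergence between N(0, Gamma) and N(0, S^-1) plus the L1 penalty. The
#' solver is block coordinate descent over rows/columns of the working
#' covariance estimate W: each column is an L1-regularized quadratic
#' subproblem solved by cyclic coordinate descent with soft-thresholding.
#' Convergence is declared when the mean absolute change of W per sweep
#' drops below \code{tol} times the mean absolute off-diagonal of S.
#'
#' With \code{penalizeDiagonal = TRUE} (the default, matching the
#' reference implementation) and \code{rho >=} the largest off-diagonal
#' |S|, the estimate is exactly diagonal: every lasso subproblem is fully
#' annihilated by the soft threshold.
#'
#' @param cov a [CovarianceModel-class] or a symmetric covariance matrix.
#' @param rho L1 penalty weight (absolute, on the covariance scale of the
#'   data).
#' @param tol relative convergence tolerance (default 1e-4).
#' @param maxIter maximum outer sweeps (default 100); if reached, the best
#'   iterate is returned with \code{converged = FALSE}.
#' @param penalizeDiagonal include the diagonal in the penalty.
#' @return a [PrecisionEstimate-class].
#' @examples
#' S <- matrix(c(2, 1, 1, 2), 2)
#' glassoFit(S, rho = 0)@gamma       # the exact inverse
#' @export
glassoFit <- function(cov, rho, tol = 1e-4, maxIter = 100,
                      penalizeDiagonal = TRUE) {
  if (is(cov, "CovarianceModel")) {
    S <- cov@S
    ids <- cov@geneIds
  } else {
    S <- as.matrix(cov)
    ids <- if (!is.null(rownames(S))) rownames(S) else
      sprintf("v%d", seq_len(nrow(S)))
    S <- unname(S)
  }
  p <- nrow(S)
  if (ncol(S) != p) stop("S must be square")
  if (max(abs(S - t(S))) > 1e-8 * max(1, max(abs(S))))
    stop("S must be symmetric")
  if (rho < 0) stop("rho must be >= 0")
  S <- (S + t(S)) / 2

  if (p == 1) {
    w <- S[1, 1] + if (penalizeDiagonal) rho else 0
    gamma <- matrix(1 / w, 1, 1)
    obj <- glassoObjective(gamma, S, rho, penalizeDiagonal)
    return(new("PrecisionEstimate", gamma = gamma, rho = rho,
               objective = obj, objectiveTrace = obj, nIter = 1,
               converged = TRUE, penalizeDiagonal = penalizeDiagonal,
               geneIds = ids))
  }

  W <- S
  diag(W) <- diag(S) + if (penalizeDiagonal) rho else 0
  B <- matrix(0, p, p)
  offMean <- mean(abs(S[upper.tri(S)]))
  thr <- tol * if (offMean > 0) offMean else 1
  innerThr <- thr / 10
  trace <- numeric(0)
  converged <- FALSE
  it <- 0
  for (sweep in seq_len(maxIter)) {
    it <- sweep
    Wold <- W
    for (j in seq_len(p)) {
      V <- W[-j, -j, drop = FALSE]
      s12 <- S[-j, j]
      b <- B[-j, j]
      dV <- diag(V)
      for (inner in seq_len(10000L)) {
        delta <- 0
        for (k in seq_len(p - 1)) {
          r <- s12[k] - sum(V[k, ] * b) + dV[k] * b[k]
          bNew <- softThreshold(r, rho) / dV[k]
          delta <- max(delta, abs(bNew - b[k]) * dV[k])
          b[k] <- bNew
        }
        if (delta < innerThr) break
      }
      B[-j, j] <- b
      w12 <- V %*% b
      W[-j, j] <- w12
      W[j, -j] <- w12
    }
    gamma <- reconstructGamma(W, B)
    obj <- glassoObjective(gamma, S, rho, penalizeDiagonal)
    if (is.na(obj)) {
      # mid-run reconstruction not yet PD: fall back to the (PD) inverse
      # of the working covariance for the trace entry
      obj <- glassoObjective(solve(W), S, rho, penalizeDiagonal)
    }
    trace <- c(trace, obj)
    if (mean(abs(W - Wold)) < thr) {
      converged <- TRUE
      break
    }
  }
  gamma <- reconstructGamma(W, B)
  objective <- glassoObjective(gamma, S, rho, penalizeDiagonal)
  new("PrecisionEstimate", gamma = gamma, rho = rho,
      objective = objective, objectiveTrace = trace, nIter = it,
      converged = converged, penalizeDiagonal = penalizeDiagonal,
      geneIds = ids)
}

#' Extract network edges from a precision estimate
#'
#' An undirected edge (i, j), i < j, is created wherever
#' \code{|Gamma_ij| >= linkThreshold} (inclusive; entries below the
#' threshold are ignored). Each edge carries the signed precision entry as
#' its weight; self-loops are excluded and symmetric duplicates collapse
#' to a single link. Nodes are the genes engaged in at least one link.
#'
#' @param est a [PrecisionEstimate-class].
#' @param linkThreshold minimum absolute precision entry (default 1e-4).
#' @param annotation optional [readAnnotation()] table for node symbols.
#' @return a [GeneNetwork-class] with method tag "glasso".
#' @export
extractEdges <- function(est, linkThreshold = 1e-4, annotation = NULL) {
  stopifnot(is(est, "PrecisionEstimate"))
  g <- est@gamma
  ids <- est@geneIds
  idx <- which(upper.tri(g) & abs(g) >= linkThreshold, arr.ind = TRUE)
  edges <- data.frame(from = ids[idx[, 1]], to = ids[idx[, 2]],
                      weight = g[idx],
                      method = rep("glasso", nrow(idx)),
                      stringsAsFactors = FALSE)
  makeGeneNetwork(edges, annotation = annotation, method = "glasso",
                  provenance = list(rho = est@rho,
                                    link_threshold = linkThreshold,
                                    penalize_diagonal = est@penalizeDiagonal))
}

#' One-norm condition number of a matrix
#'
#' Computes kappa_1 = ||M||_1 ||M^-1||_1 from an explicit inverse (exact at
#' the dimensions used here). A condition number of order 10^k signals the
#' loss of about k digits of numerical accuracy, which is why a
#' near-singular p >> n sample covariance forces sparse estimation rather
#' than direct inversion. Matrices that are singular in floating point
#' yield \code{kappa = Inf} with the singularity flag set; numerically
#' singular ones (kappa at or beyond 1/eps) keep their finite
#' floating-point value but are flagged.
#'
#' @param M square matrix.
#' @param tag label recorded in the report.
#' @return a [ConditionReport-class].
#' @examples
#' conditionNumber(diag(c(1, 10)))
#' @export
conditionNumber <- function(M, tag = "matrix") {
  M <- as.matrix(M)
  if (nrow(M) != ncol(M)) stop("M must be square")
  inv <- tryCatch(solve(M), error = function(e) NULL)
  if (is.null(inv))
    return(new("ConditionReport", matrixTag = tag, kappa = Inf,
               digitsLost = Inf, singular = TRUE))
  k <- max(norm(M, "O") * norm(inv, "O"), 1)
  new("ConditionReport", matrixTag = tag, kappa = k,
      digitsLost = log10(k),
      singular = !is.finite(k) || k >= 1 / .Machine$double.eps)
}

#' Calibrate the sparsity penalty against a reference network
#'
#' Mirrors the study's use of a well-characterized pathway with known
#' links and non-links to pick the penalty: for every rho in the grid, the
#' graphical lasso is fitted and edges extracted, and the agreement score
#' is (correctly present + correctly absent) / total unordered pairs. The
#' smallest rho achieving the maximal score is returned along with the
#' full score path.
#'
#' @param cov a [CovarianceModel-class] (or covariance matrix).
#' @param reference known adjacency over the same genes: a binary matrix
#'   or an edge data.frame with columns from/to of probe ids.
#' @param rhoGrid non-empty numeric grid of penalties.
#' @param linkThreshold edge-extraction threshold.
#' @param tol,maxIter,penalizeDiagonal passed to [glassoFit()].
#' @return list with \code{rho} (chosen penalty), \code{score} (its
#'   agreement) and \code{path} (data.frame of rho, score, n_edges).
#' @export
calibrateRho <- function(cov, reference, rhoGrid, linkThreshold = 1e-4,
                         tol = 1e-6, maxIter = 200,
                         penalizeDiagonal = TRUE) {
  if (length(rhoGrid) == 0) stop("rhoGrid must be non-empty")
  if (is(cov, "CovarianceModel")) { ids <- cov@geneIds; p <- nrow(cov@S) }
  else { p <- nrow(as.matrix(cov))
         ids <- rownames(as.matrix(cov))
         if (is.null(ids)) ids <- sprintf("v%d", seq_len(p)) }
  ut <- upper.tri(matrix(0, p, p))
  if (is.matrix(reference)) {
    stopifnot(nrow(reference) == p, ncol(reference) == p)
    refSupport <- reference[ut] != 0
  } else {
    a <- matrix(0, p, p, dimnames = list(ids, ids))
    for (k in seq_len(nrow(reference))) {
      a[reference$from[k], reference$to[k]] <- 1
      a[reference$to[k], reference$from[k]] <- 1
    }
    refSupport <- a[ut] != 0
  }
  rhoGrid <- sort(rhoGrid)
  score <- nEdges <- numeric(length(rhoGrid))
  for (i in seq_along(rhoGrid)) {
    fit <- glassoFit(cov, rhoGrid[i], tol = tol, maxIter = maxIter,
                     penalizeDiagonal = penalizeDiagonal)
    est <- abs(fit@gamma[ut]) >= linkThreshold
    score[i] <- mean(est == refSupport)
    nEdges[i] <- sum(est)
  }
  best <- which(score == max(score))[1]
  list(rho = rhoGrid[best], score = score[best],
       path = data.frame(rho = rhoGrid, score = score, n_edges = nEdges))
}

#' Write a symmetric gene matrix (covariance, precision, correlation) as TSV
#' @param M matrix.
#' @param geneIds row/column labels.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeGeneMatrix <- function(M, geneIds, path) {
  out <- data.frame(probe_id = geneIds,
                    matrix(M, nrow = length(geneIds)),
                    stringsAsFactors = FALSE)
  colnames(out) <- c("probe_id", geneIds)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
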