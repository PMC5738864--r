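test_that("sample covariance matches the direct formula", {
  x <- matrix(c(1, 2, 3, 4,
                2, 1, 0, -1,
                5, 5, 6, 8), nrow = 3, byrow = TRUE)
  expr <- toyExpression(x, nNaive = 2, nPlastic = 2)
  cm <- sampleCovariance(expr)
  # direct oracle: centered cross-product over n - 1
  cent <- x - rowMeans(x)
  expect_equal(cm@S, tcrossprod(cent) / 3, tolerance = 1e-14)
  expect_identical(cm@nSamples, 4L)
  # two perfectly correlated genes: off-diagonal = product of sds
  y <- rbind(a = c(1, 2, 3, 4), b = 2 * c(1, 2, 3, 4) + 5)
  cm2 <- sampleCovariance(toyExpression(y))
  expect_equal(cm2@S[1, 2], sd(y[1, ]) * sd(y[2, ]), tolerance = 1e-12)
  expect_error(sampleCovariance(expr, genes = "absent"), "absent")
})

test_that("analytic limits of the solver hold", {
  # identity covariance: identity precision for any rho without diagonal
  # penalty
  for (rho in c(0, 0.3, 2)) {
    f <- glassoFit(diag(4), rho = rho, penalizeDiagonal = FALSE)
    expect_equal(f@gamma, diag(4), tolerance = 1e-10)
  }
  # rho = 0 on a 2x2: the exact inverse
  S <- matrix(c(2, 1, 1, 2), 2)
  f <- glassoFit(S, rho = 0, tol = 1e-10, maxIter = 500)
  expect_equal(f@gamma, matrix(c(2, -1, -1, 2) / 3, 2), tolerance = 1e-6)
  # rho = 0 reproduces the inverse on well-conditioned matrices
  set.seed(5)
  A <- randomSpd(6, jitter = 1)
  f2 <- glassoFit(A, rho = 0, tol = 1e-10, maxIter = 1000)
  inv <- solve(A)
  expect_lt(norm(f2@gamma - inv, "F") / norm(inv, "F"), 1e-8)
})

test_that("annihilation bound gives an exactly diagonal estimate", {
  set.seed(6)
  S <- randomSpd(8)
  rho <- max(abs(S[upper.tri(S)]))
  f <- glassoFit(S, rho = rho, penalizeDiagonal = TRUE)
  expect_identical(max(abs(f@gamma[upper.tri(f@gamma)])), 0)
  net <- extractEdges(f, linkThreshold = 1e-4)
  expect_identical(nrow(networkEdges(net)), 0L)
})

test_that("solver agrees with an independent convex oracle", {
  set.seed(7)
  for (i in 1:10) {
    S <- randomSpd(5)
    for (rho in c(0.01, 0.1, 0.5)) {
      o <- admmGlasso(S, rho)
      f <- glassoFit(S, rho, tol = 1e-8, maxIter = 500)
      expect_lt(abs(f@objective - o$objective), 1e-6)
      expect_identical(abs(f@gamma[upper.tri(S)]) > 1e-6,
                       abs(o$Z[upper.tri(S)]) > 1e-6)
    }
  }
})

test_that("objective decreases over sweeps and the estimate is PD", {
  set.seed(9)
  for (i in 1:20) {
    S <- randomSpd(8)
    f <- glassoFit(S, rho = 0.1, tol = 1e-8, maxIter = 500)
    expect_true(f@converged)
    expect_true(all(diff(f@objectiveTrace) <= 1e-10))
    ev <- eigen(f@gamma, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), 0)
  }
})

test_that("edge count is non-increasing in rho on the planted family", {
  spec <- syntheticSpec(nGenes = 11, plantedAdjacency = hubAdjacency(10),
                        baseScale = 1)
  Sigma <- solve(plantedPrecision(spec))
  counts <- sapply(c(0.001, 0.01, 0.05, 0.1, 0.3, 0.6, 1),
                   function(rho) {
    f <- glassoFit(Sigma, rho = rho, tol = 1e-7, maxIter = 300)
    sum(abs(f@gamma[upper.tri(Sigma)]) >= 1e-4)
  })
  expect_true(all(diff(counts) <= 0))
})

test_that("edge extraction applies the inclusive threshold", {
  g <- diag(3)
  g[1, 2] <- g[2, 1] <- 0.00009
  g[1, 3] <- g[3, 1] <- 0.0002
  est <- new("PrecisionEstimate", gamma = g, rho = 1, objective = 0,
             objectiveTrace = 0, nIter = 1, converged = TRUE,
             penalizeDiagonal = TRUE, geneIds = c("a", "b", "c"))
  net <- extractEdges(est, linkThreshold = 0.0001)
  expect_identical(networkEdges(net)$from, "a")
  expect_identical(networkEdges(net)$to, "c")
  expect_equal(networkEdges(net)$weight, 0.0002)
  # diagonal precision matrix: empty edge set
  est2 <- new("PrecisionEstimate", gamma = diag(3), rho = 1,
              objective = 0, objectiveTrace = 0, nIter = 1,
              converged = TRUE, penalizeDiagonal = TRUE,
              geneIds = c("a", "b", "c"))
  expect_identical(nrow(networkEdges(extractEdges(est2))), 0L)
})

test_that("condition numbers follow the closed forms", {
  expect_equal(conditionNumber(diag(4))@kappa, 1)
  r <- conditionNumber(diag(c(1, 10)))
  expect_equal(r@kappa, 10)
  expect_equal(r@digitsLost, 1)
  expect_false(r@singular)
  # exactly singular in floating point
  s <- conditionNumber(matrix(c(1, 1, 1, 1), 2))
  expect_identical(s@kappa, Inf)
  expect_true(s@singular)
  # numerically singular: finite floating-point kappa, flagged
  M <- diag(c(1, 1e-17)) + matrix(1e-18, 2, 2)
  ns <- conditionNumber(M)
  expect_true(ns@singular)
})

test_that("rho calibration scores reference adjacencies", {
  set.seed(10)
  S <- randomSpd(5)
  # empty reference graph: any rho at or beyond max |off-diagonal S|
  # scores 1.0 and the smallest such grid value is returned
  rhoMax <- max(abs(S[upper.tri(S)]))
  grid <- c(rhoMax / 2, rhoMax, 2 * rhoMax, 4 * rhoMax)
  cal <- calibrateRho(S, matrix(0, 5, 5), grid)
  expect_equal(cal$score, 1.0)
  expect_equal(cal$rho, rhoMax)
  expect_identical(nrow(cal$path), 4L)
})

test_that("calibration recovers a planted hub graph at high n", {
  sp <- syntheticSpec(nGenes = 11, nNaive = 2000, nPlastic = 2000,
                      regulatedFraction = 0,
                      plantedAdjacency = hubAdjacency(10), baseScale = 1,
                      seed = 14)
  d <- generateDataset(sp)
  covm <- sampleCovariance(d$expression)
  maxOff <- max(abs(covm@S[upper.tri(covm@S)]))
  grid <- maxOff * c(0.05, 0.1, 0.2, 0.35, 0.5, 0.75, 1)
  cal <- calibrateRho(covm, sp@plantedAdjacency, grid,
                      linkThreshold = 1e-4)
  expect_equal(cal$score, 1.0)
})
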