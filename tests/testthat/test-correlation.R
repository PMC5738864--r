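test_that("pearson matrix matches the closed-form coefficient", {
  x <- c(1.0, 2.5, 3.5, 7.0)
  y <- c(2.0, 1.0, 4.5, 6.5)
  expr <- toyExpression(rbind(a = x, b = y))
  cm <- pearsonMatrix(expr)
  # closed-form oracle computed from sums
  n <- 4
  r <- (sum(x * y) - sum(x) * sum(y) / n) /
    sqrt((sum(x^2) - sum(x)^2 / n) * (sum(y^2) - sum(y)^2 / n))
  expect_equal(cm@r[1, 2], r, tolerance = 1e-14)
  expect_equal(diag(cm@r), c(1, 1))
})

test_that("duplicated and negated genes hit the correlation bounds", {
  x <- c(0.3, 1.9, 2.2, 5.0)
  expr <- toyExpression(rbind(a = x, b = x, c = -x))
  cm <- pearsonMatrix(expr)
  expect_equal(cm@r[1, 2], 1)
  expect_equal(cm@r[1, 3], -1)
})

test_that("zero-variance genes are flagged and excluded from edges", {
  expr <- toyExpression(rbind(a = c(1, 2, 3, 4), b = c(5, 5, 5, 5),
                              c = c(2, 4, 6, 8)))
  cm <- pearsonMatrix(expr)
  expect_identical(cm@flagged, "b")
  expect_true(all(is.na(cm@r[2, ])))
  net <- correlationEdges(cm, cutoff = 0.9)
  expect_false("b" %in% geneIds(net))
  expect_identical(nrow(networkEdges(net)), 1L)
})

test_that("fewer than 3 samples is rejected", {
  x <- matrix(1:4, nrow = 2)
  rownames(x) <- c("a", "b"); colnames(x) <- c("n1", "p1")
  expr <- PlasticExpression(x, groups = c("naive", "plastic"))
  expect_error(pearsonMatrix(expr), "3 samples")
})

test_that("strict cutoff at 1.0 yields no edges without duplicate genes", {
  set.seed(15)
  expr <- toyExpression(matrix(rnorm(10 * 12), nrow = 10),
                        nNaive = 6, nPlastic = 6)
  net <- correlationEdges(pearsonMatrix(expr), cutoff = 1.0)
  expect_identical(nrow(networkEdges(net)), 0L)
})

test_that("independent high-n data produce no 0.95 edges", {
  expr <- toyExpression(matrix(rnorm(30 * 400), nrow = 30),
                        nNaive = 200, nPlastic = 200)
  net <- correlationEdges(pearsonMatrix(expr), cutoff = 0.95)
  expect_identical(nrow(networkEdges(net)), 0L)
})

test_that("edges are invariant to positive affine rescaling per gene", {
  set.seed(16)
  x <- matrix(rnorm(8 * 10), nrow = 8)
  x[2, ] <- x[1, ] + rnorm(10, sd = 0.01)       # one strong pair
  e1 <- toyExpression(x, nNaive = 5, nPlastic = 5)
  y <- x * runif(8, 0.5, 4) + runif(8, -3, 3)   # per-gene affine map
  e2 <- toyExpression(y, nNaive = 5, nPlastic = 5)
  n1 <- correlationEdges(pearsonMatrix(e1), cutoff = 0.9)
  n2 <- correlationEdges(pearsonMatrix(e2), cutoff = 0.9)
  expect_identical(networkEdges(n1)[, c("from", "to")],
                   networkEdges(n2)[, c("from", "to")])
  expect_gt(nrow(networkEdges(n1)), 0)
})

test_that("signed cutoff excludes anticorrelation unless absolute is set", {
  x <- c(1, 2, 3, 4, 5, 6)
  expr <- toyExpression(rbind(a = x, b = -x + rnorm(6, sd = 1e-3)),
                        nNaive = 3, nPlastic = 3)
  cm <- pearsonMatrix(expr)
  expect_identical(nrow(networkEdges(correlationEdges(cm, 0.95))), 0L)
  expect_identical(nrow(networkEdges(
    correlationEdges(cm, 0.95, absolute = TRUE))), 1L)
})

test_that("optional per-edge significance test prunes weak edges", {
  set.seed(17)
  x <- matrix(rnorm(6 * 5), nrow = 6)
  x[2, ] <- x[1, ] + rnorm(5, sd = 0.05)
  expr <- toyExpression(x, nNaive = 3, nPlastic = 2)
  cm <- pearsonMatrix(expr)
  loose <- correlationEdges(cm, cutoff = 0.5)
  strict <- correlationEdges(cm, cutoff = 0.5, pTest = TRUE,
                             alpha = 0.05)
  expect_lte(nrow(networkEdges(strict)), nrow(networkEdges(loose)))
  expect_true(all(paste(networkEdges(strict)$from,
                        networkEdges(strict)$to) %in%
                  paste(networkEdges(loose)$from,
                        networkEdges(loose)$to)))
})

test_that("glasso edge recovery dominates Pearson thresholding on planted data", {
  # the premise of using partial correlations: direct links are isolated
  # where marginal-correlation thresholding at 0.95 finds (almost) nothing
  f1 <- function(pred, truth) {
    tp <- sum(pred & truth)
    if (tp == 0) return(0)
    2 * tp / (sum(pred) + sum(truth))
  }
  scores <- sapply(1:20, function(s) {
    sp <- syntheticSpec(nGenes = 11, nNaive = 250, nPlastic = 250,
                        regulatedFraction = 0,
                        plantedAdjacency = hubAdjacency(10),
                        baseScale = 1, seed = 400 + s)
    d <- generateDataset(sp)
    covm <- sampleCovariance(d$expression)
    ut <- upper.tri(covm@S)
    truth <- sp@plantedAdjacency[ut] == 1
    maxOff <- max(abs(covm@S[ut]))
    cal <- calibrateRho(covm, sp@plantedAdjacency,
                        maxOff * c(0.1, 0.25, 0.5, 0.75),
                        linkThreshold = 1e-4)
    fit <- glassoFit(covm, cal$rho, tol = 1e-6, maxIter = 200)
    gl <- abs(fit@gamma[ut]) >= 1e-4
    cm <- pearsonMatrix(d$expression)
    pe <- !is.na(cm@r[ut]) & cm@r[ut] > 0.95
    c(glasso = f1(gl, truth), pearson = f1(pe, truth))
  })
  expect_gte(mean(scores["glasso", ]), mean(scores["pearson", ]))
})
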