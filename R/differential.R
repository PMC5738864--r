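# Row-wise pooled-variance two-sample t-test ("ttest2" convention:
# equal-variance pooling, two-sided p).
rowPooledTTest <- function(x, idx1, idx2) {
  n1 <- length(idx1); n2 <- length(idx2)
  stopifnot(n1 >= 2, n2 >= 2)
  x1 <- x[, idx1, drop = FALSE]; x2 <- x[, idx2, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- (m2 - m1) / se
  constant <- sp2 == 0
  t[constant] <- 0
  p <- 2 * stats::pt(-abs(t), df)
  p[constant] <- 1
  p <- pmin(p, 1)
  list(t = t, p = p, df = df, constant = constant)
}

#' Per-gene two-sample t tests between naive and plastic groups
#'
#' Pooled-variance (equal-variance) two-sided t test per gene, plastic
#' minus naive. Genes with zero pooled variance get t = 0, p = 1 and are
#' flagged. Ranks are 1-based ascending in p, ties broken by decreasing
#' |t| and then lexicographic probe id, so the table is a deterministic
#' function of the data.
#'
#' @param expr a [PlasticExpression-class] with >= 2 samples per group.
#' @return data.frame(probe_id, t, p, rank, constant) in input gene order;
#'   attribute \code{"df"} carries the degrees of freedom.
#' @examples
#' d <- generateDataset(syntheticSpec(nGenes = 50, seed = 1))
#' head(tTestPerGene(d$expression))
#' @export
tTestPerGene <- function(expr) {
  stopifnot(is(expr, "PlasticExpression"))
  grp <- sampleGroups(expr)
  idx1 <- which(grp == "naive"); idx2 <- which(grp == "plastic")
  if (length(idx1) < 2 || length(idx2) < 2)
    stop("need at least 2 samples per group")
  x <- assay(expr, "exprs")
  r <- rowPooledTTest(x, idx1, idx2)
  ids <- rownames(x)
  ord <- order(r$p, -abs(r$t), ids)
  rank <- integer(length(ids))
  rank[ord] <- seq_along(ids)
  out <- data.frame(probe_id = ids, t = r$t, p = r$p, rank = rank,
                    constant = r$constant, stringsAsFactors = FALSE,
                    row.names = NULL)
  attr(out, "df") <- r$df
  out
}

#' Significance threshold from random-matrix null comparisons
#'
#' For each of \code{nRuns} comparisons, a G x (nNaive + nPlastic) matrix
#' of standard Gaussian deviates is generated and the per-gene pooled t
#' test run with the same group split as the data; the minimum p value of
#' each comparison is recorded and the threshold is the smallest of those
#' minima. This is the empirical control the study used in place of
#' formal multiple-testing corrections: only genes more significant than
#' anything pure noise produced are accepted.
#'
#' Mode \code{"data_vs_random"} instead tests each data gene's values
#' against a freshly generated Gaussian row (requires \code{expr});
#' \code{"random_split"} is the default because only the random-versus-
#' random reading yields null-distributed minima of order 1/(G * nRuns).
#'
#' @param G gene count (>= 1).
#' @param nNaive,nPlastic group sizes of the split.
#' @param nRuns number of null comparisons (default 10).
#' @param seed master seed; run k uses the fixed-offset stream
#'   \code{seed + (k - 1) * 100003} so different master seeds give
#'   non-overlapping run streams.
#' @param mode "random_split" or "data_vs_random".
#' @param expr expression matrix, only for mode "data_vs_random".
#' @return a [NullThresholdRecord-class].
#' @examples
#' nullThreshold(2000, 9, 20, nRuns = 10, seed = 1)
#' @export
nullThreshold <- function(G, nNaive = 9, nPlastic = 20, nRuns = 10,
                          seed = 1,
                          mode = c("random_split", "data_vs_random"),
                          expr = NULL) {
  mode <- match.arg(mode)
  stopifnot(G >= 1, nRuns >= 1)
  n <- nNaive + nPlastic
  if (mode == "data_vs_random") {
    if (is.null(expr)) stop("mode 'data_vs_random' requires expr")
    x <- assay(expr, "exprs")
    stopifnot(nrow(x) == G)
  }
  minp <- numeric(nRuns)
  for (k in seq_len(nRuns)) {
    set.seed((seed + (k - 1) * 100003) %% 2147483647)
    if (mode == "random_split") {
      z <- matrix(stats::rnorm(G * n), nrow = G)
      r <- rowPooledTTest(z, seq_len(nNaive), nNaive + seq_len(nPlastic))
    } else {
      z <- matrix(stats::rnorm(G * n), nrow = G)
      r <- rowPooledTTest(cbind(x, z), seq_len(n), n + seq_len(n))
    }
    minp[k] <- min(r$p)
  }
  new("NullThresholdRecord", nRuns = nRuns, perRunMinP = minp,
      threshold = min(minp), seed = seed, mode = mode)
}

#' Select the top-K differential genes under a significance threshold
#'
#' Returns the K lowest-p genes, all strictly below the threshold, in rank
#' order; overall ranks are retained so a selected gene's position in the
#' full table can be reported. If fewer than K genes pass the threshold,
#' all passing genes are returned with a warning.
#'
#' @param table output of [tTestPerGene()].
#' @param K number of genes to keep (default 500).
#' @param threshold strict upper bound on p; either a number or a
#'   [NullThresholdRecord-class].
#' @return subset of \code{table} rows in rank order.
#' @export
selectTop <- function(table, K = 500, threshold) {
  if (is(threshold, "NullThresholdRecord")) threshold <- threshold@threshold
  stopifnot(K >= 1, K <= nrow(table))
  ord <- table[order(table$rank), , drop = FALSE]
  pass <- ord[ord$p < threshold, , drop = FALSE]
  if (nrow(pass) < K) {
    warning(sprintf("only %d of %d requested genes pass p < %.3g",
                    nrow(pass), K, threshold))
    return(pass)
  }
  pass[seq_len(K), , drop = FALSE]
}

#' Write a differential table as TSV
#' @param table output of [tTestPerGene()] or [selectTop()].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeDifferentialTable <- function(table, path) {
  utils::write.table(
    format(table[, c("probe_id", "t", "p", "rank")], digits = 15,
           scientific = NA, trim = TRUE),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a null-threshold record as JSON
#' @param record a [NullThresholdRecord-class].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeNullThreshold <- function(record, path) {
  jsonlite::write_json(
    list(n_runs = record@nRuns, per_run_min_p = record@perRunMinP,
         threshold = record@threshold, seed = record@seed,
         mode = record@mode),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
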