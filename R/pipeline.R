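#' Build a pipeline configuration
#'
#' Defaults are the published analysis parameters: top K = 500 genes, 10
#' random-matrix null comparisons, graphical-lasso penalty rho = 30
#' (absolute, on the covariance scale of the data), link threshold 1e-4 on
#' precision entries, Pearson cutoff 0.95.
#'
#' @param syntheticSpec a [SyntheticSpec-class], or NULL to read data from
#'   disk.
#' @param expressionPath expression TSV (used when \code{syntheticSpec} is
#'   NULL).
#' @param groupPath 2-column sample-group TSV for \code{expressionPath}.
#' @param annotationPath optional probe annotation TSV.
#' @param scale data-scale tag for data read from disk.
#' @param K top-gene count.
#' @param nullRuns number of null comparisons.
#' @param rho graphical-lasso penalty.
#' @param rhoMode "absolute", or "relative" to use
#'   \code{rho * max(offdiag |S|)}.
#' @param linkThreshold precision-entry threshold for glasso edges.
#' @param corCutoff Pearson correlation cutoff.
#' @param corAbsolute threshold |r| instead of signed r.
#' @param filterMode richness-filter mode (see [richnessFilter()]).
#' @param seed master seed; the null-threshold stage uses
#'   \code{seed + 1000}.
#' @param outDir output directory (created if needed); NA for no file
#'   output.
#' @return a validated [PipelineConfig-class].
#' @export
pipelineConfig <- function(syntheticSpec = NULL,
                           expressionPath = NA_character_,
                           groupPath = NA_character_,
                           annotationPath = NA_character_,
                           scale = "raw", K = 500, nullRuns = 10,
                           rho = 30, rhoMode = "absolute",
                           linkThreshold = 1e-4, corCutoff = 0.95,
                           corAbsolute = FALSE, filterMode = "reachable",
                           seed = 1, outDir = NA_character_) {
  new("PipelineConfig", syntheticSpec = syntheticSpec,
      expressionPath = expressionPath, groupPath = groupPath,
      annotationPath = annotationPath, scale = scale, K = K,
      nullRuns = nullRuns, rho = rho, rhoMode = rhoMode,
      linkThreshold = linkThreshold, corCutoff = corCutoff,
      corAbsolute = corAbsolute, filterMode = filterMode, seed = seed,
      outDir = outDir)
}

pipelineStage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full network-inference pipeline
#'
#' Executes the stages in order: load or simulate the expression matrix,
#' derive the random-matrix null threshold, run per-gene t tests, select
#' the top-K significant genes, reconstruct the graphical-lasso and
#' Pearson networks over them, apply the richness filter to both,
#' intersect the filtered node sets and rank hubs. With an output
#' directory set, every intermediate is written (TSV/JSON/GraphML) along
#' with a JSON run summary; identical config and seed give byte-identical
#' outputs.
#'
#' @param cfg a [PipelineConfig-class].
#' @return (invisibly) the run summary list: parameters, null threshold,
#'   selection counts, network sizes, hub rankings and the node
#'   intersection. When fewer than 2 genes pass selection the networks
#'   are empty and the summary notes it.
#' @examples
#' cfg <- pipelineConfig(syntheticSpec = syntheticSpec(nGenes = 300,
#'                                                     seed = 2),
#'                       rho = 0.3, rhoMode = "relative")
#' summary <- runPipeline(cfg)
#' summary$hub_glasso
#' @export
runPipeline <- function(cfg) {
  stopifnot(is(cfg, "PipelineConfig"))
  validObject(cfg)
  outDir <- cfg@outDir
  writeOut <- !is.na(outDir)
  if (writeOut && !dir.exists(outDir))
    dir.create(outDir, recursive = TRUE)
  emit <- function(fn, ...) if (writeOut) fn(...)

  annotation <- if (!is.na(cfg@annotationPath))
    pipelineStage("annotation", readAnnotation(cfg@annotationPath))
  else NULL

  loaded <- pipelineStage("load", {
    if (!is.null(cfg@syntheticSpec)) {
      generateDataset(cfg@syntheticSpec)
    } else {
      gm <- if (!is.na(cfg@groupPath)) readGroups(cfg@groupPath)
            else stop("groupPath is required for expression input")
      list(expression = readExpression(cfg@expressionPath, gm,
                                       scale = cfg@scale),
           truth = NULL)
    }
  })
  expr <- loaded$expression
  truth <- loaded$truth
  grp <- sampleGroups(expr)

  null <- pipelineStage("null_threshold",
    nullThreshold(nrow(expr), sum(grp == "naive"), sum(grp == "plastic"),
                  nRuns = cfg@nullRuns, seed = cfg@seed + 1000))
  emit(writeNullThreshold, null, file.path(outDir, "null_threshold.json"))

  dt <- pipelineStage("t_test", tTestPerGene(expr))
  emit(writeDifferentialTable, dt, file.path(outDir, "differential.tsv"))

  K <- min(cfg@K, nrow(dt))
  sel <- pipelineStage("select",
    withCallingHandlers(selectTop(dt, K = K, threshold = null),
                        warning = function(w) invokeRestart("muffleWarning")))
  emit(writeDifferentialTable, sel, file.path(outDir, "selected.tsv"))

  emptyNet <- makeGeneNetwork(
    data.frame(from = character(), to = character()),
    annotation = annotation, method = "glasso")
  if (nrow(sel) >= 2) {
    covm <- pipelineStage("covariance",
                          sampleCovariance(expr, sel$probe_id))
    rhoEff <- if (cfg@rhoMode == "relative") {
      offd <- abs(covm@S[upper.tri(covm@S)])
      cfg@rho * max(offd)
    } else cfg@rho
    fit <- pipelineStage("glasso", glassoFit(covm, rho = rhoEff))
    glassoNet <- pipelineStage("glasso_edges",
      extractEdges(fit, linkThreshold = cfg@linkThreshold,
                   annotation = annotation))
    cm <- pipelineStage("pearson", pearsonMatrix(expr, sel$probe_id))
    pearsonNet <- pipelineStage("pearson_edges",
      correlationEdges(cm, cutoff = cfg@corCutoff,
                       annotation = annotation,
                       absolute = cfg@corAbsolute))
  } else {
    fit <- NULL
    glassoNet <- emptyNet
    pearsonNet <- makeGeneNetwork(
      data.frame(from = character(), to = character()),
      annotation = annotation, method = "pearson")
  }

  glassoFiltered <- pipelineStage("filter",
    richnessFilter(glassoNet, mode = cfg@filterMode))
  pearsonFiltered <- richnessFilter(pearsonNet, mode = cfg@filterMode)
  shared <- intersectNodes(glassoFiltered, pearsonFiltered)
  hubsG <- hubRank(glassoNet)
  hubsGF <- hubRank(glassoFiltered)
  hubsP <- hubRank(pearsonNet)

  if (writeOut) {
    exportNetwork(glassoNet, file.path(outDir, "glasso_edges.tsv"))
    exportNetwork(pearsonNet, file.path(outDir, "pearson_edges.tsv"))
    exportNetwork(glassoFiltered,
                  file.path(outDir, "glasso_filtered_edges.tsv"))
    exportNetwork(pearsonFiltered,
                  file.path(outDir, "pearson_filtered_edges.tsv"))
    exportNetwork(glassoNet, file.path(outDir, "glasso_network.graphml"),
                  format = "graphml")
    exportNetwork(pearsonNet, file.path(outDir, "pearson_network.graphml"),
                  format = "graphml")
    writeHubReport(hubsG, file.path(outDir, "hub_report.json"))
    if (!is.null(truth))
      writeTruth(truth, file.path(outDir, "truth.json"))
  }

  summary <- list(
    parameters = list(
      K = cfg@K, null_runs = cfg@nullRuns, rho = cfg@rho,
      rho_mode = cfg@rhoMode, link_threshold = cfg@linkThreshold,
      cor_cutoff = cfg@corCutoff, cor_absolute = cfg@corAbsolute,
      filter_mode = cfg@filterMode, scale = scaleTag(expr),
      seed = cfg@seed),
    n_genes = nrow(expr),
    n_samples = ncol(expr),
    n_naive = sum(grp == "naive"),
    n_plastic = sum(grp == "plastic"),
    null_threshold = null@threshold,
    null_per_run_min_p = null@perRunMinP,
    n_passing = sum(dt$p < null@threshold),
    n_selected = nrow(sel),
    zero_passing = nrow(sel) == 0,
    glasso = list(converged = if (!is.null(fit)) fit@converged else NA,
                  n_genes = length(geneIds(glassoNet)),
                  n_links = nrow(networkEdges(glassoNet)),
                  n_genes_filtered = length(geneIds(glassoFiltered)),
                  n_links_filtered = nrow(networkEdges(glassoFiltered))),
    pearson = list(n_genes = length(geneIds(pearsonNet)),
                   n_links = nrow(networkEdges(pearsonNet)),
                   n_genes_filtered = length(geneIds(pearsonFiltered)),
                   n_links_filtered = nrow(networkEdges(pearsonFiltered))),
    intersection = shared,
    hub_glasso = if (nrow(hubsG)) hubsG$probe_id[1] else NA_character_,
    hub_glasso_filtered = if (nrow(hubsGF)) hubsGF$probe_id[1]
                          else NA_character_,
    hub_pearson = if (nrow(hubsP)) hubsP$probe_id[1] else NA_character_,
    truth_hub = if (!is.null(truth)) truth$hub else NULL
  )
  if (writeOut)
    jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
  invisible(summary)
}
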