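#' Configuration of the discovery-and-diagnosis pipeline
#'
#' Collects every tunable setting of [runPipeline()] with the study defaults:
#' minimal-variation filter threshold 1.0 (sd on the input scale), 80:20
#' stratified split, adjusted-p threshold 1e-5, top-15 consensus, VIF
#' threshold 2.0, 85% cumulative-variance threshold, candidate k range 2..8,
#' 5-fold cross-validation.
#'
#' @param filterThreshold sd cutoff of the minimal-variation filter.
#' @param splitRatio train fraction of the stratified split.
#' @param alpha adjusted-p significance threshold for the consensus.
#' @param topN per-model top-gene count intersected for the consensus.
#' @param vifThreshold multicollinearity cutoff.
#' @param varThreshold cumulative-variance threshold (percent).
#' @param kRange candidate cluster counts for the silhouette search.
#' @param folds cross-validation folds.
#' @param seed integer seed for every stochastic stage.
#' @param inputScale default input scale of the deployed model.
#' @param borutaAlpha significance level of the Boruta decision tests.
#' @param borutaMaxIter maximum Boruta iterations.
#' @return a validated classed list (`PipelineConfig`).
#' @export
pipelineConfig <- function(filterThreshold = 1.0, splitRatio = 0.8,
                           alpha = 1e-5, topN = 15L, vifThreshold = 2.0,
                           varThreshold = 85, kRange = 2:8, folds = 5L,
                           seed = 1L, inputScale = "linear",
                           borutaAlpha = 0.05, borutaMaxIter = 100L) {
  cfg <- list(filterThreshold = filterThreshold, splitRatio = splitRatio,
              alpha = alpha, topN = as.integer(topN),
              vifThreshold = vifThreshold, varThreshold = varThreshold,
              kRange = as.integer(kRange), folds = as.integer(folds),
              seed = as.integer(seed), inputScale = inputScale,
              borutaAlpha = borutaAlpha,
              borutaMaxIter = as.integer(borutaMaxIter))
  if (cfg$filterThreshold <= 0) stop("filterThreshold must be positive",
                                     call. = FALSE)
  if (cfg$splitRatio <= 0 || cfg$splitRatio >= 1)
    stop("splitRatio must lie strictly between 0 and 1", call. = FALSE)
  if (cfg$alpha <= 0 || cfg$alpha > 1) stop("alpha must lie in (0, 1]",
                                            call. = FALSE)
  if (cfg$topN < 1L) stop("topN must be positive", call. = FALSE)
  if (!cfg$inputScale %in% c("linear", "log2"))
    stop("inputScale must be 'linear' or 'log2'", call. = FALSE)
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Run the full biomarker-discovery and diagnosis pipeline
#'
#' Executes, in order: minimal-variation filter, voom transformation,
#' stratified train/test split, the linear stage-indicator and ordinal
#' per-gene models on the training samples, consensus ranking, Boruta, RFE
#' and iterative VIF elimination, PCA of the final panel with the
#' three-criteria component-count choice, silhouette-based k optimisation,
#' the k = 2 k-means classifier with majority-class cluster mapping, pooled
#' 5-fold cross-validation on the training split and evaluation on the
#' held-out test split. Every stage's input/output dimensions are logged and
#' the whole run is reproducible from the configured seed.
#'
#' @param expression genes-by-samples matrix of non-negative expression, or a
#'   cohort `SummarizedExperiment` (e.g. from [simulateCohort()]).
#' @param annotation data.frame with per-sample `class` and `stage` (rownames
#'   or `sample_id` column matching the matrix columns); ignored when
#'   `expression` is a `SummarizedExperiment` carrying `colData`.
#' @param config a [pipelineConfig()].
#' @return a classed list (`DxPipelineResult`) with the final `panel`, the
#'   `consensus` result and gene table, the `boruta`/`rfe`/`vif` reports, the
#'   deployable `model` ([DxModel-class]), the PC-count `criteria`, the
#'   silhouette-chosen `optimalK`, pooled cross-validation metrics
#'   (`cvMetrics`), held-out `testMetrics`, the `split`, the stage `log` and
#'   the `config`.
#' @export
runPipeline <- function(expression, annotation = NULL,
                        config = pipelineConfig()) {
  if (methods::is(expression, "SummarizedExperiment")) {
    cd <- SummarizedExperiment::colData(expression)
    annotation <- data.frame(class = as.character(cd$class),
                             stage = as.integer(cd$stage),
                             row.names = rownames(cd))
    expression <- SummarizedExperiment::assay(expression)
  }
  if (is.null(annotation))
    stop("annotation is required for matrix input", call. = FALSE)
  if (!is.null(annotation$sample_id)) rownames(annotation) <- annotation$sample_id
  if (!all(colnames(expression) %in% rownames(annotation)))
    stop("input error: annotation is missing sample(s)", call. = FALSE)
  annotation <- annotation[colnames(expression), , drop = FALSE]
  cfg <- config
  log <- list()
  note <- function(stage, ...) {
    log[[stage]] <<- paste0(...)
  }

  filtered <- filterLowVariance(expression, cfg$filterThreshold)
  note("filter", nrow(expression), " -> ", nrow(filtered), " genes (sd >= ",
       cfg$filterThreshold, ")")

  v <- voomTransform(filtered)
  note("voom", "log-CPM + weights for ", nrow(filtered), " x ",
       ncol(filtered), " matrix")

  cls <- stats::setNames(annotation$class, rownames(annotation))
  split <- stratifiedSplit(cls, ratio = cfg$splitRatio, seed = cfg$seed)
  note("split", length(split$train), " train / ", length(split$test),
       " test, stratified on class")

  trainIdx <- colnames(expression) %in% split$train
  vTrain <- v[, trainIdx]
  stageTrain <- annotation$stage[trainIdx]

  linear <- fitLinearStageModel(vTrain, stageTrain)
  ordinal <- fitOrdinalModel(vTrain, stageTrain)
  note("models", "linear: ", sum(linear$adjp < cfg$alpha),
       " significant; ordinal: ", sum(ordinal$adjp < cfg$alpha),
       " significant at adj. p < ", format(cfg$alpha))

  cons <- rankAndConsensus(linear, ordinal, topN = cfg$topN,
                           alpha = cfg$alpha)
  note("consensus", length(cons$consensus), " consensus gene(s) of top-",
       cfg$topN, " per model")
  if (length(cons$consensus) < 2L)
    stop("stage error [consensus]: fewer than 2 consensus genes",
         call. = FALSE)

  xTrain <- t(vTrain$E[cons$consensus, , drop = FALSE])
  yTrain <- factor(annotation$class[trainIdx], levels = c("cancer", "normal"))

  bor <- borutaSelect(xTrain, yTrain, alpha = cfg$borutaAlpha,
                      maxIter = cfg$borutaMaxIter, seed = cfg$seed)
  note("boruta", length(cons$consensus), " -> ", length(bor$selected),
       " confirmed in ", bor$nIter, " iteration(s)")
  if (length(bor$selected) < 2L)
    stop("stage error [boruta]: fewer than 2 confirmed features",
         call. = FALSE)

  rfe <- rfeSelect(xTrain[, bor$selected, drop = FALSE], yTrain,
                   folds = cfg$folds, seed = cfg$seed)
  note("rfe", length(bor$selected), " -> ", length(rfe$kept), " kept")
  if (length(rfe$kept) < 2L)
    stop("stage error [rfe]: fewer than 2 features kept", call. = FALSE)

  vif <- vifEliminate(xTrain[, rfe$kept, drop = FALSE],
                      threshold = cfg$vifThreshold)
  panel <- vif$kept
  note("vif", length(rfe$kept), " -> ", length(panel),
       " after multicollinearity elimination")
  if (length(panel) < 2L)
    stop("stage error [vif]: fewer than 2 panel genes", call. = FALSE)

  xPanel <- xTrain[, panel, drop = FALSE]
  pca <- fitPca(xPanel)
  crit <- pcCountCriteria(pca, cfg$varThreshold)
  componentCount(pca) <- crit$q
  note("pca", length(panel), " features; criteria (kaiser ", crit$kaiser,
       ", scree ", crit$scree, ", variance ", crit$variance, ") -> q = ",
       crit$q)

  scores <- pcaScores(pca, xPanel)
  optimalK <- silhouetteOptimalK(scores, kRange = cfg$kRange,
                                 seed = cfg$seed)
  note("silhouette", "optimal k = ", optimalK,
       " (classifier is fit with k = 2)")

  clf <- fitKmeansClassifier(scores, as.character(yTrain), k = 2L,
                             seed = cfg$seed)
  model <- dxModel(pca, clf, inputScale = cfg$inputScale)

  cv <- crossValidateDx(xPanel, as.character(yTrain), folds = cfg$folds,
                        seed = cfg$seed, varThreshold = cfg$varThreshold)
  note("cv", cfg$folds, "-fold pooled balanced accuracy ",
       sprintf("%.2f%%", cv$metrics$balancedAccuracy))

  testIdx <- colnames(expression) %in% split$test
  xTest <- t(v$E[panel, testIdx, drop = FALSE])
  pr <- predict(model, xTest, inputScale = "log2")
  truthTest <- annotation$class[testIdx]
  testMetrics <- computeMetrics(confusionCounts(truthTest, pr$class),
                                scores = pr$margin, labels = truthTest)
  note("test", "held-out balanced accuracy ",
       sprintf("%.2f%%", testMetrics$balancedAccuracy))

  out <- list(panel = panel, consensus = cons, boruta = bor, rfe = rfe,
              vif = vif, model = model, criteria = crit,
              optimalK = as.integer(optimalK), cvMetrics = cv$metrics,
              cv = cv, testMetrics = testMetrics,
              testPredictions = pr, split = split, log = log, config = cfg)
  class(out) <- "DxPipelineResult"
  out
}

#' @export
print.DxPipelineResult <- function(x, ...) {
  cat("DxPipelineResult\n")
  for (stage in names(x$log))
    cat(sprintf("  %-10s %s\n", stage, x$log[[stage]]))
  cat("  panel:", paste(x$panel, collapse = ", "), "\n")
  invisible(x)
}
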