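#' Principal-component analysis of a biomarker subspace
#'
#' Eigendecomposition of the sample covariance matrix of the centered (not
#' scaled) feature columns. The eigenvalue sum equals the total feature
#' variance, and each loading column is signed so that its largest-magnitude
#' entry is positive (a deterministic sign convention).
#'
#' @param x samples-by-features numeric matrix with column names; at least 2
#'   samples and 2 features, no constant feature.
#' @param q number of components to retain initially (default: all); can be
#'   changed later with `componentCount<-` after [pcCountCriteria()].
#' @return a [PCAModel-class].
#' @export
fitPca <- function(x, q = NULL) {
  x <- as.matrix(x)
  if (nrow(x) < 2L || ncol(x) < 2L)
    stop("input error: need at least 2 samples and 2 features", call. = FALSE)
  if (is.null(colnames(x)))
    colnames(x) <- paste0("feature", seq_len(ncol(x)))
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop("degenerate-covariance error: constant feature(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "), call. = FALSE)
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  rot <- pc$rotation           # min(n - 1, p) columns, as prcomp returns
  ev <- pc$sdev^2
  for (j in seq_len(ncol(rot))) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) rot[, j] <- -rot[, j]
  }
  pct <- 100 * ev / sum(ev)
  methods::new("PCAModel",
    featureIds = colnames(x),
    centers = colMeans(x),
    loadings = rot,
    eigenvalues = ev,
    varExplained = pct,
    cumVarExplained = cumsum(pct),
    q = as.integer(if (is.null(q)) length(ev) else q)
  )
}

#' Percent and cumulative variance explained from eigenvalues
#'
#' @param eigenvalues non-negative, non-increasing eigenvalues (or a
#'   [PCAModel-class], whose eigenvalues are used).
#' @return data.frame with columns `eigenvalue`, `percent` and `cumulative`
#'   (percent of total variance, and its running sum).
#' @export
varianceExplained <- function(eigenvalues) {
  if (methods::is(eigenvalues, "PCAModel"))
    eigenvalues <- eigenvalues@eigenvalues
  if (any(eigenvalues < 0) || any(diff(eigenvalues) > 1e-8))
    stop("eigenvalues must be non-negative and non-increasing", call. = FALSE)
  total <- sum(eigenvalues)
  if (total == 0)
    stop("degenerate error: all eigenvalues are zero", call. = FALSE)
  pct <- 100 * eigenvalues / total
  data.frame(eigenvalue = eigenvalues, percent = pct,
             cumulative = cumsum(pct))
}

screeElbow <- function(ev) {
  p <- length(ev)
  if (p == 1L) return(1L)
  a <- c(1, ev[1])
  b <- c(p, ev[p])
  v <- b - a
  d <- vapply(seq_len(p), function(i) {
    w <- c(i, ev[i]) - a
    abs(v[1] * w[2] - v[2] * w[1]) / sqrt(sum(v^2))
  }, numeric(1))
  which.max(d)
}

#' Choose the number of principal components by three criteria
#'
#' * Kaiser-Guttmann: count of eigenvalues greater than 1;
#' * scree elbow: the component at maximum perpendicular distance from the
#'   chord joining `(1, lambda_1)` and `(p, lambda_p)`;
#' * cumulative variance: the smallest count whose cumulative variance
#'   explained reaches `varThreshold` percent.
#'
#' The three counts are reconciled as their median.
#'
#' @param model a [PCAModel-class], or a numeric vector of eigenvalues.
#' @param varThreshold cumulative-variance threshold in percent (default 85).
#' @return a classed list (`PcCountCriteria`) with `kaiser`, `scree`,
#'   `variance` and the reconciled `q`.
#' @export
pcCountCriteria <- function(model, varThreshold = 85) {
  ev <- if (methods::is(model, "PCAModel")) model@eigenvalues else model
  if (length(ev) == 1L) {
    out <- list(kaiser = 1L, scree = 1L, variance = 1L, q = 1L,
                varThreshold = varThreshold)
    class(out) <- "PcCountCriteria"
    return(out)
  }
  ve <- varianceExplained(ev)
  kaiser <- max(1L, sum(ev > 1))
  scree <- screeElbow(ev)
  variance <- which(ve$cumulative >= varThreshold - 1e-9)[1]
  out <- list(kaiser = as.integer(kaiser), scree = as.integer(scree),
              variance = as.integer(variance),
              q = as.integer(round(stats::median(c(kaiser, scree, variance)))),
              varThreshold = varThreshold)
  class(out) <- "PcCountCriteria"
  out
}

#' @export
print.PcCountCriteria <- function(x, ...) {
  cat("PC-count criteria: Kaiser-Guttmann = ", x$kaiser, ", scree elbow = ",
      x$scree, ", variance(", x$varThreshold, "%) = ", x$variance,
      " -> q = ", x$q, "\n", sep = "")
  invisible(x)
}

#' Project samples into the principal-component space of a model
#'
#' Centers the feature columns with the training means and projects onto the
#' top-`q` loadings. Input columns are matched to the model's features by
#' name, so column order is irrelevant.
#'
#' @param model a [PCAModel-class].
#' @param x samples-by-features matrix (log2 scale), column names covering
#'   `featureIds(model)`.
#' @param q number of components (default: the model's `q`).
#' @return samples-by-q score matrix.
#' @export
pcaScores <- function(model, x, q = componentCount(model)) {
  x <- as.matrix(x)
  miss <- setdiff(model@featureIds, colnames(x))
  if (length(miss))
    stop("input error: missing feature id(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  x <- x[, model@featureIds, drop = FALSE]
  sweep(x, 2, model@centers) %*% model@loadings[, seq_len(q), drop = FALSE]
}

#' Choose the number of k-means clusters by mean silhouette width
#'
#' Fits seeded multi-restart k-means for each candidate `k` and returns the
#' `k` maximising the mean silhouette width (ties resolve to the smaller k).
#'
#' @param scores samples-by-dimensions coordinate matrix (PC scores).
#' @param kRange candidate cluster counts (default 2:8), all within
#'   `[2, n - 1]`.
#' @param seed integer seed.
#' @param nstart k-means restarts per candidate (default 10).
#' @return the selected `k`; the per-k mean silhouette widths are attached as
#'   `attr(, "silhouette")`.
#' @export
silhouetteOptimalK <- function(scores, kRange = 2:8, seed = 1L, nstart = 10L) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  if (any(kRange < 2L) || any(kRange > n - 1L))
    stop("input error: kRange must lie within [2, n - 1]", call. = FALSE)
  set.seed(seed)
  d <- stats::dist(scores)
  sil <- vapply(kRange, function(k) {
    km <- stats::kmeans(scores, centers = k, nstart = nstart, iter.max = 100L)
    mean(cluster::silhouette(km$cluster, d)[, "sil_width"])
  }, numeric(1))
  k <- kRange[which.max(sil)]
  attr(k, "silhouette") <- stats::setNames(sil, kRange)
  k
}

#' Fit a k-means classifier on principal-component scores
#'
#' Runs multi-restart k-means (Lloyd-type, via `stats::kmeans`) on the score
#' matrix and maps each cluster to the majority training class among its
#' members. For `k = 2` the map must assign one cluster to each class.
#'
#' @param scores samples-by-q matrix of PC scores.
#' @param labels per-sample class labels in `{"cancer", "normal"}`.
#' @param k number of clusters (the diagnostic classifier uses 2).
#' @param seed integer seed.
#' @param nstart k-means restarts (default 10).
#' @return a [KMeansClassifier-class].
#' @export
fitKmeansClassifier <- function(scores, labels, k = 2L, seed = 1L,
                                nstart = 10L) {
  scores <- as.matrix(scores)
  labels <- as.character(labels)
  if (!all(labels %in% c("cancer", "normal")))
    stop("labels must be 'cancer' or 'normal'", call. = FALSE)
  if (length(unique(labels)) < 2L)
    stop("input error: both classes must be present", call. = FALSE)
  set.seed(seed)
  km <- stats::kmeans(scores, centers = k, nstart = nstart, iter.max = 100L)
  map <- character(k)
  for (cl in seq_len(k)) {
    tab <- table(labels[km$cluster == cl])
    if (length(tab) > 1L && tab[1] == tab[2])
      stop("mapping error: cluster ", cl, " has a tied class vote",
           call. = FALSE)
    map[cl] <- names(tab)[which.max(tab)]
  }
  if (k == 2L && length(unique(map)) != 2L)
    stop("mapping error: both clusters map to the same class", call. = FALSE)
  methods::new("KMeansClassifier",
    k = as.integer(k),
    centroids = km$centers,
    classMap = stats::setNames(map, as.character(seq_len(k))),
    inertia = km$tot.withinss,
    seed = as.integer(seed)
  )
}

#' Build a deployable diagnosis model
#'
#' @param pca a [PCAModel-class] (with its `q` already set).
#' @param clusterer a [KMeansClassifier-class] fit on the top-`q` scores.
#' @param inputScale default scale of prediction inputs, `"linear"` (raw
#'   expression; `log2(x + 1)` is applied) or `"log2"`.
#' @return a [DxModel-class].
#' @export
dxModel <- function(pca, clusterer, inputScale = c("linear", "log2")) {
  methods::new("DxModel", pca = pca, clusterer = clusterer,
               inputScale = match.arg(inputScale))
}

#' Predict the diagnostic class of new samples
#'
#' Applies the deployment-time preprocessing: linear-scale inputs are mapped
#' through `log2(x + 1)`, features are matched by id (column order is
#' irrelevant), centered with the training means and projected into the
#' model's principal-component space; each sample is assigned the class of
#' its nearest centroid (Euclidean). The margin is
#' `d(normal centroid) - d(cancer centroid)`, so positive margins predict
#' cancer; an exactly equidistant sample is conservatively called normal.
#'
#' @param object a [DxModel-class].
#' @param newdata samples-by-features matrix or data.frame of panel
#'   expression (a single sample may be a named vector); column names must
#'   cover the panel's feature ids.
#' @param inputScale `"linear"` or `"log2"`; defaults to the model's setting.
#' @param ... unused.
#' @return data.frame with columns `sample`, `class` and `margin`, rows in
#'   input order.
#' @export
setMethod("predict", "DxModel",
  function(object, newdata, inputScale = object@inputScale, ...) {
  if (is.null(dim(newdata)))
    newdata <- matrix(newdata, nrow = 1,
                      dimnames = list("sample1", names(newdata)))
  newdata <- as.matrix(newdata)
  if (!is.numeric(newdata))
    stop("parse error: non-numeric expression value(s)", call. = FALSE)
  if (is.null(rownames(newdata)))
    rownames(newdata) <- paste0("sample", seq_len(nrow(newdata)))
  if (!inputScale %in% c("linear", "log2"))
    stop("inputScale must be 'linear' or 'log2'", call. = FALSE)
  if (inputScale == "linear") {
    if (any(newdata < 0))
      stop("input error: linear-scale expression must be non-negative",
           call. = FALSE)
    newdata <- log2(newdata + 1)
  }
  sc <- pcaScores(object@pca, newdata)
  cent <- object@clusterer@centroids
  map <- object@clusterer@classMap
  dmat <- vapply(seq_len(nrow(cent)), function(cl)
    sqrt(rowSums(sweep(sc, 2, cent[cl, ])^2)), numeric(nrow(sc)))
  dmat <- matrix(dmat, nrow = nrow(sc))
  dNormal <- dmat[, which(map == "normal")[1]]
  dCancer <- dmat[, which(map == "cancer")[1]]
  margin <- dNormal - dCancer
  data.frame(sample = rownames(newdata),
             class = ifelse(margin > 0, "cancer", "normal"),
             margin = margin,
             row.names = NULL, stringsAsFactors = FALSE)
})

stratifiedFolds <- function(labels, folds, seed) {
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold
}

#' Cross-validate the PCA + k-means diagnostic pipeline
#'
#' Stratified k-fold cross-validation in which *all* model components — PCA,
#' component-count choice, and the k-means cluster/class map — are re-fit on
#' each fold's training portion only; held-out predictions are pooled for the
#' final metrics.
#'
#' @param x samples-by-features matrix of panel expression on the log2 scale.
#' @param labels per-sample classes in `{"cancer", "normal"}`.
#' @param folds number of folds (default 5).
#' @param seed integer seed (fold assignment and k-means restarts).
#' @param varThreshold cumulative-variance threshold for the component count.
#' @param k number of clusters (default 2).
#' @return a classed list (`CvResult`) with pooled `metrics` (a
#'   [computeMetrics()] record), the pooled `predictions` data.frame (truth,
#'   predicted class, margin, fold) and the per-fold balanced accuracies.
#' @export
crossValidateDx <- function(x, labels, folds = 5L, seed = 1L,
                            varThreshold = 85, k = 2L) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  if (folds < 2L) stop("folds must be at least 2", call. = FALSE)
  if (min(table(labels)) < folds)
    stop("stratification error: a class has fewer samples than folds",
         call. = FALSE)
  fold <- stratifiedFolds(labels, folds, seed)
  preds <- vector("list", folds)
  for (f in seq_len(folds)) {
    tr <- fold != f
    pca <- fitPca(x[tr, , drop = FALSE])
    componentCount(pca) <- pcCountCriteria(pca, varThreshold)$q
    clf <- fitKmeansClassifier(pcaScores(pca, x[tr, , drop = FALSE]),
                               labels[tr], k = k, seed = seed + f)
    mdl <- dxModel(pca, clf, inputScale = "log2")
    pr <- predict(mdl, x[!tr, , drop = FALSE], inputScale = "log2")
    pr$truth <- labels[!tr]
    pr$fold <- f
    preds[[f]] <- pr
  }
  preds <- do.call(rbind, preds)
  cc <- confusionCounts(preds$truth, preds$class)
  metrics <- computeMetrics(cc, scores = preds$margin, labels = preds$truth)
  perFold <- vapply(seq_len(folds), function(f) {
    p <- preds[preds$fold == f, ]
    computeMetrics(confusionCounts(p$truth, p$class))$balancedAccuracy
  }, numeric(1))
  out <- list(metrics = metrics, predictions = preds,
              foldBalancedAccuracy = perFold, folds = as.integer(folds),
              seed = as.integer(seed))
  class(out) <- "CvResult"
  out
}

#' @export
print.CvResult <- function(x, ...) {
  cat("CvResult (", x$folds, "-fold): pooled balanced accuracy ",
      sprintf("%.2f%%", x$metrics$balancedAccuracy), "\n", sep = "")
  invisible(x)
}
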