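#' @import methods
#' @importFrom stats predict
NULL

#' PCAModel: a fitted principal-component model of a biomarker subspace
#'
#' Holds everything needed to project new samples into the principal-component
#' space of the training data: the ordered feature identifiers, the per-feature
#' training means, the orthonormal loading matrix, the eigenvalues of the
#' sample covariance matrix, the derived variance-explained percentages, and
#' the number of components `q` retained for downstream clustering.
#'
#' @slot featureIds character vector of feature (gene) identifiers, in the
#'   order of the rows of `loadings`.
#' @slot centers numeric vector of training feature means (log2 scale).
#' @slot loadings numeric matrix, features x components, orthonormal columns.
#' @slot eigenvalues non-increasing, non-negative eigenvalues of the sample
#'   covariance matrix (variance units).
#' @slot varExplained percentage of total variance per component (sums to 100).
#' @slot cumVarExplained running sum of `varExplained`.
#' @slot q integer count of components retained, `1 <= q <= p`.
#'
#' @seealso [fitPca()], [pcCountCriteria()], [pcaScores()]
#' @export
setClass("PCAModel",
  representation(
    featureIds = "character",
    centers = "numeric",
    loadings = "matrix",
    eigenvalues = "numeric",
    varExplained = "numeric",
    cumVarExplained = "numeric",
    q = "integer"
  )
)

setValidity("PCAModel", function(object) {
  p <- length(object@featureIds)
  msg <- character()
  if (nrow(object@loadings) != p || length(object@centers) != p)
    msg <- c(msg, "loadings rows and centers must match featureIds length")
  k <- ncol(object@loadings)
  if (length(object@eigenvalues) != k)
    msg <- c(msg, "one eigenvalue per loading column required")
  if (any(diff(object@eigenvalues) > 1e-8))
    msg <- c(msg, "eigenvalues must be non-increasing")
  if (any(object@eigenvalues < -1e-8))
    msg <- c(msg, "eigenvalues must be non-negative")
  ortho <- crossprod(object@loadings)
  if (max(abs(ortho - diag(k))) > 1e-8)
    msg <- c(msg, "loading columns must be orthonormal (tolerance 1e-8)")
  if (object@q < 1L || object@q > k)
    msg <- c(msg, "q must lie in [1, ncol(loadings)]")
  if (abs(sum(object@varExplained) - 100) > 1e-6)
    msg <- c(msg, "variance-explained percentages must sum to 100")
  if (length(msg)) msg else TRUE
})

#' KMeansClassifier: a k-means clustering used as a two-class classifier
#'
#' Centroids live in the `q`-dimensional principal-component space of a
#' [PCAModel-class]. Each cluster is mapped to the majority training class of
#' its members; for `k = 2` the map must be onto \{cancer, normal\}.
#'
#' @slot k integer number of clusters.
#' @slot centroids numeric matrix, k x q, cluster centroids in PC space.
#' @slot classMap named character vector mapping cluster id ("1", "2", ...)
#'   to a diagnostic class label.
#' @slot inertia total within-cluster sum of squares at convergence.
#' @slot seed integer seed used for the (multi-restart) fit.
#' @export
setClass("KMeansClassifier",
  representation(
    k = "integer",
    centroids = "matrix",
    classMap = "character",
    inertia = "numeric",
    seed = "integer"
  )
)

setValidity("KMeansClassifier", function(object) {
  msg <- character()
  if (nrow(object@centroids) != object@k)
    msg <- c(msg, "number of centroids must equal k")
  if (length(object@classMap) != object@k)
    msg <- c(msg, "classMap must have one entry per cluster")
  if (is.null(names(object@classMap)) ||
      !setequal(names(object@classMap), as.character(seq_len(object@k))))
    msg <- c(msg, "classMap names must be the cluster ids 1..k")
  if (object@k == 2L && !setequal(object@classMap, c("cancer", "normal")))
    msg <- c(msg, "for k = 2 the classMap must be onto {cancer, normal}")
  if (length(msg)) msg else TRUE
})

#' DxModel: a deployable diagnosis model (PCA projection + k-means assignment)
#'
#' Bundles the fitted [PCAModel-class] and [KMeansClassifier-class] with the
#' expected input scale, so a new sample can be taken from raw biomarker
#' expression to a class call: log2 preprocessing (when `inputScale` is
#' `"linear"`, values are mapped through `log2(x + 1)`), centering with the
#' training feature means, projection onto the top-`q` loadings, and
#' assignment to the nearest centroid. The margin score is
#' `d(normal centroid) - d(cancer centroid)`; positive predicts cancer.
#'
#' @slot pca a [PCAModel-class].
#' @slot clusterer a [KMeansClassifier-class].
#' @slot inputScale default scale of prediction inputs, `"linear"` or
#'   `"log2"`.
#' @seealso [predict,DxModel-method], [saveDxModel()]
#' @export
setClass("DxModel",
  representation(
    pca = "PCAModel",
    clusterer = "KMeansClassifier",
    inputScale = "character"
  )
)

setValidity("DxModel", function(object) {
  msg <- character()
  if (!object@inputScale %in% c("linear", "log2"))
    msg <- c(msg, "inputScale must be 'linear' or 'log2'")
  if (ncol(object@clusterer@centroids) != object@pca@q)
    msg <- c(msg, "centroid dimension must equal the PCA component count q")
  if (length(msg)) msg else TRUE
})

#' @describeIn PCAModel-class feature identifiers of the model
#' @param object a `PCAModel` or `DxModel`
#' @export
setGeneric("featureIds", function(object) standardGeneric("featureIds"))

#' @export
setMethod("featureIds", "PCAModel", function(object) object@featureIds)

#' @export
setMethod("featureIds", "DxModel", function(object) object@pca@featureIds)

#' Eigenvalues of a fitted PCA model
#' @param object a `PCAModel`
#' @export
setGeneric("eigenvalues", function(object) standardGeneric("eigenvalues"))

#' @export
setMethod("eigenvalues", "PCAModel", function(object) object@eigenvalues)

#' Loadings (rotation matrix) of a fitted PCA model
#' @param object a `PCAModel`
#' @export
setGeneric("pcaLoadings", function(object) standardGeneric("pcaLoadings"))

#' @export
setMethod("pcaLoadings", "PCAModel", function(object) object@loadings)

#' Number of retained principal components
#' @param object a `PCAModel` or `DxModel`
#' @export
setGeneric("componentCount", function(object) standardGeneric("componentCount"))

#' @export
setMethod("componentCount", "PCAModel", function(object) object@q)

#' @export
setMethod("componentCount", "DxModel", function(object) object@pca@q)

#' Set the number of retained principal components
#' @param object a `PCAModel`
#' @param value new component count
#' @export
setGeneric("componentCount<-",
  function(object, value) standardGeneric("componentCount<-"))

#' @export
setMethod("componentCount<-", "PCAModel", function(object, value) {
  object@q <- as.integer(value)
  validObject(object)
  object
})

#' Cluster centroids of a k-means classifier
#' @param object a `KMeansClassifier` or `DxModel`
#' @export
setGeneric("centroids", function(object) standardGeneric("centroids"))

#' @export
setMethod("centroids", "KMeansClassifier", function(object) object@centroids)

#' @export
setMethod("centroids", "DxModel", function(object) object@clusterer@centroids)

#' Cluster-to-class map of a k-means classifier
#' @param object a `KMeansClassifier` or `DxModel`
#' @export
setGeneric("classMap", function(object) standardGeneric("classMap"))

#' @export
setMethod("classMap", "KMeansClassifier", function(object) object@classMap)

#' @export
setMethod("classMap", "DxModel", function(object) object@clusterer@classMap)

setMethod("show", "PCAModel", function(object) {
  p <- length(object@featureIds)
  cat("PCAModel on", p, "features,", ncol(object@loadings), "components",
      "(q =", paste0(object@q, ")"), "\n")
  cat("  features:", paste(utils::head(object@featureIds, 5), collapse = ", "),
      if (p > 5) "..." else "", "\n")
  cat("  cumulative variance at q:",
      sprintf("%.2f%%", object@cumVarExplained[object@q]), "\n")
})

setMethod("show", "KMeansClassifier", function(object) {
  cat("KMeansClassifier with k =", object@k, "in",
      ncol(object@centroids), "dimensions\n")
  cat("  cluster -> class:",
      paste(names(object@classMap), object@classMap,
            sep = ":", collapse = ", "), "\n")
})

setMethod("show", "DxModel", function(object) {
  cat("DxModel (", length(object@pca@featureIds), "-gene panel, q = ",
      object@pca@q, ", k = ", object@clusterer@k, ")\n", sep = "")
  cat("  input scale:", object@inputScale, "\n")
  cat("  panel:", paste(object@pca@featureIds, collapse = ", "), "\n")
})
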