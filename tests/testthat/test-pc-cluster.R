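# data whose sample covariance is exactly diag(v1, v2, ...)
diagCovMatrix <- function(vars, n = 20) {
  h <- stats::contr.helmert(n)
  x <- vapply(seq_along(vars), function(j) {
    u <- h[, j] / sqrt(sum(h[, j]^2))
    u * sqrt(vars[j] * (n - 1))
  }, numeric(n))
  colnames(x) <- paste0("f", seq_along(vars))
  x
}

test_that("diagonal covariance gives axis loadings and exact eigenvalues", {
  x <- diagCovMatrix(c(2, 1))
  m <- fitPca(x)
  expect_equal(eigenvalues(m), c(2, 1), tolerance = 1e-10)
  expect_equal(abs(pcaLoadings(m)), diag(2), tolerance = 1e-10,
               ignore_attr = TRUE)
  # sign convention: largest-|entry| element of each column is positive
  expect_true(all(apply(pcaLoadings(m), 2, function(cl) cl[which.max(abs(cl))]) > 0))
})

test_that("full-rank reconstruction round-trips the centered data", {
  set.seed(41)
  x <- matrix(rnorm(40 * 9), ncol = 9,
              dimnames = list(NULL, paste0("g", 1:9)))
  m <- fitPca(x)
  sc <- pcaScores(m, x, q = 9)
  rec <- sc %*% t(pcaLoadings(m))
  centered <- sweep(x, 2, colMeans(x))
  expect_equal(rec, centered, tolerance = 1e-8, ignore_attr = TRUE)
  # eigenvalue sum equals total variance (trace of the covariance)
  expect_equal(sum(eigenvalues(m)), sum(apply(x, 2, var)), tolerance = 1e-8)
})

test_that("degenerate PCA inputs are rejected", {
  x <- cbind(a = rnorm(10), b = rep(1, 10))
  expect_error(fitPca(x), "constant")
  expect_error(fitPca(matrix(1:4, 1)), "2 samples")
})

test_that("variance explained handles edge profiles", {
  expect_equal(varianceExplained(5)$percent, 100)
  ve <- varianceExplained(rep(2, 8))
  expect_equal(ve$percent, rep(100 / 8, 8))
  expect_equal(ve$cumulative[8], 100)
  expect_error(varianceExplained(c(1, 2)), "non-increasing")
  expect_error(varianceExplained(c(0, 0)), "zero")
})

test_that("component-count criteria behave on constructed spectra", {
  # single dominant component
  crit <- pcCountCriteria(c(50, 0.5, 0.4, 0.3))
  expect_identical(crit$kaiser, 1L)
  expect_identical(crit$variance, 1L)
  # p = 1 trivially yields 1
  crit1 <- pcCountCriteria(7)
  expect_identical(crit1$q, 1L)
  # reconciliation is the median of the three counts
  crit2 <- pcCountCriteria(c(40, 10, 3, 0.9, 0.8, 0.7, 0.6), varThreshold = 85)
  expect_identical(crit2$q,
                   as.integer(median(c(crit2$kaiser, crit2$scree,
                                       crit2$variance))))
})

test_that("silhouette search finds the planted number of blobs", {
  set.seed(42)
  blob <- function(center, n) sweep(matrix(rnorm(n * 2, sd = 0.3), ncol = 2),
                                    2, center, "+")
  two <- rbind(blob(c(0, 0), 40), blob(c(6, 0), 40))
  expect_identical(as.integer(silhouetteOptimalK(two, 2:6, seed = 1)), 2L)
  three <- rbind(blob(c(0, 0), 30), blob(c(6, 0), 30), blob(c(3, 5), 30))
  expect_identical(as.integer(silhouetteOptimalK(three, 2:6, seed = 1)), 3L)
  expect_error(silhouetteOptimalK(two, 1:3, seed = 1), "kRange")
})

separableScores <- function(n1 = 60, n0 = 20, gap = 8, seed = 43) {
  set.seed(seed)
  sc <- rbind(matrix(rnorm(n1 * 3), ncol = 3),
              cbind(rnorm(n0, gap), matrix(rnorm(n0 * 2), ncol = 2)))
  colnames(sc) <- paste0("g", 1:3)
  labels <- rep(c("cancer", "normal"), c(n1, n0))
  list(scores = sc, labels = labels)
}

test_that("k-means classifier maps pure clusters exactly", {
  d <- separableScores()
  clf <- fitKmeansClassifier(d$scores, d$labels, seed = 1)
  expect_setequal(classMap(clf), c("cancer", "normal"))
  # training predictions are perfect
  pca <- fitPca(d$scores)        # identity-ish frame to reuse predict()
  componentCount(pca) <- 3L
  clfScores <- fitKmeansClassifier(pcaScores(pca, d$scores), d$labels,
                                   seed = 1)
  mdl <- dxModel(pca, clfScores, inputScale = "log2")
  pr <- predict(mdl, d$scores, inputScale = "log2")
  cm <- computeMetrics(confusionCounts(d$labels, pr$class))
  expect_equal(cm$balancedAccuracy, 100)
})

test_that("label inversion flips the map but not the accuracy", {
  d <- separableScores()
  inv <- ifelse(d$labels == "cancer", "normal", "cancer")
  clf1 <- fitKmeansClassifier(d$scores, d$labels, seed = 2)
  clf2 <- fitKmeansClassifier(d$scores, inv, seed = 2)
  expect_identical(unname(classMap(clf1)),
                   unname(ifelse(classMap(clf2) == "cancer",
                                 "normal", "cancer")))
})

test_that("prediction margins follow the centroid-distance convention", {
  pca <- methods::new("PCAModel",
    featureIds = c("a", "b"), centers = c(a = 0, b = 0),
    loadings = diag(2), eigenvalues = c(2, 1),
    varExplained = c(200 / 3, 100 / 3),
    cumVarExplained = c(200 / 3, 100),
    q = 2L)
  clf <- methods::new("KMeansClassifier",
    k = 2L, centroids = rbind(c(4, 0), c(-4, 0)),
    classMap = c("1" = "cancer", "2" = "normal"),
    inertia = 0, seed = 1L)
  mdl <- dxModel(pca, clf, inputScale = "log2")

  atCancer <- predict(mdl, matrix(c(4, 0), 1, dimnames = list("s1", c("a", "b"))),
                      inputScale = "log2")
  expect_identical(atCancer$class, "cancer")
  expect_equal(atCancer$margin, 8)

  tie <- predict(mdl, matrix(c(0, 3), 1, dimnames = list("s1", c("a", "b"))),
                 inputScale = "log2")
  expect_identical(tie$class, "normal")    # conservative tie rule
  expect_equal(tie$margin, 0)

  # feature order must not matter; missing features must be named
  swapped <- predict(mdl, matrix(c(1, 4), 1,
                                 dimnames = list("s1", c("b", "a"))),
                     inputScale = "log2")
  same <- predict(mdl, matrix(c(4, 1), 1,
                              dimnames = list("s1", c("a", "b"))),
                  inputScale = "log2")
  expect_equal(swapped$margin, same$margin)
  expect_error(predict(mdl, matrix(1, 1, dimnames = list("s1", "a"))),
               "missing feature id\\(s\\): b")
})

test_that("linear-scale inputs get the log2 offset preprocessing", {
  d <- separableScores()
  x <- 2^(d$scores + 8)
  colnames(x) <- c("a", "b", "c")
  pca <- fitPca(log2(x + 1))
  componentCount(pca) <- 2L
  clf <- fitKmeansClassifier(pcaScores(pca, log2(x + 1)), d$labels, seed = 3)
  mdl <- dxModel(pca, clf, inputScale = "linear")
  prLinear <- predict(mdl, x)                       # default linear scale
  prLog <- predict(mdl, log2(x + 1), inputScale = "log2")
  expect_identical(prLinear$class, prLog$class)
  expect_equal(prLinear$margin, prLog$margin, tolerance = 1e-10)
  expect_error(predict(mdl, -x), "non-negative")
})

test_that("training projections reproduce the stored PC scores", {
  set.seed(44)
  x <- matrix(rnorm(30 * 5, 8), ncol = 5,
              dimnames = list(NULL, paste0("g", 1:5)))
  m <- fitPca(x)
  pr <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  flip <- apply(pr$rotation, 2, function(cl) sign(cl[which.max(abs(cl))]))
  expect_equal(pcaScores(m, x, q = 5),
               sweep(pr$x, 2, flip, "*"), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("cross-validation is stratified, seeded, and exact on separable data", {
  d <- separableScores(n1 = 80, n0 = 25)
  colnames(d$scores) <- paste0("g", 1:3)
  cv1 <- crossValidateDx(d$scores, d$labels, folds = 5, seed = 6)
  cv2 <- crossValidateDx(d$scores, d$labels, folds = 5, seed = 6)
  expect_equal(cv1$metrics$balancedAccuracy, 100)
  expect_identical(cv1$predictions, cv2$predictions)
  perFoldCounts <- table(cv1$predictions$fold, cv1$predictions$truth)
  expect_lte(max(perFoldCounts[, "cancer"]) - min(perFoldCounts[, "cancer"]), 1)
  expect_lte(max(perFoldCounts[, "normal"]) - min(perFoldCounts[, "normal"]), 1)
  expect_error(crossValidateDx(d$scores, d$labels, folds = 30, seed = 1),
               "stratification")
})
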