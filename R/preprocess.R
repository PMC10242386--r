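#' Remove genes with minimal variation in expression
#'
#' Drops every gene whose sample standard deviation on the input
#' (normalised-count) scale is strictly below `threshold`; a gene with sd
#' exactly equal to the threshold is retained. Row order of survivors is
#' preserved, so the operation is idempotent.
#'
#' @param x genes-by-samples matrix, or a `SummarizedExperiment` whose first
#'   assay holds the expression values.
#' @param threshold positive standard-deviation cutoff (default 1).
#' @return an object of the same type as `x` containing the retained genes;
#'   the ids of removed genes are available via `attr(, "removed")` (matrix
#'   input) or `metadata(x)$removedGenes` (`SummarizedExperiment` input).
#' @export
filterLowVariance <- function(x, threshold = 1) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L, threshold > 0)
  m <- if (methods::is(x, "SummarizedExperiment"))
    SummarizedExperiment::assay(x) else x
  if (!is.matrix(m) || nrow(m) == 0L || ncol(m) == 0L)
    stop("input error: empty expression matrix", call. = FALSE)
  sds <- rowSds(m)
  keep <- sds >= threshold
  removed <- rownames(m)[!keep]
  if (methods::is(x, "SummarizedExperiment")) {
    out <- x[keep, ]
    S4Vectors::metadata(out)$removedGenes <- removed
  } else {
    out <- m[keep, , drop = FALSE]
    attr(out, "removed") <- removed
  }
  out
}

rowSds <- function(m) {
  n <- ncol(m)
  if (n < 2L) return(rep(0, nrow(m)))
  mu <- rowMeans(m)
  sqrt(rowSums((m - mu)^2) / (n - 1))
}

#' Transform normalised counts to log-CPM with voom precision weights
#'
#' Applies the voom transformation of limma: counts are converted to
#' `log2((y + 0.5) / (libsize + 1) * 1e6)` with library size the column sum,
#' and per-observation precision weights are derived from a lowess trend of
#' sqrt residual standard deviation against mean log-count, evaluated at the
#' fitted log-counts and clamped to the trend's observed range.
#'
#' @param x genes-by-samples matrix of non-negative values (count-like), or a
#'   `SummarizedExperiment` (first assay used).
#' @return a [limma::EList] with elements `E` (log-CPM) and `weights`.
#' @seealso [limma::voom()]
#' @export
voomTransform <- function(x) {
  m <- if (methods::is(x, "SummarizedExperiment"))
    SummarizedExperiment::assay(x) else x
  if (!is.matrix(m) || ncol(m) < 2L)
    stop("input error: voom needs a matrix with at least 2 samples",
         call. = FALSE)
  if (any(!is.finite(m)) || any(m < 0))
    stop("input error: expression values must be finite and non-negative",
         call. = FALSE)
  libsize <- colSums(m)
  if (any(libsize <= 0))
    stop("input error: sample(s) with zero total expression: ",
         paste(colnames(m)[libsize <= 0], collapse = ", "), call. = FALSE)
  limma::voom(m)
}

#' Stratified train/test split of a cohort
#'
#' Splits sample ids into train and test partitions stratified on the target
#' class. Per-class train counts are `round(ratio * class size)` with
#' deterministic round-half-away-from-zero; membership within a class is a
#' seeded uniform draw, so identical seeds give identical splits.
#'
#' @param class character vector of class labels (e.g. `"cancer"`/`"normal"`),
#'   named by sample id, or a `SummarizedExperiment` with a `class` column in
#'   `colData`.
#' @param ratio train fraction, strictly between 0 and 1 (default 0.8).
#' @param seed integer seed.
#' @return a `SplitIndex`: a classed list with `train` and `test` sample ids,
#'   `ratio` and `seed`.
#' @export
stratifiedSplit <- function(class, ratio = 0.8, seed = 1L) {
  if (methods::is(class, "SummarizedExperiment")) {
    cd <- SummarizedExperiment::colData(class)
    cls <- as.character(cd$class)
    names(cls) <- rownames(cd)
    class <- cls
  }
  if (is.null(names(class)))
    names(class) <- paste0("sample", seq_along(class))
  if (!is.numeric(ratio) || length(ratio) != 1L || ratio <= 0 || ratio >= 1)
    stop("ratio must lie strictly between 0 and 1", call. = FALSE)
  tab <- table(class)
  if (length(tab) < 2L)
    stop("stratification error: both classes must be present", call. = FALSE)
  if (any(tab < 2L))
    stop("stratification error: class(es) with fewer than 2 samples: ",
         paste(names(tab)[tab < 2L], collapse = ", "), call. = FALSE)
  set.seed(seed)
  train <- character()
  for (cl in names(tab)) {
    ids <- names(class)[class == cl]
    nTrain <- floor(ratio * length(ids) + 0.5)   # round half away from zero
    train <- c(train, sample(ids, nTrain))
  }
  out <- list(
    train = names(class)[names(class) %in% train],  # preserve input order
    test = names(class)[!names(class) %in% train],
    ratio = ratio,
    seed = as.integer(seed)
  )
  class(out) <- "SplitIndex"
  out
}

#' @export
print.SplitIndex <- function(x, ...) {
  cat("SplitIndex: ", length(x$train), " train / ", length(x$test),
      " test (ratio ", x$ratio, ", seed ", x$seed, ")\n", sep = "")
  invisible(x)
}
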