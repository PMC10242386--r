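#' Boruta all-relevant feature selection
#'
#' Implements the Boruta wrapper algorithm around random-forest importance:
#' at each iteration every feature is paired with a "shadow" copy whose values
#' are independently shuffled across samples, a random forest is fit on the
#' joined matrix, and a feature scores a *hit* when its importance exceeds the
#' maximum importance among all shadows. Importance is the out-of-bag
#' permutation importance scaled by its standard error (the Z-score measure
#' of the original algorithm), which is far more resistant to persistent
#' chance correlations than impurity importance. After each iteration every undecided
#' feature is tested two-sidedly against the Binomial(iterations, 1/2) null
#' with Bonferroni correction over the undecided features: significantly more
#' hits than chance confirms the feature, significantly fewer rejects it.
#' Features still undecided at `maxIter` are reported tentative (and treated
#' as not selected downstream).
#'
#' Features are canonicalised internally by name order, so the confirmed set
#' is invariant to the column order of `x`.
#'
#' @param x samples-by-features numeric matrix with column names.
#' @param y two-level factor (or coercible) of class labels, both present.
#' @param alpha significance level of the binomial decision tests.
#' @param maxIter maximum number of shadow iterations.
#' @param seed integer seed; the run is reproducible.
#' @param numTrees trees per random forest (default 100).
#' @return a classed list (`BorutaResult`) with `decision` (named factor with
#'   levels rejected/tentative/confirmed, in input column order), `hits`,
#'   `nIter`, `alpha`, and `selected` (the confirmed feature names).
#' @export
borutaSelect <- function(x, y, alpha = 0.05, maxIter = 100L, seed = 1L,
                         numTrees = 100L) {
  x <- as.matrix(x)
  if (ncol(x) < 2L)
    stop("input error: at least 2 features required", call. = FALSE)
  if (is.null(colnames(x)))
    colnames(x) <- paste0("feature", seq_len(ncol(x)))
  y <- factor(y)
  if (nlevels(droplevels(y)) < 2L)
    stop("input error: both classes must be present in y", call. = FALSE)
  inputOrder <- colnames(x)
  x <- x[, order(colnames(x)), drop = FALSE]   # canonical feature order
  p <- ncol(x)

  set.seed(seed)
  hits <- stats::setNames(integer(p), colnames(x))
  decision <- stats::setNames(rep("tentative", p), colnames(x))
  iter <- 0L
  while (iter < maxIter && any(decision == "tentative")) {
    iter <- iter + 1L
    shadow <- apply(x, 2, sample)
    colnames(shadow) <- paste0("shadow_", colnames(x))
    rf <- ranger::ranger(
      x = cbind(x, shadow), y = y,
      num.trees = numTrees, importance = "permutation",
      scale.permutation.importance = TRUE,
      seed = sample.int(.Machine$integer.max, 1L), num.threads = 1L
    )
    imp <- rf$variable.importance
    shadowMax <- max(imp[colnames(shadow)])
    hits <- hits + as.integer(imp[colnames(x)] > shadowMax)

    und <- names(decision)[decision == "tentative"]
    m <- length(und)
    pConf <- stats::pbinom(hits[und] - 1L, iter, 0.5, lower.tail = FALSE)
    pRej <- stats::pbinom(hits[und], iter, 0.5)
    decision[und[pmin(1, pConf * m) < alpha]] <- "confirmed"
    decision[und[pmin(1, pRej * m) < alpha]] <- "rejected"
  }
  decision <- factor(decision[inputOrder],
                     levels = c("rejected", "tentative", "confirmed"))
  names(decision) <- inputOrder
  out <- list(decision = decision, hits = hits[inputOrder], nIter = iter,
              alpha = alpha,
              selected = inputOrder[decision == "confirmed"])
  class(out) <- "BorutaResult"
  out
}

#' @export
print.BorutaResult <- function(x, ...) {
  cat("BorutaResult after", x$nIter, "iteration(s):",
      sum(x$decision == "confirmed"), "confirmed,",
      sum(x$decision == "tentative"), "tentative,",
      sum(x$decision == "rejected"), "rejected\n")
  if (length(x$selected))
    cat("  confirmed:", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' Recursive feature elimination with cross-validated subset-size choice
#'
#' Backward selection over a random-forest importance ranking: within each
#' cross-validation resample, features are ranked and subsets of every size
#' are evaluated on the held-out portion; the subset size with the best
#' cross-validated accuracy is chosen (exact ties resolve to the smaller
#' subset), and the kept features are the top-ranked features of that size on
#' the full data. Delegates to [caret::rfe()] with random-forest functions.
#'
#' @param x samples-by-features numeric matrix with column names.
#' @param y two-level factor of class labels.
#' @param folds number of cross-validation folds (default 5); must not exceed
#'   the smaller class size.
#' @param seed integer seed.
#' @param repeats repetitions of the cross-validation (default 5); averaging
#'   the accuracy profile over repeats stabilises the subset-size choice.
#' @return a classed list (`RFEResult`) with `kept` (feature names), the
#'   chosen `optSize`, and the per-size `results` table.
#' @export
rfeSelect <- function(x, y, folds = 5L, seed = 1L, repeats = 5L) {
  x <- as.matrix(x)
  if (ncol(x) < 2L)
    stop("input error: at least 2 features required", call. = FALSE)
  y <- factor(y)
  if (nlevels(droplevels(y)) < 2L)
    stop("input error: both classes must be present in y", call. = FALSE)
  if (folds > min(table(y)))
    stop("configuration error: folds exceed the smallest class size",
         call. = FALSE)
  set.seed(seed)
  ctrl <- caret::rfeControl(functions = caret::rfFuncs, method = "repeatedcv",
                            number = folds, repeats = repeats,
                            verbose = FALSE)
  res <- caret::rfe(x = as.data.frame(x), y = y,
                    sizes = seq_len(ncol(x) - 1L), rfeControl = ctrl)
  out <- list(kept = caret::predictors(res),
              optSize = res$optsize,
              results = res$results,
              seed = as.integer(seed))
  class(out) <- "RFEResult"
  out
}

#' @export
print.RFEResult <- function(x, ...) {
  cat("RFEResult: kept", length(x$kept), "feature(s):",
      paste(x$kept, collapse = ", "), "\n")
  invisible(x)
}

#' Variance inflation factors of a feature matrix
#'
#' `VIF_i = 1 / (1 - R2_i)` where `R2_i` is the goodness-of-fit from
#' regressing feature `i` on all the other features (with intercept). A VIF
#' of 1.0 marks a feature perfectly independent of the rest; `R2 >= 1 -
#' 1e-12` (perfect collinearity) is reported as `Inf`.
#'
#' @param x samples-by-features numeric matrix, >= 2 non-constant features.
#' @return named numeric vector of VIF scores (all >= 1).
#' @export
vifScores <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2L)
    stop("input error: at least 2 features required", call. = FALSE)
  if (is.null(colnames(x)))
    colnames(x) <- paste0("feature", seq_len(ncol(x)))
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop("undefined-R2 error: constant feature(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "), call. = FALSE)
  v <- vapply(seq_len(ncol(x)), function(j) {
    fit <- stats::lm.fit(cbind(1, x[, -j, drop = FALSE]), x[, j])
    r2 <- 1 - sum(fit$residuals^2) / sum((x[, j] - mean(x[, j]))^2)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  stats::setNames(v, colnames(x))
}

#' One elimination decision from a round of VIF scores
#'
#' Applies the iterative-elimination rule to a single round: if the maximum
#' VIF exceeds `threshold`, the feature to remove is the one attaining it
#' (ties resolved to the lexicographically smallest feature id); otherwise
#' nothing is removed.
#'
#' @param vifs named numeric vector of VIF scores.
#' @param threshold multicollinearity cutoff (default 2.0).
#' @return the name of the feature to remove, or `NULL` when all scores pass.
#' @export
vifGate <- function(vifs, threshold = 2) {
  if (max(vifs) <= threshold) return(NULL)
  tied <- names(vifs)[vifs == max(vifs)]
  sort(tied)[1]
}

#' Iterative variance-inflation-factor elimination
#'
#' Repeatedly computes VIF scores and removes the feature with the maximum
#' VIF while it exceeds `threshold`, recording every round. Terminates in at
#' most `ncol(x)` rounds; the final kept set has maximum VIF at or below the
#' threshold (or is a single feature, for which VIF is undefined).
#'
#' @inheritParams vifScores
#' @param threshold multicollinearity cutoff (default 2.0, the level deemed
#'   multicollinear in the discovery pipeline).
#' @return a classed list (`VIFReport`) with `rounds` (each a list with the
#'   round's `vif` scores and the `removed` feature or `NULL`) and `kept`,
#'   the final feature names.
#' @export
vifEliminate <- function(x, threshold = 2) {
  x <- as.matrix(x)
  if (is.null(colnames(x)))
    colnames(x) <- paste0("feature", seq_len(ncol(x)))
  rounds <- list()
  repeat {
    if (ncol(x) < 2L) break
    v <- vifScores(x)
    drop <- vifGate(v, threshold)
    rounds[[length(rounds) + 1L]] <- list(vif = v, removed = drop)
    if (is.null(drop)) break
    x <- x[, setdiff(colnames(x), drop), drop = FALSE]
  }
  out <- list(rounds = rounds, kept = colnames(x), threshold = threshold)
  class(out) <- "VIFReport"
  out
}

#' @export
print.VIFReport <- function(x, ...) {
  cat("VIFReport:", length(x$rounds), "round(s), kept",
      length(x$kept), "feature(s) at threshold", x$threshold, "\n")
  for (i in seq_along(x$rounds)) {
    r <- x$rounds[[i]]
    cat("  round ", i, ": max VIF ", format(max(r$vif), digits = 3),
        if (is.null(r$removed)) " -> stop" else
          paste0(" -> removed ", r$removed), "\n", sep = "")
  }
  invisible(x)
}
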