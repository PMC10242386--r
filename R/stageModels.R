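#' Fit per-gene linear stage-indicator models
#'
#' For each gene, fits `Y = alpha + beta1*x1 + beta2*x2 + beta3*x3 + beta4*x4`
#' by weighted least squares, where `x_s` indicates membership in tumour stage
#' `s` and the intercept `alpha` is the baseline (control) expression. The
#' per-gene coefficients are therefore weighted group-mean contrasts of each
#' stage against the controls. Residual variances are moderated across genes
#' by empirical Bayes (Smyth-style squeezing towards a prior estimated from
#' the spread of all per-gene variances), and the per-gene significance is the
#' moderated F statistic over the four stage coefficients.
#'
#' @param v a [limma::EList] from [voomTransform()] (log-CPM + weights), or a
#'   plain genes-by-samples matrix (unit weights).
#' @param stage integer vector of per-sample stages in 0..4 (0 = control);
#'   every stage must have at least one sample.
#' @return data.frame with one row per gene: `alpha`, `beta1`..`beta4`, `lfc`
#'   (the largest-magnitude stage coefficient, signed), `sigma2` (residual
#'   variance), `df` (residual degrees of freedom), `statistic` (moderated F
#'   over the stage coefficients), `p` and BH-adjusted `adjp`. The moderation
#'   hyperparameters are attached as `attr(, "moderation")` (`d0`, `s02`,
#'   `s2post`).
#' @export
fitLinearStageModel <- function(v, stage) {
  stage <- as.integer(stage)
  ns <- ncol(if (methods::is(v, "EList")) v$E else v)
  if (length(stage) != ns)
    stop("stage vector must match the number of samples", call. = FALSE)
  missing <- setdiff(0:4, unique(stage))
  if (length(missing))
    stop("rank-deficiency error: no samples in stage(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  design <- cbind(alpha = 1,
                  beta1 = as.integer(stage == 1L),
                  beta2 = as.integer(stage == 2L),
                  beta3 = as.integer(stage == 3L),
                  beta4 = as.integer(stage == 4L))
  fit <- limma::lmFit(v, design)
  eb <- limma::eBayes(fit)
  tt <- limma::topTable(eb, coef = 2:5, number = Inf, sort.by = "none")
  betas <- as.matrix(tt[, c("beta1", "beta2", "beta3", "beta4")])
  lfc <- betas[cbind(seq_len(nrow(betas)), max.col(abs(betas), "first"))]
  p <- tt$P.Value
  out <- data.frame(
    gene = rownames(fit$coefficients),
    alpha = fit$coefficients[, "alpha"],
    beta1 = betas[, 1], beta2 = betas[, 2],
    beta3 = betas[, 3], beta4 = betas[, 4],
    lfc = lfc,
    sigma2 = fit$sigma^2,
    df = fit$df.residual,
    statistic = tt$F,
    p = p,
    adjp = bhAdjust(p),
    row.names = rownames(fit$coefficients),
    stringsAsFactors = FALSE
  )
  attr(out, "moderation") <- list(d0 = eb$df.prior, s02 = eb$s2.prior,
                                  s2post = eb$s2.post)
  out
}

#' Fit per-gene ordinal (numeric-stage) trend models
#'
#' For each gene, fits `Y = a*X + b` by weighted least squares with the stage
#' treated as a numeric variable `X` in 0..4 (0 = control), then moderates the
#' slope t-statistics by empirical Bayes.
#'
#' @inheritParams fitLinearStageModel
#' @return data.frame with one row per gene: `slope` (`a`, log2 per stage
#'   unit), `intercept` (`b`), `sigma2`, `df`, `statistic` (moderated t of the
#'   slope), `p` and BH-adjusted `adjp`; moderation hyperparameters attached
#'   as for [fitLinearStageModel()].
#' @export
fitOrdinalModel <- function(v, stage) {
  stage <- as.integer(stage)
  ns <- ncol(if (methods::is(v, "EList")) v$E else v)
  if (length(stage) != ns)
    stop("stage vector must match the number of samples", call. = FALSE)
  if (length(unique(stage)) < 2L)
    stop("degenerate-design error: all samples share one stage",
         call. = FALSE)
  design <- cbind(intercept = 1, X = as.numeric(stage))
  fit <- limma::lmFit(v, design)
  eb <- limma::eBayes(fit)
  p <- eb$p.value[, "X"]
  out <- data.frame(
    gene = rownames(fit$coefficients),
    slope = fit$coefficients[, "X"],
    intercept = fit$coefficients[, "intercept"],
    sigma2 = fit$sigma^2,
    df = fit$df.residual,
    statistic = eb$t[, "X"],
    p = p,
    adjp = bhAdjust(p),
    row.names = rownames(fit$coefficients),
    stringsAsFactors = FALSE
  )
  attr(out, "moderation") <- list(d0 = eb$df.prior, s02 = eb$s2.prior,
                                  s2post = eb$s2.post)
  out
}

#' Empirical-Bayes moderation of per-gene residual variances
#'
#' Estimates the prior degrees of freedom `d0` and prior variance `s02` by
#' matching moments of the scaled-F distribution of the per-gene residual
#' variances (Smyth's procedure), and squeezes each gene's variance towards
#' the prior: `s2post = (d0*s02 + df*s2) / (d0 + df)`. When the variances
#' show no excess spread over chi-square sampling noise, `d0` is infinite and
#' every posterior variance equals `s02`.
#'
#' @param s2 per-gene residual variances (length >= 2).
#' @param df residual degrees of freedom (scalar or per gene, positive).
#' @return list with `d0`, `s02` and `s2post`.
#' @export
moderateVariances <- function(s2, df) {
  if (length(s2) < 2L)
    stop("need at least 2 genes with positive residual df", call. = FALSE)
  if (all(s2 == 0))
    stop("degenerate-moderation error: all residual variances are zero",
         call. = FALSE)
  sq <- limma::squeezeVar(s2, df)
  list(d0 = sq$df.prior, s02 = sq$var.prior, s2post = sq$var.post)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin validated wrapper around `stats::p.adjust(method = "BH")`:
#' `adj_i = min over {j : p_j >= p_i} of (m * p_j / rank_j)`, capped at 1,
#' input order preserved.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values in the input order.
#' @export
bhAdjust <- function(p) {
  if (!is.numeric(p) || any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("input error: p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

rankGenes <- function(adjp, p, lfc, gene) {
  ord <- order(adjp, p, -abs(lfc), gene)
  rk <- integer(length(ord))
  rk[ord] <- seq_along(ord)
  rk
}

#' Rank genes under both stage models and form the consensus set
#'
#' Ranks genes by ascending BH-adjusted p-value under each model (ties broken
#' by ascending raw p, then descending |lfc|, then gene id), takes the top
#' `topN` of each ranking, and returns their intersection restricted to genes
#' significant (`adjp < alpha`) under *both* models.
#'
#' @param linear output of [fitLinearStageModel()].
#' @param ordinal output of [fitOrdinalModel()].
#' @param topN number of top-ranked genes per model to intersect (default 15).
#' @param alpha adjusted-p significance threshold both models must meet
#'   (default 1e-5).
#' @return a classed list (`ConsensusResult`) with `consensus` (gene ids,
#'   ordered by linear-model rank) and `table`, a per-gene data.frame with
#'   columns `gene`, `lfc`, `p_linear`, `adjp_linear`, `p_ordinal`,
#'   `adjp_ordinal`, `rank_linear`, `rank_ordinal`.
#' @export
rankAndConsensus <- function(linear, ordinal, topN = 15L, alpha = 1e-5) {
  if (!setequal(linear$gene, ordinal$gene))
    stop("input error: the two tables must cover the same genes",
         call. = FALSE)
  ordinal <- ordinal[match(linear$gene, ordinal$gene), ]
  n <- nrow(linear)
  if (topN > n)
    stop("input error: topN exceeds the number of genes", call. = FALSE)
  rkL <- rankGenes(linear$adjp, linear$p, linear$lfc, linear$gene)
  rkO <- rankGenes(ordinal$adjp, ordinal$p, ordinal$slope, ordinal$gene)
  tab <- data.frame(
    gene = linear$gene,
    lfc = linear$lfc,
    p_linear = linear$p,
    adjp_linear = linear$adjp,
    p_ordinal = ordinal$p,
    adjp_ordinal = ordinal$adjp,
    rank_linear = rkL,
    rank_ordinal = rkO,
    row.names = linear$gene,
    stringsAsFactors = FALSE
  )
  topL <- tab$gene[rkL <= topN]
  topO <- tab$gene[rkO <= topN]
  cons <- intersect(topL, topO)
  pass <- tab[cons, "adjp_linear"] < alpha & tab[cons, "adjp_ordinal"] < alpha
  cons <- cons[pass]
  cons <- cons[order(tab[cons, "rank_linear"])]
  out <- list(consensus = cons, table = tab, topN = as.integer(topN),
              alpha = alpha)
  class(out) <- "ConsensusResult"
  out
}

#' @export
print.ConsensusResult <- function(x, ...) {
  cat("ConsensusResult: ", length(x$consensus), " consensus gene(s) of top-",
      x$topN, " per model at adj. p < ", format(x$alpha), "\n", sep = "")
  if (length(x$consensus))
    cat("  ", paste(x$consensus, collapse = ", "), "\n")
  invisible(x)
}
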