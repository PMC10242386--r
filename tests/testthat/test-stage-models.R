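buildVoomCohort <- function(cfg) {
  se <- simulateCohort(cfg)
  list(se = se, v = voomTransform(SummarizedExperiment::assay(se)),
       stage = se$stage)
}

test_that("indicator-design coefficients are group-mean contrasts", {
  set.seed(14)
  stage <- stageVector(6, 6)
  n <- length(stage)
  E <- matrix(rnorm(20 * n, 8), nrow = 20,
              dimnames = list(sprintf("g%02d", 1:20), sprintf("s%02d", 1:n)))
  E[1, ] <- 5                                 # identical means everywhere
  E[2, stage == 0] <- 5                       # control mean 5, stage-1 mean 7
  E[2, stage == 1] <- 7
  fit <- fitLinearStageModel(E, stage)
  expect_equal(fit["g01", "alpha"], 5, tolerance = 1e-12)
  expect_equal(unlist(fit["g01", paste0("beta", 1:4)]), rep(0, 4),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(fit["g02", "beta1"], 2, tolerance = 1e-12)
})

test_that("weighted fits match a brute-force normal-equations solve", {
  set.seed(15)
  stage <- sample(stageVector(6, 6))
  n <- length(stage)
  E <- matrix(rnorm(15 * n, 6, 2), nrow = 15,
              dimnames = list(sprintf("g%02d", 1:15), sprintf("s%02d", 1:n)))
  W <- matrix(runif(15 * n, 0.5, 2), nrow = 15, dimnames = dimnames(E))
  v <- makeEList(E, W)
  X <- cbind(1, sapply(1:4, function(s) as.integer(stage == s)))

  linFit <- fitLinearStageModel(v, stage)
  for (g in rownames(E)) {
    w <- W[g, ]
    bruteforce <- solve(t(X) %*% (w * X), t(X) %*% (w * E[g, ]))
    got <- unlist(linFit[g, c("alpha", paste0("beta", 1:4))])
    expect_equal(got, as.numeric(bruteforce), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }

  ordFit <- fitOrdinalModel(v, stage)
  for (g in rownames(E)) {
    w <- W[g, ]; x <- stage; y <- E[g, ]
    xw <- sum(w * x) / sum(w); yw <- sum(w * y) / sum(w)
    slope <- sum(w * (x - xw) * (y - yw)) / sum(w * (x - xw)^2)
    expect_equal(ordFit[g, "slope"], slope, tolerance = 1e-10)
  }
})

test_that("ordinal model recovers an exact linear trend", {
  set.seed(16)
  stage <- stageVector(5, 5)
  n <- length(stage)
  E <- matrix(rnorm(10 * n, 6), nrow = 10,
              dimnames = list(sprintf("g%02d", 1:10), sprintf("s%02d", 1:n)))
  E[1, ] <- 2 * stage + 1
  E[2, ] <- 4
  fit <- fitOrdinalModel(E, stage)
  expect_equal(fit["g01", "slope"], 2, tolerance = 1e-12)
  expect_equal(fit["g01", "intercept"], 1, tolerance = 1e-12)
  expect_equal(fit["g01", "sigma2"], 0, tolerance = 1e-12)
  expect_equal(fit["g02", "slope"], 0, tolerance = 1e-12)
})

test_that("degenerate designs are rejected with the stage named", {
  E <- matrix(rnorm(40), nrow = 4)
  expect_error(fitLinearStageModel(E, c(0, 0, 1, 1, 2, 2, 3, 3, 1, 1)),
               "stage\\(s\\) 4")
  expect_error(fitOrdinalModel(E, rep(2, 10)), "degenerate-design")
})

test_that("equal residual variances squeeze to the common value", {
  md <- moderateVariances(rep(2, 50), df = 10)
  expect_true(is.infinite(md$d0))
  expect_equal(md$s2post, rep(2, 50), tolerance = 1e-8)
  expect_error(moderateVariances(rep(0, 10), 5), "zero")
})

test_that("posterior variances are convex combinations of s2 and s02", {
  set.seed(17)
  s2 <- 0.25 * 4 / rchisq(200, 4) * rchisq(200, 10) / 10
  md <- moderateVariances(s2, df = 10)
  expect_true(is.finite(md$d0) && md$d0 > 0)
  lo <- pmin(s2, md$s02) - 1e-10
  hi <- pmax(s2, md$s02) + 1e-10
  expect_true(all(md$s2post >= lo & md$s2post <= hi))
})

test_that("moderation hyperparameters are recovered from simulated variances", {
  set.seed(18)
  d0 <- 4; s02 <- 0.25; df <- 10; nGenes <- 1000
  sigma2 <- d0 * s02 / rchisq(nGenes, d0)
  s2 <- sigma2 * rchisq(nGenes, df) / df
  md <- moderateVariances(s2, df)
  expect_lt(abs(md$d0 - d0) / d0, 0.5)
  expect_lt(abs(md$s02 - s02) / s02, 0.2)
})

test_that("moderated t at zero prior df is the ordinary t", {
  set.seed(19)
  stage <- stageVector(5, 5)
  y <- 0.5 * stage + rnorm(length(stage))
  fit <- stats::lm(y ~ stage)
  s2 <- sum(residuals(fit)^2) / fit$df.residual
  d0 <- 0
  s2post <- (d0 * 1 + fit$df.residual * s2) / (d0 + fit$df.residual)
  expect_equal(s2post, s2)
  seUnscaled <- sqrt(diag(solve(crossprod(model.matrix(fit)))))[2]
  tMod <- coef(fit)[2] / (sqrt(s2post) * seUnscaled)
  expect_equal(as.numeric(tMod), summary(fit)$coefficients[2, "t value"],
               tolerance = 1e-10)
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bhAdjust(0.04), 0.04)
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")

  bruteBH <- function(p) {
    m <- length(p)
    rk <- rank(p, ties.method = "first")
    vapply(seq_len(m), function(i) {
      min(1, min(m * p[p >= p[i]] / rk[p >= p[i]]))
    }, numeric(1))
  }
  set.seed(20)
  for (rep in 1:20) {
    p <- runif(sample(1:100, 1))
    expect_equal(bhAdjust(p), bruteBH(p), tolerance = 1e-12)
  }
  # monotone in the raw values
  p <- runif(50)
  adj <- bhAdjust(p)
  ord <- order(p)
  expect_true(all(diff(adj[ord]) >= -1e-12))
})

makeStatTables <- function(pLin, pOrd, genes = sprintf("g%02d", seq_along(pLin))) {
  list(
    linear = data.frame(gene = genes, p = pLin, adjp = bhAdjust(pLin),
                        lfc = rep(2, length(genes)), row.names = genes),
    ordinal = data.frame(gene = genes, p = pOrd, adjp = bhAdjust(pOrd),
                         slope = rep(1, length(genes)), row.names = genes)
  )
}

test_that("consensus is the significant intersection of the two top lists", {
  n <- 40
  # identical rankings: full overlap
  p <- seq_len(n) * 1e-12
  tt <- makeStatTables(p, p)
  cons <- rankAndConsensus(tt$linear, tt$ordinal, topN = 15, alpha = 1e-5)
  expect_length(cons$consensus, 15)

  # disjoint top-15 lists: empty consensus
  pLin <- c(seq_len(15) * 1e-12, 16:n * 1e-3)
  pOrd <- c(seq_len(15) * 1e-3, (16:n - 15) * 1e-12)
  tt <- makeStatTables(pLin, pOrd)
  cons <- rankAndConsensus(tt$linear, tt$ordinal, topN = 15, alpha = 1e-5)
  expect_length(cons$consensus, 0)

  # 11 shared of 15, the configuration reported for the real cohort
  pLin <- rep(0.5, n); pOrd <- rep(0.5, n)
  pLin[1:15] <- seq_len(15) * 1e-12          # linear top-15 = g01..g15
  pOrd[c(1:11, 25:28)] <- seq_len(15) * 1e-12 # ordinal shares g01..g11
  tt <- makeStatTables(pLin, pOrd)
  cons <- rankAndConsensus(tt$linear, tt$ordinal, topN = 15, alpha = 1e-5)
  expect_length(cons$consensus, 11)
  expect_setequal(cons$consensus, sprintf("g%02d", 1:11))

  expect_error(rankAndConsensus(tt$linear, tt$ordinal, topN = 99), "topN")
  tabs <- cons$table
  expect_setequal(tabs$rank_linear, seq_len(n))
  expect_setequal(tabs$rank_ordinal, seq_len(n))
  expect_true(all(tabs$adjp_linear >= tabs$p_linear))
})

test_that("planted signal genes dominate the linear ranking", {
  se <- simulateCohort(cohortConfig(effectSize = 2, noiseSd = 0.5, seed = 23))
  v <- voomTransform(SummarizedExperiment::assay(se))
  lin <- fitLinearStageModel(v, se$stage)
  ord <- fitOrdinalModel(v, se$stage)
  cons <- rankAndConsensus(lin, ord)
  planted <- plantedGenes(se)
  topTwice <- cons$table$gene[cons$table$rank_linear <= 2 * length(planted)]
  expect_gte(sum(planted %in% topTwice), ceiling(0.9 * length(planted)))
})

test_that("raw linear-model p-values are calibrated on null cohorts", {
  se <- simulateCohort(cohortConfig(nGenes = 1500, nLinearSignal = 0,
                                    nOrdinalSignal = 0, nFlat = 0, seed = 24))
  v <- voomTransform(SummarizedExperiment::assay(se))
  lin <- fitLinearStageModel(v, se$stage)
  frac <- mean(lin$p < 0.05)
  expect_gte(frac, 0.03)
  expect_lte(frac, 0.07)
})
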