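# Shared fixture builders. Everything is generated in code; no stored data.

# matrix whose g-th gene has sample sd exactly sds[g] (exact in floating
# point: the base pattern has mean 0 and sum of squares n - 1)
sdMatrix <- function(sds, n = 10, base = 50) {
  z <- c(-1.5, -1.5, rep(0, n - 4), 1.5, 1.5)   # ss = 9 = n - 1 for n = 10
  stopifnot(n == 10)
  m <- t(vapply(sds, function(s) base + s * z, numeric(n)))
  rownames(m) <- sprintf("g%02d", seq_along(sds))
  colnames(m) <- sprintf("s%02d", seq_len(n))
  m
}

# deterministic stage vector: nc controls then ns per stage 1..4
stageVector <- function(nc, ns) c(rep(0L, nc), rep(1:4, each = ns))

# EList-like voom container with explicit weights
makeEList <- function(E, weights = NULL) {
  if (is.null(weights)) weights <- matrix(1, nrow(E), ncol(E))
  cls <- methods::getClassDef("EList", package = "limma")
  methods::new(cls, list(E = E, weights = weights))
}

# n samples x p features of two separated Gaussian classes (for selectors)
twoClassMatrix <- function(n = 120, pSignal = 3, pNoise = 3, delta = 2,
                           sd = 1, seed = 1, fracCancer = 0.5) {
  set.seed(seed)
  nCancer <- round(n * fracCancer)
  y <- c(rep("cancer", nCancer), rep("normal", n - nCancer))
  shift <- ifelse(y == "cancer", delta, 0)
  x <- cbind(
    vapply(seq_len(pSignal), function(j) shift + rnorm(n, sd = sd),
           numeric(n)),
    vapply(seq_len(pNoise), function(j) rnorm(n, sd = sd), numeric(n))
  )
  colnames(x) <- c(sprintf("sig%d", seq_len(pSignal)),
                   sprintf("noise%d", seq_len(pNoise)))
  rownames(x) <- sprintf("s%03d", seq_len(n))
  list(x = x, y = factor(y, levels = c("cancer", "normal")),
       signal = sprintf("sig%d", seq_len(pSignal)))
}

plantedGenes <- function(se) {
  rd <- SummarizedExperiment::rowData(se)
  rownames(rd)[rd$isLinearSignal | rd$isOrdinalSignal]
}
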