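detectDelimiter <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L)
    stop("parse error: empty file ", path, call. = FALSE)
  if (grepl("\t", first)) "\t" else ","
}

#' Read a gene-by-sample expression matrix from delimited text
#'
#' Expects a header row of sample ids and a first column of gene ids; the
#' delimiter (tab or comma) is auto-detected from the header line. Gene and
#' sample ids must be unique and every cell numeric, finite and non-negative;
#' violations raise parse errors naming the offending id or line.
#'
#' @param path path to a tab- or comma-delimited text file.
#' @return numeric matrix with gene ids as rownames, sample ids as colnames.
#' @export
readExpressionMatrix <- function(path) {
  sep <- detectDelimiter(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          comment.char = "", check.names = FALSE,
                          stringsAsFactors = FALSE, colClasses = NA)
  if (ncol(df) < 2L)
    stop("parse error: expected a gene-id column plus sample columns",
         call. = FALSE)
  genes <- as.character(df[[1]])
  dup <- genes[duplicated(genes)]
  if (length(dup))
    stop("parse error: duplicate gene id(s): ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  samples <- colnames(df)[-1]
  dupS <- samples[duplicated(samples)]
  if (length(dupS))
    stop("parse error: duplicate sample id(s): ",
         paste(unique(dupS), collapse = ", "), call. = FALSE)
  vals <- df[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    if (!is.numeric(vals[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(vals[[j]]))))[1]
      stop("parse error: non-numeric value in column '", samples[j],
           "', line ", bad + 1L, call. = FALSE)
    }
  }
  m <- as.matrix(vals)
  if (any(!is.finite(m)) || any(m < 0))
    stop("parse error: expression values must be finite and non-negative",
         call. = FALSE)
  dimnames(m) <- list(genes, samples)
  m
}

#' Read a sample annotation table (sample id, class, stage)
#'
#' Validates that classes are in `{cancer, normal}`, stages in 0..4, and that
#' `class == "normal"` iff `stage == 0`.
#'
#' @param path tab- or comma-delimited text with columns `sample_id`, `class`,
#'   `stage`.
#' @return data.frame with those columns, `sample_id` as rownames.
#' @export
readSampleAnnotation <- function(path) {
  sep <- detectDelimiter(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "class", "stage")
  if (!all(need %in% colnames(df)))
    stop("parse error: annotation needs columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (any(duplicated(df$sample_id)))
    stop("parse error: duplicate sample id(s)", call. = FALSE)
  if (!all(df$class %in% c("cancer", "normal")))
    stop("parse error: class must be 'cancer' or 'normal'", call. = FALSE)
  if (!all(df$stage %in% 0:4))
    stop("parse error: stage must lie in 0..4", call. = FALSE)
  if (any((df$class == "normal") != (df$stage == 0)))
    stop("parse error: class 'normal' must coincide with stage 0",
         call. = FALSE)
  rownames(df) <- df$sample_id
  df
}

#' Write an expression matrix as tab-delimited text
#'
#' Genes as rows with a leading `gene_id` column, sample ids as the header.
#'
#' @param m genes-by-samples matrix with dimnames.
#' @param path output path.
#' @export
writeExpressionMatrix <- function(m, path) {
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a synthetic cohort to a directory as plain text
#'
#' Writes `expression.tsv` (genes x samples), `annotation.tsv`
#' (sample_id, class, stage) and `truth.tsv` (per-gene ground-truth flags,
#' offsets and slope).
#'
#' @param se a cohort `SummarizedExperiment` from [simulateCohort()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeCohort <- function(se, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  writeExpressionMatrix(SummarizedExperiment::assay(se),
                        file.path(dir, "expression.tsv"))
  cd <- SummarizedExperiment::colData(se)
  ann <- data.frame(sample_id = rownames(cd), class = cd$class,
                    stage = cd$stage, stringsAsFactors = FALSE)
  utils::write.table(ann, file.path(dir, "annotation.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  rd <- as.data.frame(SummarizedExperiment::rowData(se))
  rd <- data.frame(gene_id = rownames(rd), rd, stringsAsFactors = FALSE)
  utils::write.table(rd, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Write the per-gene statistics table as tab-delimited text
#'
#' @param consensus a `ConsensusResult` from [rankAndConsensus()].
#' @param path output path.
#' @export
writeGeneStatTable <- function(consensus, path) {
  utils::write.table(consensus$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Persist a diagnosis model as a versioned JSON document
#'
#' Stores feature ids, training means, loadings, eigenvalues, the retained
#' component count, centroids, the cluster-to-class map and the input-scale
#' flag; [loadDxModel()] reconstructs a validated [DxModel-class] from it.
#'
#' @param model a [DxModel-class].
#' @param path output path.
#' @export
saveDxModel <- function(model, path) {
  doc <- list(
    format = "panelDx-model",
    version = 1L,
    featureIds = model@pca@featureIds,
    centers = model@pca@centers,
    loadings = model@pca@loadings,
    eigenvalues = model@pca@eigenvalues,
    q = model@pca@q,
    k = model@clusterer@k,
    centroids = model@clusterer@centroids,
    classMap = as.list(model@clusterer@classMap),
    inertia = model@clusterer@inertia,
    seed = model@clusterer@seed,
    inputScale = model@inputScale
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname saveDxModel
#' @return `loadDxModel` returns the reconstructed [DxModel-class].
#' @export
loadDxModel <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$format) || doc$format != "panelDx-model")
    stop("parse error: not a panelDx model document", call. = FALSE)
  pct <- 100 * doc$eigenvalues / sum(doc$eigenvalues)
  pca <- methods::new("PCAModel",
    featureIds = doc$featureIds,
    centers = stats::setNames(as.numeric(doc$centers), doc$featureIds),
    loadings = as.matrix(doc$loadings),
    eigenvalues = as.numeric(doc$eigenvalues),
    varExplained = pct,
    cumVarExplained = cumsum(pct),
    q = as.integer(doc$q))
  clf <- methods::new("KMeansClassifier",
    k = as.integer(doc$k),
    centroids = as.matrix(doc$centroids),
    classMap = stats::setNames(unlist(doc$classMap), names(doc$classMap)),
    inertia = as.numeric(doc$inertia),
    seed = as.integer(doc$seed))
  dxModel(pca, clf, inputScale = doc$inputScale)
}
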