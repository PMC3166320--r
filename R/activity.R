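#' Construct an ExpressionDataset
#'
#' @param values numeric gene-by-sample matrix with row and column names.
#' @param condition character/factor of \code{"disease"} / \code{"control"}
#'   per sample (column order).
#' @param dataset provenance label.
#' @return An [ExpressionDataset-class]. A warning is emitted when either
#'   condition has fewer than four samples (the usual inclusion threshold
#'   for case/control microarray studies).
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' expressionDataset(m, c("disease", "disease", "control", "control"))
#' @export
expressionDataset <- function(values, condition, dataset = NA_character_) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix must have gene rownames and sample colnames")
  condition <- as.character(condition)
  if (length(condition) != ncol(values))
    stop("one condition label per sample required")
  if (any(table(factor(condition, c("disease", "control"))) < 4))
    warning("fewer than four samples in a condition; ",
            "activity estimates will be noisy")
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = values),
    colData = S4Vectors::DataFrame(condition = condition,
                                   row.names = colnames(values)),
    metadata = list(dataset = as.character(dataset),
                    rankTransformed = FALSE))
  out <- methods::as(se, "ExpressionDataset")
  methods::validObject(out)
  out
}

#' Load an expression matrix with sample labels
#'
#' The expression file is a TSV whose first column holds gene (or probe)
#' identifiers and whose header row holds sample identifiers. Labels come
#' from a separate 2-column TSV (\code{sample_id}, \code{disease|control}).
#' An optional probe-to-gene map (2-column TSV: \code{probe_id},
#' \code{gene_id}) is applied by averaging probe rows per gene on the raw
#' scale before any ranking.
#'
#' @param path expression TSV.
#' @param labelsPath sample label TSV.
#' @param probeMapPath optional probe-to-gene TSV.
#' @param impute if TRUE, missing values are replaced by the column median;
#'   otherwise missing values are an error.
#' @param dataset provenance label (defaults to the file name).
#' @return An [ExpressionDataset-class].
#' @export
loadExpression <- function(path, labelsPath, probeMapPath = NULL,
                           impute = FALSE, dataset = basename(path)) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                           comment.char = "#", check.names = FALSE,
                           stringsAsFactors = FALSE)
  ids <- as.character(tab[[1]])
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids

  if (!is.null(probeMapPath)) {
    pm <- utils::read.table(probeMapPath, sep = "\t", quote = "",
                            comment.char = "#", stringsAsFactors = FALSE,
                            col.names = c("probe_id", "gene_id"),
                            colClasses = "character")
    hit <- rownames(m) %in% pm$probe_id
    if (!any(hit)) stop("no probes of ", path, " found in the probe map")
    m <- m[hit, , drop = FALSE]
    gene <- pm$gene_id[match(rownames(m), pm$probe_id)]
    m <- .averageByGene(m, gene)
  } else if (anyDuplicated(rownames(m))) {
    m <- .averageByGene(m, rownames(m))
  }

  if (anyNA(m)) {
    if (!impute) stop("missing expression values in ", path,
                      " (set impute = TRUE for column-median imputation)")
    for (j in seq_len(ncol(m))) {
      nas <- is.na(m[, j])
      m[nas, j] <- stats::median(m[, j], na.rm = TRUE)
    }
  }

  lab <- utils::read.table(labelsPath, sep = "\t", quote = "",
                           comment.char = "#", stringsAsFactors = FALSE,
                           col.names = c("sample_id", "condition"),
                           colClasses = "character")
  idx <- match(colnames(m), lab$sample_id)
  if (anyNA(idx))
    stop("samples without labels: ",
         paste(colnames(m)[is.na(idx)], collapse = ", "))
  expressionDataset(m, lab$condition[idx], dataset = dataset)
}

# average duplicate probe rows per gene on the raw scale
.averageByGene <- function(m, gene) {
  agg <- rowsum(m, group = gene, reorder = TRUE)
  agg / as.vector(table(gene)[rownames(agg)])
}

#' Within-sample rank transformation
#'
#' Replaces each sample's expression values by their within-sample ranks
#' (1 = lowest value; ties get the average of tied ranks), making expression
#' levels comparable across platforms and experiments.
#'
#' @param dataset an [ExpressionDataset-class].
#' @return The dataset with ranked values (idempotent on already-ranked
#'   data; a second call re-ranks ranks, which is a no-op).
#' @examples
#' m <- matrix(c(5, 1, 3, 2, 2, 9), 3, 2,
#'             dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' d <- expressionDataset(m, c("disease", "control"))
#' SummarizedExperiment::assay(suppressWarnings(rankTransform(d)))
#' @export
setGeneric("rankTransform", function(dataset) standardGeneric("rankTransform"))

#' @rdname rankTransform
#' @export
setMethod("rankTransform", "ExpressionDataset", function(dataset) {
  m <- SummarizedExperiment::assay(dataset)
  if (!nrow(m) || !ncol(m)) stop("empty expression matrix")
  ranked <- apply(m, 2, rank, ties.method = "average")
  dimnames(ranked) <- dimnames(m)
  SummarizedExperiment::assay(dataset) <- ranked
  S4Vectors::metadata(dataset)$rankTransformed <- TRUE
  dataset
})

#' Per-gene disease activity from a case/control expression dataset
#'
#' The activity of a gene is the magnitude-only differential-expression
#' signal \eqn{x_g = | \log_2( \bar r^{disease}_g / \bar r^{control}_g ) |},
#' where \eqn{\bar r} are mean within-sample expression ranks. The dataset is
#' rank-transformed first if it has not been already.
#'
#' @param dataset an [ExpressionDataset-class].
#' @return An [ActivityVector-class] over the dataset's genes.
#' @examples
#' m <- matrix(c(10, 1, 2, 8, 1, 9, 2, 7), 2, 4,
#'             dimnames = list(c("gA", "gB"), paste0("s", 1:4)))
#' d <- suppressWarnings(
#'   expressionDataset(m, c("disease", "disease", "control", "control")))
#' activityValues(computeActivity(d))
#' @export
setGeneric("computeActivity",
           function(dataset) standardGeneric("computeActivity"))

#' @rdname computeActivity
#' @export
setMethod("computeActivity", "ExpressionDataset", function(dataset) {
  if (!isTRUE(S4Vectors::metadata(dataset)$rankTransformed))
    dataset <- rankTransform(dataset)
  m <- SummarizedExperiment::assay(dataset)
  cond <- as.character(SummarizedExperiment::colData(dataset)$condition)
  md <- rowMeans(m[, cond == "disease", drop = FALSE])
  mc <- rowMeans(m[, cond == "control", drop = FALSE])
  x <- abs(log2(md / mc))               # ranks >= 1, so ratios are positive
  activityVector(x, dataset = S4Vectors::metadata(dataset)$dataset)
})
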