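#' @import methods
#' @importFrom Matrix sparseMatrix diag t isSymmetric nnzero drop0
NULL

setClassUnion("characterOrNULL", c("character", "NULL"))

#' InteractionNetwork: a weighted, undirected gene interaction graph
#'
#' Stores a symmetric gene-by-gene coupling matrix W with weights in
#' \eqn{[0,1]} and a zero diagonal (no self-interactions), as used by the
#' Katz-style score \eqn{s = (I - \phi W)^{-1}(d + \eta x)}.
#'
#' @slot genes character vector of unique gene identifiers (row/column order
#'   of the weight matrix).
#' @slot weights symmetric sparse \code{dgCMatrix} of coupling strengths.
#'
#' @seealso [loadNetwork()], [interactionNetwork()], [maxPhi()],
#'   [solveScores()]
#' @export
setClass("InteractionNetwork",
  representation(genes = "character", weights = "Matrix"))

setValidity("InteractionNetwork", function(object) {
  msg <- character()
  n <- length(object@genes)
  if (anyDuplicated(object@genes))
    msg <- c(msg, "gene identifiers must be unique")
  if (!all(dim(object@weights) == c(n, n)))
    msg <- c(msg, "weight matrix dimensions must match number of genes")
  w <- object@weights
  if (n > 0) {
    if (!Matrix::isSymmetric(w, tol = 0))
      msg <- c(msg, "weight matrix must be symmetric")
    if (any(Matrix::diag(w) != 0))
      msg <- c(msg, "diagonal must be zero (no self-interactions)")
    v <- w@x
    if (length(v) && (min(v) < 0 || max(v) > 1))
      msg <- c(msg, "weights must lie in [0,1]")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an InteractionNetwork from an edge table
#'
#' Duplicate and reciprocal edges are merged keeping the maximum weight;
#' self-loops are dropped (their genes are retained as isolated nodes).
#'
#' @param edges data.frame with columns \code{gene_a}, \code{gene_b},
#'   \code{weight} (already on the \eqn{[0,1]} scale).
#' @param genes optional character vector fixing the gene universe and its
#'   order; defaults to the sorted union of edge endpoints.
#' @return An [InteractionNetwork-class] object.
#' @examples
#' net <- interactionNetwork(data.frame(gene_a = "A", gene_b = "B",
#'                                      weight = 0.7))
#' weightMatrix(net)
#' @export
interactionNetwork <- function(edges, genes = NULL) {
  stopifnot(is.data.frame(edges),
            all(c("gene_a", "gene_b", "weight") %in% names(edges)))
  a <- as.character(edges$gene_a)
  b <- as.character(edges$gene_b)
  w <- as.numeric(edges$weight)
  if (any(!is.finite(w)) || any(w < 0) || any(w > 1))
    stop("edge weights must be finite and in [0,1]")
  if (is.null(genes)) genes <- sort(unique(c(a, b)))
  else if (anyDuplicated(genes)) stop("'genes' must be unique")
  keep <- a != b                       # drop self-loops, keep the nodes
  a <- a[keep]; b <- b[keep]; w <- w[keep]
  i <- match(a, genes); j <- match(b, genes)
  if (anyNA(i) || anyNA(j))
    stop("edge endpoints absent from the supplied gene universe")
  # canonical orientation, then max-merge duplicates/reciprocals
  lo <- pmin(i, j); hi <- pmax(i, j)
  key <- paste(lo, hi)
  if (anyDuplicated(key)) {
    w <- tapply(w, key, max)
    lo <- as.integer(sub(" .*", "", names(w)))
    hi <- as.integer(sub(".* ", "", names(w)))
    w <- as.numeric(w)
  }
  n <- length(genes)
  wm <- Matrix::sparseMatrix(i = c(lo, hi), j = c(hi, lo), x = c(w, w),
                             dims = c(n, n))
  new("InteractionNetwork", genes = genes, weights = wm)
}

#' ActivityVector: per-gene disease activity
#'
#' The nonnegative activity signal x, typically the absolute log2 ratio of
#' mean within-sample expression ranks between disease and control samples.
#'
#' @slot values named nonnegative numeric vector (names are genes).
#' @slot dataset provenance label of the originating dataset.
#' @seealso [computeActivity()], [activityVector()]
#' @export
setClass("ActivityVector",
  representation(values = "numeric", dataset = "character"))

setValidity("ActivityVector", function(object) {
  v <- object@values
  if (length(v) && is.null(names(v))) return("values must be named by gene")
  if (anyDuplicated(names(v))) return("duplicate gene names")
  if (any(!is.finite(v))) return("activities must be finite")
  if (any(v < 0)) return("activities must be nonnegative")
  TRUE
})

#' @rdname ActivityVector-class
#' @param values named nonnegative numeric vector.
#' @param dataset provenance label.
#' @return An \code{ActivityVector}.
#' @examples activityVector(c(BRCA1 = 1.2, TP53 = 0))
#' @export
activityVector <- function(values, dataset = NA_character_) {
  new("ActivityVector", values = values, dataset = as.character(dataset))
}

#' ScoreVector: per-gene prioritization scores
#'
#' Result of solving \eqn{s = \phi W s + d + \eta x} (or its known-gene
#' variant), with solver metadata.
#'
#' @slot values named numeric score per gene.
#' @slot phi,eta parameters used.
#' @slot iterations Jacobi iterations performed.
#' @slot residual final max-norm change between iterates.
#' @seealso [solveScores()], [combineScores()]
#' @export
setClass("ScoreVector",
  representation(values = "numeric", phi = "numeric", eta = "numeric",
                 iterations = "integer", residual = "numeric"))

#' CandidateSet: genes at or near one disease locus
#'
#' @slot disease disease identifier.
#' @slot locus label of the locus the set was built from.
#' @slot genes ordered candidate gene identifiers.
#' @slot benchmark the known disease gene planted in the set (or NULL).
#' @seealso [buildCandidateSet()], [rankInCandidates()]
#' @export
setClass("CandidateSet",
  representation(disease = "character", locus = "character",
                 genes = "character", benchmark = "characterOrNULL"))

setValidity("CandidateSet", function(object) {
  if (length(object@genes) < 2) return("a candidate set needs >= 2 genes")
  if (anyDuplicated(object@genes)) return("duplicate candidate genes")
  if (!is.null(object@benchmark) && !(object@benchmark %in% object@genes))
    return("benchmark gene must be a member of the candidate set")
  TRUE
})

#' @rdname CandidateSet-class
#' @param genes ordered candidate gene identifiers.
#' @param benchmark known disease gene in the set, or NULL.
#' @param disease,locus identifying labels.
#' @return A \code{CandidateSet}.
#' @export
candidateSet <- function(genes, benchmark = NULL,
                         disease = NA_character_, locus = NA_character_) {
  new("CandidateSet", disease = as.character(disease),
      locus = as.character(locus), genes = as.character(genes),
      benchmark = if (is.null(benchmark)) NULL else as.character(benchmark))
}

#' ROCCurve: TPR/FPR over prediction cutoffs
#'
#' Points are indexed by the cutoff h (top-h candidates of every set called
#' positive); the AUROC is the trapezoid area over the points anchored at
#' (0,0) and (1,1).
#'
#' @slot h integer cutoffs.
#' @slot tpr,fpr rates at each cutoff.
#' @slot auroc area under the curve.
#' @seealso [rocAnalysis()], [optimalCutoff()]
#' @export
setClass("ROCCurve",
  representation(h = "integer", tpr = "numeric", fpr = "numeric",
                 auroc = "numeric"))

setValidity("ROCCurve", function(object) {
  if (length(object@h) != length(object@tpr) ||
      length(object@h) != length(object@fpr))
    return("h, tpr, fpr lengths differ")
  if (is.unsorted(object@tpr) || is.unsorted(object@fpr))
    return("TPR and FPR must be nondecreasing in h")
  if (object@auroc < 0 || object@auroc > 1) return("AUROC must be in [0,1]")
  TRUE
})

#' CalibrationResult: outcome of a (phi, eta) grid scan
#'
#' @slot bestPhi,bestEta the grid point minimizing the mean r-ratio
#'   (ties broken by smallest phi, then smallest eta).
#' @slot meanRRatio mean benchmark r-ratio at the optimum.
#' @slot grid data.frame of (phi, eta, meanRRatio) for the full scan.
#' @seealso [calibrateParameters()]
#' @export
setClass("CalibrationResult",
  representation(bestPhi = "numeric", bestEta = "numeric",
                 meanRRatio = "numeric", grid = "data.frame"))

#' AnnotationCatalog: term-to-gene annotation sets
#'
#' @slot terms named list mapping term id to a character vector of genes.
#' @slot universe genes eligible for testing; every term is a subset.
#' @seealso [enrichGroup()], [loadCatalog()]
#' @export
setClass("AnnotationCatalog",
  representation(terms = "list", universe = "character"))

setValidity("AnnotationCatalog", function(object) {
  if (!length(object@terms)) return("catalog has no terms")
  if (is.null(names(object@terms)) || anyDuplicated(names(object@terms)))
    return("terms must be uniquely named")
  if (anyDuplicated(object@universe)) return("duplicate universe genes")
  ok <- vapply(object@terms,
               function(g) all(g %in% object@universe), logical(1))
  if (!all(ok))
    return(sprintf("term genes outside the universe: %s",
                   paste(names(object@terms)[!ok], collapse = ", ")))
  TRUE
})

#' @rdname AnnotationCatalog-class
#' @param terms named list of term -> gene character vectors.
#' @param universe gene universe; defaults to the union of all term genes.
#' @return An \code{AnnotationCatalog}.
#' @export
annotationCatalog <- function(terms, universe = NULL) {
  terms <- lapply(terms, function(g) unique(as.character(g)))
  if (is.null(universe)) universe <- sort(unique(unlist(terms)))
  new("AnnotationCatalog", terms = terms,
      universe = as.character(universe))
}

#' ExpressionDataset: case/control expression matrix
#'
#' A \linkS4class{SummarizedExperiment} whose \code{colData} carries a
#' \code{condition} column with values \code{"disease"} or \code{"control"}.
#'
#' @seealso [expressionDataset()], [rankTransform()], [computeActivity()]
#' @export
setClass("ExpressionDataset", contains = "SummarizedExperiment")

setValidity("ExpressionDataset", function(object) {
  cd <- SummarizedExperiment::colData(object)
  if (!"condition" %in% colnames(cd))
    return("colData must contain a 'condition' column")
  cond <- as.character(cd$condition)
  if (!all(cond %in% c("disease", "control")))
    return("condition values must be 'disease' or 'control'")
  if (!any(cond == "disease") || !any(cond == "control"))
    return("need at least one disease and one control sample")
  if (anyDuplicated(rownames(object)))
    return("duplicate gene rows (average probes before construction)")
  TRUE
})

#' PlantedBenchmark: synthetic prioritization benchmark with known truth
#'
#' A generated interaction network with per-disease planted modules
#' (optionally sharing pleiotropic genes), per-disease activity vectors
#' carrying a partial expression signal, and candidate sets each containing
#' exactly one true disease gene.
#'
#' @slot network the generated [InteractionNetwork-class].
#' @slot activities named list (disease -> list of [ActivityVector-class]),
#'   one element per disease-control dataset.
#' @slot knownGenes named list (disease -> character) of true module genes.
#' @slot candidateSets list of [CandidateSet-class], one per known-gene
#'   instance.
#' @slot params generation parameters.
#' @slot seed seed used.
#' @seealso [makePlantedBenchmark()], [benchmarkEvaluation()]
#' @export
setClass("PlantedBenchmark",
  representation(network = "InteractionNetwork", activities = "list",
                 knownGenes = "list", candidateSets = "list",
                 params = "list", seed = "integer"))
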