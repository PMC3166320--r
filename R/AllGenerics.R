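#' Accessors for katzRank classes
#'
#' \code{genes()} returns the gene universe of an object;
#' \code{weightMatrix()} the symmetric sparse coupling matrix;
#' \code{activityValues()} / \code{scoreValues()} the named numeric payloads;
#' \code{candidateGenes()} and \code{benchmarkGene()} the members and planted
#' gene of a candidate set; \code{numGenes()} / \code{numEdges()} network
#' sizes.
#'
#' @param x a katzRank object.
#' @return The accessed component.
#' @name accessors
#' @aliases genes weightMatrix activityValues scoreValues candidateGenes
#'   benchmarkGene numGenes numEdges
#' @examples
#' net <- interactionNetwork(data.frame(gene_a = "A", gene_b = "B",
#'                                      weight = 0.5))
#' genes(net); numEdges(net)
NULL

#' @rdname accessors
#' @export
setGeneric("genes", function(x) standardGeneric("genes"))
#' @rdname accessors
#' @export
setGeneric("weightMatrix", function(x) standardGeneric("weightMatrix"))
#' @rdname accessors
#' @export
setGeneric("activityValues", function(x) standardGeneric("activityValues"))
#' @rdname accessors
#' @export
setGeneric("scoreValues", function(x) standardGeneric("scoreValues"))
#' @rdname accessors
#' @export
setGeneric("candidateGenes", function(x) standardGeneric("candidateGenes"))
#' @rdname accessors
#' @export
setGeneric("benchmarkGene", function(x) standardGeneric("benchmarkGene"))
#' @rdname accessors
#' @export
setGeneric("numGenes", function(x) standardGeneric("numGenes"))
#' @rdname accessors
#' @export
setGeneric("numEdges", function(x) standardGeneric("numEdges"))

#' @rdname accessors
#' @export
setMethod("genes", "InteractionNetwork", function(x) x@genes)
#' @rdname accessors
#' @export
setMethod("genes", "ActivityVector", function(x) names(x@values))
#' @rdname accessors
#' @export
setMethod("genes", "ScoreVector", function(x) names(x@values))
#' @rdname accessors
#' @export
setMethod("weightMatrix", "InteractionNetwork", function(x) {
  m <- x@weights
  dimnames(m) <- list(x@genes, x@genes)
  m
})
#' @rdname accessors
#' @export
setMethod("activityValues", "ActivityVector", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("scoreValues", "ScoreVector", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("candidateGenes", "CandidateSet", function(x) x@genes)
#' @rdname accessors
#' @export
setMethod("benchmarkGene", "CandidateSet", function(x) x@benchmark)
#' @rdname accessors
#' @export
setMethod("numGenes", "InteractionNetwork", function(x) length(x@genes))
#' @rdname accessors
#' @export
setMethod("numEdges", "InteractionNetwork",
          function(x) Matrix::nnzero(x@weights) / 2L)

setMethod("show", "InteractionNetwork", function(object) {
  cat(sprintf("InteractionNetwork: %d genes, %d edges\n",
              numGenes(object), numEdges(object)))
  if (numEdges(object) > 0) {
    w <- object@weights@x
    cat(sprintf("  weights in [%.3g, %.3g]\n", min(w), max(w)))
  }
})

setMethod("show", "ActivityVector", function(object) {
  v <- object@values
  cat(sprintf("ActivityVector: %d genes (dataset: %s)\n",
              length(v), object@dataset))
  if (length(v))
    cat(sprintf("  activity in [%.3g, %.3g], mean %.3g\n",
                min(v), max(v), mean(v)))
})

setMethod("show", "ScoreVector", function(object) {
  cat(sprintf(
    "ScoreVector: %d genes (phi = %g, eta = %g; %d iterations, residual %.2e)\n",
    length(object@values), object@phi, object@eta, object@iterations,
    object@residual))
})

setMethod("show", "CandidateSet", function(object) {
  cat(sprintf("CandidateSet '%s' (disease %s): %d genes, benchmark %s\n",
              object@locus, object@disease, length(object@genes),
              if (is.null(object@benchmark)) "<none>" else object@benchmark))
})

setMethod("show", "ROCCurve", function(object) {
  cat(sprintf("ROCCurve: %d cutoffs (h = %d..%d), AUROC = %.4f\n",
              length(object@h), min(object@h), max(object@h), object@auroc))
})

setMethod("show", "CalibrationResult", function(object) {
  cat(sprintf(
    "CalibrationResult: best (phi, eta) = (%g, %g), mean r-ratio = %.4f over %d grid points\n",
    object@bestPhi, object@bestEta, object@meanRRatio, nrow(object@grid)))
})

setMethod("show", "AnnotationCatalog", function(object) {
  cat(sprintf("AnnotationCatalog: %d terms over a universe of %d genes\n",
              length(object@terms), length(object@universe)))
})

setMethod("show", "PlantedBenchmark", function(object) {
  cat(sprintf(
    "PlantedBenchmark: %d genes, %d diseases, %d candidate sets (seed %d)\n",
    numGenes(object@network), length(object@knownGenes),
    length(object@candidateSets), object@seed))
})

#' Components of a planted benchmark
#'
#' @param x a [PlantedBenchmark-class].
#' @return \code{benchmarkNetwork}: the network; \code{benchmarkActivities}:
#'   named list of per-disease activity vectors; \code{benchmarkKnownGenes}:
#'   named list of true genes; \code{benchmarkCandidateSets}: list of
#'   candidate sets.
#' @name benchmark-accessors
NULL

#' @rdname benchmark-accessors
#' @export
benchmarkNetwork <- function(x) x@network
#' @rdname benchmark-accessors
#' @export
benchmarkActivities <- function(x) x@activities
#' @rdname benchmark-accessors
#' @export
benchmarkKnownGenes <- function(x) x@knownGenes
#' @rdname benchmark-accessors
#' @export
benchmarkCandidateSets <- function(x) x@candidateSets
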