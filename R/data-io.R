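#' Load a weighted interaction network from an edge-list file
#'
#' Reads a 3-column TSV (\code{gene_a}, \code{gene_b}, \code{score}) of
#' STRING-style confidence scores, normalizes scores to \eqn{[0,1]} by
#' dividing by \code{scoreScale} and clamping, drops self-interactions
#' (keeping the genes as isolated nodes) and merges duplicate or reciprocal
#' rows keeping the maximum weight.
#'
#' @param path edge-list file; lines starting with \code{#} are comments.
#' @param scoreScale positive scale divisor (STRING scores are per-mille,
#'   hence the default 1000).
#' @return An [InteractionNetwork-class].
#' @examples
#' f <- tempfile()
#' writeLines(c("A\tB\t700", "B\tC\t400"), f)
#' loadNetwork(f)
#' @export
loadNetwork <- function(path, scoreScale = 1000) {
  stopifnot(is.numeric(scoreScale), length(scoreScale) == 1, scoreScale > 0)
  nf <- utils::count.fields(path, sep = "\t", comment.char = "#",
                            blank.lines.skip = TRUE)
  if (!length(nf)) stop("empty edge list: ", path)
  bad <- which(nf != 3)
  if (length(bad))
    stop(sprintf("malformed edge-list row (expected 3 tab-separated fields) at data line %d of %s",
                 bad[1], path))
  tab <- utils::read.table(path, sep = "\t", comment.char = "#",
                           col.names = c("gene_a", "gene_b", "score"),
                           colClasses = c("character", "character", "numeric"),
                           quote = "", stringsAsFactors = FALSE)
  if (any(!is.finite(tab$score)))
    stop("non-numeric interaction score in ", path)
  if (any(tab$score < 0)) stop("negative interaction score in ", path)
  tab$weight <- pmin(tab$score / scoreScale, 1)
  interactionNetwork(tab[, c("gene_a", "gene_b", "weight")])
}

#' Write an interaction network as an edge-list TSV
#'
#' Each undirected edge is written once (lexicographically smaller gene
#' first) with its weight on the \eqn{[0,1]} scale, so that
#' \code{loadNetwork(path, scoreScale = 1)} round-trips the object.
#'
#' @param network an [InteractionNetwork-class].
#' @param path output file.
#' @return Invisibly, \code{path}.
#' @export
writeNetwork <- function(network, path) {
  stopifnot(is(network, "InteractionNetwork"))
  m <- methods::as(Matrix::drop0(network@weights), "TsparseMatrix")
  keep <- m@i < m@j                     # upper triangle once
  df <- data.frame(gene_a = network@genes[m@i[keep] + 1L],
                   gene_b = network@genes[m@j[keep] + 1L],
                   score = m@x[keep])
  df <- df[order(df$gene_a, df$gene_b), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Load gene genomic locations
#'
#' Reads a BED-like TSV (\code{chrom}, \code{start}, \code{end},
#' \code{gene_id}[, \code{band}]) with 0-based half-open coordinates and
#' returns a \code{GRanges} (1-based internally, per Bioconductor
#' convention) with \code{gene_id} and optional \code{band} metadata.
#'
#' @param path locus table file; \code{#} comments allowed.
#' @return A [GenomicRanges::GRanges] named by gene.
#' @export
loadLoci <- function(path) {
  tab <- utils::read.table(path, sep = "\t", comment.char = "#",
                           quote = "", stringsAsFactors = FALSE)
  if (ncol(tab) < 4)
    stop("locus table needs at least 4 columns (chrom, start, end, gene_id)")
  names(tab)[1:4] <- c("chrom", "start", "end", "gene_id")
  if (any(tab$start >= tab$end))
    stop("locus table has start >= end (coordinates are 0-based half-open)")
  if (anyDuplicated(tab$gene_id))
    stop("locus table has duplicated gene ids")
  gr <- GenomicRanges::GRanges(
    seqnames = tab$chrom,
    ranges = IRanges::IRanges(start = tab$start + 1L, end = tab$end),
    gene_id = tab$gene_id,
    band = if (ncol(tab) >= 5) as.character(tab[[5]]) else NA_character_)
  names(gr) <- tab$gene_id
  gr
}

#' Load a disease-to-known-gene association table
#'
#' @param path 2-column TSV (\code{disease_id}, \code{gene_id});
#'   \code{#} comments allowed.
#' @return Named list mapping disease id to a character vector of genes.
#' @export
loadDiseaseGeneMap <- function(path) {
  tab <- utils::read.table(path, sep = "\t", comment.char = "#",
                           quote = "", stringsAsFactors = FALSE,
                           col.names = c("disease_id", "gene_id"),
                           colClasses = "character")
  if (!nrow(tab)) stop("empty disease-gene table: ", path)
  lapply(split(tab$gene_id, tab$disease_id), unique)
}

#' Published operating points of the OMIM disease-gene benchmark
#'
#' Returns the reported prediction table for the 40-disease OMIM benchmark
#' at the calibrated parameters (phi, eta) = (0.005, 39): for each cutoff h,
#' the number of known disease genes recovered (TP), the true and false
#' positive rates, and the reported TPR/FPR ratio. Shipped as a plain-text
#' fixture so that sensitivity/specificity arithmetic can be recomputed
#' without the source databases.
#'
#' @return data.frame with columns \code{h}, \code{tp}, \code{tpr},
#'   \code{fpr}, \code{tpr_fpr}.
#' @examples
#' op <- omimOperatingPoints()
#' 1 - op$fpr[op$h == 24]  # specificity at the reported optimal cutoff
#' @export
omimOperatingPoints <- function() {
  path <- system.file("extdata", "omim_operating_points.tsv",
                      package = "katzRank", mustWork = TRUE)
  utils::read.table(path, sep = "\t", header = TRUE)
}
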