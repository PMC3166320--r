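#' Upper-tail hypergeometric probability
#'
#' \eqn{P(X \ge k)} for \eqn{X \sim} Hypergeometric(M, K, n): the chance
#' that a group of n genes drawn uniformly without replacement from a
#' universe of M genes hits at least k of a term's K annotated genes.
#' Summed in log-space (log-binomial coefficients) for numerical stability.
#'
#' @param k observed overlap (\eqn{0 \le k \le \min(K, n)}).
#' @param K term size, \eqn{K \le M}.
#' @param n group size, \eqn{n \le M}.
#' @param M universe size.
#' @return Tail probability in \eqn{(0, 1]}.
#' @examples
#' hypergeomTail(4, 5, 4, 10)  # choose(5,4)/choose(10,4)
#' @export
hypergeomTail <- function(k, K, n, M) {
  stopifnot(length(k) == 1, length(K) == 1, length(n) == 1, length(M) == 1,
            k == round(k), K == round(K), n == round(n), M == round(M))
  if (k < 0 || K > M || n > M || k > min(K, n))
    stop(sprintf("invalid hypergeometric bounds: k=%d K=%d n=%d M=%d",
                 k, K, n, M))
  if (k == 0) return(1)
  kk <- seq(k, min(K, n))
  logp <- lchoose(K, kk) + lchoose(M - K, n - kk) - lchoose(M, n)
  m <- max(logp)
  min(exp(m + log(sum(exp(logp - m)))), 1)
}

#' Over-representation test of a gene group against an annotation catalog
#'
#' For every catalog term overlapping the group, computes the upper-tail
#' hypergeometric P-value of the overlap given the catalog universe. Genes
#' outside the universe are dropped with a warning. Raw P-values are
#' thresholded at \code{alpha}; Benjamini-Hochberg adjusted values are
#' reported alongside for reference.
#'
#' @param group character vector of genes.
#' @param catalog an [AnnotationCatalog-class].
#' @param alpha significance level for the \code{significant} flag.
#' @return data.frame sorted by P with columns \code{term}, \code{overlap}
#'   (k), \code{termSize} (K), \code{groupSize} (n), \code{universeSize}
#'   (M), \code{p}, \code{padj}, \code{significant}; terms with zero
#'   overlap are omitted.
#' @export
enrichGroup <- function(group, catalog, alpha = 0.05) {
  stopifnot(is(catalog, "AnnotationCatalog"), alpha > 0, alpha < 1)
  group <- unique(as.character(group))
  inside <- group %in% catalog@universe
  if (!any(inside)) stop("no group gene is in the catalog universe")
  if (!all(inside))
    warning(sum(!inside), " group genes outside the universe dropped")
  group <- group[inside]
  M <- length(catalog@universe)
  n <- length(group)
  rows <- lapply(names(catalog@terms), function(tm) {
    tg <- catalog@terms[[tm]]
    k <- sum(group %in% tg)
    if (k == 0) return(NULL)
    data.frame(term = tm, overlap = k, termSize = length(tg),
               groupSize = n, universeSize = M,
               p = hypergeomTail(k, length(tg), n, M),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(data.frame(term = character(), overlap = integer(),
                      termSize = integer(), groupSize = integer(),
                      universeSize = integer(), p = numeric(),
                      padj = numeric(), significant = logical()))
  }
  res <- do.call(rbind, rows)
  res$padj <- stats::p.adjust(res$p, method = "BH")
  res$significant <- res$p < alpha
  res <- res[order(res$p, res$term), ]
  rownames(res) <- NULL
  res
}

#' Load an annotation catalog from TSV or GMT
#'
#' Accepts a 2-column TSV (\code{term_id}, \code{gene_id}) or a GMT file
#' (term, description, genes...), auto-detected from the extension
#' (".gmt") unless \code{format} is given.
#'
#' @param path catalog file.
#' @param universe optional gene universe; defaults to the union of term
#'   genes. A typical choice is the genes shared by the network and the
#'   catalog.
#' @param format "tsv" or "gmt".
#' @return An [AnnotationCatalog-class].
#' @export
loadCatalog <- function(path, universe = NULL, format = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.gmt$", path, ignore.case = TRUE)) "gmt" else "tsv"
  terms <- switch(match.arg(format, c("tsv", "gmt")),
    tsv = {
      tab <- utils::read.table(path, sep = "\t", quote = "",
                               comment.char = "#", stringsAsFactors = FALSE,
                               col.names = c("term_id", "gene_id"),
                               colClasses = "character")
      split(tab$gene_id, tab$term_id)
    },
    gmt = {
      lines <- strsplit(readLines(path), "\t", fixed = TRUE)
      stats::setNames(lapply(lines, function(f) f[-(1:2)]),
                      vapply(lines, `[`, character(1), 1))
    })
  if (!is.null(universe))
    terms <- lapply(terms, intersect, y = universe)
  terms <- terms[lengths(terms) > 0]
  annotationCatalog(terms, universe = universe)
}
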