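#' Build a locus-based candidate gene set
#'
#' Mirrors linkage-study practice: around a mapped disease locus, collect the
#' \code{size} genes on the same chromosome nearest to the locus midpoint.
#' Genes overlapping the locus interval are taken first (ordered by midpoint
#' distance), then the nearest flanking genes; ties are broken by gene id.
#' If a benchmark (known disease) gene is given it is always included,
#' displacing the farthest other member if necessary.
#'
#' @param loci a \code{GRanges} of gene locations as from [loadLoci()].
#' @param locus the disease locus: a length-1 \code{GRanges}, a
#'   \code{"chr:start-end"} string (1-based, inclusive), or a cytogenetic
#'   band label matched against the \code{band} metadata column.
#' @param size number of candidate genes wanted (\eqn{\ge 2}); if the
#'   chromosome has fewer genes, all are returned with a warning.
#' @param benchmark optional gene id that must be in the set; it is an error
#'   if it lies on a different chromosome.
#' @param disease disease label stored on the result.
#' @return A [CandidateSet-class].
#' @examples
#' gr <- GenomicRanges::GRanges(rep("chr1", 3),
#'         IRanges::IRanges(c(1, 100, 200), width = 50),
#'         gene_id = c("g1", "g2", "g3"))
#' names(gr) <- gr$gene_id
#' buildCandidateSet(gr, "chr1:100-149", size = 2)
#' @export
buildCandidateSet <- function(loci, locus, size, benchmark = NULL,
                              disease = NA_character_) {
  stopifnot(is(loci, "GRanges"), size >= 2)
  res <- .resolveLocus(loci, locus)
  chrom <- res$chrom
  onChrom <- loci[as.character(GenomicRanges::seqnames(loci)) == chrom]
  if (!length(onChrom)) stop("no genes on chromosome ", chrom)
  if (!is.null(benchmark) && !benchmark %in% onChrom$gene_id)
    stop(sprintf("benchmark gene '%s' is not on chromosome %s",
                 benchmark, chrom))

  mid <- (GenomicRanges::start(onChrom) + GenomicRanges::end(onChrom)) / 2
  dist <- abs(mid - res$mid)
  inside <- GenomicRanges::start(onChrom) <= res$end &
    GenomicRanges::end(onChrom) >= res$start
  # interval members first, then flanking genes; midpoint distance within
  # each block, gene id as the deterministic tie-break
  ord <- order(!inside, dist, onChrom$gene_id)
  ids <- onChrom$gene_id[ord]

  if (length(ids) < size) {
    warning(sprintf("chromosome %s has only %d genes; requested %d",
                    chrom, length(ids), size))
    size <- length(ids)
  }
  sel <- ids[seq_len(size)]
  if (!is.null(benchmark) && !benchmark %in% sel)
    sel <- c(ids[seq_len(size - 1)], benchmark)
  candidateSet(sel, benchmark = benchmark, disease = disease,
               locus = res$label)
}

# Resolve a locus specification to (chrom, start, end, mid, label).
.resolveLocus <- function(loci, locus) {
  if (is(locus, "GRanges")) {
    stopifnot(length(locus) == 1)
    return(list(chrom = as.character(GenomicRanges::seqnames(locus)),
                start = GenomicRanges::start(locus),
                end = GenomicRanges::end(locus),
                mid = (GenomicRanges::start(locus) +
                         GenomicRanges::end(locus)) / 2,
                label = sprintf("%s:%d-%d",
                                as.character(GenomicRanges::seqnames(locus)),
                                GenomicRanges::start(locus),
                                GenomicRanges::end(locus))))
  }
  stopifnot(is.character(locus), length(locus) == 1)
  if (grepl("^[^:]+:[0-9]+-[0-9]+$", locus)) {
    chrom <- sub(":.*", "", locus)
    se <- as.numeric(strsplit(sub(".*:", "", locus), "-", fixed = TRUE)[[1]])
    if (se[1] > se[2]) stop("locus start exceeds end: ", locus)
    return(list(chrom = chrom, start = se[1], end = se[2],
                mid = mean(se), label = locus))
  }
  # cytogenetic band label
  band <- loci$band
  hit <- !is.na(band) & band == locus
  if (!any(hit))
    stop("locus '", locus, "' matches no band in the locus table")
  chrom <- unique(as.character(GenomicRanges::seqnames(loci[hit])))
  if (length(chrom) > 1)
    stop("band '", locus, "' spans multiple chromosomes")
  s <- min(GenomicRanges::start(loci[hit]))
  e <- max(GenomicRanges::end(loci[hit]))
  list(chrom = chrom, start = s, end = e, mid = (s + e) / 2, label = locus)
}
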