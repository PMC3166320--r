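#' Rank a benchmark gene within its candidate set
#'
#' Candidates are ordered by decreasing score (rank 1 = highest; tied scores
#' get the average of the tied positions). The benchmark gene's rank r and
#' its r-ratio r/N (N = set size) measure how strongly the known disease
#' gene is predicted; smaller is better.
#'
#' @param scores a [ScoreVector-class] (or named numeric vector).
#' @param cset a [CandidateSet-class] with a benchmark gene.
#' @return One-row data.frame (a rank record) with columns \code{gene},
#'   \code{disease}, \code{r}, \code{N}, \code{rRatio}.
#' @examples
#' cs <- candidateSet(c("A", "B", "C"), benchmark = "B")
#' rankInCandidates(c(A = 5, B = 4, C = 3), cs)
#' @export
rankInCandidates <- function(scores, cset) {
  stopifnot(is(cset, "CandidateSet"))
  if (is.null(cset@benchmark)) stop("candidate set has no benchmark gene")
  s <- if (is(scores, "ScoreVector")) scoreValues(scores) else scores
  stopifnot(is.numeric(s), !is.null(names(s)))
  g <- cset@genes
  vals <- s[g]
  if (anyNA(vals)) {
    warning(sum(is.na(vals)), " unscored candidate genes given score 0")
    vals[is.na(vals)] <- 0
  }
  r <- rank(-vals, ties.method = "average")[match(cset@benchmark, g)]
  data.frame(gene = cset@benchmark, disease = cset@disease,
             r = as.numeric(r), N = length(g),
             rRatio = as.numeric(r) / length(g),
             stringsAsFactors = FALSE)
}

#' ROC analysis of candidate-set rankings
#'
#' At each cutoff h the top h genes of every candidate set are called
#' disease-associated. A benchmark gene with rank \eqn{r \le h} is a true
#' positive; the remaining calls, \eqn{\sum_{sets} \min(h, N)} minus the
#' true positives, are false positives over \eqn{\sum_{sets} (N - 1)}
#' negatives. The AUROC is the trapezoid area over the (FPR, TPR) points
#' anchored at (0,0) and (1,1).
#'
#' @param records data.frame of rank records as from [rankInCandidates()]
#'   (rows may be concatenated with \code{rbind}).
#' @param hMax largest cutoff (the curve saturates once h exceeds every N).
#' @return A [ROCCurve-class].
#' @examples
#' recs <- data.frame(gene = c("a", "b"), disease = "d", r = c(1, 3),
#'                    N = 5, rRatio = c(0.2, 0.6))
#' rocAnalysis(recs, hMax = 5)
#' @export
rocAnalysis <- function(records, hMax = 100L) {
  stopifnot(is.data.frame(records), nrow(records) >= 1,
            all(c("r", "N") %in% names(records)), hMax >= 1)
  if (any(records$N < 1)) stop("candidate set sizes must be >= 1")
  hs <- seq_len(hMax)
  pos <- nrow(records)
  neg <- sum(records$N - 1)
  tp <- vapply(hs, function(h) sum(records$r <= h), numeric(1))
  calls <- vapply(hs, function(h) sum(pmin(h, records$N)), numeric(1))
  fp <- calls - tp
  tpr <- tp / pos
  fpr <- if (neg > 0) fp / neg else rep(0, hMax)
  new("ROCCurve", h = as.integer(hs), tpr = tpr, fpr = fpr,
      auroc = .trapezoidAUC(fpr, tpr))
}

# trapezoid area with (0,0) and (1,1) anchors
.trapezoidAUC <- function(fpr, tpr) {
  x <- c(0, fpr, 1)
  y <- c(0, tpr, 1)
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Sensitivity/specificity trade-off cutoff of a ROC curve
#'
#' Walks the curve at step granularity h to h+1 and returns the smallest h
#' whose step ratio \eqn{\Delta TPR / \Delta FPR} falls below 1 (a step with
#' \eqn{\Delta FPR = 0} counts as ratio \code{Inf}). Below 1, the gain in
#' sensitivity no longer compensates the loss of specificity. If the ratio
#' never drops below 1 the largest h is returned with
#' \code{attr(, "saturated") = TRUE}.
#'
#' @param curve a [ROCCurve-class] with at least two points.
#' @return Integer cutoff h (with optional \code{saturated} attribute).
#' @export
optimalCutoff <- function(curve) {
  stopifnot(is(curve, "ROCCurve"), length(curve@h) >= 2)
  dTPR <- diff(curve@tpr)
  dFPR <- diff(curve@fpr)
  ratio <- ifelse(dFPR == 0, Inf, dTPR / dFPR)
  below <- which(ratio < 1)
  if (length(below)) return(curve@h[below[1]])
  structure(curve@h[length(curve@h)], saturated = TRUE)
}

#' Correlation between prioritization rank and pleiotropy
#'
#' Genes are binned by the number of diseases they are associated with;
#' within each bin the mean global rank is taken, and the Pearson
#' correlation between bin pleiotropy (shared-disease count) and bin mean
#' rank is returned. A negative value means more pleiotropic genes rank
#' better (smaller rank).
#'
#' @param meanRanks named numeric vector of per-gene mean global ranks.
#' @param sharedCounts named integer vector of per-gene disease counts
#'   (names matched against \code{meanRanks}).
#' @return Pearson correlation in \eqn{[-1, 1]}.
#' @export
pleiotropyCorrelation <- function(meanRanks, sharedCounts) {
  stopifnot(is.numeric(meanRanks), is.numeric(sharedCounts),
            !is.null(names(meanRanks)), !is.null(names(sharedCounts)))
  common <- intersect(names(meanRanks), names(sharedCounts))
  if (length(common) < 2) stop("need >= 2 genes present in both inputs")
  cnt <- sharedCounts[common]
  rk <- meanRanks[common]
  binMean <- tapply(rk, cnt, mean)
  binCnt <- as.numeric(names(binMean))
  if (length(binMean) < 2) stop("need >= 2 distinct shared-count bins")
  if (stats::sd(binMean) == 0 || stats::sd(binCnt) == 0)
    stop("constant input on one axis; correlation undefined")
  as.numeric(stats::cor(binCnt, as.numeric(binMean), method = "pearson"))
}

#' Genes recurrently at the top of per-disease rankings
#'
#' Takes the top-k genes of every disease's global score ranking (ties at
#' the k-th score are all included) and returns the genes present in at
#' least \code{ceiling(fraction * number of diseases)} of the lists.
#'
#' @param perDiseaseScores list of [ScoreVector-class] (or named numeric)
#'   objects, one per disease.
#' @param k list depth (e.g. 200).
#' @param fraction required recurrence fraction in (0, 1].
#' @return Character vector of recurrent top genes (sorted).
#' @export
topGeneOverlap <- function(perDiseaseScores, k, fraction = 0.9) {
  stopifnot(is.list(perDiseaseScores), length(perDiseaseScores) >= 1,
            k >= 1, fraction > 0, fraction <= 1)
  tops <- lapply(perDiseaseScores, function(sv) {
    s <- if (is(sv, "ScoreVector")) scoreValues(sv) else sv
    stopifnot(k <= length(s))
    thr <- sort(s, decreasing = TRUE)[k]
    names(s)[s >= thr]                 # ties at the k-th score included
  })
  need <- ceiling(fraction * length(tops))
  counts <- table(unlist(lapply(tops, unique)))
  sort(names(counts)[counts >= need])
}
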