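#' Evaluate a disease bundle at fixed parameters
#'
#' A bundle collects everything needed to score and evaluate a set of
#' diseases on one network: \code{network} (an
#' [InteractionNetwork-class]), \code{activities} (named list, disease ->
#' list of [ActivityVector-class], one per disease-control dataset),
#' \code{candidateSets} (list of [CandidateSet-class] whose \code{disease}
#' slot matches the activity names) and optionally \code{knownGenes} (named
#' list, disease -> character). Per disease, each dataset is scored with
#' [solveScores()], the vectors are summed with [combineScores()], and every
#' candidate set of the disease contributes one benchmark rank record.
#'
#' @param bundle the list described above (see also
#'   [benchmarkCandidateSets()] for generated benchmarks).
#' @param phi,eta score parameters.
#' @param phiMax optional precomputed [maxPhi()] bound.
#' @return data.frame of rank records ([rankInCandidates()] rows).
#' @export
evaluateBundle <- function(bundle, phi, eta, phiMax = NULL) {
  net <- bundle$network
  stopifnot(is(net, "InteractionNetwork"), is.list(bundle$activities),
            is.list(bundle$candidateSets))
  if (is.null(phiMax)) phiMax <- maxPhi(net)
  diseases <- names(bundle$activities)
  combined <- lapply(diseases, function(d) {
    svs <- lapply(bundle$activities[[d]], solveScores, network = net,
                  phi = phi, eta = eta, phiMax = phiMax)
    combineScores(svs)
  })
  names(combined) <- diseases
  recs <- lapply(bundle$candidateSets, function(cs) {
    if (!cs@disease %in% diseases)
      stop("candidate set for unknown disease: ", cs@disease)
    rankInCandidates(combined[[cs@disease]], cs)
  })
  do.call(rbind, recs)
}

#' Calibrate (phi, eta) by minimizing the mean benchmark r-ratio
#'
#' Scans a parameter grid; at each point every disease is scored (summing
#' multi-dataset score vectors) and the r-ratio of every known-gene instance
#' is collected — genes shared by several diseases count once per disease.
#' The returned optimum minimizes the mean r-ratio, with ties broken by the
#' smaller phi and then the smaller eta.
#'
#' @param grid data.frame with columns \code{phi} and \code{eta} (or a list
#'   of length-2 vectors).
#' @param bundle disease bundle as in [evaluateBundle()].
#' @return A [CalibrationResult-class].
#' @export
calibrateParameters <- function(grid, bundle) {
  if (is.list(grid) && !is.data.frame(grid))
    grid <- do.call(rbind, lapply(grid, function(p)
      data.frame(phi = p[[1]], eta = p[[2]])))
  stopifnot(is.data.frame(grid), all(c("phi", "eta") %in% names(grid)))
  if (!nrow(grid)) stop("empty parameter grid")
  phiMax <- maxPhi(bundle$network)
  if (any(grid$phi >= phiMax))
    stop(sprintf("grid phi values must be below maxPhi = %g", phiMax))
  mean_rratio <- vapply(seq_len(nrow(grid)), function(i) {
    mean(evaluateBundle(bundle, grid$phi[i], grid$eta[i],
                        phiMax = phiMax)$rRatio)
  }, numeric(1))
  res <- data.frame(phi = grid$phi, eta = grid$eta,
                    meanRRatio = mean_rratio)
  ord <- order(res$meanRRatio, res$phi, res$eta)
  best <- res[ord[1], ]
  new("CalibrationResult", bestPhi = best$phi, bestEta = best$eta,
      meanRRatio = best$meanRRatio, grid = res)
}

#' Leave-one-out evaluation of known-gene-seeded prediction
#'
#' For every disease with at least two known genes present in the network,
#' each known gene is in turn withheld, the rest are supplied as the
#' known-gene indicator of [solveScoresWithKnown()] (score vectors summed
#' across the disease's datasets), and the withheld gene is ranked in its
#' own candidate set. Diseases with fewer than two known network genes are
#' skipped with a warning, as are withheld genes lacking a candidate set.
#'
#' @param bundle disease bundle as in [evaluateBundle()] with a
#'   \code{knownGenes} element.
#' @param phi,eta score parameters.
#' @param normalize normalization of the \eqn{x_1} term, see
#'   [solveScoresWithKnown()].
#' @return data.frame of rank records, one per withheld gene.
#' @export
looKnownGeneEval <- function(bundle, phi, eta, normalize = "max") {
  net <- bundle$network
  stopifnot(is(net, "InteractionNetwork"), is.list(bundle$knownGenes))
  phiMax <- maxPhi(net)
  csKey <- vapply(bundle$candidateSets, function(cs)
    paste(cs@disease, if (is.null(cs@benchmark)) "" else cs@benchmark),
    character(1))
  out <- list()
  for (d in names(bundle$knownGenes)) {
    known <- intersect(bundle$knownGenes[[d]], net@genes)
    dropped <- setdiff(bundle$knownGenes[[d]], known)
    if (length(dropped))
      warning(sprintf("disease %s: known genes absent from the network excluded: %s",
                      d, paste(dropped, collapse = ", ")))
    if (length(known) < 2) {
      warning(sprintf("disease %s has fewer than two known network genes; skipped", d))
      next
    }
    for (g in known) {
      idx <- which(csKey == paste(d, g))
      if (!length(idx)) next
      svs <- lapply(bundle$activities[[d]], function(x)
        solveScoresWithKnown(net, x, known = setdiff(known, g),
                             phi = phi, eta = eta, normalize = normalize,
                             phiMax = phiMax))
      s1 <- combineScores(svs)
      out[[length(out) + 1L]] <- rankInCandidates(s1, bundle$candidateSets[[idx[1]]])
    }
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

#' End-to-end evaluation of a planted benchmark
#'
#' Runs the complete study design on a generated benchmark: calibrates
#' (phi, eta) on the grid, evaluates the calibrated combined score, the
#' expression-only score (phi = 0; any eta > 0 gives the same ranking), the
#' network-only score (eta = 0, phi chosen on the same phi grid), and the
#' leave-one-out known-gene-seeded score at the calibrated optimum, each
#' summarized by its mean r-ratio and ROC curve.
#'
#' @param benchmark a [PlantedBenchmark-class] (or an [evaluateBundle()]
#'   bundle with a \code{knownGenes} element).
#' @param phiFractions fractions of [maxPhi()] defining the phi grid
#'   (0 is always added).
#' @param etaValues eta grid values (0 is always added).
#' @param hMax ROC cutoff range.
#' @return list with elements \code{calibration}
#'   ([CalibrationResult-class]), \code{records} (named list of rank-record
#'   data.frames: \code{combined}, \code{expression}, \code{network},
#'   \code{loo}), \code{roc} (named list of [ROCCurve-class]), and
#'   \code{meanRRatio} (named numeric).
#' @export
benchmarkEvaluation <- function(benchmark,
                                phiFractions = c(0.1, 0.3, 0.6, 0.9),
                                etaValues = c(1, 5, 20, 50),
                                hMax = 100L) {
  bundle <- if (is(benchmark, "PlantedBenchmark"))
    list(network = benchmark@network, activities = benchmark@activities,
         candidateSets = benchmark@candidateSets,
         knownGenes = benchmark@knownGenes)
  else benchmark
  phiMax <- maxPhi(bundle$network)
  phis <- unique(c(0, phiFractions * phiMax))
  etas <- unique(c(0, etaValues))
  grid <- expand.grid(phi = phis, eta = etas)
  cal <- calibrateParameters(grid, bundle)

  recComb <- evaluateBundle(bundle, cal@bestPhi, cal@bestEta)
  recExpr <- evaluateBundle(bundle, 0, 1)
  netGrid <- cal@grid[cal@grid$eta == 0 & cal@grid$phi > 0, ]
  bestNetPhi <- netGrid$phi[which.min(netGrid$meanRRatio)]
  recNet <- evaluateBundle(bundle, bestNetPhi, 0)
  recLoo <- looKnownGeneEval(bundle, cal@bestPhi, cal@bestEta)

  records <- list(combined = recComb, expression = recExpr,
                  network = recNet, loo = recLoo)
  roc <- lapply(records[!vapply(records, is.null, logical(1))],
                rocAnalysis, hMax = hMax)
  list(calibration = cal, records = records, roc = roc,
       meanRRatio = vapply(records, function(r)
         if (is.null(r)) NA_real_ else mean(r$rRatio), numeric(1)))
}
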