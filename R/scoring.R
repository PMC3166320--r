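#' Upper bound on the network coupling parameter phi
#'
#' The score \eqn{s = (I - \phi W)^{-1}(d + \eta x)} is well defined with an
#' entrywise-nonnegative inverse (convergent Neumann series) exactly when
#' \eqn{\phi < 1/\rho(W)}, the reciprocal spectral radius of the weight
#' matrix. The radius is computed by power iteration (relative tolerance
#' 1e-10); for an edgeless network the bound is \code{Inf}.
#'
#' @param network an [InteractionNetwork-class].
#' @return The bound \eqn{1/\rho(W)} as a positive number (possibly
#'   \code{Inf}).
#' @examples
#' net <- interactionNetwork(data.frame(gene_a = "A", gene_b = "B",
#'                                      weight = 1))
#' maxPhi(net)  # 2-node spectral radius is 1
#' @export
maxPhi <- function(network) {
  stopifnot(is(network, "InteractionNetwork"))
  1 / .spectralRadius(network@weights)
}

# power iteration for the spectral radius of a symmetric nonnegative matrix;
# the norm-ratio estimate also handles bipartite (+/- rho) spectra
.spectralRadius <- function(w, tol = 1e-10, maxIter = 100000L) {
  n <- nrow(w)
  if (n == 0 || Matrix::nnzero(w) == 0) return(0)
  v <- rep(1 / sqrt(n), n)
  est <- 0
  for (it in seq_len(maxIter)) {
    wv <- as.numeric(w %*% v)
    nrm <- sqrt(sum(wv^2))
    if (nrm == 0) return(0)            # start vector in the null space
    newEst <- nrm / sqrt(sum(v^2))
    v <- wv / nrm
    if (it > 1 && abs(newEst - est) <= tol * newEst) return(newEst)
    est <- newEst
  }
  est
}

# align a named activity vector to the network's gene order; absent -> 0
.alignActivity <- function(x, genes, warnMissing = TRUE) {
  if (is(x, "ActivityVector")) x <- activityValues(x)
  if (is.null(x)) return(numeric(length(genes)))
  stopifnot(is.numeric(x))
  if (is.null(names(x))) {
    if (length(x) != length(genes))
      stop("unnamed activity vector must match the network size")
    return(as.numeric(x))
  }
  out <- numeric(length(genes))
  idx <- match(genes, names(x))
  out[!is.na(idx)] <- x[idx[!is.na(idx)]]
  if (warnMissing && anyNA(idx))
    warning(sum(is.na(idx)), " network genes without activity; set to 0")
  out
}

# Jacobi iteration for s = phi*W*s + b, started from s0 = b (the first
# Neumann term). W has zero diagonal, so the iteration matrix is phi*W and
# convergence is guaranteed for phi < 1/rho(W).
.jacobiSolve <- function(w, phi, b, tol = 1e-10, maxIter = 10000L) {
  s <- b
  if (phi == 0) return(list(s = s, iterations = 0L, residual = 0))
  for (it in seq_len(maxIter)) {
    sNew <- phi * as.numeric(w %*% s) + b
    delta <- max(abs(sNew - s))
    s <- sNew
    if (delta < tol)
      return(list(s = s, iterations = it, residual = delta))
  }
  stop(sprintf("Jacobi iteration did not converge in %d iterations (last max-norm change %.3e)",
               maxIter, delta))
}

#' Solve the Katz-style prioritization score
#'
#' Solves \eqn{s = \phi W s + \delta d + \eta x} with \eqn{\delta = 1} and
#' \eqn{d = (1,\ldots,1)^T}, i.e. \eqn{s = (I - \phi W)^{-1}(d + \eta x)},
#' by Jacobi iteration (stopping when the max-norm change drops below
#' \code{tol}, cap \code{maxIter} sweeps). \eqn{\phi} weights proximity to
#' other high-scoring genes in the interaction network, \eqn{\eta} weights
#' the differential-expression activity; with valid \eqn{\phi} every score
#' is at least 1, the background level of an isolated, non-differentially
#' expressed gene.
#'
#' @param network an [InteractionNetwork-class].
#' @param x an [ActivityVector-class] or named nonnegative numeric vector;
#'   genes absent from \code{x} get activity 0.
#' @param phi network coupling weight, must satisfy
#'   \code{phi < maxPhi(network)}.
#' @param eta activity weight (\eqn{\ge 0}).
#' @param tol,maxIter Jacobi stopping rule.
#' @param phiMax optional precomputed [maxPhi()] value, to avoid repeated
#'   spectral-radius computations in grid scans.
#' @return A [ScoreVector-class].
#' @examples
#' net <- interactionNetwork(data.frame(gene_a = "A", gene_b = "B",
#'                                      weight = 1))
#' scoreValues(solveScores(net, c(A = 0.5, B = 0), phi = 0, eta = 2))
#' @export
solveScores <- function(network, x = NULL, phi, eta, tol = 1e-10,
                        maxIter = 10000L, phiMax = NULL) {
  stopifnot(is(network, "InteractionNetwork"),
            is.numeric(phi), length(phi) == 1, phi >= 0,
            is.numeric(eta), length(eta) == 1, eta >= 0)
  if (is.null(phiMax)) phiMax <- maxPhi(network)
  if (phi >= phiMax)
    stop(sprintf("phi = %g is not below the spectral bound maxPhi = %g",
                 phi, phiMax))
  gn <- network@genes
  xv <- .alignActivity(x, gn, warnMissing = FALSE)
  if (any(xv < 0)) stop("activities must be nonnegative")
  b <- 1 + eta * xv                     # delta = 1, d = all-ones
  sol <- .jacobiSolve(network@weights, phi, b, tol = tol, maxIter = maxIter)
  names(sol$s) <- gn
  new("ScoreVector", values = sol$s, phi = phi, eta = eta,
      iterations = sol$iterations, residual = sol$residual)
}

#' Prioritization score seeded with known disease genes
#'
#' Solves the known-gene variant \eqn{s_1 = (I - \phi W)^{-1}(x_1 + x_2)}:
#' \eqn{x_1} is the normalized \eqn{d + \eta x} (divided by its maximum so
#' its entries lie in \eqn{[0,1]}, commensurate with the unit entries of
#' \eqn{x_2}; sum-normalization available via \code{normalize}), and
#' \eqn{x_2} is the 0/1 indicator of the input known genes.
#'
#' @inheritParams solveScores
#' @param known character vector of known disease genes; genes absent from
#'   the network are dropped with a warning, and an empty set (allowed, with
#'   a warning) reduces to solving with \eqn{x_1} alone.
#' @param normalize \code{"max"} (default) or \code{"sum"} normalization of
#'   \eqn{d + \eta x}.
#' @return A [ScoreVector-class] of \eqn{s_1} scores.
#' @examples
#' net <- interactionNetwork(data.frame(gene_a = "A", gene_b = "B",
#'                                      weight = 1))
#' scoreValues(solveScoresWithKnown(net, NULL, known = "A",
#'                                  phi = 0, eta = 0))
#' @export
solveScoresWithKnown <- function(network, x = NULL, known, phi, eta,
                                 normalize = c("max", "sum"), tol = 1e-10,
                                 maxIter = 10000L, phiMax = NULL) {
  stopifnot(is(network, "InteractionNetwork"))
  normalize <- match.arg(normalize)
  if (is.null(phiMax)) phiMax <- maxPhi(network)
  if (phi >= phiMax)
    stop(sprintf("phi = %g is not below the spectral bound maxPhi = %g",
                 phi, phiMax))
  gn <- network@genes
  known <- unique(as.character(known))
  missing <- setdiff(known, gn)
  if (length(missing)) {
    warning("known genes absent from the network dropped: ",
            paste(missing, collapse = ", "))
    known <- setdiff(known, missing)
  }
  if (!length(known))
    warning("empty known-gene set; solving with the activity term alone")
  xv <- .alignActivity(x, gn, warnMissing = FALSE)
  if (any(xv < 0)) stop("activities must be nonnegative")
  x1 <- 1 + eta * xv
  x1 <- switch(normalize, max = x1 / max(x1), sum = x1 / sum(x1))
  x2 <- as.numeric(gn %in% known)
  sol <- .jacobiSolve(network@weights, phi, x1 + x2, tol = tol,
                      maxIter = maxIter)
  names(sol$s) <- gn
  new("ScoreVector", values = sol$s, phi = phi, eta = eta,
      iterations = sol$iterations, residual = sol$residual)
}

#' Sum score vectors across datasets of one disease
#'
#' When one disease has several disease-control datasets, their score
#' vectors are added elementwise to form the combined disease score.
#'
#' @param scores list of [ScoreVector-class] objects over the same gene
#'   universe (or a single ScoreVector, returned as is).
#' @return A [ScoreVector-class] holding the elementwise sum.
#' @export
combineScores <- function(scores) {
  if (is(scores, "ScoreVector")) return(scores)
  stopifnot(is.list(scores), length(scores) >= 1,
            all(vapply(scores, is, logical(1), "ScoreVector")))
  ref <- names(scores[[1]]@values)
  for (sv in scores[-1]) {
    g <- names(sv@values)
    if (!setequal(g, ref) || length(g) != length(ref)) {
      diff <- c(setdiff(ref, g), setdiff(g, ref))
      stop("score vectors over different gene universes; symmetric difference: ",
           paste(unique(diff), collapse = ", "))
    }
  }
  total <- scores[[1]]@values
  for (sv in scores[-1]) total <- total + sv@values[ref]
  new("ScoreVector", values = total, phi = scores[[1]]@phi,
      eta = scores[[1]]@eta,
      iterations = max(vapply(scores, slot, integer(1), "iterations")),
      residual = max(vapply(scores, slot, numeric(1), "residual")))
}
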