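#' Randomization control: shuffle an activity vector
#'
#' Repeatedly picks a random pair of genes and exchanges their activity
#' values, yielding a reshuffled activity vector with the same value
#' multiset — the random counterpart of a disease's expression signal.
#'
#' @param x an [ActivityVector-class] (or named numeric vector).
#' @param nSwaps number of random transpositions; the default, 10 times the
#'   gene count, is comfortably beyond mixing.
#' @param seed RNG seed for reproducibility (caller's RNG state is
#'   preserved).
#' @return An [ActivityVector-class] with permuted values.
#' @export
shuffleActivity <- function(x, nSwaps = NULL, seed = NULL) {
  v <- if (is(x, "ActivityVector")) activityValues(x) else x
  stopifnot(is.numeric(v), length(v) >= 2, !is.null(names(v)))
  if (is.null(nSwaps)) nSwaps <- 10L * length(v)
  stopifnot(nSwaps >= 0)
  vals <- unname(v)
  vals <- .withSeed(seed, {
    n <- length(vals)
    if (nSwaps > 0) {
      a <- sample.int(n, nSwaps, replace = TRUE)
      b <- sample.int(n, nSwaps, replace = TRUE)
      for (k in seq_len(nSwaps)) {
        tmp <- vals[a[k]]
        vals[a[k]] <- vals[b[k]]
        vals[b[k]] <- tmp
      }
    }
    vals
  })
  activityVector(stats::setNames(vals, names(v)),
                 dataset = if (is(x, "ActivityVector"))
                   paste0(x@dataset, ":shuffled") else "shuffled")
}

#' Randomization control: random known-gene sets
#'
#' Draws \code{count} random gene sets whose sizes are uniform integers in
#' \code{[minSize, maxSize]} (matching the observed spread of known
#' disease-gene counts, 1 to 32) and whose members are sampled without
#' replacement from the supplied genes.
#'
#' @param genes gene universe to sample from.
#' @param count number of sets.
#' @param minSize,maxSize inclusive size bounds.
#' @param seed RNG seed.
#' @return list of character vectors.
#' @export
randomKnownSets <- function(genes, count, minSize = 1L, maxSize = 32L,
                            seed = NULL) {
  genes <- as.character(genes)
  stopifnot(count >= 1, minSize >= 1, maxSize >= minSize,
            maxSize <= length(genes))
  .withSeed(seed, {
    sizes <- sample(seq.int(minSize, maxSize), count, replace = TRUE)
    lapply(sizes, function(R) sample(genes, R))
  })
}

#' Generate a small random weighted network with activities
#'
#' Erdos-Renyi-style graph with uniform edge weights and half-normal
#' activities, restricted to its largest connected component — a toy stand-in
#' for a disease interaction neighbourhood. At low phi the score ranking
#' tracks the activity x; at phi near [maxPhi()] network proximity dominates
#' and poorly expressed but well-connected genes climb the ranking.
#'
#' @param n number of genes before component filtering (\eqn{\ge 2}).
#' @param edgeProb edge probability in (0, 1].
#' @param weightRange uniform range of edge weights within \eqn{[0,1]}.
#' @param activitySd scale of the half-normal activity distribution.
#' @param seed RNG seed.
#' @return list with elements \code{network} ([InteractionNetwork-class])
#'   and \code{activity} ([ActivityVector-class]) over the retained genes.
#' @export
makeToyNetwork <- function(n = 30L, edgeProb = 0.15,
                           weightRange = c(0.1, 1), activitySd = 0.5,
                           seed = NULL) {
  stopifnot(n >= 2, edgeProb > 0, edgeProb <= 1,
            length(weightRange) == 2, weightRange[1] >= 0,
            weightRange[2] <= 1, weightRange[1] < weightRange[2],
            activitySd > 0)
  .withSeed(seed, {
    gn <- sprintf("g%03d", seq_len(n))
    pair <- .randomPairs(n, edgeProb)
    if (!length(pair$i)) stop("no edges drawn; increase n or edgeProb")
    comp <- .components(n, pair$i, pair$j)
    keepComp <- which.max(tabulate(comp))
    keep <- comp == keepComp
    sel <- pair$i %in% which(keep)      # edges are within one component
    edges <- data.frame(
      gene_a = gn[pair$i[sel]], gene_b = gn[pair$j[sel]],
      weight = stats::runif(sum(sel), weightRange[1], weightRange[2]))
    net <- interactionNetwork(edges, genes = gn[keep])
    x <- abs(stats::rnorm(sum(keep), 0, activitySd))
    list(network = net,
         activity = activityVector(stats::setNames(x, gn[keep]),
                                   dataset = "toy"))
  })
}

# draw undirected ER edges; returns index vectors with i < j
.randomPairs <- function(n, prob) {
  i <- rep.int(seq_len(n - 1L), times = rev(seq_len(n - 1L)))
  j <- sequence(rev(seq_len(n - 1L)), from = seq.int(2L, n))
  hit <- stats::runif(length(i)) < prob
  list(i = i[hit], j = j[hit])
}

#' Generate a planted disease-gene prioritization benchmark
#'
#' Builds the data structure the whole pipeline is evaluated on, with known
#' ground truth: a background random weighted interaction network; one
#' planted near-clique module per disease with boosted internal weights
#' (plus a ring through the module guaranteeing its connectivity);
#' optionally a pool of pleiotropic genes shared between several disease
#' modules; per-disease activity vectors in which only a fraction of module
#' genes carry an elevated expression signal (the rest stay at background,
#' emulating disease genes invisible in microarray data); and per known
#' gene a locus-style candidate set of the genes nearest to it on its
#' (synthetic) chromosome, containing exactly one true gene of its disease.
#'
#' @param nGenes genes in the network.
#' @param nDiseases planted diseases.
#' @param moduleSize disease-specific module genes per disease
#'   (\code{moduleSize * nDiseases <= nGenes}).
#' @param candidateSize candidate-set size (\eqn{\ge 2}).
#' @param edgeProb background edge probability.
#' @param moduleEdgeProb edge probability inside a module.
#' @param moduleWeightBoost added to background weights inside modules
#'   (clamped at 1).
#' @param activitySignal mean activity of signal genes; 0 disables the
#'   expression signal entirely.
#' @param signalFraction fraction of each disease's module genes carrying
#'   the expression signal.
#' @param backgroundSd scale of the half-normal background activity.
#' @param weightRange uniform range of background edge weights.
#' @param nShared size of the pleiotropic pool; each shared gene joins
#'   2..nDiseases disease modules (0 disables sharing).
#' @param nDatasetsPerDisease disease-control datasets per disease (score
#'   vectors are summed during evaluation).
#' @param seed RNG seed (required; the benchmark is fully reproducible).
#' @return A [PlantedBenchmark-class].
#' @export
makePlantedBenchmark <- function(nGenes = 2000L, nDiseases = 10L,
                                 moduleSize = 10L, candidateSize = 100L,
                                 edgeProb = 0.005, moduleEdgeProb = 0.8,
                                 moduleWeightBoost = 0.5,
                                 activitySignal = 1, signalFraction = 0.5,
                                 backgroundSd = 0.15,
                                 weightRange = c(0.15, 0.95),
                                 nShared = 12L, nDatasetsPerDisease = 1L,
                                 seed) {
  stopifnot(nGenes >= 4, nDiseases >= 1, moduleSize >= 2,
            moduleSize * nDiseases + nShared <= nGenes,
            candidateSize >= 2, edgeProb > 0, edgeProb <= 1,
            moduleEdgeProb > 0, moduleEdgeProb <= 1,
            moduleWeightBoost >= 0, activitySignal >= 0,
            signalFraction > 0, signalFraction <= 1,
            nShared >= 0, nDatasetsPerDisease >= 1,
            is.numeric(seed), length(seed) == 1)
  seed <- as.integer(seed)
  .withSeed(seed, {
    gn <- sprintf("g%05d", seq_len(nGenes))
    diseases <- sprintf("disease%02d", seq_len(nDiseases))

    # pleiotropic pool and disease-specific module genes
    pool <- sample(nGenes)
    shared <- if (nShared > 0) pool[seq_len(nShared)] else integer()
    own <- split(pool[nShared + seq_len(moduleSize * nDiseases)],
                 rep(seq_len(nDiseases), each = moduleSize))
    sharedMembership <- lapply(shared, function(g) {
      size <- sample(seq.int(min(2L, nDiseases), nDiseases), 1)
      sort(sample(nDiseases, size))
    })
    modules <- lapply(seq_len(nDiseases), function(d) {
      sg <- shared[vapply(sharedMembership, function(m) d %in% m,
                          logical(1))]
      sort(c(own[[d]], sg))
    })

    # background graph + boosted near-clique modules (max-merged)
    bg <- .randomPairs(nGenes, edgeProb)
    ei <- bg$i; ej <- bg$j
    ew <- stats::runif(length(ei), weightRange[1], weightRange[2])
    for (d in seq_len(nDiseases)) {
      m <- modules[[d]]
      mp <- .randomPairs(length(m), moduleEdgeProb)
      mi <- m[mp$i]; mj <- m[mp$j]
      # ring through the module guarantees a connected true-gene subgraph
      ri <- m; rj <- m[c(seq_along(m)[-1], 1L)]
      mi <- c(mi, pmin(ri, rj)); mj <- c(mj, pmax(ri, rj))
      mw <- pmin(1, stats::runif(length(mi), weightRange[1],
                                 weightRange[2]) + moduleWeightBoost)
      ei <- c(ei, mi); ej <- c(ej, mj); ew <- c(ew, mw)
    }
    net <- interactionNetwork(
      data.frame(gene_a = gn[ei], gene_b = gn[ej], weight = ew),
      genes = gn)

    # synthetic gene loci: chromosomes large enough for one candidate set
    nChrom <- max(1L, min(22L, nGenes %/% (2L * candidateSize)))
    chrom <- sample(rep_len(seq_len(nChrom), nGenes))
    pos <- stats::ave(seq_len(nGenes), chrom,
                      FUN = function(k) seq_along(k) * 10000)

    # per-disease signal genes and activity datasets
    signalGenes <- lapply(modules, function(m)
      sort(sample(m, max(1L, ceiling(signalFraction * length(m))))))
    activities <- lapply(seq_len(nDiseases), function(d) {
      lapply(seq_len(nDatasetsPerDisease), function(k) {
        x <- abs(stats::rnorm(nGenes, 0, backgroundSd))
        if (activitySignal > 0)
          x[signalGenes[[d]]] <-
            abs(stats::rnorm(length(signalGenes[[d]]),
                             activitySignal, backgroundSd))
        activityVector(stats::setNames(x, gn),
                       dataset = sprintf("%s_ds%d", diseases[d], k))
      })
    })
    names(activities) <- diseases

    # locus-style candidate sets: nearest genes on the true gene's
    # chromosome, other true genes of the same disease excluded
    csets <- list()
    for (d in seq_len(nDiseases)) {
      for (g in modules[[d]]) {
        onChrom <- which(chrom == chrom[g])
        excl <- setdiff(intersect(onChrom, modules[[d]]), g)
        cand <- setdiff(onChrom, excl)
        ord <- cand[order(abs(pos[cand] - pos[g]), gn[cand])]
        sel <- ord[seq_len(min(candidateSize, length(ord)))]
        if (!g %in% sel) sel <- c(sel[-length(sel)], g)
        csets[[length(csets) + 1L]] <- candidateSet(
          gn[sel], benchmark = gn[g], disease = diseases[d],
          locus = sprintf("chr%d:%d", chrom[g], pos[g]))
      }
    }

    known <- lapply(modules, function(m) gn[m])
    names(known) <- diseases
    new("PlantedBenchmark", network = net, activities = activities,
        knownGenes = known, candidateSets = csets,
        params = list(nGenes = nGenes, nDiseases = nDiseases,
                      moduleSize = moduleSize,
                      candidateSize = candidateSize, edgeProb = edgeProb,
                      moduleEdgeProb = moduleEdgeProb,
                      moduleWeightBoost = moduleWeightBoost,
                      activitySignal = activitySignal,
                      signalFraction = signalFraction,
                      backgroundSd = backgroundSd,
                      weightRange = weightRange, nShared = nShared,
                      nDatasetsPerDisease = nDatasetsPerDisease,
                      chrom = chrom, pos = pos,
                      signalGenes = lapply(signalGenes, function(s) gn[s])),
        seed = seed)
  })
}
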