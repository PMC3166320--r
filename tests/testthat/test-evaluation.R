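test_that("benchmark ranks and r-ratios follow the averaged-tie rule", {
  cs100 <- candidateSet(sprintf("g%03d", 1:100), benchmark = "g001")
  s <- setNames(seq(100, 1), sprintf("g%03d", 1:100))
  rec <- rankInCandidates(s, cs100)
  expect_equal(rec$r, 1); expect_equal(rec$rRatio, 0.01)

  # benchmark tied with one other gene for the top
  s2 <- s; s2["g002"] <- s2["g001"]
  rec <- rankInCandidates(s2, cs100)
  expect_equal(rec$r, 1.5); expect_equal(rec$rRatio, 0.015)

  # scores (5,4,3,2,1), benchmark scored 3 -> r = 3, r-ratio 0.6
  cs5 <- candidateSet(paste0("g", 1:5), benchmark = "g3")
  rec <- rankInCandidates(setNames(c(5, 4, 3, 2, 1), paste0("g", 1:5)), cs5)
  expect_equal(rec$r, 3); expect_equal(rec$rRatio, 0.6)

  # unscored candidates fall to 0 with a warning
  expect_warning(rec <- rankInCandidates(setNames(c(5, 4, 3), paste0("g", 1:3)),
                                         cs5), "unscored")
  expect_equal(rec$r, 3)
  expect_error(rankInCandidates(s, candidateSet(c("a", "b"))), "benchmark")
})

test_that("r-ratio is invariant under strictly increasing score transforms", {
  set.seed(2)
  gn <- sprintf("g%03d", 1:50)
  s <- setNames(runif(50), gn)
  cs <- candidateSet(gn[1:20], benchmark = gn[5])
  r0 <- rankInCandidates(s, cs)$rRatio
  expect_equal(rankInCandidates(exp(4 * s) + 2, cs)$rRatio, r0)
  expect_equal(rankInCandidates(rank(s), cs)$rRatio, r0)
})

test_that("ROC points and AUROC follow the joint candidate-set accounting", {
  # one set of 10, benchmark on top: perfect classifier
  rec <- data.frame(gene = "b", disease = "d", r = 1, N = 10, rRatio = 0.1)
  curve <- rocAnalysis(rec, hMax = 10)
  expect_equal(curve@tpr[1], 1); expect_equal(curve@fpr[1], 0)
  expect_equal(curve@auroc, 1)

  # benchmark at the bottom: no true positive until h = N
  rec$r <- 10
  curve <- rocAnalysis(rec, hMax = 10)
  expect_true(all(curve@tpr[1:9] == 0))
  expect_equal(curve@tpr[10], 1)

  # two sets of 5 with ranks 1 and 3: at h=1 TPR=1/2, FPR=1/8
  recs <- data.frame(gene = c("a", "b"), disease = "d", r = c(1, 3),
                     N = c(5, 5), rRatio = c(0.2, 0.6))
  curve <- rocAnalysis(recs, hMax = 5)
  expect_equal(curve@tpr[1], 0.5)
  expect_equal(curve@fpr[1], 1 / 8)
  expect_true(!is.unsorted(curve@tpr) && !is.unsorted(curve@fpr))
  # saturation beyond the largest set is allowed and flat
  curve2 <- rocAnalysis(recs, hMax = 20)
  expect_equal(curve2@tpr[20], 1); expect_equal(curve2@fpr[20], 1)
})

test_that("optimal cutoff is the first step with dTPR/dFPR below one", {
  mkCurve <- function(tpr, fpr) new("ROCCurve",
    h = seq_along(tpr), tpr = tpr, fpr = fpr,
    auroc = 0.5)
  # step ratios 3, 2, 1.5, 0.8 by h -> cutoff at the 0.8 step (h = 4)
  fpr <- seq(0, 0.4, by = 0.1)
  tpr <- cumsum(c(0, 0.1 * c(3, 2, 1.5, 0.8)))
  expect_equal(optimalCutoff(mkCurve(tpr, fpr)), 4)

  # ratio always above one -> last h with a saturation flag
  h <- optimalCutoff(mkCurve(seq(0, 0.8, 0.2), seq(0, 0.4, 0.1)))
  expect_equal(as.integer(h), 5)
  expect_true(attr(h, "saturated"))

  # dFPR = 0 early counts as infinite ratio, sub-1 step at h = 4 wins
  tpr <- c(0.2, 0.4, 0.6, 0.75, 0.76)
  fpr <- c(0.0, 0.0, 0.1, 0.2, 0.4)
  expect_equal(optimalCutoff(mkCurve(tpr, fpr)), 4)
})

test_that("reported cutoff arithmetic: trade-off drops below one after h = 24", {
  # on the published operating points the coarse-grained step ratios stay
  # above one through h = 30, consistent with the fine-grained drop being
  # visible only between tabulated rows
  op <- omimOperatingPoints()
  stepRatio <- diff(op$tpr) / diff(op$fpr)
  expect_true(all(stepRatio > 1))
  # sensitivity/specificity pairs at the two recommended cutoffs
  expect_equal(op$tpr[op$h == 24] * 100, 60, tolerance = 0.1)
  expect_equal((1 - op$fpr[op$h == 24]) * 100, 76.4, tolerance = 0.05)
  expect_equal((1 - op$fpr[op$h == 30]) * 100, 70.4, tolerance = 0.05)
})

test_that("calibration matches an exhaustive dense-solve oracle", {
  net <- randomNetwork(25, p = 0.2, seed = 31)
  gn <- genes(net)
  set.seed(32)
  x1 <- setNames(abs(rnorm(25)), gn)
  x2 <- setNames(abs(rnorm(25)), gn)
  csets <- list(
    candidateSet(gn[1:10], benchmark = gn[3], disease = "d1"),
    candidateSet(gn[11:20], benchmark = gn[14], disease = "d1"),
    candidateSet(gn[5:16], benchmark = gn[8], disease = "d2"))
  bundle <- list(network = net,
                 activities = list(d1 = list(activityVector(x1)),
                                   d2 = list(activityVector(x2))),
                 candidateSets = csets)
  mp <- maxPhi(net)
  grid <- expand.grid(phi = c(0, 0.2, 0.5, 0.7, 0.9) * mp,
                      eta = c(0, 1, 5, 20, 60))
  cal <- calibrateParameters(grid, bundle)

  # oracle: dense solves + hand ranking, exhaustive over the same grid
  oracleMean <- apply(grid, 1, function(p) {
    mean(vapply(csets, function(cs) {
      x <- if (cs@disease == "d1") x1 else x2
      s <- denseScoreOracle(net, x, p[["phi"]], p[["eta"]])
      v <- s[cs@genes]
      rank(-v, ties.method = "average")[match(cs@benchmark, cs@genes)] /
        length(cs@genes)
    }, numeric(1)))
  })
  best <- which(oracleMean == min(oracleMean))
  expect_equal(cal@meanRRatio, min(oracleMean), tolerance = 1e-10)
  expect_true(any(abs(grid$phi[best] - cal@bestPhi) < 1e-12 &
                    abs(grid$eta[best] - cal@bestEta) < 1e-12))
  expect_equal(nrow(cal@grid), nrow(grid))

  # single-point grid degenerates to that point
  one <- calibrateParameters(data.frame(phi = 0, eta = 1), bundle)
  expect_equal(c(one@bestPhi, one@bestEta), c(0, 1))

  # ties resolve to the smallest phi, then smallest eta: at phi = 0 the
  # ranking (hence the mean r-ratio) is identical for every eta > 0
  tie <- calibrateParameters(data.frame(phi = 0, eta = c(7, 2)), bundle)
  expect_equal(tie@bestEta, 2)
  expect_error(calibrateParameters(grid[0, ], bundle), "empty")
})

test_that("leave-one-out seeds each disease with its remaining known genes", {
  net <- randomNetwork(30, p = 0.2, seed = 44)
  gn <- genes(net)
  set.seed(45)
  x <- setNames(abs(rnorm(30, 0, 0.2)), gn)
  csets <- list(
    candidateSet(gn[1:12], benchmark = gn[2], disease = "d1"),
    candidateSet(gn[13:24], benchmark = gn[15], disease = "d1"))
  bundle <- list(network = net,
                 activities = list(d1 = list(activityVector(x))),
                 candidateSets = csets,
                 knownGenes = list(d1 = c(gn[2], gn[15])))
  recs <- looKnownGeneEval(bundle, phi = 0.3 * maxPhi(net), eta = 5)
  expect_equal(nrow(recs), 2)               # one record per withheld gene
  expect_setequal(recs$gene, c(gn[2], gn[15]))

  # a disease with fewer than two known network genes is skipped
  b2 <- bundle; b2$knownGenes <- list(d1 = gn[2])
  expect_warning(expect_null(looKnownGeneEval(b2, 0.1, 1)), "fewer than two")
  # known genes outside the network are excluded with a warning
  b3 <- bundle; b3$knownGenes <- list(d1 = c(gn[2], gn[15], "nope"))
  expect_warning(looKnownGeneEval(b3, 0.1, 1), "nope")
})

test_that("pleiotropy correlation is computed on binned means", {
  # perfect linear decrease -> -1
  ranks <- setNames(c(40, 30, 20, 10), paste0("g", 1:4))
  counts <- setNames(1:4, paste0("g", 1:4))
  expect_equal(pleiotropyCorrelation(ranks, counts), -1)
  # two bins give +/- 1 by construction
  expect_equal(abs(pleiotropyCorrelation(ranks[1:2], setNames(c(1, 3),
    paste0("g", 1:2)))), 1)
  # four hand-specified bins vs the textbook formula; per-gene ranks are
  # averaged within bins first
  ranks <- setNames(c(10, 14, 7, 9, 6, 2), paste0("g", 1:6))
  counts <- setNames(c(1, 1, 2, 3, 3, 4), paste0("g", 1:6))
  binMeans <- c(12, 7, 7.5, 2)   # hand-averaged per count 1,2,3,4
  cnt <- 1:4
  oracle <- sum((cnt - mean(cnt)) * (binMeans - mean(binMeans))) /
    sqrt(sum((cnt - mean(cnt))^2) * sum((binMeans - mean(binMeans))^2))
  expect_equal(pleiotropyCorrelation(ranks, counts), oracle)
  # constant axis is undefined
  expect_error(pleiotropyCorrelation(setNames(c(1, 1), c("a", "b")),
                                     setNames(c(1, 2), c("a", "b"))),
               "constant")
})

test_that("top-gene overlap honors ties and the recurrence fraction", {
  gn <- sprintf("g%04d", 1:100)
  s <- setNames(seq(100, 1), gn)
  # identical vectors: exactly the top-k set at any fraction
  expect_setequal(topGeneOverlap(list(s, s, s), k = 10, fraction = 0.9),
                  gn[1:10])
  # ties at the k-th score are all included
  s2 <- s; s2[11] <- s2[10]
  expect_setequal(topGeneOverlap(list(s2, s2), k = 10, fraction = 1),
                  gn[1:11])
  # pairwise-disjoint top lists overlap nowhere
  sA <- setNames(c(rep(10, 10), rep(0, 90)), gn)
  sB <- setNames(c(rep(0, 90), rep(10, 10)), gn)
  expect_length(topGeneOverlap(list(sA, sB), k = 10, fraction = 0.9), 0)

  # random independent rankings: near-empty overlap at fraction 0.35
  set.seed(77)
  gn2 <- sprintf("g%04d", 1:2000)
  rand <- lapply(1:20, function(i) setNames(runif(2000), gn2))
  expect_lte(length(topGeneOverlap(rand, k = 200, fraction = 0.35)), 5)
})
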