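# shared fixtures and independent oracles, all built in code

# random weighted network over n genes; weights uniform in (0, 1]
randomNetwork <- function(n, p = 0.3, seed = 1, binary = FALSE) {
  set.seed(seed)
  i <- rep.int(seq_len(n - 1L), times = rev(seq_len(n - 1L)))
  j <- sequence(rev(seq_len(n - 1L)), from = seq.int(2L, n))
  hit <- runif(length(i)) < p
  if (!any(hit)) hit[1] <- TRUE
  gn <- sprintf("g%03d", seq_len(n))
  w <- if (binary) rep(1, sum(hit)) else runif(sum(hit), 0.05, 1)
  interactionNetwork(
    data.frame(gene_a = gn[i[hit]], gene_b = gn[j[hit]], weight = w),
    genes = gn)
}

# independent dense oracle for s = (I - phi W)^-1 b
denseSolve <- function(net, b, phi) {
  w <- as.matrix(weightMatrix(net))
  as.numeric(solve(diag(nrow(w)) - phi * w, b))
}

denseScoreOracle <- function(net, x, phi, eta) {
  gn <- genes(net)
  xv <- numeric(length(gn))
  names(xv) <- gn
  if (!is.null(x)) xv[names(x)] <- x
  setNames(denseSolve(net, 1 + eta * xv, phi), gn)
}

# six genes on one chromosome, evenly spaced (0-based half-open on disk)
writeToyLoci <- function(path) {
  starts <- seq(0, 1000, by = 200)
  df <- data.frame(chrom = "chr1", start = starts, end = starts + 100,
                   gene_id = paste0("g", 1:6))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  path
}

writeEdgeFile <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}

# exhaustive hypergeometric tail by enumerating all n-subsets of 1..M
# against the fixed term set 1..K
enumTail <- function(k, K, n, M) {
  if (k == 0) return(1)
  if (n == 0) return(0)
  subsets <- utils::combn(M, n)
  mean(colSums(subsets <= K) >= k)
}
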