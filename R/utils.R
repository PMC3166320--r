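# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

# connected components of an undirected graph given as edge index vectors;
# returns a membership vector of length n
.components <- function(n, i, j) {
  adj <- vector("list", n)
  for (k in seq_along(i)) {
    adj[[i[k]]] <- c(adj[[i[k]]], j[k])
    adj[[j[k]]] <- c(adj[[j[k]]], i[k])
  }
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
      nb <- adj[[v]]
      new <- nb[comp[nb] == 0L]
      comp[new] <- cur
      queue <- c(queue, new)
    }
  }
  comp
}
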