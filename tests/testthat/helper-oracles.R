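# Independent oracles used to cross-check the implementation. These are
# deliberately naive (dense algebra, exhaustive loops) and share no code with
# the package internals.

# Exact propagation fixed point by dense base-R elimination:
# solve (I - d P^T) r = (1 - d) f with P the out-degree-normalized adjacency.
oracleFixedPoint <- function(edgeDf, nodeIds, f, d) {
  n <- length(nodeIds)
  W <- matrix(0, n, n, dimnames = list(nodeIds, nodeIds))
  for (k in seq_len(nrow(edgeDf)))
    W[edgeDf$from[k], edgeDf$to[k]] <- 1
  deg <- rowSums(W)
  P <- W
  for (i in seq_len(n)) if (deg[i] > 0) P[i, ] <- P[i, ] / deg[i]
  r <- solve(diag(n) - d * t(P), (1 - d) * f[nodeIds])
  setNames(as.numeric(r), nodeIds)
}

# Brute-force BH step-up, literally following the definition.
oracleBH <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  sorted <- p[ord]
  for (i in seq_len(m)) adj[i] <- sorted[i] * m / i
  for (i in rev(seq_len(m - 1))) adj[i] <- min(adj[i], adj[i + 1])
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

# Exhaustive hypergeometric upper tail: P(overlap >= k) by enumerating the
# overlap distribution from binomial coefficients.
oracleHyperUpper <- function(k, setSize, universeSize, querySize) {
  kk <- max(0, querySize + setSize - universeSize):min(setSize, querySize)
  probs <- choose(setSize, kk) * choose(universeSize - setSize, querySize - kk) /
    choose(universeSize, querySize)
  sum(probs[kk >= k])
}

# Triple-loop plug-in conditional mutual information in nats.
oracleCMI <- function(a, b, c) {
  n <- length(a)
  total <- 0
  for (cv in unique(c)) {
    idx <- c == cv
    pc <- sum(idx) / n
    av <- a[idx]; bv <- b[idx]; nc <- length(av)
    for (au in unique(av)) for (bu in unique(bv)) {
      pab <- sum(av == au & bv == bu) / nc
      if (pab > 0) {
        pa <- sum(av == au) / nc
        pb <- sum(bv == bu) / nc
        total <- total + pc * pab * log(pab / (pa * pb))
      }
    }
  }
  total
}

# Exhaustive KS sup over every rank cutoff.
oracleKSD <- function(isTarget) {
  m <- sum(isTarget); nb <- sum(!isTarget)
  best <- -Inf
  for (k in seq_along(isTarget)) {
    d <- sum(isTarget[1:k]) / m - sum(!isTarget[1:k]) / nb
    best <- max(best, d)
  }
  best
}

# Random directed network + scores for property tests (no self-loops, no
# duplicate edges).
randomInstance <- function(n, pEdge = 0.05, seed = 1) {
  withr::with_seed(seed, {
    ids <- sprintf("N%03d", seq_len(n))
    pairs <- expand.grid(from = seq_len(n), to = seq_len(n))
    pairs <- pairs[pairs$from != pairs$to, ]
    keep <- runif(nrow(pairs)) < pEdge
    f <- setNames(rexp(n), ids)
    list(ids = ids,
         edges = data.frame(from = ids[pairs$from[keep]],
                            to = ids[pairs$to[keep]],
                            stringsAsFactors = FALSE),
         f = f)
  })
}

asNetwork <- function(inst) {
  DependencyNetwork(from = inst$edges$from, to = inst$edges$to,
                    nodes = inst$ids)
}

writeTempTsv <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
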