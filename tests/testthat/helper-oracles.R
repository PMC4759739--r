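# Independent oracles and tiny fixture builders shared across test files.
# Each oracle is a deliberately naive re-derivation (brute-force sums,
# double loops, per-gene enumeration) kept free of any package internals.

# exact hypergeometric upper tail by combinatorial summation
bruteHypergeomTail <- function(k, K, n, N) {
  xs <- k:min(K, n)
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

# Benjamini-Hochberg step-up computed by hand
bruteBH <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  q[m] <- min(1, ps[m])
  if (m > 1) for (i in (m - 1):1) q[i] <- min(q[i + 1], min(1, ps[i] * m / i))
  out <- numeric(m)
  out[o] <- q
  out
}

# all significant Pearson pairs by an explicit double loop over cor.test
bruteCoexEdges <- function(mat, rMin, pMax) {
  g <- rownames(mat)
  res <- data.frame(from = character(), to = character(), r = numeric())
  for (i in seq_along(g)) for (j in seq_along(g)) {
    if (j <= i) next
    ct <- suppressWarnings(stats::cor.test(mat[i, ], mat[j, ]))
    if (is.na(ct$estimate)) next
    if (abs(ct$estimate) >= rMin && ct$p.value < pMax)
      res <- rbind(res, data.frame(from = g[i], to = g[j],
                                   r = unname(ct$estimate)))
  }
  res
}

# Venn regions by per-gene signature enumeration
bruteVennRegions <- function(sets) {
  genes <- unique(unlist(sets))
  out <- list()
  for (g in genes) {
    sig <- paste(names(sets)[vapply(sets, function(s) g %in% s, TRUE)],
                 collapse = "&")
    out[[sig]] <- c(out[[sig]], g)
  }
  lapply(out, sort)
}

# ordinary two-sample pooled-variance t statistic, written out longhand
bruteOrdinaryT <- function(a, b) {
  sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) /
    (length(a) + length(b) - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
}

# random undirected graph as a plain edge data.frame
randomGraphEdges <- function(nNodes, pEdge) {
  nodes <- sprintf("n%02d", seq_len(nNodes))
  pairs <- which(upper.tri(diag(nNodes)), arr.ind = TRUE)
  keep <- stats::runif(nrow(pairs)) < pEdge
  data.frame(from = nodes[pairs[keep, 1]], to = nodes[pairs[keep, 2]],
             stringsAsFactors = FALSE)
}

# wrap an edge data.frame into a GeneNetwork via the coexpression slots
edgeListNetwork <- function(edges, nodes = NULL, directed = FALSE) {
  if (is.null(nodes)) nodes <- unique(c(edges$from, edges$to))
  net <- induceGeneActNet(
    genes = nodes,
    relationTable = RelationTable(data.frame(
      source = edges$from, relation_type = "activation",
      target = edges$to, stringsAsFactors = FALSE)),
    keepIsolated = TRUE)
  net
}

# small deterministic expression fixture: genes x samples from one seed
randomExprMatrix <- function(nGenes, nSamples, seed) {
  set.seed(seed)
  m <- matrix(rnorm(nGenes * nSamples, 8, 1), nGenes, nSamples)
  dimnames(m) <- list(sprintf("g%03d", seq_len(nGenes)),
                      sprintf("s%02d", seq_len(nSamples)))
  m
}
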