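## Shared fixture builders. All fixtures are generated in code under fixed
## seeds; no data files.

## A MicrobialNetwork from a raw adjacency matrix.
netFromAdj <- function(adj, directed = FALSE, type = if (directed)
  "aggression" else "mutualism") {
  m <- nrow(adj)
  nodes <- rownames(adj)
  if (is.null(nodes)) nodes <- paste0("t", seq_len(m))
  w <- (adj != 0) * 1
  new("MicrobialNetwork", interactionType = type, nodes = nodes,
      adjacency = (adj != 0) * 1, weights = w, directed = directed,
      pvalues = matrix(0, 0, 0), indeterminate = matrix(FALSE, 0, 0),
      provenance = "fixture")
}

## Random connected undirected graph on m nodes (spanning tree + extras).
randomConnectedGraph <- function(m, extraProb = 0.15) {
  adj <- matrix(0, m, m)
  for (v in 2:m) {
    u <- sample.int(v - 1, 1)
    adj[u, v] <- adj[v, u] <- 1
  }
  extra <- which(upper.tri(adj) & adj == 0)
  on <- extra[stats::runif(length(extra)) < extraProb]
  adj[on] <- 1
  adj <- pmax(adj, t(adj))
  adj
}

## Random strongly-connected directed graph: a Hamiltonian cycle plus
## random extra arcs (no dangling nodes, every node reachable).
randomStrongGraph <- function(m, extraProb = 0.15) {
  adj <- matrix(0, m, m)
  ord <- sample.int(m)
  for (i in seq_len(m)) adj[ord[i], ord[i %% m + 1]] <- 1
  off <- which(adj == 0 & row(adj) != col(adj))
  on <- off[stats::runif(length(off)) < extraProb]
  adj[on] <- 1
  adj
}

## Path graph u - v - w.
pathGraph3 <- function() {
  adj <- matrix(0, 3, 3, dimnames = list(c("u", "v", "w"), c("u", "v", "w")))
  adj[1, 2] <- adj[2, 1] <- adj[2, 3] <- adj[3, 2] <- 1
  adj
}

## Draw n samples from a discrete power law P(k) ~ k^-alpha, k >= 1,
## by inverse CDF on a truncated support (independent of the package's
## internal sampler).
rPowerLawDiscrete <- function(n, alpha, kmax = 1e5) {
  ks <- seq_len(kmax)
  p <- ks^(-alpha)
  cdf <- cumsum(p) / sum(p)
  findInterval(stats::runif(n), cdf) + 1L
}

## Balanced three-class genotype vector of length n (codes 1/0/-1).
balancedGenotype <- function(n) {
  rep(c(1, 0, -1), length.out = n)[sample.int(n)]
}

## HWE genotype codes at allele frequency q.
hweGenotype <- function(n, q) stats::rbinom(n, 2, q) - 1
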