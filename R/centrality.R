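## Emergent network properties. Shortest paths, path counts and all six
## indices are implemented directly (BFS / Brandes accumulation / power
## iteration) so they can be cross-checked against an independent graph
## library in the test suite.

.adjList <- function(adj, directed) {
  m <- nrow(adj)
  if (!directed) adj <- pmax(adj, t(adj))
  lapply(seq_len(m), function(u) which(adj[u, ] != 0))
}

#' Unweighted shortest-path structure of a network
#'
#' Breadth-first search from every node, respecting directedness. Returns
#' hop distances D(u,v) (Inf for unreachable pairs) and the number of
#' distinct shortest paths g(u,v).
#'
#' @param net a \code{\linkS4class{MicrobialNetwork}}, or a plain adjacency
#'   matrix (then \code{directed} must be given).
#' @param directed only used when \code{net} is a matrix.
#' @return list with matrices \code{D} (distances) and \code{counts}
#'   (shortest-path counts; 0 when unreachable).
#' @export
shortestPaths <- function(net, directed = NULL) {
  if (is(net, "MicrobialNetwork")) {
    adj <- net@adjacency; directed <- net@directed; nodes <- net@nodes
  } else {
    adj <- as.matrix(net)
    if (is.null(directed)) stop("directed must be given for a raw matrix")
    nodes <- rownames(adj)
    if (is.null(nodes)) nodes <- as.character(seq_len(nrow(adj)))
  }
  m <- nrow(adj)
  if (m == 0) stop("empty network")
  nb <- .adjList(adj, directed)
  D <- matrix(Inf, m, m, dimnames = list(nodes, nodes))
  G <- matrix(0, m, m, dimnames = list(nodes, nodes))
  for (s in seq_len(m)) {
    dist <- rep(Inf, m); sigma <- numeric(m)
    dist[s] <- 0; sigma[s] <- 1
    frontier <- s
    while (length(frontier)) {
      nxt <- integer()
      for (u in frontier) {
        for (w in nb[[u]]) {
          if (is.infinite(dist[w])) {
            dist[w] <- dist[u] + 1
            nxt <- c(nxt, w)
            sigma[w] <- sigma[u]
          } else if (dist[w] == dist[u] + 1) {
            sigma[w] <- sigma[w] + sigma[u]
          }
        }
      }
      frontier <- unique(nxt)
    }
    D[s, ] <- dist
    G[s, ] <- sigma
  }
  list(D = D, counts = G)
}

## Brandes accumulation: betweenness with fractional counting of multiple
## shortest paths, sum over ordered source-target pairs.
.brandes <- function(adj, directed) {
  m <- nrow(adj)
  nb <- .adjList(adj, directed)
  bc <- numeric(m)
  for (s in seq_len(m)) {
    dist <- rep(-1L, m); sigma <- numeric(m); delta <- numeric(m)
    preds <- vector("list", m)
    dist[s] <- 0L; sigma[s] <- 1
    stack <- integer()
    queue <- c(s); head <- 1L
    while (head <= length(queue)) {
      u <- queue[head]; head <- head + 1L
      stack <- c(stack, u)
      for (w in nb[[u]]) {
        if (dist[w] < 0L) {
          dist[w] <- dist[u] + 1L
          queue <- c(queue, w)
        }
        if (dist[w] == dist[u] + 1L) {
          sigma[w] <- sigma[w] + sigma[u]
          preds[[w]] <- c(preds[[w]], u)
        }
      }
    }
    for (w in rev(stack)) {
      for (u in preds[[w]]) {
        delta[u] <- delta[u] + sigma[u] / sigma[w] * (1 + delta[w])
      }
      if (w != s) bc[w] <- bc[w] + delta[w]
    }
  }
  if (!directed) bc / 2 else bc
}

.leadingEigen <- function(adj, directed) {
  m <- nrow(adj)
  if (all(adj == 0)) return(rep(NA_real_, m))
  if (!directed) {
    e <- eigen(pmax(adj, t(adj)), symmetric = TRUE)
    v <- e$vectors[, which.max(e$values)]
  } else {
    ## in-edge (left) eigenvector: importance accrues from being linked
    ## to, consistent with the incoming-link PageRank recursion
    e <- eigen(t(adj))
    v <- Re(e$vectors[, which.max(Mod(e$values))])
  }
  v <- abs(v)
  v / sqrt(sum(v^2))
}

#' PageRank by the printed recursion
#'
#' Solves P(u) = (1 - d) + d * sum_v a_vu P(v) / K_v, where K_v is the
#' out-degree of the linking node v and d the damping coefficient. This is
#' the non-normalized teleportation variant as printed; the standard
#' variant with teleportation (1 - d) / m is available and its solution is
#' exactly proportional (factor m), so rankings coincide. Mass of dangling
#' nodes (K_v = 0) is redistributed uniformly.
#'
#' @param adj adjacency matrix (edges u -> v in row u).
#' @param d damping coefficient (default 0.85).
#' @param variant "printed" or "normalized".
#' @param tol fixed-point tolerance (default 1e-13).
#' @param maxIter iteration cap.
#' @export
pageRank <- function(adj, d = 0.85, variant = c("printed", "normalized"),
                     tol = 1e-13, maxIter = 100000) {
  variant <- match.arg(variant)
  m <- nrow(adj)
  K <- rowSums(adj != 0)
  dangling <- K == 0
  tele <- if (variant == "printed") rep(1 - d, m) else rep((1 - d) / m, m)
  P <- tele
  A <- (adj != 0) * 1
  for (it in seq_len(maxIter)) {
    contrib <- as.vector(crossprod(A, ifelse(dangling, 0, P / pmax(K, 1))))
    dangMass <- sum(P[dangling]) / m
    Pnew <- tele + d * (contrib + dangMass)
    if (max(abs(Pnew - P)) < tol) {
      P <- Pnew
      break
    }
    P <- Pnew
  }
  P
}

#' The six emergent-property indices of an interaction network
#'
#' Node-level: closeness C(u) = 1 / sum_v D(u,v); betweenness B(u) =
#' sum over pairs of the fraction of shortest paths through u;
#' eccentricity E(u) = 1 / max_v D(u,v); eigenvector centrality G solving
#' A G = lambda G (leading eigenpair, nonnegative, unit norm); PageRank by
#' the damped recursion (see \code{\link{pageRank}}). Network-level:
#' connectivity = mean number of neighbors. On disconnected graphs,
#' closeness and eccentricity are computed within each node's reachable
#' set (unreachable pairs excluded) and the reachable fraction is
#' reported.
#'
#' The per-host scalar phenotypes used for QTL mapping are the means over
#' nodes of each node-level index (plus connectivity), returned in
#' \code{propertySummary()}.
#'
#' @param net a \code{\linkS4class{MicrobialNetwork}}.
#' @param d PageRank damping coefficient (default 0.85).
#' @param pagerankVariant see \code{\link{pageRank}}.
#' @return a \code{\linkS4class{CentralityProfile}}; all indices NA for an
#'   empty (edgeless) network.
#' @export
centralities <- function(net, d = 0.85,
                         pagerankVariant = c("printed", "normalized")) {
  pagerankVariant <- match.arg(pagerankVariant)
  stopifnot(is(net, "MicrobialNetwork"))
  m <- length(net@nodes)
  empty <- all(net@adjacency == 0)
  if (empty) {
    ni <- data.frame(node = net@nodes,
                     closeness = NA_real_, betweenness = NA_real_,
                     eccentricity = NA_real_, eigenvector = NA_real_,
                     pagerank = NA_real_, degree = 0,
                     reachableFraction = 0, stringsAsFactors = FALSE)
    smry <- c(connectivity = NA_real_, closeness = NA_real_,
              betweenness = NA_real_, eccentricity = NA_real_,
              eigenvector = NA_real_, pagerank = NA_real_)
    return(new("CentralityProfile", nodeIndices = ni,
               connectivity = NA_real_, summary = smry, damping = d,
               pagerankVariant = pagerankVariant))
  }
  sp <- shortestPaths(net)
  D <- sp$D
  closeness <- eccentricity <- reach <- numeric(m)
  for (u in seq_len(m)) {
    dv <- D[u, -u]
    fin <- is.finite(dv)
    reach[u] <- mean(fin)
    if (any(fin)) {
      closeness[u] <- 1 / sum(dv[fin])
      eccentricity[u] <- 1 / max(dv[fin])
    } else {
      closeness[u] <- NA_real_
      eccentricity[u] <- NA_real_
    }
  }
  betweenness <- .brandes(net@adjacency, net@directed)
  eig <- .leadingEigen(net@adjacency, net@directed)
  pr <- pageRank(net@adjacency, d = d, variant = pagerankVariant)
  nbr <- .adjList(net@adjacency, directed = FALSE)  # union of in/out
  degree <- lengths(nbr)
  con <- mean(degree)
  ni <- data.frame(node = net@nodes, closeness = closeness,
                   betweenness = betweenness, eccentricity = eccentricity,
                   eigenvector = eig, pagerank = pr, degree = degree,
                   reachableFraction = reach, stringsAsFactors = FALSE)
  smry <- c(connectivity = con,
            closeness = mean(closeness, na.rm = TRUE),
            betweenness = mean(betweenness, na.rm = TRUE),
            eccentricity = mean(eccentricity, na.rm = TRUE),
            eigenvector = mean(eig, na.rm = TRUE),
            pagerank = mean(pr, na.rm = TRUE))
  new("CentralityProfile", nodeIndices = ni, connectivity = con,
      summary = smry, damping = d, pagerankVariant = pagerankVariant)
}

#' Hub (keystone) microbes and role partitions
#'
#' Hubs are nodes whose number of neighbors exceeds the configured cutoff
#' (default: median degree + 1 raw median absolute deviation). Hub vs
#' non-hub abundance is compared with a two-sample t-test. For aggression
#' networks, nodes are additionally partitioned into hawks (out-edges
#' only), doves (in-edges only) and hawk-doves (both).
#'
#' @param net a \code{\linkS4class{MicrobialNetwork}}.
#' @param abundance named numeric vector of taxon abundances (e.g. cohort
#'   means), aligned by name or position to the network nodes.
#' @param cutoff function(degrees) returning the threshold; the default is
#'   \code{median + 1 * mad} (raw MAD, constant = 1).
#' @return list with \code{hubs} (character), \code{degrees},
#'   \code{tTest} (htest or NULL), and \code{roles} (aggression networks
#'   only: named character hawk/dove/hawk-dove for linked nodes).
#' @export
detectHubs <- function(net, abundance = NULL,
                       cutoff = function(deg) stats::median(deg) +
                         stats::mad(deg, constant = 1)) {
  stopifnot(is(net, "MicrobialNetwork"))
  if (all(net@adjacency == 0)) stop("empty network")
  deg <- lengths(.adjList(net@adjacency, directed = FALSE))
  names(deg) <- net@nodes
  thr <- cutoff(deg)
  hubs <- net@nodes[deg > thr]
  if (!length(hubs))
    warning("no hubs above the degree cutoff")
  tt <- NULL
  if (!is.null(abundance)) {
    ab <- if (!is.null(names(abundance))) abundance[net@nodes] else abundance
    isHub <- net@nodes %in% hubs
    if (length(hubs) >= 2 && sum(!isHub) >= 2)
      tt <- stats::t.test(ab[isHub], ab[!isHub])
  }
  roles <- NULL
  if (net@interactionType == "aggression") {
    outd <- rowSums(net@adjacency != 0)
    ind <- colSums(net@adjacency != 0)
    roles <- ifelse(outd > 0 & ind > 0, "hawk-dove",
                    ifelse(outd > 0, "hawk",
                           ifelse(ind > 0, "dove", NA)))
    names(roles) <- net@nodes
    roles <- roles[!is.na(roles)]
  }
  list(hubs = hubs, degrees = deg, threshold = thr, tTest = tt,
       roles = roles)
}

## Hurwitz zeta for integer xmin: zeta(a) - sum_{k<xmin} k^-a
.hurwitz <- function(a, xmin) {
  z <- pracma::zeta(a)
  if (xmin > 1) z <- z - sum(seq_len(xmin - 1)^(-a))
  z
}

.plFit <- function(k, xmin) {
  k <- k[k >= xmin]
  n <- length(k)
  sl <- sum(log(k))
  nll <- function(a) n * log(.hurwitz(a, xmin)) + a * sl
  opt <- stats::optimize(nll, c(1.01, 12))
  list(alpha = opt$minimum, n = n)
}

.plCdf <- function(alpha, xmin, kmax = 100000L) {
  ks <- xmin:kmax
  pk <- ks^(-alpha) / .hurwitz(alpha, xmin)
  cumsum(pk) / sum(pk)  # renormalize the truncation
}

.plSample <- function(n, alpha, xmin, cdf = NULL) {
  if (is.null(cdf)) cdf <- .plCdf(alpha, xmin)
  xmin - 1L + findInterval(stats::runif(n), cdf) + 1L
}

.plKs <- function(k, alpha, xmin, cdf = NULL) {
  k <- k[k >= xmin]
  if (is.null(cdf)) cdf <- .plCdf(alpha, xmin)
  ks <- sort(unique(k))
  emp <- stats::ecdf(k)(ks)
  theo <- cdf[ks - xmin + 1L]
  max(abs(emp - theo))
}

#' Scale-freeness test: discrete power-law fit of the degree distribution
#'
#' Maximum-likelihood estimate of the exponent of a discrete power law
#' P(k) proportional to k^-alpha for k >= xmin, with a parametric-bootstrap
#' Kolmogorov-Smirnov goodness-of-fit p-value (small p rejects the power
#' law).
#'
#' @param net a \code{\linkS4class{MicrobialNetwork}} or a vector of
#'   degrees.
#' @param xmin smallest degree included in the fit (default 1).
#' @param nBoot bootstrap replicates for the goodness of fit (default 200).
#' @param seed RNG seed for the bootstrap.
#' @return list(alpha, ksStatistic, p, n, defined). With fewer than 10
#'   nodes of degree >= xmin the result is flagged undefined (all NA).
#' @export
powerlawTest <- function(net, xmin = 1L, nBoot = 200, seed = 1) {
  k <- if (is(net, "MicrobialNetwork")) {
    lengths(.adjList(net@adjacency, directed = FALSE))
  } else as.integer(net)
  k <- k[k >= xmin]
  if (length(k) < 10)
    return(list(alpha = NA_real_, ksStatistic = NA_real_, p = NA_real_,
                n = length(k), defined = FALSE))
  fit <- .plFit(k, xmin)
  cdf <- .plCdf(fit$alpha, xmin)
  ks0 <- .plKs(k, fit$alpha, xmin, cdf)
  oldSeed <- .saveSeed(); on.exit(.restoreSeed(oldSeed))
  set.seed(seed)
  exceed <- 0
  for (b in seq_len(nBoot)) {
    kb <- .plSample(fit$n, fit$alpha, xmin, cdf)
    fb <- .plFit(kb, xmin)
    ksb <- .plKs(kb, fb$alpha, xmin)
    if (ksb >= ks0) exceed <- exceed + 1
  }
  list(alpha = fit$alpha, ksStatistic = ks0,
       p = (1 + exceed) / (nBoot + 1), n = fit$n, defined = TRUE)
}
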