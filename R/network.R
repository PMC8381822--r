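## Network reconstruction from descriptor tensors.

.pairKey <- function(m) {
  K <- matrix(0L, m, m)
  pairs <- which(upper.tri(K), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  K[pairs] <- seq_len(nrow(pairs))
  K[lower.tri(K)] <- t(K)[lower.tri(K)]
  K
}

#' Winsorize descriptor values per host
#'
#' Z_mu and Z_an explode as the two abundances approach each other; this
#' caps each host's values at the given upper quantile before network
#' construction.
#' @param mat hosts x pairs descriptor matrix.
#' @param q upper quantile (default 0.99).
#' @keywords internal
.winsorizeRows <- function(mat, q) {
  out <- mat
  for (h in seq_len(nrow(mat))) {
    r <- mat[h, ]
    if (all(is.na(r))) next
    cap <- stats::quantile(r, q, na.rm = TRUE, names = FALSE)
    out[h, ] <- pmin(r, cap)
  }
  out
}

#' Build a cohort-average interaction network with edge significance testing
#'
#' An edge is retained when its descriptor values across hosts are
#' significantly elevated relative to a within-host permutation null: for
#' each permutation, every host's taxon labels are shuffled independently,
#' so the pair slot receives the descriptor of a random same-host pair;
#' the null statistic is the cross-host mean. One-sided permutation
#' p-values are BH-adjusted and thresholded at \code{alpha}. Edge weight is
#' the cross-host mean descriptor. Directed types (aggression, altruism)
#' are oriented from the more to the less abundant taxon by majority vote
#' across hosts.
#'
#' @param tensor an \code{\linkS4class{InteractionTensor}} (needs >= 2 hosts).
#' @param type interaction type.
#' @param alpha BH-FDR level (default 0.05).
#' @param B number of permutations (default 1000).
#' @param seed RNG seed for the permutation null (default 1).
#' @param winsorize upper quantile for per-host winsorization of Z_mu/Z_an
#'   (default 0.99; \code{NULL} disables). Logged via message when active.
#' @param provenance label stored on the network.
#' @return a \code{\linkS4class{MicrobialNetwork}}. If every edge is
#'   filtered out, an empty network is returned with a warning. Edges whose
#'   permutation null is degenerate (constant) are flagged in the
#'   \code{indeterminate} slot and not retained.
#' @export
buildNetwork <- function(tensor, type = INTERACTION_TYPES, alpha = 0.05,
                         B = 1000, seed = 1, winsorize = 0.99,
                         provenance = "cohort-average") {
  type <- match.arg(type)
  stopifnot(is(tensor, "InteractionTensor"))
  nh <- length(tensor@hosts)
  if (nh < 2) stop("need at least 2 hosts for the edge significance test")
  vals <- descriptorMatrix(tensor, type)
  if (!is.null(winsorize) && type %in% c("mutualism", "antagonism")) {
    vals <- .winsorizeRows(vals, winsorize)
    message("per-host winsorization at quantile ", winsorize, " applied")
  }
  m <- length(tensor@taxa)
  np <- nrow(tensor@pairs)
  obs <- colMeans(vals, na.rm = TRUE)
  K <- .pairKey(m)
  P1 <- tensor@pairs[, 1]; P2 <- tensor@pairs[, 2]
  oldSeed <- .saveSeed(); on.exit(.restoreSeed(oldSeed))
  set.seed(seed)
  exceed <- numeric(np)
  nullSq <- numeric(np); nullMeanAcc <- numeric(np)
  for (b in seq_len(B)) {
    acc <- numeric(np)
    cnt <- numeric(np)
    for (h in seq_len(nh)) {
      perm <- sample.int(m)
      idx <- K[cbind(perm[P1], perm[P2])]
      v <- vals[h, idx]
      ok <- !is.na(v)
      acc[ok] <- acc[ok] + v[ok]
      cnt <- cnt + ok
    }
    nb <- acc / pmax(cnt, 1)
    nb[cnt == 0] <- NA
    exceed <- exceed + (!is.na(nb) & nb >= obs - 1e-12)
    nullMeanAcc <- nullMeanAcc + ifelse(is.na(nb), 0, nb)
    nullSq <- nullSq + ifelse(is.na(nb), 0, nb^2)
  }
  pval <- (1 + exceed) / (B + 1)
  nullVar <- nullSq / B - (nullMeanAcc / B)^2
  indet <- nullVar < 1e-24
  padj <- stats::p.adjust(pval, method = "BH")
  keep <- !is.na(obs) & padj <= alpha & !indet
  if (any(indet))
    warning(sum(indet), " edge(s) with degenerate permutation null ",
            "flagged indeterminate")
  directed <- type %in% DIRECTED_TYPES
  adj <- matrix(0, m, m)
  wts <- matrix(NA_real_, m, m)
  pm <- matrix(NA_real_, m, m)
  im <- matrix(FALSE, m, m)
  for (p in which(keep)) {
    i <- P1[p]; j <- P2[p]
    if (directed) {
      ## orient from more to less abundant: majority vote of uFirst
      iIsU <- mean(tensor@uFirst[, p], na.rm = TRUE) >= 0.5
      if (iIsU) { adj[i, j] <- 1; wts[i, j] <- obs[p] }
      else { adj[j, i] <- 1; wts[j, i] <- obs[p] }
    } else {
      adj[i, j] <- adj[j, i] <- 1
      wts[i, j] <- wts[j, i] <- obs[p]
    }
  }
  for (p in seq_len(np)) {
    pm[P1[p], P2[p]] <- pm[P2[p], P1[p]] <- padj[p]
    im[P1[p], P2[p]] <- im[P2[p], P1[p]] <- indet[p]
  }
  if (!any(keep))
    warning("all edges filtered out: returning empty network")
  new("MicrobialNetwork", interactionType = type, nodes = tensor@taxa,
      adjacency = adj, weights = wts, directed = directed, pvalues = pm,
      provenance = provenance, indeterminate = im)
}

#' Build the interaction network of a single host
#'
#' Per-host networks (used as mapping phenotype sources) are built without
#' the cross-host significance test: edges are all finite descriptor
#' values, optionally restricted to those above a per-host descriptor
#' quantile.
#'
#' @param tensor an \code{\linkS4class{InteractionTensor}}.
#' @param type interaction type.
#' @param host host identifier or index.
#' @param quantile retain edges with descriptor above this per-host
#'   quantile (default 0.9; \code{NULL} keeps all finite descriptors).
#' @return a \code{\linkS4class{MicrobialNetwork}}.
#' @export
perHostNetwork <- function(tensor, type = INTERACTION_TYPES, host,
                           quantile = 0.9) {
  type <- match.arg(type)
  stopifnot(is(tensor, "InteractionTensor"))
  if (is.character(host)) host <- match(host, tensor@hosts)
  if (is.na(host) || host < 1 || host > length(tensor@hosts))
    stop("unknown host")
  vals <- descriptorMatrix(tensor, type)[host, ]
  keep <- is.finite(vals)
  if (!is.null(quantile) && any(keep)) {
    thr <- stats::quantile(vals[keep], quantile, names = FALSE)
    keep <- keep & vals >= thr
  }
  m <- length(tensor@taxa)
  adj <- matrix(0, m, m); wts <- matrix(NA_real_, m, m)
  directed <- type %in% DIRECTED_TYPES
  P1 <- tensor@pairs[, 1]; P2 <- tensor@pairs[, 2]
  for (p in which(keep)) {
    i <- P1[p]; j <- P2[p]
    if (directed) {
      if (isTRUE(tensor@uFirst[host, p])) { adj[i, j] <- 1; wts[i, j] <- vals[p] }
      else { adj[j, i] <- 1; wts[j, i] <- vals[p] }
    } else {
      adj[i, j] <- adj[j, i] <- 1
      wts[i, j] <- wts[j, i] <- vals[p]
    }
  }
  new("MicrobialNetwork", interactionType = type, nodes = tensor@taxa,
      adjacency = adj, weights = wts, directed = directed,
      pvalues = matrix(0, 0, 0), indeterminate = matrix(FALSE, 0, 0),
      provenance = paste("host", tensor@hosts[host]))
}
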