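#' @import methods
NULL

INTERACTION_TYPES <- c("mutualism", "antagonism", "aggression", "altruism")
DIRECTED_TYPES <- c("aggression", "altruism")

#' InteractionTensor: per-host, per-pair interaction descriptors
#'
#' Holds, for every host and every unordered taxon pair, the four
#' behavioral-ecology descriptors (mutualism Z_mu, antagonism Z_an,
#' aggression Z_ag, altruism Z_al) together with the pair orientation
#' (which member was the more abundant microbe u in each host).
#'
#' @slot hosts character vector of host identifiers.
#' @slot taxa character vector of taxon identifiers.
#' @slot pairs integer matrix (nPairs x 2) of taxon indices, first < second.
#' @slot descriptors named list of four numeric matrices (hosts x pairs):
#'   \code{Zmu}, \code{Zan}, \code{Zag}, \code{Zal}. Pairs whose
#'   preconditions fail (ties, zero abundance) are \code{NA}.
#' @slot uFirst logical matrix (hosts x pairs); \code{TRUE} when the first
#'   member of the pair is the more abundant microbe u in that host.
#' @slot anForm character; which rendering of the antagonism descriptor
#'   was used ("reciprocal-product" or "inverse-mutualism").
#' @export
setClass("InteractionTensor",
  representation(
    hosts = "character",
    taxa = "character",
    pairs = "matrix",
    descriptors = "list",
    uFirst = "matrix",
    anForm = "character"
  )
)

setValidity("InteractionTensor", function(object) {
  msgs <- character()
  np <- nrow(object@pairs)
  nh <- length(object@hosts)
  if (ncol(object@pairs) != 2L) msgs <- c(msgs, "pairs must have two columns")
  if (!identical(sort(names(object@descriptors)),
                 sort(c("Zmu", "Zan", "Zag", "Zal"))))
    msgs <- c(msgs, "descriptors must be Zmu, Zan, Zag, Zal")
  for (nm in names(object@descriptors)) {
    d <- object@descriptors[[nm]]
    if (!is.matrix(d) || nrow(d) != nh || ncol(d) != np)
      msgs <- c(msgs, sprintf("descriptor %s has wrong dimensions", nm))
  }
  if (nrow(object@uFirst) != nh || ncol(object@uFirst) != np)
    msgs <- c(msgs, "uFirst has wrong dimensions")
  if (np > 0 && any(object@pairs[, 1] >= object@pairs[, 2]))
    msgs <- c(msgs, "pair indices must satisfy first < second")
  if (length(msgs)) msgs else TRUE
})

#' MicrobialNetwork: a significance-filtered interaction network
#'
#' @slot interactionType one of mutualism, antagonism, aggression, altruism.
#' @slot nodes character vector of taxa.
#' @slot adjacency binary numeric matrix; symmetric for undirected types.
#' @slot weights numeric matrix of edge weights (cross-host mean
#'   descriptor); \code{NA} off-edges.
#' @slot directed logical; \code{TRUE} for aggression/altruism.
#' @slot pvalues numeric matrix of BH-adjusted edge p-values (pair-symmetric),
#'   or a 0x0 matrix for per-host networks built without a significance test.
#' @slot provenance character label (e.g. "cohort-average winter",
#'   "host H3").
#' @slot indeterminate logical matrix marking edges whose permutation null
#'   was degenerate (constant); 0x0 when not applicable.
#' @export
setClass("MicrobialNetwork",
  representation(
    interactionType = "character",
    nodes = "character",
    adjacency = "matrix",
    weights = "matrix",
    directed = "logical",
    pvalues = "matrix",
    provenance = "character",
    indeterminate = "matrix"
  )
)

setValidity("MicrobialNetwork", function(object) {
  msgs <- character()
  m <- length(object@nodes)
  if (!object@interactionType %in% INTERACTION_TYPES)
    msgs <- c(msgs, "unknown interaction type")
  if (!all(dim(object@adjacency) == c(m, m)))
    msgs <- c(msgs, "adjacency dimensions do not match nodes")
  if (m > 0 && any(diag(object@adjacency) != 0))
    msgs <- c(msgs, "self-edges are not allowed")
  if (!object@directed && m > 0 &&
      !isTRUE(all.equal(object@adjacency, t(object@adjacency))))
    msgs <- c(msgs, "undirected network must have symmetric adjacency")
  w <- object@weights[object@adjacency != 0]
  if (length(w) && any(!is.finite(w)))
    msgs <- c(msgs, "edge weights must be finite")
  if (length(msgs)) msgs else TRUE
})

#' CentralityProfile: node-level and network-level emergent properties
#'
#' @slot nodeIndices data.frame with one row per node and columns
#'   \code{node}, \code{closeness}, \code{betweenness}, \code{eccentricity},
#'   \code{eigenvector}, \code{pagerank}, \code{degree},
#'   \code{reachableFraction}.
#' @slot connectivity network-level connectivity (mean number of neighbors).
#' @slot summary named numeric vector: mean over nodes of each node-level
#'   index, plus connectivity — the per-host scalar phenotypes used for
#'   mapping.
#' @slot damping PageRank damping coefficient used.
#' @slot pagerankVariant "printed" (teleportation 1-d) or "normalized"
#'   ((1-d)/m).
#' @export
setClass("CentralityProfile",
  representation(
    nodeIndices = "data.frame",
    connectivity = "numeric",
    summary = "numeric",
    damping = "numeric",
    pagerankVariant = "character"
  )
)

#' ScanResult: genome scan of one network-property phenotype
#'
#' @slot table data.frame with one row per SNP: id, class means, pooled ML
#'   variance, log-likelihoods, LRT, n used, flags.
#' @slot threshold genome-wide permutation threshold (1-alpha quantile of
#'   the max-LRT null distribution), NA when not computed.
#' @slot alpha significance level used for the threshold.
#' @slot nPerm number of permutations used.
#' @slot phenotype name of the scanned property.
#' @export
setClass("ScanResult",
  representation(
    table = "data.frame",
    threshold = "numeric",
    alpha = "numeric",
    nPerm = "numeric",
    phenotype = "character"
  )
)

#' PathModel: direct/indirect decomposition of a SNP-phenotype correlation
#'
#' @slot direct standardized direct path coefficient P_z<-g.
#' @slot mediatorCoefficients named vector of P_z<-y_j.
#' @slot indirect named vector of indirect effects P_z<-y_j * r_gy_j.
#' @slot correlations list with r_gz, r_gy, r_yz (and the MI-based r_gy
#'   when requested).
#' @slot r2 coefficient of determination of the path system.
#' @slot residualPath path coefficient of unobserved variables,
#'   sqrt(1 - R^2).
#' @slot retained names of mediators retained by the significance screen.
#' @export
setClass("PathModel",
  representation(
    direct = "numeric",
    mediatorCoefficients = "numeric",
    indirect = "numeric",
    correlations = "list",
    r2 = "numeric",
    residualPath = "numeric",
    retained = "character"
  )
)

setValidity("PathModel", function(object) {
  msgs <- character()
  if (length(object@r2) == 1 &&
      (object@r2 < -1e-8 || object@r2 > 1 + 1e-8))
    msgs <- c(msgs, "R^2 must lie in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' CohortBundle: aligned host-level inputs for a mapping study
#'
#' @slot abundance numeric matrix, hosts x taxa.
#' @slot genotypes numeric matrix, hosts x SNPs, codes 1/0/-1 (AA/Aa/aa),
#'   NA allowed.
#' @slot covariates data.frame of host covariates (may be empty).
#' @slot phenotypes data.frame of end-point phenotypes (may be empty).
#' @slot season character vector per host ("winter"/"summer" or NA).
#' @export
setClass("CohortBundle",
  representation(
    abundance = "matrix",
    genotypes = "matrix",
    covariates = "data.frame",
    phenotypes = "data.frame",
    season = "character"
  )
)

setValidity("CohortBundle", function(object) {
  msgs <- character()
  n <- nrow(object@abundance)
  ids <- rownames(object@abundance)
  if (is.null(ids)) msgs <- c(msgs, "abundance must have host row names")
  if (nrow(object@genotypes) > 0) {
    if (nrow(object@genotypes) != n ||
        !identical(rownames(object@genotypes), ids))
      msgs <- c(msgs, "genotype hosts must match abundance hosts")
    g <- object@genotypes
    if (!all(g[!is.na(g)] %in% c(-1, 0, 1)))
      msgs <- c(msgs, "genotype codes must be in {1, 0, -1}")
  }
  if (any(object@abundance < 0, na.rm = TRUE))
    msgs <- c(msgs, "abundances must be nonnegative")
  if (length(object@season) &&
      !all(object@season %in% c("winter", "summer") | is.na(object@season)))
    msgs <- c(msgs, "season must be winter/summer or NA")
  if (length(msgs)) msgs else TRUE
})

## ---- show methods ----

setMethod("show", "InteractionTensor", function(object) {
  cat("InteractionTensor:", length(object@hosts), "hosts x",
      nrow(object@pairs), "taxon pairs (", length(object@taxa), "taxa )\n")
  nmiss <- sum(is.na(object@descriptors$Zmu))
  cat("  antagonism form:", object@anForm, "\n")
  cat("  missing Zmu entries:", nmiss, "\n")
})

setMethod("show", "MicrobialNetwork", function(object) {
  ne <- sum(object@adjacency != 0)
  if (!object@directed) ne <- ne / 2
  cat("MicrobialNetwork [", object@interactionType, "]",
      if (object@directed) "(directed)" else "(undirected)", "\n")
  cat(" ", length(object@nodes), "nodes,", ne, "edges;",
      object@provenance, "\n")
})

setMethod("show", "CentralityProfile", function(object) {
  cat("CentralityProfile:", nrow(object@nodeIndices), "nodes\n")
  cat("  connectivity:", format(object@connectivity, digits = 4), "\n")
  cat("  node-index means:\n")
  print(round(object@summary, 4))
})

setMethod("show", "ScanResult", function(object) {
  cat("ScanResult [", object@phenotype, "]:", nrow(object@table), "SNPs\n")
  if (is.finite(object@threshold))
    cat("  genome-wide threshold (alpha =", object@alpha, ",",
        object@nPerm, "permutations):",
        format(object@threshold, digits = 5), "\n")
  ns <- sum(object@table$significant, na.rm = TRUE)
  cat("  significant SNPs:", ns, "\n")
})

setMethod("show", "PathModel", function(object) {
  cat("PathModel: direct P_z<-g =", format(object@direct, digits = 4), "\n")
  if (length(object@indirect)) {
    cat("  indirect effects:\n")
    print(round(object@indirect, 4))
  }
  cat("  R^2 =", format(object@r2, digits = 4),
      " residual path =", format(object@residualPath, digits = 4), "\n")
})

setMethod("show", "CohortBundle", function(object) {
  cat("CohortBundle:", nrow(object@abundance), "hosts,",
      ncol(object@abundance), "taxa,", ncol(object@genotypes), "SNPs\n")
  if (ncol(object@covariates))
    cat("  covariates:", paste(colnames(object@covariates), collapse = ", "),
        "\n")
  if (ncol(object@phenotypes))
    cat("  phenotypes:", paste(colnames(object@phenotypes), collapse = ", "),
        "\n")
})
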