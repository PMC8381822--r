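## Accessor generics and methods. Slot access from user code is discouraged;
## these are the supported surface.

#' Host identifiers
#' @param x an object with hosts
#' @export
setGeneric("hostNames", function(x) standardGeneric("hostNames"))

#' Taxon / node identifiers
#' @param x an object with taxa or nodes
#' @export
setGeneric("taxonNames", function(x) standardGeneric("taxonNames"))

#' One descriptor matrix (hosts x pairs) from an InteractionTensor
#' @param x an InteractionTensor
#' @param type interaction type
#' @export
setGeneric("descriptorMatrix",
           function(x, type) standardGeneric("descriptorMatrix"))

#' Pair labels of an InteractionTensor
#' @param x an InteractionTensor
#' @export
setGeneric("pairNames", function(x) standardGeneric("pairNames"))

#' Adjacency matrix of a network
#' @param x a MicrobialNetwork
#' @export
setGeneric("adjacencyMatrix", function(x) standardGeneric("adjacencyMatrix"))

#' Edge table of a network
#' @param x a MicrobialNetwork
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))

#' Directedness of a network
#' @param x a MicrobialNetwork
#' @export
setGeneric("isDirected", function(x) standardGeneric("isDirected"))

#' Node-level centrality table
#' @param x a CentralityProfile
#' @export
setGeneric("nodeIndices", function(x) standardGeneric("nodeIndices"))

#' Per-host scalar summaries (means over nodes, plus connectivity)
#' @param x a CentralityProfile
#' @export
setGeneric("propertySummary", function(x) standardGeneric("propertySummary"))

#' Per-SNP scan table
#' @param x a ScanResult
#' @export
setGeneric("scanTable", function(x) standardGeneric("scanTable"))

#' Genome-wide permutation threshold
#' @param x a ScanResult
#' @export
setGeneric("scanThreshold", function(x) standardGeneric("scanThreshold"))

#' Path coefficients of a PathModel
#' @param x a PathModel
#' @export
setGeneric("pathCoefficients", function(x) standardGeneric("pathCoefficients"))

#' @describeIn hostNames hosts of an InteractionTensor
#' @export
setMethod("hostNames", "InteractionTensor", function(x) x@hosts)

#' @describeIn hostNames hosts of a CohortBundle
#' @export
setMethod("hostNames", "CohortBundle", function(x) rownames(x@abundance))

#' @describeIn taxonNames taxa of an InteractionTensor
#' @export
setMethod("taxonNames", "InteractionTensor", function(x) x@taxa)

#' @describeIn taxonNames nodes of a MicrobialNetwork
#' @export
setMethod("taxonNames", "MicrobialNetwork", function(x) x@nodes)

#' @describeIn descriptorMatrix hosts x pairs matrix of one descriptor
#' @export
setMethod("descriptorMatrix", "InteractionTensor", function(x, type) {
  key <- c(mutualism = "Zmu", antagonism = "Zan",
           aggression = "Zag", altruism = "Zal")[[match.arg(type,
                                                            INTERACTION_TYPES)]]
  m <- x@descriptors[[key]]
  dimnames(m) <- list(x@hosts, pairNames(x))
  m
})

#' @describeIn pairNames "taxonA:taxonB" labels
#' @export
setMethod("pairNames", "InteractionTensor", function(x) {
  if (nrow(x@pairs) == 0) return(character())
  paste(x@taxa[x@pairs[, 1]], x@taxa[x@pairs[, 2]], sep = ":")
})

#' @describeIn adjacencyMatrix binary adjacency with node dimnames
#' @export
setMethod("adjacencyMatrix", "MicrobialNetwork", function(x) {
  a <- x@adjacency
  dimnames(a) <- list(x@nodes, x@nodes)
  a
})

#' @describeIn isDirected TRUE for aggression/altruism networks
#' @export
setMethod("isDirected", "MicrobialNetwork", function(x) x@directed)

#' @describeIn edgeTable data.frame(u, v, type, weight, directed); one row
#'   per undirected edge (u < v) or per directed edge
#' @export
setMethod("edgeTable", "MicrobialNetwork", function(x) {
  a <- x@adjacency
  idx <- which(a != 0, arr.ind = TRUE)
  if (!x@directed && nrow(idx)) idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
  data.frame(
    u = x@nodes[idx[, 1]],
    v = x@nodes[idx[, 2]],
    type = rep(x@interactionType, nrow(idx)),
    weight = x@weights[idx],
    directed = rep(x@directed, nrow(idx)),
    stringsAsFactors = FALSE
  )
})

#' @describeIn nodeIndices node-level index table
#' @export
setMethod("nodeIndices", "CentralityProfile", function(x) x@nodeIndices)

#' @describeIn propertySummary named vector of per-network scalar properties
#' @export
setMethod("propertySummary", "CentralityProfile", function(x) x@summary)

#' @describeIn scanTable per-SNP results
#' @export
setMethod("scanTable", "ScanResult", function(x) x@table)

#' @describeIn scanThreshold the (1-alpha) quantile of the max-LRT null
#' @export
setMethod("scanThreshold", "ScanResult", function(x) x@threshold)

#' @describeIn pathCoefficients list(direct, mediators, indirect, residual)
#' @export
setMethod("pathCoefficients", "PathModel", function(x) {
  list(direct = x@direct,
       mediators = x@mediatorCoefficients,
       indirect = x@indirect,
       residual = x@residualPath)
})
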