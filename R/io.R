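## Readers and writers for the supported plain-text formats. Abundance,
## covariate and phenotype tables are tab-delimited with a header row and
## host IDs in the first column; genotypes come from a coded matrix or a
## VCF; networks go out as edge lists and GraphML.

.readHostTable <- function(path, what) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop(what, " file needs a host-ID column plus data")
  ids <- as.character(tab[[1]])
  if (anyDuplicated(ids))
    stop("duplicate host IDs in ", what, " file: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  rownames(tab) <- ids
  tab[-1]
}

#' Read a host x taxon abundance matrix
#'
#' Tab-delimited; header row of taxon names, first column host IDs,
#' nonnegative numeric entries.
#' @param path file path.
#' @export
readAbundance <- function(path) {
  tab <- .readHostTable(path, "abundance")
  mat <- as.matrix(tab)
  if (!is.numeric(mat)) {
    bad <- which(!vapply(tab, is.numeric, TRUE))
    stop("non-numeric abundances in column(s): ",
         paste(colnames(tab)[bad], collapse = ", "))
  }
  neg <- which(mat < 0, arr.ind = TRUE)
  if (nrow(neg))
    stop("negative abundance at host ", rownames(mat)[neg[1, 1]],
         ", taxon ", colnames(mat)[neg[1, 2]])
  mat
}

#' Read a coded genotype matrix
#'
#' Tab-delimited, hosts in rows (first column IDs), SNPs in columns,
#' codes 1/0/-1 (AA/Aa/aa) with NA for missing.
#' @param path file path.
#' @export
readGenotypeMatrix <- function(path) {
  tab <- .readHostTable(path, "genotype")
  mat <- as.matrix(tab)
  vals <- mat[!is.na(mat)]
  if (!all(vals %in% c(-1, 0, 1)))
    stop("genotype codes must be 1, 0, -1 or NA")
  mat
}

#' Read genotypes from a VCF
#'
#' GT fields are mapped by reference-allele dosage: 0/0 -> 1 (AA),
#' 0/1 or 1/0 -> 0 (Aa), 1/1 -> -1 (aa); missing -> NA. Returns a hosts x
#' SNPs coded matrix.
#' @param path VCF path (plain text or gzipped).
#' @export
readGenotypesVCF <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  alt <- function(x) {
    x <- sub("\\|", "/", x)
    vapply(strsplit(x, "/"), function(p) {
      if (any(p == ".") || length(p) != 2) return(NA_real_)
      sum(as.numeric(p) > 0)
    }, 0)
  }
  codes <- apply(gt, 2, alt)
  if (is.null(dim(codes))) codes <- matrix(codes, nrow = nrow(gt),
                                           dimnames = dimnames(gt))
  out <- t(1 - codes)  # alt dosage 0/1/2 -> 1/0/-1
  ids <- rownames(gt)
  if (is.null(ids)) ids <- paste0("snp", seq_len(nrow(gt)))
  colnames(out) <- ids
  out
}

#' Read a covariate or phenotype table (host IDs in the first column)
#' @param path file path.
#' @export
readHostData <- function(path) .readHostTable(path, "host data")

#' Assemble an aligned cohort bundle
#'
#' Hosts missing from any required component are dropped with a logged
#' count; host order follows the abundance table.
#'
#' @param abundance path or matrix (see \code{\link{readAbundance}}).
#' @param genotypes path (coded matrix or .vcf/.vcf.gz) or matrix;
#'   optional.
#' @param covariates,phenotypes paths or data.frames; optional.
#' @param seasonColumn name of a covariate column holding the season
#'   labels; optional.
#' @return a \code{\linkS4class{CohortBundle}}.
#' @export
loadCohort <- function(abundance, genotypes = NULL, covariates = NULL,
                       phenotypes = NULL, seasonColumn = NULL) {
  ab <- if (is.character(abundance)) readAbundance(abundance)
        else as.matrix(abundance)
  if (is.null(rownames(ab))) stop("abundance matrix needs host row names")
  gt <- if (is.null(genotypes)) {
    matrix(numeric(0), 0, 0)
  } else if (is.character(genotypes)) {
    if (grepl("\\.vcf(\\.gz)?$", genotypes)) readGenotypesVCF(genotypes)
    else readGenotypeMatrix(genotypes)
  } else as.matrix(genotypes)
  cv <- if (is.null(covariates)) data.frame()
        else if (is.character(covariates)) readHostData(covariates)
        else as.data.frame(covariates)
  ph <- if (is.null(phenotypes)) data.frame()
        else if (is.character(phenotypes)) readHostData(phenotypes)
        else as.data.frame(phenotypes)
  hosts <- rownames(ab)
  for (comp in list(gt, cv, ph)) {
    if (length(comp) && nrow(comp) > 0)
      hosts <- intersect(hosts, rownames(comp))
  }
  dropped <- nrow(ab) - length(hosts)
  if (dropped > 0)
    message(dropped, " host(s) missing from some component dropped")
  if (!length(hosts)) stop("no hosts shared across all components")
  ab <- ab[hosts, , drop = FALSE]
  if (nrow(gt) > 0) gt <- gt[hosts, , drop = FALSE]
  if (nrow(cv) > 0) cv <- cv[hosts, , drop = FALSE]
  if (nrow(ph) > 0) ph <- ph[hosts, , drop = FALSE]
  season <- character(0)
  if (!is.null(seasonColumn)) {
    if (!seasonColumn %in% colnames(cv))
      stop("season column not found in covariates")
    season <- as.character(cv[[seasonColumn]])
    cv <- cv[setdiff(colnames(cv), seasonColumn)]
  }
  new("CohortBundle", abundance = ab, genotypes = gt,
      covariates = cv, phenotypes = ph, season = season)
}

#' Write a network as a tab-delimited edge list (u, v, type, weight,
#' directed)
#' @param net a MicrobialNetwork.
#' @param path output path.
#' @export
writeEdgeList <- function(net, path) {
  utils::write.table(edgeTable(net), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an edge list written by \code{\link{writeEdgeList}}
#' @param path file path.
#' @export
readEdgeList <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Convert a MicrobialNetwork to an igraph object (used for GraphML export)
#' @param net a MicrobialNetwork.
#' @export
asIgraph <- function(net) {
  a <- adjacencyMatrix(net)
  w <- net@weights
  w[is.na(w)] <- 0
  g <- igraph::graph_from_adjacency_matrix(
    a * 1, mode = if (net@directed) "directed" else "undirected")
  et <- edgeTable(net)
  if (nrow(et)) igraph::E(g)$weight <- et$weight
  igraph::V(g)$type <- net@interactionType
  g
}

#' Write a network as GraphML
#' @param net a MicrobialNetwork.
#' @param path output path.
#' @export
writeGraphML <- function(net, path) {
  igraph::write_graph(asIgraph(net), path, format = "graphml")
  invisible(path)
}

#' Write a centrality profile as a tab-delimited node x index table
#' @param profile a CentralityProfile.
#' @param path output path.
#' @export
writeCentralityTable <- function(profile, path) {
  utils::write.table(nodeIndices(profile), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a per-SNP scan table
#' @param scan a ScanResult.
#' @param path output path.
#' @export
writeScanTable <- function(scan, path) {
  utils::write.table(scanTable(scan), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a path model as JSON plus an optional edge table
#'
#' The JSON carries coefficients, correlations, R^2 and the residual path;
#' the edge table (source, target, coefficient, sign) mirrors the visual
#' grammar of a path diagram.
#' @param model a PathModel.
#' @param path JSON output path.
#' @param edgePath optional tab-delimited edge-table path.
#' @export
writePathModel <- function(model, path, edgePath = NULL) {
  obj <- list(
    direct = model@direct,
    mediators = as.list(model@mediatorCoefficients),
    indirect = as.list(model@indirect),
    correlations = model@correlations,
    r2 = model@r2,
    residualPath = model@residualPath,
    retained = model@retained
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  if (!is.null(edgePath)) {
    rows <- data.frame(source = "SNP", target = "phenotype",
                       coefficient = model@direct,
                       sign = sign(model@direct), stringsAsFactors = FALSE)
    if (length(model@mediatorCoefficients)) {
      rows <- rbind(rows,
        data.frame(source = names(model@mediatorCoefficients),
                   target = "phenotype",
                   coefficient = unname(model@mediatorCoefficients),
                   sign = sign(unname(model@mediatorCoefficients)),
                   stringsAsFactors = FALSE),
        data.frame(source = "SNP",
                   target = names(model@indirect),
                   coefficient = unname(model@correlations$rgy[
                     names(model@indirect)]),
                   sign = sign(unname(model@correlations$rgy[
                     names(model@indirect)])),
                   stringsAsFactors = FALSE))
    }
    utils::write.table(rows, edgePath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read a YAML configuration file
#' @param path YAML path.
#' @export
readConfig <- function(path) yaml::read_yaml(path)
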