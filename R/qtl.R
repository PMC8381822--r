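#' Residualize a network-property phenotype on host covariates
#'
#' Fixed-effects linear regression of the raw property values on the
#' supplied covariates (age, sex, ...); the residuals (plus nothing else)
#' become the corrected phenotype used for mapping. A precomputed host
#' relatedness matrix can be supplied for generalized least squares; by
#' default no random effect is used.
#'
#' @param raw numeric vector of raw property values.
#' @param covariates data.frame (or model matrix) of covariates, rows
#'   aligned with \code{raw}; an intercept is added.
#' @param kinship optional n x n positive-definite relatedness matrix; when
#'   given, GLS residuals are returned.
#' @return numeric vector of residuals (centered when covariates are
#'   absent or orthogonal).
#' @export
correctPhenotype <- function(raw, covariates = NULL, kinship = NULL) {
  raw <- as.numeric(raw)
  n <- length(raw)
  X <- if (is.null(covariates) || NCOL(covariates) == 0) {
    matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    stats::model.matrix(~ ., data = as.data.frame(covariates))
  }
  if (nrow(X) != n) stop("covariates not aligned to phenotype")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient covariates; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  if (is.null(kinship)) {
    unname(stats::lm.fit(X, raw)$residuals)
  } else {
    stopifnot(all(dim(kinship) == c(n, n)))
    L <- chol(kinship)
    Xs <- backsolve(L, X, transpose = TRUE)
    ys <- backsolve(L, raw, transpose = TRUE)
    beta <- qr.coef(qr(Xs), ys)
    unname(raw - X %*% beta)[, 1]
  }
}

## Vectorized genotype-class likelihood scan.
##
## Y: n x k matrix of phenotype columns (k >= 1, e.g. observed + permuted).
## G: n x p genotype matrix with codes 1/0/-1 and NA for missing.
## For each SNP: class means are the MLEs, sigma^2 the pooled
## divide-by-n within-class variance; the null model has a single mean.
## LRT = n * ln(sigma0^2 / sigma1^2). Hosts with missing genotypes, and
## hosts in classes below minClass, are excluded per SNP.
.lrtScan <- function(Y, G, minClass = 2) {
  Y <- as.matrix(Y)
  G <- as.matrix(G)
  n <- nrow(Y); p <- ncol(G)
  stopifnot(nrow(G) == n)
  Y2 <- Y * Y
  codes <- c(1, 0, -1)
  counts <- matrix(0, p, 3)
  S <- vector("list", 3); SS <- vector("list", 3); M <- vector("list", 3)
  for (c3 in 1:3) {
    mask <- (G == codes[c3])
    mask[is.na(mask)] <- FALSE
    storage.mode(mask) <- "double"
    M[[c3]] <- mask
    counts[, c3] <- colSums(mask)
    S[[c3]] <- crossprod(mask, Y)    # p x k class sums
    SS[[c3]] <- crossprod(mask, Y2)
  }
  ok <- counts >= minClass
  nUsed <- rowSums(counts * ok)
  nClasses <- rowSums(ok)
  sse1 <- matrix(0, p, ncol(Y))
  tot <- matrix(0, p, ncol(Y)); tot2 <- matrix(0, p, ncol(Y))
  for (c3 in 1:3) {
    use <- ok[, c3]
    if (!any(use)) next
    nc <- counts[, c3]
    contrib <- SS[[c3]] - S[[c3]]^2 / pmax(nc, 1)
    sse1[use, ] <- sse1[use, , drop = FALSE] + contrib[use, , drop = FALSE]
    tot[use, ] <- tot[use, , drop = FALSE] + S[[c3]][use, , drop = FALSE]
    tot2[use, ] <- tot2[use, , drop = FALSE] + SS[[c3]][use, , drop = FALSE]
  }
  sse0 <- tot2 - tot^2 / pmax(nUsed, 1)
  degenerate <- sse1 <= 1e-12 * pmax(sse0, 1e-300)
  floorSse <- pmax(sse1, 1e-12 * pmax(sse0, .Machine$double.xmin))
  lrt <- nUsed * log(pmax(sse0, .Machine$double.xmin) / floorSse)
  lrt[sse0 <= 1e-12 * pmax(tot2, .Machine$double.xmin)] <- 0  # constant y
  lrt[nClasses < 2, ] <- NA         # single usable class: skipped
  lrt[lrt < 0] <- 0
  means <- lapply(1:3, function(c3) {
    mu <- S[[c3]] / pmax(counts[, c3], 1)
    mu[counts[, c3] == 0, ] <- NA
    mu
  })
  list(lrt = lrt, counts = counts, ok = ok, nUsed = nUsed,
       means = means, sse1 = sse1, sse0 = sse0,
       degenerate = degenerate)
}

#' Genotype-class MLEs and log-likelihood-ratio test for one SNP
#'
#' Under the alternative, the phenotype is normal with genotype-dependent
#' means mu_AA, mu_Aa, mu_aa and a common variance (pooled maximum-
#' likelihood estimate, divide-by-n); the null has a single mean. The LRT
#' statistic is n * ln(sigma0^2 / sigma1^2) = 2 (logL1 - logL0).
#'
#' @param y corrected phenotype vector.
#' @param g genotype codes 1 (AA), 0 (Aa), -1 (aa); NA allowed (hosts
#'   dropped for this SNP).
#' @param minClass classes with fewer members are excluded with a warning
#'   (default 2).
#' @return list with \code{muAA}, \code{muAa}, \code{muaa}, \code{sigma2},
#'   \code{sigma2Null}, \code{lrt}, \code{n}, \code{nPerClass},
#'   \code{degenerate} (TRUE when the within-class variance hit the
#'   floor).
#' @export
fitSnp <- function(y, g, minClass = 2) {
  stopifnot(length(y) == length(g))
  res <- .lrtScan(matrix(as.numeric(y), ncol = 1),
                  matrix(as.numeric(g), ncol = 1), minClass = minClass)
  if (any(res$counts > 0 & !res$ok))
    warning("genotype class(es) below the minimum size excluded")
  if (sum(res$ok) < 2)
    warning("fewer than 2 usable genotype classes: SNP skipped (LRT = NA)")
  if (res$degenerate[1, 1])
    warning("zero within-class variance: variance floor applied")
  list(muAA = res$means[[1]][1, 1], muAa = res$means[[2]][1, 1],
       muaa = res$means[[3]][1, 1],
       sigma2 = res$sse1[1, 1] / max(res$nUsed[1], 1),
       sigma2Null = res$sse0[1, 1] / max(res$nUsed[1], 1),
       lrt = res$lrt[1, 1], n = res$nUsed[1],
       nPerClass = stats::setNames(res$counts[1, ], c("AA", "Aa", "aa")),
       degenerate = res$degenerate[1, 1])
}

#' Genome scan of one phenotype across a SNP matrix
#'
#' Applies \code{\link{fitSnp}} to every SNP (vectorized), and optionally
#' computes the genome-wide permutation threshold: phenotype labels are
#' permuted across hosts, the maximum LRT over all SNPs is recorded per
#' permutation, and the threshold is the (1 - alpha) empirical quantile of
#' that max-LRT distribution.
#'
#' @param y corrected phenotype vector.
#' @param genotypes hosts x SNPs matrix of codes 1/0/-1 (NA allowed).
#' @param nPerm number of permutations for the threshold (0 skips it).
#' @param alpha genome-wide significance level (default 0.05).
#' @param seed RNG seed for the permutations.
#' @param minClass minimum genotype-class size (default 2).
#' @param phenotypeName label stored on the result.
#' @return a \code{\linkS4class{ScanResult}}.
#' @export
scanQTL <- function(y, genotypes, nPerm = 1000, alpha = 0.05, seed = 1,
                    minClass = 2, phenotypeName = "phenotype") {
  genotypes <- as.matrix(genotypes)
  y <- as.numeric(y)
  stopifnot(nrow(genotypes) == length(y))
  if (is.null(colnames(genotypes)))
    colnames(genotypes) <- paste0("snp", seq_len(ncol(genotypes)))
  res <- .lrtScan(matrix(y, ncol = 1), genotypes, minClass = minClass)
  thr <- NA_real_
  if (nPerm > 0) {
    thr <- permutationThreshold(y, genotypes, nPerm = nPerm, alpha = alpha,
                                seed = seed, minClass = minClass)
  }
  tab <- data.frame(
    snp = colnames(genotypes),
    muAA = res$means[[1]][, 1], muAa = res$means[[2]][, 1],
    muaa = res$means[[3]][, 1],
    sigma2 = res$sse1[, 1] / pmax(res$nUsed, 1),
    lrt = res$lrt[, 1],
    n = res$nUsed,
    degenerate = res$degenerate[, 1],
    stringsAsFactors = FALSE
  )
  tab$significant <- if (is.finite(thr)) tab$lrt > thr else NA
  new("ScanResult", table = tab, threshold = thr, alpha = alpha,
      nPerm = as.numeric(nPerm), phenotype = phenotypeName)
}

#' Genome-wide permutation threshold for a phenotype scan
#'
#' @inheritParams scanQTL
#' @return the (1 - alpha) quantile (type 1, so alpha = 1 returns the
#'   minimum) of the permutation max-LRT distribution.
#' @export
permutationThreshold <- function(y, genotypes, nPerm = 1000, alpha = 0.05,
                                 seed = 1, minClass = 2) {
  if (nPerm < 1) stop("nPerm must be >= 1")
  genotypes <- as.matrix(genotypes)
  y <- as.numeric(y)
  n <- length(y)
  oldSeed <- .saveSeed(); on.exit(.restoreSeed(oldSeed))
  set.seed(seed)
  Y <- vapply(seq_len(nPerm), function(b) y[sample.int(n)], numeric(n))
  lrt <- .lrtScan(Y, genotypes, minClass = minClass)$lrt
  maxes <- apply(lrt, 2, max, na.rm = TRUE)
  stats::quantile(maxes, probs = 1 - alpha, type = 1, names = FALSE)
}
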