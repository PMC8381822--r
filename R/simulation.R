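#' Configuration for the Monte Carlo power study
#'
#' Defaults mirror the cohort design the framework targets: 127 hosts,
#' eight interacting microbes, biallelic SNPs in Hardy-Weinberg
#' proportions with allele frequencies uniform on (0.2, 0.5), and three
#' effect-size schemes defined by the proportion of the causal SNP's
#' genetic variance to the total phenotypic variance: big (0.10-0.20),
#' moderate (0.05-0.10), small (0.01-0.05).
#'
#' @param nHosts number of hosts (default 127).
#' @param mMicrobes number of microbes (default 8).
#' @param nSnps SNPs per simulated genome scan (default 100).
#' @param scheme effect-size scheme: "small", "moderate" or "big".
#' @param scenario interaction scenario: "mutualism" (a cooperating guild
#'   of 4 microbes co-modulated positively by the causal genotype) or
#'   "aggression" (the causal genotype modulates the abundance ratio of a
#'   dominant-subordinate pair).
#' @param replicates Monte Carlo replicates (default 1000; 200 is used for
#'   reduced-scale runs).
#' @param nPerm permutations inside each replicate (default 200; 1000 for
#'   final runs).
#' @param alpha genome-wide significance level (default 0.05).
#' @param seed master seed.
#' @param noiseSd residual log-abundance standard deviation (log units,
#'   default 0.5).
#' @return validated list of class \code{SimConfig}.
#' @export
simConfig <- function(nHosts = 127, mMicrobes = 8, nSnps = 100,
                      scheme = c("small", "moderate", "big"),
                      scenario = c("mutualism", "aggression"),
                      replicates = 1000, nPerm = 200, alpha = 0.05,
                      seed = 1, noiseSd = 0.5) {
  scheme <- match.arg(scheme)
  scenario <- match.arg(scenario)
  bounds <- list(big = c(0.10, 0.20), moderate = c(0.05, 0.10),
                 small = c(0.01, 0.05))[[scheme]]
  if (nHosts < 20) stop("nHosts must be >= 20")
  if (mMicrobes < 4) stop("mMicrobes must be >= 4")
  if (any(bounds <= 0 | bounds >= 1)) stop("variance proportions must be in (0,1)")
  structure(list(nHosts = nHosts, mMicrobes = mMicrobes, nSnps = nSnps,
                 scheme = scheme, bounds = bounds, scenario = scenario,
                 replicates = replicates, nPerm = nPerm, alpha = alpha,
                 seed = seed, noiseSd = noiseSd),
            class = "SimConfig")
}

#' Simulate one synthetic cohort under a host-QTL interaction scenario
#'
#' Genotypes: biallelic SNPs in Hardy-Weinberg proportions, allele
#' frequency ~ Uniform(0.2, 0.5), coded 1/0/-1. One causal SNP (the first)
#' carries an additive effect on the log-abundance of the designated
#' microbe subset, scaled so that its realized genetic variance divided by
#' the total phenotypic variance of an affected microbe's log-abundance
#' equals a draw from the scheme interval (\code{h2 = 0} gives a null
#' cohort). Mutualism: microbes 1-4 form a cooperating guild, all
#' receiving the same positive effect. Aggression: microbe 1 (dominant)
#' gets +a and microbe 2 (subordinate) -a, modulating their abundance
#' ratio. Remaining variation is independent log-normal noise around
#' fixed, well-separated baselines.
#'
#' The phenotypes each mapping model scans are derived through the
#' descriptor machinery: traditional = log-abundance of microbe 1; new =
#' per-host mean log Z_mu over the guild's pairs (mutualism) or per-host
#' log Z_ag of the focal pair (aggression).
#'
#' @param cfg a \code{SimConfig}.
#' @param seed seed for this cohort (default: cfg$seed).
#' @param h2 override the variance-proportion draw (NULL = draw from the
#'   scheme interval; 0 = null cohort with no causal effect).
#' @return list: \code{abundance} (hosts x microbes), \code{genotypes}
#'   (hosts x SNPs), \code{traditionalPhenotype}, \code{networkPhenotype},
#'   \code{causalSnp} (index), \code{h2} (the draw), \code{effect} (a).
#' @export
simulateCohort <- function(cfg, seed = cfg$seed, h2 = NULL) {
  stopifnot(inherits(cfg, "SimConfig"))
  oldSeed <- .saveSeed(); on.exit(.restoreSeed(oldSeed))
  set.seed(seed)
  n <- cfg$nHosts; m <- cfg$mMicrobes; p <- cfg$nSnps
  maf <- stats::runif(p, 0.2, 0.5)
  G <- vapply(maf, function(q) stats::rbinom(n, 2, q) - 1, numeric(n))
  colnames(G) <- paste0("snp", seq_len(p))
  rownames(G) <- paste0("host", seq_len(n))
  if (is.null(h2)) h2 <- stats::runif(1, cfg$bounds[1], cfg$bounds[2])
  if (h2 >= 1) stop("variance proportion must be < 1")
  g <- G[, 1]
  sdg <- stats::sd(g)
  sigma <- cfg$noiseSd
  a <- if (h2 > 0 && sdg > 0) sqrt(h2 / (1 - h2)) * sigma / sdg else 0
  ## fixed baselines spanning three orders of magnitude, as genus-level
  ## abundances do; separation keeps the u/v orientation mostly stable
  mu <- seq(log(2000), log(2), length.out = m)
  E <- matrix(stats::rnorm(n * m, 0, sigma), n, m)
  logX <- sweep(E, 2, mu, "+")
  guild <- seq_len(4)
  if (cfg$scenario == "mutualism") {
    logX[, guild] <- logX[, guild] + a * g
  } else {
    logX[, 1] <- logX[, 1] + a * g
    logX[, 2] <- logX[, 2] - a * g
  }
  X <- exp(logX)
  colnames(X) <- paste0("microbe", seq_len(m))
  rownames(X) <- rownames(G)
  tensor <- suppressWarnings(descriptorTensor(X))
  newPheno <- if (cfg$scenario == "mutualism") {
    Zmu <- descriptorMatrix(tensor, "mutualism")
    pairIn <- tensor@pairs[, 1] %in% guild & tensor@pairs[, 2] %in% guild
    ## median over the guild pairs: log Z_mu has a heavy upper tail near
    ## abundance ties, so the median is the robust per-host summary
    apply(log(Zmu[, pairIn, drop = FALSE]), 1, stats::median)
  } else {
    Zag <- descriptorMatrix(tensor, "aggression")
    pairIdx <- which(tensor@pairs[, 1] == 1 & tensor@pairs[, 2] == 2)
    ## orient the ratio dominant/subordinate regardless of per-host u/v
    sgn <- ifelse(tensor@uFirst[, pairIdx], 1, -1)
    sgn * log(Zag[, pairIdx])
  }
  list(abundance = X, genotypes = G,
       traditionalPhenotype = logX[, 1],
       networkPhenotype = unname(newPheno),
       causalSnp = 1L, h2 = h2, effect = a)
}

#' Monte Carlo power comparison: abundance QTL vs network-interaction QTL
#'
#' For each replicate a cohort is simulated, both phenotypes are scanned
#' with the genotype-class likelihood-ratio test, each scan gets its own
#' genome-wide permutation threshold, and detection is recorded. Power is
#' the fraction of replicates in which the causal SNP exceeds its
#' threshold; the false-positive rate is the fraction of non-causal SNPs
#' declared significant, aggregated over replicates.
#'
#' @param cfg a \code{SimConfig}.
#' @param nullCohort if \code{TRUE}, simulate with no causal effect
#'   (h2 = 0) so every SNP is null.
#' @return data.frame of class \code{PowerTable}: one row per model with
#'   \code{power}, \code{se} (binomial), \code{fpr}, \code{replicates}.
#' @export
powerStudy <- function(cfg, nullCohort = FALSE) {
  stopifnot(inherits(cfg, "SimConfig"))
  if (cfg$replicates < 2) stop("need at least 2 replicates")
  hitT <- hitN <- logical(cfg$replicates)
  fpT <- fpN <- 0L
  nNull <- 0L
  for (r in seq_len(cfg$replicates)) {
    sim <- simulateCohort(cfg, seed = .deriveSeed(cfg$seed, r),
                          h2 = if (nullCohort) 0 else NULL)
    permSeed <- .deriveSeed(cfg$seed, r + cfg$replicates)
    for (model in c("traditional", "new")) {
      y <- if (model == "traditional") sim$traditionalPhenotype
           else sim$networkPhenotype
      res <- .lrtScan(matrix(y, ncol = 1), sim$genotypes)
      thr <- permutationThreshold(y, sim$genotypes, nPerm = cfg$nPerm,
                                  alpha = cfg$alpha, seed = permSeed)
      sig <- res$lrt[, 1] > thr
      isCausal <- seq_len(cfg$nSnps) == sim$causalSnp & !nullCohort
      hit <- isTRUE(sig[sim$causalSnp]) && !nullCohort
      fp <- sum(sig & !isCausal, na.rm = TRUE)
      if (model == "traditional") { hitT[r] <- hit; fpT <- fpT + fp }
      else { hitN[r] <- hit; fpN <- fpN + fp }
    }
    nNull <- nNull + cfg$nSnps - as.integer(!nullCohort)
  }
  pw <- function(hits) mean(hits)
  se <- function(p) sqrt(p * (1 - p) / cfg$replicates)
  out <- data.frame(
    model = c("traditional", "new"),
    scenario = cfg$scenario,
    scheme = cfg$scheme,
    power = c(pw(hitT), pw(hitN)),
    se = c(se(pw(hitT)), se(pw(hitN))),
    fpr = c(fpT, fpN) / nNull,
    nullSnpTests = nNull,
    replicates = cfg$replicates,
    stringsAsFactors = FALSE
  )
  if (nullCohort) out$power <- NA_real_
  class(out) <- c("PowerTable", "data.frame")
  out
}
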