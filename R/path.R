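#' Mutual-information correlation between a discrete genotype and a
#' continuous variable
#'
#' Estimates I(g; y) with a class-conditional Gaussian entropy estimator:
#' I = H(y) - sum_c p_c H(y | g = c), with H the Gaussian differential
#' entropy at the maximum-likelihood variance. The mutual information is
#' mapped to the correlation scale via r = sqrt(1 - exp(-2 I)), signed by
#' the genotype-dose/phenotype covariance. This estimator is a documented
#' stand-in for the cited mutual-information method; plain dose-coded
#' Pearson correlation is available via \code{method = "pearson"}.
#'
#' @param g genotype codes (1/0/-1); NA dropped pairwise with y.
#' @param y continuous variable.
#' @param method "mi" (default) or "pearson".
#' @return list(r, I, defined). A single-class genotype gives
#'   \code{defined = FALSE} and \code{r = NA}.
#' @export
miCorrelation <- function(g, y, method = c("mi", "pearson")) {
  method <- match.arg(method)
  keep <- !is.na(g) & !is.na(y)
  g <- g[keep]; y <- y[keep]
  classes <- unique(g)
  if (length(classes) < 2)
    return(list(r = NA_real_, I = NA_real_, defined = FALSE))
  if (method == "pearson") {
    r <- stats::cor(g, y)
    return(list(r = r, I = -0.5 * log(max(1 - r^2, 1e-300)),
                defined = TRUE))
  }
  n <- length(y)
  vTot <- mean((y - mean(y))^2)
  if (vTot <= 0) return(list(r = 0, I = 0, defined = TRUE))
  ## E[log s2_ML] = log s2 + digamma((m-1)/2) + log(2/m): debias each
  ## log-variance so the null MI estimate is centered at zero
  logVarDebiased <- function(v, m) {
    log(max(v, 1e-300)) - digamma((m - 1) / 2) - log(2 / m)
  }
  Hcond <- 0
  for (cl in classes) {
    yc <- y[g == cl]
    nc <- length(yc)
    if (nc < 2) next  # singleton class carries no variance information
    vc <- mean((yc - mean(yc))^2)
    Hcond <- Hcond + (nc / n) * 0.5 * logVarDebiased(vc, nc)
  }
  I <- max(0.5 * logVarDebiased(vTot, n) - Hcond, 0)
  r <- sqrt(1 - exp(-2 * I))
  s <- sign(stats::cov(g, y))
  if (s == 0) s <- 1
  list(r = s * r, I = I, defined = TRUE)
}

#' Assemble a SNP -> network-perturbation -> phenotype path system
#'
#' Computes the correlations needed by the path decomposition: r_gz and
#' r_gy_j (genotype dose vs continuous, Pearson by default with the
#' mutual-information variant reported alongside), and r_y_jz (Pearson).
#' Two-sided correlation p-values are attached for the mediator screen.
#'
#' @param g genotype codes per host.
#' @param mediators numeric matrix/data.frame of candidate mediators
#'   (e.g. winter-summer differences of the six property indices), hosts
#'   in rows.
#' @param z end-point phenotype (e.g. BMI).
#' @param gCorrelation "pearson" (default) or "mi" for the genotype-side
#'   correlations used in the decomposition.
#' @return list of class \code{PathSystem}: standardized data plus
#'   correlation vectors \code{rgy}, \code{ryz}, \code{rgz}, p-values
#'   \code{pgy}, and the MI-based genotype correlations \code{rgyMI}.
#' @export
pathSystem <- function(g, mediators, z,
                       gCorrelation = c("pearson", "mi")) {
  gCorrelation <- match.arg(gCorrelation)
  Y <- as.matrix(mediators)
  if (is.null(colnames(Y))) colnames(Y) <- paste0("y", seq_len(ncol(Y)))
  stopifnot(length(g) == nrow(Y), length(z) == nrow(Y))
  keep <- stats::complete.cases(g, Y, z)
  g <- g[keep]; Y <- Y[keep, , drop = FALSE]; z <- z[keep]
  n <- length(g)
  if (n < ncol(Y) + 2) stop("too few hosts for the path system")
  rgy <- numeric(ncol(Y)); pgy <- numeric(ncol(Y)); rgyMI <- numeric(ncol(Y))
  for (j in seq_len(ncol(Y))) {
    ct <- stats::cor.test(g, Y[, j])
    rgy[j] <- unname(ct$estimate); pgy[j] <- ct$p.value
    rgyMI[j] <- miCorrelation(g, Y[, j])$r
  }
  names(rgy) <- names(pgy) <- names(rgyMI) <- colnames(Y)
  ryz <- stats::setNames(as.vector(stats::cor(Y, z)), colnames(Y))
  rgz <- stats::cor(g, z)
  used <- if (gCorrelation == "mi") rgyMI else rgy
  rgzUsed <- if (gCorrelation == "mi") miCorrelation(g, z)$r else rgz
  structure(list(g = g, Y = Y, z = z, n = n,
                 rgy = used, rgyPearson = rgy, rgyMI = rgyMI,
                 pgy = pgy, ryz = ryz, rgz = rgzUsed,
                 rgzPearson = rgz,
                 gCorrelation = gCorrelation),
            class = "PathSystem")
}

#' Screen mediators by the significance of their genotype correlation
#'
#' Retains candidate mediators whose genotype-mediator correlation is
#' significant at or beyond the given level (two-sided, default 10%).
#'
#' @param system a \code{PathSystem}.
#' @param alpha significance level (default 0.10).
#' @return character vector of retained mediator names (possibly empty).
#' @export
selectMediators <- function(system, alpha = 0.10) {
  stopifnot(inherits(system, "PathSystem"))
  names(system$pgy)[system$pgy <= alpha]
}

#' Decompose a SNP-phenotype correlation into direct and indirect paths
#'
#' Path coefficients are the standardized multiple-regression weights of z
#' on (g, selected mediators): solving the normal equations on the
#' correlation matrix guarantees the decomposition identity
#' r_gz = P_z<-g + sum_j P_z<-y_j r_gy_j exactly, and the coefficient of
#' determination equals the quadratic form
#' R^2 = b' R b = P_z<-g^2 + sum_j P^2 + 2 sum r P P (the single-mediator
#' printed form, generalized). The residual path is sqrt(1 - R^2). With
#' \code{yzAsDirect = TRUE} the single-mediator convention P_z<-y = r_yz
#' is enforced instead (the mediator-to-phenotype link treated as a single
#' direct path) and the direct effect becomes r_gz - r_yz r_gy; note that
#' under that convention R^2 no longer equals the regression R^2 when g
#' and y are correlated.
#'
#' @param system a \code{PathSystem}.
#' @param mediators names of mediators to include; default = the 10%
#'   screen via \code{\link{selectMediators}}. May be empty (direct-only
#'   model: P_z<-g = r_gz).
#' @param alpha screening level when \code{mediators} is NULL.
#' @param yzAsDirect single-mediator convention flag (see above).
#' @return a \code{\linkS4class{PathModel}}.
#' @export
decomposePaths <- function(system, mediators = NULL, alpha = 0.10,
                           yzAsDirect = FALSE) {
  stopifnot(inherits(system, "PathSystem"))
  if (is.null(mediators)) mediators <- selectMediators(system, alpha)
  stopifnot(all(mediators %in% colnames(system$Y)))
  rgz <- system$rgz
  if (!length(mediators)) {
    return(new("PathModel", direct = rgz,
               mediatorCoefficients = stats::setNames(numeric(0),
                                                      character(0)),
               indirect = stats::setNames(numeric(0), character(0)),
               correlations = list(rgz = rgz, rgy = system$rgy,
                                   ryz = system$ryz),
               r2 = rgz^2, residualPath = sqrt(max(1 - rgz^2, 0)),
               retained = character(0)))
  }
  rgy <- system$rgy[mediators]
  ryz <- system$ryz[mediators]
  if (yzAsDirect && length(mediators) == 1) {
    Pzy <- unname(ryz)
    Pzg <- rgz - Pzy * unname(rgy)
    b <- c(Pzg, Pzy)
    R <- matrix(c(1, rgy, rgy, 1), 2)
    r2 <- as.numeric(t(b) %*% R %*% b)
  } else {
    ## correlation matrix of predictors (g first), from the data so that
    ## mediator-mediator correlations are honest
    X <- cbind(g = system$g, system$Y[, mediators, drop = FALSE])
    R <- stats::cor(X)
    ## genotype rows use the configured genotype correlation
    R[1, -1] <- rgy; R[-1, 1] <- rgy
    rxz <- c(rgz, ryz)
    cn <- kappa(R, exact = TRUE)
    if (cn > 1e10)
      stop("collinear mediators (condition number ", format(cn, digits = 3),
           "); drop mediators and refit")
    b <- solve(R, rxz)
    r2 <- sum(b * rxz)
  }
  r2 <- min(max(r2, 0), 1)
  direct <- unname(b[1])
  med <- stats::setNames(b[-1], mediators)
  indirect <- med * rgy
  new("PathModel", direct = direct, mediatorCoefficients = med,
      indirect = indirect,
      correlations = list(rgz = rgz, rgy = system$rgy, ryz = system$ryz,
                          rgyMI = system$rgyMI),
      r2 = r2, residualPath = sqrt(max(1 - r2, 0)),
      retained = mediators)
}

#' Season-driven network perturbations for hosts present in both seasons
#'
#' Winter-minus-summer differences of the per-host property summaries,
#' computed only for hosts measured in both seasons.
#'
#' @param winter,summer numeric matrices of per-host property values
#'   (hosts x properties) with host row names.
#' @return matrix of differences for the intersection of hosts.
#' @export
seasonPerturbation <- function(winter, summer) {
  common <- intersect(rownames(winter), rownames(summer))
  if (!length(common)) stop("no hosts present in both seasons")
  winter[common, , drop = FALSE] - summer[common, , drop = FALSE]
}
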