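## Sigmoidal growth equations. All three are monotone with asymptote K,
## rate r and inflection/lag parameter t0; Richards adds a shape nu > 0
## (nu = 1 recovers the logistic, nu -> 0 the Gompertz).

growthModels <- list(
  gompertz = list(
    f = function(t, p) p[["K"]] * exp(-exp(-p[["r"]] * (t - p[["t0"]]))),
    formula = y ~ K * exp(-exp(-r * (t - t0))),
    npar = 3L,
    start = function(K, r, t0) list(K = K, r = r, t0 = t0),
    lower = c(K = 1e-12, r = 1e-6, t0 = -Inf)
  ),
  logistic = list(
    f = function(t, p) p[["K"]] / (1 + exp(-p[["r"]] * (t - p[["t0"]]))),
    formula = y ~ K / (1 + exp(-r * (t - t0))),
    npar = 3L,
    start = function(K, r, t0) list(K = K, r = r, t0 = t0),
    lower = c(K = 1e-12, r = 1e-6, t0 = -Inf)
  ),
  richards = list(
    ## four-parameter form; nu is the shape
    f = function(t, p)
      p[["K"]] * (1 + p[["nu"]] * exp(-p[["r"]] * (t - p[["t0"]])))^(-1 / p[["nu"]]),
    formula = y ~ K * (1 + nu * exp(-r * (t - t0)))^(-1 / nu),
    npar = 4L,
    start = function(K, r, t0) list(K = K, r = r, t0 = t0, nu = 1),
    lower = c(K = 1e-12, r = 1e-6, t0 = -Inf, nu = 1e-3)
  )
)

## deterministic jitter multipliers for the multi-start fallback
.jitterGrid <- rbind(
  c(1.00, 1.00, 1.00),
  c(1.20, 0.50, 0.80),
  c(0.90, 2.00, 1.20),
  c(1.10, 0.25, 1.00),
  c(1.50, 1.50, 0.60)
)

.growthStarts <- function(times, abundances) {
  K <- max(abundances) * 1.05
  ## rate from the log-slope of the middle third
  o <- order(times)
  t <- times[o]; y <- abundances[o]
  idx <- seq(floor(length(t) / 3) + 1, ceiling(2 * length(t) / 3))
  pos <- y[idx] > 0
  r <- if (sum(pos) >= 2) {
    sl <- stats::coef(stats::lm(log(y[idx][pos]) ~ t[idx][pos]))[2]
    max(abs(sl), 1e-3)
  } else 0.5
  t0 <- t[which.min(abs(y - K / 2))]
  list(K = unname(K), r = unname(r), t0 = unname(t0))
}

.aicc <- function(rss, n, npar) {
  k <- npar + 1  # + residual variance
  n * log(rss / n) + 2 * k + 2 * k * (k + 1) / max(n - k - 1, 1e-8)
}

#' Fit Gompertz, logistic and Richards growth equations and pick the best
#'
#' All three sigmoidal models are fitted to an abundance time series by
#' Levenberg-Marquardt least squares, with starting values from the data
#' (K = max abundance, r from the log-slope of the middle third, t0 at the
#' half-maximum crossing) and a deterministic 5-point jittered multi-start
#' on failure. The optimal model is selected by the small-sample corrected
#' information criterion (AICc) by default; a residual-sum-of-squares F
#' comparison is available for the nested pairs.
#'
#' @param times hours, strictly increasing; at least 5 points.
#' @param abundances nonnegative abundances, same length.
#' @param models subset of c("gompertz", "logistic", "richards").
#' @param criterion "AICc" (default) or "F" (RSS F-test against the
#'   richest converged model, preferring the simpler model when not
#'   significantly worse at 0.05).
#' @return list of class \code{GrowthFit}: \code{model} (selected name),
#'   \code{parameters}, \code{sigma2} (residual ML variance),
#'   \code{criterion} (named scores), \code{fits} (all converged
#'   \code{nls} objects), \code{times}, \code{abundances}.
#' @export
fitGrowth <- function(times, abundances,
                      models = c("gompertz", "logistic", "richards"),
                      criterion = c("AICc", "F")) {
  criterion <- match.arg(criterion)
  models <- match.arg(models, several.ok = TRUE)
  stopifnot(length(times) == length(abundances))
  if (length(times) < 5) stop("need at least 5 time points")
  if (any(diff(order(times)) <= 0) || anyDuplicated(times))
    stop("times must be strictly increasing")
  if (any(abundances < 0)) stop("abundances must be nonnegative")
  if (stats::sd(abundances) == 0)
    stop("constant series: growth fit degenerate (K = constant, r -> 0)")
  st <- .growthStarts(times, abundances)
  dat <- data.frame(t = times, y = abundances)
  fits <- list()
  for (mn in models) {
    spec <- growthModels[[mn]]
    best <- NULL
    bestRss <- Inf
    for (j in seq_len(nrow(.jitterGrid))) {
      s0 <- st
      s0$K <- st$K * .jitterGrid[j, 1]
      s0$r <- st$r * .jitterGrid[j, 2]
      s0$t0 <- st$t0 * .jitterGrid[j, 3]
      start <- spec$start(s0$K, s0$r, s0$t0)
      fit <- tryCatch(
        minpack.lm::nlsLM(spec$formula, data = dat, start = start,
                          lower = spec$lower[names(start)],
                          control = minpack.lm::nls.lm.control(
                            maxiter = 500, ftol = 1e-14, ptol = 1e-14)),
        error = function(e) NULL)
      if (!is.null(fit)) {
        rssj <- sum(stats::residuals(fit)^2)
        if (rssj < bestRss) { best <- fit; bestRss <- rssj }
      }
    }
    if (!is.null(best)) fits[[mn]] <- best
  }
  if (!length(fits))
    stop("no growth model converged for this series")
  n <- length(times)
  rss <- vapply(fits, function(f) sum(stats::residuals(f)^2), 0)
  scores <- vapply(names(fits), function(mn)
    .aicc(max(rss[[mn]], 1e-300), n, growthModels[[mn]]$npar), 0)
  best <- if (criterion == "AICc") {
    names(fits)[which.min(scores)]
  } else {
    ## F comparison: prefer the simpler of each converged pair unless the
    ## richer one is significantly better
    ord <- names(fits)[order(vapply(names(fits),
                                    function(m) growthModels[[m]]$npar, 0L),
                             rss[names(fits)])]
    chosen <- ord[1]
    for (mn in ord[-1]) {
      df1 <- growthModels[[mn]]$npar - growthModels[[chosen]]$npar
      if (df1 <= 0) next
      df2 <- n - growthModels[[mn]]$npar
      Fst <- ((rss[[chosen]] - rss[[mn]]) / df1) / (rss[[mn]] / df2)
      if (is.finite(Fst) && stats::pf(Fst, df1, df2, lower.tail = FALSE) < 0.05)
        chosen <- mn
    }
    chosen
  }
  structure(list(
    model = best,
    parameters = stats::coef(fits[[best]]),
    sigma2 = rss[[best]] / n,
    criterion = scores,
    rss = rss,
    fits = fits,
    times = times,
    abundances = abundances
  ), class = "GrowthFit")
}

#' @export
print.GrowthFit <- function(x, ...) {
  cat("GrowthFit: selected", x$model, "model\n")
  cat("  parameters:", paste(names(x$parameters),
                             signif(x$parameters, 5), sep = " = ",
                             collapse = ", "), "\n")
  cat("  AICc:", paste(names(x$criterion), signif(x$criterion, 5),
                       sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

#' Evaluate the fitted growth curve
#' @param fit a GrowthFit
#' @param t times
#' @export
predictGrowth <- function(fit, t) {
  growthModels[[fit$model]]$f(t, as.list(fit$parameters))
}

#' Segment a fitted growth trajectory into lag, log and stationary phases
#'
#' Boundaries come from the extrema of the fitted curve's second
#' derivative: the lag phase ends at the time of maximum acceleration and
#' the log phase ends at the time of maximum deceleration. (For the
#' logistic these are t0 +/- ln(2 + sqrt(3)) / r.) This rule is a
#' documented convention; boundaries outside the observed window are
#' clamped with a warning.
#'
#' @param fit a \code{GrowthFit}.
#' @return numeric c(lag_end, log_end), in hours.
#' @export
segmentPhases <- function(fit) {
  f <- function(t) growthModels[[fit$model]]$f(t, as.list(fit$parameters))
  lo <- min(fit$times); hi <- max(fit$times)
  h <- (hi - lo) * 1e-5
  d2 <- function(t) (f(t + h) - 2 * f(t) + f(t - h)) / h^2
  grid <- seq(lo, hi, length.out = 2001)
  v <- d2(grid)
  refine <- function(i, maximize) {
    a <- grid[max(i - 2, 1)]; b <- grid[min(i + 2, length(grid))]
    stats::optimize(d2, c(a, b), maximum = maximize,
                    tol = .Machine$double.eps^0.5)[[1]]
  }
  iMax <- which.max(v)
  lagEnd <- refine(iMax, TRUE)
  ## deceleration maximum must come after the acceleration maximum
  after <- which(grid > lagEnd)
  iMin <- after[which.min(v[after])]
  logEnd <- refine(iMin, FALSE)
  clamped <- FALSE
  if (lagEnd <= lo + 2 * h) { lagEnd <- lo; clamped <- TRUE }
  if (logEnd >= hi - 2 * h) { logEnd <- hi; clamped <- TRUE }
  if (clamped)
    warning("phase boundary at edge of observed window; clamped")
  if (lagEnd >= logEnd)
    warning("degenerate phase segmentation: lag_end >= log_end")
  c(lag_end = lagEnd, log_end = logEnd)
}

#' The qPCR-style sampling grid used by the synthetic growth fixtures
#'
#' Every 0.5 h for the first 2 h, every 2 h to 12 h, then every 4 h to
#' 36 h — 16 time points.
#' @export
growthSamplingGrid <- function() {
  c(seq(0, 2, by = 0.5), seq(4, 12, by = 2), seq(16, 36, by = 4))
}
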