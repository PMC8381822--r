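#' Behavioral-ecology descriptors of a pairwise microbial interaction
#'
#' From a single abundance snapshot of two microbes, computes closed-form
#' proxies for the strength of the four interaction types. With u the more
#' abundant and v the less abundant microbe (x_u > x_v > 0):
#' \deqn{Z_{mu} = x_u x_v / (x_u - x_v)}
#' \deqn{Z_{ag} = x_u / x_v, \qquad Z_{al} = 1 - x_v / x_u}
#' Aggression and altruism are directed u -> v; mutualism and antagonism are
#' symmetric. The printed antagonism form is typographically ambiguous; two
#' renderings are provided (see \code{anForm}) and results that use Z_an
#' depend on this choice.
#'
#' Inputs are an unordered pair: the function relabels internally so that
#' the larger abundance is x_u, and reports the orientation.
#'
#' @param x,y abundances of the two microbes (vectors recycle).
#' @param anForm antagonism rendering: \code{"reciprocal-product"}
#'   (default), Z_an = 1 / (x_u x_v (x_u - x_v)); or
#'   \code{"inverse-mutualism"}, Z_an = (x_u - x_v) / (x_u x_v) = 1 / Z_mu.
#' @param strict if \code{TRUE}, tied or zero abundances raise an error;
#'   otherwise the affected descriptors are returned as \code{NA} with a
#'   warning.
#' @param pseudocount value added to both abundances before computation
#'   (default 0: off), for sparse count data.
#' @return data.frame with columns \code{Zmu}, \code{Zan}, \code{Zag},
#'   \code{Zal} and \code{uFirst} (\code{TRUE} when the first argument is
#'   the more abundant microbe u). For ties, Z_ag = 1 and Z_al = 0 while
#'   Z_mu and Z_an are \code{NA} (degenerate denominator); pairs with a
#'   zero abundance are entirely \code{NA}.
#' @examples
#' computeDescriptors(4, 2)   # Zag = 2, Zal = 0.5, Zmu = 4
#' @export
computeDescriptors <- function(x, y,
                               anForm = c("reciprocal-product",
                                          "inverse-mutualism"),
                               strict = FALSE, pseudocount = 0) {
  anForm <- match.arg(anForm)
  n <- max(length(x), length(y))
  x <- rep_len(as.numeric(x), n) + pseudocount
  y <- rep_len(as.numeric(y), n) + pseudocount
  if (any(x < 0 | y < 0, na.rm = TRUE))
    stop("abundances must be nonnegative")
  uFirst <- x >= y
  xu <- pmax(x, y)
  xv <- pmin(x, y)
  zero <- xu <= 0 | xv <= 0
  tie <- !zero & xu == xv
  if (any(zero, na.rm = TRUE)) {
    if (strict) stop("zero abundance: pair undefined")
    warning(sum(zero, na.rm = TRUE),
            " pair(s) with zero abundance flagged missing")
  }
  if (any(tie, na.rm = TRUE)) {
    if (strict) stop("tied abundances: Z_mu and Z_an undefined")
    warning(sum(tie, na.rm = TRUE),
            " tied pair(s): Z_mu/Z_an flagged missing")
  }
  Zag <- ifelse(zero, NA_real_, xu / xv)
  Zal <- ifelse(zero, NA_real_, 1 - xv / xu)
  d <- xu - xv
  Zmu <- ifelse(zero | tie, NA_real_, xu * xv / d)
  Zan <- if (anForm == "reciprocal-product") {
    ifelse(zero | tie, NA_real_, 1 / (xu * xv * d))
  } else {
    ifelse(zero | tie, NA_real_, d / (xu * xv))
  }
  data.frame(Zmu = Zmu, Zan = Zan, Zag = Zag, Zal = Zal, uFirst = uFirst)
}

#' Descriptor tensor for a host x taxon abundance matrix
#'
#' Applies \code{\link{computeDescriptors}} to every unordered taxon pair in
#' every host. Pairs failing preconditions (ties, zeros) are flagged
#' missing, not dropped.
#'
#' @param abundance numeric matrix, hosts as rows, taxa as columns
#'   (nonnegative); row and column names are used as identifiers.
#' @param normalize \code{"none"} (default) uses abundances as given;
#'   \code{"relative"} divides each host row by its total first. Whether
#'   descriptors should be computed on relative or absolute abundances is a
#'   modelling choice exposed here.
#' @inheritParams computeDescriptors
#' @return an \code{\linkS4class{InteractionTensor}}.
#' @export
descriptorTensor <- function(abundance,
                             normalize = c("none", "relative"),
                             anForm = c("reciprocal-product",
                                        "inverse-mutualism"),
                             strict = FALSE, pseudocount = 0) {
  normalize <- match.arg(normalize)
  anForm <- match.arg(anForm)
  abundance <- as.matrix(abundance)
  if (ncol(abundance) < 2) stop("need at least 2 taxa")
  if (any(abundance < 0, na.rm = TRUE)) stop("abundances must be nonnegative")
  if (is.null(rownames(abundance)))
    rownames(abundance) <- paste0("host", seq_len(nrow(abundance)))
  if (is.null(colnames(abundance)))
    colnames(abundance) <- paste0("taxon", seq_len(ncol(abundance)))
  if (normalize == "relative") {
    tot <- rowSums(abundance)
    tot[tot == 0] <- 1
    abundance <- abundance / tot
  }
  m <- ncol(abundance)
  pairs <- which(upper.tri(matrix(0, m, m)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  colnames(pairs) <- c("i", "j")
  np <- nrow(pairs)
  nh <- nrow(abundance)
  Zmu <- Zan <- Zag <- Zal <- matrix(NA_real_, nh, np)
  uFirst <- matrix(NA, nh, np)
  for (p in seq_len(np)) {
    d <- suppressWarnings(
      computeDescriptors(abundance[, pairs[p, 1]], abundance[, pairs[p, 2]],
                         anForm = anForm, strict = strict,
                         pseudocount = pseudocount))
    Zmu[, p] <- d$Zmu; Zan[, p] <- d$Zan
    Zag[, p] <- d$Zag; Zal[, p] <- d$Zal
    uFirst[, p] <- d$uFirst
  }
  nMiss <- sum(is.na(Zmu))
  if (nMiss > 0)
    warning(nMiss, " host-pair entries flagged missing (ties or zeros)")
  new("InteractionTensor",
      hosts = rownames(abundance), taxa = colnames(abundance),
      pairs = unname(pairs), uFirst = uFirst, anForm = anForm,
      descriptors = list(Zmu = Zmu, Zan = Zan, Zag = Zag, Zal = Zal))
}

#' Observed interaction strengths from co-culture/monoculture abundances
#'
#' Quantifies the actual strength of each interaction type by contrasting
#' co-culture abundances (x_u, x_v) with monoculture abundances (w_u, w_v),
#' u being the microbe more abundant in co-culture:
#' \deqn{M_u = \frac{(x_u/w_u)(x_v/w_v)}{|x_u/w_u - x_v/w_v|}, \quad
#'       A_n = \frac{(w_u/x_u)(w_v/x_v)}{|w_u/x_u - w_v/x_v|}}
#' \deqn{A_g = \frac{x_u/x_v}{w_u/w_v}, \quad
#'       A_l = \frac{x_v/w_v}{x_u/w_u}}
#' so that A_g * A_l = 1 identically. Mutualism applies only when both
#' co/mono ratios exceed 1 (both strains grow better together); antagonism
#' only when both are below 1.
#'
#' @param xu,xv co-culture abundances (u the more abundant in co-culture;
#'   relabeled internally if needed).
#' @param wu,wv monoculture abundances of the same strains.
#' @param strict raise on degenerate ties (equal co/mono ratios) instead of
#'   returning \code{NA}.
#' @return data.frame with \code{Mu}, \code{An}, \code{Ag}, \code{Al},
#'   applicability flags \code{muApplicable}, \code{anApplicable}, and
#'   \code{uFirst}.
#' @examples
#' observedStrengths(6, 3, 3, 2)  # Mu = 6, Ag = 4/3, Al = 3/4
#' @export
observedStrengths <- function(xu, wu, xv, wv, strict = FALSE) {
  n <- max(length(xu), length(wu), length(xv), length(wv))
  xu <- rep_len(as.numeric(xu), n); wu <- rep_len(as.numeric(wu), n)
  xv <- rep_len(as.numeric(xv), n); wv <- rep_len(as.numeric(wv), n)
  if (any(c(xu, wu, xv, wv) <= 0, na.rm = TRUE))
    stop("all four abundances must be positive")
  ## orient by co-culture abundance
  uFirst <- xu >= xv
  swap <- !uFirst
  if (any(swap, na.rm = TRUE)) {
    tmp <- xu[swap]; xu[swap] <- xv[swap]; xv[swap] <- tmp
    tmp <- wu[swap]; wu[swap] <- wv[swap]; wv[swap] <- tmp
  }
  ru <- xu / wu
  rv <- xv / wv
  tie <- ru == rv
  if (any(tie, na.rm = TRUE)) {
    if (strict) stop("equal co/mono ratios: M_u and A_n undefined")
    warning(sum(tie, na.rm = TRUE),
            " pair(s) with equal co/mono ratios: M_u/A_n flagged missing")
  }
  Mu <- ifelse(tie, NA_real_, ru * rv / abs(ru - rv))
  An <- ifelse(tie, NA_real_, (1 / ru) * (1 / rv) / abs(1 / ru - 1 / rv))
  Ag <- (xu / xv) / (wu / wv)
  Al <- (xv / wv) / (xu / wu)
  data.frame(Mu = Mu, An = An, Ag = Ag, Al = Al,
             muApplicable = ru > 1 & rv > 1,
             anApplicable = ru < 1 & rv < 1,
             uFirst = uFirst)
}

#' Correlate descriptors with observed strengths, stratified by growth phase
#'
#' The validation design: for strain pairs measured in both co-culture and
#' monoculture, each snapshot yields both a descriptor (Z) and an observed
#' strength (M/A). A positive Pearson correlation between the two, within
#' each growth phase, supports the descriptor as a proxy for the strength.
#' Mutualism and antagonism correlations are restricted to applicable pairs
#' (see \code{\link{observedStrengths}}).
#'
#' @param descriptors data.frame from \code{\link{computeDescriptors}} (one
#'   row per pair-snapshot).
#' @param strengths data.frame from \code{\link{observedStrengths}},
#'   row-aligned with \code{descriptors}.
#' @param phase character/factor of growth phases ("lag", "log",
#'   "stationary") per row.
#' @param minPairs strata with fewer applicable pairs are reported as
#'   undefined (default 3).
#' @return data.frame with one row per (phase, interaction type):
#'   \code{phase}, \code{type}, \code{n}, \code{r}, \code{p}.
#' @export
validateDescriptors <- function(descriptors, strengths, phase,
                                minPairs = 3) {
  stopifnot(nrow(descriptors) == nrow(strengths),
            nrow(descriptors) == length(phase))
  map <- list(
    mutualism = list(z = descriptors$Zmu, a = strengths$Mu,
                     ok = strengths$muApplicable),
    antagonism = list(z = descriptors$Zan, a = strengths$An,
                      ok = strengths$anApplicable),
    aggression = list(z = descriptors$Zag, a = strengths$Ag,
                      ok = rep(TRUE, nrow(strengths))),
    altruism = list(z = descriptors$Zal, a = strengths$Al,
                    ok = rep(TRUE, nrow(strengths)))
  )
  out <- list()
  for (ph in unique(as.character(phase))) {
    for (ty in names(map)) {
      sel <- phase == ph & map[[ty]]$ok &
        is.finite(map[[ty]]$z) & is.finite(map[[ty]]$a)
      sel[is.na(sel)] <- FALSE
      n <- sum(sel)
      if (n >= minPairs &&
          stats::sd(map[[ty]]$z[sel]) > 0 && stats::sd(map[[ty]]$a[sel]) > 0) {
        ct <- stats::cor.test(map[[ty]]$z[sel], map[[ty]]$a[sel])
        r <- unname(ct$estimate); p <- ct$p.value
      } else {
        r <- NA_real_; p <- NA_real_
      }
      out[[length(out) + 1L]] <- data.frame(
        phase = ph, type = ty, n = n, r = r, p = p,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Full descriptor-validation pipeline on a long culture table
#'
#' Takes the long co-culture/monoculture format (pair_id, time_h,
#' strain_role in \{u, v\}, co_abundance, mono_abundance), assigns a growth
#' phase to each time point from the fitted monoculture growth curve of the
#' pair's focal strain, computes descriptors and observed strengths per
#' time point, and returns per-phase validation correlations.
#'
#' @param culture data.frame in the long format above.
#' @param ... passed to \code{\link{fitGrowth}}.
#' @return list with elements \code{pairs} (per-snapshot table) and
#'   \code{correlations} (from \code{\link{validateDescriptors}}).
#' @export
validateCultures <- function(culture, ...) {
  need <- c("pair_id", "time_h", "strain_role", "co_abundance",
            "mono_abundance")
  if (!all(need %in% names(culture)))
    stop("culture table must have columns: ", paste(need, collapse = ", "))
  rows <- list()
  for (pid in unique(culture$pair_id)) {
    sub <- culture[culture$pair_id == pid, ]
    uu <- sub[sub$strain_role == "u", ]
    vv <- sub[sub$strain_role == "v", ]
    tt <- sort(intersect(uu$time_h, vv$time_h))
    if (length(tt) < 5) next
    uu <- uu[match(tt, uu$time_h), ]
    vv <- vv[match(tt, vv$time_h), ]
    fit <- tryCatch(fitGrowth(tt, uu$mono_abundance, ...),
                    error = function(e) NULL)
    if (is.null(fit)) next
    pb <- segmentPhases(fit)
    ph <- cut(tt, breaks = c(-Inf, pb[1], pb[2], Inf),
              labels = c("lag", "log", "stationary"))
    d <- suppressWarnings(computeDescriptors(uu$co_abundance,
                                             vv$co_abundance))
    s <- suppressWarnings(observedStrengths(uu$co_abundance,
                                            uu$mono_abundance,
                                            vv$co_abundance,
                                            vv$mono_abundance))
    rows[[length(rows) + 1L]] <- cbind(
      data.frame(pair_id = pid, time_h = tt, phase = as.character(ph),
                 stringsAsFactors = FALSE), d, s)
  }
  if (!length(rows)) stop("no usable pairs in culture table")
  tab <- do.call(rbind, rows)
  list(pairs = tab,
       correlations = validateDescriptors(
         tab[c("Zmu", "Zan", "Zag", "Zal")],
         tab[c("Mu", "An", "Ag", "Al", "muApplicable", "anApplicable")],
         tab$phase))
}
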