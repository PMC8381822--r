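test_that("phenotype correction removes covariate structure", {
  set.seed(73)
  n <- 120
  age <- rnorm(n, 40, 10)
  sex <- rep(c(0, 1), n / 2)
  y <- 2 * age + 0.8 * sex + rnorm(n)
  res <- correctPhenotype(y, data.frame(age = age, sex = sex))
  expect_lt(abs(cor(res, age)), 1e-10)
  expect_lt(abs(mean(res[sex == 1]) - mean(res[sex == 0])), 1e-8)
  ## orthogonal covariate: output = centered y
  yc <- rnorm(n)
  resC <- correctPhenotype(yc, NULL)
  expect_equal(resC, yc - mean(yc))
  ## rank-deficient design names the collinear column
  expect_error(correctPhenotype(y, data.frame(a = age, b = 2 * age)),
               "collinear.*b")
})

test_that("GLS correction accepts a relatedness matrix", {
  set.seed(79)
  n <- 50
  K <- diag(n) * 0.5 + 0.5 * tcrossprod(rnorm(n, 1, 0.1)) / n
  K <- (K + t(K)) / 2 + diag(n) * 0.5
  x <- rnorm(n)
  y <- 3 * x + rnorm(n)
  res <- correctPhenotype(y, data.frame(x = x), kinship = K)
  ## residuals orthogonal to x in the V^-1 metric
  expect_lt(abs(crossprod(x, solve(K, res))), 1e-6)
})

test_that("LRT equals the brute-force log-density oracle", {
  set.seed(83)
  n <- 60
  g <- balancedGenotype(n)
  y <- rnorm(n) + 0.4 * g
  fit <- fitSnp(y, g)
  ## oracle: direct maximization by class means + pooled ML variance,
  ## log-likelihoods summed density by density
  mu <- tapply(y, g, mean)
  s1 <- mean((y - mu[as.character(g)])^2)
  s0 <- mean((y - mean(y))^2)
  l1 <- sum(dnorm(y, mu[as.character(g)], sqrt(s1), log = TRUE))
  l0 <- sum(dnorm(y, mean(y), sqrt(s0), log = TRUE))
  expect_equal(fit$lrt, 2 * (l1 - l0), tolerance = 1e-10)
  expect_equal(fit$lrt, n * log(s0 / s1), tolerance = 1e-10)
  expect_equal(unname(fit$muAA), unname(mu[["1"]]))
  expect_equal(unname(fit$muaa), unname(mu[["-1"]]))
})

test_that("LRT is invariant under affine transforms of the phenotype", {
  set.seed(89)
  g <- balancedGenotype(90)
  y <- rnorm(90) + 0.3 * g
  l0 <- fitSnp(y, g)$lrt
  expect_equal(fitSnp(5 - 3.7 * y, g)$lrt, l0, tolerance = 1e-8)
})

test_that("degenerate phenotypes are handled by convention", {
  g <- rep(c(1, 0, -1), each = 4)
  expect_equal(suppressWarnings(fitSnp(rep(2, 12), g))$lrt, 0)  # constant y
  yDeg <- c(rep(0, 4), rep(1, 4), rep(2, 4))      # zero within-class var
  expect_warning(fit <- fitSnp(yDeg, g), "variance floor")
  expect_true(fit$degenerate)
  ## single usable class: skipped
  expect_warning(f2 <- fitSnp(rnorm(5), c(1, 1, 1, 1, 1)), "skipped")
  expect_true(is.na(f2$lrt))
  ## classes below the minimum size excluded
  expect_warning(fitSnp(rnorm(8), c(1, 1, 1, 1, 0, 0, 0, -1)),
                 "below the minimum")
})

test_that("missing genotypes drop hosts per SNP, not globally", {
  set.seed(97)
  n <- 40
  g1 <- balancedGenotype(n)
  g2 <- g1; g2[1:6] <- NA
  y <- rnorm(n)
  G <- cbind(snpA = g1, snpB = g2)
  scan <- scanQTL(y, G, nPerm = 0)
  tab <- scanTable(scan)
  expect_equal(tab$n, c(n, n - 6))
  expect_equal(tab$lrt[2], fitSnp(y[-(1:6)], g2[-(1:6)])$lrt,
               tolerance = 1e-12)
})

test_that("permutation threshold behaves like a max-statistic quantile", {
  set.seed(101)
  n <- 50
  G <- vapply(runif(30, 0.2, 0.5), function(q) hweGenotype(n, q),
              numeric(n))
  y <- rnorm(n)
  ## alpha = 1 gives the minimum of the max-LRT distribution
  thrAll <- permutationThreshold(y, G, nPerm = 50, alpha = 1, seed = 7)
  thr05 <- permutationThreshold(y, G, nPerm = 50, alpha = 0.05, seed = 7)
  thr20 <- permutationThreshold(y, G, nPerm = 50, alpha = 0.20, seed = 7)
  expect_lte(thrAll, thr20)
  expect_lte(thr20, thr05)  # monotone nonincreasing in alpha
  ## bit-exact reproducibility under a fixed seed
  expect_identical(thr05,
                   permutationThreshold(y, G, nPerm = 50, alpha = 0.05,
                                        seed = 7))
})

test_that("scan-level family-wise error is controlled at alpha", {
  set.seed(103)
  n <- 60; p <- 40
  hits <- 0; reps <- 60
  for (r in 1:reps) {
    G <- vapply(runif(p, 0.2, 0.5), function(q) hweGenotype(n, q),
                numeric(n))
    y <- rnorm(n)
    scan <- scanQTL(y, G, nPerm = 60, alpha = 0.05, seed = r)
    hits <- hits + any(scanTable(scan)$significant, na.rm = TRUE)
  }
  rate <- hits / reps
  expect_lt(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / reps))
})
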