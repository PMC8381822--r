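test_that("mutual-information correlation: null, deterministic, equal-mean", {
  set.seed(107)
  g <- hweGenotype(500, 0.4)
  ## independent y: near-zero
  r0 <- miCorrelation(g, rnorm(500))
  expect_true(r0$defined)
  expect_lt(abs(r0$r), 0.1)
  ## y equals the genotype code: r -> 1
  r1 <- miCorrelation(g, as.numeric(g) + rnorm(500, sd = 1e-8))
  expect_gt(r1$r, 0.95)
  ## equal class means and variances: small r (I = 0 analytically)
  r2 <- miCorrelation(g, rnorm(500, mean = 2, sd = 1))
  expect_lt(abs(r2$r), 0.15)
  ## single-class genotype undefined
  expect_false(miCorrelation(rep(1, 20), rnorm(20))$defined)
  ## negative dependence carries a negative sign
  r3 <- miCorrelation(g, -1.5 * g + rnorm(500, sd = 0.3))
  expect_lt(r3$r, -0.8)
})

test_that("mediator screen retains significant genotype links only", {
  set.seed(109)
  n <- 150
  g <- hweGenotype(n, 0.35)
  strong <- 0.5 * g + rnorm(n)        # clearly linked
  weak <- rnorm(n)                    # unlinked
  z <- 0.3 * g + 0.4 * strong + rnorm(n)
  sys <- pathSystem(g, cbind(strong = strong, weak = weak), z)
  kept <- selectMediators(sys, alpha = 0.10)
  expect_true("strong" %in% kept)
  expect_false("weak" %in% kept)
  ## screen responds to the p-value threshold rule directly
  sysFake <- sys
  sysFake$pgy <- c(strong = 0.05, weak = 0.2)
  expect_equal(selectMediators(sysFake, 0.10), "strong")
  ## expected retention of independent mediators ~ alpha each
  keptN <- 0
  for (r in 1:60) {
    Y <- matrix(rnorm(n * 6), n)
    s0 <- pathSystem(g, Y, rnorm(n))
    keptN <- keptN + length(selectMediators(s0, 0.10))
  }
  expect_gt(keptN / 60, 0.2)  # ~0.6 expected
  expect_lt(keptN / 60, 1.4)
})

test_that("decomposition identity and limiting cases", {
  set.seed(113)
  n <- 200
  g <- hweGenotype(n, 0.4)
  ## r_gy = 0 (orthogonalized mediator): direct = r_gz, indirect = 0
  yRaw <- rnorm(n)
  y <- residuals(lm(yRaw ~ g))
  z <- 0.4 * g + 0.6 * y + rnorm(n)
  sys <- pathSystem(g, cbind(y = y), z)
  pm <- decomposePaths(sys, mediators = "y")
  expect_equal(pm@indirect[["y"]], 0, tolerance = 1e-10)
  expect_equal(pm@direct, sys$rgz, tolerance = 1e-10)
  ## full mediation: z = y exactly
  y2 <- 0.5 * g + rnorm(n)
  sys2 <- pathSystem(g, cbind(y = y2), y2)
  pm2 <- decomposePaths(sys2, mediators = "y")
  expect_equal(pm2@mediatorCoefficients[["y"]], 1, tolerance = 1e-10)
  expect_equal(pm2@direct, 0, tolerance = 1e-10)
  expect_equal(pm2@r2, 1, tolerance = 1e-10)
  expect_equal(pm2@residualPath, 0, tolerance = 1e-5)
  ## empty mediator set reduces to the direct-only model
  sys3 <- pathSystem(g, cbind(y = rnorm(n)), z)
  pm3 <- decomposePaths(sys3, mediators = character(0))
  expect_equal(pm3@direct, sys3$rgz)
  expect_length(pm3@indirect, 0)
})

test_that("single-mediator paper convention is available", {
  set.seed(127)
  n <- 150
  g <- hweGenotype(n, 0.3)
  y <- 0.4 * g + rnorm(n)
  z <- 0.3 * g + 0.5 * y + rnorm(n)
  sys <- pathSystem(g, cbind(y = y), z)
  pm <- decomposePaths(sys, mediators = "y", yzAsDirect = TRUE)
  expect_equal(pm@mediatorCoefficients[["y"]], unname(sys$ryz["y"]))
  expect_equal(pm@direct + pm@indirect[["y"]], sys$rgz, tolerance = 1e-12)
})

test_that("dropping a zero-coefficient mediator leaves the rest unchanged", {
  set.seed(131)
  n <- 300
  g <- hweGenotype(n, 0.4)
  y1 <- 0.5 * g + rnorm(n)
  z <- 0.4 * g + 0.7 * y1 + rnorm(n)
  ## y2: correlated with g but orthogonalized against everything in z
  y2 <- residuals(lm(rnorm(n) ~ g + y1 + z))
  sys <- pathSystem(g, cbind(y1 = y1, y2 = y2), z)
  pmBoth <- decomposePaths(sys, mediators = c("y1", "y2"))
  pmOne <- decomposePaths(sys, mediators = "y1")
  expect_lt(abs(pmBoth@mediatorCoefficients[["y2"]]), 1e-10)
  expect_equal(pmBoth@direct, pmOne@direct, tolerance = 1e-10)
  expect_equal(pmBoth@mediatorCoefficients[["y1"]],
               pmOne@mediatorCoefficients[["y1"]], tolerance = 1e-10)
})

test_that("collinear mediators fail loudly with a condition number", {
  set.seed(137)
  n <- 100
  g <- hweGenotype(n, 0.4)
  y1 <- 0.3 * g + rnorm(n)
  sys <- pathSystem(g, cbind(y1 = y1, y2 = y1 + rnorm(n, sd = 1e-9)),
                    rnorm(n))
  expect_error(decomposePaths(sys, mediators = c("y1", "y2")),
               "collinear")
})

test_that("season perturbation aligns hosts present in both seasons", {
  w <- matrix(1:6, 3, 2, dimnames = list(c("a", "b", "c"), c("p", "q")))
  s <- matrix(1, 2, 2, dimnames = list(c("c", "a"), c("p", "q")))
  d <- seasonPerturbation(w, s)
  expect_equal(rownames(d), c("a", "c"))
  expect_equal(d["a", "p"], 0)  # 1 - 1
  expect_error(seasonPerturbation(w, matrix(1, 1, 2,
    dimnames = list("zz", c("p", "q")))), "both seasons")
})
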