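## A tensor where one pair's mutualism descriptor is far above all others
## in every host, on a background of exchangeable noise.
spikedTensor <- function(nHosts = 12, m = 6, spike = 10) {
  set.seed(47)
  ab <- matrix(rexp(nHosts * m) + 0.2, nHosts, m)
  ## make taxa 1 and 2 nearly tied and both large in every host: their
  ## Z_mu (product / small difference) dwarfs every other pair's
  ab[, 1] <- 50 + runif(nHosts)
  ab[, 2] <- ab[, 1] - 0.5
  suppressWarnings(descriptorTensor(ab))
}

test_that("a strongly elevated edge is retained by the permutation test", {
  tt <- spikedTensor()
  net <- suppressMessages(buildNetwork(tt, "mutualism", alpha = 0.05,
                                       B = 500, seed = 3))
  a <- adjacencyMatrix(net)
  expect_equal(unname(a[1, 2]), 1)
  expect_equal(unname(a[2, 1]), 1)  # undirected symmetry
  et <- edgeTable(net)
  expect_true(nrow(et) >= 1)
  expect_true(all(is.finite(et$weight)))
})

test_that("exchangeable null tensors retain almost nothing", {
  set.seed(53)
  falsePos <- 0; tested <- 0
  for (r in 1:25) {
    ab <- matrix(rexp(8 * 6) + 0.2, 8, 6)
    tt <- suppressWarnings(descriptorTensor(ab))
    net <- suppressMessages(
      suppressWarnings(buildNetwork(tt, "aggression", alpha = 0.05,
                                    B = 200, seed = r)))
    falsePos <- falsePos + nrow(edgeTable(net))
    tested <- tested + nrow(tt@pairs)
  }
  ## BH at 0.05 on exchangeable nulls: retained fraction well under alpha
  ## (allow binomial slack)
  expect_lt(falsePos / tested, 0.05 + 2 * sqrt(0.05 * 0.95 / tested))
})

test_that("single-pair tensors are flagged indeterminate", {
  ab <- matrix(c(4, 2, 6, 3, 8, 4), 3, 2, byrow = TRUE)
  tt <- descriptorTensor(ab)
  ws <- capture_warnings(
    net <- suppressMessages(buildNetwork(tt, "mutualism", B = 100)))
  expect_match(ws, "indeterminate", all = FALSE)
  expect_equal(nrow(edgeTable(net)), 0L)
  expect_true(net@indeterminate[1, 2])
})

test_that("directed networks have no two-cycles and majority orientation", {
  set.seed(59)
  ab <- matrix(rexp(10 * 5, 0.1) + 0.5, 10, 5)
  ab[, 1] <- ab[, 1] + 50      # taxon 1 dominates everywhere
  tt <- suppressWarnings(descriptorTensor(ab))
  net <- suppressWarnings(buildNetwork(tt, "aggression", alpha = 0.5,
                                       B = 200, seed = 5))
  a <- adjacencyMatrix(net)
  expect_true(all(a * t(a) == 0))  # no reciprocal pair
  ## taxon 1 dominates every host, so none of its edges may point at it
  expect_equal(sum(a[, 1]), 0)
})

test_that("per-host networks threshold at the descriptor quantile", {
  set.seed(61)
  ab <- matrix(rexp(4 * 8, 0.1) + 0.5, 4, 8)
  tt <- suppressWarnings(descriptorTensor(ab))
  net <- perHostNetwork(tt, "mutualism", 2, quantile = 0.75)
  vals <- descriptorMatrix(tt, "mutualism")[2, ]
  expected <- sum(vals >= stats::quantile(vals[is.finite(vals)], 0.75),
                  na.rm = TRUE)
  expect_equal(nrow(edgeTable(net)), expected)
  netAll <- perHostNetwork(tt, "altruism", 2, quantile = NULL)
  expect_true(isDirected(netAll))
  expect_equal(nrow(edgeTable(netAll)), sum(is.finite(
    descriptorMatrix(tt, "altruism")[2, ])))
})

test_that("hub detection: star graph, roles, abundance contrast", {
  star <- matrix(0, 10, 10)
  star[1, 2:10] <- star[2:10, 1] <- 1
  hubs <- detectHubs(netFromAdj(star))
  expect_equal(hubs$hubs, "t1")
  ## hawk / dove / hawk-dove partition: a->b, a->c, c->b
  adj <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  adj["a", "b"] <- adj["a", "c"] <- adj["c", "b"] <- 1
  roles <- suppressWarnings(detectHubs(netFromAdj(adj, directed = TRUE,
                                                  type = "aggression")))$roles
  expect_equal(roles[["a"]], "hawk")
  expect_equal(roles[["c"]], "hawk-dove")
  expect_equal(roles[["b"]], "dove")
  ## abundance t-test: hubs 10 +/- 1, others 1 +/- 1
  set.seed(67)
  big <- matrix(0, 20, 20)
  big[1:5, ] <- big[, 1:5] <- 1
  diag(big) <- 0
  ab <- c(rnorm(5, 10, 1), rnorm(15, 1, 1))
  rep <- detectHubs(netFromAdj(big), abundance = ab)
  expect_setequal(rep$hubs, paste0("t", 1:5))
  expect_lt(rep$tTest$p.value, 1e-3)
  ## all-equal degrees: empty hub set with warning
  ring <- matrix(0, 6, 6)
  for (i in 1:6) { j <- i %% 6 + 1; ring[i, j] <- ring[j, i] <- 1 }
  expect_warning(h0 <- detectHubs(netFromAdj(ring)), "no hubs")
  expect_length(h0$hubs, 0)
})

test_that("power-law exponent is recovered and misfit is rejected", {
  set.seed(71)
  k <- rPowerLawDiscrete(500, 2.5)
  res <- powerlawTest(k, nBoot = 50, seed = 2)
  expect_true(res$defined)
  expect_gt(res$alpha, 2.2)
  expect_lt(res$alpha, 2.8)
  ## constant-degree regular graph: power law rejected
  kReg <- rep(4L, 200)
  resReg <- powerlawTest(kReg, nBoot = 50, seed = 3)
  expect_lt(resReg$p, 0.05)
  ## tiny networks are flagged undefined
  tiny <- netFromAdj(pathGraph3())
  resTiny <- powerlawTest(tiny)
  expect_false(resTiny$defined)
  expect_true(is.na(resTiny$alpha))
})
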