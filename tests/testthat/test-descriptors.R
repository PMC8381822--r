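test_that("descriptors reproduce the printed closed forms", {
  d <- computeDescriptors(4, 2)
  expect_equal(d$Zag, 2.0)
  expect_equal(d$Zal, 0.5)
  expect_equal(d$Zmu, 4.0)          # 8 / 2
  expect_equal(d$Zan, 1 / (4 * 2 * 2))
  dAlt <- computeDescriptors(4, 2, anForm = "inverse-mutualism")
  expect_equal(dAlt$Zan, 2 / 8)
  expect_equal(dAlt$Zan, 1 / dAlt$Zmu)
})

test_that("tied and zero abundances degrade gracefully (and strictly)", {
  expect_warning(d <- computeDescriptors(3, 3), "tied")
  expect_equal(d$Zag, 1)
  expect_equal(d$Zal, 0)
  expect_true(is.na(d$Zmu) && is.na(d$Zan))
  expect_warning(z <- computeDescriptors(5, 0), "zero")
  expect_true(all(is.na(z[c("Zmu", "Zan", "Zag", "Zal")])))
  expect_error(computeDescriptors(3, 3, strict = TRUE), "tied")
  expect_error(computeDescriptors(5, 0, strict = TRUE), "zero")
  expect_error(computeDescriptors(-1, 2), "nonnegative")
})

test_that("descriptor algebra: relabeling, scale, and the Zal identity", {
  set.seed(41)
  x <- rexp(500) + 0.01
  y <- rexp(500) + 0.01
  d1 <- computeDescriptors(x, y)
  d2 <- computeDescriptors(y, x)  # swapped input order
  expect_equal(d1[c("Zmu", "Zan", "Zag", "Zal")],
               d2[c("Zmu", "Zan", "Zag", "Zal")])
  expect_equal(d1$uFirst, !d2$uFirst)
  expect_equal(d1$Zal, 1 - 1 / d1$Zag, tolerance = 1e-12)
  for (cc in c(0.5, 3, 17)) {
    ds <- computeDescriptors(cc * x, cc * y)
    expect_equal(ds$Zmu, cc * d1$Zmu, tolerance = 1e-12)
    expect_equal(ds$Zag, d1$Zag, tolerance = 1e-12)
    expect_equal(ds$Zal, d1$Zal, tolerance = 1e-12)
  }
})

test_that("descriptor tensor matches an element-wise brute-force oracle", {
  set.seed(7)
  ab <- matrix(rexp(30, 0.1) + 0.1, 5, 6,
               dimnames = list(paste0("h", 1:5), paste0("g", 1:6)))
  tt <- descriptorTensor(ab)
  for (p in seq_len(nrow(tt@pairs))) {
    i <- tt@pairs[p, 1]; j <- tt@pairs[p, 2]
    for (h in 1:5) {
      ref <- computeDescriptors(ab[h, i], ab[h, j])
      expect_equal(descriptorMatrix(tt, "mutualism")[h, p],
                   ref$Zmu, tolerance = 1e-14, ignore_attr = TRUE)
      expect_equal(descriptorMatrix(tt, "aggression")[h, p],
                   ref$Zag, tolerance = 1e-14, ignore_attr = TRUE)
      expect_equal(descriptorMatrix(tt, "altruism")[h, p],
                   ref$Zal, tolerance = 1e-14, ignore_attr = TRUE)
      expect_equal(tt@uFirst[h, p], ref$uFirst)
    }
  }
})

test_that("tensor orientation points from higher to lower abundance", {
  ab <- matrix(c(8, 4, 2), 1, 3,
               dimnames = list("h1", c("a", "b", "c")))
  tt <- descriptorTensor(ab)
  expect_equal(nrow(tt@pairs), 3L)
  expect_true(all(tt@uFirst))  # columns are in decreasing abundance
  expect_equal(unname(descriptorMatrix(tt, "aggression")[1, ]),
               c(2, 4, 2))    # 8/4, 8/2, 4/2
})

test_that("equal-abundance pairs propagate as missing in the tensor", {
  ab <- matrix(c(5, 5, 2, 6, 3, 1), 2, 3, byrow = TRUE)
  expect_warning(tt <- descriptorTensor(ab), "missing")
  expect_true(is.na(descriptorMatrix(tt, "mutualism")[1, 1]))
  expect_false(anyNA(descriptorMatrix(tt, "mutualism")[2, ]))
})

test_that("observed strengths reproduce the worked co-culture example", {
  s <- observedStrengths(6, 3, 3, 2)
  expect_equal(s$Mu, 6.0)                 # (2 * 1.5) / 0.5
  expect_equal(s$Ag, (6 / 3) / (3 / 2))   # 4/3
  expect_equal(s$Al, (3 / 2) / (6 / 3))   # 3/4
  expect_equal(s$An, 2.0, tolerance = 1e-12)
  expect_true(s$muApplicable)   # both co/mono ratios > 1
  expect_false(s$anApplicable)  # flagged not-applicable
})

test_that("strength identities hold on random culture pairs", {
  set.seed(11)
  n <- 2000
  xu <- rexp(n) + 0.05; wu <- rexp(n) + 0.05
  xv <- rexp(n) + 0.05; wv <- rexp(n) + 0.05
  s <- suppressWarnings(observedStrengths(xu, wu, xv, wv))
  expect_true(all(abs(s$Ag * s$Al - 1) < 1e-12))
  ## M_u = (xu/wu)(xv/wv) * A_n wherever both are defined
  ru <- pmax(xu / wu, xv / wv); rv <- pmin(xu / wu, xv / wv)
  ok <- !is.na(s$Mu)
  expect_equal(s$Mu[ok], (ru * rv * s$An)[ok], tolerance = 1e-10)
})

test_that("validation correlations: identity, shuffle null, attenuation", {
  set.seed(13)
  n <- 200
  phase <- rep(c("lag", "log", "stationary"), length.out = n)
  zag <- rexp(n) + 1.01
  desc <- data.frame(Zmu = rexp(n) + 0.1, Zan = rexp(n) + 0.1,
                     Zag = zag, Zal = 1 - 1 / zag)
  ## strengths equal to descriptors: r = 1 per phase
  str <- data.frame(Mu = desc$Zmu, An = desc$Zan, Ag = desc$Zag,
                    Al = desc$Zal, muApplicable = TRUE,
                    anApplicable = TRUE)
  rep1 <- validateDescriptors(desc, str, phase)
  expect_true(all(abs(rep1$r - 1) < 1e-12))
  expect_true(all(rep1$p < 1e-6))
  ## shuffled strengths: near-zero correlation
  str2 <- str[sample.int(n), ]
  rep2 <- validateDescriptors(desc, str2, rep("log", n))
  expect_true(all(abs(rep2$r[rep2$type == "aggression"]) < 0.2))
  ## additive Gaussian noise attenuates r toward 1/sqrt(1 + s2/var(Z))
  z <- rnorm(5000)
  s2 <- 0.5
  a <- z + rnorm(5000, sd = sqrt(s2))
  dd <- data.frame(Zmu = 1, Zan = 1, Zag = z, Zal = 1)
  ss <- data.frame(Mu = 1, An = 1, Ag = a, Al = 1,
                   muApplicable = FALSE, anApplicable = FALSE)
  rep3 <- validateDescriptors(dd, ss, rep("log", 5000))
  expected <- 1 / sqrt(1 + s2 / stats::var(z))
  got <- rep3$r[rep3$type == "aggression"]
  expect_equal(got, expected, tolerance = 0.05)
  ## too-small strata are undefined, not an error
  rep4 <- validateDescriptors(desc[1:2, ], str[1:2, ], c("lag", "lag"))
  expect_true(all(is.na(rep4$r)))
})

test_that("culture-table pipeline returns per-phase correlations", {
  set.seed(17)
  times <- growthSamplingGrid()
  rows <- list()
  for (p in 1:6) {
    Ku <- 2 + p / 3; Kv <- 1 + p / 4
    mono_u <- Ku / (1 + exp(-0.4 * (times - 10)))
    mono_v <- Kv / (1 + exp(-0.3 * (times - 12)))
    boost <- 1.3 + 0.05 * p
    co_u <- mono_u * boost * exp(rnorm(length(times), 0, 0.02))
    co_v <- mono_v * boost * exp(rnorm(length(times), 0, 0.02))
    rows[[p]] <- rbind(
      data.frame(pair_id = p, time_h = times, strain_role = "u",
                 co_abundance = co_u + 1e-3, mono_abundance = mono_u + 1e-3),
      data.frame(pair_id = p, time_h = times, strain_role = "v",
                 co_abundance = co_v + 1e-3, mono_abundance = mono_v + 1e-3))
  }
  culture <- do.call(rbind, rows)
  res <- validateCultures(culture)
  expect_s3_class(res$correlations, "data.frame")
  expect_true(all(c("lag", "log", "stationary") %in%
                    res$correlations$phase))
  expect_true(any(is.finite(res$correlations$r)))
})
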