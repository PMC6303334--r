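test_that("effect decomposition matches brute-force averaging oracles", {
  set.seed(101)
  # two-way design
  info <- expand.grid(replicate = 1:2, part = 1:3, individual = 1:4)
  Y <- matrix(rnorm(nrow(info) * 6), nrow(info), 6)
  dec <- decomposeEffects(Y, info, "A1")
  expect_equal(dec$ss, oracleTwoWaySS(Y, info$individual, info$part),
               tolerance = 1e-12)
  # component orthogonality and SS additivity
  cm <- do.call(cbind, lapply(dec$components, as.vector))
  G <- crossprod(cm)
  expect_lt(max(abs(G[upper.tri(G)])) / max(diag(G)), 1e-12)
  tot <- sum(sweep(Y, 2, colMeans(Y))^2)
  expect_equal(sum(dec$ss), tot, tolerance = 1e-12)
  # nested design on expanded rows
  info3 <- expand.grid(replicate = 1:2, copy = 1:2, part = 1:3,
                       individual = 1:4)
  Y3 <- matrix(rnorm(nrow(info3) * 6), nrow(info3), 6)
  dec3 <- decomposeEffects(Y3, info3, "A3")
  expect_equal(dec3$ss,
               oracleNestedSS(Y3, info3$individual, info3$part,
                              info3$copy),
               tolerance = 1e-12)
  expect_equal(sum(dec3$ss), sum(sweep(Y3, 2, colMeans(Y3))^2) / 2,
               tolerance = 1e-12)
  # degenerate input: a constant dataset has zero SS everywhere
  decC <- decomposeEffects(matrix(1, nrow(info), 4), info, "A1")
  expect_true(all(decC$ss < 1e-25))
  # unbalanced grids are rejected
  expect_error(decomposeEffects(Y[-1, ], info[-1, ], "A1"),
               "unbalanced")
})

test_that("published df bookkeeping is reproduced for the lantern structure", {
  sch <- lanternScheme()
  sim <- simulateLanterns(varianceComponents(), sch, seed = 42)
  ls <- sim$landmarks
  f1 <- rotationalAnova(ls, sch)
  t1 <- effectTable(f1)
  expect_equal(t1$convDf, c(9, 4, 36, 50))
  expect_equal(t1$shapeDf, c(90, 40, 360, 500))
  f2 <- bilateralAnova(ls, sch)
  t2 <- effectTable(f2)
  expect_equal(t2$convDf, c(4, 1, 4, 45, 45, 45))
  expect_equal(t2$shapeDf, c(40, 10, 40, 450, 450, 900))
  f3 <- nestedAnova(ls, sch)
  t3 <- effectTable(f3)
  expect_equal(t3$convDf, c(9, 4, 5, 36, 45, 45, 45, 45))
  expect_equal(t3$shapeDf, c(90, 40, 50, 360, 450, 450, 450, 900))
  fs <- centroidSizeAnova(ls, scheme = sch)
  expect_equal(effectTable(fs)$convDf, c(9, 4, 36, 50))
  # A2 reflection + interaction SS decompose A3's nested DA term
  expect_equal(t2$ss[2] + t2$ss[3], t3$ss[3], tolerance = 1e-6)
  # symmetric effects have no asymmetric projection and vice versa
  pr <- f3@projectors
  for (eff in names(f3@subspace)) {
    cmp <- f3@components[[eff]]
    if (is.null(cmp)) next
    if (f3@subspace[eff] == "symmetric")
      expect_lt(sum((cmp %*% pr@asymmetric)^2) / max(sum(cmp^2), 1e-30),
                1e-10)
    if (f3@subspace[eff] == "asymmetric")
      expect_lt(sum((cmp %*% pr@symmetric)^2) / max(sum(cmp^2), 1e-30),
                1e-10)
  }
})

test_that("a pure individual-effect simulation concentrates SS on the individual row", {
  sch <- toyScheme()
  p <- toyParams(sigmaIndividual = 0.01, sigmaRotFA = 0, sigmaBilFA = 0,
                 sigmaError = 0)
  sim <- simulateLanterns(p, sch, seed = 5)
  f1 <- suppressWarnings(rotationalAnova(sim$landmarks, sch))
  ss <- effectTable(f1)$ss
  expect_gt(ss[1] / sum(ss), 0.999)
})

test_that("Goodall F follows its definition and distributional identities", {
  expect_equal(goodallF(2, 10, 1, 5)$F, 1)
  expect_warning(res <- goodallF(1, 10, 0, 5), "zero denominator")
  expect_true(is.na(res$p))
  expect_error(goodallF(1, 0, 1, 5), "positive")
  # df1 = 1, large df2: upper tail matches the two-sided z computation
  f <- 3.7
  expect_lt(abs(goodallF(f, 1, 1e8, 1e8)$p - 2 * pnorm(-sqrt(f))), 1e-6)
  # published-table reconstruction: lantern individual effect
  expect_equal(goodallF(0.111301, 90, 0.003544, 360)$F, 125.639,
               tolerance = 2e-3)
})

test_that("null tangent data give F ratios near 1 in expectation", {
  set.seed(131)
  info <- expand.grid(replicate = 1:2, part = 1:5, individual = 1:10)
  nrep <- 300
  fI <- fIP <- numeric(nrep)
  for (b in seq_len(nrep)) {
    Y <- matrix(rnorm(nrow(info) * 8), nrow(info), 8)
    dec <- decomposeEffects(Y, info, "A1", check = FALSE)
    ms <- dec$ss / dec$convDf
    fI[b] <- ms["individual"] / ms["interaction"]
    fIP[b] <- ms["interaction"] / ms["error"]
  }
  # E[F(d1, d2)] = d2 / (d2 - 2); compare within 3 Monte-Carlo s.e.
  for (x in list(list(fI, 36 * 8), list(fIP, 50 * 8))) {
    expect_lt(abs(mean(x[[1]]) - x[[2]] / (x[[2]] - 2)),
              3 * sd(x[[1]]) / sqrt(nrep))
  }
})

test_that("centroid-size ANOVA uses conventional df and detects constant sizes", {
  info <- expand.grid(replicate = 1:2, part = 1:5, individual = 1:10)
  fit <- suppressWarnings(
    centroidSizeAnova(rep(7, nrow(info)), info = info))
  expect_true(all(effectTable(fit)$ss < 1e-25))
  expect_equal(effectTable(fit)$convDf, effectTable(fit)$shapeDf)
  # object-mode schemes are rejected: no size asymmetry exists
  sch <- symmetryScheme("object", k = 5,
                        pairs = rbind(c(2, 3), c(4, 5)), unpaired = 1)
  expect_error(centroidSizeAnova(rnorm(10, 7), info = info, scheme = sch),
               "no asymmetry in size")
  # single replicate: measurement error not estimable in A1
  sim <- simulateLanterns(toyParams(), toyScheme(), seed = 3)
  one <- sim$landmarks[sampleInfo(sim$landmarks)$replicate == 1]
  expect_error(rotationalAnova(one, toyScheme()), "single replicate")
  red <- rotationalAnova(one, toyScheme(), allowSingleReplicate = TRUE)
  expect_false("error" %in% effectTable(red)$effect)
})
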