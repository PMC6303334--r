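test_that("zero variance components give identical configurations", {
  sch <- toyScheme()
  p <- toyParams(sigmaIndividual = 0, sigmaRotFA = 0, sigmaBilFA = 0,
                 sigmaError = 0)
  p@sizeSigmaIndividual <- 0; p@sizeSigmaFA <- 0; p@sizeSigmaError <- 0
  sim <- simulateLanterns(p, sch, seed = 1, nuisance = FALSE)
  co <- landmarkCoords(sim$landmarks)
  for (i in 2:dim(co)[3])
    expect_equal(co[, , i], co[, , 1], tolerance = 1e-12)
  # and the ANOVA sees no variation at all
  f1 <- suppressWarnings(rotationalAnova(sim$landmarks, sch))
  expect_lt(sum(effectTable(f1)$ss), 1e-16)
})

test_that("DA vectors outside their subspace are rejected", {
  sch <- toyScheme()
  p <- toyParams()
  pr <- subspaceProjectors(sch, p@consensus)
  bad <- p
  bad@daBilateral <- matrix(rnorm(10, sd = 0.01), 3, 10)  # not asymmetric
  expect_error(simulateLanterns(bad, sch, seed = 1),
               "outside its declared subspace")
  good <- p
  good@daBilateral <- bad@daBilateral %*% pr@asymmetric
  expect_silent(invisible(simulateLanterns(good, sch, seed = 1)))
})

test_that("bilateral-FA-only simulations concentrate SS on the bilateral FA term", {
  sch <- toyScheme()
  p <- toyParams(sigmaIndividual = 0, sigmaRotFA = 0, sigmaBilFA = 0.003,
                 sigmaError = 0.0005)
  ratios <- numeric(50)
  for (b in 1:50) {
    sim <- simulateLanterns(p, sch, seed = 3000 + b)
    tab <- effectTable(nestedAnova(sim$landmarks, sch))
    # concentration among the random-effect rows (the fixed DA rows are
    # mean estimates whose SS absorbs FA noise by construction)
    rnd <- tab$effect %in% c("individual", "indXpart", "indXreflection")
    ratios[b] <- tab$ss[tab$effect == "indXreflection"] /
      sum(tab$ss[rnd])
  }
  expect_gt(mean(ratios), 0.95)
})

test_that("the generator reproduces its declared variance scales", {
  # tangent draws restricted to the declared subspaces, sizes additive
  sch <- toyScheme()
  p <- toyParams(sigmaIndividual = 0.01, sigmaRotFA = 0, sigmaBilFA = 0,
                 sigmaError = 0)
  sim <- simulateLanterns(p, sch, seed = 23, nuisance = FALSE)
  pr <- subspaceProjectors(sch, p@consensus)
  V <- sim$truth$tangent
  expect_lt(max(abs(V %*% pr@asymmetric)), 1e-12)
  # per-coordinate variance of the symmetric draws matches sigma
  a <- sim$truth$individual
  expect_equal(sum(a^2) / (nrow(a) * pr@dimSym), p@sigmaIndividual^2,
               tolerance = 0.5)
})
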