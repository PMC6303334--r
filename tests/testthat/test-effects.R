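test_that("effect SSCPs are consistent with the table mean squares", {
  sch <- toyScheme()
  sim <- simulateLanterns(toyParams(daBilNorm = 0.01), sch, seed = 14)
  f3 <- nestedAnova(sim$landmarks, sch)
  tab <- effectTable(f3)
  for (eff in c("individual", "part", "reflectionInPart", "indXpart",
                "indXreflection")) {
    i <- match(eff, tab$effect)
    # trace of SSCP / shape df equals the tabulated MS
    expect_equal(sum(diag(f3@sscp[[eff]])) / tab$shapeDf[i], tab$ms[i],
                 tolerance = 1e-10)
  }
  # SS additivity through the SSCP route as well
  expect_equal(sum(diag(f3@sscp$symmetricError)) +
                 sum(diag(f3@sscp$asymmetricError)),
               tab$ss[tab$effect == "totalError"], tolerance = 1e-10)
})

test_that("EMS recovery returns a zero error covariance for noiseless data", {
  sch <- toyScheme()
  p <- toyParams(sigmaError = 0, sigmaIndividual = 0.01,
                 sigmaRotFA = 0.002, sigmaBilFA = 0.002)
  sim <- simulateLanterns(p, sch, seed = 15)
  f3 <- nestedAnova(sim$landmarks, sch)
  covs <- suppressWarnings(effectCovariances(f3))
  expect_lt(max(abs(covs$error@covariance)), 1e-18)
})

test_that("EMS-based covariance recovery is approximately unbiased", {
  sch <- toyScheme()
  p <- toyParams(sigmaIndividual = 0.01, sigmaRotFA = 0.003,
                 sigmaBilFA = 0.004, sigmaError = 0.002)
  est <- matrix(0, 20, 4)
  for (b in 1:20) {
    sim <- simulateLanterns(p, sch, seed = 700 + b)
    est[b, ] <- estimateVarianceComponents(
      nestedAnova(sim$landmarks, sch))[
        c("sigmaIndividual", "sigmaRotFA", "sigmaBilFA", "sigmaError")]
  }
  truth <- c(0.01, 0.003, 0.004, 0.002)
  expect_lt(max(abs(colMeans(est) / truth - 1)), 0.10)
})

test_that("PCA of effect covariances has the expected structure", {
  set.seed(161)
  cons <- toyTemplate()
  v <- rnorm(10)
  pc <- pcaEffect(tcrossprod(v), consensus = cons)
  # rank-1 matrix: PC1 = +-v, eigenvalue |v|^2, rest zero
  expect_equal(pc$values[1], sum(v^2), tolerance = 1e-10)
  expect_lt(max(abs(pc$values[-1])), 1e-10)
  expect_equal(abs(sum(pc$vectors[, 1] * v / sqrt(sum(v^2)))), 1,
               tolerance = 1e-10)
  # eigenvalue sum equals the trace
  sch <- toyScheme()
  sim <- simulateLanterns(toyParams(daBilNorm = 0.01, sigmaBilFA = 0.004),
                          sch, seed = 17)
  f3 <- nestedAnova(sim$landmarks, sch)
  covs <- suppressWarnings(effectCovariances(f3))
  for (cv in covs) {
    ed <- pcaEffect(cv, nPC = 1)
    expect_equal(sum(ed$values), sum(diag(cv@covariance)),
                 tolerance = 1e-10)
  }
  # bilateral-FA principal components stay in the asymmetric subspace
  pr <- f3@projectors
  vecs <- pcaEffect(covs$indXreflection, nPC = 3)$vectors[, 1:3]
  expect_lt(max(abs(pr@symmetric %*% vecs)), 1e-10)
  expect_error(pcaEffect(matrix(rnorm(16), 4), consensus = cons),
               "symmetric")
})

test_that("exported DA vectors equal the original-minus-reflected mean difference", {
  sch <- toyScheme()
  # nuisance off keeps the GPA consensus in the template frame, so the
  # estimated tangent vector is comparable with the injected one
  sim <- simulateLanterns(toyParams(daBilNorm = 0.02), sch, seed = 18,
                          nuisance = FALSE)
  f2 <- bilateralAnova(sim$landmarks, sch)
  da <- directionalAsymmetry(f2)
  Y <- f2@fitInfo$tangent
  cp <- f2@fitInfo$info$copy
  halfDiff <- (colMeans(Y[cp == 1L, ]) - colMeans(Y[cp == 2L, ])) / 2
  expect_equal(da$mean, halfDiff, tolerance = 1e-10)
  # and it recovers the injected displacement direction
  inj <- sim$truth$params@daBilateral[1, ]
  cosang <- sum(da$mean * inj) / sqrt(sum(da$mean^2) * sum(inj^2))
  expect_gt(cosang, 0.95)
})

test_that("lollipop export round-trips through CSV with its amplification", {
  sch <- toyScheme()
  sim <- simulateLanterns(toyParams(daBilNorm = 0.01), sch, seed = 20)
  f3 <- nestedAnova(sim$landmarks, sch)
  covs <- suppressWarnings(effectCovariances(f3))
  lol <- lollipopData(covs, nPC = 2, amplification = 10)
  expect_setequal(unique(lol$effect), names(covs))
  path <- tempfile(fileext = ".csv")
  writeLollipop(lol, path)
  lines <- readLines(path)
  expect_match(lines[1], "amplification: 10")
  back <- read.csv(path, comment.char = "#")
  expect_equal(nrow(back), nrow(lol))
  expect_equal(back$dx, lol$dx, tolerance = 1e-12)
})
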