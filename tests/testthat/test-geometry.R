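test_that("centroid size follows the definition and scales linearly", {
  sq <- matrix(c(-1, -1, -1, 1, 1, -1, 1, 1), ncol = 2, byrow = TRUE)
  expect_equal(centroidSize(sq), sqrt(8))
  set.seed(11)
  for (i in 1:5) {
    m <- matrix(rnorm(24, sd = 3), 12, 2)
    expect_equal(centroidSize(m), oracleCS(m))
    expect_equal(centroidSize(2 * m), 2 * centroidSize(m))
    # invariance to translation and rotation
    expect_equal(centroidSize(sweep(m, 2, c(5, -2), `+`)),
                 centroidSize(m))
    expect_equal(centroidSize(m %*% rotMat(0.7)), centroidSize(m))
  }
  expect_error(centroidSize(matrix(1, 4, 2)), "degenerate")
})

test_that("GPA gives zero Procrustes SS for identical shapes", {
  tri <- matrix(c(0, 0, 1, 0, 0.5, 1), ncol = 2, byrow = TRUE)
  g <- partialGPA(list(tri, tri, tri))
  expect_lt(procrustesSS(g), 1e-20)
  expect_equal(consensusShape(g),
               {m <- sweep(tri, 2, colMeans(tri)); m / sqrt(sum(m^2))},
               tolerance = 1e-10)
  # a rotated/translated/scaled copy is the same shape
  tri2 <- 3.2 * tri %*% rotMat(1.1) + 5
  g2 <- partialGPA(list(tri, tri2))
  expect_lt(procrustesSS(g2), 1e-18)
})

test_that("alignment is invariant under similarity transforms of inputs", {
  set.seed(21)
  base <- toyTemplate()
  configs <- lapply(1:4, function(i) base + matrix(rnorm(10, sd = 0.02),
                                                  5, 2))
  g1 <- partialGPA(configs)
  configs2 <- configs
  configs2[[3]] <- 0.4 * configs2[[3]] %*% rotMat(-2.2) + 7
  g2 <- partialGPA(configs2)
  expect_equal(alignedCoords(g1), alignedCoords(g2), tolerance = 1e-8)
  expect_equal(procrustesSS(g1), procrustesSS(g2), tolerance = 1e-8)
})

test_that("GPA residual SS matches a rotation-grid-search oracle", {
  set.seed(31)
  tri <- matrix(c(0, 0, 1, 0, 0.4, 0.9), ncol = 2, byrow = TRUE)
  for (rep in 1:3) {
    configs <- lapply(1:3, function(i) {
      (tri + matrix(rnorm(6, sd = 0.05), 3, 2)) %*%
        rotMat(runif(1, -pi, pi))
    })
    g <- partialGPA(configs)
    expect_equal(procrustesSS(g), oracleGPA3(configs), tolerance = 1e-6)
  }
})

test_that("tangent projection is idempotent and zeroes the consensus", {
  set.seed(41)
  sim <- simulateLanterns(toyParams(), toyScheme(), seed = 4)
  g <- partialGPA(sim$landmarks, scheme = toyScheme())
  # the consensus itself projects to the zero tangent vector
  gc <- g
  gc@aligned <- rbind(g@aligned,
                      matrix(as.vector(t(consensusShape(g))), 1))
  tc <- tangentProjection(gc)
  expect_lt(max(abs(tangentCoords(tc)[nrow(gc@aligned), ])), 1e-12)
  # idempotence
  t1 <- tangentProjection(g)
  t2 <- tangentProjection(t1)
  expect_equal(tangentCoords(t1), tangentCoords(t2), tolerance = 1e-14)
  # the set is its own reference: tangent column means vanish
  expect_lt(max(abs(colMeans(tangentCoords(t1)))), 1e-10)
})

test_that("tangent distances approximate Procrustes distances", {
  set.seed(51)
  p <- toyParams(sigmaIndividual = 0.003, sigmaRotFA = 0,
                 sigmaBilFA = 0, sigmaError = 0.001)
  sim <- simulateLanterns(p, toyScheme(), seed = 6)
  g <- tangentProjection(partialGPA(sim$landmarks, scheme = toyScheme()))
  Y <- tangentCoords(g)
  ls <- sim$landmarks
  idx <- cbind(c(1, 2, 5), c(7, 9, 12))
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]
    dt <- sqrt(sum((Y[i, ] - Y[j, ])^2))
    dp <- procrustesDistance(getConfig(ls, i), getConfig(ls, j))
    expect_lt(abs(dt - dp) / dp, 1e-4)
  }
})

test_that("two-configuration alignment agrees with an external oracle", {
  skip_if_not_installed("vegan")
  set.seed(61)
  a <- toyTemplate() + matrix(rnorm(10, sd = 0.03), 5, 2)
  b <- toyTemplate() + matrix(rnorm(10, sd = 0.03), 5, 2)
  pre <- function(m) {
    m <- sweep(m, 2, colMeans(m)); m / sqrt(sum(m^2))
  }
  v <- vegan::procrustes(pre(a), pre(b), scale = FALSE)
  expect_equal(procrustesDistance(a, b), sqrt(sum((v$X - v$Yrot)^2)),
               tolerance = 1e-8)
})
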