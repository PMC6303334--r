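test_that("reflectRelabel negates the axis, swaps pairs, and is an involution", {
  sch <- toyScheme()
  m <- matrix(c(0.1, -1,
                -0.6, -0.2,
                0.5, -0.3,
                -0.4, 0.8,
                0.45, 0.75), ncol = 2, byrow = TRUE)
  out <- reflectRelabel(m, sch)
  # hand-computed: x negated, rows 2<->3 and 4<->5 swapped
  expect_equal(out, matrix(c(-0.1, -1,
                             -0.5, -0.3,
                             0.6, -0.2,
                             -0.45, 0.75,
                             0.4, 0.8), ncol = 2, byrow = TRUE))
  expect_identical(reflectRelabel(out, sch), m)
  # an exactly symmetric configuration is a fixed point
  expect_equal(reflectRelabel(toyTemplate(), sch), toyTemplate())
  bad <- symmetryScheme("object", k = 5, pairs = rbind(c(2, 3), c(4, 5)),
                        unpaired = 1)
  expect_error(reflectRelabel(m[1:3, ], bad), "out-of-range")
})

test_that("object-symmetry expansion doubles the set and forces a symmetric consensus", {
  sch <- toyScheme()
  sim <- simulateLanterns(toyParams(nInd = 4, daBilNorm = 0.01),
                          sch, seed = 9)
  ex <- expandObjectSymmetry(sim$landmarks, sch)
  expect_equal(length(ex), 2L * length(sim$landmarks))
  expect_setequal(unique(sampleInfo(ex)$copy), c(1L, 2L))
  expect_error(expandObjectSymmetry(ex, sch), "already expanded")
  g <- partialGPA(ex, scheme = sch)
  cons <- consensusShape(g)
  expect_lt(max(abs(reflectRelabel(cons, sch) - cons)), 1e-10)
  # mirror-pair rows remain exact mirror images after alignment
  n <- length(sim$landmarks)
  M <- nestsym:::reflectionOperator(sch)
  expect_lt(max(abs(alignedCoords(g)[n + 1, ] -
                    as.vector(M %*% alignedCoords(g)[1, ]))), 1e-8)
})

test_that("symmetrize returns the consensus of original and reflected copy", {
  sch <- toyScheme()
  set.seed(71)
  m <- toyTemplate() + matrix(rnorm(10, sd = 0.05), 5, 2)
  s <- symmetrizeConfigs(m, sch)
  # exactly symmetric and idempotent
  expect_lt(max(abs(reflectRelabel(s, sch) - s)), 1e-12)
  expect_equal(symmetrizeConfigs(s, sch), s, tolerance = 1e-8)
  # symmetric input maps to itself (as a shape)
  expect_lt(procrustesDistance(symmetrizeConfigs(toyTemplate(), sch),
                               toyTemplate()), 1e-10)
  # oracle: explicit two-configuration superimposition (iterated
  # rotation to the running consensus, averaging), no symmetrization step;
  # its fixed point is the symmetric average as a shape
  pre <- function(x) {
    x <- sweep(x, 2, colMeans(x)); x / sqrt(sum(x^2))
  }
  alignTo <- function(x, c) {
    sv <- svd(crossprod(x, c))
    s <- det(sv$u %*% t(sv$v))
    x %*% (sv$u %*% diag(c(1, s)) %*% t(sv$v))
  }
  a0 <- pre(m); b0 <- pre(reflectRelabel(m, sch))
  cons <- a0
  for (i in 1:200) cons <- pre((alignTo(a0, cons) + alignTo(b0, cons)) / 2)
  expect_lt(procrustesDistance(cons, s), 1e-6)
})

test_that("subspace projectors are orthogonal complements with the declared dims", {
  for (case in list(list(lanternScheme(), pyramidTemplate(), 10L),
                    list(toyScheme(), toyTemplate(), 3L))) {
    sch <- case[[1]]; cons <- case[[2]]; dim_ <- case[[3]]
    pr <- subspaceProjectors(sch, cons)
    expect_identical(pr@dimSym, dim_)
    expect_identical(pr@dimAsym, dim_)
    Ps <- pr@symmetric; Pa <- pr@asymmetric
    expect_lt(max(abs(Ps %*% Ps - Ps)), 1e-12)
    expect_lt(max(abs(Pa %*% Pa - Pa)), 1e-12)
    expect_lt(max(abs(Ps - t(Ps))), 1e-12)
    expect_lt(max(abs(Ps %*% Pa)), 1e-12)
    expect_equal(sum(diag(Ps)), as.numeric(dim_), tolerance = 1e-10)
    # Pythagoras on random tangent vectors
    set.seed(81)
    for (i in 1:10) {
      v <- rnorm(ncol(Ps))
      v <- v - as.vector((diag(ncol(Ps)) - Ps - Pa) %*% v)  # tangent part
      expect_equal(sum((Ps %*% v)^2) + sum((Pa %*% v)^2), sum(v^2),
                   tolerance = 1e-12)
    }
  }
  expect_error(subspaceProjectors(toyScheme(),
                                  cbind(toyTemplate(), 0)),
               "unsupported dimension")
})
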