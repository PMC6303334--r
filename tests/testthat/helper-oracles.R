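# Independent brute-force oracles and shared fixtures, coded from the
# definitions (not from the package internals).

# centroid size by explicit summation
oracleCS <- function(m) {
  cx <- mean(m[, 1]); cy <- mean(m[, 2])
  sqrt(sum((m[, 1] - cx)^2 + (m[, 2] - cy)^2))
}

# two-way balanced decomposition SS by explicit averaging loops
oracleTwoWaySS <- function(Y, ind, prt) {
  g <- colMeans(Y)
  ssI <- ssP <- ssIP <- ssE <- 0
  for (r in seq_len(nrow(Y))) {
    mi <- colMeans(Y[ind == ind[r], , drop = FALSE])
    mp <- colMeans(Y[prt == prt[r], , drop = FALSE])
    mip <- colMeans(Y[ind == ind[r] & prt == prt[r], , drop = FALSE])
    ssI <- ssI + sum((mi - g)^2)
    ssP <- ssP + sum((mp - g)^2)
    ssIP <- ssIP + sum((mip - mi - mp + g)^2)
    ssE <- ssE + sum((Y[r, ] - mip)^2)
  }
  c(individual = ssI, part = ssP, interaction = ssIP, error = ssE)
}

# nested-design decomposition SS (expanded rows; one count per physical
# observation, i.e. halved)
oracleNestedSS <- function(Y, ind, prt, cp) {
  g <- colMeans(Y)
  ss <- c(individual = 0, part = 0, reflectionInPart = 0, indXpart = 0,
          indXreflection = 0, error = 0)
  for (r in seq_len(nrow(Y))) {
    mi <- colMeans(Y[ind == ind[r], , drop = FALSE])
    mp <- colMeans(Y[prt == prt[r], , drop = FALSE])
    mpk <- colMeans(Y[prt == prt[r] & cp == cp[r], , drop = FALSE])
    mip <- colMeans(Y[ind == ind[r] & prt == prt[r], , drop = FALSE])
    mipk <- colMeans(Y[ind == ind[r] & prt == prt[r] & cp == cp[r], ,
                       drop = FALSE])
    ss["individual"] <- ss["individual"] + sum((mi - g)^2)
    ss["part"] <- ss["part"] + sum((mp - g)^2)
    ss["reflectionInPart"] <- ss["reflectionInPart"] + sum((mpk - mp)^2)
    ss["indXpart"] <- ss["indXpart"] + sum((mip - mi - mp + g)^2)
    ss["indXreflection"] <- ss["indXreflection"] +
      sum((mipk - mip - mpk + mp)^2)
    ss["error"] <- ss["error"] + sum((Y[r, ] - mipk)^2)
  }
  ss / 2
}

# rotation-angle grid search for the 3-configuration GPA objective
oracleGPA3 <- function(configs) {
  pre <- lapply(configs, function(m) {
    m <- sweep(m, 2, colMeans(m))
    m / sqrt(sum(m^2))
  })
  rot <- function(m, th)
    m %*% matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  obj <- function(t2, t3) {
    Xs <- list(pre[[1]], rot(pre[[2]], t2), rot(pre[[3]], t3))
    mn <- (Xs[[1]] + Xs[[2]] + Xs[[3]]) / 3
    sum(vapply(Xs, function(x) sum((x - mn)^2), numeric(1)))
  }
  lo <- c(-pi, -pi); hi <- c(pi, pi)
  best <- c(0, 0)
  for (round in 1:6) {
    g2 <- seq(lo[1], hi[1], length.out = 41)
    g3 <- seq(lo[2], hi[2], length.out = 41)
    vals <- outer(g2, g3, Vectorize(obj))
    ix <- which(vals == min(vals), arr.ind = TRUE)[1, ]
    best <- c(g2[ix[1]], g3[ix[2]])
    span <- c(g2[2] - g2[1], g3[2] - g3[1])
    lo <- best - 2 * span; hi <- best + 2 * span
  }
  obj(best[1], best[2])
}

# shared small fixtures ------------------------------------------------------

toyScheme <- function()
  symmetryScheme("nested", k = 5, pairs = rbind(c(2, 3), c(4, 5)),
                 unpaired = 1, nParts = 3)

toyTemplate <- function() {
  m <- rbind(c(0, -1), c(-0.6, -0.2), c(0.6, -0.2),
             c(-0.4, 0.8), c(0.4, 0.8))
  m <- sweep(m, 2, colMeans(m))
  m / sqrt(sum(m^2))
}

toyParams <- function(nInd = 6, nParts = 3,
                      sigmaIndividual = 0.01, sigmaRotFA = 0.002,
                      sigmaBilFA = 0.002, sigmaError = 0.002,
                      daRotNorm = 0, daBilNorm = 0, ...) {
  varianceComponents(toyScheme(), toyTemplate(),
                     nIndividuals = nInd, nParts = nParts,
                     sigmaIndividual = sigmaIndividual,
                     sigmaRotFA = sigmaRotFA, sigmaBilFA = sigmaBilFA,
                     sigmaError = sigmaError,
                     daRotNorm = daRotNorm, daBilNorm = daBilNorm,
                     meanSize = 5, sizeSigmaIndividual = 0.3,
                     sizeSigmaFA = 0.02, sizeSigmaError = 0.02,
                     sizePartEffects = rep(0, nParts), ...)
}

rotMat <- function(th)
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
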