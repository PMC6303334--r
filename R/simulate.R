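#' A stylized symmetric 12-landmark pyramid template
#'
#' Bilaterally symmetric about the y axis (the interradial suture), with
#' the four unpaired landmarks {1, 4, 10, 12} on the axis and the four
#' mirror pairs {2,3}, {5,8}, {6,7}, {11,9} off it; centered, unit
#' centroid size. This mirrors the landmark layout of a sea-urchin
#' pyramid-plus-epiphyses configuration without requiring real data.
#'
#' @return a 12 x 2 matrix.
#' @export
pyramidTemplate <- function() {
  m <- rbind(
    c( 0.00, -1.00),   # 1  oral tip (on axis)
    c(-0.28, -0.55),   # 2  retractor tip, left
    c( 0.28, -0.55),   # 3  retractor tip, right
    c( 0.00,  0.35),   # 4  foramen magnum base (on axis)
    c(-0.62,  0.28),   # 5  pyramid-epiphysis junction, left
    c(-0.50,  0.60),   # 6  junction upper, left
    c( 0.50,  0.60),   # 7  junction upper, right
    c( 0.62,  0.28),   # 8  pyramid-epiphysis junction, right
    c( 0.85,  0.30),   # 9  epiphysis outer, right
    c( 0.00,  0.72),   # 10 suture upper (on axis)
    c(-0.85,  0.30),   # 11 epiphysis outer, left
    c( 0.00,  0.95))   # 12 suture top (on axis)
  m <- centerConfig(m)
  m / centroidSize(m)
}

# Deterministic default directional-asymmetry vectors in the proper
# tangent subspaces at the template.
.defaultDA <- function(scheme, consensus, rotNorm, bilNorm, nParts) {
  proj <- subspaceProjectors(scheme, consensus)
  q <- scheme@k * 2L
  unit <- function(v) v / sqrt(sum(v^2))
  lm1 <- scheme@unpaired[1L]          # an on-axis landmark
  pl <- scheme@pairs[1L, ]            # a mirror pair
  # two orthonormal symmetric-subspace directions
  u1 <- numeric(q); u1[(lm1 - 1L) * 2L + 2L] <- 1      # on-axis, +y
  u1 <- unit(as.vector(u1 %*% proj@symmetric))
  u2 <- numeric(q)                                      # widen the pair
  u2[(pl[1L] - 1L) * 2L + 1L] <- -1
  u2[(pl[2L] - 1L) * 2L + 1L] <- 1
  u2 <- as.vector(u2 %*% proj@symmetric)
  u2 <- unit(u2 - sum(u2 * u1) * u1)
  if (nParts >= 2L) {
    ang <- 2 * pi * seq_len(nParts) / nParts
    daRot <- rotNorm * (cos(ang) %o% u1 + sin(ang) %o% u2)
  } else daRot <- matrix(0, 1L, q)
  # one asymmetric-subspace direction (lateral shift of the on-axis point)
  w <- numeric(q); w[(lm1 - 1L) * 2L + 1L] <- 1
  w <- unit(as.vector(w %*% proj@asymmetric))
  daBil <- matrix(bilNorm * w, nrow = nParts, ncol = q, byrow = TRUE)
  list(rot = daRot, bil = daBil)
}

#' Ground-truth variance components for the simulator
#'
#' Defines the generative conditions of [simulateLanterns()]. The default
#' magnitudes emulate the lantern case study: tangent-space standard
#' deviations (per coordinate, shape units) for the among-individual
#' effect, rotational FA, bilateral FA and measurement error, fixed
#' rotational and bilateral directional-asymmetry vectors, a centroid-size
#' model in arbitrary length units (millimetre-scale pyramids), and the
#' 10 individuals x 5 parts x 2 replicates index structure.
#'
#' @param scheme the [SymmetryScheme-class] the components refer to.
#' @param consensus symmetric template shape (unit centroid size).
#' @param sigmaIndividual,sigmaRotFA,sigmaBilFA,sigmaError random-effect
#'   standard deviations.
#' @param daRotational nParts x (k*d) matrix of symmetric-subspace part
#'   displacements (rows summing to zero), or NULL for the deterministic
#'   default of norm \code{daRotNorm} per part.
#' @param daBilateral asymmetric-subspace displacement(s) ((k*d) vector or
#'   nParts x (k*d) matrix), or NULL for the default of norm
#'   \code{daBilNorm}.
#' @param daRotNorm,daBilNorm norms used for the default DA vectors.
#' @param meanSize,sizeSigmaIndividual,sizeSigmaFA,sizeSigmaError,sizePartEffects
#'   centroid-size model parameters.
#' @param nIndividuals,nParts,nReplicates index structure.
#' @return a [VarianceComponents-class].
#' @export
varianceComponents <- function(scheme = lanternScheme(),
                               consensus = pyramidTemplate(),
                               sigmaIndividual = 0.0111,
                               sigmaRotFA = 0.0019,
                               sigmaBilFA = 0.0027,
                               sigmaError = 0.0016,
                               daRotational = NULL, daBilateral = NULL,
                               daRotNorm = 0.00207, daBilNorm = 0.0103,
                               meanSize = 10,
                               sizeSigmaIndividual = 1.25,
                               sizeSigmaFA = 0.071,
                               sizeSigmaError = 0.039,
                               sizePartEffects = NULL,
                               nIndividuals = 10L, nParts = NULL,
                               nReplicates = 2L) {
  if (is.null(nParts)) nParts <- scheme@nParts
  q <- scheme@k * ncol(consensus)
  if (is.null(daRotational) || is.null(daBilateral)) {
    da <- .defaultDA(scheme, consensus, daRotNorm, daBilNorm, nParts)
    if (is.null(daRotational)) daRotational <- da$rot
    if (is.null(daBilateral)) daBilateral <- da$bil
  }
  if (is.null(dim(daBilateral)))
    daBilateral <- matrix(daBilateral, nrow = nParts, ncol = q,
                          byrow = TRUE)
  if (is.null(sizePartEffects)) {
    sizePartEffects <- 0.0194 * cos(2 * pi * seq_len(nParts) / nParts)
    sizePartEffects <- sizePartEffects - mean(sizePartEffects)
  }
  new("VarianceComponents", consensus = consensus,
      sigmaIndividual = sigmaIndividual, sigmaRotFA = sigmaRotFA,
      sigmaBilFA = sigmaBilFA, sigmaError = sigmaError,
      daRotational = daRotational, daBilateral = daBilateral,
      meanSize = meanSize, sizeSigmaIndividual = sizeSigmaIndividual,
      sizeSigmaFA = sizeSigmaFA, sizeSigmaError = sizeSigmaError,
      sizePartEffects = sizePartEffects,
      nIndividuals = as.integer(nIndividuals),
      nParts = as.integer(nParts), nReplicates = as.integer(nReplicates))
}

setMethod("show", "VarianceComponents", function(object) {
  cat("VarianceComponents:", object@nIndividuals, "individuals x",
      object@nParts, "parts x", object@nReplicates, "replicates\n")
  cat("  sigma (individual, rotFA, bilFA, error):",
      paste(format(c(object@sigmaIndividual, object@sigmaRotFA,
                     object@sigmaBilFA, object@sigmaError),
                   digits = 3), collapse = ", "), "\n")
  cat("  |DA| rotational:",
      format(sqrt(sum(object@daRotational[1L, ]^2)), digits = 3),
      "| bilateral:",
      format(sqrt(sum(object@daBilateral[1L, ]^2)), digits = 3), "\n")
})

#' Simulate a lantern-structured landmark dataset
#'
#' Generative model: each record (individual i, part j, replicate r)
#' receives a tangent-space deviation composed of the individual effect
#' (symmetric subspace), the fixed rotational DA of its part (symmetric),
#' the individual-by-part interaction (rotational FA, symmetric), the
#' fixed bilateral DA (asymmetric), the individual-by-part bilateral FA
#' (asymmetric) and per-replicate measurement error (both subspaces); all
#' random draws are isotropic Gaussians projected into their declared
#' subspace of the tangent space at the template. The deviated shape is
#' then scaled to a centroid size drawn from the additive size model and,
#' optionally, randomly rotated and translated (nuisance transformations
#' removed again by GPA). Reflection copies are not generated: they are
#' analysis bookkeeping, produced by [expandObjectSymmetry()].
#'
#' @param params a [VarianceComponents-class].
#' @param scheme the matching [SymmetryScheme-class].
#' @param seed RNG seed (all randomness flows from it).
#' @param nuisance apply random rotation/translation to each record.
#' @return list with \code{landmarks} (a [LandmarkSet-class]),
#'   \code{truth} (exact tangent-space effect draws and the parameters)
#'   and \code{scheme}.
#' @export
simulateLanterns <- function(params, scheme = lanternScheme(),
                             seed = NULL, nuisance = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  cons <- params@consensus
  k <- nrow(cons); d <- ncol(cons); q <- k * d
  proj <- subspaceProjectors(scheme, cons)
  Tproj <- proj@symmetric + proj@asymmetric
  chk <- function(M, P, what) {
    if (max(abs(M %*% P - M)) > 1e-8 * max(1, max(abs(M))))
      stop(what, " displacement vector lies outside its declared subspace")
  }
  chk(params@daRotational, proj@symmetric, "rotational DA")
  chk(params@daBilateral, proj@asymmetric, "bilateral DA")
  nI <- params@nIndividuals; nP <- params@nParts; nR <- params@nReplicates
  cvec <- vecConfig(cons)
  draw <- function(n, sd, P) {
    if (sd == 0) return(matrix(0, n, q))
    matrix(rnorm(n * q, sd = sd), n, q) %*% P
  }
  aI <- draw(nI, params@sigmaIndividual, proj@symmetric)
  abIP <- draw(nI * nP, params@sigmaRotFA, proj@symmetric)
  agIP <- draw(nI * nP, params@sigmaBilFA, proj@asymmetric)
  info <- expand.grid(replicate = seq_len(nR), part = seq_len(nP),
                      individual = seq_len(nI))
  info <- info[, c("individual", "part", "replicate")]
  n <- nrow(info)
  E <- draw(n, params@sigmaError, Tproj)
  ipIdx <- (info$individual - 1L) * nP + info$part
  V <- aI[info$individual, , drop = FALSE] +
    params@daRotational[info$part, , drop = FALSE] +
    abIP[ipIdx, , drop = FALSE] +
    params@daBilateral[info$part, , drop = FALSE] +
    agIP[ipIdx, , drop = FALSE] + E
  # additive centroid-size model
  sI <- rnorm(nI, sd = params@sizeSigmaIndividual)
  sIP <- rnorm(nI * nP, sd = params@sizeSigmaFA)
  sE <- rnorm(n, sd = params@sizeSigmaError)
  sizes <- params@meanSize + sI[info$individual] +
    params@sizePartEffects[info$part] + sIP[ipIdx] + sE
  if (any(sizes <= 0))
    stop("size model produced nonpositive centroid sizes; ",
         "reduce the size sigmas or increase meanSize")
  coords <- array(0, dim = c(k, d, n))
  for (i in seq_len(n)) {
    m <- unvecConfig(cvec + V[i, ], d)
    m <- m / centroidSize(m) * sizes[i]
    if (nuisance) {
      th <- runif(1L, -pi, pi)
      R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L)
      m <- m %*% R
      m <- sweep(m, 2L, runif(d, -0.5, 0.5) * params@meanSize, `+`)
    }
    coords[, , i] <- m
  }
  list(landmarks = landmarkSet(coords, info = info),
       truth = list(individual = aI, rotFA = abIP, bilFA = agIP,
                    error = E, tangent = V, sizes = sizes,
                    params = params),
       scheme = scheme)
}
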