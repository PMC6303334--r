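# Vectorization convention: rows are landmark-major, (x1, y1, x2, y2, ...).
vecConfig <- function(m) as.vector(t(m))

unvecConfig <- function(v, d = 2L) matrix(v, ncol = d, byrow = TRUE)

centerConfig <- function(m) sweep(m, 2L, colMeans(m))

# Center and scale to unit centroid size.
preshape <- function(m) {
  m <- centerConfig(m)
  m / centroidSize(m)
}

# Optimal rotation R in SO(d) minimizing ||X R - C||^2 (no reflection).
optimalRotation <- function(X, C) {
  M <- crossprod(X, C)
  sv <- svd(M)
  R <- sv$u %*% t(sv$v)
  if (det(R) < 0) {
    d <- ncol(M)
    R <- sv$u %*% diag(c(rep(1, d - 1L), -1)) %*% t(sv$v)
  }
  R
}

#' Partial generalized Procrustes analysis
#'
#' Iterative superimposition of a set of landmark configurations: each
#' configuration is centered, scaled to unit centroid size, and rotated
#' (rotation only, never reflection) to minimize its summed squared
#' distance to the iteratively re-estimated consensus. Partial GPA: no
#' further scaling towards the consensus beyond the unit-size constraint.
#' The consensus is re-normalized to unit centroid size at every
#' iteration; when \code{symmetrizeConsensus} is TRUE (the default
#' whenever \code{scheme} declares a reflection) it is also averaged with
#' its reflected-relabelled copy, so the consensus of an object-symmetry
#' expanded set is exactly symmetric and mirror-pair rows stay exact
#' mirror images.
#'
#' @param x a [LandmarkSet-class], a list of k x d matrices, or a
#'   k x d x N array.
#' @param scheme optional [SymmetryScheme-class] (enables consensus
#'   symmetrization).
#' @param tol convergence tolerance on the consensus displacement.
#' @param maxIter maximum number of iterations.
#' @param symmetrizeConsensus force/suppress consensus symmetrization;
#'   by default it is enabled when the scheme declares a pairing and the
#'   input is a reflection-expanded [LandmarkSet-class] (where the
#'   consensus is exactly symmetric by construction).
#' @return an [AlignedShapes-class] (tangent slot empty; see
#'   [tangentProjection()]).
#' @examples
#' tri <- matrix(c(0, 0, 1, 0, 0.5, 1), ncol = 2, byrow = TRUE)
#' g <- partialGPA(list(tri, tri + 5, tri * 2))
#' procrustesSS(g)  # 0: same shape
#' @export
partialGPA <- function(x, scheme = NULL, tol = 1e-10, maxIter = 100L,
                       symmetrizeConsensus = NULL) {
  if (is.null(symmetrizeConsensus))
    symmetrizeConsensus <- !is.null(scheme) &&
      nrow(scheme@pairs) > 0L && is(x, "LandmarkSet") &&
      !is.null(x@info$copy) && length(unique(x@info$copy)) == 2L
  if (is(x, "LandmarkSet")) {
    info <- x@info
    configs <- lapply(seq_len(length(x)), function(i) getConfig(x, i))
  } else if (is.array(x) && length(dim(x)) == 3L) {
    info <- data.frame(individual = seq_len(dim(x)[3L]))
    configs <- lapply(seq_len(dim(x)[3L]), function(i) x[, , i])
  } else {
    info <- data.frame(individual = seq_along(x))
    configs <- x
  }
  n <- length(configs)
  if (n < 2L) stop("need at least 2 configurations")
  k <- nrow(configs[[1L]]); d <- ncol(configs[[1L]])
  if (!all(vapply(configs, function(m) nrow(m) == k && ncol(m) == d,
                  logical(1L))))
    stop("non-conformant configuration dimensions")
  css <- vapply(configs, centroidSize, numeric(1L))
  X <- lapply(configs, preshape)

  symmetrize <- function(m) {
    if (!symmetrizeConsensus) return(m)
    (m + reflectRelabel(m, scheme)) / 2
  }
  cons <- symmetrize(X[[1L]])
  cons <- cons / centroidSize(cons)
  obj <- Inf
  converged <- FALSE
  for (iter in seq_len(maxIter)) {
    X <- lapply(X, function(m) m %*% optimalRotation(m, cons))
    mean_raw <- Reduce(`+`, X) / n
    newObj <- sum(vapply(X, function(m) sum((m - mean_raw)^2), numeric(1L)))
    if (newObj > obj + 1e-9 * max(1, obj))
      warning("GPA objective increased at iteration ", iter)
    obj <- newObj
    newCons <- symmetrize(centerConfig(mean_raw))
    newCons <- newCons / centroidSize(newCons)
    delta <- sqrt(sum((newCons - cons)^2))
    cons <- newCons
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    stop("GPA did not converge after ", maxIter,
         " iterations (last consensus displacement ",
         format(delta, digits = 3), ")")
  aligned <- t(vapply(X, vecConfig, numeric(k * d)))
  mean_row <- colMeans(aligned)
  pss <- sum(sweep(aligned, 2L, mean_row)^2)
  new("AlignedShapes", aligned = aligned,
      tangent = matrix(numeric(), 0L, 0L), consensus = cons,
      procrustesSS = pss, centroidSizes = css, info = info,
      scheme = scheme, iterations = iter)
}

#' Orthogonal projection onto the tangent space
#'
#' Projects each aligned pre-shape orthogonally onto the tangent plane to
#' the pre-shape sphere at the consensus. With consensus c (unit centroid
#' size) and aligned row x, the tangent row is x - (x . c) c, so the
#' consensus itself maps to the zero vector and the projection is
#' idempotent. All ANOVA designs operate on these coordinates.
#'
#' @param aligned an [AlignedShapes-class] from [partialGPA()].
#' @return the same object with the \code{tangent} slot filled.
#' @export
tangentProjection <- function(aligned) {
  if (!is(aligned, "AlignedShapes") || nrow(aligned@consensus) == 0L)
    stop("tangentProjection needs an aligned set with a consensus")
  cvec <- vecConfig(aligned@consensus)
  X <- if (nrow(aligned@tangent)) aligned@tangent else aligned@aligned
  scores <- X %*% cvec
  aligned@tangent <- X - tcrossprod(as.vector(scores), cvec)
  aligned
}

#' Partial Procrustes distance between two configurations
#'
#' Distance between the unit-size pre-shapes after the optimal rotation
#' (no reflection, no extra scaling): \code{sqrt(2 - 2 * cos(rho))} where
#' rho is the Procrustes angle.
#'
#' @param a,b k x d coordinate matrices.
#' @return a nonnegative scalar.
#' @export
procrustesDistance <- function(a, b) {
  pa <- preshape(a); pb <- preshape(b)
  R <- optimalRotation(pa, pb)
  sqrt(sum((pa %*% R - pb)^2))
}

#' @rdname accessors
#' @export
setMethod("alignedCoords", "AlignedShapes", function(x) x@aligned)
#' @rdname accessors
#' @export
setMethod("tangentCoords", "AlignedShapes", function(x) {
  if (!nrow(x@tangent)) stop("tangent coordinates not computed yet; ",
                             "apply tangentProjection() first")
  x@tangent
})
#' @rdname accessors
#' @export
setMethod("consensusShape", "AlignedShapes", function(x) x@consensus)
#' @rdname accessors
#' @export
setMethod("procrustesSS", "AlignedShapes", function(x) x@procrustesSS)
#' @rdname accessors
#' @export
setMethod("centroidSizes", "AlignedShapes", function(x) x@centroidSizes)
#' @rdname accessors
#' @export
setMethod("sampleInfo", "AlignedShapes", function(x) x@info)

setMethod("show", "AlignedShapes", function(object) {
  cat("AlignedShapes:", nrow(object@aligned), "configurations,",
      nrow(object@consensus), "landmarks in", ncol(object@consensus), "D\n")
  cat("  Procrustes SS:", format(object@procrustesSS, digits = 6),
      "| iterations:", object@iterations,
      "| tangent:", if (nrow(object@tangent)) "yes" else "no", "\n")
})
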