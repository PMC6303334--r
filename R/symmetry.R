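#' Reflect and relabel a configuration
#'
#' Applies the bilateral symmetry transformation of the scheme: one
#' coordinate axis is negated (the first, by convention; any axis works
#' after superimposition, fixing one makes runs reproducible) and the
#' labels of landmarks that are images of each other are mutually swapped;
#' on-axis (unpaired) landmarks keep their row. Applying the operation
#' twice returns the input exactly.
#'
#' @param config a k x d coordinate matrix.
#' @param scheme a [SymmetryScheme-class] with a bilateral pairing.
#' @param axis which coordinate axis to negate (default 1, the x axis).
#' @return the transformed k x d matrix.
#' @export
reflectRelabel <- function(config, scheme, axis = 1L) {
  if (nrow(scheme@pairs) == 0L)
    stop("scheme has no bilateral pairing")
  if (max(scheme@pairs) > nrow(config))
    stop("pairing references out-of-range landmarks")
  out <- config
  out[, axis] <- -out[, axis]
  perm <- seq_len(nrow(config))
  perm[scheme@pairs[, 1L]] <- scheme@pairs[, 2L]
  perm[scheme@pairs[, 2L]] <- scheme@pairs[, 1L]
  out[perm, , drop = FALSE]
}

# (k*d) x (k*d) matrix representation of reflectRelabel on vectorized rows.
reflectionOperator <- function(scheme, d = 2L, axis = 1L) {
  k <- scheme@k
  perm <- seq_len(k)
  perm[scheme@pairs[, 1L]] <- scheme@pairs[, 2L]
  perm[scheme@pairs[, 2L]] <- scheme@pairs[, 1L]
  M <- matrix(0, k * d, k * d)
  sgn <- rep(1, d); sgn[axis] <- -1
  for (i in seq_len(k))
    for (j in seq_len(d))
      M[(perm[i] - 1L) * d + j, (i - 1L) * d + j] <- sgn[j]
  M
}

#' Expand a dataset for object-symmetry analysis
#'
#' Generates, for every configuration, its reflected and relabelled copy,
#' doubling the dataset. Each record gains a \code{copy} index (1 =
#' original, 2 = reflected). A subsequent [partialGPA()] on the expanded
#' set yields a consensus that is exactly symmetric under the declared
#' reflection.
#'
#' @param x a [LandmarkSet-class] (not yet expanded).
#' @param scheme a [SymmetryScheme-class] with a bilateral pairing.
#' @return the expanded [LandmarkSet-class].
#' @export
expandObjectSymmetry <- function(x, scheme) {
  info <- x@info
  if (!is.null(info$copy) && length(unique(info$copy)) > 1L)
    stop("dataset already expanded with reflection copies")
  n <- length(x)
  k <- dim(x@coords)[1L]; d <- dim(x@coords)[2L]
  coords <- array(0, dim = c(k, d, 2L * n))
  coords[, , seq_len(n)] <- x@coords
  for (i in seq_len(n))
    coords[, , n + i] <- reflectRelabel(getConfig(x, i), scheme)
  info$copy <- 1L
  info2 <- info
  info2$copy <- 2L
  new("LandmarkSet", coords = coords, labels = x@labels,
      info = rbind(info, info2))
}

#' Symmetrize configurations under the bilateral reflection
#'
#' Replaces each configuration by the Procrustes consensus of itself and
#' its reflected-relabelled copy (a two-configuration partial GPA with
#' consensus symmetrization), i.e. its symmetric average. The output is
#' exactly symmetric under the scheme and the operation is idempotent.
#' This is the pre-step of the rotational matching-symmetry analysis,
#' which treats each part as perfectly bilaterally symmetric.
#'
#' @param x a [LandmarkSet-class] or a single k x d matrix.
#' @param scheme a [SymmetryScheme-class] with a bilateral pairing.
#' @param tol,maxIter GPA controls.
#' @return an object of the same class as \code{x}; configurations are
#'   centered at the origin with unit centroid size.
#' @export
symmetrizeConfigs <- function(x, scheme, tol = 1e-10, maxIter = 100L) {
  symOne <- function(m) {
    g <- partialGPA(list(m, reflectRelabel(m, scheme)), scheme = scheme,
                    tol = tol, maxIter = maxIter,
                    symmetrizeConsensus = TRUE)
    g@consensus
  }
  if (is.matrix(x)) return(symOne(x))
  k <- dim(x@coords)[1L]; d <- dim(x@coords)[2L]
  coords <- array(0, dim = dim(x@coords))
  for (i in seq_len(length(x))) coords[, , i] <- symOne(getConfig(x, i))
  new("LandmarkSet", coords = coords, labels = x@labels, info = x@info)
}

#' Symmetric and asymmetric subspace projectors
#'
#' Builds the averaging and differencing projectors over {identity,
#' reflect-and-relabel} on the shape tangent space at a symmetric
#' consensus. The four similarity dimensions (two translations, rotation,
#' scale) are removed first; since the consensus is symmetric they split
#' two-and-two between the raw symmetric and antisymmetric coordinate
#' subspaces, giving dimensions 2p + u - 2 for both the symmetric and the
#' asymmetric shape subspace (d = 2, p pairs, u on-axis landmarks). The
#' closed-form dimensions are asserted against the numerical projector
#' ranks, guarding against scheme/consensus mismatches.
#'
#' @param scheme a [SymmetryScheme-class] with a bilateral pairing.
#' @param consensus a symmetric k x d consensus (unit centroid size),
#'   e.g. from a GPA of an object-symmetry expanded set.
#' @return a [SubspaceProjectors-class].
#' @export
subspaceProjectors <- function(scheme, consensus) {
  d <- ncol(consensus)
  if (d != 2L)
    stop("unsupported dimension: subspace dimension accounting is ",
         "implemented for d = 2 (3D dimensions differ)")
  k <- scheme@k
  if (nrow(consensus) != k) stop("consensus does not match the scheme")
  cons <- centerConfig(consensus)
  cons <- cons / centroidSize(cons)
  M <- reflectionOperator(scheme, d)
  cvec <- vecConfig(cons)
  if (max(abs(M %*% cvec - cvec)) > 1e-8)
    stop("consensus is not symmetric under the declared reflection")
  # nuisance (similarity) directions at the consensus
  k1 <- vecConfig(cbind(rep(1, k), rep(0, k)))  # translation x
  k2 <- vecConfig(cbind(rep(0, k), rep(1, k)))  # translation y
  rot <- vecConfig(cbind(-cons[, 2L], cons[, 1L]))  # infinitesimal rotation
  Q <- qr.Q(qr(cbind(k1, k2, cvec, rot)))
  Tproj <- diag(k * d) - tcrossprod(Q)
  Psym <- Tproj %*% ((diag(k * d) + M) / 2) %*% Tproj
  Pasym <- Tproj %*% ((diag(k * d) - M) / 2) %*% Tproj
  p <- nrow(scheme@pairs); u <- length(scheme@unpaired)
  dimSym <- 2L * p + u - 2L
  dimAsym <- 2L * p + u - 2L
  rkSym <- round(sum(diag(Psym)))
  rkAsym <- round(sum(diag(Pasym)))
  if (rkSym != dimSym || rkAsym != dimAsym)
    stop("numerical projector ranks (", rkSym, ", ", rkAsym,
         ") disagree with the closed-form dimensions (", dimSym, ", ",
         dimAsym, ")")
  new("SubspaceProjectors", symmetric = Psym, asymmetric = Pasym,
      dimSym = dimSym, dimAsym = dimAsym, consensus = cons)
}

setMethod("show", "SubspaceProjectors", function(object) {
  cat("SubspaceProjectors: dim(symmetric) =", object@dimSym,
      ", dim(asymmetric) =", object@dimAsym, "\n")
})
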