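#' Goodall's F test
#'
#' Ratio of Procrustes mean squares; degrees of freedom are the shape
#' degrees of freedom (conventional df multiplied by the dimension of the
#' tangent subspace the effect lives in), assuming isotropic variation.
#'
#' @param ssNum,ssDen numerator/denominator sums of squares.
#' @param dfNum,dfDen the corresponding (shape) degrees of freedom.
#' @return list with elements \code{F} and \code{p} (upper-tail
#'   parametric P from the F distribution).
#' @examples
#' goodallF(2, 10, 1, 5)  # equal mean squares: F = 1
#' @export
goodallF <- function(ssNum, dfNum, ssDen, dfDen) {
  if (dfNum <= 0 || dfDen <= 0) stop("degrees of freedom must be positive")
  if (ssNum < 0 || ssDen < 0) stop("sums of squares must be nonnegative")
  if (ssDen == 0) {
    warning("zero denominator sum of squares; P reported as NA")
    return(list(F = NA_real_, p = NA_real_))
  }
  Fval <- (ssNum / dfNum) / (ssDen / dfDen)
  list(F = Fval, p = pf(Fval, dfNum, dfDen, lower.tail = FALSE))
}

#' Pillai's trace with a generalized inverse
#'
#' Multivariate test statistic \code{trace(H \%*\% ginv(H + E))}. The
#' generalized inverse of the total SSCP matrix is used because shape
#' (sub)spaces are rank-deficient in the full coordinate basis. Singular
#' values below \code{dim * eps * max(singular value)} are treated as zero.
#'
#' @param H effect sum-of-squares-and-cross-products matrix.
#' @param E error (denominator) SSCP matrix from the same tangent subspace.
#' @return the Pillai trace statistic (scalar).
#' @export
pillaiTrace <- function(H, E) {
  if (!all(dim(H) == dim(E))) stop("H and E must be conformant square matrices")
  Tm <- H + E
  if (max(abs(Tm)) == 0) {
    warning("all-zero SSCP matrices; Pillai trace is NA")
    return(NA_real_)
  }
  sum(diag(H %*% MASS::ginv(Tm)))
}

# Numerical rank via singular values (standard tolerance).
.numRank <- function(M) {
  s <- svd(M, nu = 0L, nv = 0L)$d
  sum(s > max(dim(M)) * .Machine$double.eps * max(s))
}

#' Parametric P for Pillai's trace
#'
#' Standard F approximation of Pillai's trace with the dimensionality
#' taken as the numerical rank of the total SSCP matrix and conventional
#' numerator/denominator degrees of freedom.
#'
#' @param V Pillai trace statistic.
#' @param p dimensionality (numerical rank of H + E).
#' @param dfH,dfE conventional df of the effect and its denominator.
#' @return upper-tail P value (NA when the approximation is undefined).
#' @export
pillaiParamP <- function(V, p, dfH, dfE) {
  if (is.na(V)) return(NA_real_)
  s <- min(p, dfH)
  m <- (abs(p - dfH) - 1) / 2
  n <- (dfE - p - 1) / 2
  df1 <- s * (2 * m + s + 1)
  df2 <- s * (2 * n + s + 1)
  if (df2 <= 0 || V >= s) return(NA_real_)
  Fapprox <- (V / (s - V)) * ((2 * n + s + 1) / (2 * m + s + 1))
  pf(Fapprox, df1, df2, lower.tail = FALSE)
}

# --- permutation machinery -------------------------------------------------

# All permutations of 1..n as rows of a matrix (n small).
.allPerms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .allPerms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- setdiff(seq_len(n), i)
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

# Permutation P value with the add-one convention. `drawStat()` returns one
# permuted statistic vector per call; if `allStats` (matrix, one row per
# distinct permutation, identity included) is supplied the P is exact.
.permPvalue <- function(obs, drawStat, nPerm, allStats = NULL) {
  eps <- 1e-12 * pmax(1, abs(obs))
  if (!is.null(allStats)) {
    p <- colMeans(sweep(allStats, 2L, obs - eps, `>=`))
  } else {
    cnt <- numeric(length(obs))
    for (b in seq_len(nPerm)) {
      st <- drawStat()
      cnt <- cnt + as.numeric(st >= obs - eps)
    }
    p <- (1 + cnt) / (1 + nPerm)
  }
  names(p) <- names(obs)
  p
}

# Count of distinct restricted permutations: label permutations of g groups
# within each of s strata.
.strataPermCount <- function(g, s) factorial(g)^s

# Enumerate all within-strata label permutations when feasible: returns a
# list of integer matrices [perm index per stratum], or NULL.
.enumStrataPerms <- function(g, s, limit) {
  total <- .strataPermCount(g, s)
  if (!is.finite(total) || total > limit) return(NULL)
  perms <- .allPerms(g)
  np <- nrow(perms)
  idx <- rep(1L, s)
  out <- vector("list", total)
  for (t in seq_len(total)) {
    out[[t]] <- idx
    for (j in seq_len(s)) {
      idx[j] <- idx[j] + 1L
      if (idx[j] <= np) break
      idx[j] <- 1L
    }
  }
  attr(out, "perms") <- perms
  out
}
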