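# --- balanced-design effect decomposition ---------------------------------

.key <- function(...) do.call(paste, c(list(...), sep = "\r"))

# Per-row group means: rows of Y averaged within levels of `key`, expanded
# back to one row per observation.
.meanRows <- function(Y, key) {
  f <- factor(key)
  M <- rowsum(Y, f, reorder = TRUE)
  (M / tabulate(f))[as.integer(f), , drop = FALSE]
}

.grandRows <- function(Y) {
  matrix(colMeans(Y), nrow(Y), ncol(Y), byrow = TRUE)
}

# The designs assume complete balanced index grids.
.checkBalanced <- function(..., what = "dataset") {
  tab <- table(...)
  if (any(tab == 0L) || length(unique(as.vector(tab))) != 1L)
    stop("unsupported design: the ", what,
         " index grid is incomplete or unbalanced")
  invisible(as.vector(tab)[1L])
}

#' Effect decomposition for the balanced symmetry designs
#'
#' Decomposes tangent-coordinate rows into the marginal-mean effect
#' components of one of the three designs. Components are the standard
#' balanced-design means and deviations (grand mean, factor means, cell
#' interactions, within-cell replicate deviations as error) and are
#' mutually orthogonal; each SS is the squared norm of the component rows
#' summed over all records. For the object-symmetry designs (\code{"A2"},
#' \code{"A3"}) the rows include the reflected copies and every SS is
#' divided by the group order (2) so that each physical observation counts
#' once.
#'
#' @param Y numeric N x q matrix of tangent rows.
#' @param info data.frame with columns \code{individual}, \code{part},
#'   \code{replicate} and (for A2/A3) \code{copy}.
#' @param design \code{"A1"} (two-way individual x part), \code{"A2"}
#'   (two-way part x reflection after mean correction), \code{"A3"}
#'   (individual crossed with part, reflection nested in part).
#' @param correction for \code{"A2"}: \code{"full"} removes per-individual
#'   cell means in both subspaces (the default; measurement error is then
#'   the pure replicate variation), \code{"symmetric"} removes only the
#'   symmetric-component means, \code{"none"} disables the correction.
#' @param check validate grid completeness/balance (skipped internally on
#'   permuted data, where balance is preserved by construction).
#' @return list with elements \code{components} (named list of N x q
#'   matrices), \code{ss} (named numeric), \code{convDf} (named numeric)
#'   and \code{divisor} (1 or 2).
#' @export
decomposeEffects <- function(Y, info, design = c("A1", "A2", "A3"),
                             correction = c("full", "symmetric", "none"),
                             check = TRUE) {
  design <- match.arg(design)
  correction <- match.arg(correction)
  ind <- info$individual; prt <- info$part; rep_ <- info$replicate
  g <- .grandRows(Y)
  if (design == "A1") {
    if (check) .checkBalanced(ind, prt, rep_)
    nI <- length(unique(ind)); nP <- length(unique(prt))
    nR <- length(unique(rep_))
    mI <- .meanRows(Y, ind); mP <- .meanRows(Y, prt)
    mIP <- .meanRows(Y, .key(ind, prt))
    comp <- list(individual = mI - g, part = mP - g,
                 interaction = mIP - mI - mP + g, error = Y - mIP)
    convDf <- c(individual = nI - 1, part = nP - 1,
                interaction = (nI - 1) * (nP - 1),
                error = nI * nP * (nR - 1))
    div <- 1
  } else {
    cp <- info$copy
    if (is.null(cp) || length(unique(cp)) != 2L)
      stop("object-symmetry designs need reflection-expanded data ",
           "(run expandObjectSymmetry() first)")
    if (check) .checkBalanced(ind, prt, cp, rep_)
    nI <- length(unique(ind)); nP <- length(unique(prt))
    nR <- length(unique(rep_))
    div <- 2
    if (design == "A2") {
      mIPK <- .meanRows(Y, .key(ind, prt, cp))
      mPK0 <- .meanRows(Y, .key(prt, cp))
      Yc <- switch(correction,
        full = Y - mIPK + mPK0,
        symmetric = Y - .meanRows(Y, .key(ind, prt)) + .meanRows(Y, prt),
        none = Y)
      gc <- .grandRows(Yc)
      mP <- .meanRows(Yc, prt); mK <- .meanRows(Yc, cp)
      mPK <- .meanRows(Yc, .key(prt, cp))
      comp <- list(part = mP - gc, reflection = mK - gc,
                   interaction = mPK - mP - mK + gc, error = Yc - mPK)
      errDf <- switch(correction,
        full = nP * (nI - 1) * (nR - 1),
        symmetric = nP * (nI - 1) * nR,
        none = nP * (nI * nR - 1))
      convDf <- c(part = nP - 1, reflection = 1,
                  interaction = nP - 1, error = errDf)
    } else {
      mI <- .meanRows(Y, ind); mP <- .meanRows(Y, prt)
      mPK <- .meanRows(Y, .key(prt, cp))
      mIP <- .meanRows(Y, .key(ind, prt))
      mIPK <- .meanRows(Y, .key(ind, prt, cp))
      comp <- list(
        individual = mI - g,
        part = mP - g,
        reflectionInPart = mPK - mP,
        indXpart = mIP - mI - mP + g,
        indXreflection = mIPK - mIP - mPK + mP,
        error = Y - mIPK)
      convDf <- c(individual = nI - 1, part = nP - 1,
                  reflectionInPart = nP,
                  indXpart = (nI - 1) * (nP - 1),
                  indXreflection = (nI - 1) * nP,
                  error = nP * (nI - 1) * (nR - 1))
    }
  }
  ss <- vapply(comp, function(m) sum(m^2), numeric(1L)) / div
  list(components = comp, ss = ss, convDf = convDf, divisor = div)
}

# Split a component's SS into symmetric/asymmetric parts.
.splitSS <- function(comp, proj, div) {
  c(sym = sum((comp %*% proj@symmetric)^2) / div,
    asym = sum((comp %*% proj@asymmetric)^2) / div)
}
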