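# Records per level combination of each effect (the EMS divisor), per
# physical observation.
.emsDivisors <- function(fit) {
  fi <- fit@fitInfo
  nI <- fi$nInd; nP <- fi$nPart; nR <- fi$nRep
  switch(fit@design,
    A1 = ,
    size = c(individual = nP * nR, part = nI * nR, interaction = nR),
    A2 = c(part = nI * nR, reflection = nI * nP * nR,
           interaction = nI * nR),
    A3 = c(individual = nP * nR, part = nI * nR,
           reflectionInPart = nI * nR, indXpart = nR,
           indXreflection = nR))
}

#' Per-effect covariance matrices from expected mean squares
#'
#' Recovers the covariance matrix attached to each ANOVA effect by
#' subtracting the effect SSCP matrices, divided by their degrees of
#' freedom, following the expected mean squares implied by the design
#' (\code{mode = "ems"}), or returns the raw mean-square matrices
#' (\code{mode = "ms"}). The error (measurement) covariance is always the
#' error SSCP divided by the replicate-contrast degrees of freedom.
#' EMS subtraction can produce indefinite matrices on real data; they are
#' reported as-is with a warning unless \code{clip = TRUE} truncates
#' negative eigenvalues at zero.
#'
#' @param fit an [EffectTable-class] from one of the shape designs.
#' @param mode \code{"ems"} (default) or \code{"ms"}.
#' @param clip truncate negative eigenvalues at zero.
#' @return named list of [EffectCovariance-class] objects (tested effects
#'   plus \code{"error"}).
#' @export
effectCovariances <- function(fit, mode = c("ems", "ms"), clip = FALSE) {
  mode <- match.arg(mode)
  if (fit@design == "size")
    stop("effectCovariances() is for the shape designs; ",
         "size variance components are scalars (see ",
         "estimateVarianceComponents())")
  fi <- fit@fitInfo
  tab <- fit@table
  divisors <- .emsDivisors(fit)
  dfContrast <- fi$errDfContrast
  msMatrix <- function(eff) {
    if (eff %in% c("error", "symmetricError", "asymmetricError"))
      fit@sscp[[if (eff == "error") "error" else eff]] / dfContrast
    else fit@sscp[[eff]] / tab$convDf[match(eff, tab$effect)]
  }
  # EMS partner of each effect: equals the F denominator except for the
  # rotational-FA term of the nested design, whose expected mean square
  # exceeds the *symmetric* error component by nRep times its variance.
  partner <- fit@denominators
  if (fit@design == "A3") partner["indXpart"] <- "symmetricError"
  out <- list()
  for (eff in names(divisors)) {
    if (!eff %in% names(fit@sscp)) next
    C <- if (mode == "ms") msMatrix(eff)
    else (msMatrix(eff) - msMatrix(partner[[eff]])) / divisors[[eff]]
    ev <- eigen((C + t(C)) / 2, symmetric = TRUE, only.values = TRUE)$values
    indef <- min(ev) < -1e-8 * max(abs(ev), .Machine$double.eps)
    if (indef && mode == "ems" && !clip)
      warning("EMS-subtracted covariance for effect '", eff,
              "' is indefinite (retained as-is)")
    if (clip) {
      ed <- eigen((C + t(C)) / 2, symmetric = TRUE)
      C <- ed$vectors %*% diag(pmax(ed$values, 0)) %*% t(ed$vectors)
    }
    out[[eff]] <- new("EffectCovariance", effect = eff, covariance = C,
                      consensus = fit@consensus, mode = mode,
                      indefinite = indef && !clip)
  }
  errSscp <- if ("error" %in% names(fit@sscp)) fit@sscp$error
  else fit@sscp$symmetricError + fit@sscp$asymmetricError
  out$error <- new("EffectCovariance", effect = "error",
                   covariance = errSscp / dfContrast,
                   consensus = fit@consensus, mode = mode,
                   indefinite = FALSE)
  out
}

setMethod("show", "EffectCovariance", function(object) {
  cat("EffectCovariance '", object@effect, "' (", object@mode, "), ",
      nrow(object@covariance), " x ", ncol(object@covariance),
      if (object@indefinite) ", indefinite" else "", "\n", sep = "")
})

#' Variance-component estimates from expected mean squares
#'
#' Method-of-moments estimates of the isotropic tangent-space variance
#' components of the design, from the traces of the EMS-recovered
#' covariance matrices divided by the dimension of the subspace each
#' effect occupies. Negative trace estimates (possible by sampling noise)
#' are truncated at zero before the square root. For a centroid-size fit
#' the univariate components are returned.
#'
#' @param fit an [EffectTable-class].
#' @return named numeric vector of standard deviations (shape designs:
#'   some of \code{sigmaIndividual}, \code{sigmaRotFA}, \code{sigmaBilFA},
#'   \code{sigmaError}; size design: \code{sizeSigmaIndividual},
#'   \code{sizeSigmaFA}, \code{sizeSigmaError}).
#' @export
estimateVarianceComponents <- function(fit) {
  fi <- fit@fitInfo
  tab <- fit@table
  if (fit@design == "size") {
    msOf <- function(e) tab$ss[match(e, tab$effect)] /
      tab$convDf[match(e, tab$effect)]
    msE <- tab$ss[match("error", tab$effect)] / fi$errDfContrast
    return(c(
      sizeSigmaIndividual =
        sqrt(max(0, (msOf("individual") - msOf("interaction")) /
                   (fi$nPart * fi$nRep))),
      sizeSigmaFA = sqrt(max(0, (msOf("interaction") - msE) / fi$nRep)),
      sizeSigmaError = sqrt(max(0, msE))))
  }
  covs <- suppressWarnings(effectCovariances(fit, mode = "ems"))
  proj <- fit@projectors
  dims <- c(symmetric = proj@dimSym, asymmetric = proj@dimAsym,
            full = proj@dimSym + proj@dimAsym)
  sigOf <- function(eff, sub)
    sqrt(max(0, sum(diag(covs[[eff]]@covariance)) / dims[[sub]]))
  out <- c()
  if (fit@design %in% c("A1", "A3"))
    out["sigmaIndividual"] <- sigOf("individual", "symmetric")
  if (fit@design == "A1") {
    out["sigmaRotFA"] <- sigOf("interaction", "symmetric")
    out["sigmaError"] <- sigOf("error", "symmetric")
  }
  if (fit@design == "A3") {
    out["sigmaRotFA"] <- sigOf("indXpart", "symmetric")
    out["sigmaBilFA"] <- sigOf("indXreflection", "asymmetric")
    out["sigmaError"] <- sigOf("error", "full")
  }
  if (fit@design == "A2")
    out["sigmaError"] <- sigOf("error", "full")
  out
}

#' Directional-asymmetry effect vectors
#'
#' Extracts the estimated fixed directional-asymmetry displacement(s) from
#' a fitted object-symmetry design: the difference between the averages of
#' original and reflected configurations, per part for the nested design.
#' Rows are tangent vectors for the original (copy 1) orientation.
#'
#' @param fit an [EffectTable-class] of design \code{"A2"} or \code{"A3"}.
#' @return list with \code{perPart} (nParts x (k*d) matrix for A3, the
#'   pooled reflection vector for A2), \code{mean} (average DA vector) and
#'   \code{consensus}.
#' @export
directionalAsymmetry <- function(fit) {
  if (!fit@design %in% c("A2", "A3"))
    stop("directional asymmetry vectors require an object-symmetry fit")
  info <- fit@fitInfo$info
  comp <- fit@components[[if (fit@design == "A2") "reflection"
                          else "reflectionInPart"]]
  sel <- info$copy == 1L
  key <- as.character(info$part[sel])
  M <- rowsum(comp[sel, , drop = FALSE], key, reorder = TRUE)
  M <- M / as.vector(table(key)[rownames(M)])
  if (fit@design == "A2") M <- matrix(colMeans(M), 1L)
  list(perPart = M, mean = colMeans(M), consensus = fit@consensus)
}

#' PCA of an effect covariance matrix
#'
#' Eigendecomposition of a per-effect covariance matrix, with each
#' principal component reshaped into per-landmark displacement vectors
#' anchored at the consensus, scaled by the square root of its eigenvalue
#' and an amplification factor (the usual input of lollipop graphs).
#'
#' @param cov an [EffectCovariance-class] (or a symmetric matrix plus
#'   \code{consensus}).
#' @param nPC number of components to export.
#' @param amplification display multiplier for the displacements.
#' @param consensus k x d anchor (taken from \code{cov} when available).
#' @return list with \code{values} (all eigenvalues, nonincreasing),
#'   \code{vectors} (orthonormal columns) and \code{displacements}
#'   (data.frame: pc, landmark, cx, cy, dx, dy; attribute
#'   \code{amplification}).
#' @export
pcaEffect <- function(cov, nPC = 2L, amplification = 1,
                      consensus = NULL) {
  if (is(cov, "EffectCovariance")) {
    consensus <- cov@consensus
    M <- cov@covariance
  } else M <- cov
  if (max(abs(M - t(M))) > 1e-8 * max(abs(M), .Machine$double.eps))
    stop("effect covariance must be symmetric")
  ed <- eigen((M + t(M)) / 2, symmetric = TRUE)
  nPC <- min(nPC, ncol(ed$vectors))
  d <- ncol(consensus)
  disp <- do.call(rbind, lapply(seq_len(nPC), function(i) {
    v <- unvecConfig(ed$vectors[, i], d) *
      sqrt(max(ed$values[i], 0)) * amplification
    data.frame(pc = i, landmark = seq_len(nrow(consensus)),
               cx = consensus[, 1L], cy = consensus[, 2L],
               dx = v[, 1L], dy = v[, 2L])
  }))
  attr(disp, "amplification") <- amplification
  list(values = ed$values, vectors = ed$vectors, displacements = disp)
}

#' Lollipop-style shape-change data for a set of effect covariances
#'
#' @param covs named list of [EffectCovariance-class] objects (e.g. from
#'   [effectCovariances()]).
#' @param nPC,amplification passed to [pcaEffect()].
#' @return data.frame with columns effect, pc, landmark, cx, cy, dx, dy;
#'   attribute \code{amplification}.
#' @export
lollipopData <- function(covs, nPC = 2L, amplification = 1) {
  out <- do.call(rbind, lapply(names(covs), function(nm) {
    df <- pcaEffect(covs[[nm]], nPC = nPC,
                    amplification = amplification)$displacements
    cbind(effect = nm, df)
  }))
  attr(out, "amplification") <- amplification
  out
}

#' Write lollipop data to CSV
#'
#' The amplification factor is recorded in a leading comment line.
#'
#' @param df output of [lollipopData()] or [pcaEffect()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeLollipop <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# amplification: ",
                    attr(df, "amplification") %||% 1), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Render a lollipop graph
#'
#' Optional base-graphics rendering of shape-change vectors: open circles
#' at the consensus landmarks, segments showing magnitude and direction of
#' the displacement.
#'
#' @param df one effect/PC subset of [lollipopData()] output.
#' @param main plot title.
#' @return invisibly, NULL; draws on the active device.
#' @export
plotLollipop <- function(df, main = "") {
  graphics::plot(df$cx, df$cy, asp = 1, pch = 1, xlab = "", ylab = "",
                 main = main)
  graphics::segments(df$cx, df$cy, df$cx + df$dx, df$cy + df$dy, lwd = 2)
  invisible(NULL)
}
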