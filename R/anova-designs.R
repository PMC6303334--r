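# --- table assembly --------------------------------------------------------

.rowTemplate <- function(effect, convDf, shapeDf, ss) {
  data.frame(effect = effect, convDf = convDf, shapeDf = shapeDf, ss = ss,
             ms = ss / shapeDf, f = NA_real_, pParam = NA_real_,
             pPerm = NA_real_, pillai = NA_real_, pillaiPParam = NA_real_,
             pillaiPPerm = NA_real_, stringsAsFactors = FALSE)
}

# Fill F, parametric P and Pillai columns from the denominator map.
.fillTests <- function(tab, sscp, denom, subspace, pillai = TRUE) {
  for (i in seq_len(nrow(tab))) {
    eff <- tab$effect[i]
    den <- denom[eff]
    if (is.na(den)) next
    j <- match(den, tab$effect)
    gf <- goodallF(tab$ss[i], tab$shapeDf[i], tab$ss[j], tab$shapeDf[j])
    tab$f[i] <- gf$F; tab$pParam[i] <- gf$p
    if (pillai && subspace[eff] == subspace[den] &&
        !is.null(sscp[[eff]]) && !is.null(sscp[[den]])) {
      H <- sscp[[eff]]; E <- sscp[[den]]
      V <- pillaiTrace(H, E)
      tab$pillai[i] <- V
      tab$pillaiPParam[i] <- pillaiParamP(V, .numRank(H + E),
                                          tab$convDf[i], tab$convDf[j])
    }
  }
  tab
}

.newEffectTable <- function(design, tab, sscp, comp, denom, subspace, proj,
                            consensus, fitInfo) {
  new("EffectTable", design = design, table = tab, sscp = sscp,
      components = comp, denominators = denom, subspace = subspace,
      projectors = proj, consensus = consensus, fitInfo = fitInfo)
}

.needInfo <- function(info, cols, design) {
  miss <- setdiff(cols, names(info))
  if (length(miss))
    stop("design ", design, " needs index column(s): ",
         paste(miss, collapse = ", "))
}

# --- Analysis 1: rotational matching symmetry ------------------------------

#' Procrustes ANOVA for rotational matching symmetry
#'
#' Treats each repeated part as perfectly bilaterally symmetric: every
#' configuration is first replaced by its symmetric average
#' ([symmetrizeConfigs()]), all symmetrized parts are superimposed by a
#' single partial GPA and projected to tangent space, and the variation is
#' decomposed by the two-way mixed model \code{individual (random) + part
#' (fixed, rotational DA) + individual x part (rotational FA) +
#' measurement error}. F ratios test individual and part against the
#' interaction and the interaction against error; shape degrees of freedom
#' are the conventional df times the symmetric-subspace dimension.
#'
#' @param x a [LandmarkSet-class] with index columns \code{individual},
#'   \code{part}, \code{replicate} (balanced complete grid).
#' @param scheme a [SymmetryScheme-class] with a bilateral pairing.
#' @param nPerm number of permutations for the permutation P columns
#'   (0 = parametric tests only).
#' @param seed RNG seed for the permutations (required when
#'   \code{nPerm > 0}).
#' @param pillai compute Pillai's trace MANOVA columns.
#' @param tol,maxIter GPA controls.
#' @param allowSingleReplicate with a single replicate measurement error
#'   is not estimable; set TRUE to obtain the reduced table (no error row,
#'   no interaction test).
#' @return an [EffectTable-class].
#' @export
rotationalAnova <- function(x, scheme, nPerm = 0L, seed = NULL,
                            pillai = TRUE, tol = 1e-10, maxIter = 100L,
                            allowSingleReplicate = FALSE) {
  .needInfo(x@info, c("individual", "part", "replicate"), "A1")
  nR <- length(unique(x@info$replicate))
  if (nR < 2L && !allowSingleReplicate)
    stop("measurement error is not estimable from a single replicate; ",
         "set allowSingleReplicate = TRUE for a reduced table")
  sym <- symmetrizeConfigs(x, scheme, tol = tol, maxIter = maxIter)
  gpa <- tangentProjection(partialGPA(sym, scheme = scheme, tol = tol,
                                      maxIter = maxIter,
                                      symmetrizeConsensus = TRUE))
  proj <- subspaceProjectors(scheme, gpa@consensus)
  Y <- gpa@tangent
  dec <- decomposeEffects(Y, x@info, "A1")
  effects <- c("individual", "part", "interaction", "error")
  if (nR < 2L) effects <- setdiff(effects, "error")
  tab <- do.call(rbind, lapply(effects, function(e)
    .rowTemplate(e, dec$convDf[e], dec$convDf[e] * proj@dimSym, dec$ss[e])))
  denom <- c(individual = "interaction", part = "interaction",
             interaction = if (nR >= 2L) "error" else NA_character_,
             error = NA_character_)
  subspace <- setNames(rep("symmetric", 4L),
                       c("individual", "part", "interaction", "error"))
  sscp <- lapply(dec$components[effects], crossprod)
  tab <- .fillTests(tab, sscp, denom, subspace, pillai)
  fitInfo <- list(nInd = length(unique(x@info$individual)),
                  nPart = length(unique(x@info$part)), nRep = nR,
                  errDfContrast = length(unique(x@info$individual)) *
                    length(unique(x@info$part)) * (nR - 1),
                  divisor = 1, nPerm = nPerm, seed = seed,
                  info = x@info, tangent = Y)
  fit <- .newEffectTable("A1", tab, sscp, dec$components, denom, subspace,
                         proj, gpa@consensus, fitInfo)
  if (nPerm > 0L) fit <- .addPermutationP(fit, nPerm, seed, pillai)
  fit
}

# --- Analysis 2: bilateral object symmetry ---------------------------------

#' Procrustes ANOVA for bilateral object symmetry
#'
#' Object-symmetry analysis of the repeated parts pooled across
#' individuals: the dataset is expanded with reflected-relabelled copies,
#' superimposed by a single partial GPA (symmetric consensus) and
#' projected to tangent space. Before fitting, the records are corrected
#' for the individual effect and for individual deviations from rotational
#' symmetry (differences in means, removed within each part-by-reflection
#' cell by default) so that pooling labelled parts from distinct
#' individuals does not inflate the error terms. The two-way fixed-effects
#' model is \code{part + reflection (bilateral DA) + part x reflection
#' (bilateral FA)}; the part effect is tested against the symmetric
#' component of measurement error and the reflection effect and the
#' interaction against the asymmetric component.
#'
#' @inheritParams rotationalAnova
#' @param correction \code{"full"} (default) removes per-individual cell
#'   means in both tangent subspaces; \code{"symmetric"} removes only
#'   symmetric-component means (per-individual bilateral-FA deviations
#'   then remain in the asymmetric error); \code{"none"} disables it.
#' @return an [EffectTable-class] with rows part, reflection,
#'   part x reflection, symmetric/asymmetric/total error.
#' @export
bilateralAnova <- function(x, scheme, correction = c("full", "symmetric",
                                                     "none"),
                           nPerm = 0L, seed = NULL, pillai = TRUE,
                           tol = 1e-10, maxIter = 100L) {
  correction <- match.arg(correction)
  if (nrow(scheme@pairs) == 0L)
    stop("design A2 needs a bilateral scheme (landmark pairing)")
  .needInfo(x@info, c("individual", "part", "replicate"), "A2")
  ex <- expandObjectSymmetry(x, scheme)
  gpa <- tangentProjection(partialGPA(ex, scheme = scheme, tol = tol,
                                      maxIter = maxIter,
                                      symmetrizeConsensus = TRUE))
  proj <- subspaceProjectors(scheme, gpa@consensus)
  fit <- .fitA2(gpa@tangent, ex@info, proj, correction, pillai,
                gpa@consensus)
  fit@fitInfo$nPerm <- nPerm; fit@fitInfo$seed <- seed
  if (nPerm > 0L) fit <- .addPermutationP(fit, nPerm, seed, pillai)
  fit
}

.fitA2 <- function(Y, info, proj, correction, pillai, consensus) {
  dec <- decomposeEffects(Y, info, "A2", correction)
  errSplit <- .splitSS(dec$components$error, proj, dec$divisor)
  effects <- c("part", "reflection", "interaction")
  dims <- c(part = proj@dimSym, reflection = proj@dimAsym,
            interaction = proj@dimAsym)
  tab <- do.call(rbind, lapply(effects, function(e)
    .rowTemplate(e, dec$convDf[e], dec$convDf[e] * dims[e], dec$ss[e])))
  errDf <- dec$convDf["error"]
  tab <- rbind(tab,
    .rowTemplate("symmetricError", errDf, errDf * proj@dimSym,
                 errSplit["sym"]),
    .rowTemplate("asymmetricError", errDf, errDf * proj@dimAsym,
                 errSplit["asym"]),
    .rowTemplate("totalError", errDf,
                 errDf * (proj@dimSym + proj@dimAsym), sum(errSplit)))
  denom <- c(part = "symmetricError", reflection = "asymmetricError",
             interaction = "asymmetricError", symmetricError = NA,
             asymmetricError = NA, totalError = NA)
  subspace <- c(part = "symmetric", reflection = "asymmetric",
                interaction = "asymmetric", symmetricError = "symmetric",
                asymmetricError = "asymmetric", totalError = "full")
  div <- dec$divisor
  sscp <- lapply(dec$components[effects], function(m) crossprod(m) / div)
  sscp$symmetricError <-
    crossprod(dec$components$error %*% proj@symmetric) / div
  sscp$asymmetricError <-
    crossprod(dec$components$error %*% proj@asymmetric) / div
  tab <- .fillTests(tab, sscp, denom, subspace, pillai)
  nI <- length(unique(info$individual)); nP <- length(unique(info$part))
  nR <- length(unique(info$replicate))
  fitInfo <- list(nInd = nI, nPart = nP, nRep = nR,
                  errDfContrast = nI * nP * (nR - 1), divisor = div,
                  correction = correction, info = info, tangent = Y)
  .newEffectTable("A2", tab, sscp, dec$components, denom, subspace, proj,
                  consensus, fitInfo)
}

# --- Analysis 3: nested symmetries -----------------------------------------

#' Procrustes ANOVA for bilateral symmetry nested in rotational symmetry
#'
#' The full hierarchical design: bilateral object symmetry of each
#' repeated part nested within the rotational matching symmetry of the
#' whole structure. After reflection expansion, GPA and tangent
#' projection, the mixed model is \code{individual (random, symmetric) +
#' part (fixed rotational DA, symmetric) + reflection-within-part (fixed
#' bilateral DA, asymmetric) + individual x part (rotational FA,
#' symmetric) + individual x reflection-within-part (bilateral FA,
#' asymmetric) + measurement error}. F denominators: individual and part
#' against individual x part; reflection(part) and individual x part
#' against individual x reflection(part); individual x reflection(part)
#' against the asymmetric error component.
#'
#' @inheritParams rotationalAnova
#' @return an [EffectTable-class].
#' @export
nestedAnova <- function(x, scheme, nPerm = 0L, seed = NULL, pillai = TRUE,
                        tol = 1e-10, maxIter = 100L) {
  if (nrow(scheme@pairs) == 0L)
    stop("design A3 needs a bilateral scheme (landmark pairing)")
  .needInfo(x@info, c("individual", "part", "replicate"), "A3")
  ex <- expandObjectSymmetry(x, scheme)
  gpa <- tangentProjection(partialGPA(ex, scheme = scheme, tol = tol,
                                      maxIter = maxIter,
                                      symmetrizeConsensus = TRUE))
  proj <- subspaceProjectors(scheme, gpa@consensus)
  fit <- .fitA3(gpa@tangent, ex@info, proj, pillai, gpa@consensus)
  fit@fitInfo$nPerm <- nPerm; fit@fitInfo$seed <- seed
  if (nPerm > 0L) fit <- .addPermutationP(fit, nPerm, seed, pillai)
  fit
}

.fitA3 <- function(Y, info, proj, pillai, consensus) {
  dec <- decomposeEffects(Y, info, "A3")
  errSplit <- .splitSS(dec$components$error, proj, dec$divisor)
  subspace <- c(individual = "symmetric", part = "symmetric",
                reflectionInPart = "asymmetric", indXpart = "symmetric",
                indXreflection = "asymmetric", symmetricError = "symmetric",
                asymmetricError = "asymmetric", totalError = "full")
  effects <- c("individual", "part", "reflectionInPart", "indXpart",
               "indXreflection")
  dims <- c(symmetric = proj@dimSym, asymmetric = proj@dimAsym)
  tab <- do.call(rbind, lapply(effects, function(e)
    .rowTemplate(e, dec$convDf[e],
                 dec$convDf[e] * dims[subspace[e]], dec$ss[e])))
  errDf <- dec$convDf["error"]
  tab <- rbind(tab,
    .rowTemplate("symmetricError", errDf, errDf * proj@dimSym,
                 errSplit["sym"]),
    .rowTemplate("asymmetricError", errDf, errDf * proj@dimAsym,
                 errSplit["asym"]),
    .rowTemplate("totalError", errDf,
                 errDf * (proj@dimSym + proj@dimAsym), sum(errSplit)))
  denom <- c(individual = "indXpart", part = "indXpart",
             reflectionInPart = "indXreflection",
             indXpart = "indXreflection",
             indXreflection = "asymmetricError",
             symmetricError = NA, asymmetricError = NA, totalError = NA)
  div <- dec$divisor
  sscp <- lapply(dec$components[effects], function(m) crossprod(m) / div)
  sscp$symmetricError <-
    crossprod(dec$components$error %*% proj@symmetric) / div
  sscp$asymmetricError <-
    crossprod(dec$components$error %*% proj@asymmetric) / div
  tab <- .fillTests(tab, sscp, denom, subspace, pillai)
  nI <- length(unique(info$individual)); nP <- length(unique(info$part))
  nR <- length(unique(info$replicate))
  fitInfo <- list(nInd = nI, nPart = nP, nRep = nR,
                  errDfContrast = nI * nP * (nR - 1), divisor = div,
                  info = info, tangent = Y)
  .newEffectTable("A3", tab, sscp, dec$components, denom, subspace, proj,
                  consensus, fitInfo)
}

# --- centroid-size ANOVA ---------------------------------------------------

#' Centroid-size ANOVA
#'
#' Univariate two-way mixed ANOVA of centroid size with the same design
#' and denominator logic as the rotational matching-symmetry shape
#' analysis, but with the conventional degrees of freedom. Size asymmetry
#' only exists under matching symmetry: a structure analysed purely as
#' object symmetry has a single configuration for the whole structure, so
#' there is no asymmetry in size to analyse.
#'
#' @param x a [LandmarkSet-class] (sizes are computed from the raw
#'   configurations) or a numeric vector of centroid sizes.
#' @param info index data.frame (taken from \code{x} when it is a
#'   [LandmarkSet-class]).
#' @param scheme optional [SymmetryScheme-class]; an object-mode scheme is
#'   rejected.
#' @inheritParams rotationalAnova
#' @return an [EffectTable-class] (design \code{"size"}).
#' @export
centroidSizeAnova <- function(x, info = NULL, scheme = NULL, nPerm = 0L,
                              seed = NULL) {
  if (!is.null(scheme) && scheme@mode == "object")
    stop("size asymmetry is not defined under pure object symmetry: ",
         "there is a unique configuration for the whole structure, ",
         "hence no asymmetry in size")
  if (is(x, "LandmarkSet")) {
    info <- x@info
    sizes <- centroidSize(x)
  } else sizes <- as.numeric(x)
  .needInfo(info, c("individual", "part", "replicate"), "size")
  Y <- matrix(sizes, ncol = 1L)
  dec <- decomposeEffects(Y, info, "A1")
  effects <- c("individual", "part", "interaction", "error")
  tab <- do.call(rbind, lapply(effects, function(e)
    .rowTemplate(e, dec$convDf[e], dec$convDf[e], dec$ss[e])))
  denom <- c(individual = "interaction", part = "interaction",
             interaction = "error", error = NA_character_)
  subspace <- setNames(rep("full", 4L), effects)
  tab <- .fillTests(tab, sscp = list(), denom, subspace, pillai = FALSE)
  nI <- length(unique(info$individual)); nP <- length(unique(info$part))
  nR <- length(unique(info$replicate))
  fitInfo <- list(nInd = nI, nPart = nP, nRep = nR,
                  errDfContrast = nI * nP * (nR - 1), divisor = 1,
                  info = info, tangent = Y, nPerm = nPerm, seed = seed)
  fit <- .newEffectTable("size", tab, list(), dec$components, denom,
                         subspace, NULL, NULL, fitInfo)
  if (nPerm > 0L) fit <- .addPermutationP(fit, nPerm, seed,
                                          pillai = FALSE)
  fit
}

# --- EffectTable methods ---------------------------------------------------

#' @rdname accessors
#' @export
setMethod("effectTable", "EffectTable", function(x) x@table)
#' @rdname accessors
#' @export
setMethod("sscpMatrices", "EffectTable", function(x) x@sscp)
#' @rdname accessors
#' @export
setMethod("effectComponents", "EffectTable", function(x) x@components)

setMethod("show", "EffectTable", function(object) {
  cat("Procrustes ANOVA effect table (design ", object@design, ")\n",
      sep = "")
  tab <- object@table
  num <- vapply(tab, is.numeric, logical(1L))
  tab[num] <- lapply(tab[num], function(z) signif(z, 6L))
  print(tab, row.names = FALSE)
})
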