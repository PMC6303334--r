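# --- permutation tests for the ANOVA designs -------------------------------

# Goodall F (and optionally Pillai trace) for one effect, recomputed from
# scratch on (possibly permuted) data. Shape-dimension multipliers are
# applied explicitly so that cross-subspace F ratios are handled.
.statEffect <- function(design, Y, info, proj, correction, effect,
                        wantPillai) {
  if (design %in% c("A1", "size")) {
    dec <- decomposeEffects(Y, info, "A1", check = FALSE)
    den <- c(individual = "interaction", part = "interaction",
             interaction = "error")[[effect]]
    ss <- dec$ss; df <- dec$convDf
    out <- c(F = unname((ss[effect] / df[effect]) / (ss[den] / df[den])))
    if (wantPillai)
      out["pillai"] <- pillaiTrace(crossprod(dec$components[[effect]]),
                                   crossprod(dec$components[[den]]))
    return(out)
  }
  dec <- decomposeEffects(Y, info, design, correction, check = FALSE)
  div <- dec$divisor
  errSplit <- .splitSS(dec$components$error, proj, div)
  maps <- if (design == "A2") list(
    den = c(part = "symmetricError", reflection = "asymmetricError",
            interaction = "asymmetricError"),
    sub = c(part = "symmetric", reflection = "asymmetric",
            interaction = "asymmetric"))
  else list(
    den = c(individual = "indXpart", part = "indXpart",
            reflectionInPart = "indXreflection",
            indXpart = "indXreflection",
            indXreflection = "asymmetricError"),
    sub = c(individual = "symmetric", part = "symmetric",
            reflectionInPart = "asymmetric", indXpart = "symmetric",
            indXreflection = "asymmetric"))
  den <- maps$den[[effect]]
  subE <- maps$sub[[effect]]
  dims <- c(symmetric = proj@dimSym, asymmetric = proj@dimAsym)
  if (den == "symmetricError") {
    ssD <- errSplit[["sym"]]; dfD <- dec$convDf[["error"]]
    subD <- "symmetric"
  } else if (den == "asymmetricError") {
    ssD <- errSplit[["asym"]]; dfD <- dec$convDf[["error"]]
    subD <- "asymmetric"
  } else {
    ssD <- dec$ss[[den]]; dfD <- dec$convDf[[den]]
    subD <- maps$sub[[den]]
  }
  Fv <- (dec$ss[[effect]] / (dec$convDf[[effect]] * dims[[subE]])) /
    (ssD / (dfD * dims[[subD]]))
  out <- c(F = Fv)
  if (wantPillai && subE == subD) {
    H <- crossprod(dec$components[[effect]]) / div
    E <- if (den == "symmetricError")
      crossprod(dec$components$error %*% proj@symmetric) / div
    else if (den == "asymmetricError")
      crossprod(dec$components$error %*% proj@asymmetric) / div
    else crossprod(dec$components[[den]]) / div
    out["pillai"] <- pillaiTrace(H, E)
  }
  out
}

# Permute the levels of `A` among the (A, B) cells within each stratum of
# `B`; rows of the same cell move together.
.permuteLabelsWithin <- function(A, B, perm = NULL) {
  A <- as.character(A); B <- as.character(B)
  newA <- A
  strata <- sort(unique(B))
  for (si in seq_along(strata)) {
    sel <- B == strata[si]
    lev <- sort(unique(A[sel]))
    newLev <- if (is.null(perm)) sample(lev) else lev[perm[[si]]]
    names(newLev) <- lev
    newA[sel] <- newLev[A[sel]]
  }
  newA
}

# Flip the reflection-copy label of selected (individual, part) units.
.flipCopies <- function(cp, unitKey, flips) {
  sel <- flips[unitKey]
  ifelse(sel, 3L - as.integer(cp), as.integer(cp))
}

# Build, for one effect, a closure drawing one permuted statistic, plus
# (when the number of distinct permutations does not exceed nPerm) the
# full enumeration of permuted statistics.
.permDraw <- function(fit, effect, wantPillai, nPerm) {
  design <- fit@design
  info <- fit@fitInfo$info
  Y <- fit@fitInfo$tangent
  proj <- fit@projectors
  correction <- fit@fitInfo$correction
  comp <- fit@components
  ind <- as.character(info$individual)
  prt <- as.character(info$part)
  unitKey <- .key(ind, prt)
  stat <- function(Yp, infoP)
    .statEffect(design, Yp, infoP, proj, correction, effect, wantPillai)

  relabelScheme <- function(A, B, nameA) {
    g <- length(unique(A)); s <- length(unique(B))
    enum <- .enumStrataPerms(g, s, nPerm)
    draw <- function() {
      infoP <- info; infoP[[nameA]] <- .permuteLabelsWithin(A, B)
      stat(Y, infoP)
    }
    allStats <- NULL
    if (!is.null(enum)) {
      perms <- attr(enum, "perms")
      allStats <- do.call(rbind, lapply(enum, function(idx) {
        infoP <- info
        infoP[[nameA]] <- .permuteLabelsWithin(
          A, B, perm = lapply(idx, function(i) perms[i, ]))
        stat(Y, infoP)
      }))
      message("exhaustive enumeration of ", length(enum),
              " distinct permutations")
    }
    list(draw = draw, allStats = allStats)
  }

  flipScheme <- function(Yb) {
    units <- sort(unique(unitKey))
    nU <- length(units)
    draw <- function() {
      flips <- setNames(sample(c(TRUE, FALSE), nU, replace = TRUE), units)
      infoP <- info; infoP$copy <- .flipCopies(info$copy, unitKey, flips)
      stat(Yb, infoP)
    }
    allStats <- NULL
    if (2^nU <= nPerm) {
      allStats <- do.call(rbind, lapply(seq_len(2^nU) - 1L,
                                        function(mask) {
        flips <- setNames(as.logical(bitwAnd(mask, 2^(seq_len(nU) - 1L))),
                          units)
        infoP <- info
        infoP$copy <- .flipCopies(info$copy, unitKey, flips)
        stat(Yb, infoP)
      }))
      message("exhaustive enumeration of ", 2^nU,
              " distinct reflection permutations")
    }
    list(draw = draw, allStats = allStats)
  }

  # Interaction tests: residuals of the reduced model are permuted at the
  # record level across all index slots and the full statistic (numerator
  # and denominator) is recomputed from the permuted field. Reflected
  # copies move with their physical record so the dataset remains a valid
  # object-symmetry expansion.
  recordScheme <- function(Yr) {
    hasCopy <- !is.null(info$copy) && length(unique(info$copy)) == 2L
    if (!hasCopy) {
      draw <- function() stat(Yr[sample(nrow(Yr)), , drop = FALSE], info)
    } else {
      physKey <- .key(ind, prt, info$replicate)
      slots <- sort(unique(physKey))
      rows1 <- vapply(slots, function(s)
        which(physKey == s & info$copy == 1L), integer(1L))
      rows2 <- vapply(slots, function(s)
        which(physKey == s & info$copy == 2L), integer(1L))
      draw <- function() {
        pm <- sample(length(slots))
        Yp <- Yr
        Yp[rows1, ] <- Yr[rows1[pm], , drop = FALSE]
        Yp[rows2, ] <- Yr[rows2[pm], , drop = FALSE]
        stat(Yp, info)
      }
    }
    list(draw = draw, allStats = NULL)
  }

  if (design %in% c("A1", "size")) {
    switch(effect,
      individual = relabelScheme(ind, prt, "individual"),
      part = relabelScheme(prt, ind, "part"),
      interaction = recordScheme(Y - comp$individual - comp$part),
      stop("no permutation scheme for effect ", effect))
  } else if (design == "A2") {
    switch(effect,
      part = relabelScheme(prt, ind, "part"),
      reflection = flipScheme(Y),
      interaction = flipScheme(Y - comp$reflection),
      stop("no permutation scheme for effect ", effect))
  } else {
    switch(effect,
      individual = relabelScheme(ind, prt, "individual"),
      part = relabelScheme(prt, ind, "part"),
      reflectionInPart = flipScheme(Y),
      indXpart = recordScheme(Y - comp$individual - comp$part -
                                comp$reflectionInPart),
      indXreflection = flipScheme(Y - comp$reflectionInPart),
      stop("no permutation scheme for effect ", effect))
  }
}

#' Restricted permutation test for one effect
#'
#' Recomputes the permutation P value of a single effect from a fitted
#' design, using the design's restricted permutation scheme: main random
#' effects permute whole units across individuals within part strata;
#' fixed part/reflection main effects permute part labels within
#' individuals or flip reflection copies per unit; interactions permute
#' record-level residuals across all index slots (or flip copies) after
#' subtraction of the main effects, recomputing numerator and denominator
#' from the permuted field; nested effects use restricted flips within
#' their nesting level. The observed statistic is included in the null
#' set (add-one
#' rule), so P >= 1/(nPerm + 1); when fewer distinct permutations exist
#' than requested, the exact P is computed by exhaustive enumeration (a
#' notice is emitted).
#'
#' @param fit an [EffectTable-class].
#' @param effect effect name (a testable row of the table).
#' @param nPerm number of random permutations.
#' @param seed RNG seed (required).
#' @param statistic \code{"goodall"} (F ratio) or \code{"pillai"}.
#' @return the permutation P value (scalar).
#' @export
permutationTest <- function(fit, effect, nPerm = 999L, seed = NULL,
                            statistic = c("goodall", "pillai")) {
  statistic <- match.arg(statistic)
  if (is.null(seed)) stop("a seed is required for permutation tests")
  tab <- fit@table
  i <- match(effect, tab$effect)
  if (is.na(i) || is.na(fit@denominators[effect]))
    stop("effect '", effect, "' is not testable in this design")
  wantPillai <- statistic == "pillai"
  if (wantPillai && is.na(tab$pillai[i]))
    stop("no Pillai statistic available for effect '", effect, "'")
  set.seed(seed)
  obs <- if (wantPillai) c(F = tab$f[i], pillai = tab$pillai[i])
  else c(F = tab$f[i])
  sch <- .permDraw(fit, effect, wantPillai, nPerm)
  p <- .permPvalue(obs, sch$draw, nPerm, sch$allStats)
  unname(p[[if (wantPillai) "pillai" else "F"]])
}

# Fill the permutation P columns of an EffectTable.
.addPermutationP <- function(fit, nPerm, seed, pillai) {
  if (is.null(seed))
    stop("a seed is required for permutation tests")
  set.seed(seed)
  tab <- fit@table
  testable <- names(fit@denominators)[!is.na(fit@denominators)]
  for (eff in testable) {
    i <- match(eff, tab$effect)
    wantPillai <- pillai && !is.na(tab$pillai[i])
    obs <- c(F = tab$f[i])
    if (wantPillai) obs["pillai"] <- tab$pillai[i]
    sch <- .permDraw(fit, eff, wantPillai, nPerm)
    p <- .permPvalue(obs, sch$draw, nPerm, sch$allStats)
    tab$pPerm[i] <- p[["F"]]
    if (wantPillai) tab$pillaiPPerm[i] <- p[["pillai"]]
  }
  fit@table <- tab
  fit
}
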