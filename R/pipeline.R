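#' Run the full analysis pipeline
#'
#' GPA, symmetry expansion, the chosen ANOVA design, parametric and
#' permutation inference, effect-covariance PCA, and CSV export:
#' the tool-level entry point mirrored by the command-line script
#' (\code{inst/scripts/symmetry-anova.R}).
#'
#' @param input a [LandmarkSet-class], or a path to a TPS (\code{.tps}) or
#'   long-format CSV file.
#' @param scheme a [SymmetryScheme-class] or path to a YAML scheme file.
#' @param design \code{"A1"} (rotational matching symmetry), \code{"A2"}
#'   (bilateral object symmetry), \code{"A3"} (nested symmetries) or
#'   \code{"size"} (centroid-size ANOVA).
#' @param nPerm permutations (default 10000, the published protocol;
#'   0 disables permutation tests).
#' @param seed RNG seed; mandatory whenever \code{nPerm > 0}.
#' @param outDir output directory (created if missing).
#' @param amplification display multiplier for exported shape-change
#'   vectors (10 is the conventional choice for subtle DA).
#' @param correction A2 mean-correction mode (see [bilateralAnova()]).
#' @param nPC principal components exported per effect.
#' @param idPattern passed to [readTPS()].
#' @return invisibly, a list with the fitted [EffectTable-class] and the
#'   paths of the written files.
#' @export
runPipeline <- function(input, scheme, design = c("A1", "A2", "A3",
                                                  "size"),
                        nPerm = 10000L, seed = NULL, outDir = ".",
                        amplification = 10, correction = "full",
                        nPC = 2L, idPattern = "^(.+)_([^_]+)_([^_]+)$") {
  design <- match.arg(design)
  if (nPerm > 0L && is.null(seed))
    stop("a seed is mandatory when permutations are requested")
  if (is.character(scheme)) scheme <- readSymmetryScheme(scheme)
  if (is.character(input)) {
    input <- if (grepl("\\.tps$", input, ignore.case = TRUE))
      readTPS(input, idPattern = idPattern)
    else readLandmarkCSV(input)
  }
  if (design %in% c("A2", "A3") && nrow(scheme@pairs) == 0L)
    stop("design ", design, " requires a bilateral scheme")
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  fit <- switch(design,
    A1 = rotationalAnova(input, scheme, nPerm = nPerm, seed = seed),
    A2 = bilateralAnova(input, scheme, correction = correction,
                        nPerm = nPerm, seed = seed),
    A3 = nestedAnova(input, scheme, nPerm = nPerm, seed = seed),
    size = centroidSizeAnova(input, scheme = scheme, nPerm = nPerm,
                             seed = seed))
  files <- character()
  f <- file.path(outDir, paste0("effect_table_", design, ".csv"))
  writeEffectTable(fit, f)
  files <- c(files, f)
  if (design != "size") {
    covs <- suppressWarnings(effectCovariances(fit, mode = "ems"))
    eig <- do.call(rbind, lapply(names(covs), function(nm) {
      ev <- eigen((covs[[nm]]@covariance + t(covs[[nm]]@covariance)) / 2,
                  symmetric = TRUE, only.values = TRUE)$values
      data.frame(effect = nm, component = seq_along(ev),
                 eigenvalue = signif(ev, 6L))
    }))
    f <- file.path(outDir, paste0("effect_eigenvalues_", design, ".csv"))
    write.csv(eig, f, row.names = FALSE)
    files <- c(files, f)
    lol <- lollipopData(covs, nPC = nPC, amplification = amplification)
    lol[c("cx", "cy", "dx", "dy")] <-
      lapply(lol[c("cx", "cy", "dx", "dy")], signif, digits = 6L)
    f <- file.path(outDir, paste0("lollipop_", design, ".csv"))
    writeLollipop(lol, f)
    files <- c(files, f)
  }
  logf <- file.path(outDir, paste0("run_", design, ".log"))
  writeLines(c(
    paste0("nestsym version: ", as.character(packageVersion("nestsym"))),
    paste0("design: ", design),
    paste0("records: ", length(input)),
    paste0("scheme: mode=", scheme@mode, " k=", scheme@k,
           " parts=", scheme@nParts,
           " pairs=", paste(apply(scheme@pairs, 1L, paste,
                                  collapse = "-"), collapse = ","),
           " unpaired=", paste(scheme@unpaired, collapse = ",")),
    paste0("permutations: ", nPerm),
    paste0("seed: ", if (is.null(seed)) "none" else seed),
    paste0("amplification: ", amplification)), logf)
  files <- c(files, logf)
  invisible(list(fit = fit, files = files))
}
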