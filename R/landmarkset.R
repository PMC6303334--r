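#' Build a LandmarkSet
#'
#' @param coords a k x d x N array, or a list of k x d matrices.
#' @param info data.frame with one row per configuration; recognised
#'   columns are \code{individual}, \code{part}, \code{replicate},
#'   \code{copy}. Missing columns are filled with defaults.
#' @param labels landmark labels (default \code{"1"..."k"}).
#' @return a [LandmarkSet-class].
#' @export
landmarkSet <- function(coords, info = NULL, labels = NULL) {
  if (is.list(coords)) {
    k <- nrow(coords[[1L]]); d <- ncol(coords[[1L]])
    if (!all(vapply(coords, function(m) nrow(m) == k && ncol(m) == d,
                    logical(1L))))
      stop("all configurations must share the same dimensions")
    coords <- array(unlist(coords), dim = c(k, d, length(coords)))
  }
  n <- dim(coords)[3L]
  if (is.null(info)) info <- data.frame(individual = seq_len(n))
  if (is.null(info$individual)) info$individual <- seq_len(n)
  if (is.null(info$part)) info$part <- 1L
  if (is.null(info$replicate)) info$replicate <- 1L
  if (is.null(labels)) labels <- as.character(seq_len(dim(coords)[1L]))
  new("LandmarkSet", coords = coords, labels = labels, info = info)
}

#' @rdname accessors
#' @param x an object of one of the package classes.
#' @export
setMethod("landmarkCoords", "LandmarkSet", function(x) x@coords)

#' Accessors for the package classes
#'
#' \code{sampleInfo} returns the per-configuration index metadata;
#' \code{landmarkCoords} the raw coordinate array; \code{alignedCoords},
#' \code{tangentCoords}, \code{consensusShape}, \code{procrustesSS} and
#' \code{centroidSizes} the slots of an [AlignedShapes-class];
#' \code{effectTable}, \code{sscpMatrices} and \code{effectComponents} the
#' slots of an [EffectTable-class].
#'
#' @name accessors
#' @return the corresponding slot.
NULL

#' @rdname accessors
#' @export
setMethod("sampleInfo", "LandmarkSet", function(x) x@info)

setMethod("length", "LandmarkSet", function(x) dim(x@coords)[3L])

setMethod("[", "LandmarkSet", function(x, i, j, ..., drop = FALSE) {
  new("LandmarkSet", coords = x@coords[, , i, drop = FALSE],
      labels = x@labels, info = x@info[i, , drop = FALSE])
})

#' Extract one configuration as a matrix
#' @param x a [LandmarkSet-class].
#' @param i configuration index.
#' @return a k x d matrix.
#' @export
getConfig <- function(x, i) {
  m <- x@coords[, , i, drop = TRUE]
  dimnames(m) <- NULL
  m
}

setMethod("show", "LandmarkSet", function(object) {
  dm <- dim(object@coords)
  cat("LandmarkSet:", dm[3L], "configurations of", dm[1L], "landmarks in",
      dm[2L], "D\n")
  cat("  individuals:", length(unique(object@info$individual)),
      "| parts:", length(unique(object@info$part)),
      "| replicates:", length(unique(object@info$replicate)))
  if (!is.null(object@info$copy))
    cat(" | reflection copies:", length(unique(object@info$copy)))
  cat("\n")
})

#' @rdname centroidSize
#' @export
setMethod("centroidSize", "matrix", function(x) {
  cs <- sqrt(sum(scale(x, scale = FALSE)^2))
  if (cs < sqrt(.Machine$double.eps))
    stop("degenerate configuration: all landmarks coincide (zero size)")
  cs
})

#' @rdname centroidSize
#' @export
setMethod("centroidSize", "LandmarkSet", function(x) {
  vapply(seq_len(length(x)), function(i) centroidSize(getConfig(x, i)),
         numeric(1L))
})
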