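#' Centroid size
#'
#' Square root of the summed squared distances of the landmarks to their
#' centroid; the standard geometric size measure. Invariant to translation
#' and rotation, scales linearly with the coordinates.
#'
#' @param x a k x d coordinate matrix or a [LandmarkSet-class].
#' @return a positive scalar (matrix input) or a numeric vector with one
#'   size per configuration (set input).
#' @examples
#' sq <- matrix(c(-1, -1, -1, 1, 1, -1, 1, 1), ncol = 2, byrow = TRUE)
#' centroidSize(sq)  # sqrt(8)
#' @export
setGeneric("centroidSize", function(x) standardGeneric("centroidSize"))

#' @rdname accessors
#' @export
setGeneric("tangentCoords", function(x) standardGeneric("tangentCoords"))
#' @rdname accessors
#' @export
setGeneric("alignedCoords", function(x) standardGeneric("alignedCoords"))
#' @rdname accessors
#' @export
setGeneric("consensusShape", function(x) standardGeneric("consensusShape"))
#' @rdname accessors
#' @export
setGeneric("procrustesSS", function(x) standardGeneric("procrustesSS"))
#' @rdname accessors
#' @export
setGeneric("centroidSizes", function(x) standardGeneric("centroidSizes"))
#' @rdname accessors
#' @export
setGeneric("sampleInfo", function(x) standardGeneric("sampleInfo"))
#' @rdname accessors
#' @export
setGeneric("landmarkCoords", function(x) standardGeneric("landmarkCoords"))
#' @rdname accessors
#' @export
setGeneric("effectTable", function(x) standardGeneric("effectTable"))
#' @rdname accessors
#' @export
setGeneric("sscpMatrices", function(x) standardGeneric("sscpMatrices"))
#' @rdname accessors
#' @export
setGeneric("effectComponents", function(x) standardGeneric("effectComponents"))
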