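#' Declare a symmetry scheme
#'
#' @param mode type of symmetry analysis: \code{"matching"} (physically
#'   separate repeated parts), \code{"object"} (a single structure whose
#'   symmetry axis passes through it), or \code{"nested"} (bilateral object
#'   symmetry of each part nested within rotational matching symmetry of
#'   the whole).
#' @param k number of landmarks.
#' @param pairs two-column matrix (or list of length-2 vectors) of landmark
#'   indices swapped under the reflection. Landmark indices are 1-based.
#' @param unpaired integer vector of on-axis landmark indices.
#' @param nParts number of repeated parts at the matching level.
#' @return a [SymmetryScheme-class].
#' @examples
#' symmetryScheme("object", k = 5, pairs = rbind(c(2, 3), c(4, 5)),
#'                unpaired = 1)
#' @export
symmetryScheme <- function(mode = c("nested", "object", "matching"),
                           k, pairs = matrix(integer(), 0L, 2L),
                           unpaired = integer(), nParts = 1L) {
  mode <- match.arg(mode)
  if (is.list(pairs)) pairs <- do.call(rbind, pairs)
  pairs <- matrix(as.integer(pairs), ncol = 2L)
  bad <- c(pairs, unpaired)
  if (length(bad) && (any(bad < 1L) || any(bad > k)))
    stop("pairing references out-of-range landmarks")
  new("SymmetryScheme", mode = mode, k = as.integer(k), pairs = pairs,
      unpaired = as.integer(unpaired), nParts = as.integer(nParts))
}

#' The sea-urchin lantern scheme
#'
#' Twelve 2D landmarks per pyramid, four of them ({1, 4, 10, 12}) on the
#' interradial suture (the bilateral symmetry axis), four mirror pairs,
#' five pyramids arranged with five-fold rotational matching symmetry.
#' The pairing of the off-axis landmarks is a user-level declaration (it
#' depends on the digitizing protocol); the default emulates the published
#' landmark layout with pairs {2,3}, {5,8}, {6,7}, {11,9}.
#'
#' @param pairs optional replacement pairing (two-column matrix).
#' @return a nested-mode [SymmetryScheme-class] with k = 12, nParts = 5.
#' @export
lanternScheme <- function(pairs = rbind(c(2L, 3L), c(5L, 8L), c(6L, 7L),
                                        c(11L, 9L))) {
  symmetryScheme("nested", k = 12L, pairs = pairs,
                 unpaired = c(1L, 4L, 10L, 12L), nParts = 5L)
}

#' Read a symmetry scheme from a plain-text (YAML) file
#'
#' Schema: \code{mode} (matching/object/nested), \code{k}, \code{n_parts},
#' \code{pairs} (list of 2-element landmark index lists), \code{unpaired}
#' (list of on-axis landmark indices).
#'
#' @param path path to the YAML file.
#' @return a [SymmetryScheme-class].
#' @export
readSymmetryScheme <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (f in c("mode", "k")) if (is.null(cfg[[f]]))
    stop("scheme file is missing field '", f, "'")
  symmetryScheme(mode = cfg$mode, k = cfg$k,
                 pairs = if (is.null(cfg$pairs)) matrix(integer(), 0L, 2L)
                         else lapply(cfg$pairs, as.integer),
                 unpaired = as.integer(unlist(cfg$unpaired)),
                 nParts = if (is.null(cfg$n_parts)) 1L else cfg$n_parts)
}

#' Write a symmetry scheme to a YAML file
#' @param scheme a [SymmetryScheme-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeSymmetryScheme <- function(scheme, path) {
  yaml::write_yaml(list(
    mode = scheme@mode, k = scheme@k, n_parts = scheme@nParts,
    pairs = lapply(seq_len(nrow(scheme@pairs)),
                   function(i) as.integer(scheme@pairs[i, ])),
    unpaired = as.integer(scheme@unpaired)), path)
  invisible(path)
}

setMethod("show", "SymmetryScheme", function(object) {
  cat("SymmetryScheme (", object@mode, ")\n", sep = "")
  cat("  landmarks:", object@k, "| parts:", object@nParts, "\n")
  if (nrow(object@pairs))
    cat("  pairs:", paste(apply(object@pairs, 1L, paste, collapse = "-"),
                          collapse = ", "), "\n")
  cat("  unpaired:", paste(object@unpaired, collapse = ", "), "\n")
})
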