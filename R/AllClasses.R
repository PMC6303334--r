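#' @import methods
#' @importFrom stats pf rnorm runif setNames var
#' @importFrom utils head read.csv write.csv packageVersion
#' @importFrom graphics segments
NULL

#' Symmetry scheme for a landmark configuration
#'
#' A \code{SymmetryScheme} declares how the landmarks of a repeated unit map
#' onto each other under the symmetry transformations of the structure:
#' which landmark pairs are swapped by the bilateral reflection, which
#' landmarks sit on the symmetry axis (and map onto themselves), how many
#' repeated parts realize the matching-symmetry level, and whether the
#' analysis treats matching symmetry, object symmetry, or bilateral object
#' symmetry nested within rotational matching symmetry.
#'
#' @slot mode character; one of \code{"matching"}, \code{"object"},
#'   \code{"nested"}.
#' @slot k integer; number of landmarks per configuration.
#' @slot nParts integer; number of repeated parts at the matching level
#'   (5 for the sea-urchin lantern).
#' @slot pairs two-column integer matrix; landmark index pairs swapped under
#'   the reflection (first column and second column are mirror images).
#' @slot unpaired integer vector; landmarks on the symmetry axis.
#'
#' @seealso [symmetryScheme()], [lanternScheme()]
#' @export
setClass("SymmetryScheme",
  representation(mode = "character", k = "integer", nParts = "integer",
                 pairs = "matrix", unpaired = "integer"),
  validity = function(object) {
    msg <- character()
    if (!object@mode %in% c("matching", "object", "nested"))
      msg <- c(msg, "mode must be 'matching', 'object' or 'nested'")
    if (length(object@k) != 1L || object@k < 3L)
      msg <- c(msg, "k must be a single integer >= 3")
    if (ncol(object@pairs) != 2L && nrow(object@pairs) > 0L)
      msg <- c(msg, "pairs must have two columns")
    idx <- sort(c(as.integer(object@pairs), object@unpaired))
    if (!identical(idx, seq_len(object@k)))
      msg <- c(msg, "pairs and unpaired must partition 1..k exactly")
    if (nrow(object@pairs) > 0L && any(object@pairs[, 1L] == object@pairs[, 2L]))
      msg <- c(msg, "a landmark cannot be paired with itself")
    if (object@nParts < 1L) msg <- c(msg, "nParts must be >= 1")
    if (length(msg)) msg else TRUE
  })

#' A set of landmark configurations
#'
#' Container for N landmark configurations of identical dimension (k
#' landmarks in d Cartesian coordinates), together with the indexing
#' metadata (individual, part, reflection copy, replicate) used by the
#' ANOVA designs.
#'
#' @slot coords numeric array k x d x N of landmark coordinates.
#' @slot labels character vector of landmark labels (length k).
#' @slot info data.frame with N rows; columns \code{individual},
#'   \code{part}, \code{replicate} and optionally \code{copy} (reflection
#'   copy, filled by [expandObjectSymmetry()]).
#'
#' @seealso [landmarkSet()], [readTPS()]
#' @export
setClass("LandmarkSet",
  representation(coords = "array", labels = "character", info = "data.frame"),
  validity = function(object) {
    msg <- character()
    dm <- dim(object@coords)
    if (length(dm) != 3L)
      msg <- c(msg, "coords must be a k x d x N array")
    else {
      if (dm[1L] < 3L) msg <- c(msg, "need at least 3 landmarks")
      if (!all(is.finite(object@coords)))
        msg <- c(msg, "coordinates must be finite")
      if (length(object@labels) != dm[1L])
        msg <- c(msg, "labels length must equal the number of landmarks")
      if (nrow(object@info) != dm[3L])
        msg <- c(msg, "info must have one row per configuration")
    }
    if (length(msg)) msg else TRUE
  })

#' Procrustes-aligned shapes with tangent coordinates
#'
#' Result of [partialGPA()] (and, after [tangentProjection()], the
#' tangent-space coordinates used by every downstream analysis). Rows of
#' \code{aligned}/\code{tangent} are vectorized configurations in landmark-
#' major order (x1, y1, x2, y2, ...).
#'
#' @slot aligned numeric N x (k*d) matrix of aligned unit-size pre-shapes.
#' @slot tangent numeric matrix of tangent coordinates (empty until
#'   [tangentProjection()] is applied).
#' @slot consensus numeric k x d consensus (mean shape, unit centroid size).
#' @slot procrustesSS numeric; summed squared distances of the aligned
#'   configurations to their mean.
#' @slot centroidSizes numeric vector of original centroid sizes.
#' @slot info data.frame of per-row index metadata.
#' @slot scheme the [SymmetryScheme-class] used during alignment (may be
#'   an empty placeholder for plain alignments).
#' @slot iterations integer; GPA iterations used.
#' @export
setClass("AlignedShapes",
  representation(aligned = "matrix", tangent = "matrix", consensus = "matrix",
                 procrustesSS = "numeric", centroidSizes = "numeric",
                 info = "data.frame", scheme = "ANY", iterations = "integer"))

#' Orthogonal projectors onto the symmetric and asymmetric subspaces
#'
#' The reflection-and-relabel operator splits the shape tangent space at a
#' symmetric consensus into orthogonal complementary subspaces: the
#' symmetric subspace (invariant under the reflection) and the asymmetric
#' subspace (negated by it). For d = 2, p landmark pairs and u on-axis
#' landmarks, each subspace has dimension 2p + u - 2 once the four
#' similarity dimensions are removed.
#'
#' @slot symmetric,asymmetric (k*d) x (k*d) projector matrices (tangent
#'   nuisance directions already removed).
#' @slot dimSym,dimAsym integer subspace dimensions.
#' @slot consensus the symmetric consensus the projectors were built at.
#' @export
setClass("SubspaceProjectors",
  representation(symmetric = "matrix", asymmetric = "matrix",
                 dimSym = "integer", dimAsym = "integer",
                 consensus = "matrix"))

#' Procrustes ANOVA effect table
#'
#' Per-effect decomposition of shape (or centroid size) variation:
#' conventional and shape degrees of freedom, sums of squares, mean
#' squares, Goodall's F with parametric and permutation P values, and
#' Pillai's trace MANOVA with its P values.
#'
#' @slot design character; one of \code{"A1"}, \code{"A2"}, \code{"A3"},
#'   \code{"size"}.
#' @slot table data.frame with the printed columns.
#' @slot sscp named list of effect SSCP matrices (object-symmetry designs
#'   store them per physical observation, i.e. divided by the group order).
#' @slot components named list of per-row effect component matrices.
#' @slot denominators named character; F-ratio denominator of each effect.
#' @slot subspace named character; tangent subspace of each effect
#'   (\code{"symmetric"}, \code{"asymmetric"} or \code{"full"}).
#' @slot projectors [SubspaceProjectors-class] or NULL.
#' @slot consensus consensus shape of the alignment.
#' @slot fitInfo list of design constants (cell counts, contrast df, seed,
#'   permutation count, ...).
#' @export
setClass("EffectTable",
  representation(design = "character", table = "data.frame", sscp = "list",
                 components = "list", denominators = "character",
                 subspace = "character", projectors = "ANY",
                 consensus = "ANY", fitInfo = "list"))

#' Per-effect covariance matrix
#'
#' Covariance matrix attached to an ANOVA effect, recovered from the
#' effect SSCP matrices following the expected mean squares of the design.
#'
#' @slot effect character effect name.
#' @slot covariance (k*d) x (k*d) symmetric matrix.
#' @slot consensus k x d consensus shape (anchor for visualization).
#' @slot mode character; \code{"ems"} (mean-square subtraction) or
#'   \code{"ms"} (raw mean-square matrix).
#' @slot indefinite logical; TRUE when EMS subtraction produced negative
#'   eigenvalues (retained, not clipped, unless requested).
#' @export
setClass("EffectCovariance",
  representation(effect = "character", covariance = "matrix",
                 consensus = "matrix", mode = "character",
                 indefinite = "logical"))

#' Ground-truth variance components for the synthetic-data generator
#'
#' Parameters of the generative model behind [simulateLanterns()]: a
#' symmetric template shape, isotropic tangent-space standard deviations
#' for the random effects (individual, rotational FA, bilateral FA,
#' measurement error), fixed directional-asymmetry vectors, centroid-size
#' variance components, and the index structure.
#'
#' @slot consensus k x d symmetric template (unit centroid size).
#' @slot sigmaIndividual,sigmaRotFA,sigmaBilFA,sigmaError nonnegative
#'   per-coordinate standard deviations in tangent units.
#' @slot daRotational nParts x (k*d) matrix of fixed symmetric-subspace
#'   part displacement vectors (rows sum to zero).
#' @slot daBilateral (k*d) vector (or nParts x (k*d) matrix) of fixed
#'   asymmetric-subspace displacement(s).
#' @slot meanSize,sizeSigmaIndividual,sizeSigmaFA,sizeSigmaError,sizePartEffects
#'   centroid-size model: grand mean, random-effect SDs, and fixed per-part
#'   size offsets (sum to zero).
#' @slot nIndividuals,nParts,nReplicates index structure.
#' @export
setClass("VarianceComponents",
  representation(consensus = "matrix",
                 sigmaIndividual = "numeric", sigmaRotFA = "numeric",
                 sigmaBilFA = "numeric", sigmaError = "numeric",
                 daRotational = "matrix", daBilateral = "matrix",
                 meanSize = "numeric", sizeSigmaIndividual = "numeric",
                 sizeSigmaFA = "numeric", sizeSigmaError = "numeric",
                 sizePartEffects = "numeric",
                 nIndividuals = "integer", nParts = "integer",
                 nReplicates = "integer"),
  validity = function(object) {
    msg <- character()
    sig <- c(object@sigmaIndividual, object@sigmaRotFA, object@sigmaBilFA,
             object@sigmaError, object@sizeSigmaIndividual,
             object@sizeSigmaFA, object@sizeSigmaError)
    if (any(sig < 0)) msg <- c(msg, "all sigmas must be nonnegative")
    if (object@meanSize <= 0) msg <- c(msg, "meanSize must be positive")
    if (length(msg)) msg else TRUE
  })
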