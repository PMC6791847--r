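#' @include utils.R
NULL

#' Accessor generics for site models and filaments
#'
#' Small family of accessors used across the package: identifiers,
#' coordinate payloads and structural flags of [Filament-class],
#' [StructurePointSet-class] and [AttachmentSiteModel-class] objects.
#'
#' @param x an object.
#' @return The corresponding slot value; see the class documentation.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("siteId", function(x) standardGeneric("siteId"))

#' @rdname accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname accessors
#' @export
setGeneric("filaments", function(x) standardGeneric("filaments"))

#' @rdname accessors
#' @export
setGeneric("nFilaments", function(x) standardGeneric("nFilaments"))

#' @rdname accessors
#' @export
setGeneric("structures", function(x) standardGeneric("structures"))

#' @rdname accessors
#' @export
setGeneric("hasMicrotubule", function(x) standardGeneric("hasMicrotubule"))

#' @rdname accessors
#' @export
setGeneric("microtubuleAxis", function(x) standardGeneric("microtubuleAxis"))

#' @rdname accessors
#' @export
setGeneric("filamentId", function(x) standardGeneric("filamentId"))

#' @rdname accessors
#' @export
setGeneric("filamentPoints", function(x) standardGeneric("filamentPoints"))

#' @rdname accessors
#' @export
setGeneric("recordedWidth", function(x) standardGeneric("recordedWidth"))

#' @rdname accessors
#' @export
setGeneric("structureClass", function(x) standardGeneric("structureClass"))

#' @rdname accessors
#' @export
setGeneric("structurePoints", function(x) standardGeneric("structurePoints"))

#' Polyline arc length of a filament
#'
#' Sum of Euclidean lengths of consecutive segments of the filament
#' polyline, in nm. Invariant under rigid motion.
#'
#' @param x a [Filament-class].
#' @return Path length in nm (single numeric).
#' @seealso [linearDistance()], [stretchFactor()]
#' @examples
#' f <- Filament("f1", rbind(c(0, 0, 0), c(3, 4, 0), c(3, 4, 12)))
#' pathLength(f)  # 5 + 12 = 17
#' @export
setGeneric("pathLength", function(x) standardGeneric("pathLength"))

#' End-to-end (linear) distance of a filament
#'
#' Euclidean distance between the first and last stored polyline point,
#' in nm. Zero for a closed path.
#'
#' @param x a [Filament-class].
#' @return Linear distance in nm (single numeric).
#' @seealso [pathLength()], [stretchFactor()]
#' @export
setGeneric("linearDistance", function(x) standardGeneric("linearDistance"))

#' Stretch factor of a filament
#'
#' The ratio linear distance / path length. Equals 1 for a perfectly
#' straight filament and decreases as the filament ripples; always in
#' \[0, 1\] by the triangle inequality (0 only for a closed path).
#'
#' @param x a [Filament-class].
#' @return Dimensionless stretch factor in \[0, 1\].
#' @export
setGeneric("stretchFactor", function(x) standardGeneric("stretchFactor"))
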