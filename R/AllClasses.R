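#' @include AllGenerics.R
NULL

## Structure classes recognised in a label map. "linc_filament" contours
## become Filament objects; everything else becomes a StructurePointSet.
STRUCTURE_CLASSES <- c(
  "lateral_element", "central_element", "attachment_plate",
  "inner_membrane", "outer_membrane", "linc_filament",
  "microtubule", "other"
)

#' Structure classes recognised by the label map
#'
#' @return Character vector of the valid anatomical structure class names.
#' @examples
#' structureClasses()
#' @export
structureClasses <- function() STRUCTURE_CLASSES

#' Filament: one traced LINC complex as an ordered 3D polyline
#'
#' A filament is an ordered polyline of at least two 3D points (nm) traced
#' through the perinuclear space, with an optional manually recorded width
#' carried as metadata (widths are never computed here).
#'
#' @slot filamentId character(1) identifier, unique within a site.
#' @slot points numeric matrix (n x 3, n >= 2), coordinates in nm, in
#'   traced order.
#' @slot recordedWidth numeric(0 or 1), optional measured width in nm.
#'
#' @param filamentId,points,recordedWidth see slots.
#' @return `Filament()` returns a validated \code{Filament} object.
#' @examples
#' f <- Filament("f1", rbind(c(0, 0, 0), c(0, 0, 90)))
#' pathLength(f)
#' @aliases Filament
#' @export Filament
#' @exportClass Filament
Filament <- setClass("Filament", representation(
  filamentId = "character",
  points = "matrix",
  recordedWidth = "numeric"
))

setValidity("Filament", function(object) {
  p <- object@points
  if (length(object@filamentId) != 1L) return("filamentId must be a single string")
  if (!is.numeric(p) || ncol(p) != 3L) return("points must be an n x 3 numeric matrix")
  if (nrow(p) < 2L) return("a filament needs at least 2 points")
  if (!all(is.finite(p))) return("points contain non-finite coordinates")
  if (sum(row_norms(diff(p))) <= 0) return("total path length must be > 0")
  if (length(object@recordedWidth) > 1L) return("recordedWidth must be length 0 or 1")
  TRUE
})

#' @importFrom methods initialize
setMethod("initialize", "Filament", function(.Object, filamentId = "f",
                                             points = matrix(0, 0, 3),
                                             recordedWidth = numeric(0), ...) {
  if (nrow(as.matrix(points)) > 0) points <- as_coord_matrix(points)
  callNextMethod(.Object, filamentId = as.character(filamentId),
                 points = points, recordedWidth = as.numeric(recordedWidth), ...)
})

#' StructurePointSet: labelled point cloud of one anatomical structure
#'
#' All segmentation points of one structure class (lateral element,
#' membranes, attachment plates, ...) in one tomogram, in nm, with the
#' original contour grouping retained.
#'
#' @slot structureClass character(1), one of [structureClasses()].
#' @slot points numeric matrix (n x 3), coordinates in nm.
#' @slot contourIds integer vector (length n) grouping points into contours.
#'
#' @param structureClass,points,contourIds see slots.
#' @return `StructurePointSet()` returns a validated object.
#' @aliases StructurePointSet
#' @export StructurePointSet
#' @exportClass StructurePointSet
StructurePointSet <- setClass("StructurePointSet", representation(
  structureClass = "character",
  points = "matrix",
  contourIds = "integer"
))

setValidity("StructurePointSet", function(object) {
  if (!(object@structureClass %in% STRUCTURE_CLASSES))
    return(paste0("unknown structure class '", object@structureClass, "'"))
  p <- object@points
  if (!is.numeric(p) || ncol(p) != 3L) return("points must be an n x 3 numeric matrix")
  if (nrow(p) < 1L) return("a structure point set must be non-empty")
  if (!all(is.finite(p))) return("points contain non-finite coordinates")
  if (length(object@contourIds) != nrow(p))
    return("contourIds must have one entry per point")
  TRUE
})

setMethod("initialize", "StructurePointSet",
          function(.Object, structureClass = "other", points = matrix(0, 0, 3),
                   contourIds = integer(0), ...) {
  points <- as.matrix(points)
  if (nrow(points) > 0) points <- as_coord_matrix(points)
  if (length(contourIds) == 0L && nrow(points) > 0)
    contourIds <- rep(1L, nrow(points))
  callNextMethod(.Object, structureClass = structureClass, points = points,
                 contourIds = as.integer(contourIds), ...)
})

#' AttachmentSiteModel: one tomogram's segmented telomere attachment site
#'
#' The full segmentation model of one telomere attachment site: anatomical
#' structure point sets, the traced LINC filaments, the pixel size used to
#' scale the raw voxel coordinates to nm, and (optionally) the axis of the
#' single microtubule present at the site.
#'
#' @slot siteId character(1) identifier.
#' @slot pixelSize numeric(1) nm/pixel (> 0) used at load time; coordinates
#'   in the object are already in nm.
#' @slot structures named list of [StructurePointSet-class], keyed by
#'   structure class.
#' @slot filaments list of [Filament-class].
#' @slot hasMicrotubule logical(1); TRUE iff a microtubule object exists.
#' @slot microtubuleAxis numeric matrix (k x 3) polyline of the microtubule
#'   axis in nm; 0 rows when absent.
#'
#' @param siteId,pixelSize,structures,filaments,hasMicrotubule,microtubuleAxis
#'   see slots.
#' @return `AttachmentSiteModel()` returns a validated object.
#' @seealso [readPointModel()], [quantifySite()]
#' @aliases AttachmentSiteModel
#' @export AttachmentSiteModel
#' @exportClass AttachmentSiteModel
AttachmentSiteModel <- setClass("AttachmentSiteModel", representation(
  siteId = "character",
  pixelSize = "numeric",
  structures = "list",
  filaments = "list",
  hasMicrotubule = "logical",
  microtubuleAxis = "matrix"
))

setValidity("AttachmentSiteModel", function(object) {
  if (length(object@siteId) != 1L) return("siteId must be a single string")
  if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
      object@pixelSize <= 0)
    return("pixelSize must be a single positive number (nm/pixel)")
  if (length(object@structures)) {
    if (is.null(names(object@structures)) ||
        !all(names(object@structures) %in% STRUCTURE_CLASSES))
      return("structures must be a list named by structure class")
    ok <- vapply(object@structures, is, logical(1), class2 = "StructurePointSet")
    if (!all(ok)) return("structures must contain StructurePointSet objects")
  }
  if (length(object@filaments)) {
    ok <- vapply(object@filaments, is, logical(1), class2 = "Filament")
    if (!all(ok)) return("filaments must contain Filament objects")
    ids <- vapply(object@filaments, filamentId, character(1))
    if (anyDuplicated(ids)) return("filament ids must be unique within a site")
  }
  if (length(object@hasMicrotubule) != 1L)
    return("hasMicrotubule must be a single logical")
  mtPresent <- "microtubule" %in% names(object@structures) ||
    nrow(object@microtubuleAxis) > 0
  if (object@hasMicrotubule != mtPresent)
    return("hasMicrotubule must be TRUE iff a microtubule object exists")
  TRUE
})

setMethod("initialize", "AttachmentSiteModel",
          function(.Object, siteId = "site", pixelSize = 1,
                   structures = list(), filaments = list(),
                   hasMicrotubule = NA, microtubuleAxis = matrix(0, 0, 3), ...) {
  microtubuleAxis <- as.matrix(microtubuleAxis)
  if (nrow(microtubuleAxis) > 0)
    microtubuleAxis <- as_coord_matrix(microtubuleAxis, "microtubuleAxis")
  if (is.na(hasMicrotubule))
    hasMicrotubule <- "microtubule" %in% names(structures) ||
      nrow(microtubuleAxis) > 0
  callNextMethod(.Object, siteId = as.character(siteId),
                 pixelSize = as.numeric(pixelSize), structures = structures,
                 filaments = filaments, hasMicrotubule = hasMicrotubule,
                 microtubuleAxis = microtubuleAxis, ...)
})

## ---- accessors ----

#' @rdname accessors
setMethod("siteId", "AttachmentSiteModel", function(x) x@siteId)
#' @rdname accessors
setMethod("pixelSize", "AttachmentSiteModel", function(x) x@pixelSize)
#' @rdname accessors
setMethod("filaments", "AttachmentSiteModel", function(x) x@filaments)
#' @rdname accessors
setMethod("nFilaments", "AttachmentSiteModel", function(x) length(x@filaments))
#' @rdname accessors
setMethod("structures", "AttachmentSiteModel", function(x) x@structures)
#' @rdname accessors
setMethod("hasMicrotubule", "AttachmentSiteModel", function(x) x@hasMicrotubule)
#' @rdname accessors
setMethod("microtubuleAxis", "AttachmentSiteModel", function(x) x@microtubuleAxis)

#' @rdname accessors
setMethod("filamentId", "Filament", function(x) x@filamentId)
#' @rdname accessors
setMethod("filamentPoints", "Filament", function(x) x@points)
#' @rdname accessors
setMethod("recordedWidth", "Filament", function(x) x@recordedWidth)

#' @rdname accessors
setMethod("structureClass", "StructurePointSet", function(x) x@structureClass)
#' @rdname accessors
setMethod("structurePoints", "StructurePointSet", function(x) x@points)

## ---- show methods ----

setMethod("show", "Filament", function(object) {
  cat("Filament '", object@filamentId, "': ", nrow(object@points), " points, ",
      sprintf("path %.1f nm, linear %.1f nm, stretch %.3f",
              pathLength(object), linearDistance(object), stretchFactor(object)),
      if (length(object@recordedWidth))
        sprintf(", width %.1f nm", object@recordedWidth) else "",
      "\n", sep = "")
})

setMethod("show", "StructurePointSet", function(object) {
  cat("StructurePointSet '", object@structureClass, "': ",
      nrow(object@points), " points in ",
      length(unique(object@contourIds)), " contour(s)\n", sep = "")
})

setMethod("show", "AttachmentSiteModel", function(object) {
  cat("AttachmentSiteModel '", object@siteId, "'\n", sep = "")
  cat("  pixel size: ", object@pixelSize, " nm/pixel (coordinates in nm)\n", sep = "")
  cat("  structures: ",
      if (length(object@structures))
        paste(names(object@structures), collapse = ", ") else "(none)",
      "\n", sep = "")
  cat("  filaments:  ", length(object@filaments), "\n", sep = "")
  cat("  microtubule: ", if (object@hasMicrotubule) "present" else "absent",
      "\n", sep = "")
})
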