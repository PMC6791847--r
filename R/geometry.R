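#' @include AllClasses.R
NULL

#' @rdname pathLength
setMethod("pathLength", "Filament", function(x) {
  sum(row_norms(diff(x@points)))
})

#' @rdname linearDistance
setMethod("linearDistance", "Filament", function(x) {
  sqrt(sum((x@points[nrow(x@points), ] - x@points[1, ])^2))
})

#' @rdname stretchFactor
setMethod("stretchFactor", "Filament", function(x) {
  L <- pathLength(x)
  if (L <= 0) stop("zero path length", call. = FALSE)
  linearDistance(x) / L
})

#' Locate a filament's origin at the inner nuclear membrane
#'
#' The origin of a LINC filament is the polyline point with the minimum
#' Euclidean distance to the lateral-element point set (its anchor at the
#' inner nuclear membrane). Ties are broken by the lowest point index.
#' If the origin is the last stored point, the filament is re-oriented
#' (points reversed) so the origin comes first; interior origins keep the
#' stored order.
#'
#' @param filament a [Filament-class].
#' @param anchor a [StructurePointSet-class] (normally the lateral
#'   element; pass the inner membrane for the membrane-based variant) or a
#'   bare n x 3 coordinate matrix.
#' @return A list with `origin` (length-3 nm coordinates), `originIndex`
#'   (index into the possibly re-oriented polyline), `filament` (the
#'   re-oriented [Filament-class]) and `minDistance` (nm to the anchor set).
#' @examples
#' f <- Filament("f1", rbind(c(0, 0, 0), c(0, 0, 50)))
#' le <- StructurePointSet("lateral_element", rbind(c(0, 0, -10)))
#' findOrigin(f, le)$originIndex
#' @export
findOrigin <- function(filament, anchor) {
  stopifnot(is(filament, "Filament"))
  pts <- if (is(anchor, "StructurePointSet")) structurePoints(anchor)
         else as_coord_matrix(anchor, "anchor")
  if (nrow(pts) == 0L)
    stop("anchor point set is empty", call. = FALSE)
  fp <- filamentPoints(filament)
  dmin <- sqrt(apply(cross_dist2(fp, pts), 1, min))
  idx <- which.min(dmin)  # which.min takes the first of tied minima
  if (idx == nrow(fp)) {
    filament@points <- fp[rev(seq_len(nrow(fp))), , drop = FALSE]
    idx <- 1L
  }
  list(origin = filament@points[idx, ], originIndex = idx,
       filament = filament, minDistance = dmin[which.min(dmin)])
}

#' Assign filament origins to the two attachment plates
#'
#' Every attachment site carries two plates (one per lateral element end);
#' filament origins cluster over them. When attachment-plate segmentation
#' points are available each origin is assigned to the nearer plate
#' centroid (plates identified by their contours, or split by 2-means when
#' segmented as a single blob). Without plate points, origins are
#' partitioned by 2-means with deterministic initialisation at the two
#' mutually farthest origins.
#'
#' @param origins n x 3 matrix of origin coordinates (nm).
#' @param plates optional [StructurePointSet-class] of class
#'   `attachment_plate`.
#' @return Integer vector of plate ids (0 or 1), one per origin. With
#'   fewer than 2 origins all are assigned plate 0 with a warning.
#' @export
assignPlate <- function(origins, plates = NULL) {
  origins <- as_coord_matrix(origins, "origins")
  n <- nrow(origins)
  if (n < 2L) {
    warning("fewer than 2 origins; all assigned to plate 0")
    return(rep(0L, n))
  }
  centres <- NULL
  if (!is.null(plates)) {
    pp <- structurePoints(plates)
    cid <- plates@contourIds
    if (length(unique(cid)) >= 2L) {
      ## two largest contours = the two plates
      sizes <- sort(table(cid), decreasing = TRUE)
      top <- as.integer(names(sizes)[1:2])
      centres <- rbind(colMeans(pp[cid == top[1], , drop = FALSE]),
                       colMeans(pp[cid == top[2], , drop = FALSE]))
    } else if (nrow(pp) >= 2L) {
      centres <- deterministic_2means(pp)$centers
    }
  }
  if (is.null(centres)) {
    km <- deterministic_2means(origins)
    lab <- km$cluster - 1L
  } else {
    lab <- as.integer(apply(cross_dist2(origins, centres), 1, which.min)) - 1L
  }
  ## canonical labelling: plate 0 has the smaller centroid coordinate
  ## along the axis where the two centroids differ most (stable under
  ## which cluster kmeans happens to call first)
  c0 <- colMeans(origins[lab == 0L, , drop = FALSE])
  c1 <- colMeans(origins[lab == 1L, , drop = FALSE])
  if (!anyNA(c0) && !anyNA(c1) && any(c0 != c1)) {
    j <- which.max(abs(c1 - c0))
    if (c1[j] < c0[j]) lab <- 1L - lab
  }
  lab
}

## Lloyd 2-means seeded at the two mutually farthest points: no RNG involved.
deterministic_2means <- function(pts) {
  d2 <- cross_dist2(pts, pts)
  ij <- arrayInd(which.max(d2), dim(d2))
  init <- pts[c(ij[1], ij[2]), , drop = FALSE]
  if (all(init[1, ] == init[2, ])) {
    # all points coincide: single cluster
    return(list(cluster = rep(1L, nrow(pts)), centers = init))
  }
  stats::kmeans(pts, centers = init, algorithm = "Lloyd", iter.max = 100)
}

#' Per-filament geometric metrics for one site
#'
#' Runs origin extraction, path/linear length, stretch factor and plate
#' assignment over all filaments of a site and returns one row per
#' filament. Nearest-neighbour and microtubule distances are filled in by
#' [nnOriginDistances()], [nnFilamentDistances()] and
#' [distanceToMicrotubule()] via [quantifySite()].
#'
#' @param model an [AttachmentSiteModel-class]; must contain a
#'   `lateral_element` structure and at least one filament.
#' @param anchorClass structure class used for origin extraction
#'   (default `"lateral_element"`; set `"inner_membrane"` for the
#'   membrane-based sensitivity variant).
#' @return A data.frame with columns `site_id`, `filament_id`, `plate_id`,
#'   `origin_x`, `origin_y`, `origin_z`, `origin_index`, `path_length_nm`,
#'   `linear_distance_nm`, `stretch_factor`, `recorded_width_nm`.
#' @export
filamentMetrics <- function(model, anchorClass = "lateral_element") {
  stopifnot(is(model, "AttachmentSiteModel"))
  if (!anchorClass %in% names(structures(model)))
    stop("site '", siteId(model), "' has no '", anchorClass,
         "' structure; cannot extract origins", call. = FALSE)
  fls <- filaments(model)
  if (!length(fls))
    stop("site '", siteId(model), "' has no filaments", call. = FALSE)
  anchor <- structures(model)[[anchorClass]]

  n <- length(fls)
  origins <- matrix(NA_real_, n, 3)
  originIdx <- integer(n)
  pl <- ld <- numeric(n)
  w <- rep(NA_real_, n)
  ids <- character(n)
  for (i in seq_len(n)) {
    o <- findOrigin(fls[[i]], anchor)
    f <- o$filament
    origins[i, ] <- o$origin
    originIdx[i] <- o$originIndex
    pl[i] <- pathLength(f)
    ld[i] <- linearDistance(f)
    ids[i] <- filamentId(f)
    if (length(recordedWidth(f))) w[i] <- recordedWidth(f)
  }
  plate <- if (n >= 2L)
    assignPlate(origins, structures(model)[["attachment_plate"]])
  else suppressWarnings(assignPlate(origins))

  data.frame(site_id = siteId(model), filament_id = ids, plate_id = plate,
             origin_x = origins[, 1], origin_y = origins[, 2],
             origin_z = origins[, 3], origin_index = originIdx,
             path_length_nm = pl, linear_distance_nm = ld,
             stretch_factor = ld / pl, recorded_width_nm = w,
             stringsAsFactors = FALSE)
}
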