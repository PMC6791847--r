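#' @include AllClasses.R
NULL

#' Read an attachment-site model from an IMOD point-export text file
#'
#' Parses the whitespace-delimited 5-column text dialect written by IMOD's
#' \code{model2point} (object id, contour id, x, y, z in pixels), scales
#' coordinates to nm, groups points into structures by the supplied label
#' map, and turns every contour of a \code{linc_filament} object into a
#' [Filament-class] (point order = file order).
#'
#' Coordinates are taken as voxel-centre positions; no origin shift is
#' applied because every downstream quantity is a relative distance.
#'
#' @param path path to the point file.
#' @param labelMap named vector or list mapping object ids (names, coercible
#'   to integer) to structure classes from [structureClasses()]. Every
#'   object id present in the file must be mapped.
#' @param pixelSize nm/pixel, a single positive number, or a length-3
#'   vector of per-axis scales for anisotropic tomograms.
#' @param siteId identifier stored in the model (default: file name).
#' @return An [AttachmentSiteModel-class] with all coordinates in nm.
#' @examples
#' tf <- tempfile(fileext = ".txt")
#' writeLines(c("1 1 0 0 0", "1 1 0 0 10"), tf)
#' m <- readPointModel(tf, c("1" = "linc_filament"), pixelSize = 1)
#' nFilaments(m)
#' @seealso [writePointModel()], [readCohort()]
#' @export
readPointModel <- function(path, labelMap, pixelSize, siteId = basename(path)) {
  stopifnot(length(path) == 1L)
  if (!file.exists(path)) stop("point file not found: ", path, call. = FALSE)
  scale <- as.numeric(pixelSize)
  if (!length(scale) %in% c(1L, 3L) || any(!is.finite(scale)) || any(scale <= 0))
    stop("pixelSize must be a positive scalar (nm/pixel) or length-3 vector",
         call. = FALSE)
  if (length(scale) == 1L) scale <- rep(scale, 3L)

  labelMap <- unlist(labelMap)
  if (is.null(names(labelMap)) || any(names(labelMap) == ""))
    stop("labelMap must be named by object id", call. = FALSE)
  bad <- setdiff(labelMap, STRUCTURE_CLASSES)
  if (length(bad))
    stop("labelMap contains unknown structure class(es): ",
         paste(unique(bad), collapse = ", "), call. = FALSE)

  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  rows <- which(keep)
  if (length(rows) == 0L) {
    recs <- data.frame(object = integer(0), contour = integer(0),
                       x = numeric(0), y = numeric(0), z = numeric(0))
  } else {
    toks <- strsplit(trimws(lines[rows]), "[[:space:]]+")
    nf <- lengths(toks)
    if (any(nf != 5L))
      stop("parse error at line ", rows[which(nf != 5L)[1L]],
           ": expected 5 whitespace-delimited columns, found ",
           nf[which(nf != 5L)[1L]], call. = FALSE)
    vals <- suppressWarnings(as.numeric(unlist(toks)))
    if (anyNA(vals)) {
      badLine <- rows[ceiling(which(is.na(vals))[1L] / 5)]
      stop("parse error at line ", badLine, ": non-numeric field", call. = FALSE)
    }
    m <- matrix(vals, ncol = 5L, byrow = TRUE)
    recs <- data.frame(object = as.integer(m[, 1]), contour = as.integer(m[, 2]),
                       x = m[, 3], y = m[, 4], z = m[, 5])
    if (any(recs$object < 1L) || any(recs$contour < 1L))
      stop("object and contour ids must be >= 1", call. = FALSE)
  }

  unmapped <- setdiff(unique(recs$object), as.integer(names(labelMap)))
  if (length(unmapped))
    stop("labeling error: object id(s) not in label map: ",
         paste(unmapped, collapse = ", "), call. = FALSE)

  # pixels -> nm
  recs$x <- recs$x * scale[1]; recs$y <- recs$y * scale[2]; recs$z <- recs$z * scale[3]
  cls <- unname(labelMap[as.character(recs$object)])

  filamentList <- list()
  structureList <- list()
  mtAxis <- matrix(0, 0, 3)

  for (obj in sort(unique(recs$object))) {
    sel <- recs$object == obj
    objCls <- unname(labelMap[as.character(obj)])
    sub <- recs[sel, , drop = FALSE]
    if (objCls == "linc_filament") {
      for (ct in unique(sub$contour)) {
        p <- as.matrix(sub[sub$contour == ct, c("x", "y", "z")])
        if (nrow(p) < 2L)
          stop("validation error: filament contour ", ct, " of object ", obj,
               " has fewer than 2 points", call. = FALSE)
        filamentList[[length(filamentList) + 1L]] <-
          Filament(sprintf("o%d_c%d", obj, ct), p)
      }
    } else {
      pts <- as.matrix(sub[, c("x", "y", "z")])
      if (objCls %in% names(structureList)) {
        prev <- structureList[[objCls]]
        pts <- rbind(structurePoints(prev), pts)
        cids <- c(prev@contourIds, max(prev@contourIds) + as.integer(factor(sub$contour)))
      } else {
        cids <- as.integer(factor(sub$contour))
      }
      structureList[[objCls]] <- StructurePointSet(objCls, pts, cids)
      if (objCls == "microtubule" && nrow(mtAxis) == 0L)
        mtAxis <- as.matrix(sub[, c("x", "y", "z")])
    }
  }

  AttachmentSiteModel(siteId = siteId, pixelSize = mean(scale),
                      structures = structureList, filaments = filamentList,
                      hasMicrotubule = "microtubule" %in% cls,
                      microtubuleAxis = mtAxis)
}

## Canonical object-id layout used when writing a model back out:
## structures first (file order = class order below), then one object holding
## all filament contours.
write_order <- c("lateral_element", "central_element", "attachment_plate",
                 "inner_membrane", "outer_membrane", "microtubule", "other")

#' Write an attachment-site model as an IMOD-style point text file
#'
#' Inverse of [readPointModel()]: emits one `object contour x y z` line per
#' point, with coordinates converted back to pixels using the model's pixel
#' size. Structure classes are written first (one object each), then a
#' single object containing one contour per filament. The label map that
#' makes the file readable again is returned invisibly (and can be written
#' as a YAML config via [writeCohort()]).
#'
#' @param model an [AttachmentSiteModel-class].
#' @param path output file path.
#' @param digits decimal places for coordinates (default 4; round-trip is
#'   exact to this precision).
#' @return Invisibly, the named label map (object id -> structure class)
#'   describing the file just written.
#' @seealso [readPointModel()]
#' @export
writePointModel <- function(model, path, digits = 4) {
  stopifnot(is(model, "AttachmentSiteModel"))
  validObject(model)
  s <- model@pixelSize
  con <- try(file(path, "w"), silent = TRUE)
  if (inherits(con, "try-error"))
    stop("I/O error: cannot open '", path, "' for writing", call. = FALSE)
  on.exit(close(con))

  fmt <- paste0("%d %d %.", digits, "f %.", digits, "f %.", digits, "f")
  labelMap <- character(0)
  objId <- 0L

  present <- intersect(write_order, names(model@structures))
  for (clsName in present) {
    objId <- objId + 1L
    labelMap[as.character(objId)] <- clsName
    st <- model@structures[[clsName]]
    p <- structurePoints(st) / s
    cid <- st@contourIds
    writeLines(sprintf(fmt, objId, cid, p[, 1], p[, 2], p[, 3]), con)
  }
  if (length(model@filaments)) {
    objId <- objId + 1L
    labelMap[as.character(objId)] <- "linc_filament"
    for (i in seq_along(model@filaments)) {
      p <- filamentPoints(model@filaments[[i]]) / s
      writeLines(sprintf(fmt, objId, i, p[, 1], p[, 2], p[, 3]), con)
    }
  }
  invisible(labelMap)
}

#' Read a cohort of attachment-site models from a YAML config
#'
#' The config lists one entry per site under `sites:`, each with `path`
#' (point file, relative paths resolved against the config file),
#' `pixel_size_nm`, a `labels:` mapping of object id to structure class,
#' and optionally `site_id` and `has_microtubule` (cross-checked against
#' the file content when given).
#'
#' @param configPath path to the YAML config.
#' @return A list of [AttachmentSiteModel-class] objects.
#' @seealso [writeCohort()], [quantifyCohort()]
#' @export
readCohort <- function(configPath) {
  cfg <- yaml::read_yaml(configPath)
  if (is.null(cfg$sites) || !length(cfg$sites))
    stop("config has no 'sites' entries", call. = FALSE)
  base <- dirname(normalizePath(configPath))
  lapply(cfg$sites, function(sc) {
    p <- sc$path
    if (!file.exists(p)) p <- file.path(base, sc$path)
    m <- readPointModel(p, unlist(sc$labels), sc$pixel_size_nm,
                        siteId = sc$site_id %||% basename(sc$path))
    if (!is.null(sc$has_microtubule) &&
        isTRUE(sc$has_microtubule) != hasMicrotubule(m))
      stop("site '", siteId(m), "': has_microtubule in config (",
           sc$has_microtubule, ") contradicts file content", call. = FALSE)
    m
  })
}

#' Write a cohort of site models to a directory
#'
#' Writes one point file per site plus a `cohort.yaml` config readable by
#' [readCohort()]. When ground truth and a manifest are supplied (as from
#' [generateCohort()]), they are written alongside as `ground_truth.csv`
#' and `manifest.json`.
#'
#' @param models list of [AttachmentSiteModel-class].
#' @param dir output directory (created if needed).
#' @param groundTruth optional data.frame of per-filament generating
#'   parameters.
#' @param manifest optional list serialised to JSON.
#' @return Invisibly, the path of the YAML config written.
#' @export
writeCohort <- function(models, dir, groundTruth = NULL, manifest = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sites <- vector("list", length(models))
  for (i in seq_along(models)) {
    m <- models[[i]]
    fn <- sprintf("%s.txt", siteId(m))
    lm <- writePointModel(m, file.path(dir, fn))
    sites[[i]] <- list(site_id = siteId(m), path = fn,
                       pixel_size_nm = pixelSize(m),
                       has_microtubule = hasMicrotubule(m),
                       labels = as.list(lm))
  }
  cfgPath <- file.path(dir, "cohort.yaml")
  yaml::write_yaml(list(sites = sites), cfgPath)
  if (!is.null(groundTruth))
    utils::write.csv(groundTruth, file.path(dir, "ground_truth.csv"),
                     row.names = FALSE)
  if (!is.null(manifest))
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(cfgPath)
}
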