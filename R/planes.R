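#' @include AllClasses.R
NULL

#' Fit a plane to filament origins by principal component analysis
#'
#' The origins of the filaments over one attachment plate form a flat
#' patch apposed to the inner nuclear membrane. PCA of the origin cloud
#' yields the patch plane: the first two principal directions span it, the
#' third is its normal. In-plane extents are min-max projection ranges —
#' physical side lengths of the patch — and `extent1` (the larger) is the
#' side running parallel to the nuclear envelope used in the
#' dynein-dynactin packing arithmetic (see [maxDyneinComplexes()]).
#'
#' @param origins n x 3 matrix (nm) of origins, n >= 3, not all collinear.
#' @param plateId optional plate label carried into the result.
#' @return An object of class `PlaneFit`: a list with `plate_id`,
#'   `centroid`, `axis1`, `axis2`, `normal` (unit vectors), `extent1`,
#'   `extent2` (nm, `extent1 >= extent2`), `rms_residual` (nm) and
#'   `n_points`.
#' @examples
#' rect <- rbind(c(0, 0, 7), c(150, 0, 7), c(0, 60, 7), c(150, 60, 7))
#' fitPlanePCA(rect)$extent1  # 150
#' @export
fitPlanePCA <- function(origins, plateId = NA_integer_) {
  p <- as_coord_matrix(origins, "origins")
  if (nrow(p) < 3L)
    stop("plane fit needs at least 3 points", call. = FALSE)
  pc <- prcomp(p, center = TRUE, scale. = FALSE)
  if (pc$sdev[2] < 1e-9 * max(pc$sdev[1], 1))
    stop("points are collinear; plane undetermined", call. = FALSE)
  scores <- pc$x
  e1 <- diff(range(scores[, 1]))
  e2 <- diff(range(scores[, 2]))
  structure(list(
    plate_id = plateId,
    centroid = unname(pc$center),
    axis1 = unname(pc$rotation[, 1]),
    axis2 = unname(pc$rotation[, 2]),
    normal = unname(pc$rotation[, 3]),
    extent1 = e1, extent2 = e2,
    rms_residual = sqrt(mean(scores[, 3]^2)),
    n_points = nrow(p)
  ), class = "PlaneFit")
}

#' @export
print.PlaneFit <- function(x, ...) {
  cat(sprintf(
    "PlaneFit (plate %s): %d points, extents %.1f x %.1f nm, RMS residual %.2f nm\n",
    as.character(x$plate_id), x$n_points, x$extent1, x$extent2, x$rms_residual))
  invisible(x)
}

#' Plane fits for both attachment plates of a site
#'
#' Applies [fitPlanePCA()] to the origins of each plate (per the
#' `plate_id` column of the metrics). Plates with fewer than 3 origins are
#' skipped with a warning.
#'
#' @param metrics per-filament metrics of one site ([filamentMetrics()]).
#' @return A list of `PlaneFit` objects, one per fitted plate.
#' @export
platePlaneFits <- function(metrics) {
  fits <- list()
  for (pid in sort(unique(metrics$plate_id))) {
    sm <- metrics[metrics$plate_id == pid, , drop = FALSE]
    if (nrow(sm) < 3L) {
      warning("plate ", pid, " of site '", sm$site_id[1],
              "' has < 3 origins; plane fit skipped")
      next
    }
    o <- as.matrix(sm[, c("origin_x", "origin_y", "origin_z")])
    fit <- try(fitPlanePCA(o, plateId = pid), silent = TRUE)
    if (inherits(fit, "try-error")) {
      warning("plane fit failed for plate ", pid, " of site '",
              sm$site_id[1], "'")
      next
    }
    fits[[length(fits) + 1L]] <- fit
  }
  fits
}
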