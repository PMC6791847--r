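#' @include AllClasses.R
NULL

#' Minimum distance between two filaments
#'
#' Minimum Euclidean distance over all pairs of stored polyline points of
#' the two filaments (pure point-set distance, matching how segmented
#' models are compared; see [minPairDistanceSegments()] for the
#' segment-interpolated variant). Symmetric in its arguments.
#'
#' @param a,b [Filament-class] objects or n x 3 coordinate matrices.
#' @return Distance in nm.
#' @export
minPairDistance <- function(a, b) {
  pa <- if (is(a, "Filament")) filamentPoints(a) else as_coord_matrix(a, "a")
  pb <- if (is(b, "Filament")) filamentPoints(b) else as_coord_matrix(b, "b")
  if (nrow(pa) == 0L || nrow(pb) == 0L)
    stop("empty filament", call. = FALSE)
  sqrt(min(cross_dist2(pa, pb)))
}

#' Segment-interpolated minimum distance between two filaments
#'
#' Sensitivity-analysis variant of [minPairDistance()]: minimum distance
#' between the two polylines treated as continuous curves (closest
#' approach over every segment pair).
#'
#' @inheritParams minPairDistance
#' @return Distance in nm (always <= the vertex-only distance).
#' @export
minPairDistanceSegments <- function(a, b) {
  pa <- if (is(a, "Filament")) filamentPoints(a) else as_coord_matrix(a, "a")
  pb <- if (is(b, "Filament")) filamentPoints(b) else as_coord_matrix(b, "b")
  if (nrow(pa) == 0L || nrow(pb) == 0L)
    stop("empty filament", call. = FALSE)
  if (nrow(pa) == 1L) return(min(points_to_polyline_dist(pa, pb)))
  if (nrow(pb) == 1L) return(min(points_to_polyline_dist(pb, pa)))
  best <- Inf
  for (i in seq_len(nrow(pa) - 1L)) for (j in seq_len(nrow(pb) - 1L)) {
    d2 <- seg_seg_dist2(pa[i, ], pa[i + 1L, ], pb[j, ], pb[j + 1L, ])
    if (d2 < best) best <- d2
  }
  sqrt(best)
}

#' Nearest-neighbour distances between filament origins
#'
#' For each filament of a site, the Euclidean distance from its origin to
#' the nearest other filament origin of the same site. Sites are processed
#' independently; a site with a single filament contributes no sample (a
#' warning is raised).
#'
#' @param metrics data.frame as returned by [filamentMetrics()] (or
#'   [quantifySite()]/[quantifyCohort()]), possibly spanning several sites.
#' @return A data.frame with columns `site_id`, `filament_id`, `kind`
#'   (`"origin_nn"`), `distance_nm`, `neighbor_id`.
#' @seealso [nnFilamentDistances()], [globalMinimumShift()]
#' @export
nnOriginDistances <- function(metrics) {
  out <- lapply(split(metrics, metrics$site_id), function(sm) {
    n <- nrow(sm)
    if (n < 2L) {
      warning("site '", sm$site_id[1], "' has a single filament; skipped")
      return(NULL)
    }
    o <- as.matrix(sm[, c("origin_x", "origin_y", "origin_z")])
    d <- cross_dist(o, o)
    diag(d) <- Inf
    j <- apply(d, 1, which.min)
    data.frame(site_id = sm$site_id, filament_id = sm$filament_id,
               kind = "origin_nn", distance_nm = d[cbind(seq_len(n), j)],
               neighbor_id = sm$filament_id[j], stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Nearest-neighbour whole-filament distances
#'
#' For each filament, the minimum [minPairDistance()] to any other
#' filament of the same site — the distance to its nearest neighbour over
#' the entire filament lengths. Because origins are member points of the
#' polylines, this is never larger than the origin-to-origin distance for
#' the same neighbour.
#'
#' @param models a single [AttachmentSiteModel-class] or a list of them.
#' @return A data.frame with columns `site_id`, `filament_id`, `kind`
#'   (`"filament_nn"`), `distance_nm`, `neighbor_id`.
#' @export
nnFilamentDistances <- function(models) {
  if (is(models, "AttachmentSiteModel")) models <- list(models)
  out <- lapply(models, function(m) {
    fls <- filaments(m)
    n <- length(fls)
    if (n < 2L) {
      warning("site '", siteId(m), "' has fewer than 2 filaments; skipped")
      return(NULL)
    }
    ids <- vapply(fls, filamentId, character(1))
    dm <- matrix(Inf, n, n)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      dm[i, j] <- dm[j, i] <- minPairDistance(fls[[i]], fls[[j]])
    }
    j <- apply(dm, 1, which.min)
    data.frame(site_id = siteId(m), filament_id = ids, kind = "filament_nn",
               distance_nm = dm[cbind(seq_len(n), j)], neighbor_id = ids[j],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Global minimum spacing of a nearest-neighbour distance sample
#'
#' The nearest-neighbour histograms resemble an exponential distribution
#' shifted away from zero; the shift is read as a global minimum spacing
#' between filaments (steric exclusion). Two estimators are reported: the
#' sample minimum (the headline value) and the maximum-likelihood fit of a
#' shifted exponential, for which the location estimate coincides with the
#' sample minimum and the rate is `1 / (mean - min)`.
#'
#' @param distances numeric vector of nearest-neighbour distances (nm), or
#'   a data.frame from [nnOriginDistances()]/[nnFilamentDistances()].
#' @return A list with `sample_min` (nm), `shift` (nm, MLE location),
#'   `rate` (1/nm; `NA` with `degenerate = TRUE` when all values are
#'   equal) and `n`.
#' @export
globalMinimumShift <- function(distances) {
  if (is.data.frame(distances)) distances <- distances$distance_nm
  x <- as.numeric(distances)
  if (!length(x) || anyNA(x)) stop("empty or NA distance sample", call. = FALSE)
  mn <- min(x)
  spread <- mean(x) - mn
  degenerate <- spread <= 0
  list(sample_min = mn, shift = mn,
       rate = if (degenerate) NA_real_ else 1 / spread,
       degenerate = degenerate, n = length(x))
}

#' Fixed-bin-width histogram of a distance sample
#'
#' Histogram counts on a fixed-width grid starting at 0 (bins
#' `[0, w), [w, 2w), ...`), the representation in which a spacing floor
#' shows up as empty leading bins. Default bin width 2 nm, the
#' granularity at which the global minima of interest are read.
#'
#' @param values numeric vector of distances (nm), all >= 0.
#' @param binWidth bin width in nm (default 2).
#' @return A data.frame with `bin_start_nm`, `bin_end_nm`, `count`.
#' @export
distanceHistogram <- function(values, binWidth = 2) {
  x <- as.numeric(values)
  if (!length(x) || anyNA(x)) stop("empty or NA distance sample", call. = FALSE)
  if (any(x < 0)) stop("distances must be >= 0", call. = FALSE)
  if (binWidth <= 0) stop("binWidth must be > 0", call. = FALSE)
  idx <- floor(x / binWidth)
  nBins <- max(idx) + 1L
  counts <- tabulate(idx + 1L, nbins = nBins)
  data.frame(bin_start_nm = (seq_len(nBins) - 1L) * binWidth,
             bin_end_nm = seq_len(nBins) * binWidth,
             count = counts)
}

#' Gaussian kernel density curve with mode counting
#'
#' Thin wrapper around [stats::density()] (Gaussian kernel, Silverman's
#' rule-of-thumb bandwidth by default) that also reports the local maxima
#' of the estimate, used to check length distributions for subpopulations.
#'
#' @param values numeric vector (>= 2 distinct values).
#' @param bandwidth kernel bandwidth in data units; default
#'   `stats::bw.nrd0(values)`.
#' @param n grid size (default 512).
#' @param modeThreshold relative height (fraction of the global maximum)
#'   below which local maxima are not counted (default 0.05).
#' @return A list with `grid`, `density`, `bandwidth`, `modes` (grid
#'   locations of counted local maxima) and `n_modes`.
#' @export
densityCurve <- function(values, bandwidth = NULL, n = 512, modeThreshold = 0.05) {
  x <- as.numeric(values)
  if (length(x) < 2L) stop("need at least 2 values", call. = FALSE)
  if (stats::var(x) == 0) stop("degenerate sample: zero variance", call. = FALSE)
  bw <- bandwidth %||% bw.nrd0(x)
  d <- density(x, bw = bw, n = n)
  y <- d$y
  isMax <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n], FALSE)
  isMax <- isMax & y > modeThreshold * max(y)
  list(grid = d$x, density = y, bandwidth = bw,
       modes = d$x[isMax], n_modes = sum(isMax))
}

#' @importFrom stats var
NULL
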