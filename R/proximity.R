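#' @include AllClasses.R
NULL

#' Distance from a filament to the microtubule axis
#'
#' Minimum Euclidean distance from any filament polyline point to the
#' microtubule axis polyline, computed point-to-segment (the axis is a
#' continuous curve, not a vertex set). Distances are to the centreline;
#' an optional radius offset can be subtracted (clamped at 0) when a
#' surface distance is wanted.
#'
#' @param filament a [Filament-class].
#' @param mtAxis k x 3 polyline of the axis (nm), or an
#'   [AttachmentSiteModel-class] whose axis is used.
#' @param radiusOffset nm subtracted from the centreline distance
#'   (default 0).
#' @return Distance in nm, or `NA` when the site has no microtubule.
#' @export
distanceToMicrotubule <- function(filament, mtAxis, radiusOffset = 0) {
  if (is(mtAxis, "AttachmentSiteModel")) {
    if (!hasMicrotubule(mtAxis)) return(NA_real_)
    mtAxis <- microtubuleAxis(mtAxis)
  }
  mtAxis <- as_coord_matrix(mtAxis, "mtAxis")
  if (nrow(mtAxis) == 0L) return(NA_real_)
  d <- min(points_to_polyline_dist(filamentPoints(filament), mtAxis))
  max(0, d - radiusOffset)
}

#' Split filaments into close/far groups at a proximity cutoff
#'
#' Filaments at microtubule-bearing sites are `close` when their
#' microtubule distance is strictly below the cutoff, `far` otherwise.
#'
#' @param mtDistances numeric vector of microtubule distances (nm), or a
#'   metrics data.frame with an `mt_distance_nm` column.
#' @param cutoff nm, > 0.
#' @return Logical vector, `TRUE` = close. An all-`FALSE` result carries
#'   attribute `empty_group = "close"` (and conversely), as a flag.
#' @export
classifyByCutoff <- function(mtDistances, cutoff) {
  if (is.data.frame(mtDistances)) mtDistances <- mtDistances$mt_distance_nm
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0)
    stop("cutoff must be a single positive number (nm)", call. = FALSE)
  x <- as.numeric(mtDistances)
  if (anyNA(x))
    stop("NA microtubule distances: restrict to microtubule-bearing sites",
         call. = FALSE)
  close <- x < cutoff
  if (!any(close)) attr(close, "empty_group") <- "close"
  if (all(close)) attr(close, "empty_group") <- "far"
  close
}

#' Scan proximity cutoffs for the linear-distance difference
#'
#' For each cutoff, filaments of microtubule-bearing sites are split into
#' close/far groups ([classifyByCutoff()]) and the difference of mean
#' end-to-end linear distances (close minus far) is computed together
#' with a Wilcoxon rank-sum p-value. Cutoffs that leave a group empty
#' yield an undefined (NA) row.
#'
#' P-values are reported raw, one per cutoff, as a scan profile; no
#' multiplicity correction is applied.
#'
#' @param metrics data.frame with `mt_distance_nm` and
#'   `linear_distance_nm` columns, restricted to microtubule-bearing
#'   sites.
#' @param cutoffs numeric vector of cutoffs (nm); default 20-300 nm in
#'   2 nm steps, bracketing the plateau seen in real data.
#' @return A data.frame with one row per cutoff: `cutoff_nm`, `n_close`,
#'   `n_far`, `mean_linear_close`, `mean_linear_far`, `mean_difference`,
#'   `wilcoxon_p`.
#' @export
cutoffScan <- function(metrics, cutoffs = seq(20, 300, by = 2)) {
  if (!length(cutoffs)) stop("empty cutoff list", call. = FALSE)
  x <- metrics$mt_distance_nm
  y <- metrics$linear_distance_nm
  if (anyNA(x))
    stop("NA microtubule distances: restrict to microtubule-bearing sites",
         call. = FALSE)
  rows <- lapply(cutoffs, function(ct) {
    cl <- x < ct
    nc <- sum(cl); nf <- sum(!cl)
    if (nc < 2L || nf < 2L)
      return(data.frame(cutoff_nm = ct, n_close = nc, n_far = nf,
                        mean_linear_close = NA_real_, mean_linear_far = NA_real_,
                        mean_difference = NA_real_, wilcoxon_p = NA_real_))
    mc <- mean(y[cl]); mf <- mean(y[!cl])
    p <- wilcoxonRankSum(y[cl], y[!cl])$p_value
    data.frame(cutoff_nm = ct, n_close = nc, n_far = nf,
               mean_linear_close = mc, mean_linear_far = mf,
               mean_difference = mc - mf, wilcoxon_p = p)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare stretch factors between microtubule cohorts
#'
#' Compares the stretch-factor distributions of filaments at sites with a
#' microtubule against sites without: difference of means, Wilcoxon
#' rank-sum test, and per-cohort density curves (skipped with a warning
#' for cohorts of fewer than 2 distinct values).
#'
#' @param stretchWithMt,stretchWithoutMt numeric vectors of stretch
#'   factors, or metrics data.frames with a `stretch_factor` column.
#' @return A list with `mean_with_mt`, `mean_without_mt`,
#'   `mean_difference` (with minus without), `test` (a `TestResult`),
#'   `n_with_mt`, `n_without_mt` and `density` (list of two
#'   [densityCurve()] results or `NULL`).
#' @export
stretchCohortCompare <- function(stretchWithMt, stretchWithoutMt) {
  if (is.data.frame(stretchWithMt)) stretchWithMt <- stretchWithMt$stretch_factor
  if (is.data.frame(stretchWithoutMt)) stretchWithoutMt <- stretchWithoutMt$stretch_factor
  a <- as.numeric(stretchWithMt); b <- as.numeric(stretchWithoutMt)
  if (!length(a) || !length(b)) stop("empty cohort", call. = FALSE)
  dens <- NULL
  if (length(a) >= 2L && length(b) >= 2L && stats::var(a) > 0 && stats::var(b) > 0) {
    dens <- list(with_mt = densityCurve(a), without_mt = densityCurve(b))
  } else {
    warning("cohort too small/degenerate for density estimation; means only")
  }
  test <- if (length(a) >= 1L && length(b) >= 1L) wilcoxonRankSum(a, b) else NULL
  list(mean_with_mt = mean(a), mean_without_mt = mean(b),
       mean_difference = mean(a) - mean(b), test = test,
       n_with_mt = length(a), n_without_mt = length(b), density = dens)
}
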