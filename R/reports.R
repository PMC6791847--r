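#' @include AllClasses.R
NULL

#' Quantify one attachment site end to end
#'
#' Runs the whole per-site pipeline: per-filament geometry
#' ([filamentMetrics()]), origin and whole-filament nearest-neighbour
#' distances, plate plane fits ([platePlaneFits()]) and, when a
#' microtubule is present, per-filament microtubule distances.
#'
#' @param model an [AttachmentSiteModel-class] with a lateral element and
#'   at least one filament.
#' @param anchorClass passed to [filamentMetrics()].
#' @param verbose log per-stage counts to stderr.
#' @return A list with `metrics` (per-filament data.frame, including
#'   `nn_origin_nm`, `nn_filament_nm` and `mt_distance_nm` columns),
#'   `planes` (list of `PlaneFit`), `distance_samples` (long-format
#'   data.frame) and `site_summary` (one-row data.frame).
#' @export
quantifySite <- function(model, anchorClass = "lateral_element",
                         verbose = FALSE) {
  stopifnot(is(model, "AttachmentSiteModel"))
  say <- function(...) if (verbose) message("[", siteId(model), "] ", ...)

  metrics <- filamentMetrics(model, anchorClass = anchorClass)
  say(nrow(metrics), " filaments quantified")

  nnO <- if (nrow(metrics) >= 2L) nnOriginDistances(metrics) else NULL
  nnF <- if (nrow(metrics) >= 2L) nnFilamentDistances(model) else NULL
  metrics$nn_origin_nm <- if (!is.null(nnO))
    nnO$distance_nm[match(metrics$filament_id, nnO$filament_id)] else NA_real_
  metrics$nn_filament_nm <- if (!is.null(nnF))
    nnF$distance_nm[match(metrics$filament_id, nnF$filament_id)] else NA_real_

  metrics$mt_distance_nm <- NA_real_
  if (hasMicrotubule(model)) {
    axis <- microtubuleAxis(model)
    metrics$mt_distance_nm <- vapply(
      filaments(model), distanceToMicrotubule, numeric(1), mtAxis = axis)
    say("microtubule present; distances computed")
  }

  fits <- suppressWarnings(platePlaneFits(metrics))
  say(length(fits), " plate plane(s) fitted")

  siteSummary <- data.frame(
    site_id = siteId(model),
    n_filaments = nrow(metrics),
    has_microtubule = hasMicrotubule(model),
    mean_length_nm = mean(metrics$path_length_nm),
    sd_length_nm = sd(metrics$path_length_nm),
    mean_stretch = mean(metrics$stretch_factor),
    min_nn_origin_nm = if (!is.null(nnO)) min(nnO$distance_nm) else NA_real_,
    min_nn_filament_nm = if (!is.null(nnF)) min(nnF$distance_nm) else NA_real_,
    mean_plane_extent1_nm = if (length(fits))
      mean(vapply(fits, `[[`, numeric(1), "extent1")) else NA_real_,
    stringsAsFactors = FALSE)

  list(metrics = metrics, planes = fits,
       distance_samples = rbind(nnO, nnF), site_summary = siteSummary)
}

#' Quantify a cohort of sites
#'
#' Applies [quantifySite()] to each model; per-site failures are caught,
#' reported, and surfaced in the `failures` element rather than aborting
#' the rest of the cohort.
#'
#' @param models list of [AttachmentSiteModel-class] (e.g. from
#'   [readCohort()] or [generateCohort()]).
#' @param verbose log per-stage counts to stderr.
#' @return A list with `metrics` (row-bound per-filament table), `sites`
#'   (row-bound site summaries), `planes` (named per site),
#'   `distance_samples`, and `failures` (named character vector of error
#'   messages, empty on full success).
#' @export
quantifyCohort <- function(models, verbose = FALSE) {
  if (is(models, "AttachmentSiteModel")) models <- list(models)
  if (!length(models)) stop("no site models supplied", call. = FALSE)
  res <- lapply(models, function(m) {
    tryCatch(quantifySite(m, verbose = verbose),
             error = function(e) structure(conditionMessage(e), class = "siteError"))
  })
  names(res) <- vapply(models, siteId, character(1))
  failed <- vapply(res, inherits, logical(1), what = "siteError")
  if (any(failed))
    warning("site(s) failed: ",
            paste(names(res)[failed], unlist(res[failed]),
                  sep = ": ", collapse = "; "))
  ok <- res[!failed]
  list(metrics = do.call(rbind, c(lapply(ok, `[[`, "metrics"),
                                  list(make.row.names = FALSE))),
       sites = do.call(rbind, c(lapply(ok, `[[`, "site_summary"),
                                list(make.row.names = FALSE))),
       planes = lapply(ok, `[[`, "planes"),
       distance_samples = do.call(rbind, c(lapply(ok, `[[`, "distance_samples"),
                                           list(make.row.names = FALSE))),
       failures = unlist(res[failed]))
}

#' Compare the with- and without-microtubule cohorts
#'
#' The full comparison battery over a quantified cohort: KS test on
#' per-site filament counts, t-test on filament path lengths, KS test on
#' whole-filament nearest-neighbour distances, rank-sum comparison of
#' stretch factors, the proximity cutoff scan at microtubule-bearing
#' sites, and the force model evaluated at the measured mean plate-plane
#' extent and mean per-site count.
#'
#' @param quantified result of [quantifyCohort()].
#' @param cutoffs cutoff grid for [cutoffScan()].
#' @param forceParams base [forceModelParams()]; its interaction length
#'   is replaced by the measured mean plane extent.
#' @return A list of class `CohortReport`: `group_sizes`, `counts_ks`,
#'   `lengths_t`, `nn_filament_ks`, `stretch` (from
#'   [stretchCohortCompare()]), `cutoff_scan`, `origin_spacing` /
#'   `filament_spacing` ([globalMinimumShift()] per cohort), and
#'   `force_model`. When only one group is present the comparisons are
#'   `NULL` and `note` says so.
#' @export
compareCohorts <- function(quantified, cutoffs = seq(20, 300, by = 2),
                           forceParams = forceModelParams()) {
  sites <- quantified$sites
  metrics <- quantified$metrics
  if (is.null(sites) || !nrow(sites)) stop("empty cohort", call. = FALSE)
  withMt <- sites$has_microtubule
  siteHasMt <- metrics$site_id %in% sites$site_id[withMt]

  report <- list(group_sizes = c(with_mt = sum(withMt),
                                 without_mt = sum(!withMt)))
  oneGroup <- !any(withMt) || all(withMt)
  if (oneGroup) {
    report$note <- "single-group cohort: comparisons skipped"
    report[c("counts_ks", "lengths_t", "nn_filament_ks", "stretch",
             "cutoff_scan")] <- list(NULL)
  } else {
    report$counts_ks <- ksTwoSample(sites$n_filaments[withMt],
                                    sites$n_filaments[!withMt],
                                    mode = "asymptotic")
    report$lengths_t <- tTwoSample(metrics$path_length_nm[siteHasMt],
                                   metrics$path_length_nm[!siteHasMt])
    nnf <- metrics$nn_filament_nm
    report$nn_filament_ks <- ksTwoSample(nnf[siteHasMt & !is.na(nnf)],
                                         nnf[!siteHasMt & !is.na(nnf)],
                                         mode = "asymptotic")
    report$stretch <- stretchCohortCompare(metrics[siteHasMt, ],
                                           metrics[!siteHasMt, ])
    mtMetrics <- metrics[siteHasMt & !is.na(metrics$mt_distance_nm), ]
    report$cutoff_scan <- if (nrow(mtMetrics) >= 4L)
      cutoffScan(mtMetrics, cutoffs) else NULL
  }

  report$origin_spacing <- globalMinimumShift(
    metrics$nn_origin_nm[!is.na(metrics$nn_origin_nm)])
  report$filament_spacing <- globalMinimumShift(
    metrics$nn_filament_nm[!is.na(metrics$nn_filament_nm)])

  ext <- sites$mean_plane_extent1_nm
  meanExtent <- if (any(!is.na(ext))) mean(ext, na.rm = TRUE)
                else forceParams$interactionLengthPerPlate
  fp <- forceParams
  fp$interactionLengthPerPlate <- meanExtent
  report$force_model <- nucleusTotals(mean(sites$n_filaments), fp)
  report$mean_plane_extent1_nm <- meanExtent

  class(report) <- "CohortReport"
  report
}

#' @export
print.CohortReport <- function(x, ...) {
  cat("CohortReport: ", x$group_sizes["with_mt"], " site(s) with / ",
      x$group_sizes["without_mt"], " without microtubule\n", sep = "")
  if (!is.null(x$note)) cat("  note: ", x$note, "\n", sep = "")
  if (!is.null(x$counts_ks))
    cat(sprintf("  counts KS: D = %.4f, p = %.3f\n",
                x$counts_ks$statistic, x$counts_ks$p_value))
  if (!is.null(x$lengths_t))
    cat(sprintf("  lengths t: t = %.3f, p = %.3f\n",
                x$lengths_t$statistic, x$lengths_t$p_value))
  if (!is.null(x$stretch))
    cat(sprintf("  stretch difference (with - without): %.4f (p = %.3g)\n",
                x$stretch$mean_difference, x$stretch$test$p_value))
  cat(sprintf("  origin spacing: min %.2f nm; filament spacing: min %.2f nm\n",
              x$origin_spacing$sample_min, x$filament_spacing$sample_min))
  cat(sprintf("  mean plate-plane extent: %.1f nm\n", x$mean_plane_extent1_nm))
  print(x$force_model)
  invisible(x)
}

#' Serialise metrics and reports to CSV/JSON
#'
#' `writeMetricsCsv()` writes any of the package's data.frame outputs as
#' comma-separated UTF-8 with a header row. `writeReportJson()`
#' serialises a [compareCohorts()] report (or any list) as JSON at full
#' numeric precision.
#'
#' @param x data.frame (for CSV) or list/report (for JSON).
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
writeMetricsCsv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname writeMetricsCsv
#' @export
writeReportJson <- function(x, path) {
  x <- rapply(unclass(x), unclass, how = "replace")
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
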