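make_quantified_cohort <- function(seed, nSites = 4, nFil = 16,
                                   mtFraction = 0.5, ...) {
  cfg <- syntheticConfig(nSites = nSites,
                         filamentsPerSite = rep(nFil, nSites),
                         mtFraction = mtFraction, seed = seed, ...)
  co <- generateCohort(cfg)
  list(cohort = co, quantified = quantifyCohort(co$models))
}

test_that("quantifySite produces a coherent per-site bundle", {
  set.seed(111)
  g <- generateSite(syntheticConfig(), hasMt = FALSE, nFilaments = 12,
                    siteId = "q1")
  q <- quantifySite(g$model)
  expect_equal(nrow(q$metrics), 12L)
  expect_equal(q$site_summary$n_filaments, 12L)
  expect_false(q$site_summary$has_microtubule)
  # no microtubule -> empty mt distance column
  expect_true(all(is.na(q$metrics$mt_distance_nm)))
  # summary values trace back to stage outputs without drift
  expect_equal(q$site_summary$mean_length_nm, mean(q$metrics$path_length_nm))
  expect_equal(q$site_summary$min_nn_origin_nm, min(q$metrics$nn_origin_nm))
  expect_equal(q$site_summary$mean_plane_extent1_nm,
               mean(vapply(q$planes, `[[`, numeric(1), "extent1")))
  expect_setequal(unique(q$distance_samples$kind),
                  c("origin_nn", "filament_nn"))
})

test_that("quantifyCohort isolates per-site failures", {
  set.seed(112)
  good <- generateSite(syntheticConfig(), hasMt = FALSE, nFilaments = 8,
                       siteId = "good")$model
  bad <- AttachmentSiteModel(siteId = "bad", pixelSize = 1,
                             structures = list(),
                             filaments = list(Filament("f", cbind(0:1, 0, 0))))
  expect_warning(qc <- quantifyCohort(list(good, bad)), "bad")
  expect_equal(unique(qc$metrics$site_id), "good")
  expect_length(qc$failures, 1L)
  expect_match(qc$failures, "lateral_element")
  expect_error(quantifyCohort(list()), "no site models")
})

test_that("cohort comparison covers the full battery with per-group sizes", {
  x <- make_quantified_cohort(113, nSites = 6, nFil = 20, mtFraction = 0.5)
  rep <- compareCohorts(x$quantified)
  expect_s3_class(rep$counts_ks, "TestResult")
  expect_s3_class(rep$lengths_t, "TestResult")
  expect_s3_class(rep$nn_filament_ks, "TestResult")
  expect_equal(unname(rep$group_sizes), c(3L, 3L))
  expect_equal(rep$counts_ks$n1 + rep$counts_ks$n2, 6L)
  expect_true(is.data.frame(rep$cutoff_scan))
  expect_equal(rep$force_model$complexes_per_site,
               maxDyneinComplexes(forceModelParams(
                 interactionLengthPerPlate = rep$mean_plane_extent1_nm)))
  # headline spacing minima trace to the metrics table
  expect_equal(rep$origin_spacing$sample_min,
               min(x$quantified$metrics$nn_origin_nm, na.rm = TRUE))

  # single-group cohort: comparisons skipped, summaries still produced
  x1 <- make_quantified_cohort(114, nSites = 2, nFil = 10, mtFraction = 0)
  rep1 <- compareCohorts(x1$quantified)
  expect_match(rep1$note, "single-group")
  expect_null(rep1$counts_ks)
  expect_false(is.null(rep1$origin_spacing))
})

test_that("near-null cohorts give large p-values, boosted cohorts flag with-mt", {
  # both groups generated identically apart from microtubule presence,
  # with the near-mt stretch boost disabled
  x <- make_quantified_cohort(115, nSites = 6, nFil = 18, mtFraction = 0.5,
                              stretchTargetNearMt = 0.77)
  rep <- compareCohorts(x$quantified)
  expect_gt(rep$stretch$test$p_value, 0.01)
  expect_lt(abs(rep$stretch$mean_difference), 0.02)

  # default boost: with-mt cohort has the larger mean stretch
  y <- make_quantified_cohort(116, nSites = 6, nFil = 24, mtFraction = 0.5)
  repy <- compareCohorts(y$quantified)
  expect_gt(repy$stretch$mean_difference, 0)
})

test_that("serialisation round-trips through CSV and JSON", {
  x <- make_quantified_cohort(117, nSites = 2, nFil = 8, mtFraction = 0.5)
  met <- x$quantified$metrics
  csv <- withr::local_tempfile(fileext = ".csv")
  writeMetricsCsv(met, csv)
  back <- read.csv(csv)
  expect_equal(nrow(back), nrow(met))
  expect_equal(back$path_length_nm, met$path_length_nm, tolerance = 1e-12)

  js <- withr::local_tempfile(fileext = ".json")
  writeReportJson(compareCohorts(x$quantified), js)
  parsed <- jsonlite::read_json(js)
  expect_true("force_model" %in% names(parsed))
  expect_equal(parsed$force_model$complexes_per_site,
               compareCohorts(x$quantified)$force_model$complexes_per_site)
})
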