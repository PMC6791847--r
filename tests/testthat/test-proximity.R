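test_that("microtubule distance is point-to-segment, matching a dense oracle", {
  # straight filament 30 nm from a parallel axis
  f <- Filament("f", rbind(c(0, 30, 0), c(50, 30, 0)))
  axis <- rbind(c(-100, 0, 0), c(100, 0, 0))
  expect_equal(distanceToMicrotubule(f, axis), 30)

  # filament touching the axis
  ft <- Filament("t", rbind(c(0, 0, 0), c(0, 50, 0)))
  expect_equal(distanceToMicrotubule(ft, axis), 0)

  # filament opposite a sparse-vertex axis: vertex-only distance would be wrong
  fmid <- Filament("m", rbind(c(0, 5, 0), c(0, 5, 10)))
  expect_equal(distanceToMicrotubule(fmid, axis), 5)

  # random cases vs axis resampled at 0.1 nm (vertex distance on dense axis)
  set.seed(61)
  for (rep in 1:10) {
    f <- random_filament(6, scale = 20)
    v <- matrix(rnorm(9, 0, 30), 3)
    dense <- do.call(rbind, lapply(1:2, function(i) {
      n <- ceiling(sqrt(sum((v[i + 1, ] - v[i, ])^2)) / 0.1)
      outer(seq(0, 1, length.out = n + 1), v[i + 1, ] - v[i, ]) +
        matrix(v[i, ], n + 1, 3, byrow = TRUE)
    }))
    want <- sqrt(min(lincQuant:::cross_dist2(filamentPoints(f), dense)))
    expect_equal(distanceToMicrotubule(f, v), want, tolerance = 1e-3)
  }

  # absent microtubule yields NA, not zero
  m <- toy_site(rbind(c(0, 0, 0), c(10, 0, 0)))
  expect_true(is.na(distanceToMicrotubule(f, m)))
  # radius offset clamps at zero
  expect_equal(distanceToMicrotubule(ft, axis, radiusOffset = 12.5), 0)
})

test_that("cutoff classification uses a strict boundary and flags empty groups", {
  d <- c(50, 99.9, 100, 140)
  cl <- classifyByCutoff(d, 100)
  expect_equal(as.vector(cl), c(TRUE, TRUE, FALSE, FALSE))

  below <- classifyByCutoff(d, 10)
  expect_equal(attr(below, "empty_group"), "close")
  expect_error(classifyByCutoff(d, -1), "positive")
  expect_error(classifyByCutoff(c(1, NA), 10), "NA")
})

test_that("cutoff scan recovers a known near-microtubule length boost", {
  # generator with a stretch boost sized to give ~ +4 nm linear distance
  # inside the influence radius (0.044 x 91 nm)
  cfg <- syntheticConfig(nSites = 6, filamentsPerSite = rep(67, 6),
                         mtFraction = 1, stretchTargetNearMt = 0.814,
                         stretchTargetNoMt = 0.770, seed = 62)
  co <- generateCohort(cfg)
  qc <- quantifyCohort(co$models)
  mtMet <- qc$metrics[!is.na(qc$metrics$mt_distance_nm), ]
  expect_gte(nrow(mtMet), 400 - 2)

  scan <- cutoffScan(mtMet, cutoffs = c(100))
  at100 <- scan[scan$cutoff_nm == 100, ]
  expect_lt(abs(at100$mean_difference - 4), 1)
  expect_lt(at100$wilcoxon_p, 0.05)
  expect_equal(at100$n_close + at100$n_far, nrow(mtMet))

  # decay past the boost radius, on a scan profile with a known shape:
  # +4 nm boost strictly inside 100 nm, distances spread over 0-300 nm
  set.seed(620)
  dist <- runif(600, 0, 300)
  crafted <- data.frame(mt_distance_nm = dist,
                        linear_distance_nm = 70 + 4 * (dist < 100) +
                          rnorm(600, 0, 2))
  cs <- cutoffScan(crafted, cutoffs = c(100, 200, 280))
  expect_lt(abs(cs$mean_difference[1] - 4), 1)
  expect_lt(cs$mean_difference[2], cs$mean_difference[1])
  expect_lt(cs$mean_difference[3], cs$mean_difference[2])

  # close group mean exceeds far group mean (generator ground truth)
  cl <- classifyByCutoff(mtMet, 100)
  expect_gt(mean(mtMet$linear_distance_nm[cl]),
            mean(mtMet$linear_distance_nm[!cl]))

  # antisymmetry under swapping group labels
  expect_equal(at100$mean_difference,
               -(at100$mean_linear_far - at100$mean_linear_close))

  # all-equal distances: every cutoff gives an empty group -> undefined rows
  same <- mtMet[1:6, ]
  same$mt_distance_nm <- 50
  scan0 <- cutoffScan(same, cutoffs = c(10, 50, 100))
  expect_true(all(is.na(scan0$mean_difference)))
  expect_error(cutoffScan(mtMet, numeric(0)), "empty cutoff")
})

test_that("with the stretch boost off the scan is centred on zero", {
  cfg <- syntheticConfig(nSites = 4, filamentsPerSite = rep(40, 4),
                         mtFraction = 1, stretchTargetNearMt = 0.77,
                         stretchTargetNoMt = 0.77, seed = 63)
  co <- generateCohort(cfg)
  qc <- quantifyCohort(co$models)
  mtMet <- qc$metrics[!is.na(qc$metrics$mt_distance_nm), ]
  scan <- cutoffScan(mtMet, cutoffs = c(100))
  # mean difference within 2 SE of zero
  se <- sd(mtMet$linear_distance_nm) *
    sqrt(1 / scan$n_close + 1 / scan$n_far)
  expect_lt(abs(scan$mean_difference), 2 * se)
})

test_that("stretch cohort comparison reports means, test and densities", {
  set.seed(64)
  x <- rnorm(100, 0.8, 0.05)
  same <- stretchCohortCompare(x, x)
  expect_equal(same$mean_difference, 0)
  expect_equal(same$test$p_value, 1, tolerance = 1e-6)
  expect_length(same$density, 2L)

  expect_warning(tiny <- stretchCohortCompare(0.8, 0.7), "too small")
  expect_equal(tiny$mean_difference, 0.1)
  expect_null(tiny$density)
  expect_error(stretchCohortCompare(numeric(0), 1), "empty cohort")
})
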