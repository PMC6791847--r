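test_that("minPairDistance handles aligned, touching and random pairs", {
  a <- Filament("a", cbind(0:5, 0, 0))
  b <- Filament("b", cbind(0:5, 2, 0))
  expect_equal(minPairDistance(a, b), 2)

  shared <- Filament("c", rbind(c(5, 0, 0), c(9, 9, 9)))
  expect_equal(minPairDistance(a, shared), 0)

  set.seed(31)
  for (rep in 1:20) {
    f1 <- random_filament(sample(3:15, 1))
    f2 <- random_filament(sample(3:15, 1))
    want <- brute_min_pair(filamentPoints(f1), filamentPoints(f2))
    expect_equal(minPairDistance(f1, f2), want)
    expect_equal(minPairDistance(f2, f1), want)  # symmetry
  }

  # segment-interpolated variant can only be smaller
  f1 <- Filament("s1", rbind(c(-10, 1, 0), c(10, 1, 0)))
  f2 <- Filament("s2", rbind(c(0, -10, 0), c(0, 10, 0)))
  expect_equal(minPairDistanceSegments(f1, f2), 0)
  expect_lte(minPairDistanceSegments(f1, f2), minPairDistance(f1, f2))
})

test_that("origin nearest-neighbour distances per site", {
  # collinear origins at 0, 5, 12 nm -> nn distances 5, 5, 7
  origins <- rbind(c(0, 0, 0), c(5, 0, 0), c(12, 0, 0))
  m <- toy_site(origins)
  met <- suppressWarnings(filamentMetrics(m))
  nn <- nnOriginDistances(met)
  expect_equal(nn$distance_nm, c(5, 5, 7))
  expect_true(all(nn$neighbor_id != nn$filament_id))

  # duplicate origins -> 0 nm entries
  met2 <- met
  met2[2, c("origin_x", "origin_y", "origin_z")] <-
    met2[1, c("origin_x", "origin_y", "origin_z")]
  nn2 <- nnOriginDistances(met2)
  expect_equal(nn2$distance_nm[1:2], c(0, 0))

  # singleton site skipped with warning
  met1 <- met[1, , drop = FALSE]
  expect_warning(nn1 <- nnOriginDistances(met1), "single filament")
  expect_null(nn1)
})

test_that("whole-filament nn distances beat origin distances when tips approach", {
  # origins 6 nm apart, tips converging to 1 nm
  f1 <- Filament("f01", rbind(c(0, 0, 0), c(0, 0, 50)))
  f2 <- Filament("f02", rbind(c(6, 0, 0), c(1, 0, 50)))
  le <- StructurePointSet("lateral_element", rbind(c(0, 0, -10), c(6, 0, -10)))
  m <- AttachmentSiteModel(siteId = "s", pixelSize = 1,
                           structures = list(lateral_element = le),
                           filaments = list(f1, f2))
  nn <- nnFilamentDistances(m)
  expect_equal(nn$distance_nm, c(1, 1))

  met <- suppressWarnings(filamentMetrics(m))
  nnO <- nnOriginDistances(met)
  expect_true(all(nn$distance_nm <= nnO$distance_nm))  # origins are member points

  # brute-force all-pairs minimum per filament on random sites
  set.seed(32)
  fls <- lapply(1:5, function(i) random_filament(8, sprintf("f%02d", i)))
  le2 <- StructurePointSet("lateral_element", matrix(rnorm(30, 0, 40), ncol = 3))
  m2 <- AttachmentSiteModel(siteId = "r", pixelSize = 1,
                            structures = list(lateral_element = le2),
                            filaments = fls)
  nn2 <- nnFilamentDistances(m2)
  for (i in 1:5) {
    want <- min(vapply(setdiff(1:5, i), function(j)
      brute_min_pair(filamentPoints(fls[[i]]), filamentPoints(fls[[j]])),
      numeric(1)))
    expect_equal(nn2$distance_nm[i], want)
  }
})

test_that("shifted-exponential global minimum estimation", {
  r <- globalMinimumShift(c(5.1, 6.0, 9.7))
  expect_equal(r$sample_min, 5.1)

  set.seed(33)
  x <- 5 + rexp(800, rate = 0.2)
  fit <- globalMinimumShift(x)
  expect_lt(abs(fit$shift - 5), 0.2)
  expect_lt(abs(fit$rate - 0.2) / 0.2, 0.1)
  expect_false(fit$degenerate)

  deg <- globalMinimumShift(rep(4, 10))
  expect_equal(deg$shift, 4)
  expect_true(deg$degenerate)
  expect_true(is.na(deg$rate))

  expect_error(globalMinimumShift(numeric(0)), "empty")
})

test_that("density curves integrate to one and count modes correctly", {
  set.seed(34)
  x <- rnorm(800, 91, 18)
  dc <- densityCurve(x)
  expect_equal(dc$n_modes, 1L)
  # a unimodal length distribution peaks at its single empirical centre
  expect_lt(abs(dc$modes - mean(x)), 3)
  expect_lt(abs(dc$modes - 91), 5)
  area <- sum(diff(dc$grid) * (head(dc$density, -1) + tail(dc$density, -1)) / 2)
  expect_lt(abs(area - 1), 0.01)

  bim <- c(rnorm(400, 60, 8), rnorm(400, 120, 8))
  expect_equal(densityCurve(bim)$n_modes, 2L)

  two <- densityCurve(c(0, 100), bandwidth = 5)
  expect_equal(two$n_modes, 2L)

  expect_error(densityCurve(rep(3, 10)), "zero variance")
  expect_error(densityCurve(1), "at least 2")
})

test_that("distance histograms show a spacing floor as empty leading bins", {
  h <- distanceHistogram(c(5.1, 6.0, 9.7, 1.9), binWidth = 2)
  expect_equal(h$count, c(1, 0, 1, 1, 1))  # [0,2) [2,4) [4,6) [6,8) [8,10)
  expect_equal(sum(h$count), 4)
  floorOnly <- distanceHistogram(c(5.1, 6.0, 9.7), binWidth = 2)
  expect_equal(floorOnly$count[1:2], c(0, 0))  # empty below the 5 nm floor
  expect_error(distanceHistogram(numeric(0)), "empty")
  expect_error(distanceHistogram(c(1, -1)), ">= 0")
})

test_that("distance samples are invariant under rigid motion of a site", {
  set.seed(35)
  g <- generateSite(syntheticConfig(), hasMt = FALSE, nFilaments = 12,
                    siteId = "rm")
  m <- g$model
  q1 <- quantifySite(m)
  mo <- random_rigid_motion()
  m2 <- AttachmentSiteModel(
    siteId = "rm", pixelSize = 1,
    structures = lapply(structures(m), function(s)
      StructurePointSet(structureClass(s), apply_motion(structurePoints(s), mo),
                        s@contourIds)),
    filaments = lapply(filaments(m), function(f)
      Filament(filamentId(f), apply_motion(filamentPoints(f), mo))))
  q2 <- quantifySite(m2)
  expect_equal(q2$metrics$nn_origin_nm, q1$metrics$nn_origin_nm)
  expect_equal(q2$metrics$nn_filament_nm, q1$metrics$nn_filament_nm)
})
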