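#' @include AllClasses.R
NULL

#' Configuration of the synthetic attachment-site generator
#'
#' Defines the statistical structure of generated sites: two
#' attachment-plate origin clusters per site, per-site filament counts
#' drawn from the observed per-attachment counts
#' ([referenceSiteCounts()]), filament lengths from a truncated normal
#' (91 +/- 18 nm), a hard minimum origin spacing (5 nm) and
#' inter-filament clearance (2 nm), rippled polylines with realized
#' stretch factor calibrated to a per-filament target, and, at
#' microtubule-bearing sites, a single microtubule axis parallel to the
#' plate long axis near which filaments are straighter (higher stretch
#' target).
#'
#' @param nSites number of sites to generate.
#' @param filamentsPerSite `"reference"` (draw from the observed 11
#'   per-site counts), `"normal"` (round of Normal(76, 12), clamped >= 4),
#'   or an integer vector of length `nSites`.
#' @param lengthMean,lengthSd filament path length distribution, nm
#'   (truncated at 3 SD and below at twice the point spacing).
#' @param minOriginSpacing minimum pairwise origin distance within a
#'   plate, nm.
#' @param minFilamentClearance minimum whole-filament distance between
#'   filaments of a site, nm (enforced by rejection).
#' @param plateExtent length-2 vector, plate patch side lengths in nm
#'   (long side runs parallel to the nuclear envelope).
#' @param plateSeparation distance between the two plate centres, nm.
#' @param stretchTargetNoMt,stretchTargetNearMt mean per-filament stretch
#'   target away from/near a microtubule.
#' @param stretchJitter SD of the per-filament stretch target around its
#'   cohort mean.
#' @param mtFraction fraction of sites carrying a microtubule.
#' @param mtInfluenceRadius origins within this distance of the
#'   microtubule axis get the near-microtubule stretch target, nm.
#' @param pointSpacing spacing of polyline sample points along a
#'   filament, nm.
#' @param seed integer seed; every stochastic step of the generator draws
#'   from the R RNG seeded with it.
#' @return A validated list of class `SyntheticConfig`.
#' @seealso [generateCohort()], [generateSite()]
#' @export
syntheticConfig <- function(nSites = 11,
                            filamentsPerSite = "reference",
                            lengthMean = 91, lengthSd = 18,
                            minOriginSpacing = 5,
                            minFilamentClearance = 2,
                            plateExtent = c(150, 60),
                            plateSeparation = 250,
                            stretchTargetNoMt = 0.77,
                            stretchTargetNearMt = 0.80,
                            stretchJitter = 0.05,
                            mtFraction = 5 / 11,
                            mtInfluenceRadius = 100,
                            pointSpacing = 4,
                            seed = 1L) {
  cfg <- list(nSites = as.integer(nSites), filamentsPerSite = filamentsPerSite,
              lengthMean = lengthMean, lengthSd = lengthSd,
              minOriginSpacing = minOriginSpacing,
              minFilamentClearance = minFilamentClearance,
              plateExtent = plateExtent, plateSeparation = plateSeparation,
              stretchTargetNoMt = stretchTargetNoMt,
              stretchTargetNearMt = stretchTargetNearMt,
              stretchJitter = stretchJitter,
              mtFraction = mtFraction, mtInfluenceRadius = mtInfluenceRadius,
              pointSpacing = pointSpacing, seed = as.integer(seed))
  stopifnot(cfg$nSites >= 0,
            cfg$lengthMean > 0, cfg$lengthSd > 0,
            cfg$minOriginSpacing > 0, cfg$minFilamentClearance > 0,
            length(cfg$plateExtent) == 2, all(cfg$plateExtent > 0),
            cfg$plateSeparation > 0,
            cfg$stretchTargetNoMt > 0, cfg$stretchTargetNoMt <= 1,
            cfg$stretchTargetNearMt > 0, cfg$stretchTargetNearMt <= 1,
            cfg$stretchJitter >= 0,
            cfg$mtFraction >= 0, cfg$mtFraction <= 1,
            cfg$mtInfluenceRadius > 0, cfg$pointSpacing > 0)
  if (is.numeric(cfg$filamentsPerSite) &&
      length(cfg$filamentsPerSite) != cfg$nSites)
    stop("explicit filamentsPerSite must have one count per site", call. = FALSE)
  structure(cfg, class = "SyntheticConfig")
}

#' Poisson-disk origin sampling on a plate patch
#'
#' Dart-throwing sampler: uniform candidate points on the rectangular
#' plate patch (in its own plane), accepted only when at least
#' `minSpacing` away from every already-accepted point, emulating the
#' steric exclusion observed between filament origins.
#'
#' @param n number of origins.
#' @param extent length-2 plate side lengths (nm).
#' @param minSpacing hard minimum pairwise distance (nm).
#' @param maxAttempts dart-throwing retry cap (default `1000 * n`).
#' @return n x 3 matrix of points in the local plate frame (z = 0,
#'   centred at the origin).
#' @export
poissonDiskOrigins <- function(n, extent = c(150, 60), minSpacing = 5,
                               maxAttempts = 1000 * n) {
  stopifnot(n >= 0, length(extent) == 2, all(extent > 0), minSpacing > 0)
  if (n == 0L) return(matrix(0, 0, 3))
  if (n * pi * (minSpacing / 2)^2 >= prod(extent))
    stop("infeasible density: ", n, " disks of diameter ", minSpacing,
         " nm exceed the ", extent[1], " x ", extent[2], " nm plate; ",
         "reduce the count or the spacing", call. = FALSE)
  pts <- matrix(NA_real_, n, 3)
  placed <- 0L
  attempts <- 0L
  while (placed < n) {
    attempts <- attempts + 1L
    if (attempts > maxAttempts)
      stop("Poisson-disk sampling exhausted ", maxAttempts,
           " attempts at ", placed, "/", n,
           " points; reduce density or spacing", call. = FALSE)
    cand <- c(runif(1, -extent[1] / 2, extent[1] / 2),
              runif(1, -extent[2] / 2, extent[2] / 2), 0)
    if (placed > 0L) {
      d2 <- rowSums(sweep(pts[seq_len(placed), , drop = FALSE], 2, cand)^2)
      if (min(d2) < minSpacing^2) next
    }
    placed <- placed + 1L
    pts[placed, ] <- cand
  }
  pts
}

## Realized stretch factor of a candidate polyline.
polyline_stretch <- function(p) {
  sqrt(sum((p[nrow(p), ] - p[1, ])^2)) / sum(row_norms(diff(p)))
}

#' Generate a rippled filament polyline with a target stretch factor
#'
#' Builds a polyline of the requested arc length whose realized stretch
#' factor (end-to-end / arc length) matches the target: a straight
#' backbone is perturbed by a transverse Gaussian random walk whose
#' amplitude is found by bisection (stretch decreases monotonically with
#' amplitude), then the whole polyline is rescaled to the exact requested
#' arc length (uniform scaling leaves the stretch factor unchanged),
#' rotated to the outward direction and anchored at the origin.
#'
#' @param origin length-3 start point (the filament origin), nm.
#' @param direction length-3 outward direction (normalised internally).
#' @param pathLength requested arc length, nm.
#' @param stretchTarget target stretch factor in (0, 1]; 1 gives an
#'   exactly straight polyline.
#' @param pointSpacing nominal point spacing along the polyline, nm.
#' @param tol acceptable |realized - target| (default 0.005).
#' @param filamentId id for the returned [Filament-class].
#' @return A [Filament-class] whose first point is `origin`.
#' @export
rippledPolyline <- function(origin, direction, pathLength, stretchTarget,
                            pointSpacing = 4, tol = 0.005,
                            filamentId = "f") {
  stopifnot(pathLength > 0, stretchTarget > 0, stretchTarget <= 1,
            pointSpacing > 0)
  nSeg <- max(1L, as.integer(round(pathLength / pointSpacing)))
  nPts <- nSeg + 1L
  base <- cbind(0, 0, seq(0, pathLength, length.out = nPts))
  R <- rotation_to(as.numeric(direction))

  finalize <- function(p) {
    L <- sum(row_norms(diff(p)))
    p <- p * (pathLength / L)
    p <- t(R %*% t(p))
    p <- sweep(p, 2, as.numeric(origin) - p[1, ], "+")
    Filament(filamentId, p)
  }
  if (stretchTarget >= 1 - 1e-12 || nPts == 2L) return(finalize(base))

  ## Transverse Brownian-bridge perturbation: both ends stay on the backbone,
  ## so end-to-end distance is fixed and the stretch factor decreases strictly
  ## monotonically with amplitude -> the bisection root is unique.
  for (try in 1:25) {
    bridge <- function(n) {
      w <- c(0, cumsum(rnorm(n)))
      w - seq(0, 1, length.out = n + 1L) * w[n + 1L]
    }
    walk <- cbind(bridge(nSeg), bridge(nSeg), 0)
    if (max(abs(walk)) < 1e-9) next  # degenerate draw
    candidate <- function(a) base + a * walk
    lo <- 0; hi <- pointSpacing
    while (polyline_stretch(candidate(hi)) > stretchTarget && hi < 1e6)
      hi <- hi * 2
    ok <- FALSE
    for (it in 1:80) {
      mid <- (lo + hi) / 2
      s <- polyline_stretch(candidate(mid))
      if (abs(s - stretchTarget) <= tol) { ok <- TRUE; break }
      if (s > stretchTarget) lo <- mid else hi <- mid
    }
    if (ok) return(finalize(candidate(mid)))
  }
  stop("could not reach stretch target ", stretchTarget,
       " within tolerance after bounded attempts", call. = FALSE)
}

## Rectangular grid of scaffold points in a z = const plane.
grid_points <- function(xr, yr, z, spacing) {
  xs <- seq(xr[1], xr[2], by = spacing)
  ys <- seq(yr[1], yr[2], by = spacing)
  cbind(rep(xs, times = length(ys)), rep(ys, each = length(xs)), z)
}

## Truncated-normal filament length draw: within 3 SD and above a floor.
draw_length <- function(mean, sd, floor_) {
  lo <- max(floor_, mean - 3 * sd)
  hi <- mean + 3 * sd
  for (i in 1:1000) {
    x <- rnorm(1, mean, sd)
    if (x >= lo && x <= hi) return(x)
  }
  mean  # pathological parameters only
}

#' Generate one synthetic attachment site
#'
#' Emits a full [AttachmentSiteModel-class] in nm (pixel size 1): coarse
#' planar scaffolds for the inner/outer membranes, lateral elements,
#' central element and the two attachment plates; two Poisson-disk origin
#' clusters (one per plate); rippled filaments with truncated-normal
#' lengths growing outward from the inner membrane; and, when requested,
#' a single microtubule axis running parallel to the plate long axis over
#' one plate. Filaments whose whole-length clearance to previously placed
#' filaments falls below the configured minimum are regenerated
#' (bounded rejection).
#'
#' Draws from the current RNG state; seed via [generateCohort()] or
#' `set.seed()` for reproducibility.
#'
#' @param config a [syntheticConfig()].
#' @param hasMt does this site carry a microtubule?
#' @param nFilaments filament count for the site (default: drawn
#'   according to `config$filamentsPerSite`).
#' @param siteId site identifier.
#' @return A list with `model` (the site) and `truth` (data.frame of
#'   per-filament generating parameters: plate, target length, target
#'   stretch, near-microtubule flag).
#' @export
generateSite <- function(config, hasMt = FALSE, nFilaments = NULL,
                         siteId = "synthetic_site") {
  stopifnot(inherits(config, "SyntheticConfig"))
  if (is.null(nFilaments)) nFilaments <- draw_site_count(config, 1L)
  nFilaments <- as.integer(nFilaments)
  if (nFilaments < 2L) stop("a site needs at least 2 filaments", call. = FALSE)

  ex <- config$plateExtent
  sep <- config$plateSeparation
  yc <- c(-sep / 2, sep / 2)  # plate centres along y; MT (if any) over plate 1

  ## scaffolds; the lateral-element grid is fine enough (6 nm) that the
  ## first polyline point (on the membrane, z = 0) is always the point
  ## closest to the lateral element, i.e. the recoverable origin
  leSpacing <- 6
  le <- rbind(
    grid_points(c(-ex[1] / 2, ex[1] / 2), yc[1] + c(-ex[2] / 2, ex[2] / 2), -15, leSpacing),
    grid_points(c(-ex[1] / 2, ex[1] / 2), yc[2] + c(-ex[2] / 2, ex[2] / 2), -15, leSpacing))
  leCid <- rep(1:2, each = nrow(le) / 2)
  ce <- cbind(0, seq(yc[1] + ex[2] / 2, yc[2] - ex[2] / 2, by = 10), -15)
  plate <- rbind(
    grid_points(c(-ex[1] / 2, ex[1] / 2), yc[1] + c(-ex[2] / 2, ex[2] / 2), -2, 15),
    grid_points(c(-ex[1] / 2, ex[1] / 2), yc[2] + c(-ex[2] / 2, ex[2] / 2), -2, 15))
  plateCid <- rep(1:2, each = nrow(plate) / 2)
  inm <- grid_points(c(-ex[1] / 2 - 25, ex[1] / 2 + 25),
                     c(yc[1] - ex[2], yc[2] + ex[2]), 0, 25)
  onm <- inm + matrix(rep(c(0, 0, 40), each = nrow(inm)), ncol = 3)

  structuresList <- list(
    lateral_element = StructurePointSet("lateral_element", le, leCid),
    central_element = StructurePointSet("central_element", ce),
    attachment_plate = StructurePointSet("attachment_plate", plate, plateCid),
    inner_membrane = StructurePointSet("inner_membrane", inm),
    outer_membrane = StructurePointSet("outer_membrane", onm))

  mtAxis <- matrix(0, 0, 3)
  if (hasMt) {
    mtAxis <- cbind(seq(-ex[1] / 2 - 50, ex[1] / 2 + 50, by = 20), yc[1], 70)
    structuresList$microtubule <- StructurePointSet("microtubule", mtAxis)
  }

  ## Place origins and filaments; clearance is enforced by rejection.
  ## Late retries draw progressively straighter, more upright candidates;
  ## if a filament still cannot be placed the whole site is redrawn
  ## (fresh origins) a few times before giving up.
  lengthFloor <- max(2 * config$pointSpacing, 1)
  build_site <- function() {
    n1 <- stats::rbinom(1, nFilaments, 0.5)
    n1 <- min(max(n1, min(2L, nFilaments)), max(nFilaments - 2L, 0L))
    n1 <- max(n1, min(2L, nFilaments))
    counts <- c(n1, nFilaments - n1)
    originsByPlate <- lapply(1:2, function(k) {
      o <- poissonDiskOrigins(counts[k], ex, config$minOriginSpacing)
      sweep(o, 2, c(0, yc[k], 0), "+")
    })
    filamentsList <- vector("list", nFilaments)
    truth <- vector("list", nFilaments)
    idx <- 0L
    for (k in 1:2) {
      orig <- originsByPlate[[k]]
      for (i in seq_len(counts[k])) {
        idx <- idx + 1L
        o <- orig[i, ]
        nearMt <- hasMt && {
          dMt <- min(points_to_polyline_dist(matrix(o, 1), mtAxis))
          dMt <= config$mtInfluenceRadius
        }
        targetMean <- if (nearMt) config$stretchTargetNearMt else config$stretchTargetNoMt
        targetStretch <- min(0.995, max(0.3, rnorm(1, targetMean, config$stretchJitter)))
        targetLength <- draw_length(config$lengthMean, config$lengthSd, lengthFloor)
        fid <- sprintf("f%03d", idx)
        placed <- FALSE
        for (attempt in 1:80) {
          tiltSd <- if (attempt <= 40) 0.1 else 0.03
          dir <- c(rnorm(2, 0, tiltSd), 1)
          f <- rippledPolyline(o, dir, targetLength, targetStretch,
                               config$pointSpacing, filamentId = fid)
          clear <- TRUE
          if (idx > 1L) {
            for (j in seq_len(idx - 1L)) {
              if (minPairDistance(f, filamentsList[[j]]) < config$minFilamentClearance) {
                clear <- FALSE; break
              }
            }
          }
          if (clear) { placed <- TRUE; break }
        }
        if (!placed) return(NULL)  # redraw the whole site
        filamentsList[[idx]] <- f
        truth[[idx]] <- data.frame(
          site_id = siteId, filament_id = fid, plate = k - 1L,
          target_length_nm = targetLength, target_stretch = targetStretch,
          near_mt = nearMt, stringsAsFactors = FALSE)
      }
    }
    list(filaments = filamentsList, truth = truth)
  }

  built <- NULL
  for (siteAttempt in 1:5) {
    built <- build_site()
    if (!is.null(built)) break
  }
  if (is.null(built))
    stop("could not place ", nFilaments, " filaments with ",
         config$minFilamentClearance, " nm clearance; relax the config",
         call. = FALSE)
  filamentsList <- built$filaments
  truth <- built$truth

  model <- AttachmentSiteModel(siteId = siteId, pixelSize = 1,
                               structures = structuresList,
                               filaments = filamentsList,
                               hasMicrotubule = hasMt,
                               microtubuleAxis = mtAxis)
  list(model = model, truth = do.call(rbind, truth))
}

draw_site_count <- function(config, n) {
  spec <- config$filamentsPerSite
  if (is.numeric(spec)) return(as.integer(spec)[seq_len(n)])
  ref <- referenceSiteCounts()$filaments
  switch(spec,
         reference = sample(ref, n, replace = TRUE),
         normal = pmax(4L, as.integer(round(rnorm(n, 76, 12)))),
         stop("unknown filamentsPerSite rule '", spec, "'", call. = FALSE))
}

#' Generate a synthetic cohort of attachment sites
#'
#' Seeds the RNG from `config$seed` and generates `nSites` site models,
#' the last `round(mtFraction * nSites)` of which carry a microtubule
#' (matching the observed layout where the microtubule-bearing sites are
#' listed last). Returns the models, the combined ground-truth table and
#' a manifest recording the seed and a hash of the configuration.
#'
#' @param config a [syntheticConfig()].
#' @return A list with `models` (list of [AttachmentSiteModel-class]),
#'   `truth` (data.frame), `manifest` (list with `seed`, `n_sites`,
#'   `n_microtubule_sites`, `config_hash`) and `config`.
#' @seealso [writeCohort()] to materialise the cohort on disk.
#' @export
generateCohort <- function(config = syntheticConfig()) {
  stopifnot(inherits(config, "SyntheticConfig"))
  set.seed(config$seed)
  n <- config$nSites
  nMt <- as.integer(round(config$mtFraction * n))
  hasMt <- c(rep(FALSE, n - nMt), rep(TRUE, nMt))
  counts <- draw_site_count(config, max(n, 1L))[seq_len(n)]
  models <- vector("list", n)
  truths <- vector("list", n)
  for (i in seq_len(n)) {
    g <- generateSite(config, hasMt = hasMt[i], nFilaments = counts[i],
                      siteId = sprintf("site%02d", i))
    models[[i]] <- g$model
    truths[[i]] <- g$truth
  }
  manifest <- list(seed = config$seed, n_sites = n, n_microtubule_sites = nMt,
                   config_hash = rlang::hash(unclass(config)))
  list(models = models,
       truth = if (n) do.call(rbind, truths) else NULL,
       manifest = manifest, config = config)
}
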