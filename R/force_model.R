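#' @include AllClasses.R
NULL

#' Parameters of the dynein-dynactin force/stoichiometry model
#'
#' Constants of the per-site force arithmetic: a microtubule interacts
#' with the LINC cluster over one ~150 nm segment per attachment plate
#' (two plates per site); microtubule-bound dynein-dynactin complexes are
#' ~43 nm long and exert ~5 pN per dynein; a dynactin can engage one or
#' two dyneins; a murine pachytene nucleus has 40 autosomal-equivalent
#' attachment sites (80 telomeres paired two by two); LINC complexes are
#' trimeric in SUN and in KASH.
#'
#' @param interactionLengthPerPlate nm of microtubule-LINC interaction
#'   per plate (default 150).
#' @param platesPerSite plates per attachment site (default 2).
#' @param complexLength dynein-dynactin footprint on the microtubule in
#'   nm (default 43).
#' @param forcePerDynein stall force per dynein motor in pN (default 5).
#' @param dyneinsPerDynactin 1 or 2 dynein motors per dynactin
#'   (default 1).
#' @param sitesPerNucleus attachment sites per nucleus (default 40; use
#'   41 to count the partially synapsed XY bivalent's extra site).
#' @param subunitsPerComplex SUN (and KASH) monomers per LINC complex
#'   (default 3, trimer).
#' @return A validated list of class `ForceModelParams`.
#' @seealso [maxDyneinComplexes()], [siteForce()], [nucleusTotals()]
#' @export
forceModelParams <- function(interactionLengthPerPlate = 150,
                             platesPerSite = 2,
                             complexLength = 43,
                             forcePerDynein = 5,
                             dyneinsPerDynactin = 1,
                             sitesPerNucleus = 40,
                             subunitsPerComplex = 3) {
  p <- list(interactionLengthPerPlate = interactionLengthPerPlate,
            platesPerSite = platesPerSite,
            complexLength = complexLength,
            forcePerDynein = forcePerDynein,
            dyneinsPerDynactin = dyneinsPerDynactin,
            sitesPerNucleus = sitesPerNucleus,
            subunitsPerComplex = subunitsPerComplex)
  num <- vapply(p, function(v) is.numeric(v) && length(v) == 1L && is.finite(v),
                logical(1))
  if (!all(num)) stop("all parameters must be finite scalars", call. = FALSE)
  if (any(unlist(p[names(p) != "forcePerDynein"]) <= 0))
    stop("all parameters must be strictly positive", call. = FALSE)
  if (forcePerDynein < 0) stop("forcePerDynein must be >= 0", call. = FALSE)
  if (!dyneinsPerDynactin %in% c(1, 2))
    stop("dyneinsPerDynactin must be 1 or 2", call. = FALSE)
  structure(p, class = "ForceModelParams")
}

#' Maximum dynein-dynactin complexes per attachment site
#'
#' Packing arithmetic: with complexes packed at maximum density along the
#' microtubule interaction segment of each plate, each plate accommodates
#' `ceiling(interactionLengthPerPlate / complexLength)` complexes (a
#' started footprint counts; the conservative `floor` variant is
#' available as an option), times the number of plates.
#'
#' @param params a [forceModelParams()] object.
#' @param packing `"ceiling"` (default) or `"floor"`.
#' @return Integer complex count per site (defaults: 2 x ceil(150/43) = 8).
#' @export
maxDyneinComplexes <- function(params = forceModelParams(),
                               packing = c("ceiling", "floor")) {
  packing <- match.arg(packing)
  perPlate <- params$interactionLengthPerPlate / params$complexLength
  perPlate <- if (packing == "ceiling") ceiling(perPlate) else floor(perPlate)
  as.integer(params$platesPerSite * perPlate)
}

#' Maximum force per attachment site
#'
#' Product of the maximum dynein-dynactin complex count
#' ([maxDyneinComplexes()]), the dyneins engaged per dynactin, and the
#' per-dynein stall force. With the defaults: 8 x 1 x 5 = 40 pN; with two
#' dyneins per dynactin, 80 pN.
#'
#' @inheritParams maxDyneinComplexes
#' @return Force in pN.
#' @export
siteForce <- function(params = forceModelParams(),
                      packing = c("ceiling", "floor")) {
  maxDyneinComplexes(params, packing) * params$dyneinsPerDynactin *
    params$forcePerDynein
}

#' Per-nucleus filament and LINC-monomer totals
#'
#' Scales the mean filament count per attachment site to the whole
#' nucleus and to SUN/KASH monomer counts (trimer stoichiometry per
#' complex).
#'
#' @param meanFilamentsPerSite mean LINC filament count per site (>= 0).
#' @param params a [forceModelParams()] object.
#' @return A list of class `ForceModelResult` with `complexes_per_site`,
#'   `force_per_site_pN`, `filaments_per_nucleus`,
#'   `filaments_per_nucleus_rounded` (nearest thousand),
#'   `sun_monomers_per_nucleus`, `kash_monomers_per_nucleus`.
#' @examples
#' nucleusTotals(76)  # 3040 filaments, 9120 SUN monomers
#' @export
nucleusTotals <- function(meanFilamentsPerSite, params = forceModelParams()) {
  if (!is.numeric(meanFilamentsPerSite) || meanFilamentsPerSite < 0)
    stop("meanFilamentsPerSite must be >= 0", call. = FALSE)
  filaments <- params$sitesPerNucleus * meanFilamentsPerSite
  structure(list(
    complexes_per_site = maxDyneinComplexes(params),
    force_per_site_pN = siteForce(params),
    filaments_per_nucleus = filaments,
    filaments_per_nucleus_rounded = round(filaments / 1000) * 1000,
    sun_monomers_per_nucleus = params$subunitsPerComplex * filaments,
    kash_monomers_per_nucleus = params$subunitsPerComplex * filaments
  ), class = "ForceModelResult")
}

#' @export
print.ForceModelResult <- function(x, ...) {
  cat(sprintf(
    paste0("Force/stoichiometry model:\n",
           "  dynein-dynactin complexes per site: %d\n",
           "  force per site: %g pN\n",
           "  filaments per nucleus: %g (~%g)\n",
           "  SUN monomers per nucleus: %g; KASH monomers: %g\n"),
    x$complexes_per_site, x$force_per_site_pN, x$filaments_per_nucleus,
    x$filaments_per_nucleus_rounded, x$sun_monomers_per_nucleus,
    x$kash_monomers_per_nucleus))
  invisible(x)
}
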