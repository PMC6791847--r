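Package: lincQuant
Title: Quantification of LINC Complex Filaments at Meiotic Telomere
    Attachment Sites
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of LINC (linker of nucleoskeleton and
    cytoskeleton) complex filaments segmented from electron tomograms of
    meiotic telomere attachment sites. Reads IMOD model2point text exports
    into labelled 3D site models, extracts per-filament geometry (origin at
    the inner nuclear membrane, polyline path length, end-to-end linear
    distance, stretch factor, attachment-plate assignment), computes
    nearest-neighbour distance distributions among filament origins and
    whole filaments with shifted-exponential minimum-spacing estimates,
    fits attachment-plate planes by principal component analysis,
    classifies filaments by proximity to a microtubule with cutoff
    scanning and rank-sum testing, and evaluates a dynein-dynactin
    packing/force model for per-site forces and per-nucleus molecule
    totals. A seeded synthetic attachment-site generator reproduces the
    reported statistical structure so every pipeline stage can be
    exercised and validated without tomogram data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    yaml,
    jsonlite,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllGenerics.R'
    'AllClasses.R'
    'data.R'
    'distances.R'
    'force_model.R'
    'geometry.R'
    'model_io.R'
    'planes.R'
    'proximity.R'
    'reports.R'
    'stats.R'
    'synthetic.R'
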