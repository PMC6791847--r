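# lincQuant

Quantitative analysis of **LINC complex filaments at meiotic telomere
attachment sites**, as segmented from electron tomograms of murine
pachytene spermatocytes.

During meiotic prophase I, telomeres attach to the nuclear envelope and
are moved along it by cytoplasmic dynein–dynactin motors. The coupling is
made by LINC complexes — trimeric SUN1/2 proteins in the inner nuclear
membrane bound to trimeric KASH5 in the outer membrane — visible in
tomograms as ~90 nm filaments rising from the two attachment plates of
each site. `lincQuant` turns point-model exports of such segmentations
into the quantities that describe this machine:

* **per-filament geometry** — origin at the inner nuclear membrane
  (the filament point minimising distance to the lateral element), polyline
  path length *L*, end-to-end linear distance *d*, stretch factor
  *s = d / L ∈ (0, 1]*, attachment-plate assignment;
* **spacing statistics** — nearest-neighbour distances between origins and
  between whole filaments (min over all point pairs), with the
  shifted-exponential reading of their hard minimum:
  shift = min(x), rate = 1/(mean − min);
* **plate geometry** — PCA plane fit to each plate's origins with min–max
  in-plane extents (the long side runs parallel to the nuclear envelope);
* **microtubule proximity** — point-to-segment distance of each filament
  to the microtubule axis, close/far classification at a cutoff, a cutoff
  scan of the close-minus-far linear-distance difference with Wilcoxon
  rank-sum p-values, and cohort stretch-factor comparisons;
* **two-sample tests** — KS (exact lattice-path or Stephens-corrected
  asymptotic), t, Wilcoxon rank-sum with exact small-sample handling;
* **force / stoichiometry model** — dynein–dynactin packing on the two
  ~150 nm microtubule interaction segments per site:
  `n = 2 · ⌈150/43⌉ = 8` complexes, `F = n · k · 5 pN` (40 pN with one
  dynein per dynactin, 80 pN with two), and per-nucleus totals
  (40 sites × 76 filaments ≈ 3000 filaments; ×3 ≈ 9120 SUN monomers);
* a **seeded synthetic generator** of whole attachment-site cohorts with
  the reported statistical structure (counts, 91 ± 18 nm lengths, 5 nm
  origin spacing, 2 nm filament clearance, near-microtubule stretch
  boost), providing ground truth for every stage since the original
  tomograms are not deposited.

Input is the 5-column text dialect of IMOD's `model2point`
(`object contour x y z`, pixels) plus a YAML label map and per-site pixel
size; outputs are CSV metrics tables and JSON reports.

## Worked example

```r
library(lincQuant)

cfg <- syntheticConfig(nSites = 11, seed = 42)   # study-sized cohort
cohort <- generateCohort(cfg)                    # 5 of 11 sites with microtubule
qc <- quantifyCohort(cohort$models)              # io -> geometry -> distances -> planes -> proximity
compareCohorts(qc)
```

```
CohortReport: 5 site(s) with / 6 without microtubule
  counts KS: D = 0.4333, p = 0.550
  lengths t: t = 1.256, p = 0.210
  stretch difference (with - without): 0.0138 (p = 0.000122)
  origin spacing: min 5.02 nm; filament spacing: min 2.00 nm
  mean plate-plane extent: 144.1 nm
Force/stoichiometry model:
  dynein-dynactin complexes per site: 8
  force per site: 40 pN
  filaments per nucleus: 3054.55 (~3000)
  SUN monomers per nucleus: 9163.64; KASH monomers: 9163.64
```

Reading this: filament counts and lengths do not differ between sites
with and without a microtubule (large KS/t p-values), but filaments at
microtubule-bearing sites are measurably straighter (positive stretch
difference, tiny rank-sum p) — the conformational signature of motor
engagement. The hard spacing floors (5 nm between origins, 2 nm between
filaments) and the ~150 nm plate patch are recovered from the generated
geometry, and feeding the measured patch extent into the packing model
yields the 8-complex / 40 pN per-site bound.

Real segmentations are loaded the same way via
`readCohort("cohort.yaml")` or `readPointModel(file, labelMap, pixelSize)`;
`writeCohort()` materialises any cohort (with ground truth and manifest)
back to disk.

## Package layout

| Area | Functions |
|---|---|
| I/O | `readPointModel`, `writePointModel`, `readCohort`, `writeCohort` |
| Geometry | `pathLength`, `linearDistance`, `stretchFactor`, `findOrigin`, `assignPlate`, `filamentMetrics` |
| Distances | `minPairDistance`, `nnOriginDistances`, `nnFilamentDistances`, `globalMinimumShift`, `densityCurve` |
| Planes | `fitPlanePCA`, `platePlaneFits` |
| Proximity | `distanceToMicrotubule`, `classifyByCutoff`, `cutoffScan`, `stretchCohortCompare` |
| Tests | `ksTwoSample`, `tTwoSample`, `wilcoxonRankSum`, `summarizeValues` |
| Force model | `forceModelParams`, `maxDyneinComplexes`, `siteForce`, `nucleusTotals` |
| Synthetic | `syntheticConfig`, `generateSite`, `generateCohort`, `poissonDiskOrigins`, `rippledPolyline` |
| Reports | `quantifySite`, `quantifyCohort`, `compareCohorts`, `writeMetricsCsv`, `writeReportJson` |

The methods vignette (`vignettes/linc-filament-analysis.Rmd`) documents
the model, its assumptions, the generator design and the package's
numerical conventions in detail.
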