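# floraNMR

1H-NMR metabolite fingerprinting for flower species ingredient
verification.

Flowers sold as food, beverage and natural-health-product ingredients are
frequently traded dried, powdered or extracted, where neither morphology
nor (often) DNA can confirm the species on the label. A one-dimensional
proton NMR spectrum of a crude extract is a holistic metabolite
fingerprint: signal positions are fixed chemistry, amplitudes track
metabolite concentrations, and species differ enough in their sugar,
amino-acid, organic-acid and flavonoid complements that fingerprints
classify them. floraNMR is an R (S4 / Bioconductor-style) implementation
of the complete workflow for analysts building such authentication
panels:

* **Simulation** — a curated chemical-shift library of 20 flower
  metabolites (chemical shift δ, multiplicity, J-couplings, proton
  weights); first-order multiplet patterns (d: two lines split by J/ν₀
  ppm; t: 1/4, 1/2, 1/4; dd: four lines at (±J₁±J₂)/2ν₀); Lorentzian
  lineshapes; residual solvent peaks; Gaussian noise; and a 33-sample /
  23-species synthetic cohort generator with color-variant edits and
  splittable per-sample seeding.
* **Preprocessing** — apex calibration to the TMS/TSP reference at
  0.0 ppm and asymmetric-least-squares baseline correction.
* **Bucketing** — rectangular buckets of positive intensities without
  scaling (default 0.01 ppm wide, 1–12 ppm) with solvent exclusion
  windows (4.75–5.06, 3.16–3.45, −0.05–0.05 ppm; 1040 buckets retained),
  then per-spectrum normalization: below-mean buckets → 0, above-mean
  buckets → integers 1–100.
* **Clustering** — Euclidean distances, Ward linkage (Ward.D2 via the
  Lance–Williams recurrence, deterministic tie-breaking), tree cutting,
  species-recovery scoring, Newick export.
* **Assignment** — SNR-thresholded peak picking, multiplet grouping with
  pattern and J estimation, and all-resonances library matching
  (δ tolerance 0.03 ppm, J tolerance 1.0 Hz) with the standard
  aromatic / sugar / organic-amino region taxonomy.

Spectra are read and written as plain two-column TSV or JCAMP-DX; the
whole pipeline is driven by YAML configurations and is byte-reproducible
for a fixed seed.

## Worked example

```r
library(floraNMR)

lib <- flowerSignatureLibrary()
lib
#> SignatureLibrary: 20 metabolites, 33 resonances, 0.91 to 8.07 ppm

design <- defaultCohortDesign()
design
#> CohortDesign: 33 samples, 23 species, cv = 0.05

spectra <- generateCohort(design, lib, seed = 42)
spectra[["S01"]]
#> NMRSpectrum: 32768 points, 12.500 to -0.500 ppm
#>   sample: S01
#>   species: Rosa chinensis (pink)
#>   field: 400 MHz

tab <- buildBucketTable(spectra, BucketSpec(), normalize = TRUE)
dim(bucketValues(tab))
#> [1]   33 1040

dend <- wardLinkage(euclideanDistances(tab))
truth <- setNames(design@entries$species, design@entries$sample_id)
rec <- speciesRecovery(cutDendrogram(dend, 23), truth)
rec$recovered; rec$purity
#> [1] 23
#> [1] 1
```

All 33 samples fall into 23 pure single-species clusters — every species,
including the rose, chrysanthemum and calendula color variants, is
recovered intact (purity 1.0). Metabolite assignment works the same way
on any spectrum:

```r
p0 <- SpectrumParams(noise_sigma = 0,
                     solvent_peaks = data.frame(ppm = numeric(),
                                                amplitude = numeric()))
s <- renderSpectrum(lib, c(Sucrose = 1, Alanine = 0.5), p0)
report <- matchLibrary(groupMultiplets(pickPeaks(s)), lib)
report
#> AssignmentReport: 2 metabolites identified
#>   Sucrose, Alanine
#>   unmatched multiplets: 0
```

The full pipeline (simulate → preprocess → bucket → cluster → assign,
with CSV/Newick/JSON outputs and a parameter log) runs from one YAML
file:

```r
runPipeline(system.file("extdata", "pipeline_config.yaml",
                        package = "floraNMR"), out_dir = "run1")
```

or from the shell via `inst/scripts/run_pipeline.R`.

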