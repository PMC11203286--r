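---
title: "Methods: 1H-NMR fingerprinting for flower species verification"
author: "floraNMR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 1H-NMR fingerprinting for flower species verification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(floraNMR)
```

## The problem

Flowers traded as food, beverage and natural-health-product ingredients are
hard to authenticate once dried, powdered or extracted: the morphology that
a taxonomist would use is gone, and DNA recovery from petal tissue is often
poor. A one-dimensional proton NMR spectrum of a crude extract is a
*metabolite fingerprint*: every proton-bearing metabolite contributes
signals whose positions (chemical shifts, ppm) are species-independent
physics and whose amplitudes reflect concentrations. Two samples of the
same species give closely similar fingerprints; different species — with
different sugar, amino-acid, organic-acid and flavonoid complements — give
fingerprints different enough to classify. floraNMR implements this
workflow end to end: spectral simulation from a chemical-shift library,
referencing and baseline correction, rectangular bucketing with solvent
exclusion, per-spectrum integer normalization, Euclidean/Ward hierarchical
clustering with species-recovery scoring, and metabolite assignment by
library matching.

Because no public raw spectra exist for this application, the package
ships a synthetic-data generator as a first-class, tested module. The
generator's defaults define the study conditions under which every
downstream claim is tested: a 400 MHz instrument digitized to 32K points
over -0.5 to 12.5 ppm, 33 samples spanning 23 species, and color variants
within *Rosa chinensis*, *Chrysanthemum* x *morifolium* and *Calendula
officinalis* expressed as presence/absence and scaling of individual
resonances.

## Spectral model

A resonance is a chemical shift $\delta$ (ppm), a multiplicity code and
its scalar couplings $J$ (Hz). First-order splitting gives line offsets
and weights:

* singlet: one line, weight 1;
* doublet: two half-weight lines separated by $J/\nu_0$ ppm at
  spectrometer frequency $\nu_0$ (MHz);
* triplet: three lines spaced $J/\nu_0$, weights 1/4, 1/2, 1/4;
* doublet of doublets: four quarter-weight lines at
  $(\pm J_1 \pm J_2)/(2\nu_0)$;
* unresolved multiplet ('m', no $J$ reported): five equal lines spanning
  0.008 ppm (3.2 Hz at 400 MHz). The line spacing, 0.8 Hz, is below the
  default 1.5 Hz linewidth, so the envelope renders as a single broad
  hump — which is what "unresolved" means physically. A wider footprint
  would instead produce five resolved spikes and would fuse neighboring
  library entries (malate 2.73 / methionine 2.77 / citrate 2.79 sit only
  0.02–0.04 ppm apart) into single observations during assignment.

Each line is a unit-height Lorentzian of configurable full width at half
maximum (default 1.5 Hz, ordinary solution-state linewidth), scaled by
amount x proton weight x line weight. Residual reference and solvent
signals (TMS at 0.00 ppm, methanol at 3.31 ppm, water at 4.87 ppm — all
inside the exclusion windows below) and i.i.d. Gaussian noise (default
sigma 0.002 relative to a unit singlet, mirroring well-suppressed,
64-scan spectra) complete the model. Spectra are generated directly in
the frequency domain: there is no FID, Fourier transform, apodization or
phase-error model, so phase correction is deliberately absent from the
preprocessing stage and would be needed for real instrument data. No
pH- or temperature-dependent shift drift is modeled either.

The signature library holds 20 metabolites (33 resonances) spanning the
three canonical regions of a flower-extract spectrum: aromatic
(6.00–10.00 ppm; flavonoids such as kaempferol), sugar (3.50–6.00 ppm;
sucrose 5.41, alpha-glucose 5.15, beta-glucose 4.53, fructose), and
organic/amino acid (0.00–3.50 ppm; amino acids, succinate, acetate,
citrate, malate). One library entry, the glucose/fructose CH/CH2
envelope, is reported in the source data only as a 3.49–3.89 ppm band;
it is encoded as two unresolved multiplets at the band edges, which keeps
the envelope from chaining into the isoleucine 3.66 and leucine 3.72
multiplets during grouping. Region boundaries are assigned to the lower
region; where the literature gives the sugar-region floor inconsistently
as 3.0 or 3.50 ppm, 3.50 is used, which makes the three regions an exact
partition of 0–10 ppm.

## Cohort generator

The packaged design (`inst/extdata/synthetic_cohort.yaml`, read by
`defaultCohortDesign()`) is a *synthetic* roster: the multi-sample species
and their color variants are those discussed in the application (3 *Rosa
chinensis* colors, 4 *Chrysanthemum* samples in 3 colors, 3 *Calendula*
colors, 3 *Brassica oleracea* varieties, duplicate *Chenopodium album*),
and the remaining 18 single-sample species are common edible flowers.
Per-species mean concentration profiles are lognormal draws (sdlog 1)
with six metabolites zeroed per species, fixed once inside the fixture;
presence/absence plus amplitude differences across 20 metabolites is what
separates species fingerprints, as in real floral metabolomes.

Within a species, sample concentrations jitter lognormally with
coefficient of variation 0.05 — small, reflecting the reported
within-species consistency of replicate flowers — with the mean preserved
($\mu = \log m - \sigma^2/2$, $\sigma^2 = \log(1+cv^2)$). Color variants
add, delete or rescale specific resonances (e.g. the red rose deletes a
kaempferol line and doubles sucrose; the orange calendula gains an
aromatic-aldehyde singlet). Edit magnitudes are deliberately modest: the
study conditions require variants to remain visibly different in their
spectra *and* still cluster within their species, which bounds them from
both sides. Seeding is splittable: each sample's seed is
`subSeed(master, sample_id)` (a documented string hash), so cohorts are
reproducible sample-by-sample.

What the generator does **not** emulate: peak-position drift from pH,
temperature or ionic strength; ring-current and matrix effects; baseline
roll and phase errors from real receivers; inter-batch instrument
variation; metabolites outside the library. Passing tests therefore show
that the analysis chain is correct and discriminating under the stated
statistical structure, not that any particular real supply-chain sample
would classify correctly.

## Preprocessing

Calibration finds the intensity apex within ±0.2 ppm of the reference
position (0.0 ppm, TMS/TSP) and shifts the axis so the apex sits exactly
there; intensities are untouched. If nothing in the window exceeds a
noise floor of 3 x the (scaled) median absolute deviation of the window,
the spectrum is returned unshifted and flagged — a robust, parameter-free
guard for blank or reference-free inputs. Calibration is idempotent to
within one axis step.

Baseline correction uses asymmetric least squares: a Whittaker smoother
with second-difference penalty (smoothness 1e7 in index units) and
asymmetry 0.01, iterated at most 10 times. Points above the running
baseline get weight 0.01, points below weight 0.99, so peaks do not pull
the baseline up while offsets and slow ramps are removed. These are the
standard defaults for spectroscopy-scale baselines; the axis is never
altered.

## Bucketing and normalization

Fingerprints are rectangular buckets of **positive** intensities, without
scaling: bucket value = sum over axis points in [low, high) of
max(intensity, 0) x axis step. The default geometry is 0.01 ppm buckets
from 1 to 12 ppm (1100 buckets), with three exclusion windows — water
4.75–5.06, methanol 3.16–3.45, reference -0.05–0.05 ppm. A bucket
overlapping an exclusion window *at all* is dropped (the conservative
reading; nothing of a solvent tail can leak into a retained bucket),
which removes 31 + 29 + 0 buckets and retains exactly 1040. Edges are
computed by index arithmetic, never repeated addition, so they are exact
at 0.01 ppm steps; intervals are half-open [low, high), and each point
contributes to exactly one bucket with no interpolation.

Normalization is per spectrum, over retained buckets only: with $m$ the
arithmetic mean of the vector, values $\le m$ map to 0 and values $> m$
map linearly onto 1..100 (round half up, documented so results are
bit-identical across platforms); the smallest above-mean value becomes 1
and the largest exactly 100. The transform is invariant to overall
intensity scaling, which is what makes fingerprints comparable across
samples of different mass and receiver gain.

## Clustering

Distances are plain Euclidean on the normalized integer fingerprints
(delegated to `stats::dist`). Ward linkage is implemented in the package
via the Lance–Williams recurrence on *squared* distances with heights
reported back on the distance scale (the Ward.D2 convention — the
standard modern reading of "Ward's algorithm on a Euclidean matrix");
ties are broken by the lowest index pair so merge order is deterministic.
The implementation is verified in the test suite against two independent
routes: an exhaustive oracle that evaluates the exact variance increase
of every candidate merge from raw coordinates, and
`stats::hclust(method = "ward.D2")`. Trees cut at $k$ clusters number the
clusters by smallest member index; species recovery scores a species as
recovered only when its samples form one cluster containing no other
species. Newick export goes through `ape`; the plotting leaf order uses a
smaller-subtree-first traversal (cosmetic only).

## Assignment

Peak picking takes local maxima above `snr_threshold` (default 5) times a
noise floor estimated as 1.4826 x the median absolute deviation of the
full intensity vector — signal points are sparse, so the MAD tracks the
noise; on a noiseless spectrum the floor collapses and all genuine maxima
survive. Adjacent peaks closer than a 12 Hz window (0.03 ppm at 400 MHz,
the span of ordinary proton couplings) form one multiplet observation,
summarized by its height-weighted centroid, line count, a pattern guess,
and a coupling estimate from adjacent-line spacing (for doublets and
triplets). Pattern guessing demands regularity, not just line count: three
lines must be evenly spaced with a dominant middle line to be called 't',
and four lines must show symmetric spacings and near-equal heights to be
called 'dd' — otherwise the observation is 'unresolved', which matches any
library pattern. Without the regularity requirement, chance neighbors
(e.g. the isoleucine 1.47 hump beside the alanine doublet) masquerade as
four-line multiplets.

Matching requires, per library resonance: centroid within 0.03 ppm
(library shifts are reported to 2 decimals), compatible pattern, and —
when both sides define a coupling — agreement within 1.0 Hz (couplings
reported to 1 decimal). One deliberate compatibility rule beyond exact
code equality: a doublet of doublets whose two couplings differ by less
than the coupling tolerance is accepted in its *pseudo-triplet*
presentation (observed 't', 'd' or 's', expected $J = (J_1+J_2)/2$). This
is not a relaxation but spin physics: a dd with $J_1 = 2.0$, $J_2 = 2.1$
Hz splits its inner lines by 0.1 Hz — far below both the 1.5 Hz linewidth
and the 0.16 Hz digital resolution — and *cannot* present four lines at
this field; it is a 1:2:1 triplet to any peak picker. A metabolite is
identified only when **all** its library resonances are matched
(conservative: multi-resonance signatures like isoleucine's six shifts
cannot be claimed from one crowded peak), and one observation may serve
several metabolites, as overlapping sugar-region signals demand.
Observation intensity is deliberately *not* a matching criterion:
concentrations vary across samples even though simulated peak areas are
proton-weighted.

## Numerical and scale choices

Digital resolution at the defaults is 13/32767 ≈ 0.0004 ppm per point,
so picked positions and centroid estimates carry sub-0.001 ppm
quantization error against the 0.03 ppm matching tolerance and the 0.01
ppm centroid checks in the acceptance tests. Test problem sizes are
chosen to keep the full suite fast while exercising the real geometry:
the clustering oracle runs exhaustively at n ≤ 6 (100 random trials),
unit tests use 2K–8K-point axes and small cohorts, and the end-to-end
checks use the full 33-sample cohort at 32K points. The pipeline is
deterministic end to end: identical configuration and seed give
byte-identical CSV, Newick and JSON outputs, which the suite asserts by
rerunning the packaged configuration.

The acquisition value "2.54 ppm spectral width" reported alongside the
source instrument settings is inconsistent with spectra spanning 0–12
ppm; it is carried in the cohort fixture as acquisition metadata only and
plays no computational role. Whether real cohorts would mix methanol and
water extracts per sample is likewise unresolved in the source; the
generator labels extraction per sample and the default cohort uses
methanol throughout.

## Known limitations

* Real Bruker data need phase correction before this pipeline; the
  package starts at absorption-mode (ppm, intensity) arrays (plain TSV or
  JCAMP-DX AFFN; raw spectrometer directories are out of scope).
* The all-resonances identification rule is conservative by design: a
  metabolite whose signature is partially obscured by a true overlap will
  be reported unidentified rather than guessed.
* Cluster purity at k = number of species is a strict criterion; it says
  nothing about how close to the decision boundary a sample sits. Real
  quality-assurance use would add replicate acquisition and a
  library-match threshold tuned on authentic reference material.
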