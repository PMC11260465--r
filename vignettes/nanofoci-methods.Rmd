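---
title: "Methods: nanoscale repair-focus topology and high-content quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nanoscale repair-focus topology and high-content quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanofoci)
```

# Scope

`nanofoci` implements the quantitative chain behind a nanoscale study of
DNA double-strand-break (DSB) repair foci: STED nanoscopy resolves each
micron-scale focus into discrete *nanodomains* of repair proteins, with a
single BRCA1-marked nanodomain at the centre and partner proteins (RAD18,
53BP1) arranged around it; high-content microscopy counts repair foci per
nucleus with cell-cycle resolution; and a trichromatic "traffic light"
reporter quantifies the balance between homologous recombination (HR) and
mutagenic non-homologous end joining (NHEJ). Because the raw microscopy
data cannot ship with a package, a synthetic-data module generates images
and event tables with known ground truth, and every stage is validated
against that truth or against independent oracles.

# The synthetic scenes

`simulate_sted_scene()` emulates a dual-channel STED acquisition: 22 nm
lateral pixels, five optical sections 149.7 nm apart, photon-counting
detection. Each focus contributes one centre nanodomain (channel
`center`) and $k$ partner nanodomains (channel `partner`) with $k$ drawn
from a configurable discrete law, placed at gamma-distributed radial
distances and uniform angles. Every nanodomain is rendered as an
isotropic 2D Gaussian (default $\sigma = 25$ nm, i.e. a ~59 nm FWHM —
the lateral resolution of a well-aligned STED system) whose photon budget
is split across the z sections by a discrete Gaussian axial profile
centred on a random section; the pixel value is the integral of the
Gaussian over the pixel, so the photon budget is conserved up to the
$\pm 5\sigma$ truncation window. Poisson noise is applied last, matching
a photon-counting detector with no read noise.

Choices worth calling out:

* **Radial laws are configuration, not claims.** The study design only
  fixes the *ordering* (RAD18 proximal, 53BP1 peripheral). The defaults
  used in the analyses are gamma(9, 17) (mean 153 nm) for the proximal
  channel and gamma(20, 14) (mean 280 nm, sd 63 nm) for the peripheral
  one. The peripheral law is deliberately concentrated inside the 500 nm
  radial gate that defines a focus: nanodomains belonging to a focus live
  within it by definition, so a law with appreciable mass beyond the gate
  would describe background, not focus structure.
* **Minimum partner separation (80 nm).** Nanodomains are discrete
  chromatin clusters tens of nanometres across; two of them cannot
  occupy the same spot. The generator therefore redraws a partner that
  falls within 80 nm of a sibling (up to 1000 attempts, then an error).
  Without this physical exclusion a measurable fraction of simulated
  partner pairs would be closer than any optical system could separate —
  a property of the simulation, not of chromatin.
* **Rejection caps.** All placements (foci, nuclei, partners) use
  rejection sampling with a 1000-attempt cap and a clear error rather
  than a silent infinite loop. Focus centres keep a 1200 nm minimum
  separation so that analysis disks of neighbouring foci cannot overlap.
* **What the generator does not model:** deconvolution artefacts, drift,
  chromatic offset, detector read noise, 3D localization ground truth
  beyond the axial intensity profile. Passing tests therefore show the
  *analysis* is correct under idealized optics; they do not certify
  performance on aberrated real data.

`simulate_hcs_field()` produces non-overlapping circular nuclei
(radius 12 px at 320 nm/px) whose integrated DAPI intensity is
proportional to DNA content — 2n in G1, 4n in G2/M, uniformly in between
in S, with a lognormal spread (CV 0.08, a typical integrated-intensity
CV for flat-field-corrected high-content data). S-phase cells are
EdU-positive (mean 60 vs background 2). Marker foci are Poisson per
phase (defaults G1 = 2, S = 8, G2/M = 4) and rendered as
diffraction-limited spots. `simulate_reporter_events()` draws flow
events: a transfected (BFP+) fraction, an outcome per transfected event
(HR, mutagenic NHEJ, or neither), and lognormal positive/negative
intensity populations per channel.

# Spot detection and localization

`find_maxima()` detects local maxima by **topographic prominence**: a
peak's prominence is its height above the highest saddle on any path to
strictly higher terrain; the image border never bounds a peak, so the
global maximum has prominence `max - min`. This mirrors the
noise-tolerance semantics of the classical ImageJ-style maxima finder
while being exactly defined and oracle-checkable: the test suite
recomputes prominences by exhaustive level-set thresholding (label the
pixels $\geq L$ at every distinct level $L$ and find the first level
joining each peak to higher ground) and requires identical peak sets.
Plateaus are reported once, at their integer centroid. The
implementation is a single descending sweep with union-find component
merging, in compiled code; equal-summit components are kept jointly open
until strictly higher terrain appears, which reproduces the level-set
definition exactly (including twin global maxima).

The detection threshold is the one genuinely free parameter: the study
protocol does not report the tolerance used. `auto_tolerance()` offers a
robust default (5 x 1.4826 x MAD, falling back to the Poisson shot-noise
scale $\sqrt{\bar I}$ when more than half the pixels share one value),
but the analyses pass an explicit tolerance (10 photons for the STED
scenes, about a quarter of a nanodomain's peak amplitude) so the choice
is visible and reproducible.

`refine_subpixel()` then fits
$A\,e^{-((x-x_0)^2+(y-y_0)^2)/2\sigma^2}+b$ over a 7x7 window
(+-66 nm at 22 nm pixels) by Levenberg-Marquardt. A fit is accepted only
if it converges with $|x_0 - x_{peak}| \le 1$ px and
$\sigma \in [0.3, 5]$ px; otherwise the peak keeps integer-pixel
coordinates and is flagged, so detection *counts* are decoupled from fit
fragility. Coordinates follow the pixel-centre convention: pixel
$(i, j)$ is centred at $((i+0.5)\,\mathrm{px}, (j+0.5)\,\mathrm{px})$,
0-based.

# Focus topology

The topology stage reproduces the study's selection and measurement
rules:

* a focus centre is a centre-channel nanodomain with no other centre
  within 1000 nm (the protocol requires isolated foci with a single
  central BRCA1 nanodomain but does not quantify "non-overlapping";
  1000 nm — twice the radial gate — is the weakest criterion that
  guarantees two analysis disks cannot intersect);
* each partner nanodomain is assigned to its nearest centre and dropped
  if farther than 500 nm; the exclusion is strict ("> 500 nm"), so a
  distance of exactly 500.0 nm is retained;
* per focus: partner count, minimal and mean 2D Euclidean distance from
  the centre, all on the maximum-intensity projection (the protocol
  analyses projections; no 3D distances);
* foci with zero partners stay in the count statistics but are excluded
  from distance statistics — an undefined minimum cannot be imputed —
  and their number is reported so the exclusion is auditable.

`signal_average()` reproduces the focus-centred average image (pixel-wise
mean of square crops; partial crops at the border are skipped and
counted). `compare_groups()` runs the two-tailed Mann-Whitney U test on
any per-focus variable, the test used for all nanoscale comparisons.

# High-content quantification

Nuclei are segmented by Otsu threshold, hole filling and a
distance-transform watershed (the study used vendor software; this is an
explicit, documented substitute whose accuracy is checked on synthetic
fields). Cell-cycle gating follows the DAPI/EdU convention: S phase is
EdU-positive; EdU-negative cells split into G1 vs G2/M on integrated
DAPI (2n vs 4n). Auto gates are midpoints of deterministic 2-class
1-D k-means splits on log intensities, with centres initialized at the
observed extremes — quantile initialization fails when one class is
rare (e.g. a few percent of GFP-positive events), because both starting
centres then sit inside the majority mode. With fewer than 10 cells or
a degenerate distribution
the affected gate falls back conservatively (no S calls / all
EdU-negative cells G1) with a warning. G2 and M are merged ("G2/M");
mitotic-figure detection is out of scope.

Foci counts are normalized to 2n DNA content as

$$\mathrm{normalized\_foci} = \mathrm{foci} \times \frac{D_{2n}}{\mathrm{DAPI_{total}}},$$

with $D_{2n}$ the median integrated DAPI of G1 cells — i.e. counts per
2n DNA equivalent, so a G2/M cell with twice the DNA and the same count
reports half the normalized value. The study states the normalization
but not its formula; this reading is the one that makes the result
invariant to global DAPI gain (asserted in the tests). Colocalization
reports the per-nucleus Pearson correlation of two channels over nuclear
pixels plus object-level fractions (A-foci with a B-focus within 500 nm,
and vice versa); a constant channel yields a flagged `NA`, not an error.

# Reporter quantification

Events enter as CSV tables (the gating is pure arithmetic; FCS parsing
is a non-goal). Among BFP-positive events,
$\mathrm{pct_{HR}} = 100\,\#(\mathrm{GFP^+})/\#(\mathrm{BFP^+})$ and
likewise for RFP. Relative repair divides a sample's percentages by the
control's total $(\mathrm{pct_{HR}} + \mathrm{pct_{NHEJ}})$, so the
control self-normalizes to exactly 1. Auto thresholds are the same
deterministic 2-class log-intensity splits as in gating, and every
resolved threshold is echoed into the provenance output. The knockdown
experiment in the analysis scripts scales the true HR probability by 0.6
and simulates both arms from a shared random stream (a paired design:
the comparison then isolates the probability change rather than
compounding two independent sampling errors).

# Statistics

Standard procedures delegate to the standard implementations, wrapped to
fix conventions and checked in the suite against hand-built oracles:

* **Mann-Whitney U** — exact p by the full permutation distribution when
  $n_1 + n_2 \le 16$ and tie-free (verified against explicit enumeration
  of all $\binom{n_1+n_2}{n_1}$ assignments), otherwise normal
  approximation with tie and continuity correction (agrees with the
  exact p within 0.02 at $n = 8+8$; type-I error calibrated to
  [0.035, 0.065] at nominal 0.05 over 2000 null replicates).
* **Unpaired t-test** — pooled-variance Student's by default (that is
  the test an "unpaired two-tailed t-test" names); Welch by flag.
* **Two-way ANOVA** — fixed effects with interaction, Type II sums of
  squares (identical to Type I/III when balanced; checked against a
  cell-means oracle to 1e-9).
* **Fisher's exact test** — two-sided p as the sum of hypergeometric
  probabilities no larger than the observed table's; odds ratio as the
  conditional MLE with an exact central CI (tails inverted at
  $\alpha/2$), the convention that accompanies exact-test reporting; the
  sample OR $ad/bc$ is also emitted. A zero margin returns p = 1 with a
  flagged, undefined OR.
* **Carrier frequency** — $100\,c/n$ rounded half-up to two decimals and
  formatted (`13/17654` prints `0.07%`).

No multiple-testing correction is applied anywhere, matching the study's
reporting.

# Numerical choices and degenerate inputs

* Distances at exactly the 500 nm gate are retained (strict exclusion).
* A constant image yields zero peaks (every summit has zero prominence).
* Fit windows clipped below 9 valid pixels skip fitting and keep integer
  coordinates, flagged.
* `dapi_total = 0` makes the normalized count `NA` (flagged), never an
  error; an all-zero EdU channel produces "no S cells" with a warning.
* Seeds: every generator takes an explicit seed and restores the
  caller's RNG state, so identical configurations are bit-reproducible
  and independent of call order.

# Problem sizes

The shipped analyses and checks use 300 foci per STED condition
(15 fields x 20 foci, 512 x 512 px), 1000 nuclei per high-content field
(1600 x 1600 px), 10000 flow events per reporter arm, 500 spots for the
localization-precision estimate, 100 random images for the detection
oracle comparison, and 2000 replicates for the type-I calibration —
sizes at which the Monte-Carlo intervals asserted in the tests are a few
per cent wide while the whole battery still runs in minutes on one CPU.

# Known limitations

* Detection counts saturate when nanodomains approach within ~2 PSF
  widths; the generator's 80 nm exclusion keeps this rare, but real foci
  denser than the simulated ones would be under-counted (a limitation
  shared with any maxima-based counting, including the original
  protocol's).
* Segmentation is validated only on synthetic disk-like nuclei;
  irregular or touching real nuclei will need parameter adjustment.
* Auto gates assume clearly bimodal intensity distributions; the
  fallbacks are conservative, and gate thresholds can always be fixed
  manually.
* All topology is 2D on projections; axial structure is integrated out.
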