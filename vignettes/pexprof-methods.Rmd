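---
title: "pexprof: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pexprof: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pexprof)
```

# Scope

`pexprof` implements the quantitative core of a peroxisome-associated
translation study: a 3D ribosome-density profiler around modeled
organelle membranes, a proximity-specific ribosome-profiling enrichment
caller, and spot-colocalization statistics, together with synthetic-data
generators that provide ground truth for every stage. Everything upstream
of these quantities — image acquisition, pixel classification, read
mapping — is out of scope; the pipeline starts at membrane models plus
ribosome centroids, at aligned footprints, and at spot coordinates.

# The shell-density profiler

## Model

A peroxisome membrane is modeled as a sphere (center and radius in
pixels, isotropic pixel size 1.159 nm — anisotropic voxels are not
supported). The profiler builds `nShells = 20` concentric shells outside
the membrane, each `shellThicknessPx = 5` px thick. Conceptually these
are produced by iteratively dilating the 1-voxel membrane surface with a
5-px-radius spherical structuring element; `pexprof` implements the
equivalent *Euclidean distance bands*: shell $i$ contains the voxels
whose distance to the sphere surface lies in $((i-1)t,\ it]$, exterior
side only. For a spherical membrane the two constructions agree up to the
chamfer error of a discrete ball, and the band form makes the partition
property (shells disjoint, exhaustive over the dilation region,
monotonically growing volumes) exact — which the test suite asserts
against an exhaustive per-voxel oracle. `shellIndexVolume()` exposes the
voxel-mask representation for cross-checking.

Each ribosome centroid is projected as a sphere of
`ribosomeRadiusPx = 9` px (a ~20-nm ribosome at this calibration); the
density in a shell is the fraction of its voxels covered by at least one
projected ribosome. Ribosome spheres are effectively clipped to the
membrane exterior because shells only contain exterior voxels; whether a
centroid's sphere dips into the membrane interior therefore never
inflates a shell. The shell's x-coordinate is the mean analytic surface
distance of its voxels times the pixel size; the analytic distance
$(|\vec c - \vec m| - R)$ is exact for spheres and grid-free.

## REZ width estimator

Profiles from many organelles are averaged per shell (densities and
distances both). The exclusion-zone width is read off the averaged
profile as the distance at which the linearly interpolated profile first
reaches 50% of the cytosolic plateau, the plateau being the mean density
of the outermost 25% of shells. The estimator returns 0 when the first
shell already exceeds half the plateau (no exclusion), and errors on a
zero plateau (no cytosolic ribosomes — nothing to be excluded from).
The half-plateau rule is a deliberate choice: for a sharp exclusion
boundary convolved with a symmetric projection kernel (the 9-px ribosome
sphere), the 50% crossing sits at the true boundary. Two small,
systematic deviations remain: the occupancy is $1-e^{-\rho v}$ rather
than linear in $\rho$ (concave, shifting the crossing slightly inward),
and planted membrane-contacting ribosomes contribute density to the
innermost shells, raising the profile there. At the default preset both
effects together bias the estimate by roughly $-1.5$ nm relative to the
planted exclusion width — a fraction of one 5.8-nm shell, which is the
resolution the profile is reported at.

## Proximal ribosomes

A ribosome is membrane-proximal when $0 \le (|\vec c - \vec m| - R)
\cdot \text{px} < 20\ \text{nm}$ (strict upper bound). Centroids strictly
inside the sphere are anatomically implausible segmentation artifacts;
they are excluded from the count and reported via an attribute rather
than silently dropped. The size-association summary reports the Pearson
correlation of proximal count against radius — with the convention that
zero variance on either side yields $r = 0$ plus a `degenerate` flag —
and group means for small (diameter < 100 nm) versus large organelles.

## Centroid segmentation

For volumes (e.g., MRC-exchanged label maps) the package segments
ribosome pixels into centroids watershed-style: foreground = value
> 0.5, Euclidean distance transform (exact, Felzenszwalb's algorithm),
Gaussian smoothing at $\sigma = 2$ px (the map is only specified as
"smoothed"; a fixed $\sigma$ makes results reproducible), local maxima
as seeds with suppression within half the nominal 18-px blob diameter
(ties broken by lexicographic voxel order), nearest-seed assignment of
foreground voxels, and discarding of blobs below half the nominal
ribosome volume. Nearest-seed assignment is the flooding order that
matters for convex blob pairs, which is the regime here; a full
priority-queue watershed would differ only for strongly non-convex
clumps.

# The tomogram scene generator

The generator emulates what the profiler consumes, not electron optics:
no contrast transfer function, no shot noise, no missing wedge, no
rRNA/crowding texture — recovering the planted geometry from clean
centroids is exactly what it tests, so passing says nothing about
segmentation robustness on noisy real data (that enters only through the
watershed module, tested on its own synthetic volumes).

One scene is a slab crop of `sectionThicknessPx = 172` px (~200 nm, the
physical section) bounded in XY by the sphere plus a
`cropHalfwidthPx = 100` px margin beyond the membrane — "100 pixels
around the membrane" is read as a margin outside the surface, which also
guarantees the 20 shells always fit in XY. The slab is *not* required to
contain large spheres in Z (a 200-nm section cannot contain a 200-nm
vesicle); all masks and volumes are clipped to the crop, and densities
remain unbiased because the point process is uniform over the same crop.

Cytosolic ribosomes are a hard-core point process: $N \sim
\text{Poisson}(\rho V_{\text{free}})$ centroids placed uniformly in the
crop minus the sphere-plus-exclusion region, rejecting candidates closer
than one ribosome diameter (18 px) to an accepted centroid — ribosomes
are solid bodies, and overlap-free placement keeps the density
bookkeeping exact. $V_{\text{free}}$ is computed analytically
(sphere-box intersection by 1D quadrature of circle-rectangle sections),
and the test suite checks the generated mean count against a Monte-Carlo
volume oracle. Placement failure after a bounded number of attempts (a
density beyond jamming) is an error, not a silent under-fill.

Defaults and their reasoning:

| parameter | default | why |
|---|---|---|
| `sphereRadiusPx` | 43 px (~50 nm radius) | mid-range organelle |
| `exclusionHalfwidthNm` | 20.862 nm (= 18 px) | one projected ribosome diameter |
| `plantedProximalCount` | 2 | the observed one-to-three membrane-contacting ribosomes |
| `plantedMaxDistNm` | 20 nm | planted distances uniform in (0, 20) nm, inside the proximity gate by construction |
| `cytosolDensityPerPx3` | 2.25e-5 | calibrated once from mean = $\rho V_{\text{free}}$ so a default crop holds ~300 ribosomes (the realistic 200-400 bracket); the cytosolic concentration is a free parameter, not a measured value |
| `hardCoreDiameterPx` | 18 px | solid ~20-nm ribosomes |

The occupancy plateau this density produces is $1 - e^{-\rho v_{rib}}
\approx 0.066$, and planted proximal ribosomes contribute ~15-20% of the
plateau to the innermost shells — visible in profiles as a small
non-zero floor inside the exclusion zone.

# Footprint simulation and enrichment

## Definitions

P-sites are assigned at a 15-nt offset from the footprint 3' end toward
the read 5' direction: `psite = three_prime - 15` on plus, `+ 15` on
minus strands. Internally all coordinates are 0-based half-open; GFF3
I/O converts at the boundary through a single audited pair of functions,
and whether a footprint file records 3' ends 0- or 1-based is fixed by
this package as 0-based and documented rather than guessed per file.

Footprint *density* is reads-per-million within the gene's countable
CDS: `count * 1e6 / librarySize`. No length normalization enters the
enrichment, because the log2 ratio of matched samples cancels any
per-length factor; a per-countable-position density is reported
separately for completeness. The countable CDS excludes positions
covered by another same-strand CDS (for both genes involved);
opposite-strand overlap does not exclude. Filters: < 100 input CDS
footprints, dubious annotation, mitochondrial chromosome, empty
countable mask. z-normalized enrichments (mean/SD over passing genes)
are computed and reported; decade count bins on min(input, pulldown)
serve stratified QC only and play no role in calling.

## Calling

The 0.5 cutoff is applied to the **raw** log2 enrichment by default.
The methods convention interleaving z-normalization, count binning and
the 0.5 threshold is genuinely ambiguous; the published enrichment
scatter anchors the cutoff on the log2 axis, so raw is the default and
`mode = "normalized"` is available rather than resolved away. "Enriched"
across experiments means called in *every* bait (intersection;
`requireAllBaits = FALSE` gives the union) — a thresholding rule, not a
p-value procedure, because that is how the enrichment is defined. How
the 2- and 5-minute biotin-pulse samples were combined is likewise not
specified; per-sample calling plus the intersection/union switch exposes
both readings.

## Generator

The synthetic dataset plants `nEnriched = 40` genes at log2 effect 2.0
among `nGenes = 4540` single-CDS genes (~1500 nt, a typical CDS length)
laid out without overlap on one synthetic chromosome; input counts are
Poisson around 1000 per gene and pulldown counts Poisson around
$1000 \cdot 2^{\text{effect}}$. Library-scale matching happens through
the RPM densities at analysis time, which compresses every estimated
enrichment by the constant $\log_2 \overline{2^{e}}$ (~0.038 at the
default preset) — a property of ratio-to-library normalization, not a
bug, and well inside the 0.1 recovery tolerance the tests assert.
Planted genes are drawn from *unflagged* genes only: flags are assigned
independently (10% dubious, 1% mitochondrial), and flagging a planted
gene would make the ground truth unrecoverable by the pipeline's own
correct filters. Footprint length is fixed at 28 nt — length
heterogeneity is deliberately absent so the P-site logic is isolated;
the generator guarantees every footprint's P-site maps back inside its
source CDS, and the tests assert it. Poisson counts mean no biological
overdispersion: recovery on this generator bounds statistical noise
only, not between-replicate variability of real libraries.

# Spot colocalization

Colocalization is peroxisome-centric — the percentage of peroxisomes
with at least one mRNA spot within `thresholdNm` — matching how such
quantifications are reported. The 300-nm default approximates the
optical resolution limit at which manual counting operates; it is an
operationalization exposed as a parameter, not a measured constant, and
the estimate is monotone in it (asserted as a property test). A field
without peroxisomes yields a flagged `NA` rather than an error, so batch
summaries survive empty segmentations.

The chance level is estimated per field by resampling the mRNA channel
uniformly within the cell mask (disk or polygon) and recomputing the
percentage; this within-field permutation replaces the control-transcript
measurement used experimentally and needs no second channel pairing. For
a peroxisome at the center of a disk cell the capture probability has
the closed form $1-(1-a)^m$ with $a = (r_{thr}/r_{cell})^2$, which the
tests use as an analytic oracle.

The generator draws peroxisomes uniformly in a 2.5-µm-radius disk cell
(truncated Poisson(4) per cell, at least one), gives each a colocalized
mRNA partner with probability `trueColocProb` at a Gaussian 50-nm jitter
(resampled into the mask), and scatters the remaining copies of a
Poisson(1) total uniformly. The low default copy number is what makes
the estimator's contract hold: chance hits by untargeted copies
contribute ~0.5-1 percentage point, below the sampling error of the
estimate, so the planted probability is recoverable — a high-abundance
transcript would require the control-transcript baseline instead. The
`pex14SpotPreset()` pins `trueColocProb = 0.30`. Jitter far above the
threshold makes the truth unrecoverable by construction; the generator
records a warning rather than failing. Group comparisons wrap the
two-sided unpaired t and Mann-Whitney tests.

# Numerical choices and degenerate inputs

* Shell assignment uses half-open bands $((i-1)t, it]$; a voxel exactly
  on a band boundary belongs to the inner shell. Surface voxels
  ($d \le 0$) belong to no shell.
* The REZ crossing interpolates linearly between adjacent shell
  midpoints; a profile that never reaches half its plateau is an error.
* Empty shells (crop too small for the requested reach) error rather
  than biasing the profile.
* Watershed seed ties are broken by lexicographic voxel order; the
  suppression radius is half `minBlobDiameterPx`.
* Pearson correlation with zero variance on either margin returns 0
  with a `degenerate` flag instead of `NA`, so downstream summaries
  need no special-casing.
* A passing gene with zero pulldown density carries a $-\infty$
  sentinel, excluded from the z-normalization but reported.
* All generators require an explicit integer seed and are byte-identical
  under it; refusing to run unseeded is deliberate.
* Scene JSON without a pixel size is rejected — a calibration is never
  assumed.

# Problem sizes

The test and acceptance runs use the sizes the analyses are designed
for: 51 organelles for the averaged profile (radii 25-100 nm), 100
scenes for the count calibration check, the full 4,540-gene dual-bait
dataset at 1000 mean input footprints, and 150 cells for the
colocalization estimate; oracle-equality checks run on reduced
geometries (spheres of 5-8 px, 3-4 shells) where exhaustive enumeration
is exact. The complete suite runs in about a minute on one CPU.

# Known limitations

* Membranes are spheres; ellipsoidal or tubular organelles are not
  modeled, and the analytic distance shortcut depends on this.
* Isotropic pixels only.
* The enrichment module starts at aligned footprints: no mapping,
  rRNA/tRNA filtering, or adapter handling, and no codon-resolution
  analysis.
* The synthetic scenes contain no other organelles or membranes, so the
  "cytosolic plateau" is cleaner than in real tomograms where
  neighboring structures depress outer-shell densities.
* Colocalization is 2D (post maximum-projection); 3D distances are not
  computed.
* The permutation baseline conditions on the observed mRNA count per
  field; fields with zero mRNA have a degenerate (zero) baseline.
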