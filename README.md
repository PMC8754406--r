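# pexprof

Quantitative machinery for detecting **peroxisome-associated translation**
in yeast, for cell biologists and image/sequencing analysts working on
organelle-localized protein synthesis. The package covers the three assays
such a study rests on, each exercised end to end on synthetic data with
known ground truth:

1. **Ribosome exclusion-zone (REZ) profiling** from electron tomograms:
   given a modeled spherical organelle membrane and a set of ribosome
   centroids, measure ribosome density as a function of distance from the
   membrane and estimate the width of the depleted shell around it.
2. **Proximity-specific ribosome profiling**: gene-level translational
   enrichment of streptavidin-pulldown footprints over matched input, with
   the field's standard filters and a dual-bait calling rule.
3. **smFISH spot colocalization**: the percentage of peroxisomes with a
   nearby mRNA spot, against a permutation baseline for chance
   colocalization.

## The quantities at the core

**Shell density profile.** The membrane surface (a sphere of radius *R*,
pixel size 1.159 nm) is expanded into 20 concentric shells, each 5 px
thick (the distance-band form of iteratively dilating the 1-voxel surface
mask with a 5-px spherical structuring element). Every ribosome centroid
is projected as a sphere of 9-px radius, and the density in shell *i* is

    density_i = (ribosome voxels in shell i) / (voxels in shell i),

plotted against the mean surface distance of the shell's voxels.
Averaging profiles over organelles and taking the distance at which the
profile first reaches 50% of its cytosolic plateau (outermost 25% of
shells) gives the REZ width. A ribosome is *membrane-proximal* when its
centroid-to-surface distance `(|c - center| - R) * pixelSize` is below
20 nm.

**Enrichment.** With P-sites assigned at a 15-nt offset from the footprint
3' end (toward 5' in genome coordinates), per-gene footprint densities are
reads-per-million within the countable CDS (CDS minus same-strand overlap
with another gene), and

    log2E(g) = log2( density_pulldown(g) / density_input(g) ).

Genes with fewer than 100 input CDS footprints, dubious annotation, or a
mitochondrial location are excluded; a gene is called enriched when
log2E > 0.5 in **every** bait experiment (two baits by default).

**Colocalization.** `percent_colocalized = 100 x (#peroxisomes with an
mRNA spot within 300 nm) / (#peroxisomes)`, with a within-field
permutation baseline (mRNA resampled uniformly in the cell mask).

## Worked example

```r
library(pexprof)

# --- a synthetic tomogram crop around one peroxisome -----------------
scn  <- generateTomoScene(TomoSceneParams(seed = 1))
nRibosomes(scn$ribosomes)                        # 284
countProximal(scn$membrane, scn$ribosomes)       # 2
prof <- shellDensityProfile(scn$membrane, scn$ribosomes,
                            ShellSpec(), dims = scn$dims)
round(profileDensity(prof)[1:5], 4)  # 0.0184 0.0128 0.0102 0.0272 0.0385
estimateRezWidth(prof)                           # 23.01 nm (one scene)

# --- planted translational enrichment --------------------------------
ds  <- generateFootprintDataset(RiboSimParams(nGenes = 500L,
                                              nEnriched = 5L, seed = 2))
res <- runEnrichmentPipeline(ds)
res$called$called        # SYN0119 SYN0247 SYN0270 SYN0274 SYN0316
all(res$called$called %in% ds$truth$gene_id[ds$truth$enriched])  # TRUE

# --- spot colocalization at the PEX14 preset --------------------------
sim  <- generateSpotFields(pex14SpotPreset(nCells = 50L, seed = 3))
pcts <- vapply(sim$fields, percentColocalized, numeric(1), thresholdNm = 300)
mean(pcts)                                       # 32.4 %
randomBaseline(sim$fields[[1]], nPerm = 500, seed = 4)$baselinePercent
                                                 # 0.8 % (chance level)
```

The 284 ribosomes sit in the realistic 200-400 bracket for a 100-px crop;
the 2 proximal ribosomes are the planted membrane-contacting ones (the
cytosolic cloud is excluded from the 20.9-nm zone); the inner shells are
nearly empty while the plateau is ~0.065 occupancy, and the half-plateau
crossing lands near the planted exclusion width. A single-organelle
profile is noisy — the averaged 51-scene estimate (see below) is the
meaningful one. The enrichment caller recovers exactly the planted genes,
and the colocalization estimator returns the planted ~30% against a ~1%
chance baseline.

## Layout

- `R/`, `src/` — S4 classes, pipeline operations, Rcpp voxel kernels
- `exec/pexprof` — command-line wrapper
- `tests/testthat/` — unit, property and end-to-end suites with
  brute-force oracles
- `vignettes/pexprof-methods.Rmd` — model, parameters, generator design,
  numerical choices, limitations
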