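#' Construct a SphereMembrane
#'
#' @param center numeric(3) sphere center in pixel coordinates.
#' @param radius positive sphere radius in pixels.
#' @param pixelSizeNm physical pixel size in nm (default 1.159, the
#'   calibrated tomogram pixel size).
#' @return A \linkS4class{SphereMembrane}.
#' @examples
#' SphereMembrane(center = c(143, 143, 85.5), radius = 43)
#' @export
SphereMembrane <- function(center, radius, pixelSizeNm = 1.159) {
  new("SphereMembrane", center = as.numeric(center),
      radius = as.numeric(radius), pixelSizeNm = as.numeric(pixelSizeNm))
}

#' Construct a RibosomeSet
#'
#' @param centroids numeric matrix (n x 3) of ribosome centers, px; an
#'   empty set is allowed.
#' @param pixelSizeNm physical pixel size in nm.
#' @return A \linkS4class{RibosomeSet}.
#' @export
RibosomeSet <- function(centroids = matrix(numeric(0), ncol = 3),
                        pixelSizeNm = 1.159) {
  centroids <- as.matrix(centroids)
  if (length(centroids) == 0L) centroids <- matrix(numeric(0), ncol = 3)
  storage.mode(centroids) <- "double"
  colnames(centroids) <- c("x", "y", "z")
  new("RibosomeSet", centroids = centroids,
      pixelSizeNm = as.numeric(pixelSizeNm))
}

#' Construct a ShellSpec
#'
#' Defaults reproduce the published profiling geometry: 20 shells, each
#' 5 px thick (one 5-px-radius dilation step per shell), ribosomes projected
#' as 9-px-radius spheres.
#'
#' @param nShells number of shells.
#' @param shellThicknessPx shell thickness, px.
#' @param structRadiusPx structuring-element radius per dilation step, px.
#' @param ribosomeRadiusPx projected ribosome radius, px.
#' @return A \linkS4class{ShellSpec}.
#' @export
ShellSpec <- function(nShells = 20L, shellThicknessPx = 5L,
                      structRadiusPx = 5L, ribosomeRadiusPx = 9L) {
  new("ShellSpec", nShells = as.integer(nShells),
      shellThicknessPx = as.integer(shellThicknessPx),
      structRadiusPx = as.integer(structRadiusPx),
      ribosomeRadiusPx = as.integer(ribosomeRadiusPx))
}

#' Construct a DensityProfile
#'
#' @param shellDistanceNm mean shell distances from the membrane, nm.
#' @param density occupancy fraction per shell, in [0, 1].
#' @param nPeroxisomes number of organelles averaged (default 1).
#' @param shellThicknessNm shell thickness in nm.
#' @return A \linkS4class{DensityProfile}.
#' @export
DensityProfile <- function(shellDistanceNm, density, nPeroxisomes = 1L,
                           shellThicknessNm = NA_real_) {
  new("DensityProfile", shellDistanceNm = as.numeric(shellDistanceNm),
      density = as.numeric(density), nPeroxisomes = as.integer(nPeroxisomes),
      shellThicknessNm = as.numeric(shellThicknessNm))
}

#' Construct a GeneModel
#'
#' @param geneId gene identifier.
#' @param chrom chromosome name.
#' @param strand "+" or "-".
#' @param cdsStarts 0-based inclusive CDS interval starts.
#' @param cdsEnds 0-based exclusive CDS interval ends.
#' @param dubious logical flag; dubious genes are excluded from enrichment.
#' @param mitochondrial logical flag; mitochondrial genes are excluded.
#' @return A \linkS4class{GeneModel}.
#' @examples
#' # a GFF3 CDS 100..200 (1-based inclusive) is [99, 200) internally
#' GeneModel("YAL001C", "chrI", "+", cdsStarts = 99, cdsEnds = 200)
#' @export
GeneModel <- function(geneId, chrom, strand, cdsStarts, cdsEnds,
                      dubious = FALSE, mitochondrial = FALSE) {
  o <- order(cdsStarts)
  new("GeneModel", geneId = as.character(geneId), chrom = as.character(chrom),
      strand = as.character(strand), cdsStarts = as.numeric(cdsStarts[o]),
      cdsEnds = as.numeric(cdsEnds[o]), dubious = isTRUE(dubious),
      mitochondrial = isTRUE(mitochondrial))
}

#' Construct a FootprintTable
#'
#' @param footprints data.frame with columns chrom, strand,
#'   three_prime_pos (0-based) and length; zero rows allowed.
#' @return A \linkS4class{FootprintTable}.
#' @export
FootprintTable <- function(footprints = data.frame(
    chrom = character(0), strand = character(0),
    three_prime_pos = integer(0), length = integer(0))) {
  footprints <- as.data.frame(footprints)
  footprints$chrom <- as.character(footprints$chrom)
  footprints$strand <- as.character(footprints$strand)
  new("FootprintTable", footprints = footprints)
}

#' Construct a SpotField
#'
#' @param peroxisomes numeric matrix (n x 2) of peroxisome spots, nm.
#' @param mrna numeric matrix (m x 2) of mRNA spots, nm.
#' @param cellMask mask list; see \linkS4class{SpotField}.
#' @param fieldId field identifier.
#' @return A \linkS4class{SpotField}.
#' @export
SpotField <- function(peroxisomes, mrna, cellMask, fieldId = "field") {
  fixm <- function(m) {
    m <- as.matrix(m)
    if (length(m) == 0L) m <- matrix(numeric(0), ncol = 2)
    storage.mode(m) <- "double"
    colnames(m) <- c("x", "y")
    m
  }
  new("SpotField", peroxisomes = fixm(peroxisomes), mrna = fixm(mrna),
      cellMask = cellMask, fieldId = as.character(fieldId))
}

#' Construct a PipelineConfig
#'
#' @param pixelSizeNm tomogram pixel size, nm.
#' @param proximalThresholdNm membrane-proximity threshold for ribosomes, nm.
#' @param psiteOffsetNt P-site offset from the footprint 3' end, nt.
#' @param minInputFootprints minimum input CDS footprints per gene.
#' @param enrichmentCutoffLog2 log2 enrichment calling cutoff.
#' @param colocThresholdNm spot colocalization distance threshold, nm.
#' @param rngSeed integer seed (NA if unset).
#' @return A \linkS4class{PipelineConfig}.
#' @export
PipelineConfig <- function(pixelSizeNm = 1.159, proximalThresholdNm = 20,
                           psiteOffsetNt = 15L, minInputFootprints = 100L,
                           enrichmentCutoffLog2 = 0.5, colocThresholdNm = 300,
                           rngSeed = NA_integer_) {
  new("PipelineConfig", pixelSizeNm = as.numeric(pixelSizeNm),
      proximalThresholdNm = as.numeric(proximalThresholdNm),
      psiteOffsetNt = as.integer(psiteOffsetNt),
      minInputFootprints = as.integer(minInputFootprints),
      enrichmentCutoffLog2 = as.numeric(enrichmentCutoffLog2),
      colocThresholdNm = as.numeric(colocThresholdNm),
      rngSeed = as.integer(rngSeed))
}

#' @describeIn RibosomeSet-class Number of ribosomes in the set.
#' @param x a RibosomeSet.
#' @export
nRibosomes <- function(x) {
  stopifnot(is(x, "RibosomeSet"))
  nrow(x@centroids)
}

#' Accessors
#'
#' \code{riboCentroids} returns the centroid matrix of a
#' \linkS4class{RibosomeSet}; \code{profileDensity} and
#' \code{profileDistance} return the density and distance grids of a
#' \linkS4class{DensityProfile}; \code{pixelSizeNm} returns the physical
#' calibration of a membrane or ribosome set.
#'
#' @param x the object.
#' @return The corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
riboCentroids <- function(x) { stopifnot(is(x, "RibosomeSet")); x@centroids }

#' @rdname accessors
#' @export
profileDensity <- function(x) { stopifnot(is(x, "DensityProfile")); x@density }

#' @rdname accessors
#' @export
profileDistance <- function(x) {
  stopifnot(is(x, "DensityProfile"))
  x@shellDistanceNm
}

#' @rdname accessors
#' @export
pixelSizeNm <- function(x) {
  stopifnot(is(x, "SphereMembrane") || is(x, "RibosomeSet"))
  x@pixelSizeNm
}

#' @rdname accessors
#' @export
footprints <- function(x) { stopifnot(is(x, "FootprintTable")); x@footprints }

setMethod("show", "SphereMembrane", function(object) {
  cat(sprintf(
    "SphereMembrane: center (%.1f, %.1f, %.1f) px, radius %.1f px (%.1f nm)\n",
    object@center[1], object@center[2], object@center[3], object@radius,
    object@radius * object@pixelSizeNm))
})

setMethod("show", "RibosomeSet", function(object) {
  cat(sprintf("RibosomeSet: %d centroids (pixel size %.3f nm)\n",
              nrow(object@centroids), object@pixelSizeNm))
})

setMethod("show", "DensityProfile", function(object) {
  cat(sprintf(
    "DensityProfile: %d shells, %.1f-%.1f nm, %d organelle(s)\n",
    length(object@density), min(object@shellDistanceNm),
    max(object@shellDistanceNm), object@nPeroxisomes))
})

setMethod("show", "GeneModel", function(object) {
  flags <- c(if (object@dubious) "dubious",
             if (object@mitochondrial) "mitochondrial")
  cat(sprintf("GeneModel %s: %s%s, %d CDS interval(s), %d nt%s\n",
              object@geneId, object@chrom, object@strand,
              length(object@cdsStarts),
              sum(object@cdsEnds - object@cdsStarts),
              if (length(flags)) paste0(" [", paste(flags, collapse = ","), "]")
              else ""))
})

setMethod("show", "FootprintTable", function(object) {
  cat(sprintf("FootprintTable: %d footprints\n", nrow(object@footprints)))
})

setMethod("show", "SpotField", function(object) {
  cat(sprintf("SpotField %s: %d peroxisome spot(s), %d mRNA spot(s) [%s mask]\n",
              object@fieldId, nrow(object@peroxisomes), nrow(object@mrna),
              object@cellMask$type))
})

setMethod("show", "PipelineConfig", function(object) {
  cat("PipelineConfig:\n")
  for (s in slotNames(object))
    cat(sprintf("  %s = %s\n", s, format(slot(object, s))))
})

# total CDS length (nt) of a GeneModel, 0-based half-open bookkeeping
cdsLength <- function(gene) sum(gene@cdsEnds - gene@cdsStarts)
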