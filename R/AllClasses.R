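#' @useDynLib pexprof, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
NULL

#' Spherical organelle membrane model
#'
#' A modeled organelle boundary, as produced by fitting a sphere to a membrane
#' in a tomogram. Coordinates are in pixels of the tomogram crop (0-based
#' voxel coordinates); the physical calibration travels with the object.
#'
#' @slot center numeric(3), sphere center in pixel coordinates.
#' @slot radius positive numeric, sphere radius in pixels.
#' @slot pixelSizeNm positive numeric, physical pixel size in nm.
#' @export
setClass("SphereMembrane",
  representation(center = "numeric", radius = "numeric",
                 pixelSizeNm = "numeric"),
  validity = function(object) {
    if (length(object@center) != 3L || !all(is.finite(object@center)))
      return("center must be 3 finite coordinates")
    if (length(object@radius) != 1L || !is.finite(object@radius) ||
        object@radius <= 0)
      return("radius must be a single positive number")
    if (length(object@pixelSizeNm) != 1L || !is.finite(object@pixelSizeNm) ||
        object@pixelSizeNm <= 0)
      return("pixelSizeNm must be a single positive number")
    TRUE
  })

#' Set of ribosome centroids
#'
#' One 3D centroid per segmented ribosome, in pixel coordinates of the same
#' crop as the membrane model it accompanies.
#'
#' @slot centroids numeric matrix with one row per ribosome and columns
#'   (x, y, z), in pixels.
#' @slot pixelSizeNm positive numeric, physical pixel size in nm.
#' @export
setClass("RibosomeSet",
  representation(centroids = "matrix", pixelSizeNm = "numeric"),
  validity = function(object) {
    m <- object@centroids
    if (!is.numeric(m) || ncol(m) != 3L)
      return("centroids must be a numeric matrix with 3 columns")
    if (nrow(m) > 0L && !all(is.finite(m)))
      return("centroid coordinates must be finite")
    if (length(object@pixelSizeNm) != 1L || !is.finite(object@pixelSizeNm) ||
        object@pixelSizeNm <= 0)
      return("pixelSizeNm must be a single positive number")
    TRUE
  })

#' Shell-mask specification for the density profiler
#'
#' Defines the concentric shell masks built outward from the membrane
#' surface: \code{nShells} shells, each \code{shellThicknessPx} pixels thick
#' (the 5-px spherical structuring element used for iterative dilation),
#' and the radius of the sphere each ribosome centroid is projected as.
#'
#' @slot nShells positive integer, number of shells (default 20).
#' @slot shellThicknessPx positive integer, thickness of each shell in px
#'   (default 5).
#' @slot structRadiusPx positive integer, structuring-element radius used per
#'   dilation step (default 5; one dilation step = one shell).
#' @slot ribosomeRadiusPx positive integer, projected ribosome radius in px
#'   (default 9).
#' @export
setClass("ShellSpec",
  representation(nShells = "integer", shellThicknessPx = "integer",
                 structRadiusPx = "integer", ribosomeRadiusPx = "integer"),
  prototype(nShells = 20L, shellThicknessPx = 5L, structRadiusPx = 5L,
            ribosomeRadiusPx = 9L),
  validity = function(object) {
    for (s in c("nShells", "shellThicknessPx", "structRadiusPx",
                "ribosomeRadiusPx")) {
      v <- slot(object, s)
      if (length(v) != 1L || is.na(v) || v <= 0L)
        return(sprintf("%s must be a single positive integer", s))
    }
    TRUE
  })

#' Ribosome density as a function of distance from the membrane
#'
#' Occupancy fraction (fraction of shell volume covered by projected
#' ribosome voxels) per concentric shell, against the mean distance of each
#' shell's voxels from the membrane surface.
#'
#' @slot shellDistanceNm numeric, strictly increasing mean shell distances
#'   from the membrane surface, in nm.
#' @slot density numeric in [0, 1], occupancy fraction per shell.
#' @slot nPeroxisomes integer, number of organelle profiles averaged into
#'   this one (1 for a single-organelle profile).
#' @slot shellThicknessNm numeric, shell thickness in nm (grid identity used
#'   when averaging profiles).
#' @export
setClass("DensityProfile",
  representation(shellDistanceNm = "numeric", density = "numeric",
                 nPeroxisomes = "integer", shellThicknessNm = "numeric"),
  validity = function(object) {
    if (length(object@shellDistanceNm) != length(object@density))
      return("shellDistanceNm and density must have equal length")
    if (any(!is.finite(object@density)) ||
        any(object@density < 0 | object@density > 1))
      return("density values must lie in [0, 1]")
    if (length(object@shellDistanceNm) > 1L &&
        any(diff(object@shellDistanceNm) <= 0))
      return("shell distances must be strictly increasing")
    if (length(object@nPeroxisomes) != 1L || object@nPeroxisomes < 1L)
      return("nPeroxisomes must be a positive integer")
    TRUE
  })

#' Gene model with CDS intervals
#'
#' Internal coordinates are 0-based half-open; GFF3 I/O converts at the
#' boundary (see \code{\link{gffToZeroBased}}).
#'
#' @slot geneId character gene identifier.
#' @slot chrom character chromosome name.
#' @slot strand "+" or "-".
#' @slot cdsStarts integer, 0-based inclusive interval starts, sorted.
#' @slot cdsEnds integer, 0-based exclusive interval ends.
#' @slot dubious logical, annotated as dubious (excluded from enrichment).
#' @slot mitochondrial logical, maps to the mitochondrial chromosome.
#' @export
setClass("GeneModel",
  representation(geneId = "character", chrom = "character",
                 strand = "character", cdsStarts = "numeric",
                 cdsEnds = "numeric", dubious = "logical",
                 mitochondrial = "logical"),
  prototype(dubious = FALSE, mitochondrial = FALSE),
  validity = function(object) {
    if (!object@strand %in% c("+", "-"))
      return("strand must be '+' or '-'")
    s <- object@cdsStarts; e <- object@cdsEnds
    if (length(s) != length(e) || length(s) < 1L)
      return("cdsStarts/cdsEnds must be non-empty and of equal length")
    if (any(s < 0) || any(e <= s))
      return("intervals must satisfy 0 <= start < end")
    if (length(s) > 1L && any(s[-1] < e[-length(e)]))
      return("CDS intervals must be sorted and non-overlapping")
    TRUE
  })

#' Table of aligned ribosome footprints
#'
#' Each row is one aligned footprint, recorded by its 3' end (0-based genome
#' coordinate) and length; duplicates are allowed and each row counts once.
#'
#' @slot footprints data.frame with columns \code{chrom} (character),
#'   \code{strand} ("+"/"-"), \code{three_prime_pos} (0-based integer) and
#'   \code{length} (positive integer).
#' @export
setClass("FootprintTable",
  representation(footprints = "data.frame"),
  validity = function(object) {
    df <- object@footprints
    need <- c("chrom", "strand", "three_prime_pos", "length")
    if (!all(need %in% names(df)))
      return(paste("footprints must have columns:", paste(need, collapse = ", ")))
    if (nrow(df) > 0L) {
      if (!all(df$strand %in% c("+", "-")))
        return("strand must be '+' or '-'")
      if (any(df$three_prime_pos < 0))
        return("three_prime_pos must be >= 0")
      if (any(df$length <= 0))
        return("length must be positive")
    }
    TRUE
  })

#' Two-channel 2D spot field
#'
#' Peroxisome and mRNA spot coordinates within one cell, in nm, together
#' with the cell mask (a disk or polygon) they are constrained to.
#'
#' @slot peroxisomes numeric matrix (n x 2) of peroxisome spot positions, nm.
#' @slot mrna numeric matrix (m x 2) of mRNA spot positions, nm.
#' @slot cellMask list describing the mask: either
#'   \code{list(type = "disk", center = c(x, y), radius = r)} or
#'   \code{list(type = "polygon", vertices = <k x 2 matrix>)}, in nm.
#' @slot fieldId character identifier of the field/cell.
#' @export
setClass("SpotField",
  representation(peroxisomes = "matrix", mrna = "matrix", cellMask = "list",
                 fieldId = "character"),
  validity = function(object) {
    for (nm in c("peroxisomes", "mrna")) {
      m <- slot(object, nm)
      if (!is.numeric(m) || ncol(m) != 2L)
        return(sprintf("%s must be a numeric matrix with 2 columns", nm))
      if (nrow(m) > 0L && !all(is.finite(m)))
        return(sprintf("%s coordinates must be finite", nm))
    }
    mk <- object@cellMask
    if (is.null(mk$type) || !mk$type %in% c("disk", "polygon"))
      return("cellMask$type must be 'disk' or 'polygon'")
    if (mk$type == "disk" &&
        (length(mk$center) != 2L || length(mk$radius) != 1L || mk$radius <= 0))
      return("disk mask needs center (x, y) and positive radius")
    if (mk$type == "polygon" &&
        (!is.matrix(mk$vertices) || ncol(mk$vertices) != 2L ||
         nrow(mk$vertices) < 3L))
      return("polygon mask needs a vertex matrix with >= 3 rows")
    ok <- pointsInMask(rbind(object@peroxisomes, object@mrna), mk,
                       tol = 1e-6)
    if (!all(ok)) return("all spots must lie inside the cell mask")
    TRUE
  })

#' Pipeline configuration
#'
#' Houses the calibration constants and thresholds shared across the
#' pipeline stages: the tomogram pixel size, the membrane-proximity
#' threshold for ribosomes, the P-site offset from the footprint 3' end,
#' the minimum input footprint count for a gene to enter enrichment
#' analysis, the log2 enrichment calling cutoff and the spot colocalization
#' distance threshold.
#'
#' @slot pixelSizeNm positive numeric, default 1.159.
#' @slot proximalThresholdNm positive numeric, default 20.
#' @slot psiteOffsetNt non-negative integer, default 15.
#' @slot minInputFootprints positive integer, default 100.
#' @slot enrichmentCutoffLog2 numeric, default 0.5.
#' @slot colocThresholdNm positive numeric, default 300.
#' @slot rngSeed integer seed (NA if unset).
#' @export
setClass("PipelineConfig",
  representation(pixelSizeNm = "numeric", proximalThresholdNm = "numeric",
                 psiteOffsetNt = "integer", minInputFootprints = "integer",
                 enrichmentCutoffLog2 = "numeric", colocThresholdNm = "numeric",
                 rngSeed = "integer"),
  prototype(pixelSizeNm = 1.159, proximalThresholdNm = 20,
            psiteOffsetNt = 15L, minInputFootprints = 100L,
            enrichmentCutoffLog2 = 0.5, colocThresholdNm = 300,
            rngSeed = NA_integer_),
  validity = function(object) {
    if (object@pixelSizeNm <= 0) return("pixelSizeNm must be positive")
    if (object@proximalThresholdNm <= 0)
      return("proximalThresholdNm must be positive")
    if (is.na(object@psiteOffsetNt) || object@psiteOffsetNt < 0L)
      return("psiteOffsetNt must be >= 0")
    if (is.na(object@minInputFootprints) || object@minInputFootprints <= 0L)
      return("minInputFootprints must be positive")
    if (!is.finite(object@enrichmentCutoffLog2))
      return("enrichmentCutoffLog2 must be finite")
    if (object@colocThresholdNm <= 0)
      return("colocThresholdNm must be positive")
    TRUE
  })
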