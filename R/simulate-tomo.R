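#' Parameters for synthetic tomogram scenes
#'
#' Describes the simulated crop around one spherical organelle: a slab of
#' \code{sectionThicknessPx} (the ~200-nm physical section) bounded in XY by
#' the sphere plus a \code{cropHalfwidthPx} margin beyond the membrane, a
#' uniform cytosolic ribosome point cloud with a hard exclusion zone of
#' \code{exclusionHalfwidthNm} outside the membrane and a hard-core minimum
#' spacing of one ribosome diameter between centroids, plus
#' \code{plantedProximalCount} extra ribosomes placed at surface distance
#' uniform in (0, \code{plantedMaxDistNm}).
#'
#' The default cytosolic density is calibrated once so that a default crop
#' holds on the order of 300 ribosomes (the realistic 200-400 bracket for a
#' 100-px crop); the exclusion half-width defaults to one projected ribosome
#' diameter (18 px = 20.862 nm at 1.159 nm/px).
#'
#' @slot sphereRadiusPx positive real, sphere radius (px); default 43.
#' @slot cropHalfwidthPx positive integer, XY margin beyond the membrane
#'   surface (px); default 100.
#' @slot sectionThicknessPx positive integer, slab thickness in Z (px);
#'   default 172 (~200 nm).
#' @slot cytosolDensityPerPx3 non-negative real, cytosolic centroid density
#'   per px^3; default 2.25e-5.
#' @slot exclusionHalfwidthNm non-negative real, width of the planted
#'   exclusion zone outside the membrane (nm); default 20.862.
#' @slot plantedProximalCount non-negative integer; default 2.
#' @slot plantedMaxDistNm positive real, upper bound of planted surface
#'   distances (nm); default 20 (the proximity threshold).
#' @slot hardCoreDiameterPx positive real, minimum centroid spacing (px);
#'   default 18 (one ribosome diameter).
#' @slot pixelSizeNm positive real; default 1.159.
#' @slot seed integer RNG seed; must be set before generating.
#' @export
setClass("TomoSceneParams",
  representation(sphereRadiusPx = "numeric", cropHalfwidthPx = "integer",
                 sectionThicknessPx = "integer",
                 cytosolDensityPerPx3 = "numeric",
                 exclusionHalfwidthNm = "numeric",
                 plantedProximalCount = "integer", plantedMaxDistNm = "numeric",
                 hardCoreDiameterPx = "numeric", pixelSizeNm = "numeric",
                 seed = "integer"),
  prototype(sphereRadiusPx = 43, cropHalfwidthPx = 100L,
            sectionThicknessPx = 172L, cytosolDensityPerPx3 = 2.25e-5,
            exclusionHalfwidthNm = 20.862, plantedProximalCount = 2L,
            plantedMaxDistNm = 20, hardCoreDiameterPx = 18,
            pixelSizeNm = 1.159, seed = NA_integer_),
  validity = function(object) {
    if (object@sphereRadiusPx <= 0) return("sphereRadiusPx must be positive")
    if (object@cropHalfwidthPx <= 0L) return("cropHalfwidthPx must be positive")
    if (object@sectionThicknessPx <= 0L)
      return("sectionThicknessPx must be positive")
    if (object@cytosolDensityPerPx3 < 0)
      return("cytosolDensityPerPx3 must be >= 0")
    if (object@exclusionHalfwidthNm < 0)
      return("exclusionHalfwidthNm must be >= 0")
    if (object@plantedProximalCount < 0L)
      return("plantedProximalCount must be >= 0")
    if (object@plantedMaxDistNm <= 0) return("plantedMaxDistNm must be positive")
    if (object@hardCoreDiameterPx <= 0)
      return("hardCoreDiameterPx must be positive")
    if (object@pixelSizeNm <= 0) return("pixelSizeNm must be positive")
    TRUE
  })

#' @rdname TomoSceneParams-class
#' @param ... slot values overriding the defaults (see slots).
#' @return A \code{TomoSceneParams} object.
#' @export
TomoSceneParams <- function(...) {
  args <- list(...)
  for (s in c("cropHalfwidthPx", "sectionThicknessPx", "plantedProximalCount",
              "seed"))
    if (!is.null(args[[s]])) args[[s]] <- as.integer(args[[s]])
  do.call(new, c(list("TomoSceneParams"), args))
}

# area of {x in [0,a], y in [0,b], x^2+y^2 <= r^2}
.quarterCircRect <- function(r, a, b) {
  if (r <= 0) return(0)
  a <- min(a, r); b <- min(b, r)
  if (a <= 0 || b <= 0) return(0)
  if (a * a + b * b <= r * r) return(a * b)
  F <- function(x) (x * sqrt(pmax(r^2 - x^2, 0)) + r^2 * asin(pmin(x / r, 1))) / 2
  x1 <- min(a, sqrt(max(r^2 - b^2, 0)))
  b * x1 + (F(a) - F(x1))
}

#' Volume of a centered sphere clipped to a centered box
#'
#' Exact (to quadrature accuracy) volume of the intersection between a
#' sphere of radius \code{r} and a box of half-widths \code{ax, ay, az},
#' both centered at the origin. Used for the free-volume bookkeeping of the
#' scene generator.
#'
#' @param r sphere radius.
#' @param ax,ay,az box half-widths.
#' @return The intersection volume.
#' @export
sphereBoxVolume <- function(r, ax, ay, az) {
  if (r <= 0) return(0)
  zmax <- min(az, r)
  f <- function(z) vapply(z, function(zz)
    4 * .quarterCircRect(sqrt(max(r^2 - zz^2, 0)), ax, ay), numeric(1))
  2 * stats::integrate(f, 0, zmax, rel.tol = 1e-9)$value
}

# continuous free volume of a scene's crop: box minus (sphere + exclusion)
sceneFreeVolume <- function(params) {
  cx <- ceiling(params@sphereRadiusPx + params@cropHalfwidthPx)
  nz <- params@sectionThicknessPx
  Rex <- params@sphereRadiusPx +
    params@exclusionHalfwidthNm / params@pixelSizeNm
  Lx <- 2 * cx
  Lz <- nz - 1
  Lx * Lx * Lz - sphereBoxVolume(Rex, Lx / 2, Lx / 2, Lz / 2)
}

#' Generate a synthetic tomogram scene with known ground truth
#'
#' Draws a Poisson number of cytosolic ribosome centroids uniformly in the
#' crop minus the sphere-plus-exclusion-zone region, with a hard-core
#' minimum spacing between centroids, then plants
#' \code{plantedProximalCount} additional membrane-proximal ribosomes at
#' surface distances uniform in (0, \code{plantedMaxDistNm}) nm. The crop is
#' the box \code{[0, dims - 1]} with the sphere at its center.
#'
#' @param params a \linkS4class{TomoSceneParams} with \code{seed} set.
#' @return A list: \code{membrane} (\linkS4class{SphereMembrane}),
#'   \code{ribosomes} (\linkS4class{RibosomeSet}), \code{labels}
#'   (data.frame with per-centroid \code{kind} "cytosolic"/"proximal" and
#'   \code{surface_dist_nm}), \code{dims} (crop dimensions) and
#'   \code{params}.
#' @examples
#' scn <- generateTomoScene(TomoSceneParams(seed = 1))
#' nRibosomes(scn$ribosomes)
#' @export
generateTomoScene <- function(params) {
  stopifnot(is(params, "TomoSceneParams"))
  validObject(params)
  if (is.na(params@seed)) stop("params@seed must be set")
  set.seed(params@seed)
  px <- params@pixelSizeNm
  R <- params@sphereRadiusPx
  cx <- ceiling(R + params@cropHalfwidthPx)
  nz <- params@sectionThicknessPx
  dims <- c(2L * cx + 1L, 2L * cx + 1L, nz)
  center <- c(cx, cx, (nz - 1) / 2)
  Rex <- R + params@exclusionHalfwidthNm / px
  hc2 <- params@hardCoreDiameterPx^2
  Lx <- 2 * cx; Lz <- nz - 1

  vfree <- sceneFreeVolume(params)
  nCyt <- if (params@cytosolDensityPerPx3 > 0)
    stats::rpois(1, params@cytosolDensityPerPx3 * vfree) else 0L
  pts <- matrix(NA_real_, nrow = nCyt + params@plantedProximalCount, ncol = 3)
  placed <- 0L
  minSep2 <- function(p) {
    if (placed == 0L) return(Inf)
    d <- pts[seq_len(placed), , drop = FALSE]
    min((d[, 1] - p[1])^2 + (d[, 2] - p[2])^2 + (d[, 3] - p[3])^2)
  }
  attempts <- 0L
  maxAttempts <- 1000L + 500L * nCyt
  while (placed < nCyt) {
    attempts <- attempts + 1L
    if (attempts > maxAttempts)
      stop("cytosolic density too high: hard-core placement failed after ",
           maxAttempts, " attempts")
    p <- c(stats::runif(1, 0, Lx), stats::runif(1, 0, Lx),
           stats::runif(1, 0, Lz))
    if (sum((p - center)^2) <= Rex^2) next
    if (minSep2(p) < hc2) next
    placed <- placed + 1L
    pts[placed, ] <- p
  }
  plantedDist <- numeric(0)
  for (i in seq_len(params@plantedProximalCount)) {
    ok <- FALSE
    for (try in seq_len(10000L)) {
      dNm <- stats::runif(1, 0, params@plantedMaxDistNm)
      u <- stats::rnorm(3)
      u <- u / sqrt(sum(u^2))
      p <- center + (R + dNm / px) * u
      if (any(p < 0) || any(p > c(Lx, Lx, Lz))) next
      if (minSep2(p) < hc2) next
      placed <- placed + 1L
      pts[placed, ] <- p
      plantedDist <- c(plantedDist, dNm)
      ok <- TRUE
      break
    }
    if (!ok) stop("failed to place planted proximal ribosome ", i)
  }
  pts <- pts[seq_len(placed), , drop = FALSE]
  surfDistNm <- (sqrt(colSums((t(pts) - center)^2)) - R) * px
  labels <- data.frame(
    kind = rep(c("cytosolic", "proximal"),
               c(nCyt, params@plantedProximalCount)),
    surface_dist_nm = surfDistNm)
  list(membrane = SphereMembrane(center, R, px),
       ribosomes = RibosomeSet(pts, px),
       labels = labels, dims = dims, params = params)
}

#' Voxelize a scene into a labeled volume
#'
#' Produces an integer volume over the grid \code{[0, dims - 1]}: 0 =
#' background, 1 = membrane surface (1-voxel-thick spherical shell), 2 =
#' ribosome voxels (union of spheres of \code{ribosomeRadiusPx} around each
#' centroid; membrane label takes precedence where they touch).
#'
#' @param membrane a \linkS4class{SphereMembrane}.
#' @param ribosomes a \linkS4class{RibosomeSet}.
#' @param dims integer(3) volume dimensions.
#' @param ribosomeRadiusPx projected ribosome radius (default 9 px).
#' @return Integer 3D array of labels.
#' @export
voxelizeScene <- function(membrane, ribosomes, dims, ribosomeRadiusPx = 9) {
  stopifnot(is(membrane, "SphereMembrane"), is(ribosomes, "RibosomeSet"),
            length(dims) == 3L)
  dims <- as.integer(dims)
  cents <- ribosomes@centroids
  if (nrow(cents) > 0L &&
      (any(cents < 0) || any(t(cents) > (dims - 1))))
    stop("centroid outside volume extent")
  mem <- cpp_surface_mask(dims, membrane@center, membrane@radius)
  rib <- if (nrow(cents) > 0L)
    cpp_raster_spheres(dims, cents, ribosomeRadiusPx)
  else logical(prod(dims))
  lab <- integer(prod(dims))
  lab[rib] <- 2L
  lab[mem] <- 1L
  array(lab, dim = dims)
}
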