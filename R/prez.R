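#' Ribosome density profile in concentric shells around the membrane
#'
#' Builds \code{nShells} disjoint shell masks outside the membrane surface
#' (shell i holds the voxels whose Euclidean distance to the surface lies in
#' \code{((i-1) t, i t]} with t the shell thickness — the distance-band form
#' of iteratively dilating the 1-voxel surface mask with a spherical
#' structuring element), projects every ribosome centroid as a sphere of
#' \code{ribosomeRadiusPx}, and reports per shell the fraction of shell
#' volume occupied by ribosome voxels against the mean surface distance of
#' the shell's voxels. Ribosome spheres are clipped to the membrane
#' exterior by construction (shells only contain exterior voxels).
#'
#' @param membrane a \linkS4class{SphereMembrane}.
#' @param ribosomes a \linkS4class{RibosomeSet} in the same crop coordinates.
#' @param spec a \linkS4class{ShellSpec}.
#' @param dims integer(3) crop dimensions; the grid is \code{[0, dims - 1]}.
#'   When NULL a cube just covering the full shell reach around the
#'   membrane center is used.
#' @return A \linkS4class{DensityProfile} (one organelle).
#' @export
shellDensityProfile <- function(membrane, ribosomes, spec = ShellSpec(),
                                dims = NULL) {
  stopifnot(is(membrane, "SphereMembrane"), is(ribosomes, "RibosomeSet"),
            is(spec, "ShellSpec"))
  if (abs(membrane@pixelSizeNm - ribosomes@pixelSizeNm) > 1e-9)
    stop("membrane and ribosome pixel sizes differ")
  reach <- spec@nShells * spec@shellThicknessPx
  if (is.null(dims))
    dims <- as.integer(ceiling(membrane@center + membrane@radius + reach) + 1)
  dims <- as.integer(dims)
  cents <- ribosomes@centroids
  rib <- if (nrow(cents) > 0L)
    cpp_raster_spheres(dims, cents, spec@ribosomeRadiusPx)
  else logical(prod(dims))
  tal <- cpp_shell_tally(dims, membrane@center, membrane@radius,
                         spec@shellThicknessPx, spec@nShells, rib)
  if (any(tal$volume == 0))
    stop("empty shell mask: crop too small for ", spec@nShells, " shells of ",
         spec@shellThicknessPx, " px")
  px <- membrane@pixelSizeNm
  DensityProfile(shellDistanceNm = tal$dist_sum / tal$volume * px,
                 density = tal$occupied / tal$volume,
                 nPeroxisomes = 1L,
                 shellThicknessNm = spec@shellThicknessPx * px)
}

#' Shell-index volume (mask cross-check path)
#'
#' Returns, for every voxel of the grid \code{[0, dims - 1]}, the index of
#' the shell it belongs to (1..nShells; 0 for the membrane interior, the
#' surface, and voxels beyond the shell reach). This is the voxel-mask
#' representation of the shell masks used by \code{shellDensityProfile} and
#' exists so the mask path can be compared against the analytic path.
#'
#' @inheritParams shellDensityProfile
#' @return Integer 3D array of shell indices.
#' @export
shellIndexVolume <- function(membrane, dims, spec = ShellSpec()) {
  dims <- as.integer(dims)
  array(cpp_shell_index(dims, membrane@center, membrane@radius,
                        spec@shellThicknessPx, spec@nShells), dim = dims)
}

#' Average density profiles across organelles
#'
#' Per-shell arithmetic mean of densities and of mean shell distances over
#' a set of profiles sharing the same shell grid.
#'
#' @param profiles list of \linkS4class{DensityProfile}.
#' @return A \linkS4class{DensityProfile} with \code{nPeroxisomes} equal to
#'   the number of profiles.
#' @export
averageProfiles <- function(profiles) {
  if (length(profiles) == 0L) stop("no profiles to average")
  stopifnot(all(vapply(profiles, is, logical(1), "DensityProfile")))
  n <- length(profiles[[1]]@density)
  th <- profiles[[1]]@shellThicknessNm
  for (p in profiles) {
    if (length(p@density) != n ||
        (!is.na(th) && !is.na(p@shellThicknessNm) &&
         abs(p@shellThicknessNm - th) > 1e-9))
      stop("profiles do not share the same shell grid")
  }
  dens <- rowMeans(vapply(profiles, profileDensity, numeric(n)))
  dist <- rowMeans(vapply(profiles, profileDistance, numeric(n)))
  DensityProfile(dist, dens,
                 nPeroxisomes = sum(vapply(profiles,
                                           function(p) p@nPeroxisomes,
                                           integer(1))),
                 shellThicknessNm = th)
}

#' Estimate the ribosome-exclusion-zone width from an averaged profile
#'
#' The cytosolic plateau is the mean density over the outermost 25% of
#' shells; the REZ width is the distance at which the linearly interpolated
#' profile first reaches 50% of that plateau (0 when the innermost shell
#' already exceeds it). For a sharp exclusion boundary blurred by a
#' symmetric projection kernel, the half-plateau crossing recovers the true
#' boundary position.
#'
#' @param avg a \linkS4class{DensityProfile} (typically averaged).
#' @return REZ width in nm.
#' @export
estimateRezWidth <- function(avg) {
  stopifnot(is(avg, "DensityProfile"))
  dens <- avg@density
  dist <- avg@shellDistanceNm
  n <- length(dens)
  outer <- dens[seq.int(n - max(1L, floor(n / 4)) + 1L, n)]
  plateau <- mean(outer)
  if (plateau <= 0)
    stop("zero plateau density: no cytosolic ribosomes in the outer shells")
  half <- plateau / 2
  if (dens[1] >= half) return(0)
  i <- which(dens >= half)[1]
  if (is.na(i))
    stop("profile never reaches half of the plateau density")
  # linear interpolation between shells i-1 and i
  dist[i - 1] + (half - dens[i - 1]) / (dens[i] - dens[i - 1]) *
    (dist[i] - dist[i - 1])
}

#' Count membrane-proximal ribosomes
#'
#' A ribosome is proximal when its centroid-to-surface distance
#' \code{(|centroid - center| - radius) * pixelSize} is non-negative and
#' strictly less than \code{thresholdNm}. Centroids strictly inside the
#' sphere are excluded from the count and reported via the
#' \code{insideCount} attribute.
#'
#' @param membrane a \linkS4class{SphereMembrane}.
#' @param ribosomes a \linkS4class{RibosomeSet}.
#' @param thresholdNm proximity threshold in nm (default 20).
#' @return Integer count with attribute \code{insideCount}.
#' @export
countProximal <- function(membrane, ribosomes, thresholdNm = 20) {
  stopifnot(is(membrane, "SphereMembrane"), is(ribosomes, "RibosomeSet"))
  if (thresholdNm <= 0) stop("thresholdNm must be positive")
  if (abs(membrane@pixelSizeNm - ribosomes@pixelSizeNm) > 1e-9)
    stop("membrane and ribosome pixel sizes differ")
  cents <- ribosomes@centroids
  if (nrow(cents) == 0L) {
    out <- 0L
    attr(out, "insideCount") <- 0L
    return(out)
  }
  dNm <- (sqrt(colSums((t(cents) - membrane@center)^2)) - membrane@radius) *
    membrane@pixelSizeNm
  out <- sum(dNm >= 0 & dNm < thresholdNm)
  attr(out, "insideCount") <- sum(dNm < 0)
  out
}

#' Association between proximal ribosome count and organelle size
#'
#' Pearson correlation of proximal count against radius, plus mean counts
#' for small (diameter < 100 nm) and large (diameter >= 100 nm) organelles.
#' When either variable has zero variance the correlation is reported as 0
#' with \code{degenerate = TRUE}.
#'
#' @param records data.frame with columns \code{radius_nm} and
#'   \code{proximal_count}; at least 3 rows.
#' @return List with \code{pearsonR}, \code{degenerate}, \code{meanSmall},
#'   \code{meanLarge}, \code{nSmall}, \code{nLarge}.
#' @export
proximalSizeAssociation <- function(records) {
  stopifnot(all(c("radius_nm", "proximal_count") %in% names(records)))
  if (nrow(records) < 3L) stop("need at least 3 records for a correlation")
  r <- records$radius_nm
  k <- records$proximal_count
  degenerate <- stats::var(r) == 0 || stats::var(k) == 0
  small <- r < 50          # diameter < 100 nm
  list(pearsonR = if (degenerate) 0 else stats::cor(r, k),
       degenerate = degenerate,
       meanSmall = if (any(small)) mean(k[small]) else NA_real_,
       meanLarge = if (any(!small)) mean(k[!small]) else NA_real_,
       nSmall = sum(small), nLarge = sum(!small))
}

#' Segment ribosome centroids from a labeled or probability volume
#'
#' Splits the foreground (ribosome pixels, value > 0.5) into blobs by a
#' watershed-style procedure: the Euclidean distance transform of the
#' foreground is Gaussian-smoothed (sigma 2 px), its local maxima (with
#' suppression within half the nominal blob diameter, ties broken by voxel
#' order) seed the split, and each foreground voxel joins its nearest seed.
#' Blobs smaller than half the nominal ribosome volume are discarded.
#'
#' @param volume 3D numeric/logical array (binary or probability map).
#' @param minBlobDiameterPx nominal blob diameter (default 18 px, one
#'   ribosome).
#' @param pixelSizeNm pixel calibration attached to the result.
#' @param sigma smoothing sigma in px before seed detection (default 2).
#' @return A \linkS4class{RibosomeSet} with one centroid per retained blob.
#' @export
segmentRibosomeCentroids <- function(volume, minBlobDiameterPx = 18,
                                     pixelSizeNm = 1.159, sigma = 2) {
  if (!is.array(volume) || length(dim(volume)) != 3L)
    stop("volume must be a 3D array")
  dims <- dim(volume)
  fg <- as.logical(volume > 0.5)
  if (!any(fg)) return(RibosomeSet(pixelSizeNm = pixelSizeNm))
  edt <- sqrt(cpp_edt3d(fg, dims))
  sm <- cpp_gauss3d(edt, dims, sigma)
  seeds <- cpp_local_maxima(sm, dims, fg, min_sep = minBlobDiameterPx / 2)
  if (nrow(seeds) == 0L) return(RibosomeSet(pixelSizeNm = pixelSizeNm))
  labs <- cpp_nearest_seed_label(fg, dims, seeds)
  idx <- which(labs > 0L)
  lab <- labs[idx]
  i0 <- (idx - 1L) %% dims[1]
  j0 <- ((idx - 1L) %/% dims[1]) %% dims[2]
  k0 <- (idx - 1L) %/% (dims[1] * dims[2])
  sizes <- tabulate(lab, nbins = nrow(seeds))
  minVol <- 0.5 * 4 / 3 * pi * (minBlobDiameterPx / 2)^3
  keep <- which(sizes >= minVol)
  if (length(keep) == 0L) return(RibosomeSet(pixelSizeNm = pixelSizeNm))
  cents <- cbind(
    rowsum(as.numeric(i0), lab)[, 1] / sizes,
    rowsum(as.numeric(j0), lab)[, 1] / sizes,
    rowsum(as.numeric(k0), lab)[, 1] / sizes)
  RibosomeSet(cents[keep, , drop = FALSE], pixelSizeNm)
}
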