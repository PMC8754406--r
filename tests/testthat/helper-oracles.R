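# Independent brute-force oracles used across the test files. These stay
# deliberately naive (loops, enumeration, set arithmetic) so they cannot
# share a bug with the vectorized/compiled implementation paths.

# number of lattice voxels of the grid [0, dims-1] within `radius` of
# `center`, by exhaustive enumeration over the full grid
oracleSphereVoxelCount <- function(center, radius, dims) {
  n <- 0L
  for (k in 0:(dims[3] - 1))
    for (j in 0:(dims[2] - 1))
      for (i in 0:(dims[1] - 1))
        if ((i - center[1])^2 + (j - center[2])^2 + (k - center[3])^2 <=
            radius^2)
          n <- n + 1L
  n
}

# per-shell (volume, occupied) by exhaustive per-voxel evaluation:
# shell s = surface distance in ((s-1)*t, s*t]; occupied = within
# riboRadius of any centroid
oracleShellTally <- function(center, R, thickness, nshells, dims, cents,
                             riboRadius) {
  vol <- occ <- numeric(nshells)
  dsum <- numeric(nshells)
  for (k in 0:(dims[3] - 1))
    for (j in 0:(dims[2] - 1))
      for (i in 0:(dims[1] - 1)) {
        d <- sqrt((i - center[1])^2 + (j - center[2])^2 + (k - center[3])^2) - R
        if (d <= 0) next
        s <- ceiling(d / thickness)
        if (s < 1 || s > nshells) next
        vol[s] <- vol[s] + 1
        dsum[s] <- dsum[s] + d
        if (nrow(cents) > 0) {
          dd <- apply(cents, 1, function(cc)
            (i - cc[1])^2 + (j - cc[2])^2 + (k - cc[3])^2)
          if (min(dd) <= riboRadius^2) occ[s] <- occ[s] + 1
        }
      }
  list(volume = vol, occupied = occ, dist_sum = dsum)
}

# pairwise-distance proximal count: surface distance in [0, thr) nm
oracleProximalCount <- function(center, R, px, cents, thrNm) {
  n <- 0L
  for (i in seq_len(nrow(cents))) {
    d <- (sqrt(sum((cents[i, ] - center)^2)) - R) * px
    if (d >= 0 && d < thrNm) n <- n + 1L
  }
  n
}

# countable-mask oracle by explicit position sets (0-based positions)
oracleCountableMask <- function(genes) {
  pos <- lapply(genes, function(g)
    unlist(mapply(seq, g@cdsStarts, g@cdsEnds - 1, SIMPLIFY = FALSE)))
  key <- vapply(genes, function(g) paste(g@chrom, g@strand), character(1))
  out <- vector("list", length(genes))
  for (i in seq_along(genes)) {
    others <- unlist(pos[setdiff(which(key == key[i]), i)])
    out[[i]] <- sort(setdiff(pos[[i]], others))
  }
  names(out) <- vapply(genes, function(g) g@geneId, character(1))
  out
}

# mask intervals (data.frame start/end, 0-based half-open) -> position set
maskToPositions <- function(m) {
  if (nrow(m) == 0) return(integer(0))
  sort(unlist(mapply(seq, m$start, m$end - 1, SIMPLIFY = FALSE)))
}

# textbook pooled-variance two-sample t statistic
oracleTStat <- function(a, b) {
  sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) /
    (length(a) + length(b) - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
}

# hand-built countAndDensity output for genes with full countable masks
mkDensity <- function(genes, counts, librarySize) {
  lens <- vapply(genes, function(g) sum(g@cdsEnds - g@cdsStarts), numeric(1))
  rpm <- counts * 1e6 / librarySize
  data.frame(gene_id = vapply(genes, function(g) g@geneId, character(1)),
             count = as.integer(counts), density_rpm = rpm,
             density_per_position = rpm / lens, countable_length = lens,
             empty_mask = FALSE, stringsAsFactors = FALSE)
}
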