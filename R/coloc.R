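# point-in-mask test shared by SpotField validity and the permutation
# baseline; tol expands the mask slightly to absorb round-tripped floats
pointsInMask <- function(pts, mask, tol = 0) {
  pts <- as.matrix(pts)
  if (nrow(pts) == 0L) return(logical(0))
  if (mask$type == "disk") {
    d2 <- (pts[, 1] - mask$center[1])^2 + (pts[, 2] - mask$center[2])^2
    return(d2 <= (mask$radius * (1 + tol))^2)
  }
  # even-odd ray casting for polygon masks
  v <- mask$vertices
  nv <- nrow(v)
  apply(pts, 1, function(p) {
    inside <- FALSE
    j <- nv
    for (i in seq_len(nv)) {
      if ((v[i, 2] > p[2]) != (v[j, 2] > p[2]) &&
          p[1] < (v[j, 1] - v[i, 1]) * (p[2] - v[i, 2]) /
            (v[j, 2] - v[i, 2]) + v[i, 1])
        inside <- !inside
      j <- i
    }
    inside
  })
}

#' Maximum-intensity projection of an image stack
#'
#' Converts a Z-stack to a single plane by the per-pixel maximum over
#' planes.
#'
#' @param stack 3D numeric array (x, y, z) with at least one plane.
#' @return 2D numeric matrix.
#' @export
maxProject <- function(stack) {
  if (!is.array(stack) || length(dim(stack)) != 3L || dim(stack)[3] < 1L)
    stop("stack must be a 3D array with at least one plane")
  out <- stack[, , 1]
  for (k in seq_len(dim(stack)[3])[-1]) out <- pmax(out, stack[, , k])
  out
}

# separable 2D Gaussian smoothing with reflective borders
.gauss2d <- function(img, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-0.5 * ((-r):r)^2 / sigma^2)
  k <- k / sum(k)
  reflect <- function(idx, n) ifelse(idx < 1, 1 - idx,
                                     ifelse(idx > n, 2 * n - idx + 1, idx))
  nr <- nrow(img); nc <- ncol(img)
  tmp <- matrix(0, nr, nc)
  for (t in (-r):r)
    tmp <- tmp + k[t + r + 1] * img[reflect(seq_len(nr) + t, nr), , drop = FALSE]
  out <- matrix(0, nr, nc)
  for (t in (-r):r)
    out <- out + k[t + r + 1] * tmp[, reflect(seq_len(nc) + t, nc), drop = FALSE]
  out
}

#' Detect spots in a 2D image
#'
#' Blob-style detection: the image is Gaussian-smoothed at the geometric
#' mean of \code{minSigma} and \code{maxSigma}, local maxima above
#' \code{threshold} are kept (with suppression of maxima closer than
#' \code{2 * minSigma} to a brighter one), and each detection is refined to
#' sub-pixel precision by the intensity-weighted centroid (above
#' \code{threshold}) in a window of radius \code{2 * maxSigma}.
#'
#' @param image 2D numeric matrix.
#' @param minSigma,maxSigma expected spot scale range, px.
#' @param threshold intensity threshold for maxima.
#' @return Numeric matrix (n x 2) of spot centers in 0-based pixel
#'   coordinates (row, col); zero rows when nothing is found.
#' @export
detectSpots <- function(image, minSigma = 1, maxSigma = 3, threshold = 0.1) {
  stopifnot(is.matrix(image), all(is.finite(image)))
  sm <- .gauss2d(image, sqrt(minSigma * maxSigma))
  nr <- nrow(sm); nc <- ncol(sm)
  cand <- which(sm > threshold)
  if (length(cand) == 0L) return(matrix(numeric(0), ncol = 2))
  keepMax <- logical(length(cand))
  for (ci in seq_along(cand)) {
    id <- cand[ci]
    i <- (id - 1L) %% nr + 1L
    j <- (id - 1L) %/% nr + 1L
    v <- sm[i, j]
    nbr <- sm[max(1, i - 1):min(nr, i + 1), max(1, j - 1):min(nc, j + 1)]
    keepMax[ci] <- all(nbr <= v)
  }
  cand <- cand[keepMax]
  if (length(cand) == 0L) return(matrix(numeric(0), ncol = 2))
  ord <- order(sm[cand], decreasing = TRUE)
  cand <- cand[ord]
  ci <- (cand - 1L) %% nr + 1L
  cj <- (cand - 1L) %/% nr + 1L
  minSep2 <- (2 * minSigma)^2
  keep <- integer(0)
  for (t in seq_along(cand)) {
    if (length(keep) == 0L ||
        all((ci[keep] - ci[t])^2 + (cj[keep] - cj[t])^2 > minSep2))
      keep <- c(keep, t)
  }
  w <- ceiling(2 * maxSigma)
  out <- matrix(NA_real_, length(keep), 2)
  for (s in seq_along(keep)) {
    i <- ci[keep[s]]; j <- cj[keep[s]]
    ri <- max(1, i - w):min(nr, i + w)
    rj <- max(1, j - w):min(nc, j + w)
    win <- pmax(sm[ri, rj, drop = FALSE] - threshold, 0)
    tot <- sum(win)
    out[s, 1] <- sum(win * (ri - 1)) / tot
    out[s, 2] <- sum(t(win) * (rj - 1)) / tot
  }
  out
}

#' Percentage of peroxisomes with a nearby mRNA spot
#'
#' Peroxisome-centric colocalization: the fraction of peroxisome spots
#' having at least one mRNA spot within \code{thresholdNm}, as a
#' percentage. A field with no peroxisome spots yields \code{NA} with
#' attribute \code{flagged = TRUE} rather than an error.
#'
#' @param field a \linkS4class{SpotField}.
#' @param thresholdNm positive distance threshold in nm (default 300,
#'   approximately the optical resolution limit).
#' @return Percentage in [0, 100] (or flagged NA).
#' @export
percentColocalized <- function(field, thresholdNm = 300) {
  stopifnot(is(field, "SpotField"))
  if (thresholdNm <= 0) stop("thresholdNm must be positive")
  P <- field@peroxisomes
  M <- field@mrna
  if (nrow(P) == 0L) {
    out <- NA_real_
    attr(out, "flagged") <- TRUE
    return(out)
  }
  if (nrow(M) == 0L) return(0)
  hit <- vapply(seq_len(nrow(P)), function(i) {
    d2 <- (M[, 1] - P[i, 1])^2 + (M[, 2] - P[i, 2])^2
    any(d2 <= thresholdNm^2)
  }, logical(1))
  100 * mean(hit)
}

#' Permutation baseline for random colocalization
#'
#' Estimates the colocalization percentage expected by chance by
#' resampling the field's mRNA spots uniformly within the cell mask
#' \code{nPerm} times and recomputing \code{\link{percentColocalized}}
#' each time. This is the within-field analogue of measuring a control
#' transcript with no targeting signal.
#'
#' @param field a \linkS4class{SpotField}.
#' @param nPerm number of permutations (>= 1).
#' @param seed integer RNG seed.
#' @param thresholdNm colocalization threshold, nm.
#' @return List with \code{baselinePercent} (mean over permutations),
#'   \code{ci} (2.5%/97.5% percentile interval) and \code{percents}.
#' @export
randomBaseline <- function(field, nPerm = 1000, seed, thresholdNm = 300) {
  stopifnot(is(field, "SpotField"))
  if (nPerm < 1) stop("nPerm must be >= 1")
  set.seed(seed)
  m <- nrow(field@mrna)
  mask <- field@cellMask
  percents <- vapply(seq_len(nPerm), function(p) {
    mr <- if (m == 0L) matrix(numeric(0), ncol = 2)
    else if (mask$type == "disk")
      .uniformInDisk(m, mask$center, mask$radius)
    else .uniformInPolygon(m, mask)
    f <- SpotField(field@peroxisomes, mr, mask, field@fieldId)
    percentColocalized(f, thresholdNm)
  }, numeric(1))
  list(baselinePercent = mean(percents),
       ci = unname(stats::quantile(percents, c(0.025, 0.975))),
       percents = percents)
}

.uniformInPolygon <- function(n, mask) {
  v <- mask$vertices
  lo <- apply(v, 2, min); hi <- apply(v, 2, max)
  out <- matrix(NA_real_, n, 2)
  got <- 0L
  while (got < n) {
    p <- c(stats::runif(1, lo[1], hi[1]), stats::runif(1, lo[2], hi[2]))
    if (pointsInMask(rbind(p), mask)) {
      got <- got + 1L
      out[got, ] <- p
    }
  }
  out
}

#' Compare per-field colocalization between two conditions
#'
#' Two-sided unpaired comparison of per-field percentages, by Student's
#' t test or the Mann-Whitney (Wilcoxon rank-sum) test.
#'
#' @param groupA,groupB numeric vectors of per-field percentages.
#' @param test "t" or "mannwhitney".
#' @return List with \code{statistic}, \code{pValue}, \code{method}.
#' @export
compareConditions <- function(groupA, groupB, test = c("t", "mannwhitney")) {
  test <- match.arg(test)
  if (length(groupA) == 0L || length(groupB) == 0L) stop("empty group")
  if (test == "t") {
    if (length(groupA) < 2L || length(groupB) < 2L)
      stop("t test needs >= 2 values per group")
    ht <- stats::t.test(groupA, groupB, var.equal = TRUE)
  } else {
    ht <- suppressWarnings(stats::wilcox.test(groupA, groupB))
  }
  list(statistic = unname(ht$statistic), pValue = ht$p.value,
       method = ht$method)
}
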