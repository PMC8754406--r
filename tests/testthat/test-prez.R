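test_that("shell masks partition the dilation region outside the sphere", {
  mem <- SphereMembrane(c(30, 30, 30), 8, 1.159)
  dims <- c(61L, 61L, 61L)
  spec <- ShellSpec(nShells = 4L, shellThicknessPx = 5L)
  idx <- shellIndexVolume(mem, dims, spec)
  # exhaustive per-voxel recomputation of the band index
  coords <- as.matrix(expand.grid(x = 0:60, y = 0:60, z = 0:60))
  d <- sqrt(rowSums((coords - 30)^2)) - 8
  expected <- ifelse(d > 0 & d <= 20, ceiling(d / 5), 0)
  expect_identical(as.integer(idx)[order(coords[, 3], coords[, 2],
                                         coords[, 1])],
                   as.integer(expected)[order(coords[, 3], coords[, 2],
                                              coords[, 1])])
  # every shell non-empty, volumes increase with index for a sphere
  vols <- tabulate(idx[idx > 0], nbins = 4)
  expect_true(all(vols > 0))
  expect_true(all(diff(vols) > 0))
})

test_that("shell density profile equals the exhaustive voxel oracle", {
  mem <- SphereMembrane(c(20, 20, 20), 6, 1.159)
  dims <- c(41L, 41L, 41L)
  spec <- ShellSpec(nShells = 3L, shellThicknessPx = 4L, ribosomeRadiusPx = 4L)
  cents <- rbind(c(28, 20, 20), c(20, 31, 22), c(10, 10, 30))
  rib <- RibosomeSet(cents, 1.159)
  prof <- shellDensityProfile(mem, rib, spec, dims = dims)
  oracle <- oracleShellTally(c(20, 20, 20), 6, 4, 3, dims, cents, 4)
  expect_equal(profileDensity(prof), oracle$occupied / oracle$volume)
  expect_equal(profileDistance(prof),
               oracle$dist_sum / oracle$volume * 1.159)
  # empty ribosome set: all densities zero
  prof0 <- shellDensityProfile(mem, RibosomeSet(pixelSizeNm = 1.159), spec,
                               dims = dims)
  expect_equal(profileDensity(prof0), rep(0, 3))
})

test_that("a crop too small for the shells is an error, not a bias", {
  mem <- SphereMembrane(c(10, 10, 10), 5, 1.159)
  expect_error(
    shellDensityProfile(mem, RibosomeSet(pixelSizeNm = 1.159),
                        ShellSpec(nShells = 20L), dims = c(21L, 21L, 21L)),
    "crop too small")
})

test_that("profile averaging is the per-shell arithmetic mean", {
  p1 <- DensityProfile(c(5, 10, 15), c(0, 0, 0), 1L, 5.795)
  v <- c(0.02, 0.08, 0.1)
  p2 <- DensityProfile(c(5, 10, 15), v, 1L, 5.795)
  expect_equal(profileDensity(averageProfiles(list(p2))), v)
  avg <- averageProfiles(list(p1, p2))
  expect_equal(profileDensity(avg), v / 2)
  expect_equal(avg@nPeroxisomes, 2L)
  expect_error(averageProfiles(list()), "no profiles")
  p3 <- DensityProfile(c(4, 8), c(0.1, 0.1), 1L, 4)
  expect_error(averageProfiles(list(p1, p3)), "grid")
})

test_that("REZ width estimator recovers analytic cases", {
  # flat profile: no exclusion
  flat <- DensityProfile(seq(2.9, by = 5.8, length.out = 20), rep(0.07, 20),
                         1L, 5.8)
  expect_equal(estimateRezWidth(flat), 0)
  # densely sampled step at 20 nm: half-plateau crossing sits at the step
  d <- seq(0.05, 120, by = 0.1)
  step <- DensityProfile(d, ifelse(d < 20, 0, 0.07), 1L, 0.1)
  expect_equal(estimateRezWidth(step), 20, tolerance = 0.01)
  # zero plateau is an error
  zero <- DensityProfile(seq(2.9, by = 5.8, length.out = 20), rep(0, 20),
                         1L, 5.8)
  expect_error(estimateRezWidth(zero), "plateau")
})

test_that("proximal counting matches hand arithmetic at the 20-nm gate", {
  mem <- SphereMembrane(c(0, 0, 0), 43, 1.159)
  # 60 px from center: 17 px x 1.159 = 19.70 nm -> proximal
  # 61 px from center: 18 px x 1.159 = 20.86 nm -> not proximal
  rib <- RibosomeSet(rbind(c(60, 0, 0), c(0, 61, 0)), 1.159)
  expect_equal(as.integer(countProximal(mem, rib, 20)), 1L)
  # centroid inside the sphere is excluded and flagged
  rib2 <- RibosomeSet(rbind(c(10, 0, 0), c(60, 0, 0)), 1.159)
  cnt <- countProximal(mem, rib2, 20)
  expect_equal(as.integer(cnt), 1L)
  expect_equal(attr(cnt, "insideCount"), 1L)
  expect_equal(as.integer(countProximal(mem, RibosomeSet(pixelSizeNm = 1.159),
                                        20)), 0L)
  expect_error(countProximal(mem, rib, -1), "positive")
})

test_that("proximal counting agrees with the brute-force distance oracle", {
  set.seed(42)
  for (rep in 1:10) {
    R <- runif(1, 10, 50)
    cents <- matrix(runif(60, -80, 80), ncol = 3)
    mem <- SphereMembrane(c(0, 0, 0), R, 1.159)
    rib <- RibosomeSet(cents, 1.159)
    expect_equal(as.integer(countProximal(mem, rib, 20)),
                 oracleProximalCount(c(0, 0, 0), R, 1.159, cents, 20))
  }
})

test_that("size association handles degenerate and perfect cases", {
  rec <- data.frame(radius_nm = c(25, 50, 80), proximal_count = c(2, 2, 2))
  r <- proximalSizeAssociation(rec)
  expect_equal(r$pearsonR, 0)
  expect_true(r$degenerate)
  rec2 <- data.frame(radius_nm = c(25, 50, 80),
                     proximal_count = c(25, 50, 80) * 0.04)
  r2 <- proximalSizeAssociation(rec2)
  expect_equal(r2$pearsonR, 1)
  expect_false(r2$degenerate)
  expect_equal(r2$nSmall, 1L)  # only radius 25 (diameter 50 nm) is small
  expect_error(proximalSizeAssociation(rec2[1:2, ]), "3 records")
})

test_that("proximal counts planted independently of size do not correlate", {
  set.seed(7)
  radii_nm <- runif(51, 25, 100)
  planted <- sample(1:3, 51, replace = TRUE)   # 1-3 per organelle, size-blind
  counts <- vapply(seq_along(radii_nm), function(i) {
    scn <- generateTomoScene(TomoSceneParams(
      sphereRadiusPx = radii_nm[i] / 1.159, cropHalfwidthPx = 30L,
      sectionThicknessPx = 172L, cytosolDensityPerPx3 = 0,
      plantedProximalCount = planted[i], seed = 500L + i))
    as.integer(countProximal(scn$membrane, scn$ribosomes, 20))
  }, integer(1))
  res <- proximalSizeAssociation(data.frame(radius_nm = radii_nm,
                                            proximal_count = counts))
  expect_lt(abs(res$pearsonR), 0.3)
})

test_that("watershed segmentation splits separate and touching ribosomes", {
  # all-zero volume: nothing to segment
  expect_equal(nRibosomes(segmentRibosomeCentroids(array(0, c(20, 20, 20)))),
               0L)
  expect_error(segmentRibosomeCentroids(matrix(0, 5, 5)), "3D")

  mkvol <- function(centers, dims, r = 9) {
    vol <- array(0, dims)
    idx <- as.matrix(expand.grid(x = 0:(dims[1] - 1), y = 0:(dims[2] - 1),
                                 z = 0:(dims[3] - 1)))
    for (ci in seq_len(nrow(centers))) {
      inside <- rowSums((idx - rep(centers[ci, ], each = nrow(idx)))^2) <= r^2
      vol[idx[inside, , drop = FALSE] + 1] <- 1
    }
    vol
  }
  # well-separated spheres (centers 30 px apart)
  v1 <- mkvol(rbind(c(15, 15, 15), c(45, 15, 15)), c(60, 30, 30))
  s1 <- segmentRibosomeCentroids(v1)
  expect_equal(nRibosomes(s1), 2L)
  got <- riboCentroids(s1)[order(riboCentroids(s1)[, 1]), ]
  expect_lt(max(abs(got[1, ] - c(15, 15, 15))), 1)
  expect_lt(max(abs(got[2, ] - c(45, 15, 15))), 1)

  # touching spheres (centers 14 px apart) are split by the watershed
  v2 <- mkvol(rbind(c(15, 15, 15), c(29, 15, 15)), c(45, 30, 30))
  s2 <- segmentRibosomeCentroids(v2)
  expect_equal(nRibosomes(s2), 2L)
  got2 <- riboCentroids(s2)[order(riboCentroids(s2)[, 1]), ]
  expect_lt(abs(got2[1, 1] - 15), 2)
  expect_lt(abs(got2[2, 1] - 29), 2)
})

test_that("REZ width grows monotonically with the planted exclusion width", {
  widths <- c(0, 10, 20, 30)
  est <- vapply(widths, function(w) {
    profs <- lapply(1:5, function(s) {
      scn <- generateTomoScene(TomoSceneParams(
        sphereRadiusPx = 20, cropHalfwidthPx = 65L, sectionThicknessPx = 130L,
        exclusionHalfwidthNm = w, plantedProximalCount = 0L,
        seed = 100L * w + s))
      shellDensityProfile(scn$membrane, scn$ribosomes,
                          ShellSpec(nShells = 12L), dims = scn$dims)
    })
    estimateRezWidth(averageProfiles(profs))
  }, numeric(1))
  # no-exclusion scenes estimate within one shell of zero
  expect_lt(est[1], 5.8)
  expect_true(all(diff(est) > 0))
})

test_that("the profiling pipeline is reproducible end to end", {
  run <- function() {
    scn <- generateTomoScene(TomoSceneParams(sphereRadiusPx = 20,
                                             cropHalfwidthPx = 40L,
                                             sectionThicknessPx = 80L,
                                             seed = 9L))
    prof <- shellDensityProfile(scn$membrane, scn$ribosomes,
                                ShellSpec(nShells = 7L), dims = scn$dims)
    list(profileDensity(prof),
         as.integer(countProximal(scn$membrane, scn$ribosomes)))
  }
  expect_identical(run(), run())
})
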