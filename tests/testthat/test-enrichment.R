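mkFt <- function(strand, tp, len = 28L, chrom = "chrI") {
  FootprintTable(data.frame(chrom = chrom, strand = strand,
                            three_prime_pos = tp, length = len,
                            stringsAsFactors = FALSE))
}

test_that("P-site assignment applies the 3'-anchored offset per strand", {
  expect_equal(assignPsites(mkFt("+", 1000L), 15L)$psite, 985)
  expect_equal(assignPsites(mkFt("-", 1000L), 15L)$psite, 1015)
  expect_equal(assignPsites(mkFt("+", 1000L), 0L)$psite, 1000)
  # P-site below zero: dropped and reported
  ps <- assignPsites(mkFt("+", 5L), 15L)
  expect_equal(nrow(ps), 0L)
  expect_equal(attr(ps, "nDropped"), 1L)
  expect_error(assignPsites(mkFt("+", 10L), -1L), ">= 0")
})

test_that("countable mask excludes same-strand overlap for both genes", {
  A <- GeneModel("A", "chrI", "+", 99, 200)
  B <- GeneModel("B", "chrI", "+", 149, 250)
  m <- buildCountableMask(list(A, B))
  expect_equal(unname(m$countableLength), c(50, 50))
  expect_equal(maskToPositions(m$masks$A), 99:148)
  expect_equal(maskToPositions(m$masks$B), 200:249)
  # opposite strands: full lengths retained
  B2 <- GeneModel("B", "chrI", "-", 149, 250)
  m2 <- buildCountableMask(list(A, B2))
  expect_equal(unname(m2$countableLength), c(101, 101))
  # single gene: mask equals its CDS
  m3 <- buildCountableMask(list(A))
  expect_equal(maskToPositions(m3$masks$A), 99:199)
})

test_that("countable mask agrees with the position-set oracle", {
  set.seed(5)
  for (rep in 1:15) {
    n <- sample(2:5, 1)
    genes <- lapply(seq_len(n), function(i) {
      s <- sample(0:300, 1)
      GeneModel(paste0("g", i), sample(c("chrI", "chrII"), 1),
                sample(c("+", "-"), 1), s, s + sample(30:150, 1))
    })
    m <- buildCountableMask(genes)
    oracle <- oracleCountableMask(genes)
    for (i in seq_len(n))
      expect_equal(maskToPositions(m$masks[[i]]), oracle[[i]])
  }
})

test_that("counts and RPM densities follow the worked arithmetic", {
  g <- GeneModel("g1", "chrI", "+", 0, 1000)
  masks <- buildCountableMask(list(g))
  ps <- data.frame(chrom = "chrI", strand = "+",
                   psite = seq(0, 999, length.out = 50))
  d <- countAndDensity(ps, list(g), masks, librarySize = 1e6)
  expect_equal(d$count, 50L)
  expect_equal(d$density_rpm, 50)
  expect_equal(d$density_per_position, 0.05)
  # P-site on the wrong strand inside the CDS is not counted
  psBad <- data.frame(chrom = "chrI", strand = "-", psite = 500)
  expect_equal(countAndDensity(psBad, list(g), masks, 1e6)$count, 0L)
  # no P-sites at all
  ps0 <- data.frame(chrom = character(0), strand = character(0),
                    psite = numeric(0))
  expect_equal(countAndDensity(ps0, list(g), masks, 1e6)$count, 0L)
  expect_error(countAndDensity(ps, list(g), masks, 0), "positive")
})

test_that("enrichment records implement the ratio, filters and z-scores", {
  genes <- list(GeneModel("a", "chrI", "+", 0, 1000),
                GeneModel("b", "chrI", "+", 2000, 3000),
                GeneModel("c", "chrI", "+", 4000, 5000),
                GeneModel("d", "chrI", "+", 6000, 7000, dubious = TRUE),
                GeneModel("e", "chrI", "+", 8000, 9000, mitochondrial = TRUE))
  # identical input and pulldown: log2 = 0, z-scores mean 0 sd 1
  inp <- mkDensity(genes, c(500, 600, 700, 800, 900), 1e6)
  rec <- computeEnrichment(inp, inp, genes)
  expect_equal(rec$log2_enrichment[1:3], rep(0, 3))
  # 10 RPM input vs 40 RPM pulldown: log2 = 2
  pd <- mkDensity(genes, c(500 * 4, 600, 700, 800, 900), 1e6)
  rec2 <- computeEnrichment(inp, pd, genes)
  expect_equal(rec2$log2_enrichment[1], 2)
  expect_equal(mean(rec2$normalized_enrichment[1:3]), 0)
  expect_equal(sd(rec2$normalized_enrichment[1:3]), 1)
  # flagged genes never pass, whatever their counts
  expect_false(any(rec2$passed_filters[4:5]))
  # the 100-input-footprint filter: 99 fails, 100 passes
  inp3 <- mkDensity(genes, c(99, 100, 700, 800, 900), 1e6)
  rec3 <- computeEnrichment(inp3, pd, genes)
  expect_false(rec3$passed_filters[1])
  expect_true(rec3$passed_filters[2])
  expect_true(is.na(rec3$log2_enrichment[1]))
  # zero pulldown density for a passing gene: -Inf sentinel, kept out of z
  pd4 <- mkDensity(genes, c(0, 1200, 700, 800, 900), 1e6)
  rec4 <- computeEnrichment(inp, pd4, genes)
  expect_equal(rec4$log2_enrichment[1], -Inf)
  expect_true(is.na(rec4$normalized_enrichment[1]))
  expect_false(any(is.na(rec4$normalized_enrichment[2:3])))
})

test_that("RPM densities make enrichment invariant to library scaling", {
  genes <- list(GeneModel("a", "chrI", "+", 0, 1000),
                GeneModel("b", "chrI", "+", 2000, 3000))
  inp <- mkDensity(genes, c(500, 800), 1e6)
  pd <- mkDensity(genes, c(1500, 800), 2e6)
  base <- computeEnrichment(inp, pd, genes)$log2_enrichment
  # triple every count and library size on both sides
  inp3 <- mkDensity(genes, 3 * c(500, 800), 3e6)
  pd3 <- mkDensity(genes, 3 * c(1500, 800), 6e6)
  scaled <- computeEnrichment(inp3, pd3, genes)$log2_enrichment
  expect_equal(scaled, base)
})

test_that("calling respects the cutoff, baits and monotonicity", {
  rec <- data.frame(gene_id = c("a", "b", "c"),
                    log2_enrichment = c(0.6, 0.4, 1.2),
                    normalized_enrichment = c(0.5, -0.5, 2),
                    passed_filters = c(TRUE, TRUE, TRUE),
                    stringsAsFactors = FALSE)
  expect_equal(callEnriched(rec, 0.5)$called, c("a", "c"))
  expect_equal(callEnriched(rec, Inf)$called, character(0))
  # dual bait: called in one bait only is excluded under the both-baits rule
  rec2 <- rec
  rec2$log2_enrichment <- c(0.4, 0.4, 1.2)
  expect_equal(callEnriched(list(rec, rec2), 0.5,
                            requireAllBaits = TRUE)$called, "c")
  expect_equal(callEnriched(list(rec, rec2), 0.5,
                            requireAllBaits = FALSE)$called, c("a", "c"))
  expect_error(callEnriched(list()), "empty")
  # monotone: raising the cutoff never adds genes
  set.seed(8)
  rr <- data.frame(gene_id = sprintf("g%02d", 1:40),
                   log2_enrichment = rnorm(40),
                   normalized_enrichment = rnorm(40),
                   passed_filters = runif(40) > 0.2,
                   stringsAsFactors = FALSE)
  cuts <- sort(runif(6, -2, 2))
  sets <- lapply(cuts, function(ct) callEnriched(rr, ct)$called)
  for (i in seq_len(length(sets) - 1))
    expect_true(all(sets[[i + 1]] %in% sets[[i]]))
})

test_that("two-organelle comparison classifies shared genes", {
  recA <- data.frame(gene_id = c("a", "b", "c"),
                     log2_enrichment = c(1, 1, 0),
                     normalized_enrichment = c(1, 1, 0),
                     passed_filters = TRUE, stringsAsFactors = FALSE)
  recB <- data.frame(gene_id = c("a", "b", "c"),
                     log2_enrichment = c(1, 0, 0),
                     normalized_enrichment = c(1, 0, 0),
                     passed_filters = TRUE, stringsAsFactors = FALSE)
  out <- compareLocalizations(recA, recB, 0.5)
  cls <- setNames(out$classes$class, out$classes$gene_id)
  expect_equal(unname(cls[c("a", "b", "c")]), c("both", "A-only", "neither"))
  # an empty B side leaves every A-called gene A-only
  recB0 <- recB
  recB0$log2_enrichment <- c(0, 0, 0)
  out2 <- compareLocalizations(recA, recB0, 0.5)
  expect_equal(unname(out2$summary["A-only"]), 2L)
  recD <- recB
  recD$gene_id <- c("x", "y", "z")
  expect_error(compareLocalizations(recA, recD), "disjoint")
})

test_that("planted disjoint subsets are recovered exactly at high counts", {
  ds <- generateFootprintDataset(RiboSimParams(
    nGenes = 60L, nEnriched = 10L, trueLog2Effect = 2,
    meanInputFootprints = 2000, fracDubious = 0, fracMito = 0,
    nBaits = 1L, seed = 21L))
  dsB <- generateFootprintDataset(RiboSimParams(
    nGenes = 60L, nEnriched = 10L, trueLog2Effect = 2,
    meanInputFootprints = 2000, fracDubious = 0, fracMito = 0,
    nBaits = 1L, seed = 22L))
  recA <- runEnrichmentPipeline(ds, requireAllBaits = FALSE)$records[[1]]
  recB <- runEnrichmentPipeline(dsB, requireAllBaits = FALSE)$records[[1]]
  out <- compareLocalizations(recA, recB, 0.5)
  truthA <- ds$truth$gene_id[ds$truth$enriched]
  truthB <- dsB$truth$gene_id[dsB$truth$enriched]
  cls <- setNames(out$classes$class, out$classes$gene_id)
  for (g in setdiff(truthA, truthB)) expect_equal(unname(cls[g]), "A-only")
  for (g in setdiff(truthB, truthA)) expect_equal(unname(cls[g]), "B-only")
  for (g in intersect(truthA, truthB)) expect_equal(unname(cls[g]), "both")
  neither <- setdiff(out$classes$gene_id, union(truthA, truthB))
  expect_true(all(cls[neither] == "neither"))
})

test_that("a single gene's planted effect is recovered within sampling error", {
  e <- 1.5
  ds <- generateFootprintDataset(RiboSimParams(
    nGenes = 1L, nEnriched = 1L, trueLog2Effect = e,
    meanInputFootprints = 20000, fracDubious = 0, fracMito = 0,
    nBaits = 1L, seed = 13L))
  # the single-gene library carries no scale information, so densities are
  # computed against matched external library sizes
  masks <- buildCountableMask(ds$genes)
  b <- ds$baits[[1]]
  dIn <- countAndDensity(assignPsites(b$input), ds$genes, masks, 1e6)
  dPd <- countAndDensity(assignPsites(b$pulldown), ds$genes, masks, 1e6)
  est <- log2(dPd$density_rpm / dIn$density_rpm)
  se <- sqrt(1 / dIn$count + 1 / dPd$count) / log(2)
  expect_lt(abs(est - e), 3 * se)
  # in a many-gene library, RPM renormalization compresses the planted
  # effect by log2(mean(2^effect)), a known constant
  ds2 <- generateFootprintDataset(RiboSimParams(
    nGenes = 200L, nEnriched = 1L, trueLog2Effect = e,
    meanInputFootprints = 5000, fracDubious = 0, fracMito = 0,
    nBaits = 1L, seed = 14L))
  rec <- runEnrichmentPipeline(ds2)$records[[1]]
  planted <- rec$log2_enrichment[ds2$truth$enriched]
  shift <- log2(sum(2^ds2$truth$effect) / 200)   # library renormalization
  seP <- sqrt(2 / 5000) / log(2)
  expect_lt(abs(planted - (e - shift)), 3 * seP)
})

test_that("planted enrichment is recovered across the gene set", {
  # enriched fraction mirrors the default preset (~1% of genes), keeping
  # the RPM-renormalization compression log2(mean(2^effect)) ~ 0.04
  ds <- generateFootprintDataset(RiboSimParams(
    nGenes = 400L, nEnriched = 4L, trueLog2Effect = 2,
    meanInputFootprints = 1000, seed = 31L))
  res <- runEnrichmentPipeline(ds)
  rec <- res$records[[1]]
  planted <- rec$log2_enrichment[match(ds$truth$gene_id[ds$truth$enriched],
                                       rec$gene_id)]
  expect_lt(abs(median(planted) - 2), 0.1)
  expect_setequal(res$called$called, ds$truth$gene_id[ds$truth$enriched])
  # flagged genes never pass or get called
  flagged <- ds$truth$gene_id[ds$truth$dubious | ds$truth$mitochondrial]
  expect_false(any(rec$passed_filters[match(flagged, rec$gene_id)]))
  expect_length(intersect(res$called$called, flagged), 0L)
})

test_that("every generated footprint P-site maps back into its source CDS", {
  ds <- generateFootprintDataset(RiboSimParams(
    nGenes = 50L, nEnriched = 5L, meanInputFootprints = 60, seed = 17L))
  masks <- buildCountableMask(ds$genes)
  for (b in ds$baits) {
    for (tbl in list(b$input, b$pulldown)) {
      ps <- assignPsites(tbl)
      expect_equal(attr(ps, "nDropped"), 0L)
      d <- countAndDensity(ps, ds$genes, masks, librarySize = nrow(ps))
      # genes are non-overlapping, so in-CDS P-sites equal total P-sites
      expect_equal(sum(d$count), nrow(ps))
    }
  }
})

test_that("the footprint generator is deterministic and validates", {
  p <- RiboSimParams(nGenes = 30L, nEnriched = 3L, meanInputFootprints = 50,
                     seed = 4L)
  a <- generateFootprintDataset(p)
  b <- generateFootprintDataset(p)
  expect_identical(footprints(a$baits[[1]]$input),
                   footprints(b$baits[[1]]$input))
  expect_identical(a$truth, b$truth)
  expect_equal(generateFootprintDataset(RiboSimParams(nGenes = 0L,
                                                      nEnriched = 0L,
                                                      seed = 1L))$genes,
               list())
  expect_error(RiboSimParams(nGenes = 10L, nEnriched = 11L, seed = 1L),
               "nEnriched")
  expect_error(RiboSimParams(geneLengthNt = 30L, seed = 1L), "geneLengthNt")
})
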