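#' Parameters for synthetic footprint datasets
#'
#' Describes a planted-enrichment ribosome-profiling experiment: a set of
#' non-overlapping single-CDS genes on one synthetic chromosome, per-bait
#' matched input and pulldown footprint tables, and a known subset of genes
#' whose pulldown density is scaled by \code{2^trueLog2Effect}; the
#' reads-per-million normalization at analysis time brings both libraries
#' to a common scale. Planted enriched genes are drawn from unflagged
#' genes only, so the ground truth survives the dubious/mitochondrial
#' filters.
#'
#' @slot nGenes positive integer; default 4540.
#' @slot nEnriched non-negative integer; default 40.
#' @slot trueLog2Effect real planted effect; default 2.0.
#' @slot meanInputFootprints positive real, mean input CDS footprints per
#'   gene; default 1000.
#' @slot geneLengthNt positive integer CDS length; default 1500.
#' @slot fracDubious,fracMito reals in [0, 1]; defaults 0.10 and 0.01.
#' @slot nBaits positive integer; default 2.
#' @slot psiteOffsetNt non-negative integer; default 15.
#' @slot footprintLengthNt positive integer; default 28.
#' @slot seed integer RNG seed; must be set.
#' @export
setClass("RiboSimParams",
  representation(nGenes = "integer", nEnriched = "integer",
                 trueLog2Effect = "numeric", meanInputFootprints = "numeric",
                 geneLengthNt = "integer", fracDubious = "numeric",
                 fracMito = "numeric", nBaits = "integer",
                 psiteOffsetNt = "integer", footprintLengthNt = "integer",
                 seed = "integer"),
  prototype(nGenes = 4540L, nEnriched = 40L, trueLog2Effect = 2.0,
            meanInputFootprints = 1000, geneLengthNt = 1500L,
            fracDubious = 0.10, fracMito = 0.01, nBaits = 2L,
            psiteOffsetNt = 15L, footprintLengthNt = 28L,
            seed = NA_integer_),
  validity = function(object) {
    if (object@nGenes < 0L) return("nGenes must be >= 0")
    if (object@nEnriched < 0L || object@nEnriched > object@nGenes)
      return("need 0 <= nEnriched <= nGenes")
    if (object@meanInputFootprints <= 0)
      return("meanInputFootprints must be positive")
    if (object@geneLengthNt <= 0L) return("geneLengthNt must be positive")
    if (object@fracDubious < 0 || object@fracDubious > 1 ||
        object@fracMito < 0 || object@fracMito > 1)
      return("flag fractions must lie in [0, 1]")
    if (object@nBaits < 1L) return("nBaits must be >= 1")
    if (object@psiteOffsetNt < 0L) return("psiteOffsetNt must be >= 0")
    if (object@footprintLengthNt <= 0L)
      return("footprintLengthNt must be positive")
    if (object@geneLengthNt < object@psiteOffsetNt + object@footprintLengthNt)
      return("geneLengthNt must be >= psiteOffsetNt + footprintLengthNt")
    TRUE
  })

#' @rdname RiboSimParams-class
#' @param ... slot values overriding the defaults.
#' @return A \code{RiboSimParams} object.
#' @export
RiboSimParams <- function(...) {
  args <- list(...)
  for (s in c("nGenes", "nEnriched", "geneLengthNt", "nBaits",
              "psiteOffsetNt", "footprintLengthNt", "seed"))
    if (!is.null(args[[s]])) args[[s]] <- as.integer(args[[s]])
  do.call(new, c(list("RiboSimParams"), args))
}

# footprint table rows for `counts[i]` P-sites uniform in gene i's CDS,
# with 3'-end bookkeeping inverted so assignPsites lands back on the P-site
.sampleFootprints <- function(starts, strands, counts, L, offset, flen,
                              chrom) {
  gidx <- rep(seq_along(counts), counts)
  n <- length(gidx)
  psite <- starts[gidx] + floor(stats::runif(n) * L)
  tp <- ifelse(strands[gidx] == "+", psite + offset, psite - offset)
  FootprintTable(data.frame(chrom = rep(chrom, n),
                            strand = strands[gidx],
                            three_prime_pos = as.integer(tp),
                            length = rep(as.integer(flen), n),
                            stringsAsFactors = FALSE))
}

#' Generate a synthetic footprint dataset with planted enrichment
#'
#' Builds \code{nGenes} non-overlapping genes on a synthetic chromosome,
#' assigns dubious/mitochondrial flags at the configured fractions, picks
#' \code{nEnriched} enriched genes among the unflagged ones, and draws, per
#' bait, Poisson input counts around \code{meanInputFootprints} and
#' pulldown counts around \code{meanInputFootprints * 2^effect}; the
#' renormalization to a common library scale happens through the
#' reads-per-million densities at analysis time, so planted log2 ratios are
#' recovered up to the constant \code{-log2(mean(2^effect))} the library
#' renormalization absorbs.
#' Footprint 3' ends are recorded so that P-site assignment at
#' \code{psiteOffsetNt} lands back inside the source CDS.
#'
#' @param params a \linkS4class{RiboSimParams} with \code{seed} set.
#' @return List: \code{genes} (list of \linkS4class{GeneModel}),
#'   \code{baits} (per bait, list with \code{input} and \code{pulldown}
#'   \linkS4class{FootprintTable}s and their \code{librarySize}s),
#'   \code{truth} (data.frame gene_id, enriched, effect, dubious,
#'   mitochondrial) and \code{params}.
#' @export
generateFootprintDataset <- function(params) {
  stopifnot(is(params, "RiboSimParams"))
  validObject(params)
  if (is.na(params@seed)) stop("params@seed must be set")
  set.seed(params@seed)
  n <- params@nGenes
  if (n == 0L)
    return(list(genes = list(), baits = list(),
                truth = data.frame(gene_id = character(0),
                                   enriched = logical(0), effect = numeric(0),
                                   dubious = logical(0),
                                   mitochondrial = logical(0)),
                params = params))
  L <- params@geneLengthNt
  gap <- 300L
  offset <- params@psiteOffsetNt
  flen <- params@footprintLengthNt
  chrom <- "chr_syn"
  starts <- 1000L + (seq_len(n) - 1L) * (L + gap)
  strands <- sample(c("+", "-"), n, replace = TRUE)
  dub <- stats::runif(n) < params@fracDubious
  mito <- stats::runif(n) < params@fracMito
  flagged <- dub | mito
  if (sum(!flagged) < params@nEnriched)
    stop("not enough unflagged genes to plant enrichment in")
  enriched <- logical(n)
  enriched[sample(which(!flagged), params@nEnriched)] <- TRUE
  effect <- ifelse(enriched, params@trueLog2Effect, 0)
  ids <- sprintf("SYN%04d", seq_len(n))
  genes <- lapply(seq_len(n), function(i)
    GeneModel(ids[i], chrom, strands[i], cdsStarts = starts[i],
              cdsEnds = starts[i] + L, dubious = dub[i],
              mitochondrial = mito[i]))
  m <- params@meanInputFootprints
  w <- m * 2^effect
  baits <- vector("list", params@nBaits)
  names(baits) <- sprintf("bait%d", seq_len(params@nBaits))
  for (b in seq_len(params@nBaits)) {
    inCounts <- stats::rpois(n, m)
    pdCounts <- stats::rpois(n, w)
    baits[[b]] <- list(
      input = .sampleFootprints(starts, strands, inCounts, L, offset, flen,
                                chrom),
      pulldown = .sampleFootprints(starts, strands, pdCounts, L, offset,
                                   flen, chrom),
      inputLibrarySize = sum(inCounts),
      pulldownLibrarySize = sum(pdCounts))
  }
  truth <- data.frame(gene_id = ids, enriched = enriched, effect = effect,
                      dubious = dub, mitochondrial = mito,
                      stringsAsFactors = FALSE)
  list(genes = genes, baits = baits, truth = truth, params = params)
}

#' Run the full enrichment pipeline on a (synthetic or real) dataset
#'
#' Convenience wrapper chaining \code{\link{assignPsites}},
#' \code{\link{buildCountableMask}}, \code{\link{countAndDensity}},
#' \code{\link{computeEnrichment}} and \code{\link{callEnriched}} across
#' the baits of a dataset shaped like the output of
#' \code{\link{generateFootprintDataset}}.
#'
#' @param dataset list with \code{genes} and \code{baits}.
#' @param config a \linkS4class{PipelineConfig}.
#' @param mode calling mode, "raw" or "normalized".
#' @param requireAllBaits dual-bait intersection rule (default TRUE).
#' @return List with \code{records} (per-bait enrichment data.frames) and
#'   \code{called} (result of \code{\link{callEnriched}}).
#' @export
runEnrichmentPipeline <- function(dataset, config = PipelineConfig(),
                                  mode = "raw", requireAllBaits = TRUE) {
  masks <- buildCountableMask(dataset$genes)
  records <- lapply(dataset$baits, function(b) {
    psIn <- assignPsites(b$input, config@psiteOffsetNt)
    psPd <- assignPsites(b$pulldown, config@psiteOffsetNt)
    dIn <- countAndDensity(psIn, dataset$genes, masks,
                           librarySize = nrow(b$input@footprints))
    dPd <- countAndDensity(psPd, dataset$genes, masks,
                           librarySize = nrow(b$pulldown@footprints))
    computeEnrichment(dIn, dPd, dataset$genes, config)
  })
  list(records = records,
       called = callEnriched(records, cutoff = config@enrichmentCutoffLog2,
                             mode = mode, requireAllBaits = requireAllBaits))
}
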