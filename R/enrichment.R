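#' Assign P-site positions to footprints
#'
#' The P-site nucleotide is a fixed offset from the footprint 3' end,
#' applied toward the read 5' direction in genome coordinates: on the plus
#' strand \code{psite = three_prime_pos - offset}, on the minus strand
#' \code{psite = three_prime_pos + offset}. Footprints whose P-site would
#' fall below position 0 are dropped and counted in the \code{nDropped}
#' attribute.
#'
#' @param fp a \linkS4class{FootprintTable}.
#' @param offsetNt non-negative offset in nt (default 15).
#' @return data.frame with columns \code{chrom}, \code{strand},
#'   \code{psite} (0-based), plus attribute \code{nDropped}.
#' @examples
#' ft <- FootprintTable(data.frame(chrom = "chrI", strand = "+",
#'                                 three_prime_pos = 1000, length = 28))
#' assignPsites(ft)$psite  # 985
#' @export
assignPsites <- function(fp, offsetNt = 15L) {
  stopifnot(is(fp, "FootprintTable"))
  if (offsetNt < 0) stop("offsetNt must be >= 0")
  df <- fp@footprints
  psite <- ifelse(df$strand == "+", df$three_prime_pos - offsetNt,
                  df$three_prime_pos + offsetNt)
  keep <- psite >= 0
  out <- data.frame(chrom = df$chrom[keep], strand = df$strand[keep],
                    psite = psite[keep], stringsAsFactors = FALSE)
  attr(out, "nDropped") <- sum(!keep)
  out
}

#' Build per-gene countable CDS masks
#'
#' For each gene, removes from its CDS every position covered by another
#' gene's CDS on the same strand and chromosome (such regions are countable
#' for neither gene); opposite-strand overlap does not exclude. Genes left
#' with an empty mask are kept with countable length 0 and flagged.
#'
#' @param genes list of \linkS4class{GeneModel}.
#' @return List with \code{masks} (per-gene list of data.frames of 0-based
#'   half-open intervals), \code{countableLength} (named numeric) and
#'   \code{emptyMask} (named logical).
#' @importFrom GenomicRanges reduce setdiff findOverlaps
#' @importFrom S4Vectors queryHits subjectHits
#' @export
buildCountableMask <- function(genes) {
  stopifnot(length(genes) == 0L ||
              all(vapply(genes, is, logical(1), "GeneModel")))
  ids <- vapply(genes, function(g) g@geneId, character(1))
  if (anyDuplicated(ids)) stop("duplicate gene ids")
  gr <- genesToGRanges(genes)
  hits <- GenomicRanges::findOverlaps(gr, gr)
  cross <- S4Vectors::queryHits(hits)[gr$geneIdx[S4Vectors::queryHits(hits)] !=
                                        gr$geneIdx[S4Vectors::subjectHits(hits)]]
  affected <- unique(gr$geneIdx[cross])
  masks <- vector("list", length(genes))
  names(masks) <- ids
  lens <- numeric(length(genes))
  for (i in seq_along(genes)) {
    g <- genes[[i]]
    if (i %in% affected) {
      own <- gr[gr$geneIdx == i]
      others <- gr[gr$geneIdx != i]
      m <- GenomicRanges::setdiff(own, others, ignore.strand = FALSE)
      masks[[i]] <- data.frame(start = GenomicRanges::start(m) - 1,
                               end = GenomicRanges::end(m))
    } else {
      masks[[i]] <- data.frame(start = g@cdsStarts, end = g@cdsEnds)
    }
    lens[i] <- sum(masks[[i]]$end - masks[[i]]$start)
  }
  names(lens) <- ids
  list(masks = masks, countableLength = lens, emptyMask = lens == 0)
}

#' Count P-sites per gene and compute footprint densities
#'
#' Counts the P-sites that fall inside each gene's countable CDS mask on
#' the gene's strand and converts counts to reads-per-million densities:
#' \code{density_rpm = count * 1e6 / librarySize}. A per-countable-position
#' density is reported alongside. Genes with an empty countable mask get
#' \code{NA} densities and are flagged.
#'
#' @param psites data.frame from \code{\link{assignPsites}}.
#' @param genes list of \linkS4class{GeneModel}.
#' @param masks result of \code{\link{buildCountableMask}} on \code{genes}.
#' @param librarySize total mapped footprints in the sample (> 0).
#' @return data.frame with columns \code{gene_id}, \code{count},
#'   \code{density_rpm}, \code{density_per_position},
#'   \code{countable_length}, \code{empty_mask}.
#' @importFrom GenomicRanges GRanges countOverlaps
#' @importFrom IRanges IRanges
#' @export
countAndDensity <- function(psites, genes, masks = buildCountableMask(genes),
                            librarySize) {
  if (librarySize <= 0) stop("librarySize must be positive")
  ids <- vapply(genes, function(g) g@geneId, character(1))
  nIv <- vapply(masks$masks, nrow, integer(1))
  counts <- integer(length(genes))
  if (nrow(psites) > 0L && sum(nIv) > 0L) {
    maskGr <- GenomicRanges::GRanges(
      seqnames = rep(vapply(genes, function(g) g@chrom, character(1)), nIv),
      ranges = IRanges::IRanges(
        start = unlist(lapply(masks$masks, function(m) m$start)) + 1,
        end = unlist(lapply(masks$masks, function(m) m$end))),
      strand = rep(vapply(genes, function(g) g@strand, character(1)), nIv))
    pGr <- GenomicRanges::GRanges(
      seqnames = psites$chrom,
      ranges = IRanges::IRanges(start = psites$psite + 1, width = 1),
      strand = psites$strand)
    per <- GenomicRanges::countOverlaps(maskGr, pGr)
    rs <- rowsum(per, rep(seq_along(genes), nIv))
    counts[as.integer(rownames(rs))] <- as.integer(rs[, 1])
  }
  lens <- masks$countableLength
  rpm <- counts * 1e6 / librarySize
  data.frame(gene_id = ids, count = counts, density_rpm = rpm,
             density_per_position = ifelse(lens > 0, rpm / lens, NA_real_),
             countable_length = as.numeric(lens),
             empty_mask = lens == 0, stringsAsFactors = FALSE)
}

#' Compute gene-level pulldown/input enrichment records
#'
#' For each gene, the enrichment is the log2 ratio of pulldown footprint
#' density (RPM in the countable CDS) over matched input density. Genes are
#' filtered out (\code{passed_filters = FALSE}, no enrichment value) when
#' they have fewer than \code{minInputFootprints} input CDS footprints, are
#' flagged dubious, map to the mitochondrial chromosome, or have an empty
#' countable mask. Enrichments of passing genes are z-normalized
#' (subtract mean, divide by SD); a passing gene with zero pulldown density
#' carries a \code{-Inf} sentinel excluded from the normalization. Genes
#' are binned by \code{floor(log10(min(input, pulldown) counts))} for
#' stratified reporting.
#'
#' @param input,pulldown data.frames from \code{\link{countAndDensity}} for
#'   the matched samples (same gene universe).
#' @param genes list of \linkS4class{GeneModel}, same order/universe.
#' @param config a \linkS4class{PipelineConfig} (supplies
#'   \code{minInputFootprints}).
#' @return data.frame of enrichment records: \code{gene_id},
#'   \code{input_count}, \code{pulldown_count}, \code{input_density_rpm},
#'   \code{pulldown_density_rpm}, \code{log2_enrichment},
#'   \code{normalized_enrichment}, \code{count_bin}, \code{passed_filters}.
#' @export
computeEnrichment <- function(input, pulldown, genes,
                              config = PipelineConfig()) {
  stopifnot(identical(input$gene_id, pulldown$gene_id))
  ids <- vapply(genes, function(g) g@geneId, character(1))
  stopifnot(identical(input$gene_id, ids))
  dub <- vapply(genes, function(g) g@dubious, logical(1))
  mito <- vapply(genes, function(g) g@mitochondrial, logical(1))
  passed <- !dub & !mito & !input$empty_mask &
    input$count >= config@minInputFootprints
  log2e <- rep(NA_real_, length(ids))
  ok <- passed & input$density_rpm > 0
  log2e[ok] <- log2(pulldown$density_rpm[ok] / input$density_rpm[ok])
  finite <- passed & is.finite(log2e)
  mu <- mean(log2e[finite])
  sdev <- stats::sd(log2e[finite])
  norm <- rep(NA_real_, length(ids))
  if (is.finite(sdev) && sdev > 0) norm[finite] <- (log2e[finite] - mu) / sdev
  minCount <- pmin(input$count, pulldown$count)
  data.frame(gene_id = ids,
             input_count = input$count, pulldown_count = pulldown$count,
             input_density_rpm = input$density_rpm,
             pulldown_density_rpm = pulldown$density_rpm,
             log2_enrichment = log2e, normalized_enrichment = norm,
             count_bin = ifelse(minCount > 0, floor(log10(minCount)), -1L),
             passed_filters = passed, stringsAsFactors = FALSE)
}

#' Call enriched genes across one or more baits
#'
#' Per bait, a gene is called when it passed the filters and its enrichment
#' (raw log2 by default, z-normalized with \code{mode = "normalized"}) lies
#' strictly above the cutoff. The final set is the intersection across
#' baits when \code{requireAllBaits} (a transcript must be enriched in
#' every bait experiment), otherwise the union.
#'
#' @param records one enrichment data.frame or a list of them (one per
#'   bait), sharing the gene universe.
#' @param cutoff calling cutoff (default 0.5, on the log2 scale in raw
#'   mode).
#' @param mode "raw" or "normalized".
#' @param requireAllBaits logical (default TRUE).
#' @return List with \code{called} (sorted character vector) and
#'   \code{perBait} (list of per-bait called sets).
#' @export
callEnriched <- function(records, cutoff = 0.5, mode = c("raw", "normalized"),
                         requireAllBaits = TRUE) {
  mode <- match.arg(mode)
  if (is.data.frame(records)) records <- list(records)
  if (length(records) == 0L) stop("empty record list")
  col <- if (mode == "raw") "log2_enrichment" else "normalized_enrichment"
  perBait <- lapply(records, function(r) {
    v <- r[[col]]
    sort(r$gene_id[r$passed_filters & !is.na(v) & is.finite(v) & v > cutoff])
  })
  called <- if (requireAllBaits) Reduce(intersect, perBait)
            else Reduce(union, perBait)
  list(called = sort(called), perBait = perBait)
}

#' Classify genes by enrichment at two organelles
#'
#' Given enrichment records for two localizations (e.g., peroxisome and
#' ER), classifies every shared gene as enriched at A only, B only, both,
#' or neither, using the same calling rule on each side.
#'
#' @param setA,setB enrichment data.frames (or lists of per-bait
#'   data.frames) for the two organelles.
#' @param cutoff calling cutoff (default 0.5).
#' @param mode "raw" or "normalized".
#' @param requireAllBaits per-side multi-bait rule (default TRUE).
#' @return List with \code{classes} (data.frame gene_id, class) and
#'   \code{summary} (named counts).
#' @export
compareLocalizations <- function(setA, setB, cutoff = 0.5,
                                 mode = c("raw", "normalized"),
                                 requireAllBaits = TRUE) {
  mode <- match.arg(mode)
  uni <- function(x) if (is.data.frame(x)) x$gene_id else x[[1]]$gene_id
  shared <- intersect(uni(setA), uni(setB))
  if (length(shared) == 0L) stop("disjoint gene universes")
  a <- callEnriched(setA, cutoff, mode, requireAllBaits)$called
  b <- callEnriched(setB, cutoff, mode, requireAllBaits)$called
  cls <- ifelse(shared %in% a & shared %in% b, "both",
         ifelse(shared %in% a, "A-only",
         ifelse(shared %in% b, "B-only", "neither")))
  classes <- data.frame(gene_id = shared, class = cls,
                        stringsAsFactors = FALSE)
  list(classes = classes,
       summary = c(`A-only` = sum(cls == "A-only"),
                   `B-only` = sum(cls == "B-only"),
                   both = sum(cls == "both"),
                   neither = sum(cls == "neither")))
}
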