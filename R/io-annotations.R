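#' Read gene annotations from GFF3 or BED
#'
#' Parses CDS annotations into \linkS4class{GeneModel}s with internal
#' 0-based half-open coordinates. Gene flags (dubious / mitochondrial) are
#' taken from GFF3 attributes (\code{dubious=...}, \code{mitochondrial=...}
#' or \code{orf_classification=Dubious}) and/or from a sidecar flag table
#' with columns \code{gene_id}, \code{dubious}, \code{mitochondrial}.
#' Genes on a recognizably mitochondrial chromosome (chrM, chrMT, chrmt,
#' Mito, MT) are flagged mitochondrial automatically.
#'
#' @param path GFF3 (.gff/.gff3) or BED (.bed) file.
#' @param flagsPath optional TSV of gene flags.
#' @return List of \linkS4class{GeneModel}, one per gene, ordered by first
#'   appearance. Empty input yields an empty list.
#' @export
readGeneAnnotations <- function(path, flagsPath = NULL) {
  stopifnot(file.exists(path))
  isBed <- grepl("\\.bed$", path, ignore.case = TRUE)
  if (isBed) df <- .parseBed(path) else df <- .parseGff3(path)
  if (nrow(df) == 0L) return(list())
  flags <- NULL
  if (!is.null(flagsPath)) {
    flags <- utils::read.delim(flagsPath, stringsAsFactors = FALSE)
    stopifnot("gene_id" %in% names(flags))
  }
  mitoChroms <- c("chrM", "chrMT", "chrmt", "Mito", "MT", "chrMito")
  genes <- list()
  for (gid in unique(df$gene_id)) {
    rows <- df[df$gene_id == gid, , drop = FALSE]
    dub <- any(rows$dubious)
    mito <- any(rows$mitochondrial) || rows$chrom[1] %in% mitoChroms
    if (!is.null(flags)) {
      fr <- flags[flags$gene_id == gid, , drop = FALSE]
      if (nrow(fr) > 0L) {
        if ("dubious" %in% names(fr)) dub <- dub || .asFlag(fr$dubious[1])
        if ("mitochondrial" %in% names(fr))
          mito <- mito || .asFlag(fr$mitochondrial[1])
      }
    }
    genes[[gid]] <- GeneModel(gid, rows$chrom[1], rows$strand[1],
                              cdsStarts = rows$start0, cdsEnds = rows$end0,
                              dubious = dub, mitochondrial = mito)
  }
  unname(genes)
}

.asFlag <- function(x) {
  if (is.logical(x)) return(isTRUE(x))
  tolower(as.character(x)) %in% c("true", "1", "yes", "t")
}

# Line-by-line GFF3 CDS parser. Validates each line before use so that a
# malformed line is reported by number.
.parseGff3 <- function(path) {
  lines <- readLines(path)
  out <- list()
  for (ln in seq_along(lines)) {
    line <- lines[ln]
    if (!nzchar(line) || startsWith(line, "#")) next
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(f) != 9L)
      stop(sprintf("malformed GFF3 line %d: expected 9 tab-separated fields, got %d",
                   ln, length(f)))
    if (tolower(f[3]) != "cds") next
    start1 <- suppressWarnings(as.numeric(f[4]))
    end1 <- suppressWarnings(as.numeric(f[5]))
    if (is.na(start1) || is.na(end1) || start1 < 1 || end1 < start1)
      stop(sprintf("malformed GFF3 line %d: bad coordinates '%s'..'%s'",
                   ln, f[4], f[5]))
    if (!f[7] %in% c("+", "-"))
      stop(sprintf("malformed GFF3 line %d: unknown strand symbol '%s'",
                   ln, f[7]))
    attrs <- .parseGffAttrs(f[9])
    gid <- attrs[["gene_id"]] %||% attrs[["Parent"]] %||% attrs[["ID"]] %||%
      attrs[["Name"]]
    if (is.null(gid))
      stop(sprintf("malformed GFF3 line %d: no gene identifier attribute", ln))
    conv <- gffToZeroBased(start1, end1)
    out[[length(out) + 1L]] <- data.frame(
      gene_id = gid, chrom = f[1], strand = f[7],
      start0 = conv$start, end0 = conv$end,
      dubious = .asFlag(attrs[["dubious"]] %||%
                          identical(attrs[["orf_classification"]], "Dubious")),
      mitochondrial = .asFlag(attrs[["mitochondrial"]] %||% FALSE),
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(gene_id = character(0), chrom = character(0),
                      strand = character(0), start0 = numeric(0),
                      end0 = numeric(0), dubious = logical(0),
                      mitochondrial = logical(0)))
  do.call(rbind, out)
}

.parseGffAttrs <- function(s) {
  if (!nzchar(s) || s == ".") return(list())
  kv <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
  vals <- lapply(kv, function(p) if (length(p) >= 2) utils::URLdecode(p[2]) else NA)
  names(vals) <- vapply(kv, function(p) trimws(p[1]), character(1))
  vals
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# BED is already 0-based half-open; columns chrom, start, end, name, score,
# strand. One interval per line; intervals sharing a name form one gene.
.parseBed <- function(path) {
  lines <- readLines(path)
  out <- list()
  for (ln in seq_along(lines)) {
    line <- lines[ln]
    if (!nzchar(line) || startsWith(line, "#") || startsWith(line, "track"))
      next
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(f) < 6L)
      stop(sprintf("malformed BED line %d: need >= 6 fields for stranded genes", ln))
    if (!f[6] %in% c("+", "-"))
      stop(sprintf("malformed BED line %d: unknown strand symbol '%s'", ln, f[6]))
    s <- suppressWarnings(as.numeric(f[2])); e <- suppressWarnings(as.numeric(f[3]))
    if (is.na(s) || is.na(e) || s < 0 || e <= s)
      stop(sprintf("malformed BED line %d: bad coordinates", ln))
    out[[length(out) + 1L]] <- data.frame(
      gene_id = f[4], chrom = f[1], strand = f[6], start0 = s, end0 = e,
      dubious = FALSE, mitochondrial = FALSE, stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(gene_id = character(0), chrom = character(0),
                      strand = character(0), start0 = numeric(0),
                      end0 = numeric(0), dubious = logical(0),
                      mitochondrial = logical(0)))
  do.call(rbind, out)
}

#' Write gene annotations as GFF3
#'
#' Inverse of \code{\link{readGeneAnnotations}}: one CDS feature per
#' interval, 1-based inclusive coordinates, flags as attributes.
#'
#' @param genes list of \linkS4class{GeneModel}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeGeneAnnotations <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (g in genes) {
    conv <- zeroBasedToGff(g@cdsStarts, g@cdsEnds)
    for (i in seq_along(g@cdsStarts)) {
      attrs <- sprintf("ID=%s.CDS%d;gene_id=%s;dubious=%s;mitochondrial=%s",
                       g@geneId, i, g@geneId,
                       tolower(g@dubious), tolower(g@mitochondrial))
      writeLines(sprintf("%s\tpexprof\tCDS\t%d\t%d\t.\t%s\t0\t%s",
                         g@chrom, conv$start[i], conv$end[i], g@strand, attrs),
                 con)
    }
  }
  invisible(path)
}
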