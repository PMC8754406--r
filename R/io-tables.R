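#' Read aligned ribosome footprints from a TSV
#'
#' Expects a header with columns \code{chrom}, \code{strand},
#' \code{three_prime_pos} (0-based genome coordinate of the read 3' end)
#' and \code{length} (nt). Duplicate rows are allowed; each row is one
#' footprint.
#'
#' @param path tab-separated file.
#' @return A \linkS4class{FootprintTable} (0 rows for an empty file).
#' @export
readFootprints <- function(path) {
  stopifnot(file.exists(path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) return(FootprintTable())
  need <- c("chrom", "strand", "three_prime_pos", "length")
  if (!all(need %in% names(df)))
    stop("footprint table must have columns: ", paste(need, collapse = ", "))
  if (!all(df$strand %in% c("+", "-")))
    stop("strand values must be '+' or '-'; found: ",
         paste(setdiff(unique(df$strand), c("+", "-")), collapse = ", "))
  if (any(df$three_prime_pos < 0)) stop("negative three_prime_pos")
  if (any(df$length <= 0)) stop("non-positive footprint length")
  FootprintTable(df[need])
}

#' Write a FootprintTable as TSV
#'
#' @param ft a \linkS4class{FootprintTable}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeFootprints <- function(ft, path) {
  stopifnot(is(ft, "FootprintTable"))
  utils::write.table(ft@footprints, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write a flat key-value pipeline configuration
#'
#' The config file holds one \code{key = value} pair per line, keys matching
#' the \linkS4class{PipelineConfig} slots. Numeric values are written with
#' full precision so a write/read cycle is lossless.
#'
#' @param path config file.
#' @return \code{readPipelineConfig}: a \linkS4class{PipelineConfig}.
#' @export
readPipelineConfig <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- which(vapply(kv, length, integer(1)) != 2L)
  if (length(bad))
    stop(sprintf("malformed config line %d: expected 'key = value'", bad[1]))
  keys <- vapply(kv, function(p) trimws(p[1]), character(1))
  vals <- vapply(kv, function(p) trimws(p[2]), character(1))
  cfg <- PipelineConfig()
  intSlots <- c("psiteOffsetNt", "minInputFootprints", "rngSeed")
  for (i in seq_along(keys)) {
    k <- keys[i]
    if (!k %in% slotNames(cfg)) stop("unknown config key: ", k)
    v <- if (vals[i] == "NA") NA else as.numeric(vals[i])
    slot(cfg, k) <- if (k %in% intSlots) as.integer(v) else as.numeric(v)
  }
  validObject(cfg)
  cfg
}

#' @rdname readPipelineConfig
#' @param config a \linkS4class{PipelineConfig} to serialize.
#' @export
writePipelineConfig <- function(config, path) {
  stopifnot(is(config, "PipelineConfig"))
  con <- file(path, "w")
  on.exit(close(con))
  for (s in slotNames(config)) {
    v <- slot(config, s)
    writeLines(sprintf("%s = %s", s,
                       if (is.na(v)) "NA" else format(v, digits = 17)), con)
  }
  invisible(path)
}
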