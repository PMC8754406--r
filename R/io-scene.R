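#' Read / write a tomogram scene (membrane + ribosome centroids) as JSON
#'
#' The scene JSON carries the sphere model (center, radius, in px), the
#' pixel calibration, the ribosome centroid list and, optionally, the crop
#' geometry (\code{dims}, 3 integers). A file without \code{pixel_size_nm}
#' is rejected rather than silently assuming a calibration.
#'
#' @param path JSON scene file.
#' @return \code{readScene}: a list with elements \code{membrane}
#'   (\linkS4class{SphereMembrane}), \code{ribosomes}
#'   (\linkS4class{RibosomeSet}) and, when present in the file,
#'   \code{dims} (integer(3) crop dimensions).
#' @importFrom jsonlite read_json write_json
#' @export
readScene <- function(path) {
  stopifnot(file.exists(path))
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(js$pixel_size_nm))
    stop("scene file has no 'pixel_size_nm'; refusing to assume a calibration")
  if (is.null(js$sphere) || is.null(js$sphere$center) ||
      is.null(js$sphere$radius_px))
    stop("scene file must carry sphere center and radius_px")
  px <- as.numeric(js$pixel_size_nm)
  cents <- js$centroids
  if (is.null(cents) || length(cents) == 0L)
    cents <- matrix(numeric(0), ncol = 3)
  cents <- matrix(as.numeric(as.matrix(cents)), ncol = 3)
  out <- list(
    membrane = SphereMembrane(as.numeric(js$sphere$center),
                              as.numeric(js$sphere$radius_px), px),
    ribosomes = RibosomeSet(cents, px))
  if (!is.null(js$dims)) out$dims <- as.integer(js$dims)
  out
}

#' @rdname readScene
#' @param membrane a \linkS4class{SphereMembrane}.
#' @param ribosomes a \linkS4class{RibosomeSet}.
#' @param dims optional integer(3) crop dimensions to record.
#' @export
writeScene <- function(membrane, ribosomes, path, dims = NULL) {
  stopifnot(is(membrane, "SphereMembrane"), is(ribosomes, "RibosomeSet"))
  if (abs(membrane@pixelSizeNm - ribosomes@pixelSizeNm) > 1e-9)
    stop("membrane and ribosome pixel sizes differ")
  js <- list(
    pixel_size_nm = membrane@pixelSizeNm,
    sphere = list(center = membrane@center, radius_px = membrane@radius),
    centroids = unname(ribosomes@centroids))
  if (!is.null(dims)) js$dims <- as.integer(dims)
  jsonlite::write_json(js, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Minimal MRC volume I/O
#'
#' Reads/writes single-volume MRC2014 files (modes 0, 1, 2; little-endian),
#' enough to exchange labeled/segmented volumes with EM tools. The voxel
#' size is taken from the cell dimensions (\code{cella}, in Angstrom) and
#' attached as attribute \code{pixelSizeNm}; a file with a zero cell is
#' read with \code{pixelSizeNm = NA}.
#'
#' @param path MRC file.
#' @return \code{readMrc}: a numeric 3D array with attribute
#'   \code{pixelSizeNm}.
#' @export
readMrc <- function(path) {
  stopifnot(file.exists(path))
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "integer", n = 10, size = 4, endian = "little")
  nx <- hdr[1]; ny <- hdr[2]; nz <- hdr[3]; mode <- hdr[4]
  if (nx <= 0 || ny <= 0 || nz <= 0 || !mode %in% c(0L, 1L, 2L))
    stop("unsupported or corrupt MRC header (mode ", mode, ")")
  cella <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  seek(con, 92)
  nsymbt <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  seek(con, 1024 + nsymbt)
  n <- as.double(nx) * ny * nz
  data <- switch(as.character(mode),
    "0" = as.numeric(readBin(con, "integer", n = n, size = 1, signed = TRUE)),
    "1" = as.numeric(readBin(con, "integer", n = n, size = 2,
                             endian = "little")),
    "2" = readBin(con, "numeric", n = n, size = 4, endian = "little"))
  if (length(data) != n) stop("truncated MRC data block")
  vol <- array(data, dim = c(nx, ny, nz))
  attr(vol, "pixelSizeNm") <- if (cella[1] > 0) cella[1] / nx / 10 else NA_real_
  vol
}

#' @rdname readMrc
#' @param volume numeric 3D array.
#' @param pixelSizeNm voxel size in nm, stored in the header cell.
#' @export
writeMrc <- function(volume, path, pixelSizeNm = 1.159) {
  stopifnot(is.array(volume), length(dim(volume)) == 3L)
  d <- dim(volume)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.integer(c(d, 2L, 0L, 0L, 0L, d)), con, size = 4,
           endian = "little")                                  # words 1-10
  writeBin(as.numeric(c(d * pixelSizeNm * 10, 90, 90, 90)), con, size = 4,
           endian = "little")                                  # cella, cellb
  writeBin(as.integer(c(1L, 2L, 3L)), con, size = 4, endian = "little")
  writeBin(as.numeric(c(min(volume), max(volume), mean(volume))), con,
           size = 4, endian = "little")                        # words 20-22
  writeBin(integer(2), con, size = 4, endian = "little")       # ispg, nsymbt
  writeBin(integer(25), con, size = 4, endian = "little")      # extra
  writeBin(numeric(3), con, size = 4, endian = "little")       # origin
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)             # machine stamp
  writeBin(as.numeric(stats::sd(volume)), con, size = 4, endian = "little")
  writeBin(0L, con, size = 4, endian = "little")               # nlabl
  writeBin(raw(800), con)                                      # labels
  writeBin(as.numeric(volume), con, size = 4, endian = "little")
  invisible(path)
}
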