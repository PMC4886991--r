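#' Still-image frames and SMV-format input/output
#'
#' An `image_frame` bundles a 2-D intensity raster (matrix, rows = slow
#' axis, columns = fast axis, non-negative integers), its
#' [detector_geometry()], the wavelength, an optional exclusion mask
#' (logical matrix, TRUE = excluded) and a source identifier.
#'
#' Frames are stored on disk in an SMV dialect: a 512-byte ASCII header
#' delimited by `{`...`}` followed by the raster as 16-bit unsigned
#' little-endian integers in slow-major order.  Header keys:
#' `HEADER_BYTES`, `DIM=2`, `TYPE=unsigned_short`,
#' `BYTE_ORDER=little_endian`, `SIZE1` (slow), `SIZE2` (fast),
#' `PIXEL_SIZE` (mm), `DISTANCE` (mm), `WAVELENGTH` (angstrom),
#' `BEAM_CENTER_X` (fast, mm), `BEAM_CENTER_Y` (slow, mm).  Beam-center mm
#' values relate to 1-based pixel coordinates as `mm = (px - 1) *
#' PIXEL_SIZE`.  A mask, when present, is a companion file with suffix
#' `.mask` holding a 0/1 raster with the same header.
#'
#' @param raster integer matrix (slow x fast).
#' @param geometry `detector_geometry` with pixel counts equal to `dim(raster)`.
#' @param wavelength angstrom.
#' @param mask optional logical matrix, same shape; TRUE = excluded.
#' @param source_id string identifying the frame.
#' @return an object of class `image_frame`.
#' @export
image_frame <- function(raster, geometry, wavelength, mask = NULL,
                        source_id = "frame") {
  stopifnot(is.matrix(raster), inherits(geometry, "detector_geometry"))
  if (nrow(raster) != geometry$n_slow || ncol(raster) != geometry$n_fast)
    stop("raster shape ", nrow(raster), "x", ncol(raster),
         " does not match geometry ", geometry$n_slow, "x", geometry$n_fast)
  if (!is.null(mask)) {
    stopifnot(is.logical(mask))
    if (!all(dim(mask) == dim(raster))) stop("mask shape must equal raster shape")
  }
  if (wavelength <= 0) stop("wavelength must be positive")
  structure(list(raster = raster, geometry = geometry,
                 wavelength = wavelength, mask = mask,
                 source_id = source_id),
            class = "image_frame")
}

#' @export
print.image_frame <- function(x, ...) {
  cat(sprintf("still frame '%s': %d x %d px, lambda %.4g A, %s\n",
              x$source_id, nrow(x$raster), ncol(x$raster), x$wavelength,
              if (is.null(x$mask)) "no mask"
              else sprintf("%d px masked", sum(x$mask))))
  print(x$geometry)
  invisible(x)
}

smv_header_string <- function(frame) {
  g <- frame$geometry
  keys <- c(
    "HEADER_BYTES= 512;",
    "DIM=2;",
    "TYPE=unsigned_short;",
    "BYTE_ORDER=little_endian;",
    sprintf("SIZE1=%d;", g$n_slow),
    sprintf("SIZE2=%d;", g$n_fast),
    sprintf("PIXEL_SIZE=%.8g;", g$pixel_size),
    sprintf("DISTANCE=%.8g;", g$distance),
    sprintf("WAVELENGTH=%.8g;", frame$wavelength),
    sprintf("BEAM_CENTER_X=%.8g;", (g$beam_center[2] - 1) * g$pixel_size),
    sprintf("BEAM_CENTER_Y=%.8g;", (g$beam_center[1] - 1) * g$pixel_size))
  hdr <- paste0("{\n", paste(keys, collapse = "\n"), "\n}\n")
  if (nchar(hdr) > 512) stop("header exceeds 512 bytes")
  paste0(hdr, strrep(" ", 512 - nchar(hdr)))
}

#' @rdname read_frame
#' @param frame `image_frame` to write.
#' @export
write_frame <- function(frame, path) {
  stopifnot(inherits(frame, "image_frame"))
  v <- as.vector(t(frame$raster))        # slow-major
  v <- pmin(pmax(round(v), 0), 65535)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(smv_header_string(frame), con, eos = NULL)
  writeBin(as.integer(v), con, size = 2, endian = "little")
  if (!is.null(frame$mask)) {
    mf <- image_frame(matrix(as.integer(frame$mask), nrow(frame$raster)),
                      frame$geometry, frame$wavelength,
                      source_id = paste0(frame$source_id, ".mask"))
    write_frame(mf, paste0(path, ".mask"))
  }
  invisible(path)
}

parse_smv_header <- function(raw512, path) {
  txt <- rawToChar(raw512[raw512 != as.raw(0)])
  if (!grepl("\\{", txt) || !grepl("\\}", txt))
    stop("not an SMV header (missing {...}) in ", path)
  body <- sub("^[^{]*\\{", "", txt)
  body <- sub("\\}.*$", "", body)
  lines <- strsplit(body, "[;\n]+")[[1]]
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "=")
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = "="), ""))
  names(vals) <- toupper(keys)
  need <- function(k) {
    if (!k %in% names(vals)) stop("SMV header of ", path, " is missing key ", k)
    vals[[k]]
  }
  list(dim = as.integer(need("DIM")),
       type = need("TYPE"),
       size1 = as.integer(need("SIZE1")),
       size2 = as.integer(need("SIZE2")),
       pixel_size = as.numeric(need("PIXEL_SIZE")),
       distance = as.numeric(need("DISTANCE")),
       wavelength = as.numeric(need("WAVELENGTH")),
       bcx_mm = as.numeric(need("BEAM_CENTER_X")),
       bcy_mm = as.numeric(need("BEAM_CENTER_Y")))
}

#' Read and write SMV still frames
#'
#' `read_frame` parses the 512-byte header and the 16-bit payload; if a
#' companion `<path>.mask` file exists its non-zero pixels become the
#' frame mask.  `write_frame` is the inverse; `write_frame` then
#' `read_frame` is the identity on the raster (bit exact) and on the
#' geometry within header precision.
#'
#' @param path file path.
#' @param read_mask look for the companion mask file (default TRUE).
#' @return `read_frame`: an `image_frame`; `write_frame`: the path, invisibly.
#' @export
read_frame <- function(path, read_mask = TRUE) {
  con <- file(path, "rb")
  on.exit(close(con))
  raw512 <- readBin(con, "raw", 512)
  if (length(raw512) < 512) stop("truncated header in ", path)
  h <- parse_smv_header(raw512, path)
  if (h$dim != 2L) stop("unsupported SMV DIM=", h$dim, " (only DIM=2 supported)")
  if (h$type != "unsigned_short") stop("unsupported SMV TYPE=", h$type)
  n <- h$size1 * h$size2
  v <- readBin(con, "integer", n, size = 2, signed = FALSE, endian = "little")
  if (length(v) < n)
    stop("truncated SMV payload in ", path, ": expected ", 2 * n,
         " bytes, found ", 2 * length(v))
  raster <- matrix(v, nrow = h$size1, ncol = h$size2, byrow = TRUE)
  geom <- detector_geometry(h$size1, h$size2, h$pixel_size, h$distance,
                            c(h$bcy_mm / h$pixel_size + 1,
                              h$bcx_mm / h$pixel_size + 1))
  mask <- NULL
  mpath <- paste0(path, ".mask")
  if (read_mask && file.exists(mpath)) {
    mframe <- read_frame(mpath, read_mask = FALSE)
    mask <- mframe$raster != 0
  }
  image_frame(raster, geom, h$wavelength, mask = mask,
              source_id = basename(path))
}
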