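#' Write a cube as an ENVI raster
#'
#' Emits 32-bit little-endian IEEE floats (ENVI data type 4) plus a plain
#' text key-value header (`<path>.hdr`) carrying `samples`, `lines`,
#' `bands`, `interleave`, `data type`, `byte order` and the wavelength
#' list in nm. Values are quantized to float32 on disk; cubes already
#' representable in float32 round-trip bit-exactly.
#'
#' @param cube a [spectral_cube]; all values must be finite and
#'   non-negative.
#' @param path output data file path; the header is written to
#'   `paste0(path, ".hdr")`.
#' @param interleave one of `"BSQ"` (band sequential), `"BIL"` (band
#'   interleaved by line), `"BIP"` (band interleaved by pixel).
#' @return `path`, invisibly.
#' @seealso [read_cube]
#' @export
write_cube <- function(cube, path, interleave = c("BSQ", "BIL", "BIP")) {
  if (inherits(cube, "spectral_cube") && any(cube$data < 0, na.rm = TRUE))
    stop("refusing to write cube with negative reflectance", call. = FALSE)
  write_envi_raster(cube, path, interleave)
}

# Same layout as write_cube but without the reflectance sign check, for
# score/abundance rasters which may legitimately be negative.
write_envi_raster <- function(cube, path, interleave = c("BSQ", "BIL", "BIP")) {
  interleave <- match.arg(interleave)
  if (!inherits(cube, "spectral_cube")) stop("`cube` must be a spectral_cube")
  if (any(!is.finite(cube$data)))
    stop("refusing to write cube with non-finite values", call. = FALSE)
  d <- dim(cube$data)
  # disk element order: fastest-varying first
  perm <- switch(interleave,
    BSQ = c(2L, 1L, 3L),  # sample, line, band
    BIL = c(2L, 3L, 1L),  # sample, band, line
    BIP = c(3L, 2L, 1L))  # band, sample, line
  payload <- as.vector(aperm(cube$data, perm))
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(payload, con, size = 4L, endian = "little")
  hdr <- c(
    "ENVI",
    paste0("samples = ", d[2L]),
    paste0("lines = ", d[1L]),
    paste0("bands = ", d[3L]),
    "header offset = 0",
    "data type = 4",
    paste0("interleave = ", tolower(interleave)),
    "byte order = 0",
    "wavelength units = Nanometers",
    paste0("wavelength = { ",
           paste(format(cube$wavelengths, trim = TRUE, digits = 12),
                 collapse = ", "), " }"))
  writeLines(hdr, paste0(path, ".hdr"))
  invisible(path)
}

# Parse the minimal ENVI header dialect: "key = value" lines, values in
# braces may span lines.
parse_envi_header <- function(hdr_path) {
  lines <- readLines(hdr_path, warn = FALSE)
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    ln <- lines[i]
    if (grepl("=", ln, fixed = TRUE)) {
      key <- tolower(trimws(sub("=.*", "", ln)))
      val <- trimws(sub("^[^=]*=", "", ln))
      if (startsWith(val, "{")) {
        while (!grepl("}", val, fixed = TRUE) && i < length(lines)) {
          i <- i + 1L
          val <- paste(val, trimws(lines[i]))
        }
        val <- gsub("[{}]", "", val)
      }
      out[[key]] <- trimws(val)
    }
    i <- i + 1L
  }
  out
}

#' Read an ENVI raster into a spectral cube
#'
#' Reads the data file plus its `<path>.hdr` header as written by
#' [write_cube]. Only the float32 little-endian dialect is supported;
#' BSQ, BIL and BIP interleaves all load to the same in-memory layout.
#'
#' @param path data file path (header expected at `paste0(path, ".hdr")`).
#' @return a [spectral_cube].
#' @export
read_cube <- function(path) {
  hdr_path <- paste0(path, ".hdr")
  if (!file.exists(hdr_path)) stop("missing ENVI header: ", hdr_path, call. = FALSE)
  h <- parse_envi_header(hdr_path)
  need <- c("samples", "lines", "bands", "interleave", "data type",
            "byte order", "wavelength")
  missing_keys <- setdiff(need, names(h))
  if (length(missing_keys))
    stop("ENVI header missing required field(s): ",
         paste(missing_keys, collapse = ", "), call. = FALSE)
  if (h[["data type"]] != "4")
    stop("unsupported ENVI data type ", h[["data type"]],
         " (only 4 = float32)", call. = FALSE)
  if (h[["byte order"]] != "0")
    stop("unsupported byte order ", h[["byte order"]],
         " (only 0 = little-endian)", call. = FALSE)
  interleave <- toupper(h[["interleave"]])
  if (!interleave %in% c("BSQ", "BIL", "BIP"))
    stop("unsupported interleave '", h[["interleave"]], "'", call. = FALSE)
  W <- as.integer(h[["samples"]]); H <- as.integer(h[["lines"]])
  B <- as.integer(h[["bands"]])
  wl <- as.numeric(strsplit(h[["wavelength"]], ",")[[1L]])
  if (length(wl) != B)
    stop("header declares ", B, " bands but lists ", length(wl),
         " wavelengths", call. = FALSE)
  n <- as.numeric(W) * H * B
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 4 * n)
    stop("data file smaller than ", W, "x", H, "x", B,
         " float32 payload", call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  payload <- readBin(con, "numeric", n = n, size = 4L, endian = "little")
  dims <- switch(interleave,
    BSQ = c(W, H, B), BIL = c(W, B, H), BIP = c(B, W, H))
  unperm <- switch(interleave,
    BSQ = c(2L, 1L, 3L),  # back to (line, sample, band)
    BIL = c(3L, 1L, 2L),
    BIP = c(3L, 2L, 1L))
  arr <- aperm(array(payload, dims), unperm)
  spectral_cube(arr, wl)
}

#' Write a binary mask as a single-band ENVI raster
#'
#' Stored as float32 0/1; read back with [read_mask].
#' @param mask logical matrix.
#' @param path output data file path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(is.matrix(mask))
  # wavelength 0 placeholder: masks carry no spectral axis
  cube <- spectral_cube(array(as.numeric(mask), c(dim(mask), 1L)), 0)
  write_cube(cube, path, "BSQ")
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  cube <- read_cube(path)
  if (dim(cube$data)[3L] != 1L)
    stop("mask raster must have exactly one band", call. = FALSE)
  cube$data[, , 1L] > 0.5
}
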