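#' Construct a hyperspectral reflectance cube
#'
#' A `spectral_cube` bundles an H x W x B reflectance array with its band
#' wavelengths (nm). Reflectance is unitless; values are expected in
#' \[0, 1\] up to noise. Pixels are addressed `(row, col, band)` and pixel
#' flattening (e.g. for the autocorrelation matrix) is row-major, so pixel
#' `i` of the flattened list is `(row = (i-1) %/% W + 1, col = (i-1) %% W + 1)`.
#'
#' @param data numeric array with `dim = c(H, W, B)`, all values finite.
#' @param wavelengths numeric vector of length B, nm, strictly increasing.
#' @return An object of class `spectral_cube` with elements `data` and
#'   `wavelengths`.
#' @examples
#' cube <- spectral_cube(array(runif(4 * 5 * 3), c(4, 5, 3)), c(900, 905, 910))
#' dim(cube)
#' @export
spectral_cube <- function(data, wavelengths) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-d array (rows x cols x bands)", call. = FALSE)
  wavelengths <- as.numeric(wavelengths)
  if (length(wavelengths) != dim(data)[3L])
    stop("wavelength count (", length(wavelengths),
         ") does not match band count (", dim(data)[3L], ")", call. = FALSE)
  if (any(!is.finite(wavelengths)) || any(diff(wavelengths) <= 0))
    stop("`wavelengths` must be finite and strictly increasing", call. = FALSE)
  if (any(!is.finite(data)))
    stop("cube contains non-finite reflectance values", call. = FALSE)
  structure(list(data = data, wavelengths = wavelengths),
            class = "spectral_cube")
}

#' @export
dim.spectral_cube <- function(x) dim(x$data)

#' @export
print.spectral_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<spectral_cube> %d x %d pixels, %d bands (%.0f-%.0f nm)\n",
              d[1L], d[2L], d[3L], min(x$wavelengths), max(x$wavelengths)))
  cat(sprintf("  reflectance range [%.4g, %.4g]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' Flatten a cube to an N x L pixel matrix
#'
#' Rows are pixels in row-major order, columns are bands.
#'
#' @param cube a [spectral_cube].
#' @return numeric matrix, `H*W` rows by `B` columns.
#' @export
cube_pixels <- function(cube) {
  d <- dim(cube$data)
  # aperm to (col, row, band) then fold rows-within-cols? Row-major pixel
  # order means row varies slowest within the pixel index only if we take
  # pixels as (row-1)*W + col; build via aperm to (band) last, pixels in
  # row-major order = t over the H x W slice.
  m <- matrix(aperm(cube$data, c(2L, 1L, 3L)), nrow = d[1L] * d[2L], ncol = d[3L])
  m
}

#' Find the band nearest a target wavelength
#'
#' Returns the index of the band whose wavelength is closest to
#' `target_nm`; ties are broken toward the lower index. The target must lie
#' within one band spacing of the grid ends.
#'
#' @param cube a [spectral_cube].
#' @param target_nm target wavelength, nm.
#' @return integer band index (1-based).
#' @examples
#' cube <- spectral_cube(array(0.5, c(2, 2, 161)), seq(900, 1700, by = 5))
#' nearest_band(cube, 1073)  # the 1075 nm band
#' @export
nearest_band <- function(cube, target_nm) {
  w <- cube$wavelengths
  n <- length(w)
  lo <- w[1L] - if (n > 1L) w[2L] - w[1L] else 0
  hi <- w[n] + if (n > 1L) w[n] - w[n - 1L] else 0
  if (!is.finite(target_nm) || target_nm < lo || target_nm > hi)
    stop("target wavelength ", target_nm, " nm outside the grid [",
         lo, ", ", hi, "] nm", call. = FALSE)
  which.min(abs(w - target_nm))
}

#' Render a three-band pseudocolor composite
#'
#' Each requested wavelength is resolved with [nearest_band] and the three
#' band images are independently min-max normalized to \[0, 1\]; a constant
#' channel maps to 0. The default bands sit inside the NIR-II biological
#' window, where tissue absorption is low and penetration deepest.
#'
#' @param cube a [spectral_cube].
#' @param bands_nm three wavelengths (nm) for the R, G, B channels.
#' @return H x W x 3 numeric array in \[0, 1\].
#' @export
pseudocolor <- function(cube, bands_nm = c(1091, 1211, 1318)) {
  stopifnot(length(bands_nm) == 3L)
  idx <- vapply(bands_nm, function(b) nearest_band(cube, b), integer(1))
  out <- array(0, c(dim(cube$data)[1:2], 3L))
  for (k in 1:3) {
    ch <- cube$data[, , idx[k]]
    rng <- range(ch)
    if (rng[2L] > rng[1L]) out[, , k] <- (ch - rng[1L]) / (rng[2L] - rng[1L])
  }
  out
}

#' @describeIn spectral_cube Display a pseudocolor composite of the cube.
#' @param x,y,... plot method arguments; `...` passes `bands_nm` on to
#'   [pseudocolor].
#' @export
plot.spectral_cube <- function(x, y, ...) {
  img <- pseudocolor(x, ...)
  graphics::plot.new()
  graphics::plot.window(c(0, 1), c(0, 1), asp = dim(img)[1L] / dim(img)[2L])
  graphics::rasterImage(img, 0, 0, 1, 1, interpolate = FALSE)
  invisible(x)
}
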