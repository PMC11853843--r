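#' Describe a synthetic SWIR phantom scene
#'
#' A `phantom_scene` is the complete, seedable description of one simulated
#' acquisition: the phantom geometry, the effective optics, the noise level
#' and the RNG seed. The same scene with the same seed always yields a
#' bit-identical cube and ground truth; changing only the seed changes the
#' noise but never the ground truth.
#'
#' Geometries mirror the four phantom designs the experiments use:
#' \describe{
#'   \item{`slab_series`}{collagen slabs of increasing thickness imaged
#'     over a bright/dark background grid (penetration study).}
#'   \item{`embedded_target`}{a square lard (lipid) block under
#'     `depth_mm` of collagen; the target pixels carry the mixed spectrum
#'     `f * lipid + (1 - f) * collagen` with `f = exp(-2 * mu_eff * depth)`.}
#'   \item{`concentration_panels`}{vertical panels of collagen at the
#'     listed concentrations, each pixel a linear mix of the 2% and 5%
#'     endmember spectra.}
#'   \item{`sloped_wedge`}{a lard layer descending linearly with column
#'     index at `slope_deg`, down to `max_depth_mm`.}
#' }
#'
#' The factor 2 in `exp(-2 * mu_eff * depth)` models the two-way
#' (illumination + return) path of reflectance geometry; `mu_eff` is an
#' effective attenuation coefficient per mm of collagen.
#'
#' @param geometry one of `"slab_series"`, `"embedded_target"`,
#'   `"concentration_panels"`, `"sloped_wedge"`.
#' @param mu_eff effective attenuation coefficient, 1/mm. Default 0.04/mm
#'   spans strong (f ~ 0.57 at 7 mm) to faint (f ~ 0.004 at 68 mm) targets
#'   over the depth range studied.
#' @param sigma per-band Gaussian noise standard deviation, reflectance
#'   units; samples are clipped at 0 so reflectance stays non-negative.
#' @param seed integer RNG seed.
#' @param nrow,ncol scene raster size in pixels.
#' @param wavelengths wavelength grid, nm.
#' @param thicknesses_mm slab thickness list (`slab_series`), mm,
#'   strictly increasing.
#' @param depth_mm lard depth (`embedded_target`), mm.
#' @param target_fraction optional direct lipid mixing fraction for
#'   `embedded_target`; overrides `depth_mm` via
#'   `depth = -log(f) / (2 * mu_eff)`.
#' @param target_size target block edge length, pixels.
#' @param concentrations collagen concentrations (percent) for
#'   `concentration_panels`, each in \[2, 5\].
#' @param slope_deg wedge slope, degrees, in (0, 90).
#' @param max_depth_mm greatest wedge depth, mm.
#' @param mixing `"linear_reflectance"` (pixels are convex combinations of
#'   endmember spectra) or `"beer_lambert"` (concentration scales
#'   absorbance).
#' @return an object of class `phantom_scene`.
#' @export
phantom_scene <- function(geometry = c("slab_series", "embedded_target",
                                       "concentration_panels", "sloped_wedge"),
                          mu_eff = 0.04, sigma = 0.005, seed = 1L,
                          nrow = 120L, ncol = 120L,
                          wavelengths = default_wavelengths(),
                          thicknesses_mm = c(10, 20, 30, 40, 60, 80),
                          depth_mm = 20, target_fraction = NULL,
                          target_size = 40L,
                          concentrations = c(2, 3, 4, 5),
                          slope_deg = 28.25, max_depth_mm = 40,
                          mixing = c("linear_reflectance", "beer_lambert")) {
  geometry <- match.arg(geometry)
  mixing <- match.arg(mixing)
  if (mu_eff < 0) stop("mu_eff must be >= 0", call. = FALSE)
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  if (geometry == "slab_series" && any(diff(thicknesses_mm) <= 0))
    stop("thicknesses must be strictly increasing", call. = FALSE)
  if (geometry == "embedded_target") {
    if (!is.null(target_fraction)) {
      if (target_fraction <= 0 || target_fraction > 1)
        stop("target_fraction must be in (0, 1]", call. = FALSE)
      depth_mm <- if (mu_eff > 0) -log(target_fraction) / (2 * mu_eff) else 0
    }
    if (depth_mm < 0) stop("depth must be >= 0", call. = FALSE)
    if (target_size > min(nrow, ncol))
      stop("target block exceeds image bounds", call. = FALSE)
  }
  if (geometry == "concentration_panels") {
    if (length(concentrations) < 2L) stop("need >= 2 panels", call. = FALSE)
    if (any(concentrations <= 0 | concentrations >= 100))
      stop("concentrations must lie in (0, 100)", call. = FALSE)
    if (ncol %/% length(concentrations) < 1L)
      stop("panel width < 1 pixel", call. = FALSE)
  }
  if (geometry == "sloped_wedge") {
    if (slope_deg <= 0 || slope_deg >= 90)
      stop("slope must be in (0, 90) degrees", call. = FALSE)
    if (max_depth_mm <= 0) stop("max depth must be > 0", call. = FALSE)
    if (ncol < 2L) stop("wedge needs at least 2 columns", call. = FALSE)
  }
  structure(list(geometry = geometry, mu_eff = mu_eff, sigma = sigma,
                 seed = as.integer(seed), nrow = as.integer(nrow),
                 ncol = as.integer(ncol), wavelengths = wavelengths,
                 thicknesses_mm = thicknesses_mm, depth_mm = depth_mm,
                 target_size = as.integer(target_size),
                 concentrations = concentrations, slope_deg = slope_deg,
                 max_depth_mm = max_depth_mm, mixing = mixing),
            class = "phantom_scene")
}

#' @export
print.phantom_scene <- function(x, ...) {
  cat(sprintf("<phantom_scene> %s, %dx%d px, %d bands\n", x$geometry,
              x$nrow, x$ncol, length(x$wavelengths)))
  cat(sprintf("  mu_eff = %g /mm, sigma = %g, seed = %d\n",
              x$mu_eff, x$sigma, x$seed))
  invisible(x)
}

# Truncated additive Gaussian band noise; clip keeps reflectance >= 0.
add_noise <- function(arr, sigma) {
  if (sigma <= 0) return(arr)
  pmax(arr + stats::rnorm(length(arr), sd = sigma), 0)
}

# two-way attenuation of a target seen through `depth` mm of medium
attenuation_fraction <- function(mu_eff, depth_mm) exp(-2 * mu_eff * depth_mm)

#' Simulate the slab penetration series
#'
#' One cube per thickness: a bright/dark checker grid background seen
#' through the collagen slab, modelled as the background albedo times the
#' slab transmission spectrum times the two-way attenuation
#' `exp(-2 * mu_eff * thickness)`, plus truncated Gaussian noise. Thicker
#' slabs are strictly darker at every band whenever `mu_eff > 0`.
#'
#' @param scene a [phantom_scene] with `geometry = "slab_series"`.
#' @return named list (one element per thickness, names in mm) of
#'   [spectral_cube]s.
#' @export
simulate_slab_series <- function(scene) {
  stopifnot(inherits(scene, "phantom_scene"), scene$geometry == "slab_series")
  slab <- material_spectrum("collagen", scene$wavelengths)
  # background grid: dark lines every 10 px over a bright field
  bg <- matrix(0.9, scene$nrow, scene$ncol)
  lines_r <- seq_len(scene$nrow) %% 10L == 0L
  lines_c <- seq_len(scene$ncol) %% 10L == 0L
  bg[lines_r, ] <- 0.3
  bg[, lines_c] <- 0.3
  set.seed(scene$seed)
  out <- lapply(scene$thicknesses_mm, function(th) {
    att <- attenuation_fraction(scene$mu_eff, th)
    arr <- outer(bg * att, slab$reflectance)
    spectral_cube(add_noise(arr, scene$sigma), scene$wavelengths)
  })
  names(out) <- as.character(scene$thicknesses_mm)
  out
}

#' Simulate a lard block embedded at depth in collagen
#'
#' Target-bearing pixels carry `f * lipid + (1 - f) * collagen` with
#' `f = exp(-2 * mu_eff * depth)`; the background is pure collagen.
#' Ground truth is the exact target block mask plus the per-pixel true
#' lipid fraction.
#'
#' @param scene a [phantom_scene] with `geometry = "embedded_target"`.
#' @return list with `cube` ([spectral_cube]), `truth` (list: `mask`
#'   logical H x W, `fraction` the lipid mixing fraction f, `depth_mm`),
#'   and `endmembers` (the pure lipid/collagen spectra used).
#' @export
simulate_embedded_target <- function(scene) {
  stopifnot(inherits(scene, "phantom_scene"),
            scene$geometry == "embedded_target")
  lipid <- material_spectrum("lipid", scene$wavelengths)
  collagen <- material_spectrum("collagen", scene$wavelengths)
  f <- attenuation_fraction(scene$mu_eff, scene$depth_mm)
  mask <- matrix(FALSE, scene$nrow, scene$ncol)
  r0 <- (scene$nrow - scene$target_size) %/% 2L + 1L
  c0 <- (scene$ncol - scene$target_size) %/% 2L + 1L
  rows <- r0:(r0 + scene$target_size - 1L)
  cols <- c0:(c0 + scene$target_size - 1L)
  mask[rows, cols] <- TRUE
  target_spec <- f * lipid$reflectance + (1 - f) * collagen$reflectance
  B <- length(scene$wavelengths)
  arr <- array(rep(collagen$reflectance, each = scene$nrow * scene$ncol),
               c(scene$nrow, scene$ncol, B))
  for (b in seq_len(B)) {
    plane <- arr[, , b]
    plane[mask] <- target_spec[b]
    arr[, , b] <- plane
  }
  set.seed(scene$seed)
  cube <- spectral_cube(add_noise(arr, scene$sigma), scene$wavelengths)
  list(cube = cube,
       truth = list(mask = mask, fraction = f, depth_mm = scene$depth_mm),
       endmembers = list(lipid = lipid, collagen = collagen))
}

#' Simulate side-by-side collagen concentration panels
#'
#' The image is split into equal-width vertical panels, one per
#' concentration. Each pixel is the convex combination of the 2% and 5%
#' collagen endmember spectra with true abundance `alpha1 = (5 - c) / 3`
#' on the 2% endmember, plus truncated Gaussian noise. Ground truth stores
#' the per-pixel abundance pair (rows sum to 1 exactly).
#'
#' @param scene a [phantom_scene] with `geometry = "concentration_panels"`.
#' @return list with `cube`, `truth` (list: `abundance` H x W x 2 array,
#'   `panel` integer H x W panel index map, `concentrations`), and
#'   `endmembers` (the 2% and 5% spectra).
#' @export
simulate_concentration_panels <- function(scene) {
  stopifnot(inherits(scene, "phantom_scene"),
            scene$geometry == "concentration_panels")
  base <- material_spectrum("collagen", scene$wavelengths)
  e2 <- collagen_at_concentration(base, 2, mode = "beer_lambert")
  e5 <- collagen_at_concentration(base, 5, mode = "beer_lambert")
  k <- length(scene$concentrations)
  panel_of <- pmin(((seq_len(scene$ncol) - 1L) * k) %/% scene$ncol + 1L, k)
  a1_of <- (5 - scene$concentrations) / 3
  B <- length(scene$wavelengths)
  arr <- array(0, c(scene$nrow, scene$ncol, B))
  abund <- array(0, c(scene$nrow, scene$ncol, 2L))
  panel_map <- matrix(panel_of[col(matrix(0, scene$nrow, scene$ncol))],
                      scene$nrow, scene$ncol)
  for (j in seq_len(scene$ncol)) {
    a1 <- a1_of[panel_of[j]]
    spec <- a1 * e2$reflectance + (1 - a1) * e5$reflectance
    arr[, j, ] <- matrix(rep(spec, each = scene$nrow), scene$nrow, B)
    abund[, j, 1L] <- a1
    abund[, j, 2L] <- 1 - a1
  }
  set.seed(scene$seed)
  cube <- spectral_cube(add_noise(arr, scene$sigma), scene$wavelengths)
  list(cube = cube,
       truth = list(abundance = abund, panel = panel_map,
                    concentrations = scene$concentrations),
       endmembers = list(e2, e5))
}

#' Simulate the sloped lard wedge
#'
#' Lard depth grows linearly with column index,
#' `z(col) = col_offset_mm * tan(slope)`, scaled so the last column sits at
#' `max_depth_mm`; each column's spectrum is `f(z) * lipid +
#' (1 - f(z)) * collagen` with `f(z) = exp(-2 * mu_eff * z)`.
#' Ground truth stores per-column depth and lipid fraction.
#'
#' @param scene a [phantom_scene] with `geometry = "sloped_wedge"`.
#' @return list with `cube`, `truth` (list: `depth_mm` per-column vector,
#'   `fraction` per-column lipid fraction), and `endmembers`.
#' @export
simulate_sloped_wedge <- function(scene) {
  stopifnot(inherits(scene, "phantom_scene"), scene$geometry == "sloped_wedge")
  lipid <- material_spectrum("lipid", scene$wavelengths)
  collagen <- material_spectrum("collagen", scene$wavelengths)
  # pixel pitch chosen so the wedge spans 0..max_depth across the columns
  run_mm <- scene$max_depth_mm / tan(scene$slope_deg * pi / 180)
  pitch <- run_mm / (scene$ncol - 1L)
  z <- pmin((seq_len(scene$ncol) - 1L) * pitch * tan(scene$slope_deg * pi / 180),
            scene$max_depth_mm)
  f <- attenuation_fraction(scene$mu_eff, z)
  B <- length(scene$wavelengths)
  arr <- array(0, c(scene$nrow, scene$ncol, B))
  for (j in seq_len(scene$ncol)) {
    spec <- f[j] * lipid$reflectance + (1 - f[j]) * collagen$reflectance
    arr[, j, ] <- matrix(rep(spec, each = scene$nrow), scene$nrow, B)
  }
  set.seed(scene$seed)
  cube <- spectral_cube(add_noise(arr, scene$sigma), scene$wavelengths)
  list(cube = cube,
       truth = list(depth_mm = z, fraction = f),
       endmembers = list(lipid = lipid, collagen = collagen))
}

#' Run the simulator a scene describes
#'
#' Dispatches to the geometry-specific simulator.
#' @param scene a [phantom_scene].
#' @return the geometry-specific simulator's value.
#' @export
simulate_phantom <- function(scene) {
  switch(scene$geometry,
         slab_series = simulate_slab_series(scene),
         embedded_target = simulate_embedded_target(scene),
         concentration_panels = simulate_concentration_panels(scene),
         sloped_wedge = simulate_sloped_wedge(scene))
}
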