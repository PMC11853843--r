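#' Default SWIR wavelength grid
#'
#' 900-1700 nm at 5 nm spacing (161 bands), the default sampling for all
#' simulated scenes. The band count is configurable throughout; sensors in
#' this range variously report a 5 nm optical resolution or several hundred
#' detector bands, so nothing downstream assumes 161.
#'
#' @param from,to grid limits, nm.
#' @param by band spacing, nm.
#' @return numeric vector of wavelengths.
#' @export
default_wavelengths <- function(from = 900, to = 1700, by = 5) {
  seq(from, to, by = by)
}

#' Build a synthetic endmember reflectance spectrum
#'
#' Reflectance is modelled as a Beer-Lambert style exponential of a smooth
#' absorbance curve: a flat baseline plus one Gaussian per absorption peak,
#' `reflectance(lambda) = exp(-baseline - sum_i depth_i *
#' exp(-(lambda - center_i)^2 / (2 width_i^2)))`. Peaks whose center lies
#' above the top of the wavelength grid are dropped with a message: lipid
#' and collagen both have C-H overtone peaks above 1700 nm that a 900-1700
#' nm sensor never sees.
#'
#' @param name label, e.g. `"water"`, `"lipid"`, `"collagen"`.
#' @param peak_centers absorption peak centers, nm.
#' @param peak_depths peak absorbance depths (>= 0), same length.
#' @param peak_widths Gaussian peak standard deviations, nm (> 0).
#' @param baseline flat background absorbance.
#' @param wavelengths wavelength grid, nm.
#' @return an `endmember_spectrum`: list with `name`, `wavelengths`,
#'   `reflectance`, `peak_centers` (the realized peaks).
#' @examples
#' w <- build_endmember("water", c(970, 1180, 1430), c(0.6, 0.8, 1.2), 30)
#' plot(w$wavelengths, w$reflectance, type = "l")
#' @export
build_endmember <- function(name, peak_centers, peak_depths,
                            peak_widths = 30, baseline = 0.3,
                            wavelengths = default_wavelengths()) {
  if (length(wavelengths) == 0L) stop("empty wavelength grid", call. = FALSE)
  k <- length(peak_centers)
  peak_depths <- rep_len(peak_depths, k)
  peak_widths <- rep_len(peak_widths, k)
  if (any(peak_depths < 0)) stop("negative peak depth", call. = FALSE)
  if (any(peak_widths <= 0)) stop("peak widths must be > 0", call. = FALSE)
  keep <- peak_centers <= max(wavelengths)
  if (any(!keep))
    message("dropping out-of-grid peak(s) at ",
            paste(peak_centers[!keep], collapse = ", "), " nm for '", name, "'")
  absorb <- rep(baseline, length(wavelengths))
  for (i in which(keep)) {
    absorb <- absorb + peak_depths[i] *
      exp(-(wavelengths - peak_centers[i])^2 / (2 * peak_widths[i]^2))
  }
  structure(list(name = name, wavelengths = wavelengths,
                 reflectance = exp(-absorb),
                 peak_centers = peak_centers[keep]),
            class = "endmember_spectrum")
}

#' @export
print.endmember_spectrum <- function(x, ...) {
  cat(sprintf("<endmember_spectrum> '%s', %d bands, peaks at %s nm\n",
              x$name, length(x$wavelengths),
              paste(x$peak_centers, collapse = ", ")))
  invisible(x)
}

#' Reference material spectra for the phantom simulator
#'
#' Canonical water, lipid and collagen endmembers on a given grid. Peak
#' centers follow the SWIR overtone assignments for these molecules: water
#' O-H at 970, 1180 and 1430 nm; lipid C-H at 920, 1210, 1730 and 1760 nm;
#' collagen C-H/CH2 at 1200, 1500 and 1725 nm. Peaks above the grid top are
#' dropped by [build_endmember]. Depths and baselines are declared model
#' defaults, not fits to any instrument.
#'
#' @param material one of `"water"`, `"lipid"`, `"collagen"`.
#' @param wavelengths wavelength grid, nm.
#' @return an `endmember_spectrum`.
#' @export
material_spectrum <- function(material = c("water", "lipid", "collagen"),
                              wavelengths = default_wavelengths()) {
  material <- match.arg(material)
  spec <- switch(material,
    water    = list(centers = c(970, 1180, 1430),
                    depths  = c(0.6, 0.8, 1.2), baseline = 0.40),
    lipid    = list(centers = c(920, 1210, 1730, 1760),
                    depths  = c(0.5, 0.9, 1.0, 0.8), baseline = 0.25),
    collagen = list(centers = c(1200, 1500, 1725),
                    depths  = c(0.4, 0.7, 0.9), baseline = 0.35))
  suppressMessages(
    build_endmember(material, spec$centers, spec$depths,
                    peak_widths = 30, baseline = spec$baseline,
                    wavelengths = wavelengths))
}

#' Scale a collagen spectrum to a given concentration
#'
#' Two scaling laws are supported. In `beer_lambert` mode absorbance scales
#' linearly with concentration, so reflectance is raised elementwise to the
#' power `concentration / reference_concentration`. In `linear_reflectance`
#' mode the spectrum is the convex combination of the 2% and 5% spectra
#' (themselves Beer-Lambert scalings of `base`) with weight
#' `(5 - c) / 3` on the 2% spectrum — the rule the concentration-panel
#' simulator and its ground-truth abundances share.
#'
#' @param base an `endmember_spectrum` at the reference concentration.
#' @param concentration target concentration, percent.
#' @param reference_concentration concentration `base` represents, percent.
#' @param mode `"beer_lambert"` or `"linear_reflectance"`.
#' @return an `endmember_spectrum` at the requested concentration.
#' @export
collagen_at_concentration <- function(base, concentration,
                                      reference_concentration = 4,
                                      mode = c("beer_lambert",
                                               "linear_reflectance")) {
  mode <- match.arg(mode)
  if (concentration <= 0 || reference_concentration <= 0)
    stop("concentrations must be > 0", call. = FALSE)
  if (mode == "beer_lambert") {
    refl <- base$reflectance ^ (concentration / reference_concentration)
  } else {
    if (concentration < 2 || concentration > 5)
      stop("linear_reflectance mode interpolates between the 2% and 5% ",
           "spectra; concentration ", concentration,
           "% would extrapolate", call. = FALSE)
    r2 <- base$reflectance ^ (2 / reference_concentration)
    r5 <- base$reflectance ^ (5 / reference_concentration)
    w2 <- (5 - concentration) / 3
    refl <- w2 * r2 + (1 - w2) * r5
  }
  structure(list(name = sprintf("%s_%g%%", base$name, concentration),
                 wavelengths = base$wavelengths, reflectance = refl,
                 peak_centers = base$peak_centers),
            class = "endmember_spectrum")
}
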