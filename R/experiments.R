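#' Depth-detection experiment: CEM + Otsu + Tanimoto vs. lard depth
#'
#' For each depth, simulates an embedded-lard scene, runs CEM detection
#' with the pure lipid spectrum as the target signature, binarizes the
#' abundance map with Otsu's method, and scores the detection against the
#' ground-truth block mask with the Tanimoto index. Besides the plain TI
#' (whose ground truth includes the block boundary), an interior TI is
#' reported that excludes a one-pixel ring around the block boundary,
#' where partial-volume disagreement concentrates.
#'
#' @param depths_mm lard depths to test, mm.
#' @param scene template [phantom_scene] (geometry fields other than depth
#'   are reused); defaults to the standard embedded-target scene.
#' @param seed RNG seed; depth k uses `seed + k - 1` so scenes are
#'   independent.
#' @return data.frame with columns `depth_mm`, `fraction` (true lipid
#'   mixing fraction), `threshold`, `ti`, `ti_interior`; class
#'   `depth_experiment`. Failed depths yield `NA` rows rather than
#'   aborting the run.
#' @export
run_depth_experiment <- function(depths_mm = c(7, 15, 20, 55, 60, 68),
                                 scene = phantom_scene("embedded_target"),
                                 seed = scene$seed) {
  stopifnot(all(depths_mm > 0))
  rows <- lapply(seq_along(depths_mm), function(k) {
    sc <- scene
    sc$depth_mm <- depths_mm[k]
    sc$seed <- as.integer(seed + k - 1L)
    tryCatch({
      sim <- simulate_embedded_target(sc)
      amap <- cem_detect(sim$cube, sim$endmembers$lipid)
      ot <- otsu_threshold(amap)
      ti <- tanimoto_index(ot$mask, sim$truth$mask)
      keep <- !boundary_ring(sim$truth$mask)
      ti_in <- tanimoto_index(ot$mask & keep, sim$truth$mask & keep)
      data.frame(depth_mm = depths_mm[k], fraction = sim$truth$fraction,
                 threshold = ot$threshold, ti = ti, ti_interior = ti_in)
    }, error = function(e) {
      warning("depth ", depths_mm[k], " mm failed: ", conditionMessage(e),
              call. = FALSE)
      data.frame(depth_mm = depths_mm[k], fraction = NA_real_,
                 threshold = NA_real_, ti = NA_real_, ti_interior = NA_real_)
    })
  })
  out <- do.call(rbind, rows)
  class(out) <- c("depth_experiment", class(out))
  out
}

# one-pixel ring around the boundary of the TRUE region of a mask
boundary_ring <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  shift <- function(m, dr, dc) {
    out <- matrix(mask[1L] & FALSE, H, W)
    rs <- seq_len(H) - dr; cs <- seq_len(W) - dc
    ok_r <- rs >= 1L & rs <= H; ok_c <- cs >= 1L & cs <= W
    out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
    out
  }
  interior <- mask
  exterior <- !mask
  for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
    interior <- interior & shift(mask, d[1L], d[2L])
    exterior <- exterior & shift(!mask, d[1L], d[2L])
  }
  (mask & !interior) | (!mask & !exterior)
}

#' Concentration experiment: FCLS abundance vs. collagen concentration
#'
#' Simulates side-by-side collagen panels, takes the mean spectra of the
#' lowest- and highest-concentration panels as the two endmembers, runs
#' FCLS unmixing on every pixel, and reports per-panel mean abundances.
#' Accuracy is summarized as the squared Pearson correlation between the
#' panel-mean abundance of the high-concentration endmember and the true
#' concentration — a linear-correlation analysis over the panel means.
#'
#' @param concentrations collagen concentrations, percent; must include
#'   the two extremes used as endmembers and at least 3 distinct values
#'   for the correlation to be defined.
#' @param scene template [phantom_scene]; geometry forced to
#'   `concentration_panels` with these concentrations.
#' @param seed RNG seed.
#' @return object of class `concentration_experiment`: list with `table`
#'   (data.frame: concentration, mean_alpha1, mean_alpha2), `r_squared`,
#'   `endmember_source`.
#' @export
run_concentration_experiment <- function(concentrations = c(2, 3, 4, 5),
                                         scene = NULL, seed = 11L) {
  if (length(unique(concentrations)) < 3L)
    stop("R^2 undefined with fewer than 3 distinct concentrations",
         call. = FALSE)
  if (is.null(scene))
    scene <- phantom_scene("concentration_panels", sigma = 0.002,
                           concentrations = concentrations, seed = seed)
  scene$geometry <- "concentration_panels"
  scene$concentrations <- concentrations
  scene$seed <- as.integer(seed)
  sim <- simulate_concentration_panels(scene)
  k <- length(concentrations)
  lo <- which.min(concentrations); hi <- which.max(concentrations)
  panel_cols <- function(j) which(apply(sim$truth$panel == j, 2L, any))
  M <- select_endmembers_from_image(
    sim$cube,
    list(list(rows = seq_len(scene$nrow), cols = panel_cols(lo)),
         list(rows = seq_len(scene$nrow), cols = panel_cols(hi))),
    names = c(sprintf("collagen_%g%%", concentrations[lo]),
              sprintf("collagen_%g%%", concentrations[hi])))
  fit <- unmix(sim$cube, M, model = "FCLS")
  tab <- do.call(rbind, lapply(seq_len(k), function(j) {
    sel <- sim$truth$panel == j
    data.frame(concentration = concentrations[j],
               mean_alpha1 = mean(fit$abundance[, , 1L][sel]),
               mean_alpha2 = mean(fit$abundance[, , 2L][sel]))
  }))
  r2 <- stats::cor(tab$mean_alpha2, tab$concentration)^2
  structure(list(table = tab, r_squared = r2,
                 endmember_source = sprintf(
                   "mean spectra of the %g%% and %g%% panels",
                   concentrations[lo], concentrations[hi]),
                 fit = fit),
            class = "concentration_experiment")
}

#' @export
print.concentration_experiment <- function(x, ...) {
  cat("Collagen concentration unmixing experiment\n")
  cat("  endmembers:", x$endmember_source, "\n")
  print(transform(x$table,
                  mean_alpha1 = round(mean_alpha1, 4),
                  mean_alpha2 = round(mean_alpha2, 4)))
  cat(sprintf("  R^2 (panel-mean abundance vs concentration) = %.4f\n",
              x$r_squared))
  invisible(x)
}

#' Sloped-wedge experiment: FCLS fractions vs. depth
#'
#' Simulates the sloped lard wedge, takes the shallowest and deepest
#' columns' mean spectra as the two endmembers, unmixes with FCLS, and
#' averages the abundance of each endmember over every column. For each
#' marker depth, Spearman's rank correlation between the column-mean
#' fraction and the column depth is computed cumulatively over all columns
#' from the surface down to that marker.
#'
#' @param scene template [phantom_scene]; geometry forced to
#'   `sloped_wedge`. Defaults to the 80-column wedge reaching 40 mm.
#' @param marker_depths_cm depths at which to report fractions and
#'   correlations, cm, within (0, max depth].
#' @param seed RNG seed.
#' @return object of class `slope_experiment`: list with `columns`
#'   (data.frame: depth_mm, frac1, frac2), `markers` (data.frame:
#'   depth_cm, frac1, frac2, rho1, rho2).
#' @export
run_slope_experiment <- function(scene = NULL,
                                 marker_depths_cm = c(1, 2, 3, 4),
                                 seed = 5L) {
  if (is.null(scene))
    scene <- phantom_scene("sloped_wedge", nrow = 60L, ncol = 80L,
                           sigma = 0.005, seed = seed)
  scene$geometry <- "sloped_wedge"
  scene$seed <- as.integer(seed)
  if (any(marker_depths_cm * 10 > scene$max_depth_mm + 1e-9) ||
      any(marker_depths_cm <= 0))
    stop("marker depth outside the wedge (max ",
         scene$max_depth_mm / 10, " cm)", call. = FALSE)
  sim <- simulate_sloped_wedge(scene)
  M <- select_endmembers_from_image(
    sim$cube,
    list(list(rows = seq_len(scene$nrow), cols = 1L),
         list(rows = seq_len(scene$nrow), cols = scene$ncol)),
    names = c("shallow (lard)", "deep (collagen)"))
  fit <- unmix(sim$cube, M, model = "FCLS")
  frac1 <- colMeans(fit$abundance[, , 1L])
  frac2 <- colMeans(fit$abundance[, , 2L])
  cols <- data.frame(depth_mm = sim$truth$depth_mm,
                     frac1 = frac1, frac2 = frac2)
  markers <- do.call(rbind, lapply(marker_depths_cm, function(dc) {
    upto <- which(cols$depth_mm <= dc * 10 + 1e-9)
    at <- upto[which.min(abs(cols$depth_mm[upto] - dc * 10))]
    data.frame(depth_cm = dc,
               frac1 = cols$frac1[at], frac2 = cols$frac2[at],
               rho1 = stats::cor(cols$frac1[upto], cols$depth_mm[upto],
                                 method = "spearman"),
               rho2 = stats::cor(cols$frac2[upto], cols$depth_mm[upto],
                                 method = "spearman"))
  }))
  structure(list(columns = cols, markers = markers, fit = fit),
            class = "slope_experiment")
}

#' @export
print.slope_experiment <- function(x, ...) {
  cat("Sloped-wedge unmixing experiment\n")
  print(transform(x$markers, frac1 = round(frac1, 4),
                  frac2 = round(frac2, 4), rho1 = round(rho1, 4),
                  rho2 = round(rho2, 4)))
  invisible(x)
}

#' Penetration experiment: reflectance vs. slab thickness
#'
#' Simulates the slab thickness series and reports the mean reflectance at
#' the band nearest 1073 nm per slab, plus pseudocolor composites at the
#' NIR-II window bands (1091, 1211, 1318 nm). With any positive
#' attenuation the reported means decrease with thickness.
#'
#' @param thicknesses_mm slab thicknesses, mm, strictly increasing.
#' @param scene template [phantom_scene]; geometry forced to
#'   `slab_series`.
#' @param seed RNG seed.
#' @param reference_nm wavelength at which mean reflectance is reported.
#' @return object of class `penetration_experiment`: list with `table`
#'   (data.frame: thickness_mm, mean_reflectance), `reference_nm`,
#'   `pseudocolor` (list of H x W x 3 arrays, one per thickness).
#' @export
run_penetration_experiment <- function(thicknesses_mm = c(10, 20, 30, 40, 60, 80),
                                       scene = NULL, seed = 1L,
                                       reference_nm = 1073) {
  if (any(diff(thicknesses_mm) <= 0))
    stop("thicknesses must be strictly increasing", call. = FALSE)
  if (is.null(scene)) scene <- phantom_scene("slab_series", seed = seed)
  scene$geometry <- "slab_series"
  scene$thicknesses_mm <- thicknesses_mm
  scene$seed <- as.integer(seed)
  cubes <- simulate_slab_series(scene)
  band <- nearest_band(cubes[[1L]], reference_nm)
  tab <- data.frame(
    thickness_mm = thicknesses_mm,
    mean_reflectance = vapply(cubes, function(cb) mean(cb$data[, , band]),
                              numeric(1)))
  rownames(tab) <- NULL
  structure(list(table = tab, reference_nm = reference_nm,
                 band = band,
                 pseudocolor = lapply(cubes, pseudocolor)),
            class = "penetration_experiment")
}

#' @export
print.penetration_experiment <- function(x, ...) {
  cat(sprintf("Slab penetration experiment (mean reflectance at %g nm)\n",
              x$reference_nm))
  print(transform(x$table,
                  mean_reflectance = signif(mean_reflectance, 5)))
  invisible(x)
}
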