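#' Sample autocorrelation matrix of a cube
#'
#' `R = (1/N) * sum_i r_i r_i^T` over all N = H*W pixel spectra, the
#' background second-moment statistic the CEM filter whitens against.
#' Every pixel contributes, target pixels included.
#'
#' @param cube a [spectral_cube] (or an N x L pixel matrix).
#' @return symmetric positive semidefinite L x L matrix.
#' @export
autocorrelation_matrix <- function(cube) {
  X <- if (inherits(cube, "spectral_cube")) cube_pixels(cube) else as.matrix(cube)
  if (nrow(X) < 1L) stop("empty cube", call. = FALSE)
  R <- crossprod(X) / nrow(X)
  (R + t(R)) / 2  # enforce exact symmetry against fp drift
}

#' Fit a constrained energy minimization (CEM) matched filter
#'
#' CEM finds the linear filter `w` minimizing the average output energy
#' `w' R w` over the image subject to a unit response on the target
#' signature, `d' w = 1`. The closed form is
#' `w = R^{-1} d / (d' R^{-1} d)`. A small ridge
#' `eps = ridge_scale * trace(R) / L` is added before the symmetric solve
#' so that low-rank scenes (few distinct spectra) remain invertible; the
#' applied `eps` is recorded on the fit. Applied to a pixel spectrum the
#' filter returns an abundance-like score that is exactly 1 on the target
#' signature itself.
#'
#' @param cube a [spectral_cube], or a precomputed L x L autocorrelation
#'   matrix from [autocorrelation_matrix].
#' @param target the target signature: a length-L numeric vector or an
#'   `endmember_spectrum`.
#' @param ridge `"auto"` (default, `1e-6 * trace(R)/L`) or a non-negative
#'   scalar added to the diagonal of `R`.
#' @return an object of class `cem`: list with `w` (filter weights),
#'   `R`, `ridge` (the scalar actually applied), `d`, `wavelengths`.
#' @examples
#' sc <- phantom_scene("embedded_target", depth_mm = 10, sigma = 0.002)
#' sim <- simulate_embedded_target(sc)
#' fit <- cem(sim$cube, sim$endmembers$lipid)
#' fit
#' sum(fit$d * coef(fit))  # unit target response
#' @export
cem <- function(cube, target, ridge = "auto") {
  d <- if (inherits(target, "endmember_spectrum")) target$reflectance
       else as.numeric(target)
  if (any(!is.finite(d)) || all(d == 0))
    stop("target signature must be finite and not all-zero", call. = FALSE)
  wavelengths <- NULL
  if (inherits(cube, "spectral_cube")) {
    if (length(d) != dim(cube$data)[3L])
      stop("target signature length (", length(d),
           ") does not match band count (", dim(cube$data)[3L], ")",
           call. = FALSE)
    wavelengths <- cube$wavelengths
    R <- autocorrelation_matrix(cube)
  } else {
    R <- as.matrix(cube)
    if (nrow(R) != ncol(R) || nrow(R) != length(d))
      stop("R must be L x L with L = length(d)", call. = FALSE)
  }
  L <- length(d)
  eps <- if (identical(ridge, "auto")) 1e-6 * sum(diag(R)) / L
         else as.numeric(ridge)
  if (eps < 0) stop("ridge must be >= 0", call. = FALSE)
  Rr <- R + diag(eps, L)
  Rinv_d <- tryCatch(solve(Rr, d),
                     error = function(e)
                       stop("autocorrelation matrix singular even after ",
                            "ridge ", format(eps), ": ", conditionMessage(e),
                            call. = FALSE))
  denom <- sum(d * Rinv_d)
  if (denom <= 0)
    stop("d' R^{-1} d = ", format(denom),
         " <= 0: matrix not positive definite at the target direction",
         call. = FALSE)
  structure(list(w = Rinv_d / denom, R = R, ridge = eps, d = d,
                 wavelengths = wavelengths),
            class = "cem")
}

#' @export
print.cem <- function(x, ...) {
  cat(sprintf("<cem> matched filter, %d bands, ridge = %.3g\n",
              length(x$w), x$ridge))
  cat(sprintf("  d'w = %.12f (unit target-response constraint)\n",
              sum(x$d * x$w)))
  invisible(x)
}

#' @export
coef.cem <- function(object, ...) object$w

#' @export
summary.cem <- function(object, ...) {
  ans <- list(L = length(object$w), ridge = object$ridge,
              constraint = sum(object$d * object$w),
              energy = drop(crossprod(object$w, object$R %*% object$w)))
  class(ans) <- "summary.cem"
  ans
}

#' @export
print.summary.cem <- function(x, ...) {
  cat("CEM matched filter\n")
  cat(sprintf("  bands             : %d\n", x$L))
  cat(sprintf("  ridge applied     : %.4g\n", x$ridge))
  cat(sprintf("  d'w constraint    : %.12f\n", x$constraint))
  cat(sprintf("  mean output energy: %.6g\n", x$energy))
  invisible(x)
}

#' Apply a CEM filter to a cube
#'
#' The per-pixel filter output `A = w' r` is linear in the pixel spectrum
#' and equals 1 wherever the spectrum equals the target signature.
#'
#' @param object a fitted [cem] filter.
#' @param newdata a [spectral_cube] with matching band count.
#' @param ... unused.
#' @return H x W numeric matrix of abundance scores (class
#'   `abundance_map`).
#' @export
predict.cem <- function(object, newdata, ...) {
  stopifnot(inherits(newdata, "spectral_cube"))
  if (dim(newdata$data)[3L] != length(object$w))
    stop("band count mismatch between filter and cube", call. = FALSE)
  d <- dim(newdata$data)
  scores <- cube_pixels(newdata) %*% object$w
  # row-major pixel order back to H x W
  out <- matrix(scores, d[1L], d[2L], byrow = TRUE)
  class(out) <- c("abundance_map", class(out))
  out
}

#' One-call CEM detection
#'
#' Fits the filter on the cube's own global statistics and evaluates it at
#' every pixel.
#'
#' @inheritParams cem
#' @return H x W abundance map matrix.
#' @export
cem_detect <- function(cube, target, ridge = "auto") {
  predict(cem(cube, target, ridge = ridge), cube)
}

#' Otsu threshold of an abundance map
#'
#' Min-max normalizes the map, histograms it into `bins` equal-width bins,
#' and picks the bin-edge threshold maximizing the between-class variance
#' `w0 * w1 * (mu0 - mu1)^2`; ties are broken toward the lower threshold.
#' The returned threshold is on the original value scale and the mask is
#' `values > threshold`.
#'
#' @param map numeric matrix (e.g. from [cem_detect]); must not be
#'   constant.
#' @param bins histogram bin count.
#' @return list with `threshold` (original scale) and `mask` (logical
#'   matrix).
#' @export
otsu_threshold <- function(map, bins = 256L) {
  v <- as.numeric(map)
  rng <- range(v)
  if (!all(is.finite(rng)) || rng[2L] <= rng[1L])
    stop("cannot threshold a constant map", call. = FALSE)
  u <- (v - rng[1L]) / (rng[2L] - rng[1L])
  # bin index 1..bins; u = 1 lands in the last bin
  idx <- pmin(floor(u * bins) + 1L, bins)
  counts <- tabulate(idx, nbins = bins)
  p <- counts / length(v)
  bin_mid <- (seq_len(bins) - 0.5) / bins
  w0 <- cumsum(p)                 # class {bins <= t}
  m0 <- cumsum(p * bin_mid)
  mu_total <- m0[bins]
  # candidate thresholds are the upper edges of bins 1..bins-1
  w0c <- w0[-bins]; m0c <- m0[-bins]
  w1c <- 1 - w0c
  valid <- w0c > 0 & w1c > 0
  bcv <- rep(-Inf, bins - 1L)
  bcv[valid] <- (mu_total * w0c[valid] - m0c[valid])^2 /
    (w0c[valid] * w1c[valid])
  if (!any(is.finite(bcv)))
    stop("cannot threshold a constant map", call. = FALSE)
  t_bin <- which.max(bcv)  # first maximum = lower threshold on ties
  thr_norm <- t_bin / bins
  threshold <- rng[1L] + thr_norm * (rng[2L] - rng[1L])
  list(threshold = threshold,
       mask = matrix(as.numeric(map) > threshold, nrow(map), ncol(map)))
}

#' Tanimoto (Jaccard) index of two binary masks
#'
#' `TI = |X intersect Y| / |X union Y|`: 1 means the detection and ground
#' truth coincide, 0 means they are disjoint. Undefined (an error) when
#' both masks are empty.
#'
#' @param X,Y logical matrices of identical dimensions.
#' @return scalar in \[0, 1\].
#' @export
tanimoto_index <- function(X, Y) {
  if (!identical(dim(X), dim(Y)))
    stop("masks have different dimensions", call. = FALSE)
  X <- as.logical(X); Y <- as.logical(Y)
  uni <- sum(X | Y)
  if (uni == 0L)
    stop("Tanimoto index undefined: both masks empty", call. = FALSE)
  sum(X & Y) / uni
}
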