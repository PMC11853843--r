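#' Build an endmember matrix
#'
#' Columns are the p pure-component spectra `m_1 ... m_p` of the linear
#' mixing model `r = M alpha + n`. Columns must be numerically linearly
#' independent.
#'
#' @param ... endmember spectra: `endmember_spectrum` objects and/or
#'   numeric vectors, all of one length L; alternatively a single L x p
#'   matrix.
#' @param names optional column labels.
#' @return an `endmember_matrix`: L x p numeric matrix with column names.
#' @export
endmember_matrix <- function(..., names = NULL) {
  args <- list(...)
  if (length(args) == 1L && is.matrix(args[[1L]])) {
    M <- args[[1L]]
    if (is.null(names)) names <- colnames(M)
  } else {
    cols <- lapply(args, function(a)
      if (inherits(a, "endmember_spectrum")) a$reflectance else as.numeric(a))
    if (length(unique(lengths(cols))) != 1L)
      stop("endmember spectra have differing lengths", call. = FALSE)
    M <- do.call(cbind, cols)
    if (is.null(names))
      names <- vapply(seq_along(args), function(i) {
        a <- args[[i]]
        if (inherits(a, "endmember_spectrum")) a$name else paste0("em", i)
      }, character(1))
  }
  if (ncol(M) < 2L) stop("need at least p = 2 endmembers", call. = FALSE)
  qrM <- qr(M)
  if (qrM$rank < ncol(M)) {
    dep <- setdiff(seq_len(ncol(M)), qrM$pivot[seq_len(qrM$rank)])
    stop("endmember columns linearly dependent (offending column(s): ",
         paste(dep, collapse = ", "), ")", call. = FALSE)
  }
  kap <- kappa(M, exact = FALSE)
  if (kap > 1e10)
    warning("endmember matrix badly conditioned (kappa ~ ",
            format(kap, digits = 3), ")", call. = FALSE)
  colnames(M) <- names
  class(M) <- c("endmember_matrix", class(M))
  M
}

# strip class for plain matrix algebra
em_mat <- function(M) {
  class(M) <- setdiff(class(M), "endmember_matrix")
  M
}

abundance_vec <- function(alpha, r, M, model) {
  list(alpha = as.numeric(alpha),
       residual = sum((r - em_mat(M) %*% alpha)^2),
       model = model)
}

#' Unconstrained least-squares unmixing of one pixel
#'
#' Minimizes `||r - M alpha||^2` with no constraints, via QR factorization
#' (numerically equal to the normal-equation solution
#' `(M'M)^{-1} M' r`).
#'
#' @param r length-L pixel spectrum.
#' @param M an [endmember_matrix] (L x p, full column rank).
#' @return list with `alpha` (length p), `residual` (`||r - M alpha||^2`),
#'   `model = "LS"`.
#' @export
ls_unmix <- function(r, M) {
  alpha <- qr.coef(qr(em_mat(M)), as.numeric(r))
  abundance_vec(alpha, r, M, "LS")
}

# Solve min ||r - M a||^2 s.t. sum(a) = 1 by the closed-form correction of
# the LS solution along the (M'M)^{-1} 1 direction.
scls_solve <- function(r, M) {
  G <- crossprod(M)
  cG <- chol(G)
  a_ls <- backsolve(cG, forwardsolve(t(cG), crossprod(M, as.numeric(r))))
  u <- backsolve(cG, forwardsolve(t(cG), rep(1, ncol(M))))  # (M'M)^{-1} 1
  drop(a_ls + u * (1 - sum(a_ls)) / sum(u))
}

#' Sum-to-one constrained least-squares unmixing of one pixel
#'
#' Minimizes `||r - M alpha||^2` subject to `sum(alpha) = 1`. The solution
#' is the unconstrained LS estimate plus a closed-form correction along
#' the `(M'M)^{-1} 1` direction that restores the abundance sum.
#'
#' @inheritParams ls_unmix
#' @return list with `alpha`, `residual`, `model = "SCLS"`.
#' @export
scls_unmix <- function(r, M) {
  abundance_vec(scls_solve(as.numeric(r), em_mat(M)), r, M, "SCLS")
}

#' Fully constrained least-squares unmixing of one pixel
#'
#' Minimizes `||r - M alpha||^2` over the probability simplex
#' (`alpha >= 0`, `sum(alpha) = 1`). Active-set iteration in the
#' Heinz-Chang style: start from the sum-to-one solution, clamp the most
#' negative coordinate to zero, re-solve the sum-to-one problem on the
#' surviving support, and repeat until all abundances are >= `-tol`;
#' clamped coordinates never re-enter, so the loop terminates in at most
#' p - 1 steps. Final magnitudes below `tol` are set to 0 and the vector
#' renormalized.
#'
#' @inheritParams ls_unmix
#' @param tol nonnegativity tolerance.
#' @param max_iter iteration cap (default `10 * p`).
#' @return list with `alpha` (on the simplex), `residual`,
#'   `model = "FCLS"`.
#' @export
fcls_unmix <- function(r, M, tol = 1e-9, max_iter = NULL) {
  M <- em_mat(M)
  r <- as.numeric(r)
  p <- ncol(M)
  if (is.null(max_iter)) max_iter <- 10L * p
  support <- seq_len(p)
  alpha <- scls_solve(r, M)
  iter <- 0L
  while (min(alpha) < -tol) {
    iter <- iter + 1L
    if (iter > max_iter)
      stop("FCLS active-set iteration did not converge within ", max_iter,
           " steps (last iterate: ",
           paste(format(alpha, digits = 6), collapse = ", "), ")",
           call. = FALSE)
    drop_local <- which.min(alpha)
    support <- support[-drop_local]
    if (length(support) == 1L) {
      alpha <- 1
      break
    }
    alpha <- scls_solve(r, M[, support, drop = FALSE])
  }
  full <- numeric(p)
  full[support] <- alpha
  full[abs(full) < tol] <- 0
  full <- pmax(full, 0)
  full <- full / sum(full)
  abundance_vec(full, r, structure(M, class = c("endmember_matrix",
                                                class(M))), "FCLS")
}

#' Mean spectra of image regions as endmembers
#'
#' Builds an endmember matrix from the mean spectrum of each selected
#' region of a cube; a single pixel is a one-pixel region. This is how the
#' experiment pipelines obtain in-scene endmembers (e.g. the 2% and 5%
#' panel means, or the shallowest and deepest wedge columns).
#'
#' @param cube a [spectral_cube].
#' @param regions list of region selectors, each a list with `rows` and
#'   `cols` (integer vectors).
#' @param names optional endmember labels.
#' @return an [endmember_matrix].
#' @export
select_endmembers_from_image <- function(cube, regions, names = NULL) {
  cols <- lapply(regions, function(rg) {
    if (length(rg$rows) == 0L || length(rg$cols) == 0L)
      stop("empty endmember region", call. = FALSE)
    if (any(rg$rows < 1L | rg$rows > dim(cube$data)[1L]) ||
        any(rg$cols < 1L | rg$cols > dim(cube$data)[2L]))
      stop("endmember region out of bounds", call. = FALSE)
    sub <- cube$data[rg$rows, rg$cols, , drop = FALSE]
    apply(sub, 3L, mean)
  })
  do.call(endmember_matrix, c(cols, list(names = names)))
}

#' Unmix every pixel of a cube
#'
#' Applies the chosen linear-unmixing model per pixel and returns a
#' classed fit holding one abundance plane per endmember. LS and SCLS are
#' solved in one vectorized pass; FCLS re-solves only the pixels whose
#' sum-to-one solution leaves the simplex.
#'
#' @param cube a [spectral_cube].
#' @param M an [endmember_matrix]; band counts must match.
#' @param model `"FCLS"` (default), `"SCLS"` or `"LS"`.
#' @param tol,max_iter passed to [fcls_unmix].
#' @return an object of class `unmix_fit`: list with `abundance`
#'   (H x W x p array), `endmembers`, `model`, `residual_map` (H x W),
#'   `n_nonconverged`.
#' @examples
#' sc <- phantom_scene("concentration_panels", nrow = 20, ncol = 40,
#'                     sigma = 0)
#' sim <- simulate_concentration_panels(sc)
#' M <- endmember_matrix(sim$endmembers[[1]], sim$endmembers[[2]])
#' fit <- unmix(sim$cube, M)
#' fit
#' @export
unmix <- function(cube, M, model = c("FCLS", "SCLS", "LS"),
                  tol = 1e-9, max_iter = NULL) {
  model <- match.arg(model)
  stopifnot(inherits(cube, "spectral_cube"))
  Mm <- em_mat(M)
  d <- dim(cube$data)
  if (nrow(Mm) != d[3L])
    stop("endmember band count (", nrow(Mm),
         ") does not match cube band count (", d[3L], ")", call. = FALSE)
  p <- ncol(Mm)
  X <- t(cube_pixels(cube))            # L x N
  N <- ncol(X)
  G <- crossprod(Mm)
  cG <- chol(G)
  A_ls <- backsolve(cG, forwardsolve(t(cG), crossprod(Mm, X)))  # p x N
  if (model == "LS") {
    A <- A_ls
  } else {
    u <- backsolve(cG, forwardsolve(t(cG), rep(1, p)))
    A <- A_ls + outer(u / sum(u), 1 - colSums(A_ls))
  }
  n_bad <- 0L
  if (model == "FCLS") {
    fix <- which(apply(A, 2L, min) < -tol)
    for (i in fix) {
      res <- tryCatch(fcls_unmix(X[, i], Mm, tol = tol, max_iter = max_iter),
                      error = function(e) NULL)
      if (is.null(res)) {
        n_bad <- n_bad + 1L
      } else {
        A[, i] <- res$alpha
      }
    }
    A[abs(A) < tol] <- 0
    A <- pmax(A, 0)
    A <- sweep(A, 2L, colSums(A), "/")
  }
  resid <- colSums((X - Mm %*% A)^2)
  # row-major pixel order back to images
  abund <- array(0, c(d[1L], d[2L], p),
                 dimnames = list(NULL, NULL, colnames(Mm)))
  for (k in seq_len(p))
    abund[, , k] <- matrix(A[k, ], d[1L], d[2L], byrow = TRUE)
  structure(list(abundance = abund, endmembers = M, model = model,
                 residual_map = matrix(resid, d[1L], d[2L], byrow = TRUE),
                 n_nonconverged = n_bad),
            class = "unmix_fit")
}

#' @export
print.unmix_fit <- function(x, ...) {
  d <- dim(x$abundance)
  cat(sprintf("<unmix_fit> %s, %d x %d pixels, %d endmembers (%s)\n",
              x$model, d[1L], d[2L], d[3L],
              paste(dimnames(x$abundance)[[3L]], collapse = ", ")))
  cat(sprintf("  mean residual ||r - M alpha||^2 = %.4g; %d pixel(s) failed\n",
              mean(x$residual_map), x$n_nonconverged))
  invisible(x)
}

#' @export
summary.unmix_fit <- function(object, ...) {
  p <- dim(object$abundance)[3L]
  tab <- t(vapply(seq_len(p), function(k) {
    a <- object$abundance[, , k]
    c(mean = mean(a), sd = stats::sd(a), min = min(a), max = max(a))
  }, numeric(4)))
  rownames(tab) <- dimnames(object$abundance)[[3L]]
  structure(list(model = object$model, table = tab,
                 mean_residual = mean(object$residual_map)),
            class = "summary.unmix_fit")
}

#' @export
print.summary.unmix_fit <- function(x, ...) {
  cat(sprintf("Linear unmixing fit (%s)\n", x$model))
  print(round(x$table, 4))
  cat(sprintf("mean residual: %.4g\n", x$mean_residual))
  invisible(x)
}

#' @export
coef.unmix_fit <- function(object, ...) object$abundance

#' @export
fitted.unmix_fit <- function(object, ...) {
  d <- dim(object$abundance)
  Mm <- em_mat(object$endmembers)
  A <- t(apply(object$abundance, 3L, function(x) as.numeric(t(x))))
  X <- Mm %*% A  # L x N, pixels row-major
  arr <- array(0, c(d[1L], d[2L], nrow(Mm)))
  for (b in seq_len(nrow(Mm)))
    arr[, , b] <- matrix(X[b, ], d[1L], d[2L], byrow = TRUE)
  arr
}

#' @export
residuals.unmix_fit <- function(object, ...) object$residual_map

#' @describeIn unmix Image the abundance plane of one endmember.
#' @param x an `unmix_fit`.
#' @param endmember plane index or name.
#' @param ... unused.
#' @export
plot.unmix_fit <- function(x, endmember = 1L, ...) {
  a <- x$abundance[, , endmember]
  graphics::image(t(a[nrow(a):1, ]), zlim = c(0, 1), useRaster = TRUE,
                  main = paste("abundance:",
                               dimnames(x$abundance)[[3L]][endmember]))
  invisible(x)
}
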