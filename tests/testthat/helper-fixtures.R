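# Shared fixture builders. Cubes destined for disk round-trips are pushed
# through float32 first, since that is the on-disk precision.

as_float32 <- function(x) {
  readBin(writeBin(as.numeric(x), raw(), size = 4L, endian = "little"),
          "numeric", n = length(x), size = 4L, endian = "little")
}

random_cube <- function(H, W, B, seed = 1, f32 = TRUE) {
  set.seed(seed)
  vals <- runif(H * W * B)
  if (f32) vals <- as_float32(vals)
  spectral_cube(array(vals, c(H, W, B)),
                seq(900, by = 5, length.out = B))
}

# cube from an explicit N-pixel spectrum list laid out 1 x N
pixel_cube <- function(spectra) {
  B <- length(spectra[[1L]])
  arr <- array(0, c(1L, length(spectra), B))
  for (j in seq_along(spectra)) arr[1L, j, ] <- spectra[[j]]
  spectral_cube(arr, seq(900, by = 5, length.out = B))
}

# random point on the p-simplex interior
random_simplex <- function(p) {
  x <- -log(runif(p))
  x / sum(x)
}

# Exhaustive simplex grid search minimizing ||r - M a||^2, via the
# quadratic form a'Ga - 2 b'a (constant dropped); step on the grid.
fcls_grid_oracle <- function(r, M, step = 1e-3) {
  p <- ncol(M)
  G <- crossprod(M)
  b <- drop(crossprod(M, r))
  g <- seq(0, 1, by = step)
  if (p == 2L) {
    A <- rbind(g, 1 - g)
  } else if (p == 3L) {
    a1 <- rep(g, each = length(g))
    a2 <- rep(g, times = length(g))
    keep <- a1 + a2 <= 1 + 1e-12
    A <- rbind(a1[keep], a2[keep], pmax(1 - a1[keep] - a2[keep], 0))
  } else stop("oracle supports p in {2,3}")
  obj <- colSums(A * (G %*% A)) - 2 * colSums(A * b)
  best <- which.min(obj)
  alpha <- A[, best]
  list(alpha = alpha, residual = sum((r - M %*% alpha)^2))
}

# Brute-force Otsu oracle: quantize to bin midpoints, then test every
# bin-edge threshold by direct class statistics over the data.
otsu_oracle <- function(v, bins = 256L) {
  v <- as.numeric(v)
  rng <- range(v)
  u <- (v - rng[1L]) / (rng[2L] - rng[1L])
  idx <- pmin(floor(u * bins) + 1L, bins)
  mids <- (idx - 0.5) / bins
  best <- -Inf; best_t <- NA_integer_
  for (t in seq_len(bins - 1L)) {
    lo <- idx <= t
    n0 <- sum(lo); n1 <- length(v) - n0
    if (n0 == 0L || n1 == 0L) next
    w0 <- n0 / length(v); w1 <- 1 - w0
    bcv <- w0 * w1 * (mean(mids[lo]) - mean(mids[!lo]))^2
    if (bcv > best + 1e-15) { best <- bcv; best_t <- t }
  }
  rng[1L] + (best_t / bins) * (rng[2L] - rng[1L])
}

# Lagrange-multiplier solve of min ||r - Ma||^2 s.t. 1'a = 1 (KKT system)
scls_kkt_oracle <- function(r, M) {
  p <- ncol(M)
  K <- rbind(cbind(2 * crossprod(M), rep(1, p)), c(rep(1, p), 0))
  rhs <- c(2 * drop(crossprod(M, r)), 1)
  unname(drop(solve(K, rhs))[seq_len(p)])
}
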