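# Shared numeric helpers: phase wrapping, spectral grids, DCT, stencils, masks.

#' Wrap phase to the principal interval
#'
#' Maps phase values onto the half-open interval (-pi, pi]. Wrapping is
#' idempotent: applying it to already-wrapped values changes nothing.
#'
#' @param x Numeric vector, matrix or array of phase values (radians).
#' @return Object of the same shape with all values in (-pi, pi].
#' @export
#' @examples
#' wrap_phase(c(0, pi, -pi, 3 * pi / 2))
wrap_phase <- function(x) {
  x - 2 * pi * ceiling((x - pi) / (2 * pi))
}

# Spatial frequencies (cycles per metre) for an n-sample axis with spacing h,
# in FFT (wrap-around) order.
fft_freq <- function(n, h) {
  k <- c(seq(0, floor((n - 1) / 2)), seq(-ceiling((n - 1) / 2), -1))
  k / (n * h)
}

fft2 <- function(x) stats::fft(x)
ifft2 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

# Orthonormal DCT-II matrix, cached per size. Used by the least-squares
# phase unwrapper (Neumann Poisson solve).
.dct_cache <- new.env(parent = emptyenv())
dct_matrix <- function(n) {
  key <- as.character(n)
  if (!is.null(.dct_cache[[key]])) return(.dct_cache[[key]])
  k <- seq_len(n) - 1
  m <- sqrt(2 / n) * cos(pi * outer(k, k + 0.5) / n)
  m[1, ] <- m[1, ] / sqrt(2)
  .dct_cache[[key]] <- m
  m
}

dct2 <- function(x) {
  dct_matrix(nrow(x)) %*% x %*% t(dct_matrix(ncol(x)))
}

idct2 <- function(x) {
  t(dct_matrix(nrow(x))) %*% x %*% dct_matrix(ncol(x))
}

# Discrete 5-point Laplacian with spacing h; border pixels return NA.
laplacian5 <- function(u, h) {
  nr <- nrow(u); nc <- ncol(u)
  out <- matrix(NA_complex_, nr, nc)
  i <- 2:(nr - 1); j <- 2:(nc - 1)
  out[i, j] <- (u[i - 1, j] + u[i + 1, j] + u[i, j - 1] + u[i, j + 1] -
                  4 * u[i, j]) / h^2
  out
}

#' Erode a binary mask
#'
#' Removes `steps` one-pixel layers from the boundary of a logical mask
#' (4-connected erosion), the standard guard against inversion stencil
#' artefacts at mask edges.
#'
#' @param mask Logical matrix.
#' @param steps Number of erosion passes (non-negative integer).
#' @return Logical matrix of the same dimension.
#' @export
erode_mask <- function(mask, steps = 1) {
  stopifnot(is.matrix(mask), steps >= 0)
  m <- mask
  storage.mode(m) <- "logical"
  if (steps == 0) return(m)
  nr <- nrow(m); nc <- ncol(m)
  for (s in seq_len(steps)) {
    padded <- matrix(FALSE, nr + 2, nc + 2)
    padded[2:(nr + 1), 2:(nc + 1)] <- m
    i <- 2:(nr + 1); j <- 2:(nc + 1)
    m <- padded[i, j] & padded[i - 1, j] & padded[i + 1, j] &
      padded[i, j - 1] & padded[i, j + 1]
  }
  m
}

# Unit propagation direction in (row, col) index space. Row 1 is the top of
# the field of view, so "bottom_to_top" means decreasing row index.
direction_vector <- function(direction) {
  switch(direction,
    bottom_to_top = c(-1, 0),
    top_to_bottom = c(1, 0),
    left_to_right = c(0, 1),
    right_to_left = c(0, -1),
    stop("unknown direction: ", direction)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Apply a k-space gain to a complex image, optionally on an even-reflected
# (doubled) domain so the periodic FFT boundary does not introduce a jump.
# gain_fn(kr, kc) receives the axis frequencies (cycles/m) and returns the
# gain matrix.
apply_kspace_gain <- function(data, h, gain_fn, pad = TRUE) {
  n1 <- nrow(data); n2 <- ncol(data)
  if (pad) {
    data <- rbind(cbind(data, data[, n2:1]),
                  cbind(data[n1:1, ], data[n1:1, n2:1]))
  }
  kr <- fft_freq(nrow(data), h)
  kc <- fft_freq(ncol(data), h)
  out <- ifft2(fft2(data) * gain_fn(kr, kc))
  if (pad) out <- out[seq_len(n1), seq_len(n2)]
  out
}
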