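# Shared fixtures built in code: small acquisition geometries, exact-grid
# plane waves, and independent brute-force oracles.

FOV <- 0.025
MAT <- 128
PIX <- FOV / MAT

# Complex plane wave exp(2i*pi*cycles*index/n) along rows or columns of an
# n x n matrix; exactly periodic when `cycles` is an integer.
grid_plane_wave <- function(n, cycles, axis = c("row", "col"),
                            sign = 1) {
  axis <- match.arg(axis)
  idx <- matrix(0:(n - 1), n, n, byrow = (axis == "col"))
  exp(sign * 2i * pi * cycles * idx / n)
}

# Minimal elastogram object for summary-level tests.
fake_elastogram <- function(gstar, valid = NULL, density = 1000,
                            frequency = 900, pixel_spacing = PIX) {
  structure(
    list(gstar = gstar, valid = valid %||% matrix(TRUE, nrow(gstar),
                                                  ncol(gstar)),
         density = density, drive_frequency = frequency,
         pixel_spacing = pixel_spacing, provenance = "fixture"),
    class = "elastogram")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent Spearman oracle: explicit loop over utils-generated
# permutations, statistic recomputed with stats::cor on ranks each time.
all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_permutations(n - 1)) {
    for (k in seq_len(n)) {
      out[[length(out) + 1]] <- append(p, n, after = k - 1)
    }
  }
  out
}

spearman_oracle_p <- function(x, y, perms = NULL) {
  xr <- rank(x); yr <- rank(y)
  obs <- stats::cor(xr, yr)
  perms <- perms %||% all_permutations(length(y))
  rhos <- vapply(perms, function(p) stats::cor(xr, yr[p]), numeric(1))
  mean(abs(rhos) >= abs(obs) - 1e-12)
}

# Cramer-Rao bound on the T1 estimate for the 2-parameter saturation
# recovery model at Gaussian noise sd `sigma`.
t1_crlb_sd <- function(t1, s0, tr, sigma) {
  J <- cbind(1 - exp(-tr / t1), -s0 * exp(-tr / t1) * tr / t1^2)
  sqrt(solve(t(J) %*% J * (1 / sigma^2))[2, 2])
}
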