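# Phase-image series: the raw unit of an MRE acquisition. A series holds one
# wrapped (or unwrapped) phase image per temporal offset within the vibration
# period, together with the sign of the motion-sensitizing gradient (MSG),
# the mechanical drive frequency and the pixel spacing.

#' Construct a phase-image series
#'
#' @param data Numeric 3D array (row, col, temporal offset) of phase values
#'   in radians.
#' @param msg_sign Sign of the motion-sensitizing gradient, `+1` or `-1`.
#' @param drive_frequency Mechanical vibration frequency in Hz.
#' @param pixel_spacing In-plane pixel size in metres.
#' @param wrapped Logical; whether values are wrapped to (-pi, pi].
#' @return An object of class `phase_series`.
#' @export
phase_series <- function(data, msg_sign, drive_frequency, pixel_spacing,
                         wrapped = TRUE) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  if (!msg_sign %in% c(-1, 1)) stop("msg_sign must be +1 or -1")
  if (drive_frequency <= 0) stop("drive_frequency must be positive")
  if (pixel_spacing <= 0) stop("pixel_spacing must be positive")
  if (dim(data)[3] < 4) stop("n_dynamics must be at least 4")
  if (wrapped && (max(data) > pi + 1e-9 || min(data) <= -pi - 1e-9))
    stop("series flagged wrapped but values fall outside (-pi, pi]")
  structure(
    list(data = data, msg_sign = msg_sign,
         drive_frequency = drive_frequency,
         pixel_spacing = pixel_spacing, wrapped = wrapped),
    class = "phase_series"
  )
}

#' @export
print.phase_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "MRE phase series: %d x %d pixels, %d temporal offsets, MSG sign %+d\n",
    d[1], d[2], d[3], x$msg_sign))
  cat(sprintf("  drive %.0f Hz, pixel %.3g mm, %s\n",
              x$drive_frequency, 1e3 * x$pixel_spacing,
              if (x$wrapped) "wrapped" else "unwrapped"))
  invisible(x)
}

n_dynamics <- function(series) dim(series$data)[3]

#' Phase-difference images from sign-alternated acquisitions
#'
#' Subtracts the negative-MSG series from the positive-MSG series and rewraps
#' to (-pi, pi]. Static phase contributions (receiver phase, B0-related
#' background) are identical in both acquisitions and cancel exactly, while
#' the motion-encoded phase doubles.
#'
#' @param pos,neg `phase_series` objects with opposite `msg_sign` and
#'   identical geometry, temporal sampling and drive frequency.
#' @return A wrapped `phase_series` with `msg_sign = +1` holding the doubled
#'   motion-encoded phase.
#' @export
phase_difference <- function(pos, neg) {
  stopifnot(inherits(pos, "phase_series"), inherits(neg, "phase_series"))
  if (!identical(dim(pos$data), dim(neg$data)))
    stop("phase_difference: series shapes differ: ",
         paste(dim(pos$data), collapse = "x"), " vs ",
         paste(dim(neg$data), collapse = "x"))
  if (pos$drive_frequency != neg$drive_frequency)
    stop("phase_difference: drive frequencies differ")
  if (pos$pixel_spacing != neg$pixel_spacing)
    stop("phase_difference: pixel spacings differ")
  if (pos$msg_sign * neg$msg_sign != -1)
    stop("phase_difference: MSG signs must be opposite")
  phase_series(wrap_phase(pos$data - neg$data), msg_sign = 1,
               drive_frequency = pos$drive_frequency,
               pixel_spacing = pos$pixel_spacing, wrapped = TRUE)
}

#' Spatial 2D phase unwrapping
#'
#' Unwraps each temporal frame with the unweighted least-squares (DCT-based
#' Poisson) method: wrapped first differences define a discrete Laplacian,
#' the Neumann Poisson equation is solved exactly in the DCT-II basis, and
#' the smooth solution is then rounded back onto the lattice
#' `wrapped + 2*pi*k` (congruence step). For residue-free fields the result
#' equals the true phase up to one global integer multiple of 2*pi per frame;
#' that offset lands in the DC bin of the later temporal Fourier transform
#' and is discarded there.
#'
#' @param series A wrapped `phase_series`. An already-unwrapped series is
#'   returned unchanged (unwrapping is idempotent).
#' @return An unwrapped `phase_series`.
#' @export
unwrap_phase <- function(series) {
  stopifnot(inherits(series, "phase_series"))
  if (!series$wrapped) return(series)
  out <- series$data
  for (t in seq_len(dim(out)[3])) out[, , t] <- unwrap2d(out[, , t])
  series$data <- out
  series$wrapped <- FALSE
  series
}

# Least-squares unwrap of a single wrapped frame.
unwrap2d <- function(psi) {
  nr <- nrow(psi); nc <- ncol(psi)
  dx <- matrix(0, nr, nc)  # column-direction wrapped differences
  dy <- matrix(0, nr, nc)  # row-direction wrapped differences
  if (nc > 1) dx[, 1:(nc - 1)] <- wrap_phase(psi[, 2:nc] - psi[, 1:(nc - 1)])
  if (nr > 1) dy[1:(nr - 1), ] <- wrap_phase(psi[2:nr, ] - psi[1:(nr - 1), ])
  rho <- dx + dy
  rho[, 2:nc] <- rho[, 2:nc] - dx[, 1:(nc - 1)]
  rho[2:nr, ] <- rho[2:nr, ] - dy[1:(nr - 1), ]
  rhat <- dct2(rho)
  denom <- outer(2 * cos(pi * (seq_len(nr) - 1) / nr),
                 2 * cos(pi * (seq_len(nc) - 1) / nc), `+`) - 4
  denom[1, 1] <- 1
  rhat <- rhat / denom
  rhat[1, 1] <- 0
  phi <- idct2(rhat)
  # Congruence: estimate the constant (mod 2*pi) between the smooth solution
  # and the wrapped input, then snap to the nearest 2*pi-shifted copy.
  r <- phi - psi
  c0 <- Arg(mean(exp(1i * r)))
  psi + 2 * pi * round((r - c0) / (2 * pi))
}
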