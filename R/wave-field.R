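# Complex harmonic wave fields and the spectral filters applied to them.
# A wave field is the first temporal harmonic of the unwrapped
# phase-difference series: a complex image proportional to the harmonic
# tissue displacement at the drive frequency.

#' Construct a complex wave field
#'
#' @param data Complex matrix (row, col).
#' @param drive_frequency Drive frequency in Hz.
#' @param pixel_spacing Pixel size in metres.
#' @param provenance Character vector of processing steps already applied
#'   (append-only).
#' @return An object of class `wave_field`.
#' @export
wave_field <- function(data, drive_frequency, pixel_spacing,
                       provenance = character()) {
  stopifnot(is.matrix(data))
  if (!all(is.finite(Re(data)) & is.finite(Im(data))))
    stop("wave field must be finite everywhere")
  structure(
    list(data = as.matrix(data) + 0i, drive_frequency = drive_frequency,
         pixel_spacing = pixel_spacing, provenance = provenance),
    class = "wave_field"
  )
}

#' @export
print.wave_field <- function(x, ...) {
  cat(sprintf("Complex wave field: %d x %d, drive %.0f Hz, pixel %.3g mm\n",
              nrow(x$data), ncol(x$data), x$drive_frequency,
              1e3 * x$pixel_spacing))
  cat("  provenance:", paste(x$provenance, collapse = " -> "), "\n")
  invisible(x)
}

#' Extract the first temporal harmonic
#'
#' Per pixel, computes the first-harmonic coefficient of the temporal DFT
#' over the vibration period, normalised by 2/n so that a time course
#' `A*cos(w*t + theta)` maps to the complex number `A*exp(1i*theta)`. The DC
#' component (including any global 2*pi unwrapping offset) lands in bin 0 and
#' is discarded.
#'
#' @param series An unwrapped `phase_series` sampled uniformly over exactly
#'   one vibration period (a wrapped series is unwrapped first).
#' @return A `wave_field` at the drive frequency.
#' @export
temporal_harmonic <- function(series) {
  stopifnot(inherits(series, "phase_series"))
  if (series$wrapped) series <- unwrap_phase(series)
  n <- n_dynamics(series)
  if (n < 4) stop("temporal_harmonic: need at least 4 temporal offsets")
  w <- exp(-2i * pi * (seq_len(n) - 1) / n)
  d <- dim(series$data)
  u <- matrix(0i, d[1], d[2])
  for (t in seq_len(n)) u <- u + series$data[, , t] * w[t]
  wave_field(2 * u / n, series$drive_frequency, series$pixel_spacing,
             provenance = "temporal_harmonic")
}

#' Radial Butterworth band-pass filter
#'
#' Multiplies the 2D spatial spectrum by
#' `H(k) = [1 - 1/(1 + (k/k_low)^(2*order))] * [1/(1 + (k/k_high)^(2*order))]`
#' on the radial spatial frequency `k` (cycles per metre). Setting
#' `k_low = 0` disables the high-pass factor.
#'
#' Filtering is carried out on an even-reflected (doubled) domain by default,
#' so the wrap-around jump of the periodic FFT does not ring into the image
#' (`pad = FALSE` filters the raw periodic domain).
#'
#' @param field A `wave_field`.
#' @param k_low,k_high Low and high cut-off spatial frequencies in 1/m;
#'   `0 <= k_low < k_high`.
#' @param order Filter order (>= 1).
#' @param pad Logical; filter on the even-reflected domain.
#' @return The filtered `wave_field`.
#' @export
butterworth_bandpass <- function(field, k_low = 20, k_high = 2000,
                                 order = 3, pad = TRUE) {
  stopifnot(inherits(field, "wave_field"))
  if (!(k_low >= 0 && k_low < k_high)) stop("need 0 <= k_low < k_high")
  if (order < 1) stop("order must be >= 1")
  gain_fn <- function(kr, kc) {
    k <- sqrt(outer(kr^2, kc^2, `+`))
    gain <- 1 / (1 + (k / k_high)^(2 * order))
    if (k_low > 0) gain <- gain * (1 - 1 / (1 + (k / k_low)^(2 * order)))
    gain
  }
  field$data <- apply_kspace_gain(field$data, field$pixel_spacing, gain_fn,
                                  pad = pad)
  field$provenance <- c(field$provenance,
                        sprintf("butterworth_bandpass(%g,%g,order=%d)",
                                k_low, k_high, order))
  field
}

#' Directional wave filter
#'
#' Retains the half-plane of the 2D spatial spectrum corresponding to waves
#' propagating in the requested direction and suppresses the
#' counter-propagating half-plane, with a raised-cosine transition of width
#' `taper_width` across the dividing line. Applied to the complex harmonic
#' field this is equivalent to a spatiotemporal (k-t) filter restricted to
#' the drive frequency, and is the standard remedy against reflected-wave
#' contamination of the inversion.
#'
#' Image row 1 is the top of the field of view, so `"bottom_to_top"` means
#' wave propagation towards decreasing row index. With the temporal-harmonic
#' convention used here (`A*cos(w*t + theta) -> A*exp(1i*theta)`), a wave
#' travelling along unit vector `d` occupies spatial frequencies `xi` with
#' `xi . d < 0`; that half-plane is the one retained.
#'
#' @param field A `wave_field`.
#' Unlike the band-pass, this filter acts on the raw periodic FFT domain
#' (`pad = FALSE`): an even-reflected extension would place a mirror image of
#' the wave - a counter-propagating copy - inside the analysis domain, and
#' removing it breaks the exact pass-through of travelling waves. On the
#' periodic domain a plane wave at a grid frequency passes (or is rejected)
#' exactly. The cost is that a strongly damped one-sided wave, whose envelope
#' has genuine spectral mass in the opposing half-plane, is perturbed near
#' the driver edge; see the package vignette for when to engage this filter.
#'
#' @param field A `wave_field`.
#' @param direction One of `"bottom_to_top"`, `"top_to_bottom"`,
#'   `"left_to_right"`, `"right_to_left"`.
#' @param taper_width Width of the raised-cosine transition band in 1/m.
#' @param pad Logical; filter on the even-reflected domain (see above).
#' @return The filtered `wave_field`.
#' @export
directional_filter <- function(field, direction = "bottom_to_top",
                               taper_width = 100, pad = FALSE) {
  stopifnot(inherits(field, "wave_field"), taper_width >= 0)
  d <- direction_vector(direction)
  gain_fn <- function(kr, kc) {
    p <- outer(kr * d[1], kc * d[2], `+`)  # xi . d  (cycles/m)
    if (taper_width > 0) {
      gain <- 0.5 * (1 - sin(pi * p / taper_width))
      gain[p <= -taper_width / 2] <- 1
      gain[p >= taper_width / 2] <- 0
    } else {
      gain <- ifelse(p < 0, 1, ifelse(p > 0, 0, 0.5))
    }
    gain
  }
  field$data <- apply_kspace_gain(field$data, field$pixel_spacing, gain_fn,
                                  pad = pad)
  field$provenance <- c(field$provenance,
                        sprintf("directional_filter(%s,taper=%g)",
                                direction, taper_width))
  field
}
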