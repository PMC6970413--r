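# Forward simulation of every input the reconstruction consumes, with ground
# truth attached. The wave model is plane-wave superposition in a locally
# homogeneous viscoelastic medium: u(x, t) = Re[A exp(i(w t - kappa s))] with
# complex wavenumber kappa = w * sqrt(rho / G*) (principal branch, so
# Im(kappa) <= 0 and a lossy medium attenuates along propagation), plus an
# optional counter-propagating reflection. Displacement is encoded into MR
# phase with opposite sign for the two MSG polarities, a static smooth
# background phase is added to both, the result is wrapped to (-pi, pi] and
# Gaussian phase noise applied.

#' Configuration for the MRE wave simulator
#'
#' Defaults mirror the acquisition this package targets: 900 Hz drive, eight
#' temporal offsets per vibration period, a 128-pixel matrix over a 25 mm
#' field of view, and soft-tissue density 1000 kg/m^3. The encoding gain
#' (radians of phase per unit displacement amplitude) defaults to 2 so the
#' peak phase-difference amplitude (~4 rad) exercises wrapping; the inversion
#' is invariant to this scale.
#'
#' @param true_modulus_map Complex shear modulus G* in Pa: a scalar for a
#'   homogeneous medium or a matrix (`matrix_size` x `matrix_size`). Requires
#'   `Re(G*) > 0` and `Im(G*) >= 0` everywhere.
#' @param density Tissue density in kg/m^3.
#' @param frequency Vibration frequency in Hz.
#' @param matrix_size Image matrix size in pixels (>= 16).
#' @param fov Field of view in metres.
#' @param n_dynamics Temporal offsets per vibration period (>= 4).
#' @param reflection_coefficient Relative amplitude of the counter-propagating
#'   wave, in [0, 1].
#' @param noise_sd Gaussian phase noise standard deviation (radians).
#' @param encoding_gain Radians of phase per unit displacement amplitude.
#' @param background Logical; add a static low-order polynomial background
#'   phase (identical in both MSG polarities, cancelled by the
#'   phase-difference step).
#' @param seed RNG seed; all randomness flows from it.
#' @return A `wave_sim_config` list.
#' @export
wave_sim_config <- function(true_modulus_map = 3000 + 0i, density = 1000,
                            frequency = 900, matrix_size = 128, fov = 0.025,
                            n_dynamics = 8, reflection_coefficient = 0,
                            noise_sd = 0, encoding_gain = 2,
                            background = TRUE, seed = 1) {
  if (matrix_size < 16) stop("matrix_size must be >= 16")
  if (frequency <= 0) stop("frequency must be positive")
  if (density <= 0) stop("density must be positive")
  if (n_dynamics < 4) stop("n_dynamics must be >= 4")
  if (fov <= 0) stop("fov must be positive")
  if (reflection_coefficient < 0 || reflection_coefficient > 1)
    stop("reflection_coefficient must lie in [0, 1]")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  g <- true_modulus_map + 0i
  if (length(g) == 1) {
    g <- matrix(g, matrix_size, matrix_size)
  } else if (!identical(dim(g), c(matrix_size, matrix_size))) {
    stop("true_modulus_map must be scalar or matrix_size x matrix_size")
  }
  if (any(Re(g) <= 0) || any(Im(g) < 0))
    stop("need Re(G*) > 0 and Im(G*) >= 0 everywhere")
  structure(
    list(true_modulus_map = g, density = density, frequency = frequency,
         matrix_size = matrix_size, fov = fov, n_dynamics = n_dynamics,
         reflection_coefficient = reflection_coefficient, noise_sd = noise_sd,
         encoding_gain = encoding_gain, background = background, seed = seed),
    class = "wave_sim_config"
  )
}

# Complex wavenumber field (rad/m) for a modulus map; principal branch gives
# Im(kappa) <= 0 so exp(-1i * kappa * s) decays with propagation distance s.
complex_wavenumber <- function(g, density, frequency) {
  2 * pi * frequency * sqrt(density / g)
}

# Distance from the source edge (metres) per pixel.
source_distance <- function(n, h, source_edge) {
  idx <- seq_len(n) - 1
  along <- switch(source_edge,
    bottom = rev(idx), top = idx, left = idx, right = rev(idx),
    stop("unknown source_edge: ", source_edge))
  if (source_edge %in% c("bottom", "top")) {
    matrix(along * h, n, n, byrow = FALSE)
  } else {
    matrix(along * h, n, n, byrow = TRUE)
  }
}

source_direction <- function(source_edge) {
  switch(source_edge,
    bottom = "bottom_to_top", top = "top_to_bottom",
    left = "left_to_right", right = "right_to_left")
}

# Noise-free complex displacement amplitude field U(x) such that
# u(x, t) = Re[U(x) exp(1i w t)]; includes the reflected component.
simulated_displacement <- function(config, source_edge) {
  n <- config$matrix_size
  h <- config$fov / n
  kappa <- complex_wavenumber(config$true_modulus_map, config$density,
                              config$frequency)
  lambda_min <- 2 * pi / max(Re(kappa))
  if (lambda_min < 4 * h)
    stop(sprintf(
      "aliased simulation: wavelength %.3g mm < 4 pixels at the stiffest region",
      1e3 * lambda_min))
  s <- source_distance(n, h, source_edge)
  len <- (n - 1) * h
  u <- exp(-1i * kappa * s)
  if (config$reflection_coefficient > 0)
    u <- u + config$reflection_coefficient * exp(-1i * kappa * (len - s))
  u
}

static_background <- function(n, scale = 0.5) {
  x <- matrix(seq(-1, 1, length.out = n), n, n, byrow = TRUE)
  y <- matrix(seq(-1, 1, length.out = n), n, n, byrow = FALSE)
  co <- stats::rnorm(6, sd = scale)
  co[1] + co[2] * x + co[3] * y + co[4] * x * y + co[5] * x^2 + co[6] * y^2
}

#' Simulate a matched pair of sign-alternated MRE phase-image series
#'
#' @param config A `wave_sim_config`.
#' @param source_edge Edge the shear wave enters from: `"bottom"`, `"top"`,
#'   `"left"` or `"right"`.
#' @return A list with elements `pos` and `neg` (`phase_series` objects with
#'   opposite MSG sign), `truth` (list with `modulus_map` and
#'   `regional_means`), and `clean_field` (the noise-free forward-propagating
#'   complex displacement, useful as an oracle in filter tests).
#' @export
simulate_wave_series <- function(config, source_edge = "bottom") {
  stopifnot(inherits(config, "wave_sim_config"))
  set.seed(config$seed)
  n <- config$matrix_size
  h <- config$fov / n
  u <- simulated_displacement(config, source_edge)
  refl <- config$reflection_coefficient
  config0 <- config
  config0$reflection_coefficient <- 0
  u_fwd <- simulated_displacement(config0, source_edge)
  bg <- if (config$background) static_background(n) else matrix(0, n, n)
  nd <- config$n_dynamics
  make_series <- function(sign) {
    dat <- array(0, dim = c(n, n, nd))
    for (t in seq_len(nd)) {
      ut <- Re(u * exp(1i * 2 * pi * (t - 1) / nd))
      ph <- sign * config$encoding_gain * ut + bg
      if (config$noise_sd > 0)
        ph <- ph + stats::rnorm(n * n, sd = config$noise_sd)
      dat[, , t] <- wrap_phase(ph)
    }
    phase_series(dat, msg_sign = sign, drive_frequency = config$frequency,
                 pixel_spacing = h, wrapped = TRUE)
  }
  pos <- make_series(1)
  neg <- make_series(-1)
  truth <- list(
    modulus_map = config$true_modulus_map,
    regional_means = list(whole = mean(config$true_modulus_map))
  )
  list(pos = pos, neg = neg, truth = truth, clean_field = u_fwd,
       source_edge = source_edge,
       direction = source_direction(source_edge))
}

#' Simulate a two-region stiffness phantom
#'
#' Builds a piecewise-constant modulus map split at a column index (anterior
#' region = columns up to `junction`, posterior = the rest) and simulates the
#' matched sign-alternated series. Waves are computed per pixel from the
#' local modulus; displacement/stress continuity is not enforced across the
#' interface, which is why recovery tests exclude a boundary band.
#'
#' @param anterior_modulus,posterior_modulus Complex moduli in Pa.
#' @param config A `wave_sim_config`; its `true_modulus_map` is replaced.
#' @param junction Column index of the last anterior column (defaults to the
#'   midline).
#' @param source_edge Source edge, as in [simulate_wave_series()]. The
#'   default `"bottom"` propagates waves parallel to the interface so each
#'   column remains homogeneous along the propagation path.
#' @return As [simulate_wave_series()], with `truth$regional_means` holding
#'   the two constants and `truth$masks` the anterior/posterior masks.
#' @export
simulate_two_region_phantom <- function(anterior_modulus, posterior_modulus,
                                        config, junction = NULL,
                                        source_edge = "bottom") {
  stopifnot(inherits(config, "wave_sim_config"))
  n <- config$matrix_size
  junction <- junction %||% (n %/% 2)
  if (junction < 1 || junction >= n) stop("junction outside matrix")
  g <- matrix(posterior_modulus + 0i, n, n)
  g[, seq_len(junction)] <- anterior_modulus + 0i
  config$true_modulus_map <- g
  out <- simulate_wave_series(config, source_edge)
  anterior <- matrix(FALSE, n, n); anterior[, seq_len(junction)] <- TRUE
  out$truth$regional_means <- list(
    whole = mean(g),
    anterior = anterior_modulus + 0i,
    posterior = posterior_modulus + 0i)
  out$truth$masks <- list(anterior = anterior, posterior = !anterior)
  out$truth$junction <- junction
  out
}

#' Simulate a variable-TR saturation-recovery series
#'
#' Noise-free signal follows `S(TR) = S0 * (1 - exp(-TR / T1))` exactly.
#'
#' @param t1_map Matrix of T1 values (ms), all positive.
#' @param s0_map Matrix of equilibrium signals (same shape), or scalar.
#' @param tr_list Strictly increasing vector of repetition times (ms).
#' @param noise_sd Gaussian signal noise SD.
#' @param seed RNG seed.
#' @return A `t1_series` list with `data` (row, col, tr index) and `tr_list`.
#' @export
simulate_t1_series <- function(t1_map, s0_map, tr_list, noise_sd = 0,
                               seed = 1) {
  t1_map <- as.matrix(t1_map)
  if (length(s0_map) == 1)
    s0_map <- matrix(s0_map, nrow(t1_map), ncol(t1_map))
  s0_map <- as.matrix(s0_map)
  stopifnot(identical(dim(t1_map), dim(s0_map)))
  if (any(t1_map <= 0)) stop("all T1 values must be positive")
  if (is.unsorted(tr_list, strictly = TRUE))
    stop("tr_list must be strictly increasing")
  set.seed(seed)
  d <- c(dim(t1_map), length(tr_list))
  dat <- array(0, dim = d)
  for (k in seq_along(tr_list)) {
    s <- s0_map * (1 - exp(-tr_list[k] / t1_map))
    if (noise_sd > 0) s <- s + stats::rnorm(length(s), sd = noise_sd)
    dat[, , k] <- s
  }
  structure(list(data = dat, tr_list = tr_list), class = "t1_series")
}

#' Simulate a cohort table with a known score-stiffness dependence
#'
#' Per-animal records emulating the statistical structure of an EAE
#' (experimental autoimmune encephalomyelitis) imaging cohort: diseased
#' animals carry a clinical disability score on the 0-5 scale in 0.5 steps
#' and a whole-brain magnitude modulus drawn as
#' `baseline + stiffness_slope * score + N(0, noise_sd)`; controls have score
#' 0 and baseline stiffness. Regional rows (anterior cerebrum / posterior
#' cerebellum) use a softer posterior baseline and a stronger posterior
#' disease effect, matching the regional vulnerability the model shows.
#' A fibronectin fold-change column increases as the (posterior) modulus
#' falls; delta-T1 and SI% columns are drawn independently of score,
#' emulating contrast-enhancement metrics that need not track disability.
#'
#' @param n_eae,n_control Group sizes (each >= 3 for EAE; >= 1 control).
#' @param score_range Range of symptomatic scores (drawn on the 0.5-step
#'   grid within this range).
#' @param stiffness_slope Change of |G*| per score unit, Pa (negative to
#'   emulate softening with disability).
#' @param noise_sd SD of the stiffness noise, Pa.
#' @param seed RNG seed.
#' @param baseline_gstar Whole-brain control |G*| in Pa.
#' @return A data frame with one row per animal x region: `animal_id`,
#'   `group`, `score`, `region`, `gstar_abs`, `gstar_real`, `gstar_imag`,
#'   `phi`, `delta_t1`, `si_pct`, `fn_fold`.
#' @export
simulate_cohort <- function(n_eae = 15, n_control = 7,
                            score_range = c(0.5, 3.5),
                            stiffness_slope = -300, noise_sd = 150,
                            seed = 1, baseline_gstar = 3500) {
  if (n_eae < 3 || n_control < 1) stop("need n_eae >= 3 and n_control >= 1")
  if (stiffness_slope >= 0)
    warning("stiffness_slope >= 0 does not emulate disease-related softening")
  set.seed(seed)
  grid <- seq(0.5, 5, by = 0.5)
  grid <- grid[grid >= score_range[1] & grid <= score_range[2]]
  scores <- c(sample(grid, n_eae, replace = TRUE), rep(0, n_control))
  group <- c(rep("EAE", n_eae), rep("control", n_control))
  n <- n_eae + n_control
  regions <- c(whole = 1, anterior = 1.05, posterior = 0.85)
  effect <- c(whole = 1, anterior = 0.7, posterior = 1.3)
  rows <- list()
  post_baseline <- baseline_gstar * regions[["posterior"]]
  for (rg in names(regions)) {
    base <- baseline_gstar * regions[[rg]]
    gabs <- base + effect[[rg]] * stiffness_slope * scores +
      stats::rnorm(n, sd = noise_sd)
    gabs <- pmax(gabs, 200)
    phi <- stats::rnorm(n, mean = 0.32, sd = 0.02)
    rows[[rg]] <- data.frame(
      animal_id = sprintf("m%02d", seq_len(n)), group = group,
      score = scores, region = rg, gstar_abs = gabs,
      gstar_real = gabs * cos(phi), gstar_imag = gabs * sin(phi),
      phi = phi, stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  # Per-animal covariates, constant across regions.
  dt1 <- ifelse(group == "EAE", stats::rnorm(n, 300, 80),
                stats::rnorm(n, 100, 40))
  sip <- ifelse(group == "EAE", stats::rnorm(n, 15, 5),
                stats::rnorm(n, 5, 2))
  gpost <- tab$gstar_abs[tab$region == "posterior"]
  fn <- exp((post_baseline - gpost) / 400 + stats::rnorm(n, sd = 0.15))
  idx <- match(tab$animal_id, sprintf("m%02d", seq_len(n)))
  tab$delta_t1 <- dt1[idx]
  tab$si_pct <- sip[idx]
  tab$fn_fold <- fn[idx]
  tab
}
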