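test_that("phase difference cancels static phase and doubles motion", {
  n <- 16; nd <- 8
  motion <- array(0, c(n, n, nd))
  for (t in 1:nd) motion[, , t] <- 0.3 * cos(2 * pi * (t - 1) / nd)
  bg <- array(rep(outer(seq(-1, 1, length.out = n)^2,
                        seq(-1, 1, length.out = n)), nd), c(n, n, nd))
  mk <- function(dat, s) phase_series(wrap_phase(dat), s, 900, PIX)
  pos <- mk(motion + bg, 1)
  neg <- mk(-motion + bg, -1)
  d <- phase_difference(pos, neg)
  expect_equal(d$data, wrap_phase(2 * motion), tolerance = 1e-12)
  # pure static phase: all-zero output
  z <- phase_difference(mk(bg, 1), mk(bg, -1))
  expect_true(all(abs(z$data) < 1e-12))
  # mismatches are hard errors
  expect_error(phase_difference(pos, mk(-motion + bg, 1)), "MSG")
  small <- phase_series(array(0, c(8, 8, nd)), -1, 900, PIX)
  expect_error(phase_difference(pos, small), "shape")
})

test_that("simulated polynomial background is removed exactly by subtraction", {
  cfg_bg <- wave_sim_config(true_modulus_map = 3000 + 0i, encoding_gain = 0.8,
                            background = TRUE, seed = 9)
  cfg_no <- wave_sim_config(true_modulus_map = 3000 + 0i, encoding_gain = 0.8,
                            background = FALSE, seed = 9)
  with_bg <- simulate_wave_series(cfg_bg, "bottom")
  no_bg <- simulate_wave_series(cfg_no, "bottom")
  d_bg <- phase_difference(with_bg$pos, with_bg$neg)
  d_no <- phase_difference(no_bg$pos, no_bg$neg)
  expect_equal(d_bg$data, d_no$data, tolerance = 1e-12)
})

test_that("least-squares unwrapping recovers a steep ramp modulo 2*pi", {
  n <- 64
  ramp <- matrix(seq(0, 4 * pi, length.out = n), n, n, byrow = TRUE)
  dat <- array(rep(wrap_phase(ramp), 4), c(n, n, 4))
  ser <- phase_series(dat, 1, 900, PIX)
  un <- unwrap_phase(ser)
  resid <- un$data[, , 1] - ramp
  expect_lt(diff(range(resid)), 1e-9)                   # spatially constant
  expect_equal(mean(resid) / (2 * pi),
               round(mean(resid) / (2 * pi)), tolerance = 1e-9)  # 2*pi multiple
  # idempotence
  expect_identical(unwrap_phase(un)$data, un$data)
  # smooth in-range input is untouched
  mild <- array(0.3 * cos(outer(1:n, 1:n) / n^2 * 2), c(n, n, 4))
  sm <- phase_series(mild, 1, 900, PIX)
  expect_equal(unwrap_phase(sm)$data, mild, tolerance = 1e-9)
})

test_that("temporal harmonic obeys the A*cos(wt + theta) -> A*exp(i*theta) convention", {
  n <- 4; nd <- 8
  mk <- function(f) {
    dat <- array(0, c(n, n, nd))
    for (t in 1:nd) dat[, , t] <- f(2 * pi * (t - 1) / nd)
    phase_series(dat, 1, 900, PIX, wrapped = FALSE)
  }
  # hand-evaluated 8-point DFT: 3 + 2cos(wt + pi/3) -> 2 exp(i pi/3)
  fld <- temporal_harmonic(mk(function(wt) 3 + 2 * cos(wt + pi / 3)))
  expect_equal(fld$data[2, 2], 2 * exp(1i * pi / 3), tolerance = 1e-12)
  # DC rejected, pure cosine keeps amplitude
  expect_equal(temporal_harmonic(mk(function(wt) 7))$data[1, 1], 0 + 0i)
  expect_equal(temporal_harmonic(mk(function(wt) 5 * cos(wt)))$data[1, 1],
               5 + 0i, tolerance = 1e-12)
  # fewer than 4 offsets cannot resolve the first harmonic
  expect_error(phase_series(array(0, c(n, n, 3)), 1, 900, PIX), "n_dynamics")
})

test_that("Butterworth band-pass matches its analytic gain", {
  n <- 128
  H <- function(k, kl, kh, o) {
    g <- 1 / (1 + (k / kh)^(2 * o))
    if (kl > 0) g <- g * (1 - 1 / (1 + (k / kl)^(2 * o)))
    g
  }
  step <- 1 / (n * PIX)  # 40 cycles/m grid
  mkf <- function(cycles) wave_field(grid_plane_wave(n, cycles), 900, PIX)
  amp_ratio <- function(out, inp) sqrt(sum(Mod(out$data)^2) / sum(Mod(inp$data)^2))
  # passband centre k = sqrt(k_low*k_high) = 400: amplitude preserved within 2%
  f <- mkf(10)                       # 400 cycles/m
  out <- butterworth_bandpass(f, k_low = 80, k_high = 2000, order = 3)
  expect_equal(amp_ratio(out, f), 1, tolerance = 0.02)
  # on the raw periodic domain a grid wave is a single bin: gain is exactly H
  outp <- butterworth_bandpass(f, k_low = 80, k_high = 2000, order = 3,
                               pad = FALSE)
  expect_equal(amp_ratio(outp, f), H(400, 80, 2000, 3), tolerance = 1e-10)
  # half-power at k_high (k_high >> k_low)
  f25 <- mkf(25)                     # 1000 cycles/m
  out25 <- butterworth_bandpass(f25, k_low = 40, k_high = 1000, order = 3,
                                pad = FALSE)
  expect_equal(amp_ratio(out25, f25), H(1000, 40, 1000, 3), tolerance = 1e-10)
  expect_equal(H(1000, 40, 1000, 3), 0.5, tolerance = 1e-6)
  # constant field is zeroed by any high-pass
  fc <- wave_field(matrix(1 + 0i, n, n), 900, PIX)
  expect_lt(max(Mod(butterworth_bandpass(fc, 20, 2000)$data)), 1e-10)
  expect_error(butterworth_bandpass(f, k_low = 100, k_high = 50), "k_low")
})

test_that("band-pass never increases total spectral energy", {
  set.seed(42)
  for (i in 1:5) {
    m <- matrix(complex(real = rnorm(64^2), imaginary = rnorm(64^2)), 64)
    f <- wave_field(m, 900, PIX)
    out <- butterworth_bandpass(f, k_low = 20, k_high = 2000)
    expect_lte(sum(Mod(out$data)^2), sum(Mod(f$data)^2) * (1 + 1e-12))
  }
})

test_that("directional filter passes forward and rejects counter-propagating waves", {
  n <- 128
  # bottom-to-top wave: spectral content at +row frequency (see convention)
  fwd <- wave_field(grid_plane_wave(n, 13, "row", sign = +1), 900, PIX)
  bwd <- wave_field(grid_plane_wave(n, 13, "row", sign = -1), 900, PIX)
  out_f <- directional_filter(fwd, "bottom_to_top")
  out_b <- directional_filter(bwd, "bottom_to_top")
  expect_lt(sqrt(sum(Mod(out_f$data - fwd$data)^2) / sum(Mod(fwd$data)^2)),
            0.01)
  expect_lt(sqrt(sum(Mod(out_b$data)^2) / sum(Mod(bwd$data)^2)), 0.01)
  # and the simulator's conventions agree with the filter's
  cfg <- wave_sim_config(true_modulus_map = 3000 + 0i, background = FALSE)
  sim <- simulate_wave_series(cfg, "bottom")
  u <- wave_field(sim$clean_field, 900, PIX)
  kept <- directional_filter(u, "bottom_to_top")
  gone <- directional_filter(u, "top_to_bottom")
  expect_gt(sum(Mod(kept$data)^2) / sum(Mod(u$data)^2), 0.98)
  expect_lt(sum(Mod(gone$data)^2) / sum(Mod(u$data)^2), 0.02)
})

test_that("directional filter isolates the forward component of a superposition", {
  cfg <- wave_sim_config(true_modulus_map = 3000 + 0i,
                         reflection_coefficient = 0.5, background = FALSE)
  u_tot <- mrelastic:::simulated_displacement(cfg, "bottom")
  cfg$reflection_coefficient <- 0
  u_fwd <- mrelastic:::simulated_displacement(cfg, "bottom")
  out <- directional_filter(wave_field(u_tot, 900, PIX), "bottom_to_top")
  rel <- sqrt(sum(Mod(out$data - u_fwd)^2) / sum(Mod(u_fwd)^2))
  expect_lt(rel, 0.05)
})

test_that("filters are linear and provenance records the processing order", {
  set.seed(3)
  m <- matrix(complex(real = rnorm(64^2), imaginary = rnorm(64^2)), 64)
  f <- wave_field(m, 900, PIX)
  a <- 2.5 - 1.25i
  fa <- wave_field(a * m, 900, PIX)
  for (filt in list(function(x) butterworth_bandpass(x, 20, 2000),
                    function(x) directional_filter(x, "left_to_right"))) {
    expect_equal(filt(fa)$data, a * filt(f)$data, tolerance = 1e-10)
  }
  cfg <- wave_sim_config(true_modulus_map = 3000 + 0i, encoding_gain = 0.8,
                         background = FALSE)
  sim <- simulate_wave_series(cfg, "bottom")
  el <- mre_reconstruct(sim$pos, sim$neg)
  expect_match(el$provenance[1], "temporal_harmonic")
  expect_match(el$provenance[2], "butterworth")
  expect_match(el$provenance[3], "directional")
  expect_match(el$provenance[4], "helmholtz")
})
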