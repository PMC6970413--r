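# End-to-end orchestration: a validated configuration object and a
# run_pipeline() driver that goes from (simulated or stored) sign-alternated
# phase series to elastogram maps, regional summaries and a correlation
# report, writing every artefact with provenance metadata.

#' Build and validate a pipeline configuration
#'
#' Nested configuration for [run_pipeline()]. Acquisition defaults follow the
#' targeted protocol (900 Hz drive, 8 dynamics, 128 matrix, 25 mm FOV,
#' density 1000 kg/m^3); TE/TR of the scanner protocol are metadata only and
#' play no computational role. Every numeric field is validated against the
#' preconditions of the stage it feeds, before any computation runs.
#'
#' @param acquisition,filters,inversion,t1,stats Named lists overriding the
#'   per-block defaults (see the function body for the complete field list).
#' @param seed Integer seed controlling all simulated randomness.
#' @return A validated `mre_config` list.
#' @export
mre_config <- function(acquisition = list(), filters = list(),
                       inversion = list(), t1 = list(), stats = list(),
                       seed = 1) {
  cfg <- list(
    acquisition = utils::modifyList(list(
      frequency = 900, n_dynamics = 8, matrix_size = 128, fov = 0.025,
      density = 1000, te_ms = 14.3, tr_ms = 166.0), acquisition),
    filters = utils::modifyList(list(
      k_low = 20, k_high = 2000, order = 3,
      direction = "bottom_to_top", taper_width = 100), filters),
    inversion = utils::modifyList(list(
      mask_threshold = 0.1, min_amplitude = 0.05,
      stencil_correction = FALSE, averaging = "complex", erode = 2,
      junction = NULL), inversion),
    t1 = utils::modifyList(list(
      tr_list = c(230, 460, 1061, 1485, 2080, 3080, 7500),
      model = "two_parameter"), t1),
    stats = utils::modifyList(list(
      pairs = list(c("score", "gstar_abs", "spearman")),
      region = "whole", symptomatic_only = TRUE), stats),
    seed = seed)
  validate_config(cfg)
  structure(cfg, class = "mre_config")
}

validate_config <- function(cfg) {
  a <- cfg$acquisition; f <- cfg$filters; inv <- cfg$inversion; t1 <- cfg$t1
  if (a$frequency <= 0) stop("config: frequency must be positive")
  if (a$n_dynamics < 4) stop("config: n_dynamics must be >= 4")
  if (a$matrix_size < 16) stop("config: matrix_size must be >= 16")
  if (a$fov <= 0) stop("config: fov must be positive")
  if (a$density <= 0) stop("config: density must be positive")
  if (!(f$k_low >= 0 && f$k_low < f$k_high))
    stop("config: need 0 <= k_low < k_high")
  if (f$order < 1) stop("config: filter order must be >= 1")
  if (!is.null(f$direction))
    direction_vector(f$direction)  # errors on unknown direction
  if (f$taper_width < 0) stop("config: taper_width must be >= 0")
  if (inv$mask_threshold < 0) stop("config: mask_threshold must be >= 0")
  if (inv$min_amplitude < 0 || inv$min_amplitude >= 1)
    stop("config: min_amplitude must be in [0, 1)")
  if (!inv$averaging %in% c("complex", "magnitude"))
    stop("config: averaging must be 'complex' or 'magnitude'")
  if (length(t1$tr_list) < 3 || is.unsorted(t1$tr_list, strictly = TRUE))
    stop("config: tr_list must be >= 3 strictly increasing values")
  invisible(cfg)
}

#' Run the reconstruction pipeline end to end
#'
#' Stages: obtain the sign-alternated phase series (either the `pos`/`neg`
#' pair supplied in `inputs`, or a fresh simulation when `inputs$simulate`
#' is a list of [simulate_two_region_phantom()] arguments), then
#' phase-difference, unwrap, temporal harmonic, band-pass, directional
#' filter, Helmholtz inversion, regional summaries, and (when a cohort table
#' is supplied) the correlation report. All artefacts are written under
#' `out_dir` together with a provenance YAML (config, seed, stage list,
#' config file checksum).
#'
#' @param config An `mre_config` (or a path to a YAML file holding one).
#' @param inputs List: either `pos` and `neg` (`phase_series`), or
#'   `simulate = list(anterior_modulus=, posterior_modulus=, ...)`;
#'   optionally `cohort` (data frame) for the statistics stage.
#' @param out_dir Output directory.
#' @return Invisibly, a list with the `elastogram`, the `summaries` data
#'   frame, the correlation `report` (or NULL) and the output `paths`.
#' @export
run_pipeline <- function(config, inputs = list(), out_dir = tempfile("mre_")) {
  if (is.character(config)) {
    raw <- yaml::read_yaml(config)
    config <- mre_config(acquisition = raw$acquisition %||% list(),
                         filters = raw$filters %||% list(),
                         inversion = raw$inversion %||% list(),
                         t1 = raw$t1 %||% list(),
                         stats = raw$stats %||% list(),
                         seed = raw$seed %||% 1)
  }
  stopifnot(inherits(config, "mre_config"))
  validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  a <- config$acquisition; f <- config$filters; inv <- config$inversion
  stages <- character()
  truth <- NULL

  if (!is.null(inputs$simulate)) {
    sim_args <- inputs$simulate
    cfg <- wave_sim_config(
      density = a$density, frequency = a$frequency,
      matrix_size = a$matrix_size, fov = a$fov,
      n_dynamics = a$n_dynamics,
      reflection_coefficient = sim_args$reflection_coefficient %||% 0,
      noise_sd = sim_args$noise_sd %||% 0, seed = config$seed)
    sim <- simulate_two_region_phantom(
      sim_args$anterior_modulus, sim_args$posterior_modulus, cfg,
      junction = sim_args$junction)
    pos <- sim$pos; neg <- sim$neg; truth <- sim$truth
    write_phase_series(pos, file.path(out_dir, "phase_pos.nii.gz"),
                       extra = list(seed = config$seed))
    write_phase_series(neg, file.path(out_dir, "phase_neg.nii.gz"),
                       extra = list(seed = config$seed))
    stages <- c(stages, "simulate")
  } else if (!is.null(inputs$pos) && !is.null(inputs$neg)) {
    pos <- inputs$pos; neg <- inputs$neg
  } else {
    stop("inputs must supply either pos/neg series or a simulate block")
  }

  el <- mre_reconstruct(
    pos, neg, density = a$density, k_low = f$k_low, k_high = f$k_high,
    order = f$order, direction = f$direction, taper_width = f$taper_width,
    mask_threshold = inv$mask_threshold, min_amplitude = inv$min_amplitude,
    stencil_correction = inv$stencil_correction)
  stages <- c(stages, "phase_difference", "unwrap", "temporal_harmonic",
              "bandpass",
              if (!is.null(f$direction)) "directional_filter",
              "helmholtz_invert")
  write_elastogram(el, out_dir)

  junction <- inv$junction %||% (a$matrix_size %/% 2)
  whole <- matrix(TRUE, nrow(el$gstar), ncol(el$gstar))
  rois <- split_anterior_posterior(whole, junction)
  summaries <- do.call(rbind, lapply(names(rois), function(nm) {
    s <- summarize_roi(el, rois[[nm]], erode = inv$erode,
                       mode = inv$averaging)
    data.frame(region = sub("_brain", "", nm), g_prime = s$g_prime,
               g_doubleprime = s$g_doubleprime, g_abs = s$g_abs,
               phi = s$phi, n_pixels = s$n_pixels)
  }))
  utils::write.csv(summaries, file.path(out_dir, "summaries.csv"),
                   row.names = FALSE)
  stages <- c(stages, "summarize")

  report <- NULL
  if (!is.null(inputs$cohort)) {
    report <- correlation_report(
      inputs$cohort, config$stats$pairs, region = config$stats$region,
      symptomatic_only = config$stats$symptomatic_only)
    utils::write.csv(report, file.path(out_dir, "correlations.csv"),
                     row.names = FALSE)
    stages <- c(stages, "stats")
  }

  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(unclass(config), cfg_path)
  yaml::write_yaml(
    list(seed = config$seed, stages = as.list(stages),
         config_md5 = unname(tools::md5sum(cfg_path)),
         truth = if (!is.null(truth)) list(
           anterior = format(truth$regional_means$anterior),
           posterior = format(truth$regional_means$posterior))),
    file.path(out_dir, "provenance.yaml"))

  invisible(list(elastogram = el, summaries = summaries, report = report,
                 truth = truth, paths = out_dir))
}
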