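# File interchange: NIfTI image stacks with YAML sidecars carrying the
# acquisition geometry, wrap state and provenance; CSV for cohort tables.

#' Write a phase-image series as NIfTI plus YAML sidecar
#'
#' The third NIfTI axis is the temporal offset. The sidecar records the axis
#' layout, MSG sign, drive frequency, pixel spacing, wrap state and any
#' extra metadata (e.g. simulation seed), making the write/read round trip
#' self-describing.
#'
#' @param series A `phase_series`.
#' @param path Output path (`.nii` / `.nii.gz`); the sidecar is written next
#'   to it with extension `.yaml`.
#' @param extra Optional named list merged into the sidecar.
#' @return `path`, invisibly.
#' @export
write_phase_series <- function(series, path, extra = list()) {
  stopifnot(inherits(series, "phase_series"))
  img <- RNifti::asNifti(series$data,
                         pixdim = c(rep(series$pixel_spacing * 1e3, 2), 1))
  RNifti::writeNifti(img, path)
  meta <- c(list(kind = "phase_series",
                 layout = c("row", "col", "dynamic"),
                 dim = as.integer(dim(series$data)),
                 msg_sign = series$msg_sign,
                 drive_frequency = series$drive_frequency,
                 pixel_spacing = series$pixel_spacing,
                 wrapped = series$wrapped), extra)
  yaml::write_yaml(meta, sidecar_path(path), precision = 15)
  invisible(path)
}

sidecar_path <- function(path) {
  sub("\\.nii(\\.gz)?$", ".yaml", path)
}

#' Read an image stack written by this package
#'
#' Reads a NIfTI stack and its YAML sidecar and reconstructs the original
#' object. The caller states the expected axis layout; a mismatch with the
#' stored layout or stored dimensions is an error (data are never silently
#' permuted).
#'
#' @param path NIfTI file path.
#' @param layout Character vector naming the expected axis order, e.g.
#'   `c("row", "col", "dynamic")` for a phase series or
#'   `c("row", "col", "tr")` for a variable-TR series.
#' @return A `phase_series` or `t1_series`, per the sidecar `kind`.
#' @export
read_image_stack <- function(path, layout = c("row", "col", "dynamic")) {
  if (!file.exists(path)) stop("no such file: ", path)
  sc <- sidecar_path(path)
  if (!file.exists(sc)) stop("missing sidecar: ", sc)
  meta <- yaml::read_yaml(sc)
  dat <- array(as.numeric(RNifti::readNifti(path)),
               dim = as.integer(meta$dim))
  if (!identical(as.character(layout), as.character(meta$layout)))
    stop("layout mismatch: expected (", paste(layout, collapse = ", "),
         ") but file stores (", paste(meta$layout, collapse = ", "), ")")
  if (!identical(as.integer(dim(dat)), as.integer(meta$dim)))
    stop("dimension mismatch: sidecar says ",
         paste(meta$dim, collapse = "x"), ", file has ",
         paste(dim(dat), collapse = "x"))
  if (identical(meta$kind, "phase_series")) {
    phase_series(dat, msg_sign = meta$msg_sign,
                 drive_frequency = meta$drive_frequency,
                 pixel_spacing = meta$pixel_spacing,
                 wrapped = isTRUE(meta$wrapped))
  } else if (identical(meta$kind, "t1_series")) {
    structure(list(data = dat, tr_list = as.numeric(meta$tr_list)),
              class = "t1_series")
  } else {
    stop("unknown stack kind: ", meta$kind %||% "<missing>")
  }
}

#' Write a variable-TR series as NIfTI plus YAML sidecar
#'
#' @param series A `t1_series`.
#' @param path Output path.
#' @param extra Optional named list merged into the sidecar.
#' @return `path`, invisibly.
#' @export
write_t1_series <- function(series, path, extra = list()) {
  stopifnot(inherits(series, "t1_series"))
  RNifti::writeNifti(RNifti::asNifti(series$data), path)
  meta <- c(list(kind = "t1_series", layout = c("row", "col", "tr"),
                 dim = as.integer(dim(series$data)),
                 tr_list = as.numeric(series$tr_list)), extra)
  yaml::write_yaml(meta, sidecar_path(path), precision = 15)
  invisible(path)
}

#' Write elastogram maps as NIfTI volumes
#'
#' Writes four volumes (`<prefix>_greal`, `_gimag`, `_gabs`, `_phi`) plus a
#' validity mask and a YAML sidecar with density, frequency and provenance.
#' Invalid pixels are written as NA.
#'
#' @param el An `elastogram`.
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @return Named character vector of file paths, invisibly.
#' @export
write_elastogram <- function(el, dir, prefix = "elastogram") {
  stopifnot(inherits(el, "elastogram"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- el$gstar
  g[!el$valid] <- NA_complex_
  planes <- list(greal = Re(g), gimag = Im(g), gabs = Mod(g),
                 phi = atan2(Im(g), Re(g)), valid = el$valid * 1)
  paths <- vapply(names(planes), function(nm) {
    p <- file.path(dir, paste0(prefix, "_", nm, ".nii.gz"))
    RNifti::writeNifti(RNifti::asNifti(planes[[nm]]), p)
    p
  }, character(1))
  yaml::write_yaml(
    list(kind = "elastogram", density = el$density,
         drive_frequency = el$drive_frequency,
         pixel_spacing = el$pixel_spacing,
         provenance = as.list(el$provenance)),
    file.path(dir, paste0(prefix, ".yaml")))
  invisible(paths)
}
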