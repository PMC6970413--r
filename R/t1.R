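# Saturation-recovery T1 mapping and the two global contrast-uptake metrics
# derived from it: delta-T1 (mean pre-contrast T1 minus mean post-contrast
# T1 over a brain mask) and the percent signal-intensity change SI%.

#' Fit a voxelwise T1 map from a variable-TR series
#'
#' Per voxel, nonlinear least-squares fit of the two-parameter saturation
#' recovery model `S(TR) = S0 * (1 - exp(-TR / T1))` (Levenberg-Marquardt).
#' Initialisation: `S0` from the signal at the longest TR, `T1` from the
#' log-linearised shortest-TR point. Voxels that fail to converge, or whose
#' fitted T1 falls outside (1, 10000) ms, are flagged `fit_ok = FALSE`.
#'
#' @param series A `t1_series` (see [simulate_t1_series()]), or a list with
#'   `data` (row, col, tr index array) and `tr_list` (ms, strictly
#'   increasing, length >= 3).
#' @param mask Optional logical matrix restricting the fit.
#' @return An object of class `t1_map`: matrices `t1` (ms), `s0`, and
#'   logical `fit_ok`.
#' @export
fit_t1_map <- function(series, mask = NULL) {
  tr <- series$tr_list
  if (length(tr) < 3) stop("need at least 3 TRs for a 2-parameter fit")
  if (is.unsorted(tr, strictly = TRUE))
    stop("tr_list must be strictly increasing")
  dat <- series$data
  nr <- dim(dat)[1]; nc <- dim(dat)[2]
  mask <- mask %||% matrix(TRUE, nr, nc)
  t1 <- matrix(NA_real_, nr, nc)
  s0 <- matrix(NA_real_, nr, nc)
  ok <- matrix(FALSE, nr, nc)
  idx <- which(mask)
  for (v in idx) {
    i <- (v - 1) %% nr + 1
    j <- (v - 1) %/% nr + 1
    y <- dat[i, j, ]
    fit <- fit_t1_voxel(tr, y)
    if (!is.null(fit)) {
      t1[i, j] <- fit[["t1"]]
      s0[i, j] <- fit[["s0"]]
      ok[i, j] <- TRUE
    }
  }
  structure(list(t1 = t1, s0 = s0, fit_ok = ok), class = "t1_map")
}

fit_t1_voxel <- function(tr, y) {
  s0_init <- y[length(y)]
  if (!is.finite(s0_init) || s0_init <= 0) return(NULL)
  frac <- 1 - y[1] / s0_init
  t1_init <- if (is.finite(frac) && frac > 0 && frac < 1)
    -tr[1] / log(frac) else stats::median(tr)
  t1_init <- min(max(t1_init, 1.5), 9000)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ s0 * (1 - exp(-tr / t1)),
      start = list(s0 = s0_init, t1 = t1_init),
      lower = c(s0 = 0, t1 = 1), upper = c(s0 = Inf, t1 = 10000),
      control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  co <- stats::coef(fit)
  if (!all(is.finite(co)) || co[["t1"]] <= 1 || co[["t1"]] >= 10000)
    return(NULL)
  c(s0 = co[["s0"]], t1 = co[["t1"]])
}

#' @export
print.t1_map <- function(x, ...) {
  cat(sprintf("T1 map: %d x %d, %d fitted voxels, median T1 = %.0f ms\n",
              nrow(x$t1), ncol(x$t1), sum(x$fit_ok),
              stats::median(x$t1[x$fit_ok])))
  invisible(x)
}

slice_list <- function(x) {
  if (is.list(x)) return(x)
  if (is.matrix(x)) return(list(x))
  stopifnot(is.array(x), length(dim(x)) == 3)
  lapply(seq_len(dim(x)[3]), function(k) x[, , k])
}

masked_slice_means <- function(maps, masks, label) {
  maps <- slice_list(maps)
  masks <- slice_list(masks)
  if (length(maps) != length(masks))
    stop(label, ": number of slices and masks differ")
  vapply(seq_along(maps), function(k) {
    m <- masks[[k]]
    if (!any(m)) stop(label, ": empty mask on slice ", k)
    mean(maps[[k]][m])
  }, numeric(1))
}

#' Whole-brain delta-T1
#'
#' Per slice, the mask-mean T1 is computed; slice means are averaged
#' unweighted across slices for the pre- and post-contrast maps, and
#' `delta = pre - post` (ms). Positive values indicate contrast uptake
#' (T1 shortening).
#'
#' @param pre_map,post_map Per-slice T1 values: a matrix, a 3D array
#'   (row, col, slice), or a list of matrices. `t1_map` objects are accepted
#'   (their `t1` matrix is used, restricted to fitted voxels).
#' @param brain_masks Matching per-slice logical masks.
#' @return The delta-T1 in ms, with the per-slice means attached as
#'   attributes `pre_slice_means` and `post_slice_means`.
#' @export
delta_t1 <- function(pre_map, post_map, brain_masks) {
  grab <- function(x) if (inherits(x, "t1_map")) x$t1 else x
  pre <- masked_slice_means(grab(pre_map), brain_masks, "pre")
  post <- masked_slice_means(grab(post_map), brain_masks, "post")
  if (length(pre) != length(post)) stop("pre/post slice counts differ")
  structure(mean(pre) - mean(post),
            pre_slice_means = pre, post_slice_means = post)
}

#' Percent signal-intensity change
#'
#' `SI% = (mean(post) - mean(pre)) / mean(pre) * 100`, where the means are
#' taken across per-slice masked mean signal intensities.
#'
#' @param pre_si,post_si Numeric vectors of per-slice masked mean signal
#'   intensities (equal length).
#' @return Percent signal-intensity change (negative when signal drops).
#' @export
signal_intensity_change <- function(pre_si, post_si) {
  if (length(pre_si) != length(post_si))
    stop("pre/post slice counts differ")
  pre <- mean(pre_si)
  if (pre <= 0) stop("pre-contrast mean must be positive")
  (mean(post_si) - pre) / pre * 100
}
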