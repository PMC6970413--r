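# Downstream statistical layer: score-viscoelasticity and imaging-expression
# correlations, and relative qPCR quantification by the 2^-ddCt method.

#' Spearman rank correlation with exact small-sample permutation p-value
#'
#' Computes the rank correlation (midranks for ties). For n <= 9 the
#' two-sided p-value is exact, obtained by enumerating all n! permutations of
#' one rank vector (valid with ties, where the classical null tables are
#' not); for larger n the usual t-approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` with n - 2 degrees of freedom is
#' used.
#'
#' @param x,y Numeric vectors of equal length (n >= 3), finite values.
#' @return An object of class `htest` with `estimate` (rho) and `p.value`.
#' @export
spearman_test <- function(x, y) {
  dname <- paste(deparse1(substitute(x)), "and", deparse1(substitute(y)))
  check_corr_input(x, y)
  n <- length(x)
  xr <- rank(x)
  yr <- rank(y)
  rho <- stats::cor(xr, yr)
  if (n <= 9) {
    rho_perm <- all_perm_correlations(xr, yr)
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
    method <- "Spearman rank correlation (exact permutation p)"
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    method <- "Spearman rank correlation (t approximation)"
  }
  structure(
    list(estimate = c(rho = rho), p.value = min(p, 1),
         statistic = c(n = n), method = method, data.name = dname,
         alternative = "two.sided"),
    class = "htest"
  )
}

check_corr_input <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("values must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: zero variance")
  invisible(TRUE)
}

# Correlations of xr against every permutation of yr, via one matrix product
# over the n! x n permutation matrix. With xc centred, sum(xc * y_perm) is
# n times the sample covariance, so the denominator is permutation-invariant.
all_perm_correlations <- function(xr, yr) {
  perms <- permutation_matrix(length(xr))
  ymat <- matrix(yr[perms], nrow = nrow(perms))
  xc <- xr - mean(xr)
  denom <- sqrt(sum(xc^2) * sum((yr - mean(yr))^2))
  as.vector(ymat %*% xc) / denom
}

# All permutations of 1:n as an (n! x n) integer matrix.
permutation_matrix <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutation_matrix(n - 1)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (k in seq_len(n)) {
    block <- matrix(0L, nrow(sub), n)
    block[, k] <- n
    block[, -k] <- sub
    out[row:(row + nrow(sub) - 1), ] <- block
    row <- row + nrow(sub)
  }
  out
}

#' Pearson correlation test
#'
#' Sample product-moment correlation with the two-sided p-value from the
#' t-transform on n - 2 degrees of freedom (delegates to
#' [stats::cor.test()]).
#'
#' @param x,y Numeric vectors of equal length (n >= 3), finite values.
#' @return An object of class `htest`.
#' @export
pearson_test <- function(x, y) {
  dname <- paste(deparse1(substitute(x)), "and", deparse1(substitute(y)))
  check_corr_input(x, y)
  out <- stats::cor.test(x, y, method = "pearson",
                         alternative = "two.sided")
  out$data.name <- dname
  out
}

#' Relative expression by the 2^-ddCt method
#'
#' Per sample, `dCt = Ct(target) - Ct(reference)`; `ddCt` centres `dCt` on
#' the arithmetic mean of the control group; the fold change is `2^-ddCt`.
#' By construction the control group has mean ddCt of zero.
#'
#' @param ct Data frame with columns `sample_id`, `group`, `gene`, `ct`.
#' @param target_gene Gene to quantify.
#' @param reference_gene Endogenous reference gene (default `"18s"`).
#' @param control_group Group label used for centring (default `"control"`).
#' @return Data frame with one row per sample: `sample_id`, `group`, `dct`,
#'   `ddct`, `fold`.
#' @export
ddct_fold_change <- function(ct, target_gene, reference_gene = "18s",
                             control_group = "control") {
  stopifnot(is.data.frame(ct),
            all(c("sample_id", "group", "gene", "ct") %in% names(ct)))
  tgt <- ct[ct$gene == target_gene, ]
  ref <- ct[ct$gene == reference_gene, ]
  if (nrow(tgt) == 0) stop("no Ct values for target gene ", target_gene)
  missing_ref <- setdiff(tgt$sample_id, ref$sample_id)
  if (length(missing_ref))
    stop("missing reference Ct for sample(s): ",
         paste(missing_ref, collapse = ", "))
  m <- match(tgt$sample_id, ref$sample_id)
  dct <- tgt$ct - ref$ct[m]
  grp <- tgt$group
  if (!any(grp == control_group)) stop("control group is empty")
  ddct <- dct - mean(dct[grp == control_group])
  data.frame(sample_id = tgt$sample_id, group = grp, dct = dct,
             ddct = ddct, fold = 2^(-ddct), stringsAsFactors = FALSE)
}

#' Batch correlation report over a cohort table
#'
#' Runs the requested correlation tests over columns of a cohort table and
#' returns one tidy row per pair.
#'
#' @param cohort Data frame (as from [simulate_cohort()]); must contain the
#'   requested variables, and `score`/`group`/`region` if filtering is used.
#' @param pairs List of character triples `c(var1, var2, method)` with
#'   method `"spearman"` or `"pearson"`, or a 3-column data frame.
#' @param region Restrict to one region (`NULL` keeps all rows).
#' @param symptomatic_only Keep only animals with `score > 0`.
#' @param adjust Add a Benjamini-Hochberg adjusted p-value column.
#' @return Data frame with columns `var1`, `var2`, `method`, `n`,
#'   `estimate`, `p`, `filter` (and `p_adj` if `adjust`).
#' @export
correlation_report <- function(cohort, pairs, region = "whole",
                               symptomatic_only = FALSE, adjust = FALSE) {
  stopifnot(is.data.frame(cohort))
  if (is.data.frame(pairs))
    pairs <- lapply(seq_len(nrow(pairs)), function(i)
      as.character(unlist(pairs[i, ])))
  filt <- character()
  if (!is.null(region)) {
    if (!"region" %in% names(cohort)) stop("cohort lacks a region column")
    cohort <- cohort[cohort$region == region, ]
    filt <- c(filt, paste0("region=", region))
  }
  if (symptomatic_only) {
    if (!"score" %in% names(cohort)) stop("cohort lacks a score column")
    cohort <- cohort[cohort$score > 0, ]
    filt <- c(filt, "score>0")
  }
  if (nrow(cohort) == 0) stop("no rows remain after filtering")
  filt <- if (length(filt)) paste(filt, collapse = ",") else "none"
  rows <- lapply(pairs, function(p) {
    stopifnot(length(p) == 3)
    v1 <- p[1]; v2 <- p[2]; method <- match.arg(p[3],
                                                c("spearman", "pearson"))
    for (v in c(v1, v2)) if (!v %in% names(cohort))
      stop("unknown variable name: ", v)
    keep <- is.finite(cohort[[v1]]) & is.finite(cohort[[v2]])
    x <- cohort[[v1]][keep]; y <- cohort[[v2]][keep]
    ht <- if (method == "spearman") spearman_test(x, y)
          else pearson_test(x, y)
    data.frame(var1 = v1, var2 = v2, method = method, n = length(x),
               estimate = unname(ht$estimate), p = ht$p.value,
               filter = filt, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (adjust) out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out
}
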