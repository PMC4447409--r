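# ROI-level statistical design: per-ROI summaries, before/after paired
# t-tests per tissue class, and the cross-modality Pearson correlation grid
# between CT/DCE perfusion parameters and the IVIM perfusion parameters
# (f, D*). Subject-level values entering the tests are ROI means.

#' Mean, SD and voxel count of a map over one labelled ROI
#'
#' @param map 3D numeric volume.
#' @param labels 3D integer label volume of the same shape.
#' @param code integer mask code; must be present in `labels`.
#' @return List with `mean`, `sd` (n-1 denominator; 0 for a single voxel)
#'   and `n`.
#' @export
roi_mean <- function(map, labels, code) {
  if (!identical(dim(map), dim(labels)))
    stop("map and labels must have identical shape")
  v <- map[labels == code]
  v <- v[!is.na(v)]
  if (length(v) == 0) stop("mask code ", code, " absent from labels")
  list(mean = mean(v), sd = if (length(v) > 1) stats::sd(v) else 0,
       n = length(v))
}

#' Paired (dependent-samples) t-test
#'
#' t = mean(d) / (SD(d)/sqrt(n)) on d = before - after, two-sided p from the
#' t distribution with n - 1 degrees of freedom. Identical vectors give
#' t = 0, p = 1. Zero-variance nonzero differences are degenerate: p = 0
#' with a warning.
#'
#' @param before,after numeric vectors of equal length n >= 2 (same subjects,
#'   two phases).
#' @return List with `t`, `df`, `p`.
#' @export
#' @examples
#' paired_t_test(c(0.29, 0.31, 0.27), c(0.15, 0.14, 0.16))
paired_t_test <- function(before, after) {
  n <- length(before)
  if (length(after) != n) stop("before and after must have equal length")
  if (n < 2) stop("need n >= 2 pairs")
  d <- before - after
  sdd <- stats::sd(d)
  df <- n - 1
  if (sdd == 0) {
    if (all(d == 0)) return(list(t = 0, df = df, p = 1))
    warning("zero-variance nonzero differences: degenerate paired t-test")
    return(list(t = sign(mean(d)) * Inf, df = df, p = 0))
  }
  t <- mean(d) / (sdd / sqrt(n))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Pearson product-moment correlation with two-sided p-value
#'
#' p is computed from t = r sqrt((n-2)/(1-r^2)) on n - 2 degrees of freedom.
#'
#' @param x,y numeric vectors of equal length n >= 3 with nonzero variance.
#' @return List with `r`, `p`, `n`.
#' @export
pearson_r <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 3) stop("need n >= 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in x or y")
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  r <- clip(r, -1, 1)
  if (abs(r) == 1) return(list(r = r, p = 0, n = n))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t), n - 2), n = n)
}

significance_flag <- function(p) {
  ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))
}

check_fits_frame <- function(fits) {
  need <- c("subject", "class", "phase", "param", "value")
  if (!all(need %in% names(fits)))
    stop("fits must have columns ", paste(need, collapse = ", "))
  invisible(fits)
}

#' Before/after group-comparison table
#'
#' One row per tissue class x parameter: mean +/- SD in each phase across
#' subjects, the paired t statistic, its two-sided p-value, and the
#' significance flag ("*" for p < 0.05, "**" for p < 0.01). Every subject
#' must have both phases for every class x parameter.
#'
#' @param fits tidy data.frame of subject-level ROI values with columns
#'   `subject`, `class`, `phase`, `param`, `value`.
#' @return data.frame with columns `class`, `param`, `mean_before`,
#'   `sd_before`, `mean_after`, `sd_after`, `t`, `df`, `p`, `flag`.
#' @export
build_parameter_tables <- function(fits) {
  check_fits_frame(fits)
  combos <- unique(fits[, c("class", "param")])
  out <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    cl <- combos$class[i]; pm <- combos$param[i]
    sub <- fits[fits$class == cl & fits$param == pm, ]
    wide <- merge(sub[sub$phase == "BEFORE", c("subject", "value")],
                  sub[sub$phase == "AFTER", c("subject", "value")],
                  by = "subject", suffixes = c("_before", "_after"))
    n_sub <- length(unique(sub$subject))
    if (nrow(wide) != n_sub)
      stop("missing phase for some subject in (", cl, ", ", pm, ")")
    tt <- paired_t_test(wide$value_before, wide$value_after)
    data.frame(class = cl, param = pm,
               mean_before = mean(wide$value_before),
               sd_before = stats::sd(wide$value_before),
               mean_after = mean(wide$value_after),
               sd_after = stats::sd(wide$value_after),
               t = tt$t, df = tt$df, p = tt$p,
               flag = significance_flag(tt$p),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Cross-modality correlation table
#'
#' For each tissue class, Pearson r and two-sided p between each perfusion
#' parameter (BF, BV, PMB, Ktrans, Ve, Kep) and each IVIM perfusion
#' parameter (D*, f) across subjects, using values from one phase
#' (default BEFORE, when all regions are perfused).
#'
#' @inheritParams build_parameter_tables
#' @param phase which phase's subject-level values to correlate.
#' @param perfusion_params,ivim_params_ parameter name sets forming the grid.
#' @return data.frame with columns `class`, `perfusion_param`, `ivim_param`,
#'   `r`, `p`, `n`.
#' @export
build_correlation_table <- function(fits, phase = "BEFORE",
                                    perfusion_params = c("BF", "BV", "PMB",
                                                         "Ktrans", "Ve", "Kep"),
                                    ivim_params_ = c("D_star", "f")) {
  check_fits_frame(fits)
  fits <- fits[fits$phase == phase, ]
  classes <- unique(fits$class)
  need <- c(perfusion_params, ivim_params_)
  miss <- setdiff(need, unique(fits$param))
  if (length(miss))
    stop("missing parameter(s) in fits: ", paste(miss, collapse = ", "))
  out <- do.call(rbind, lapply(classes, function(cl) {
    sub <- fits[fits$class == cl, ]
    get <- function(p) {
      v <- sub[sub$param == p, ]
      v <- v[order(v$subject), ]
      stats::setNames(v$value, v$subject)
    }
    do.call(rbind, lapply(perfusion_params, function(pp) {
      do.call(rbind, lapply(ivim_params_, function(ip) {
        x <- get(pp); y <- get(ip)
        if (!identical(names(x), names(y)))
          stop("subject mismatch between ", pp, " and ", ip)
        pr <- pearson_r(x, y)
        data.frame(class = cl, perfusion_param = pp, ivim_param = ip,
                   r = pr$r, p = pr$p, n = pr$n, stringsAsFactors = FALSE)
      }))
    }))
  }))
  rownames(out) <- NULL
  out
}
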