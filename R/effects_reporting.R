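#' Percentage change in relative rate
#'
#' Transforms a log-scale coefficient to the reporting scale
#' `(exp(scale * coef) - 1) * 100` with a Gaussian confidence interval
#' transformed monotonically: `scale = 1` for indicator variables, the
#' interquartile range for pollutant terms.
#'
#' @param coef log-scale coefficient.
#' @param scale positive multiplier applied before exponentiating.
#' @param se standard error of `coef` (0 gives a degenerate interval).
#' @param level confidence level (default 0.95).
#' @return list with `pct`, `lo`, `hi`.
#' @export
pct_rr_change <- function(coef, scale = 1, se = 0, level = 0.95) {
  stopifnot(scale > 0, se >= 0, level > 0, level < 1)
  z <- stats::qnorm(1 - (1 - level) / 2)
  tr <- function(b) (exp(scale * b) - 1) * 100
  list(pct = tr(coef), lo = tr(coef - z * se), hi = tr(coef + z * se))
}

#' Interquartile range (linear-interpolation quantiles)
#'
#' 75th minus 25th percentile using the linear-interpolation quantile
#' definition (R type 7). Missing values are dropped.
#'
#' @param x numeric vector with at least 4 finite values.
#' @return numeric IQR.
#' @export
iqr <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 4) stop("need at least 4 finite values for an IQR")
  qs <- stats::quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
  qs[2] - qs[1]
}

#' Effect report on the relative-rate scale
#'
#' Tabulates the fixed effects (DOW, ADS period, post-ADS period) at scale 1
#' and each pollutant at its interquartile-range scale, as percentage
#' changes in relative rate with confidence intervals.
#'
#' @param fit a [star_fit][fit_star].
#' @param covariates daily covariate table used to compute pollutant IQRs
#'   (default: the table stored in the fit).
#' @param level confidence level.
#' @return data frame with columns `term`, `scale`, `pct`, `lo`, `hi`.
#' @export
effect_report <- function(fit, covariates = NULL, level = 0.95) {
  stopifnot(inherits(fit, "star_fit"))
  if (is.null(covariates)) covariates <- fit$meta$cov_day
  fixed_idx <- fit$blocks[[1]]$idx
  terms <- names(fit$coefficients)[fixed_idx]
  terms <- setdiff(terms, "(Intercept)")
  rows <- lapply(terms, function(tm) {
    pr <- pct_rr_change(fit$coefficients[[tm]], 1, fit$se[[tm]], level)
    data.frame(term = tm, scale = 1, pct = pr$pct, lo = pr$lo, hi = pr$hi)
  })
  for (p in fit$meta$spec$pollutants) {
    sc <- iqr(covariates[[p]])
    pr <- pct_rr_change(fit$coefficients[[p]], sc, fit$se[[p]], level)
    rows[[length(rows) + 1L]] <-
      data.frame(term = p, scale = sc, pct = pr$pct, lo = pr$lo, hi = pr$hi)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify district effects by posterior interval position
#'
#' Classifies each district's spatial relative rate as `positive` if the
#' whole `level` posterior interval lies above 1, `negative` if below 1, and
#' `nonsignificant` otherwise. Classification happens on the log scale and
#' is then exponentiated (equivalent, numerically safer).
#'
#' @param mean,sd numeric vectors of posterior means and standard deviations
#'   of the log-scale district effects (sd > 0); names carry district ids.
#' @param level posterior interval level (default 0.95).
#' @return data frame (class `spatial_effect_map`) with columns `district`,
#'   `rr`, `lo`, `hi`, `class`.
#' @export
classify_spatial <- function(mean, sd, level = 0.95) {
  stopifnot(length(mean) == length(sd), all(sd > 0))
  z <- stats::qnorm(1 - (1 - level) / 2)
  lo <- mean - z * sd; hi <- mean + z * sd
  cls <- ifelse(lo > 0, "positive", ifelse(hi < 0, "negative", "nonsignificant"))
  out <- data.frame(
    district = if (is.null(names(mean))) as.character(seq_along(mean)) else names(mean),
    rr = exp(mean), lo = exp(lo), hi = exp(hi),
    class = factor(cls, levels = c("positive", "negative", "nonsignificant")))
  class(out) <- c("spatial_effect_map", "data.frame")
  out
}

#' Spatial effect map from a fitted model
#'
#' Extracts per-district posterior means and standard deviations of the CAR
#' spatial effect (back-transformed through the sum-to-zero
#' reparameterization) and classifies them with [classify_spatial()].
#'
#' @param fit a [star_fit][fit_star] whose spec included the spatial term.
#' @param level posterior interval level.
#' @return a [spatial_effect_map][classify_spatial].
#' @export
spatial_effect_map <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "star_fit"))
  blk <- Filter(function(b) b$name == "f_spat", fit$blocks)
  if (!length(blk)) stop("fit has no spatial term")
  idx <- blk[[1]]$idx
  Z <- fit$meta$spat_Z
  f <- drop(Z %*% fit$coefficients[idx])
  V <- Z %*% fit$cov[idx, idx, drop = FALSE] %*% t(Z)
  sd <- sqrt(pmax(diag(V), 1e-300))
  classify_spatial(setNames(f, fit$meta$districts), sd, level)
}

#' Smoother curve with credible bands
#'
#' Evaluates a fitted smooth term on a grid and returns the relative-rate
#' curve `exp(f̂)` with pointwise bands from the block's posterior
#' covariance (default 80% and 95%).
#'
#' @param fit a [star_fit][fit_star].
#' @param term `"f_time"` or `"f_temp"`.
#' @param grid numeric vector inside the fitted covariate domain (default:
#'   a 100-point grid over the domain).
#' @param levels band levels (default `c(0.80, 0.95)`).
#' @return data frame (class `smoother_curve`) with `x`, `rr`, and
#'   `lo_<level>` / `hi_<level>` columns per band.
#' @export
smoother_curve <- function(fit, term = c("f_temp", "f_time"), grid = NULL,
                           levels = c(0.80, 0.95)) {
  stopifnot(inherits(fit, "star_fit"))
  term <- match.arg(term)
  blk <- Filter(function(b) b$name == term, fit$blocks)
  if (!length(blk)) stop(sprintf("fit has no '%s' term", term))
  idx <- blk[[1]]$idx
  sb <- if (term == "f_time") fit$meta$time_block else fit$meta$temp_block
  if (is.null(grid)) grid <- seq(sb$domain[1], sb$domain[2], length.out = 100)
  B <- spline_block_eval(sb, grid)
  f <- drop(B %*% fit$coefficients[idx])
  V <- B %*% fit$cov[idx, idx, drop = FALSE] %*% t(B)
  sd <- sqrt(pmax(diag(V), 0))
  out <- data.frame(x = grid, rr = exp(f))
  for (lv in sort(levels)) {
    z <- stats::qnorm(1 - (1 - lv) / 2)
    out[[sprintf("lo_%d", round(lv * 100))]] <- exp(f - z * sd)
    out[[sprintf("hi_%d", round(lv * 100))]] <- exp(f + z * sd)
  }
  class(out) <- c("smoother_curve", "data.frame")
  out
}

#' Episode-stratified pollutant summary
#'
#' Mean and standard deviation of each pollutant (and temperature, if
#' present) within the ADS / post-ADS / other strata, optionally with a
#' one-way ANOVA F-test p-value per pollutant for the null of equal stratum
#' means.
#'
#' @param covariates daily covariate table with a `date` column.
#' @param calendar an [exposure_calendar][label_periods].
#' @param anova compute the per-pollutant F-test p-value (default `TRUE`).
#' @return data frame with `pollutant`, `period`, `n`, `mean`, `sd`, and
#'   (if requested) `p_value` repeated across the pollutant's rows. Strata
#'   with fewer than 2 days get `NA` sd.
#' @export
episode_pollutant_summary <- function(covariates, calendar, anova = TRUE) {
  stopifnot(inherits(calendar, "exposure_calendar"))
  covariates$date <- as.Date(covariates$date)
  m <- merge(covariates, calendar[, c("date", "period")], by = "date")
  if (!nrow(m)) stop("calendar and covariates share no dates")
  vars <- setdiff(names(covariates), "date")
  rows <- list()
  for (v in vars) {
    pv <- NA_real_
    if (anova && nlevels(droplevels(m$period)) > 1) {
      fit <- stats::aov(m[[v]] ~ droplevels(m$period))
      pv <- summary(fit)[[1]][["Pr(>F)"]][1]
    }
    for (per in levels(m$period)) {
      x <- m[[v]][m$period == per & is.finite(m[[v]])]
      if (!length(x)) next
      rows[[length(rows) + 1L]] <- data.frame(
        pollutant = v, period = per, n = length(x), mean = mean(x),
        sd = if (length(x) >= 2) stats::sd(x) else NA_real_,
        p_value = if (anova) pv else NA_real_)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
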