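#' Residualized change score
#'
#' Regresses the follow-up score on the baseline score by simple least
#' squares and returns each subject's standardized residual about the
#' regression line as the measure of change. Residuals are exactly
#' uncorrelated with baseline by construction, which is the point of the
#' residualized-change approach (unlike raw difference scores, which
#' regress to the mean). The slope is also reported standardized (the fit
#' on z-scored inputs), so `r2 = beta^2`.
#'
#' @param baseline,followup Numeric score vectors; pairs with a missing
#'   value in either are dropped from the fit and return `NA` residuals.
#' @return A `change_score` list: `z` (standardized residuals), `residuals`
#'   (raw), `beta` (standardized slope), `slope`, `intercept`, `r2`,
#'   `n`, and `zero_variance` (TRUE when follow-up is perfectly predicted,
#'   in which case SD-normalization is skipped and `z` is all zero).
#' @export
residualized_change <- function(baseline, followup) {
  stopifnot(length(baseline) == length(followup))
  ok <- !is.na(baseline) & !is.na(followup)
  if (sum(ok) < 3) stop("residualized_change needs at least 3 complete pairs")
  b <- baseline[ok]; f <- followup[ok]
  if (max(b) == min(b)) stop("constant baseline: degenerate regression")
  slope <- stats::cov(b, f) / stats::var(b)
  intercept <- mean(f) - slope * mean(b)
  res <- f - (intercept + slope * b)
  sdr <- stats::sd(res)
  zero_variance <- sdr < 1e-12 * max(1, stats::sd(f))
  z <- rep(NA_real_, length(baseline))
  r <- rep(NA_real_, length(baseline))
  r[ok] <- res
  z[ok] <- if (zero_variance) 0 else res / sdr
  beta <- if (stats::sd(f) < 1e-12) 0 else stats::cor(b, f)
  structure(list(z = z, residuals = r, beta = beta, slope = slope,
                 intercept = intercept, r2 = beta^2, n = sum(ok),
                 zero_variance = zero_variance),
            class = "change_score")
}

#' Raw difference change score
#'
#' Both waves are z-scored on the complete-pair subset and the earlier wave
#' subtracted from the later (later minus earlier), giving the raw
#' difference scores C-delta used to adjust correlations for cognitive
#' change. Missing in either wave propagates. The result has mean 0 on
#' complete pairs by construction.
#'
#' @param wave_a Earlier wave scores.
#' @param wave_b Later wave scores.
#' @return Numeric vector `z(wave_b) - z(wave_a)`.
#' @export
raw_difference_change <- function(wave_a, wave_b) {
  stopifnot(length(wave_a) == length(wave_b))
  ok <- !is.na(wave_a) & !is.na(wave_b)
  if (sum(ok) < 2) stop("raw_difference_change needs at least 2 complete pairs")
  if (max(wave_a[ok]) == min(wave_a[ok]) || max(wave_b[ok]) == min(wave_b[ok]))
    stop("constant wave: degenerate input")
  out <- rep(NA_real_, length(wave_a))
  za <- (wave_a[ok] - mean(wave_a[ok])) / stats::sd(wave_a[ok])
  zb <- (wave_b[ok] - mean(wave_b[ok])) / stats::sd(wave_b[ok])
  out[ok] <- zb - za
  out
}

#' All three raw-difference change scores from an IQ panel
#'
#' C-delta-1 = IQ-57 - IQ-20, C-delta-2 = IQ-63 - IQ-57,
#' C-delta-3 = IQ-20 - IQ-11, each on within-wave z-scored scores.
#'
#' @param panel Data frame with columns `iq11`, `iq20`, `iq57`, `iq63`.
#' @return Data frame with columns `cdelta1`, `cdelta2`, `cdelta3`.
#' @export
cdelta_scores <- function(panel) {
  data.frame(cdelta1 = raw_difference_change(panel$iq20, panel$iq57),
             cdelta2 = raw_difference_change(panel$iq57, panel$iq63),
             cdelta3 = raw_difference_change(panel$iq11, panel$iq20))
}

#' Extreme-group selection on residualized change
#'
#' Subjects with `|z| > cutoff` are excluded as extreme-score artifacts;
#' retained subjects split at z = 0 into improvers (z > 0) and decliners
#' (z <= 0). An optional quantile `q` keeps only the top/bottom q of the
#' retained subjects for a stricter extreme-groups design; the default
#' keeps all retained subjects, matching a near-even split.
#'
#' @param change A `change_score` from [residualized_change()] (or a
#'   numeric vector of standardized residuals).
#' @param cutoff Exclusion cutoff on `|z|` (default 3).
#' @param q Optional tail fraction in (0, 0.5]; `NULL` keeps all retained.
#' @return A `group_assignment` list: `label` (factor improver / decliner /
#'   excluded per subject) and `counts`.
#' @export
select_extreme_groups <- function(change, cutoff = 3, q = NULL) {
  z <- if (inherits(change, "change_score")) change$z else change
  label <- rep(NA_character_, length(z))
  label[!is.na(z) & abs(z) > cutoff] <- "excluded"
  retained <- !is.na(z) & abs(z) <= cutoff
  if (!any(retained)) stop("all subjects excluded: empty groups")
  label[retained & z > 0] <- "improver"
  label[retained & z <= 0] <- "decliner"
  if (!is.null(q)) {
    stopifnot(q > 0, q <= 0.5)
    zr <- z[retained]
    lo <- stats::quantile(zr, q)
    hi <- stats::quantile(zr, 1 - q)
    mid <- retained & z > lo & z < hi
    label[mid] <- "excluded"
  }
  label <- factor(label, levels = c("improver", "decliner", "excluded"))
  structure(list(label = label,
                 counts = table(label)),
            class = "group_assignment")
}

#' @export
print.group_assignment <- function(x, ...) {
  cat("group_assignment:",
      paste(sprintf("%s=%d", names(x$counts), x$counts), collapse = ", "),
      "\n")
  invisible(x)
}

#' Partial correlation adjusting for a change score
#'
#' Residualizes `x` and `y` each on an intercept plus the change score and
#' reports the Pearson correlation of the residuals with a t-based p-value
#' on n - 3 degrees of freedom. A constant change score falls back to the
#' plain correlation (df n - 2) with a warning.
#'
#' @param x,y Numeric vectors.
#' @param cdelta Change-score vector to adjust for.
#' @return List with `r`, `p`, `n`, `df`, `adjusted`.
#' @export
adjust_for_change <- function(x, y, cdelta) {
  ok <- stats::complete.cases(x, y, cdelta)
  if (sum(ok) < 4) stop("adjust_for_change needs at least 4 complete triples")
  x <- x[ok]; y <- y[ok]; cd <- cdelta[ok]
  n <- length(x)
  if (max(cd) == min(cd)) {
    warning("constant change score; returning unadjusted correlation")
    r <- stats::cor(x, y)
    df <- n - 2
    adjusted <- FALSE
  } else {
    rx <- stats::residuals(stats::lm(x ~ cd))
    ry <- stats::residuals(stats::lm(y ~ cd))
    r <- stats::cor(rx, ry)
    df <- n - 3
    adjusted <- TRUE
  }
  tstat <- r * sqrt(df / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tstat), df), n = n, df = df,
       adjusted = adjusted)
}
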