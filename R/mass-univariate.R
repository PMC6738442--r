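#' All-pairs Pearson correlation screen
#'
#' Correlates every variable of `table_x` with every variable of `table_y`
#' on pairwise-complete observations. Two-sided p-values come from
#' `t = r * sqrt((n_eff - 2) / (1 - r^2))` on `n_eff - 2` degrees of
#' freedom. Pairs with fewer than 4 complete observations, or a constant
#' column within the complete pairs, are flagged `excluded` and carry `NA`
#' statistics. P-values are floored at the smallest positive double so
#' `-log10(p)` stays finite.
#'
#' @param table_x,table_y Preprocessed [phenotype_table()]s (normalized and
#'   deconfounded) sharing subjects in the same order.
#' @param cdelta Optional change-score vector; when supplied, each pair is
#'   adjusted for it via partial correlation (df `n_eff - 3`).
#' @return Data frame of correlation records: `var_x`, `block_x`, `var_y`,
#'   `block_y`, `r`, `n_eff`, `p`, `neg_log10_p`, `excluded`.
#' @export
pairwise_correlations <- function(table_x, table_y, cdelta = NULL) {
  if (!identical(rownames(table_x$values), rownames(table_y$values)))
    stop("tables do not share subjects")
  X <- table_x$values
  Y <- table_y$values
  if (nrow(X) == 0) stop("zero shared subjects")
  df_offset <- 2L
  if (!is.null(cdelta)) {
    # residualize every column on the change score first (complete triples
    # handled pairwise through the NA pattern of the residualized columns)
    X <- residualize_on(X, cdelta)
    Y <- residualize_on(Y, cdelta)
    df_offset <- 3L
  }
  suppressWarnings(r <- stats::cor(X, Y, use = "pairwise.complete.obs"))
  n_eff <- crossprod(!is.na(X), !is.na(Y))
  df <- n_eff - df_offset
  tstat <- r * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), pmax(df, 1))
  p <- pmax(p, .Machine$double.xmin)
  excluded <- is.na(r) | n_eff < 4
  p[excluded] <- NA
  rec <- data.frame(
    var_x = rep(colnames(X), times = ncol(Y)),
    block_x = rep(table_x$manifest$block, times = ncol(Y)),
    var_y = rep(colnames(Y), each = ncol(X)),
    block_y = rep(table_y$manifest$block, each = ncol(X)),
    r = as.vector(r),
    n_eff = as.vector(n_eff),
    p = as.vector(p),
    excluded = as.vector(excluded))
  rec$neg_log10_p <- -log10(rec$p)
  rec
}

residualize_on <- function(M, cdelta) {
  out <- M
  for (j in seq_len(ncol(M))) {
    ok <- !is.na(M[, j]) & !is.na(cdelta)
    out[, j] <- NA
    if (sum(ok) >= 4 && max(cdelta[ok]) > min(cdelta[ok]))
      out[ok, j] <- stats::residuals(stats::lm(M[ok, j] ~ cdelta[ok]))
  }
  out
}

#' Multiple-testing control over a correlation screen
#'
#' Flags each record against the Bonferroni familywise threshold
#' `alpha / m` and the Benjamini-Hochberg step-up rule at level `alpha`,
#' where m is the number of testable (non-excluded) records, or a
#' user-supplied effective number of tests.
#'
#' @param records Output of [pairwise_correlations()].
#' @param alpha Level (default 0.05).
#' @param m_eff Optional effective number of tests overriding the record
#'   count in the Bonferroni threshold.
#' @return List with `records` (augmented with `pass_fwe`, `pass_fdr`) and
#'   `report` (alpha, m, `bonferroni_p`, `fdr_p`, `n_pass_fwe`,
#'   `n_pass_fdr`).
#' @export
multiple_testing <- function(records, alpha = 0.05, m_eff = NULL) {
  if (nrow(records) == 0) stop("empty record list")
  testable <- !records$excluded & !is.na(records$p)
  m <- sum(testable)
  if (m == 0) stop("no testable records")
  m_bonf <- if (is.null(m_eff)) m else m_eff
  bonferroni_p <- alpha / m_bonf
  records$pass_fwe <- records$pass_fdr <- FALSE
  records$pass_fwe[testable] <- records$p[testable] <= bonferroni_p
  bh <- stats::p.adjust(records$p[testable], method = "BH")
  records$pass_fdr[testable] <- bh <= alpha
  fdr_p <- if (any(records$pass_fdr))
    max(records$p[records$pass_fdr]) else NA_real_
  list(records = records,
       report = list(alpha = alpha, m = m, bonferroni_p = bonferroni_p,
                     fdr_p = fdr_p,
                     n_pass_fwe = sum(records$pass_fwe),
                     n_pass_fdr = sum(records$pass_fdr)))
}

#' Per-subgroup consistency check of significant associations
#'
#' Recomputes each whole-group FWE-significant correlation within each
#' subgroup and raises a Simpson's-paradox flag when both subgroup
#' correlations have sign opposite to the pooled one. Groups with fewer
#' than 4 usable subjects contribute `NA` with a warning.
#'
#' @param table_x,table_y The preprocessed tables used for the screen.
#' @param groups A `group_assignment` from [select_extreme_groups()] (or a
#'   factor of labels aligned with the tables' subjects).
#' @param records Flagged records from [multiple_testing()].
#' @return Data frame of significant pairs with `r_pooled`, per-group
#'   correlations `r_improver`, `r_decliner`, and `simpson_flag`.
#' @export
subgroup_consistency <- function(table_x, table_y, groups, records) {
  label <- if (inherits(groups, "group_assignment")) groups$label else groups
  stopifnot(length(label) == nrow(table_x$values))
  sig <- records[records$pass_fwe & !records$excluded, , drop = FALSE]
  if (nrow(sig) == 0)
    return(data.frame(var_x = character(), var_y = character(),
                      r_pooled = numeric(), r_improver = numeric(),
                      r_decliner = numeric(), simpson_flag = logical()))
  group_r <- function(grp, vx, vy) {
    rows <- which(label == grp)
    x <- table_x$values[rows, vx]
    y <- table_y$values[rows, vy]
    ok <- stats::complete.cases(x, y)
    if (sum(ok) < 4) {
      warning(sprintf("group %s has < 4 usable subjects for %s x %s",
                      grp, vx, vy))
      return(NA_real_)
    }
    if (max(x[ok]) == min(x[ok]) || max(y[ok]) == min(y[ok])) return(NA_real_)
    stats::cor(x[ok], y[ok])
  }
  out <- sig[, c("var_x", "var_y", "r")]
  names(out)[3] <- "r_pooled"
  out$r_improver <- mapply(group_r, "improver", sig$var_x, sig$var_y)
  out$r_decliner <- mapply(group_r, "decliner", sig$var_x, sig$var_y)
  out$simpson_flag <- !is.na(out$r_improver) & !is.na(out$r_decliner) &
    sign(out$r_improver) == sign(out$r_decliner) &
    sign(out$r_improver) != 0 &
    sign(out$r_improver) != sign(out$r_pooled)
  rownames(out) <- NULL
  out
}

#' Plot-ready Manhattan table of a correlation screen
#'
#' One row per testable record: an x-position grouping records by the
#' y-set variable, `-log10(p)` heights, the x-set block as a colour key,
#' and the FWE threshold line (plus the FDR line when it adds discoveries
#' beyond Bonferroni, mirroring the convention of only drawing FDR when it
#' matters).
#'
#' @param flagged Output of [multiple_testing()].
#' @return Data frame with attributes `fwe_line` and `fdr_line`
#'   (`-log10`-transformed thresholds; `fdr_line` is `NA` when FDR adds
#'   nothing).
#' @export
manhattan_export <- function(flagged) {
  records <- flagged$records
  report <- flagged$report
  rec <- records[!records$excluded, , drop = FALSE]
  ylev <- unique(rec$var_y)
  rec$x <- match(rec$var_y, ylev) +
    (stats::ave(seq_len(nrow(rec)), rec$var_y, FUN = seq_along) - 1) /
    (1 + stats::ave(seq_len(nrow(rec)), rec$var_y, FUN = length)) - 0.5
  out <- rec[, c("x", "var_x", "var_y", "block_x", "neg_log10_p",
                 "pass_fwe", "pass_fdr")]
  attr(out, "fwe_line") <- -log10(report$bonferroni_p)
  attr(out, "fdr_line") <- if (report$n_pass_fdr > report$n_pass_fwe &&
                               !is.na(report$fdr_p))
    -log10(report$fdr_p) else NA_real_
  rownames(out) <- NULL
  out
}

#' Manhattan plot of a correlation screen
#'
#' @param flagged Output of [multiple_testing()].
#' @return A ggplot object.
#' @export
plot_manhattan <- function(flagged) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  tab <- manhattan_export(flagged)
  p <- ggplot2::ggplot(tab, ggplot2::aes(x = x, y = neg_log10_p,
                                         colour = block_x)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.7) +
    ggplot2::geom_hline(yintercept = attr(tab, "fwe_line"),
                        linetype = "dashed") +
    ggplot2::labs(x = NULL, y = expression(-log[10] ~ p),
                  colour = "block") +
    ggplot2::theme_minimal()
  if (!is.na(attr(tab, "fdr_line")))
    p <- p + ggplot2::geom_hline(yintercept = attr(tab, "fdr_line"),
                                 linetype = "dotted")
  p
}
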