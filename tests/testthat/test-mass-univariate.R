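two_tables <- function(X, Y) {
  n <- nrow(X)
  ids <- sprintf("S%04d", seq_len(n))
  rownames(X) <- rownames(Y) <- ids
  mx <- data.frame(variable = paste0("x", seq_len(ncol(X))), block = "bx",
                   subdomain = "sx", polarity = 1)
  my <- data.frame(variable = paste0("y", seq_len(ncol(Y))), block = "by",
                   subdomain = "sy", polarity = 1)
  colnames(X) <- mx$variable; colnames(Y) <- my$variable
  list(x = phenotype_table(X, mx), y = phenotype_table(Y, my))
}

test_that("pairwise correlations match cor.test on pairwise-complete data", {
  withr::with_seed(3, {
    X <- matrix(rnorm(40), 10, 4)
    Y <- matrix(rnorm(30), 10, 3)
    X[sample(40, 6)] <- NA
    Y[sample(30, 4)] <- NA
    tabs <- two_tables(X, Y)
    rec <- pairwise_correlations(tabs$x, tabs$y)
    expect_equal(nrow(rec), 12L)
    Xv <- tabs$x$values; Yv <- tabs$y$values
    for (k in seq_len(nrow(rec))) {
      i <- match(rec$var_x[k], colnames(Xv))
      j <- match(rec$var_y[k], colnames(Yv))
      ok <- complete.cases(Xv[, i], Yv[, j])
      expect_equal(rec$n_eff[k], sum(ok))
      if (rec$excluded[k]) next
      ct <- cor.test(Xv[ok, i], Yv[ok, j])
      expect_equal(rec$r[k], unname(ct$estimate), tolerance = 1e-12)
      expect_equal(rec$p[k], ct$p.value, tolerance = 1e-12)
    }
  })
})

test_that("a variable correlated with itself sits at the numerical floor", {
  x <- matrix(rnorm(20), 20, 1)
  tabs <- two_tables(x, x)
  rec <- pairwise_correlations(tabs$x, tabs$y)
  expect_equal(rec$r, 1)
  expect_equal(rec$p, .Machine$double.xmin)
  expect_true(is.finite(rec$neg_log10_p))
})

test_that("the five-point worked pair matches a t-density quadrature oracle", {
  tabs <- two_tables(matrix(c(1, 2, 3, 4, 5), 5, 1),
                     matrix(c(2, 1, 4, 3, 5), 5, 1))
  rec <- pairwise_correlations(tabs$x, tabs$y)
  expect_equal(rec$r, 0.8)
  tstat <- 0.8 * sqrt(3 / (1 - 0.64))
  p_oracle <- 2 * integrate(function(u) dt(u, df = 3), tstat, Inf,
                            rel.tol = 1e-12)$value
  expect_equal(rec$p, p_oracle, tolerance = 1e-9)
})

test_that("correlations are invariant to affine transforms applied before normalization", {
  withr::with_seed(5, {
    X <- matrix(rnorm(120), 30, 4)
    Y <- matrix(rnorm(90), 30, 3)
    t1 <- two_tables(qn_safe(X), qn_safe(Y))
    t2 <- two_tables(qn_safe(3 * X - 7), qn_safe(Y * 0.1 + 2))
    expect_equal(pairwise_correlations(t1$x, t1$y)$r,
                 pairwise_correlations(t2$x, t2$y)$r, tolerance = 1e-12)
  })
})

test_that("multiple-testing control follows Bonferroni and BH step-up", {
  rec <- data.frame(var_x = letters[1:5], block_x = "b", var_y = "y",
                    block_y = "b", r = 0.1, n_eff = 50,
                    p = c(0.001, 0.01, 0.02, 0.03, 0.9),
                    excluded = FALSE)
  rec$neg_log10_p <- -log10(rec$p)
  out <- multiple_testing(rec, alpha = 0.05)
  # BH step-up by hand: largest k with p(k) <= k * 0.05 / 5 is k = 4
  expect_equal(sum(out$records$pass_fdr), 4L)
  # p <= alpha/m is inclusive, so 0.001 and 0.01 both pass FWE
  expect_equal(sum(out$records$pass_fwe), 2L)
  expect_equal(out$report$bonferroni_p, 0.01)
  expect_equal(out$report$fdr_p, 0.03)
  # m = 1: Bonferroni threshold is alpha itself
  one <- multiple_testing(rec[1, ], alpha = 0.05)
  expect_equal(one$report$bonferroni_p, 0.05)
  # user-supplied effective number of tests
  eff <- multiple_testing(rec, alpha = 0.05, m_eff = 2)
  expect_equal(eff$report$bonferroni_p, 0.025)
  expect_error(multiple_testing(rec[0, ]), "empty")
})

test_that("BH never yields fewer discoveries than Bonferroni", {
  withr::with_seed(21, {
    for (i in 1:20) {
      p <- runif(200)^sample(1:4, 1)
      rec <- data.frame(var_x = paste0("v", 1:200), block_x = "b",
                        var_y = "y", block_y = "b", r = 0, n_eff = 50,
                        p = p, excluded = FALSE, neg_log10_p = -log10(p))
      out <- multiple_testing(rec)
      expect_gte(out$report$n_pass_fdr, out$report$n_pass_fwe)
    }
  })
})

test_that("the screen is calibrated under a global null", {
  # 50 replicates of a null family; the mean family-level fraction of
  # p < 0.05 stays within 3 standard errors of 0.05
  fracs <- vapply(1:50, function(seed) {
    b <- generate_cohort(cohort_config(
      n_subjects = 60, idp_manifest = tiny_idp_manifest(12),
      nonidp_manifest = tiny_nonidp_manifest(8), rho_target = 0,
      missing_rate_nonidp = 0, seed = seed))
    prep <- preprocess_cohort(b$idp_table, b$nonidp_table, b$confounds,
                              impute = FALSE)
    rec <- pairwise_correlations(prep$idp, prep$nonidp)
    mean(rec$p < 0.05)
  }, numeric(1))
  expect_lt(abs(mean(fracs) - 0.05), 3 * sd(fracs) / sqrt(50))
})

test_that("a constructed Simpson instance is flagged, homogeneous groups are not", {
  withr::with_seed(33, {
    # within both groups slope -0.5; group mean offsets induce pooled r > 0
    n <- 60
    t1 <- rnorm(n); t2 <- rnorm(n)
    x <- c(t1, t2 + 6)
    y <- c(-0.5 * t1 + rnorm(n, sd = 0.3), -0.5 * t2 + 4 + rnorm(n, sd = 0.3))
    tabs <- two_tables(matrix(x), matrix(y))
    rec <- multiple_testing(pairwise_correlations(tabs$x, tabs$y))
    expect_true(rec$records$pass_fwe[1])
    expect_gt(rec$records$r[1], 0)
    label <- factor(rep(c("improver", "decliner"), each = n),
                    levels = c("improver", "decliner", "excluded"))
    out <- subgroup_consistency(tabs$x, tabs$y, label, rec$records)
    expect_true(out$simpson_flag[1])
    expect_lt(out$r_improver[1], 0)

    # homogeneous groups: same generating model in both halves, no flags
    flags <- vapply(1:20, function(seed) {
      withr::with_seed(seed, {
        xx <- rnorm(2 * n); yy <- 0.6 * xx + rnorm(2 * n)
        tt <- two_tables(matrix(xx), matrix(yy))
        rr <- multiple_testing(pairwise_correlations(tt$x, tt$y))
        oo <- subgroup_consistency(tt$x, tt$y, label, rr$records)
        any(oo$simpson_flag)
      })
    }, logical(1))
    expect_false(any(flags))

    # a degenerate group (< 4 subjects) warns and yields NA
    lab3 <- factor(c(rep("improver", 3), rep("decliner", 2 * n - 3)),
                   levels = levels(label))
    expect_warning(o3 <- subgroup_consistency(tabs$x, tabs$y, lab3,
                                              rec$records),
                   "4 usable subjects")
    expect_true(is.na(o3$r_improver[1]))
  })
})

test_that("the Manhattan export carries consistent heights and thresholds", {
  withr::with_seed(44, {
    X <- matrix(rnorm(200), 20, 10)
    Y <- matrix(rnorm(60), 20, 3)
    tabs <- two_tables(X, Y)
    flagged <- multiple_testing(pairwise_correlations(tabs$x, tabs$y))
    tab <- manhattan_export(flagged)
    expect_equal(nrow(tab), 30L)
    expect_equal(attr(tab, "fwe_line"),
                 -log10(flagged$report$bonferroni_p))
    # -log10 arithmetic: p = 0.01 plots at 2
    expect_equal(tab$neg_log10_p,
                 -log10(flagged$records$p[!flagged$records$excluded]))
  })
})
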