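test_that("fit_cca matches the brute-force generalized eigenproblem", {
  withr::with_seed(101, {
    worst <- 0
    for (i in 1:100) {
      dx <- sample(2:4, 1); dy <- sample(2:5, 1)
      x <- matrix(rnorm(20 * dx), 20, dx)
      y <- matrix(rnorm(20 * dy), 20, dy)
      rc <- fit_cca(x, y)$rc
      worst <- max(worst, max(abs(rc - eigen_cca_rc(x, y))))
    }
    expect_lt(worst, 1e-8)
  })
})

test_that("canonical correlations hit their analytic boundary cases", {
  withr::with_seed(7, {
    x <- matrix(rnorm(60), 20, 3)
    expect_lt(max(abs(fit_cca(x, x)$rc - 1)), 1e-10)
    # bivariate reduction: rc_1 = |r|
    a <- rnorm(25); b <- -0.6 * a + rnorm(25)
    expect_equal(fit_cca(matrix(a), matrix(b))$rc, abs(cor(a, b)))
  })
})

test_that("canonical variates are unit-variance and mutually uncorrelated", {
  withr::with_seed(8, {
    x <- matrix(rnorm(200), 50, 4)
    y <- matrix(rnorm(150), 50, 3)
    fit <- fit_cca(x, y)
    expect_equal(apply(fit$U, 2, sd), rep(1, 3), tolerance = 1e-10,
                 ignore_attr = TRUE)
    cuv <- cor(fit$U, fit$V)
    expect_equal(diag(cuv), fit$rc, tolerance = 1e-10, ignore_attr = TRUE)
    expect_lt(max(abs(cuv[upper.tri(cuv)]), abs(cuv[lower.tri(cuv)])), 1e-8)
    expect_lt(max(abs(cor(fit$U)[upper.tri(diag(3))])), 1e-8)
  })
})

test_that("rank-deficient input is reduced with a warning", {
  withr::with_seed(9, {
    x <- matrix(rnorm(60), 20, 3)
    x <- cbind(x, x[, 1] + x[, 2])        # dependent column
    y <- matrix(rnorm(40), 20, 2)
    expect_warning(fit <- fit_cca(x, y), "rank-deficient")
    expect_equal(length(fit$rc), 2L)
    expect_equal(fit$rank_x, 3L)
  })
})

test_that("pca_reduce agrees with an independent eigendecomposition", {
  m <- matrix(c(2, 0, 1, 1, 1, 0, 0, 2, 1, 3, 1, 2), 4, 3)
  p <- pca_reduce(m, d = 3)
  ev <- eigen(cov(m))
  # component variances: singular values vs eigenvalues of the covariance
  expect_equal(apply(p$scores, 2, var), ev$values, tolerance = 1e-10,
               ignore_attr = TRUE)
  # basis matches within sign
  for (j in 1:2)
    expect_equal(abs(sum(p$basis[, j] * ev$vectors[, j])), 1,
                 tolerance = 1e-8)
  expect_equal(p$cumulative_variance[3], 1, tolerance = 1e-10)
  expect_error(pca_reduce(m, d = 5), "exceeds")
  expect_error(pca_reduce(matrix(c(1, NA, 2, 3), 2, 2), d = 1), "complete")
})

test_that("pca_reduce keeps the study's reduced dimensions", {
  withr::with_seed(11, {
    m <- matrix(rnorm(193 * 60), 193, 60)
    p <- pca_reduce(m, d = 30)
    expect_equal(dim(p$scores), c(193L, 30L))
    expect_true(all(diff(p$variance_explained) <= 1e-12))
    expect_true(all(diff(p$cumulative_variance) >= 0))
  })
})

test_that("permutation FWE p-values follow the +1 convention and are monotone", {
  withr::with_seed(13, {
    n <- 80
    z <- rnorm(n)
    x <- matrix(rnorm(n * 3), n, 3) + z     # strong shared signal
    y <- matrix(rnorm(n * 3), n, 3) + z
    fit <- permutation_fwe(x, y, n_perm = 199, seed = 5)
    expect_equal(fit$p_fwe[1], 1 / 200)     # observed above every null max
    expect_true(all(diff(fit$p_fwe) >= 0))
    expect_warning(permutation_fwe(x, y, n_perm = 50, seed = 5),
                   "resolution")
  })
})

test_that("identically permuting subjects of both tables changes nothing", {
  withr::with_seed(14, {
    n <- 60
    x <- matrix(rnorm(n * 4), n, 4)
    y <- matrix(rnorm(n * 3), n, 3)
    f1 <- permutation_fwe(x, y, n_perm = 499, seed = 21)
    pr <- sample.int(n)
    f2 <- permutation_fwe(x[pr, ], y[pr, ], n_perm = 499, seed = 21)
    expect_equal(f1$rc, f2$rc, tolerance = 1e-10)
    # the null stream composes with the relabeling, so p-values agree in
    # distribution: check within Monte-Carlo resolution
    expect_lt(max(abs(f1$p_fwe - f2$p_fwe)), 0.1)
  })
})

test_that("structure loadings equal direct correlations and square to r2", {
  withr::with_seed(15, {
    n <- 40
    vals <- matrix(rnorm(n * 10), n, 10)
    man <- data.frame(variable = paste0("v", 1:10), block = "b",
                      subdomain = rep(c("cognition", "health"), 5),
                      polarity = rep(c(1, -1), 5))
    colnames(vals) <- man$variable
    rownames(vals) <- sprintf("S%04d", 1:n)
    tab <- phenotype_table(vals, man)
    u <- rnorm(n)
    ld <- structure_loadings(tab, u)
    # independent covariance-based oracle
    for (j in 1:10) {
      v <- man$polarity[j] * vals[, j]
      r_direct <- (mean(v * u) - mean(v) * mean(u)) /
        sqrt((mean(v^2) - mean(v)^2) * (mean(u^2) - mean(u)^2))
      expect_equal(ld$loading[j], r_direct, tolerance = 1e-12)
    }
    expect_equal(ld$r2, ld$loading^2)
    expect_equal(ld$reported, abs(ld$loading) >= 0.2)
    # a variable identical to the variate loads at exactly 1
    tab$values[, 1] <- u
    expect_equal(structure_loadings(tab, u)$loading[1], 1)
  })
})

test_that("mode orientation follows the cognition anchor", {
  ld <- data.frame(variable = c("a", "b", "c"), block = "b",
                   subdomain = c("cognition", "cognition", "health"),
                   polarity = 1, loading = c(-0.5, -0.3, 0.4))
  other <- data.frame(variable = "z", block = "b", subdomain = "tbss_fa",
                      polarity = 1, loading = 0.2)
  out <- orient_mode(other, ld)
  expect_true(out$flipped)
  expect_equal(out$nonidp$loading, c(0.5, 0.3, -0.4))
  expect_equal(out$idp$loading, -0.2)
  out2 <- orient_mode(other, transform(ld, loading = -loading))
  expect_false(out2$flipped)
})

test_that("subdomain importance splits squared loadings by sign", {
  one <- data.frame(variable = "v", block = "b", subdomain = "s",
                    polarity = 1, loading = 0.5)
  imp <- subdomain_importance(one)
  expect_equal(imp$positive_r2_mean, 0.25)
  expect_equal(imp$negative_r2_mean, 0)
  # {+0.6, -0.3, 0}: positive bar = (0.36 + 0) / 3, negative = 0.09 / 3;
  # enumeration: members 1 and 3 count as non-negative, member 2 negative
  three <- data.frame(variable = c("a", "b", "c"), block = "b",
                      subdomain = "s", polarity = 1,
                      loading = c(0.6, -0.3, 0))
  imp3 <- subdomain_importance(three)
  expect_equal(imp3$positive_r2_mean, 0.36 / 3)
  expect_equal(imp3$negative_r2_mean, 0.09 / 3)
  zero <- transform(three, loading = 0)
  impz <- subdomain_importance(zero)
  expect_equal(impz$positive_r2_mean + impz$negative_r2_mean, 0)
})

test_that("Tucker congruence behaves as the normalized inner product", {
  a <- c(0.3, -0.2, 0.8)
  expect_equal(factor_congruence(a, 2 * a), 1)
  expect_equal(factor_congruence(c(1, 0), c(0, 1)), 0)
  expect_equal(factor_congruence(c(1, 0, 1), c(1, 1, 0)), 0.5)
  expect_equal(factor_congruence(c(a, NA), c(2 * a, 0.1)), 1) # pairwise drop
  expect_error(factor_congruence(c(0, 0), c(1, 1)), "zero-norm")
})

test_that("estimated first canonical correlation is consistent at large n", {
  cfg <- cohort_config(n_subjects = 5000,
                       idp_manifest = idp_manifest()[seq_len(60), ],
                       nonidp_manifest = tiny_nonidp_manifest(40),
                       missing_rate_nonidp = 0, seed = 19)
  b <- generate_cohort(cfg)
  prep <- preprocess_cohort(b$idp_table, b$nonidp_table, b$confounds,
                            impute = FALSE)
  fit <- fit_cca(pca_reduce(prep$idp, 30)$scores,
                 pca_reduce(prep$nonidp, 30)$scores)
  expect_lt(abs(fit$rc[1] - 0.75), 0.02)
})

test_that("subgroup loadings from a common generating model are congruent", {
  phis <- t(vapply(1:10, function(seed) {
    b <- generate_cohort(cohort_config(n_subjects = 193, seed = seed))
    prep <- preprocess_cohort(b$idp_table, b$nonidp_table, b$confounds,
                              seed = stage_seed(seed, 2L))
    g <- select_extreme_groups(
      residualized_change(b$iq_panel$iq20, b$iq_panel$iq57))
    an <- cca_mode_analysis(prep$idp_imputed, prep$nonidp_imputed,
                            d = 30, n_perm = 199,
                            seed = stage_seed(seed, 4L), groups = g,
                            idp_original = prep$idp,
                            nonidp_original = prep$nonidp)
    c(an$congruence$phi_idp, an$congruence$phi_nonidp)
  }, numeric(2)))
  # the study context reports 0.75 (IDP) and 0.71 (non-IDP)
  expect_gte(median(phis[, 1]), 0.6)
  expect_gte(median(phis[, 2]), 0.6)
})
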