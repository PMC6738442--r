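# reduced-size manifests and configs for fast module tests; the full
# 453 x 70 layout is exercised where the bookkeeping itself is under test

tiny_idp_manifest <- function(p = 24) {
  man <- idp_manifest()
  # keep continuous TBSS rows: homogeneous, no ordinal thresholding
  man <- man[man$block == "TBSS", ][seq_len(p), ]
  rownames(man) <- NULL
  man
}

tiny_nonidp_manifest <- function(p = 16, continuous_only = TRUE) {
  man <- nonidp_manifest()
  if (continuous_only) man <- man[is.na(man$levels), ]
  man <- man[seq_len(p), ]
  rownames(man) <- NULL
  man
}

tiny_config <- function(n_subjects = 60, seed = 1L, ...) {
  cohort_config(n_subjects = n_subjects,
                idp_manifest = tiny_idp_manifest(),
                nonidp_manifest = tiny_nonidp_manifest(),
                seed = seed, ...)
}

# brute-force canonical correlations from the generalized eigenproblem
# inv(Sxx) Sxy inv(Syy) Syx -- independent of the QR-SVD implementation
eigen_cca_rc <- function(x, y) {
  sxx <- stats::cov(x); syy <- stats::cov(y); sxy <- stats::cov(x, y)
  m <- solve(sxx, sxy %*% solve(syy, t(sxy)))
  ev <- eigen(m, only.values = TRUE)$values
  sort(sqrt(pmax(Re(ev), 0)), decreasing = TRUE)[seq_len(min(ncol(x), ncol(y)))]
}

qn_safe <- function(m) {
  out <- apply(m, 2, quantile_normalize)
  dimnames(out) <- dimnames(m)
  out
}

# normal quantile by bisection on pnorm: independent of qnorm
bisect_qnorm <- function(p, lo = -10, hi = 10, tol = 1e-10) {
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (stats::pnorm(mid) < p) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# two vectors with an exact given sample correlation
exact_cor_pair <- function(r, n = 50, seed = 1) {
  withr::with_seed(seed, {
    u <- stats::rnorm(n)
    w <- stats::residuals(stats::lm(stats::rnorm(n) ~ u))
    us <- drop(scale(u)); ws <- drop(scale(w))
    x <- us
    y <- r * us + sqrt(1 - r^2) * ws
    list(x = x, y = y)
  })
}
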