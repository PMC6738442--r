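#' PCA reduction of a phenotype table
#'
#' Column-centered SVD of the complete (post-imputation) matrix; scores are
#' the top-d left singular vectors scaled by their singular values, i.e.
#' subject-eigenvector coordinates, and variance fractions come from the
#' squared singular values.
#'
#' @param table A complete [phenotype_table()] or numeric matrix.
#' @param d Number of components (default 30); must not exceed
#'   `min(subjects, variables)`.
#' @return A `pca_reduction` list: `scores` (subjects x d), `basis`
#'   (variables x d), `variance_explained`, `cumulative_variance`, `d`,
#'   `center`.
#' @export
pca_reduce <- function(table, d = 30L) {
  vals <- if (inherits(table, "phenotype_table")) table$values else table
  if (anyNA(vals)) stop("pca_reduce requires a complete table (impute first)")
  d <- as.integer(d)
  if (d > min(dim(vals)))
    stop("d exceeds min(subjects, variables)")
  mu <- colMeans(vals)
  xc <- sweep(vals, 2, mu)
  s <- svd(xc)
  ve <- s$d^2 / sum(s$d^2)
  scores <- s$u[, seq_len(d), drop = FALSE] %*% diag(s$d[seq_len(d)], d)
  rownames(scores) <- rownames(vals)
  colnames(scores) <- paste0("PC", seq_len(d))
  basis <- s$v[, seq_len(d), drop = FALSE]
  rownames(basis) <- colnames(vals)
  colnames(basis) <- colnames(scores)
  structure(list(scores = scores, basis = basis,
                 variance_explained = ve[seq_len(d)],
                 cumulative_variance = cumsum(ve)[seq_len(d)],
                 d = d, center = mu),
            class = "pca_reduction")
}

#' @export
print.pca_reduction <- function(x, ...) {
  cat(sprintf("pca_reduction: %d subjects x %d components (%.1f%% variance)\n",
              nrow(x$scores), x$d, 100 * x$cumulative_variance[x$d]))
  invisible(x)
}

#' Canonical correlation analysis of two score matrices
#'
#' Fits U = X A and V = Y B maximizing corr(U_i, V_i) subject to the
#' variates being mutually uncorrelated with unit variance. Computed by the
#' numerically stable QR-then-SVD route: thin QR of each centered matrix,
#' SVD of the cross-product of the Q factors. Signs are fixed by making the
#' largest-magnitude element of each column of A positive. Rank-deficient
#' inputs are reduced to their effective rank with a warning.
#'
#' @param xp,yp Numeric matrices on the same subjects (e.g. PCA scores).
#' @return A `cca_result` list: weight matrices `A`, `B`, variates `U`,
#'   `V` (unit variance), canonical correlations `rc` (descending), and
#'   the effective ranks used.
#' @export
fit_cca <- function(xp, yp) {
  xp <- as.matrix(xp); yp <- as.matrix(yp)
  if (nrow(xp) != nrow(yp)) stop("xp and yp must share subjects")
  n <- nrow(xp)
  xc <- sweep(xp, 2, colMeans(xp))
  yc <- sweep(yp, 2, colMeans(yp))
  qx <- qr(xc)
  qy <- qr(yc)
  rx <- qx$rank; ry <- qy$rank
  if (rx < ncol(xc) || ry < ncol(yc))
    warning(sprintf("rank-deficient input (x: %d/%d, y: %d/%d); reduced",
                    rx, ncol(xc), ry, ncol(yc)))
  Qx <- qr.Q(qx)[, seq_len(rx), drop = FALSE]
  Qy <- qr.Q(qy)[, seq_len(ry), drop = FALSE]
  Rx <- qr.R(qx)[seq_len(rx), seq_len(rx), drop = FALSE]
  Ry <- qr.R(qy)[seq_len(ry), seq_len(ry), drop = FALSE]
  k <- min(rx, ry)
  s <- svd(crossprod(Qx, Qy), nu = k, nv = k)
  rc <- pmin(pmax(s$d[seq_len(k)], 0), 1)
  # weights for the pivoted, rank-retained columns; dropped (dependent)
  # columns receive zero weight
  Ared <- backsolve(Rx, s$u) * sqrt(n - 1)
  Bred <- backsolve(Ry, s$v) * sqrt(n - 1)
  A <- matrix(0, ncol(xc), k)
  B <- matrix(0, ncol(yc), k)
  A[qx$pivot[seq_len(rx)], ] <- Ared
  B[qy$pivot[seq_len(ry)], ] <- Bred
  # sign convention: largest-magnitude element of each x-weight positive
  for (j in seq_len(k)) {
    sgn <- sign(A[which.max(abs(A[, j])), j])
    if (sgn < 0) { A[, j] <- -A[, j]; B[, j] <- -B[, j] }
  }
  U <- xc %*% A
  V <- yc %*% B
  dimnames(A) <- list(colnames(xp), paste0("mode", seq_len(k)))
  dimnames(B) <- list(colnames(yp), colnames(A))
  dimnames(U) <- list(rownames(xp), colnames(A))
  dimnames(V) <- dimnames(U)
  structure(list(A = A, B = B, U = U, V = V, rc = rc,
                 rank_x = rx, rank_y = ry),
            class = "cca_result")
}

#' @export
print.cca_result <- function(x, ...) {
  cat(sprintf("cca_result: %d modes; rc_1 = %.3f\n", length(x$rc), x$rc[1]))
  if (!is.null(x$p_fwe))
    cat(sprintf("  p_fwe_1 = %.4g (%d permutations)\n", x$p_fwe[1], x$n_perm))
  invisible(x)
}

# largest canonical correlation given precomputed Q factors, with rows of
# Qy permuted; column means are unchanged by row permutation so the Q
# factors can be reused across permutations
max_rc_perm <- function(Qx, Qy, perm) {
  svd(crossprod(Qx, Qy[perm, , drop = FALSE]), nu = 0, nv = 0)$d[1]
}

#' Max-statistic permutation familywise inference for CCA
#'
#' Permutes the subject rows of `yp` relative to `xp` `n_perm` times,
#' refits the CCA after each permutation, and records the largest canonical
#' correlation. Each observed rc_i is compared against this null
#' distribution of the maximum, giving familywise-error-corrected p-values
#' over all modes: `p_fwe_i = (1 + #\{max_null >= rc_i\}) / (n_perm + 1)`.
#' The +1 convention avoids zero p-values; p_fwe is non-decreasing across
#' modes by construction.
#'
#' @param xp,yp Score matrices as given to [fit_cca()].
#' @param n_perm Number of permutations (default 10000); fewer than 100
#'   triggers a resolution warning.
#' @param seed Integer seed driving the permutation stream.
#' @param fit Optional pre-computed [fit_cca()] result for the observed
#'   data.
#' @return The `cca_result` augmented with `p_fwe`, `n_perm`, and the null
#'   maxima `null_max`.
#' @export
permutation_fwe <- function(xp, yp, n_perm = 10000L, seed = 1L, fit = NULL) {
  n_perm <- as.integer(n_perm)
  if (n_perm < 100L)
    warning("fewer than 100 permutations: p-value resolution is coarse")
  if (is.null(fit)) fit <- fit_cca(xp, yp)
  xc <- sweep(as.matrix(xp), 2, colMeans(as.matrix(xp)))
  yc <- sweep(as.matrix(yp), 2, colMeans(as.matrix(yp)))
  qx <- qr(xc); qy <- qr(yc)
  Qx <- qr.Q(qx)[, seq_len(qx$rank), drop = FALSE]
  Qy <- qr.Q(qy)[, seq_len(qy$rank), drop = FALSE]
  n <- nrow(Qx)
  null_max <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_perm),
           function(i) max_rc_perm(Qx, Qy, sample.int(n)),
           numeric(1))
  })
  fit$p_fwe <- vapply(fit$rc,
                      function(r) (1 + sum(null_max >= r)) / (n_perm + 1),
                      numeric(1))
  fit$n_perm <- n_perm
  fit$null_max <- null_max
  fit
}

#' Canonical structure loadings
#'
#' Correlation between each (polarity-adjusted) observed variable and a
#' canonical variate — the canonical structure coefficients, analogous to
#' factor loadings. Variables whose absolute loading falls below 0.2 are
#' marked not reported, following the display convention for mode
#' summaries. Constant variables give a missing loading.
#'
#' @param table The preprocessed (deconfounded, pre-PCA) [phenotype_table()].
#' @param variate Canonical variate vector (a column of U or V) on the same
#'   subjects.
#' @param report_threshold Absolute-loading display threshold (default 0.2).
#' @return Data frame: `variable`, `block`, `subdomain`, `polarity`,
#'   `loading`, `r2`, `reported`.
#' @export
structure_loadings <- function(table, variate, report_threshold = 0.2) {
  stopifnot(nrow(table$values) == length(variate))
  vals <- sweep(table$values, 2, table$manifest$polarity, `*`)
  suppressWarnings(
    loading <- as.vector(stats::cor(vals, variate,
                                    use = "pairwise.complete.obs")))
  out <- data.frame(variable = table$manifest$variable,
                    block = table$manifest$block,
                    subdomain = table$manifest$subdomain,
                    polarity = table$manifest$polarity,
                    loading = loading)
  out$r2 <- out$loading^2
  out$reported <- !is.na(out$loading) & abs(out$loading) >= report_threshold
  out
}

#' Orient a CCA mode along the positive-negative axis
#'
#' CCA signs are arbitrary; this fixes the global sign of one mode so that
#' the mean loading of the cognition subdomain is positive, matching the
#' positive-negative framing of the mode. Returns the possibly sign-flipped
#' loadings for both sets plus the flip indicator (to be applied to U, V
#' and the weight columns as well).
#'
#' @param idp_loadings,nonidp_loadings Loading tables from
#'   [structure_loadings()].
#' @param orient_subdomain Subdomain whose mean loading anchors the sign
#'   (default "cognition", from the non-IDP set).
#' @return List `idp`, `nonidp`, `flipped`.
#' @export
orient_mode <- function(idp_loadings, nonidp_loadings,
                        orient_subdomain = "cognition") {
  anchor <- nonidp_loadings$loading[
    nonidp_loadings$subdomain == orient_subdomain]
  flip <- isTRUE(mean(anchor, na.rm = TRUE) < 0)
  if (flip) {
    idp_loadings$loading <- -idp_loadings$loading
    nonidp_loadings$loading <- -nonidp_loadings$loading
  }
  list(idp = idp_loadings, nonidp = nonidp_loadings, flipped = flip)
}

#' Subdomain importance of a mode
#'
#' For each subdomain, the positive bar is the sum of squared loadings over
#' non-negatively signed loadings divided by the subdomain's total member
#' count, and the negative bar likewise over negatively signed loadings —
#' so an all-positive subdomain's positive bar equals its plain mean
#' squared loading. Missing loadings count toward the member total but
#' contribute nothing.
#'
#' @param loadings Loading table from [structure_loadings()] (polarity
#'   already applied there; sign conventions from [orient_mode()]).
#' @return Data frame: `subdomain`, `n`, `positive_r2_mean`,
#'   `negative_r2_mean`.
#' @export
subdomain_importance <- function(loadings) {
  sds <- unique(loadings$subdomain)
  out <- do.call(rbind, lapply(sds, function(s) {
    l <- loadings$loading[loadings$subdomain == s]
    n <- length(l)
    if (all(is.na(l)))
      warning(sprintf("subdomain %s has no usable loadings", s))
    l <- l[!is.na(l)]
    data.frame(subdomain = s, n = n,
               positive_r2_mean = sum(l[l >= 0]^2) / n,
               negative_r2_mean = sum(l[l < 0]^2) / n)
  }))
  rownames(out) <- NULL
  out
}

#' Tucker coefficient of factor congruence
#'
#' `phi = sum(a*b) / sqrt(sum(a^2) * sum(b^2))`: the normalized inner
#' product of two loading vectors. Scale-invariant; phi = 1 iff the vectors
#' are proportional with positive factor. Pairs with a missing loading in
#' either vector are dropped.
#'
#' @param loadings_a,loadings_b Numeric loading vectors over the same
#'   variables in the same order.
#' @return The congruence coefficient in `[-1, 1]`.
#' @export
factor_congruence <- function(loadings_a, loadings_b) {
  stopifnot(length(loadings_a) == length(loadings_b),
            length(loadings_a) >= 2)
  ok <- !is.na(loadings_a) & !is.na(loadings_b)
  a <- loadings_a[ok]; b <- loadings_b[ok]
  na <- sum(a^2); nb <- sum(b^2)
  if (na == 0 || nb == 0) stop("zero-norm loading vector: congruence undefined")
  sum(a * b) / sqrt(na * nb)
}

#' PCA-reduced CCA with permutation inference and post-hoc summaries
#'
#' The full multivariate stage: reduce both preprocessed, completed tables
#' to `d` principal components, fit the CCA, attach max-statistic
#' permutation FWE p-values, compute polarity-adjusted structure loadings
#' of mode 1 against the pre-PCA (deconfounded) tables, orient the mode by
#' the cognition subdomain, and summarize subdomain importance. When a
#' group assignment is supplied, per-group loadings and Tucker congruence
#' between the groups are added.
#'
#' @param idp,nonidp Preprocessed complete [phenotype_table()]s (imputed).
#' @param d Number of PCA components per set (default 30, with a guardrail
#'   `d <= n/6` unless `relax_d`).
#' @param n_perm Permutations for FWE inference (default 10000).
#' @param seed Integer seed.
#' @param groups Optional `group_assignment` for subgroup loadings and
#'   congruence.
#' @param relax_d Lift the overfitting guardrail on d.
#' @param idp_original,nonidp_original Deconfounded tables with missing
#'   entries preserved, used (pairwise-complete) for the structure
#'   loadings; default to the imputed inputs.
#' @return A `cca_mode_analysis` list: `pca_idp`, `pca_nonidp`, `cca`
#'   (with `p_fwe`), `loadings_idp`, `loadings_nonidp`, `importance_idp`,
#'   `importance_nonidp`, and optionally `congruence`.
#' @export
cca_mode_analysis <- function(idp, nonidp, d = 30L, n_perm = 10000L,
                              seed = 1L, groups = NULL, relax_d = FALSE,
                              idp_original = idp,
                              nonidp_original = nonidp) {
  n <- nrow(idp$values)
  if (!relax_d && d > n / 6)
    stop("d > n/6 risks overfitting; set relax_d = TRUE to override")
  px <- pca_reduce(idp, d)
  py <- pca_reduce(nonidp, d)
  cca <- permutation_fwe(px$scores, py$scores, n_perm = n_perm, seed = seed)
  lx <- structure_loadings(idp_original, cca$U[, 1])
  ly <- structure_loadings(nonidp_original, cca$V[, 1])
  orient <- orient_mode(lx, ly)
  if (orient$flipped) {
    cca$U[, 1] <- -cca$U[, 1]; cca$V[, 1] <- -cca$V[, 1]
    cca$A[, 1] <- -cca$A[, 1]; cca$B[, 1] <- -cca$B[, 1]
  }
  out <- list(pca_idp = px, pca_nonidp = py, cca = cca,
              loadings_idp = orient$idp, loadings_nonidp = orient$nonidp,
              importance_idp = subdomain_importance(orient$idp),
              importance_nonidp = subdomain_importance(orient$nonidp))
  if (!is.null(groups)) {
    label <- if (inherits(groups, "group_assignment")) groups$label else groups
    # post-hoc correlations per subgroup: the whole-group variates are
    # restricted to each subgroup's rows and the loadings recomputed there
    sub_load <- function(grp) {
      rows <- which(label == grp)
      lx_g <- structure_loadings(subset_table(idp_original, rows),
                                 cca$U[rows, 1])
      ly_g <- structure_loadings(subset_table(nonidp_original, rows),
                                 cca$V[rows, 1])
      list(idp = lx_g, nonidp = ly_g)
    }
    la <- sub_load("improver")
    lb <- sub_load("decliner")
    out$subgroup_loadings <- list(improver = la, decliner = lb)
    out$congruence <- list(
      phi_idp = factor_congruence(la$idp$loading, lb$idp$loading),
      phi_nonidp = factor_congruence(la$nonidp$loading, lb$nonidp$loading))
  }
  class(out) <- "cca_mode_analysis"
  out
}

subset_table <- function(table, rows) {
  table$values <- table$values[rows, , drop = FALSE]
  table
}

#' @export
print.cca_mode_analysis <- function(x, ...) {
  cat(sprintf("cca_mode_analysis: %d modes, rc_1 = %.3f, p_fwe_1 = %.4g\n",
              length(x$cca$rc), x$cca$rc[1], x$cca$p_fwe[1]))
  if (!is.null(x$congruence))
    cat(sprintf("  congruence: IDP %.2f, non-IDP %.2f\n",
                x$congruence$phi_idp, x$congruence$phi_nonidp))
  invisible(x)
}
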