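#' Rank-based inverse normal (quantile) transformation
#'
#' Replaces the m non-missing entries of a vector by
#' \eqn{\Phi^{-1}((r - 3/8)/(m + 1/4))} where r is the (average-tie) rank —
#' the Blom convention. Missing entries stay missing. The output is a
#' monotone function of the input ranks, so any monotone transform applied
#' beforehand leaves it unchanged (up to ties).
#'
#' @param x Numeric vector, possibly with `NA`.
#' @return Numeric vector of the same length.
#' @export
quantile_normalize <- function(x) {
  obs <- !is.na(x)
  m <- sum(obs)
  if (m < 3) stop("quantile_normalize needs at least 3 non-missing values")
  v <- x[obs]
  if (max(v) == min(v)) stop("constant column cannot be quantile normalized")
  r <- rank(v, ties.method = "average")
  out <- x
  out[obs] <- stats::qnorm((r - 3 / 8) / (m + 1 / 4))
  out
}

# apply quantile_normalize column-wise to a matrix
qn_matrix <- function(values) {
  out <- apply(values, 2, quantile_normalize)
  dimnames(out) <- dimnames(values)
  out
}

#' Regress confounds out of every variable
#'
#' Each column of the table is replaced by its least-squares residual on
#' an intercept plus the four confound columns. Rows with a missing
#' phenotype value are excluded from that column's fit and stay missing in
#' the output. Confounds should be quantile normalized first (the pipeline
#' wrapper does this). A rank-deficient confound matrix triggers a warning
#' and a minimum-norm (pseudoinverse) fit.
#'
#' @param table A [phenotype_table()].
#' @param confounds A [confound_set()] aligned with `table`, or a numeric
#'   matrix with matching rows.
#' @return A [phenotype_table()] of residuals.
#' @export
deconfound <- function(table, confounds) {
  cm <- if (inherits(confounds, "confound_set")) confounds$values else confounds
  if (inherits(confounds, "confound_set")) check_aligned(table, confounds)
  if (nrow(cm) != nrow(table$values))
    stop("subject rows of table and confounds are misaligned")
  X <- cbind(intercept = 1, cm)
  qrX <- qr(X)
  deficient <- qrX$rank < ncol(X)
  if (deficient)
    warning("rank-deficient confound matrix; using pseudoinverse fit")
  vals <- table$values
  out <- vals
  n_par <- if (deficient) qrX$rank else ncol(X)
  for (j in seq_len(ncol(vals))) {
    y <- vals[, j]
    ok <- !is.na(y)
    if (sum(ok) <= n_par) next
    Xo <- X[ok, , drop = FALSE]
    if (deficient) {
      fit <- svd_lstsq(Xo, y[ok])
    } else {
      fit <- qr.coef(qr(Xo), y[ok])
      fit[is.na(fit)] <- 0
    }
    out[ok, j] <- y[ok] - drop(Xo %*% fit)
  }
  table$values <- out
  table
}

# minimum-norm least squares via SVD (pseudoinverse)
svd_lstsq <- function(X, y) {
  s <- svd(X)
  pos <- s$d > max(dim(X)) * .Machine$double.eps * s$d[1]
  drop(s$v[, pos, drop = FALSE] %*%
         ((crossprod(s$u[, pos, drop = FALSE], y)) / s$d[pos]))
}

#' Low-rank matrix completion by iterative soft-thresholded SVD
#'
#' Fills missing entries by iterating: fill -> SVD -> soft-threshold the
#' singular values by `lambda` (and truncate to `rank_max`) -> reconstruct
#' -> restore observed entries, until the relative Frobenius change between
#' successive iterates drops below `tol` or `max_iter` is reached. Observed
#' entries are never altered. When `lambda` is `NULL` it is chosen by a
#' small internal grid that minimizes reconstruction error on a 5% held-out
#' subset of the observed entries.
#'
#' @param table A [phenotype_table()] (or numeric matrix), already quantile
#'   normalized.
#' @param lambda Soft-threshold for the singular values; `NULL` (default)
#'   selects it by held-out error.
#' @param rank_max Maximum rank of the reconstruction (default
#'   `min(dim) - 1`).
#' @param tol Convergence tolerance on the relative Frobenius change
#'   (default 1e-6).
#' @param max_iter Iteration cap (default 500); non-convergence returns the
#'   best iterate with a warning and `converged = FALSE`.
#' @param seed Seed for the held-out mask used in lambda selection.
#' @return The completed table, with attributes accessible via
#'   [impute_log()]: `lambda`, `iterations`, `converged`.
#' @export
soft_impute <- function(table, lambda = NULL, rank_max = NULL, tol = 1e-6,
                        max_iter = 500L, seed = 1L) {
  is_pt <- inherits(table, "phenotype_table")
  vals <- if (is_pt) table$values else table
  miss <- is.na(vals)
  if (any(colSums(!miss) < 2))
    stop("soft_impute requires at least 2 observed values per column")
  if (!any(miss)) {
    res <- structure(vals, impute_info = list(lambda = NA_real_,
                                              iterations = 0L,
                                              converged = TRUE))
    if (is_pt) { table$values <- vals
                 attr(table, "impute_info") <- attr(res, "impute_info")
                 return(table) }
    return(res)
  }
  if (is.null(rank_max)) rank_max <- min(dim(vals)) - 1L

  if (is.null(lambda)) {
    lambda <- withr::with_seed(as.integer(seed), {
      obs_idx <- which(!miss)
      hold <- sample(obs_idx, max(1L, round(0.05 * length(obs_idx))))
      vals_ho <- vals
      vals_ho[hold] <- NA
      if (any(colSums(!is.na(vals_ho)) < 2)) {
        # degenerate hold-out (tiny table): fall back to a fixed fraction
        0.05 * svd(fill_na(vals), nu = 0, nv = 0)$d[1]
      } else {
        d1 <- svd(fill_na(vals_ho), nu = 0, nv = 0)$d[1]
        grid <- d1 * c(0, 0.01, 0.05, 0.1, 0.2, 0.4)
        err <- vapply(grid, function(l) {
          comp <- impute_iterate(vals_ho, l, rank_max, tol, max_iter)$x
          sqrt(mean((comp[hold] - vals[hold])^2))
        }, numeric(1))
        grid[which.min(err)]
      }
    })
  }
  fit <- impute_iterate(vals, lambda, rank_max, tol, max_iter)
  if (!fit$converged)
    warning(sprintf("soft_impute did not converge in %d iterations", max_iter))
  info <- list(lambda = lambda, iterations = fit$iterations,
               converged = fit$converged, deltas = fit$deltas)
  if (is_pt) {
    table$values <- fit$x
    attr(table, "impute_info") <- info
    table
  } else structure(fit$x, impute_info = info)
}

fill_na <- function(x) {
  mu <- colMeans(x, na.rm = TRUE)
  for (j in seq_len(ncol(x))) x[is.na(x[, j]), j] <- mu[j]
  x
}

impute_iterate <- function(vals, lambda, rank_max, tol, max_iter) {
  miss <- is.na(vals)
  x <- fill_na(vals)
  converged <- FALSE
  it <- 0L
  deltas <- numeric(0)
  for (it in seq_len(max_iter)) {
    s <- svd(x)
    d <- pmax(s$d - lambda, 0)
    k <- min(rank_max, sum(d > 0))
    xh <- if (k >= 1)
      s$u[, 1:k, drop = FALSE] %*% (d[1:k] * t(s$v[, 1:k, drop = FALSE]))
    else matrix(0, nrow(x), ncol(x))
    xnew <- x
    xnew[miss] <- xh[miss]
    delta <- sqrt(sum((xnew - x)^2)) / max(1, sqrt(sum(x^2)))
    deltas[it] <- delta
    x <- xnew
    if (delta < tol) { converged <- TRUE; break }
  }
  dimnames(x) <- dimnames(vals)
  list(x = x, iterations = it, converged = converged, deltas = deltas)
}

#' Imputation log of a completed table
#' @param table Output of [soft_impute()].
#' @return List with `lambda`, `iterations`, `converged`.
#' @export
impute_log <- function(table) attr(table, "impute_info")

#' Normalize, deconfound and (optionally) complete a cohort's tables
#'
#' The pipeline order contract: quantile normalize every phenotype column
#' and every confound column, regress the confounds out of every variable,
#' then soft-impute missing entries (for the CCA path only; the univariate
#' screen uses pairwise-complete observations of the non-imputed tables).
#'
#' @param idp_table,nonidp_table [phenotype_table()]s sharing subjects with
#'   `confounds`.
#' @param confounds A [confound_set()].
#' @param impute Whether to produce the completed (`*_imputed`) tables.
#' @param ... Passed on to [soft_impute()].
#' @return List with `idp`, `nonidp` (normalized + deconfounded, missing
#'   preserved), `idp_imputed`, `nonidp_imputed` (if `impute`), and
#'   `confounds_qn`.
#' @export
preprocess_cohort <- function(idp_table, nonidp_table, confounds,
                              impute = TRUE, ...) {
  check_aligned(idp_table, confounds)
  check_aligned(nonidp_table, confounds)
  cqn <- confounds
  cqn$values <- qn_matrix(confounds$values)
  idp_table$values <- qn_matrix(idp_table$values)
  nonidp_table$values <- qn_matrix(nonidp_table$values)
  idp <- deconfound(idp_table, cqn)
  nonidp <- deconfound(nonidp_table, cqn)
  out <- list(idp = idp, nonidp = nonidp, confounds_qn = cqn)
  if (impute) {
    out$idp_imputed <- if (anyNA(idp$values)) soft_impute(idp, ...) else idp
    out$nonidp_imputed <- if (anyNA(nonidp$values))
      soft_impute(nonidp, ...) else nonidp
  }
  out
}
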