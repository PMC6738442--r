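#' Phenotype table
#'
#' A `phenotype_table` holds a subjects-by-variables numeric matrix together
#' with a per-variable manifest (block, subdomain, polarity and, for
#' thresholded survey items, the number of ordinal levels). Missing values
#' are stored as `NA`. Row names of `values` are the subject identifiers.
#'
#' @param values Numeric matrix, subjects in rows (row names = subject IDs),
#'   variables in columns (column names = variable names).
#' @param manifest Data frame with columns `variable`, `block`, `subdomain`,
#'   `polarity` (+1 or -1) and optionally `levels` (NA for continuous
#'   variables). Row order must match the columns of `values`.
#' @return An object of class `phenotype_table`.
#' @export
phenotype_table <- function(values, manifest) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("S%04d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- manifest$variable
  manifest <- as.data.frame(manifest, stringsAsFactors = FALSE)
  if (!all(c("variable", "block", "subdomain", "polarity") %in% names(manifest)))
    stop("manifest must have columns variable, block, subdomain, polarity")
  if (nrow(manifest) != ncol(values))
    stop("manifest length (", nrow(manifest), ") does not match column count (",
         ncol(values), ")")
  if (anyDuplicated(manifest$variable))
    stop("duplicate variable names in manifest: ",
         paste(unique(manifest$variable[duplicated(manifest$variable)]), collapse = ", "))
  if (anyDuplicated(rownames(values)))
    stop("duplicate subject IDs")
  if (!all(manifest$polarity %in% c(-1, 1)))
    stop("polarity must be +1 or -1")
  if (!identical(colnames(values), manifest$variable))
    colnames(values) <- manifest$variable
  structure(list(values = values, manifest = manifest),
            class = "phenotype_table")
}

#' @export
print.phenotype_table <- function(x, ...) {
  cat(sprintf("phenotype_table: %d subjects x %d variables\n",
              nrow(x$values), ncol(x$values)))
  tab <- table(x$manifest$block)
  cat("blocks:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  nmiss <- sum(is.na(x$values))
  cat(sprintf("missing entries: %d (%.1f%%)\n",
              nmiss, 100 * nmiss / length(x$values)))
  invisible(x)
}

#' @export
dim.phenotype_table <- function(x) dim(x$values)

#' Subject identifiers of a phenotype table
#' @param table A `phenotype_table`.
#' @return Character vector of subject IDs, in row order.
#' @export
subject_ids <- function(table) rownames(table$values)

#' Confound set
#'
#' Subjects-by-4 matrix of the nuisance regressors used throughout: age,
#' absolute motion during MRI, relative motion during MRI, and head size
#' (scaling factor). No missing values are allowed and the row order must
#' match the phenotype tables it is used with.
#'
#' @param values Numeric matrix with 4 columns and subject IDs as row names.
#' @return An object of class `confound_set`.
#' @export
confound_set <- function(values) {
  if (!is.matrix(values) || ncol(values) != 4L)
    stop("confounds must be a subjects x 4 matrix")
  if (anyNA(values)) stop("confounds may not contain missing values")
  if (is.null(colnames(values)))
    colnames(values) <- c("age", "abs_motion", "rel_motion", "head_size")
  structure(list(values = values), class = "confound_set")
}

#' @export
print.confound_set <- function(x, ...) {
  cat(sprintf("confound_set: %d subjects x %d confounds (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(colnames(x$values), collapse = ", ")))
  invisible(x)
}

check_aligned <- function(table, confounds) {
  if (!identical(rownames(table$values), rownames(confounds$values)))
    stop("subject IDs of phenotype table and confounds are misaligned")
  invisible(TRUE)
}
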