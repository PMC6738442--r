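#' Derive a per-stage seed from a master seed
#'
#' Counter-based splitting: each pipeline stage gets an independent,
#' reproducible seed so toggling one stage does not perturb another's
#' random stream. Kept below 2^31 - 1.
#'
#' @param master Master integer seed.
#' @param stage Stage counter (integer).
#' @return Integer seed.
#' @export
stage_seed <- function(master, stage) {
  as.integer((as.numeric(master) * 48271 + as.numeric(stage) * 16807) %%
               2147483647)
}

#' Read a phenotype table from TSV
#'
#' Expects a header row, a first column of subject IDs, and one column per
#' variable; `NA` or an empty field encodes missing. The manifest is read
#' from a companion TSV (columns `variable`, `block`, `subdomain`,
#' `polarity`, optionally `levels`).
#'
#' @param path Path to the values TSV.
#' @param manifest_path Path to the manifest TSV.
#' @return A [phenotype_table()].
#' @export
read_phenotype_tsv <- function(path, manifest_path) {
  df <- utils::read.delim(path, check.names = FALSE, na.strings = c("NA", ""),
                          comment.char = "#")
  if (anyDuplicated(names(df)))
    stop("duplicate column in ", path, ": ",
         paste(unique(names(df)[duplicated(names(df))]), collapse = ", "))
  ids <- as.character(df[[1]])
  vals <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- ids
  man <- utils::read.delim(manifest_path, check.names = FALSE,
                           comment.char = "#")
  if (!"levels" %in% names(man)) man$levels <- NA_integer_
  keep <- match(colnames(vals), man$variable)
  if (anyNA(keep))
    stop("manifest is missing entries for: ",
         paste(colnames(vals)[is.na(keep)], collapse = ", "))
  phenotype_table(vals, man[keep, , drop = FALSE])
}

#' Write a phenotype table (and its manifest) to TSV
#'
#' @param table A [phenotype_table()].
#' @param path Output TSV path (first column `subject_id`).
#' @param manifest_path Optional manifest TSV path.
#' @param header_comment Optional comment line (e.g. a config hash) written
#'   as a leading `#` line.
#' @return `path`, invisibly.
#' @export
write_phenotype_tsv <- function(table, path, manifest_path = NULL,
                                header_comment = NULL) {
  df <- data.frame(subject_id = rownames(table$values),
                   table$values, check.names = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment)) writeLines(paste0("# ", header_comment), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  if (!is.null(manifest_path))
    utils::write.table(table$manifest, manifest_path, sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Hash of a run configuration
#'
#' MD5 digest of the deparsed configuration, recorded in output headers so
#' a report can be traced back to its exact inputs.
#'
#' @param config Any R object.
#' @return Character MD5 hash.
#' @export
config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(config), f)
  unname(tools::md5sum(f))
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate -> preprocess -> extreme-group selection ->
#' mass-univariate screen -> CCA as a single reproducible run. Inputs are
#' either a [cohort_config()] (a cohort is generated) or a pre-built
#' `cohort_bundle`. Identical configuration and seed give an identical
#' report.
#'
#' @param config A [cohort_config()], or `NULL` when `bundle` is supplied.
#' @param bundle Optional pre-built cohort bundle (exactly one of `config`
#'   or `bundle`).
#' @param alpha Level for the univariate screen (default 0.05).
#' @param d PCA components per set (default 30).
#' @param n_perm CCA permutations (default 10000).
#' @param cutoff Extreme-group exclusion cutoff on |z| (default 3).
#' @param adjust_cdelta `"none"`, `1`, `2` or `3`: adjust the univariate
#'   screen for the corresponding raw-difference change score.
#' @param seed Master seed; per-stage seeds are split from it.
#' @param out_dir Optional directory to persist stage outputs as TSV.
#' @param stages Character subset of `c("univariate", "cca")` to run (the
#'   generation, preprocessing and selection stages always run).
#' @return A `run_report` list with stage outputs, counts and timings.
#' @export
run_pipeline <- function(config = NULL, bundle = NULL, alpha = 0.05, d = 30L,
                         n_perm = 10000L, cutoff = 3, adjust_cdelta = "none",
                         seed = 1L, out_dir = NULL,
                         stages = c("univariate", "cca")) {
  if (is.null(config) == is.null(bundle))
    stop("supply exactly one of `config` or `bundle`")
  t0 <- proc.time()[["elapsed"]]
  timings <- list()
  tick <- function(name) {
    t1 <- proc.time()[["elapsed"]]
    timings[[name]] <<- t1 - t0
    t0 <<- t1
  }
  if (is.null(bundle)) bundle <- generate_cohort(config)
  hash <- config_hash(list(bundle$config, alpha, d, n_perm, cutoff,
                           adjust_cdelta, seed, stages))
  tick("simulate")

  prep <- preprocess_cohort(bundle$idp_table, bundle$nonidp_table,
                            bundle$confounds, impute = "cca" %in% stages,
                            seed = stage_seed(seed, 2L))
  tick("preprocess")

  change <- residualized_change(bundle$iq_panel$iq20, bundle$iq_panel$iq57)
  groups <- select_extreme_groups(change, cutoff = cutoff)
  cdelta <- cdelta_scores(bundle$iq_panel)
  tick("egd")

  report <- list(config_hash = hash, seed = seed,
                 n_subjects = nrow(bundle$idp_table$values),
                 groups = groups, change = change)

  if ("univariate" %in% stages) {
    cd <- if (identical(adjust_cdelta, "none")) NULL
          else cdelta[[paste0("cdelta", adjust_cdelta)]]
    rec <- pairwise_correlations(prep$idp, prep$nonidp, cdelta = cd)
    flagged <- multiple_testing(rec, alpha = alpha)
    report$univariate <- flagged
    report$n_univariate_records <- nrow(rec)
    report$manhattan <- manhattan_export(flagged)
    report$subgroup <- subgroup_consistency(prep$idp, prep$nonidp, groups,
                                            flagged$records)
    tick("univariate")
  }

  if ("cca" %in% stages) {
    report$cca <- cca_mode_analysis(prep$idp_imputed, prep$nonidp_imputed,
                                    d = d, n_perm = n_perm,
                                    seed = stage_seed(seed, 4L),
                                    groups = groups,
                                    idp_original = prep$idp,
                                    nonidp_original = prep$nonidp)
    tick("cca")
  }
  report$timings <- timings

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_phenotype_tsv(prep$idp, file.path(out_dir, "idp_preprocessed.tsv"),
                        file.path(out_dir, "idp_manifest.tsv"),
                        header_comment = paste("config", hash))
    write_phenotype_tsv(prep$nonidp,
                        file.path(out_dir, "nonidp_preprocessed.tsv"),
                        file.path(out_dir, "nonidp_manifest.tsv"),
                        header_comment = paste("config", hash))
    gtab <- data.frame(subject_id = rownames(bundle$idp_table$values),
                       z = change$z, label = groups$label)
    utils::write.table(gtab, file.path(out_dir, "groups.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (!is.null(report$univariate))
      utils::write.table(report$univariate$records,
                         file.path(out_dir, "univariate_records.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(report$cca)) {
      utils::write.table(
        data.frame(mode = seq_along(report$cca$cca$rc),
                   rc = report$cca$cca$rc, p_fwe = report$cca$cca$p_fwe),
        file.path(out_dir, "cca_modes.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(rbind(report$cca$loadings_idp,
                               report$cca$loadings_nonidp),
                         file.path(out_dir, "loadings.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  class(report) <- "run_report"
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("run_report (config", substr(x$config_hash, 1, 8), ")\n")
  cat(sprintf("  subjects: %d; groups: %s\n", x$n_subjects,
              paste(sprintf("%s=%d", names(x$groups$counts),
                            x$groups$counts), collapse = ", ")))
  if (!is.null(x$univariate))
    cat(sprintf("  univariate: %d records, %d FWE-significant\n",
                x$n_univariate_records, x$univariate$report$n_pass_fwe))
  if (!is.null(x$cca))
    cat(sprintf("  cca: rc_1 = %.3f, p_fwe_1 = %.4g\n",
                x$cca$cca$rc[1], x$cca$cca$p_fwe[1]))
  invisible(x)
}
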