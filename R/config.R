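#' Run configuration for classification and cutoff search
#'
#' Bundles the tunable parameters shared by [classify_allelic()],
#' [crossval_cutoff()], [subsampled_splits()] and [fit_vaf_cutoff()].
#' Defaults reproduce the published analysis settings: a 23% VAF cutoff,
#' minimum node size 15 for the split search, 30 cross-validation runs with
#' 80/20 train/test splits, and a 20% clonality detection floor for del(17p).
#'
#' @param cutoff VAF cutoff separating probable monoallelic from probable
#'   biallelic calls, as a fraction in (0, 0.5]. Default 0.23.
#' @param min_node Minimum number of patients required on each side of a
#'   candidate split. Default 15.
#' @param cv_runs Number of train/test cross-validation runs. Default 30.
#' @param test_fraction Fraction of the cohort held out as the test set in
#'   each run. Default 0.2.
#' @param subsamples Number of bootstrap resamples for [subsampled_splits()].
#'   Default 1000.
#' @param seed Integer seed controlling every stochastic step downstream.
#' @param del17p_detection_limit Smallest del(17p) clone fraction detectable
#'   by cytogenetics/SNP-array, as a fraction. Default 0.20.
#'
#' @return An object of class `"run_config"`: a validated named list.
#' @examples
#' cfg <- run_config(seed = 7)
#' cfg$cutoff
#' @export
run_config <- function(cutoff = 0.23, min_node = 15L, cv_runs = 30L,
                       test_fraction = 0.2, subsamples = 1000L, seed = 1L,
                       del17p_detection_limit = 0.20) {
  stopifnot(
    is.numeric(cutoff), length(cutoff) == 1L, cutoff > 0, cutoff <= 0.5,
    is.numeric(min_node), length(min_node) == 1L, min_node >= 2,
    is.numeric(cv_runs), length(cv_runs) == 1L, cv_runs >= 1,
    is.numeric(test_fraction), length(test_fraction) == 1L,
    test_fraction > 0, test_fraction < 1,
    is.numeric(subsamples), length(subsamples) == 1L, subsamples >= 1,
    is.numeric(seed), length(seed) == 1L, is.finite(seed),
    is.numeric(del17p_detection_limit), length(del17p_detection_limit) == 1L,
    del17p_detection_limit >= 0, del17p_detection_limit <= 1
  )
  structure(
    list(
      cutoff = as.numeric(cutoff),
      min_node = as.integer(min_node),
      cv_runs = as.integer(cv_runs),
      test_fraction = as.numeric(test_fraction),
      subsamples = as.integer(subsamples),
      seed = as.integer(seed),
      del17p_detection_limit = as.numeric(del17p_detection_limit)
    ),
    class = "run_config"
  )
}

#' @export
print.run_config <- function(x, ...) {
  cat("TP53 allelic-configuration run settings\n")
  cat(sprintf("  VAF cutoff:            %.1f%%\n", 100 * x$cutoff))
  cat(sprintf("  min node size:         %d\n", x$min_node))
  cat(sprintf("  CV runs (test frac):   %d (%.0f%%)\n",
              x$cv_runs, 100 * x$test_fraction))
  cat(sprintf("  bootstrap subsamples:  %d\n", x$subsamples))
  cat(sprintf("  del17p detection lim:  %.0f%%\n",
              100 * x$del17p_detection_limit))
  cat(sprintf("  seed:                  %d\n", x$seed))
  invisible(x)
}

#' Read a flat key:value configuration file
#'
#' Parses a plain-text file with one `key: value` pair per line (keys are the
#' [run_config()] argument names; `#` starts a comment) and returns the
#' corresponding `run_config` object. Keys absent from the file keep their
#' defaults.
#'
#' @param path Path to the configuration file.
#' @return A `"run_config"` object.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, ":", fixed = TRUE)
  bad <- vapply(kv, length, 1L) != 2L
  if (any(bad)) {
    stop("malformed config line(s): ", paste(lines[bad], collapse = "; "))
  }
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- as.numeric(trimws(vapply(kv, `[`, "", 2L)))
  known <- names(formals(run_config))
  unknown <- setdiff(keys, known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(run_config, as.list(stats::setNames(vals, keys)))
}
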