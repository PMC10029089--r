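#' Candidate VAF cutpoints under a minimum-node-size constraint
#'
#' Midpoints between consecutive distinct sorted VAFs, keeping only cutpoints
#' that leave at least `min_node` patients on each side. Intended to be fed
#' VAFs of patients that are not already obligatory biallelic, since the
#' cutoff only separates probable monoallelic from probable biallelic cases.
#'
#' @param vafs Numeric VAF fractions.
#' @param min_node Minimum patients required on each side of a cutpoint.
#' @return Increasing numeric vector of candidate cutoffs (possibly empty).
#' @export
candidate_grid <- function(vafs, min_node) {
  stopifnot(is.numeric(vafs), min_node >= 1)
  if (length(vafs) < 2 * min_node) return(numeric())
  u <- sort(unique(vafs))
  if (length(u) < 2) return(numeric())
  mid <- (u[-1] + u[-length(u)]) / 2
  keep <- vapply(mid, function(c) {
    sum(vafs <= c) >= min_node && sum(vafs > c) >= min_node
  }, logical(1))
  mid[keep]
}

#' Fixed percent-step candidate grid
#'
#' The 1%-step grid from 1% to 49% used for cutoff profiling, filtered by the
#' same minimum-node-size constraint as [candidate_grid()].
#'
#' @inheritParams candidate_grid
#' @param step Grid step as a fraction (default 0.01).
#' @return Increasing numeric vector of candidate cutoffs.
#' @export
fixed_grid <- function(vafs, min_node, step = 0.01) {
  g <- seq(step, 0.5 - step, by = step)
  g[vapply(g, function(c) {
    sum(vafs <= c) >= min_node && sum(vafs > c) >= min_node
  }, logical(1))]
}

# Two-sample log-rank statistics for the splits {VAF <= c} vs {VAF > c},
# evaluated for all candidates at once. Returns one chi-square per candidate
# (0 where the split has no variance, e.g. all event times tied).
logrank_split_stats <- function(vafs, times, events, candidates) {
  n <- length(vafs)
  m <- length(candidates)
  if (m == 0L) return(numeric())
  events <- as.logical(events)
  ord <- order(times)
  t <- times[ord]; e <- events[ord]; v <- vafs[ord]

  M <- outer(v, candidates, ">") + 0            # group-1 membership, n x m
  cum <- apply(M[n:1, , drop = FALSE], 2, cumsum)[n:1, , drop = FALSE]

  dt <- unique(t[e])
  if (length(dt) == 0L) return(numeric(m))
  first_idx <- match(dt, t)
  key <- as.character(dt)
  Y <- (n:1)[first_idx]                          # total at risk
  D <- as.numeric(rowsum(as.numeric(e), t)[key, ])
  Y1 <- cum[first_idx, , drop = FALSE]           # group-1 at risk, |dt| x m
  D1 <- rowsum(M * e, t)[key, , drop = FALSE]    # group-1 deaths

  O1 <- colSums(D1)
  E1 <- colSums(Y1 * (D / Y))
  fac <- D * (Y - D) / pmax(Y - 1, 1) / Y^2
  V <- colSums(fac * Y1 * (Y - Y1))
  stat <- ifelse(V > 1e-12, (O1 - E1)^2 / V, 0)
  as.numeric(stat)
}

#' Best single VAF split by the two-sample log-rank statistic
#'
#' Returns the candidate cutoff maximizing the log-rank separation between
#' \{VAF <= c\} and \{VAF > c\}; ties are broken toward the smallest cutoff.
#'
#' @param vafs,times,events Equal-length vectors.
#' @param min_node Minimum node size for the candidate grid.
#' @param candidates Optional explicit candidate grid; defaults to
#'   [candidate_grid()] on `vafs`.
#' @return The selected cutoff (fraction).
#' @export
best_split <- function(vafs, times, events, min_node, candidates = NULL) {
  if (is.null(candidates)) candidates <- candidate_grid(vafs, min_node)
  if (length(candidates) == 0L) {
    stop("empty candidate grid: fewer than 2 * min_node usable patients")
  }
  stat <- logrank_split_stats(vafs, times, events, candidates)
  candidates[which.max(stat)]
}

#' Bootstrap subsampling of the best log-rank split
#'
#' Draws `config$subsamples` bootstrap resamples (with replacement, size n),
#' finds the best split of each resample over the candidate grid computed
#' from the ORIGINAL data (candidates violating the minimum-node constraint
#' within a resample are dropped for that resample), and tabulates how often
#' each candidate is chosen. Resamples with no feasible candidate are counted
#' as no-splits and excluded from the frequencies. Fully determined by
#' `config$seed`.
#'
#' @inheritParams best_split
#' @param config A [run_config()]; uses `subsamples`, `min_node`, `seed`.
#' @param candidates Optional explicit grid.
#' @return List with `candidates`, `frequencies` (integer, same length),
#'   `n_no_split`, `subsamples`, `seed`.
#' @export
subsampled_splits <- function(vafs, times, events, config, candidates = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(candidates)) candidates <- candidate_grid(vafs, config$min_node)
  if (length(candidates) == 0L) stop("empty candidate grid")
  n <- length(vafs)
  B <- config$subsamples
  freq <- integer(length(candidates))
  n_no_split <- 0L
  set.seed(config$seed)
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    vb <- vafs[idx]
    nd <- vapply(candidates, function(c) {
      min(sum(vb <= c), sum(vb > c))
    }, numeric(1))
    feas <- nd >= config$min_node
    if (!any(feas)) {
      n_no_split <- n_no_split + 1L
      next
    }
    stat <- logrank_split_stats(vb, times[idx], events[idx],
                                candidates[feas])
    pick <- which(feas)[which.max(stat)]
    freq[pick] <- freq[pick] + 1L
  }
  list(candidates = candidates, frequencies = freq,
       n_no_split = n_no_split, subsamples = B, seed = config$seed)
}

# Harrell's C given a precomputed comparability matrix (see harrell_c);
# comp[i, j] is TRUE when the pair is comparable with subject i failing first.
harrell_from_comp <- function(comp, n_comp, scores) {
  gt <- outer(scores, scores, ">")
  eq <- outer(scores, scores, "==")
  (sum(comp & gt) + 0.5 * sum(comp & eq)) / n_comp
}

#' Cross-validated concordance profile over candidate VAF cutoffs
#'
#' For each of `config$cv_runs` random train/test splits
#' (`config$test_fraction` held out) and each candidate cutoff c, patients
#' are classified by [classify_allelic()] at cutoff c, the ordinal risk score
#' WT = 0 < probable monoallelic = 1 < probable biallelic = 2 < obligatory
#' biallelic = 3 is applied to the held-out patients, and Harrell's C is
#' computed on the held-out set. The selected cutoff maximizes the mean
#' test-set concordance, ties toward the smaller cutoff. Obligatory-biallelic
#' calls do not depend on the candidate, so only the probable classes move.
#'
#' @param cohort A `tp53_cohort` containing wild-type and mutated patients.
#' @param candidate_cutoffs Increasing candidate cutoffs; default is
#'   [candidate_grid()] on the combined VAFs of mutated, non-obligatory
#'   patients with `config$min_node`.
#' @param config A [run_config()].
#' @return List of class `"cutoff_cv"`: `candidate_cutoffs`, `cv_mean`,
#'   `cv_sd`, `selected_cutoff`, `runs`, `runs_skipped`, `seed`.
#' @export
crossval_cutoff <- function(cohort, candidate_cutoffs = NULL,
                            config = run_config()) {
  stopifnot(inherits(cohort, "tp53_cohort"), inherits(config, "run_config"))
  calls <- classify_allelic(cohort, config)
  oblig <- calls$label == "obligatory_biallelic"
  wt <- calls$label == "WT"
  del_only <- calls$label == "del17p_only"
  movable <- !(oblig | wt | del_only)          # probable classes: score 1 or 2
  cv <- calls$combined_vaf

  if (is.null(candidate_cutoffs)) {
    candidate_cutoffs <- candidate_grid(cv[movable], config$min_node)
  }
  m <- length(candidate_cutoffs)
  if (m == 0L) stop("no candidate cutoffs")
  stopifnot(!is.unsorted(candidate_cutoffs))

  base_score <- ifelse(oblig, 3L, ifelse(del_only, 1L, 0L))
  p <- cohort$patients
  n <- nrow(p)
  n_test <- max(2L, floor(config$test_fraction * n))

  sums <- numeric(m); sums2 <- numeric(m)
  used <- 0L; skipped <- 0L
  set.seed(config$seed)
  for (r in seq_len(config$cv_runs)) {
    test <- sample.int(n, n_test)
    tt <- p$os_months[test]; te <- p$os_event[test]
    comp <- outer(tt, tt, "<") & te
    n_comp <- sum(comp)
    if (n_comp == 0L) {
      skipped <- skipped + 1L
      next
    }
    mv <- movable[test]; bs <- base_score[test]; cvt <- cv[test]
    for (j in seq_len(m)) {
      sc <- bs
      sc[mv] <- ifelse(cvt[mv] > candidate_cutoffs[j], 2L, 1L)
      cc <- harrell_from_comp(comp, n_comp, sc)
      sums[j] <- sums[j] + cc
      sums2[j] <- sums2[j] + cc^2
    }
    used <- used + 1L
  }
  if (used == 0L) stop("all cross-validation runs had no comparable pairs")
  cv_mean <- sums / used
  cv_sd <- if (used > 1) sqrt(pmax(sums2 / used - cv_mean^2, 0) * used / (used - 1))
           else rep(NA_real_, m)
  structure(list(candidate_cutoffs = candidate_cutoffs, cv_mean = cv_mean,
                 cv_sd = cv_sd,
                 selected_cutoff = candidate_cutoffs[which.max(cv_mean)],
                 runs = used, runs_skipped = skipped, seed = config$seed),
            class = "cutoff_cv")
}

#' Fit the survival-optimized VAF cutoff
#'
#' The package's central fit: searches for the VAF cutoff that best separates
#' probable monoallelic from probable biallelic TP53 mutations, using
#' survival as a surrogate for the unobserved allelic status. Combines
#' bootstrap-subsampled log-rank split selection ([subsampled_splits()]) on
#' the mutated, non-obligatory patients with repeated train/test
#' cross-validation scored by Harrell's C on the whole cohort
#' ([crossval_cutoff()]). Everything is determined by `config$seed`.
#'
#' @param cohort A `tp53_cohort`.
#' @param config A [run_config()].
#' @param candidates Optional explicit candidate grid (fractions); defaults
#'   to [candidate_grid()] on the mutated, non-obligatory combined VAFs.
#' @param subsample Logical; also run the bootstrap split-frequency analysis
#'   (default `TRUE`).
#' @return Object of class `"vaf_cutoff_fit"` with elements
#'   `candidate_cutoffs`, `cv_concordance` (data.frame: `cutoff`, `mean_c`,
#'   `sd_c`), `selected_cutoff`, `split_frequencies` (or `NULL`),
#'   `n_no_split`, `runs`, `seed`, `config`, `n`, `n_movable`.
#' @examples
#' sim <- simulate_changepoint_cohort(n = 400, seed = 42)
#' fit <- fit_vaf_cutoff(sim$cohort, run_config(cv_runs = 10, seed = 42,
#'                                              subsamples = 50))
#' coef(fit)
#' @export
fit_vaf_cutoff <- function(cohort, config = run_config(), candidates = NULL,
                           subsample = TRUE) {
  stopifnot(inherits(cohort, "tp53_cohort"))
  calls <- classify_allelic(cohort, config)
  movable <- !(calls$label %in% c("obligatory_biallelic", "WT", "del17p_only"))
  if (is.null(candidates)) {
    candidates <- candidate_grid(calls$combined_vaf[movable], config$min_node)
  }
  if (length(candidates) == 0L) {
    stop("no candidate cutoffs satisfy the minimum-node constraint")
  }

  cvres <- crossval_cutoff(cohort, candidates, config)

  split_freq <- NULL; n_no_split <- NA_integer_
  if (subsample) {
    idx <- which(movable)
    ss <- subsampled_splits(calls$combined_vaf[idx],
                            cohort$patients$os_months[idx],
                            cohort$patients$os_event[idx],
                            config, candidates)
    split_freq <- ss$frequencies
    n_no_split <- ss$n_no_split
  }

  structure(list(
    candidate_cutoffs = candidates,
    cv_concordance = data.frame(cutoff = candidates, mean_c = cvres$cv_mean,
                                sd_c = cvres$cv_sd),
    selected_cutoff = cvres$selected_cutoff,
    split_frequencies = split_freq,
    n_no_split = n_no_split,
    runs = cvres$runs,
    runs_skipped = cvres$runs_skipped,
    seed = config$seed,
    config = config,
    n = nrow(cohort$patients),
    n_movable = sum(movable)
  ), class = "vaf_cutoff_fit")
}

#' @export
print.vaf_cutoff_fit <- function(x, ...) {
  cat("Survival-optimized TP53 VAF cutoff\n")
  cat(sprintf("  cohort: %d patients (%d in the probable classes)\n",
              x$n, x$n_movable))
  cat(sprintf("  %d candidate cutoffs in [%.1f%%, %.1f%%]\n",
              length(x$candidate_cutoffs),
              100 * min(x$candidate_cutoffs), 100 * max(x$candidate_cutoffs)))
  cat(sprintf("  selected cutoff: %.1f%% (mean test C = %.3f over %d runs)\n",
              100 * x$selected_cutoff,
              max(x$cv_concordance$mean_c), x$runs))
  if (!is.null(x$split_frequencies)) {
    mode_i <- which.max(x$split_frequencies)
    cat(sprintf("  modal bootstrap split: %.1f%% (%d of %d resamples)\n",
                100 * x$candidate_cutoffs[mode_i],
                x$split_frequencies[mode_i], sum(x$split_frequencies)))
  }
  invisible(x)
}

#' @export
summary.vaf_cutoff_fit <- function(object, top = 5L, ...) {
  prof <- object$cv_concordance
  prof <- prof[order(-prof$mean_c), ]
  cat("Top candidate cutoffs by mean test-set concordance:\n")
  show <- utils::head(prof, top)
  show$cutoff <- sprintf("%.1f%%", 100 * show$cutoff)
  print(show, row.names = FALSE, digits = 4)
  cat(sprintf("\nSelected: %.1f%%; runs used %d, skipped %d; seed %d\n",
              100 * object$selected_cutoff, object$runs,
              object$runs_skipped, object$seed))
  invisible(object)
}

#' @export
coef.vaf_cutoff_fit <- function(object, ...) {
  c(cutoff = object$selected_cutoff)
}

#' @export
plot.vaf_cutoff_fit <- function(x, ...) {
  prof <- x$cv_concordance
  graphics::plot(100 * prof$cutoff, prof$mean_c, type = "b", pch = 16,
                 cex = 0.6, xlab = "VAF cutoff (%)",
                 ylab = "Mean test-set Harrell's C", ...)
  if (all(is.finite(prof$sd_c))) {
    graphics::arrows(100 * prof$cutoff, prof$mean_c - prof$sd_c,
                     100 * prof$cutoff, prof$mean_c + prof$sd_c,
                     length = 0.02, angle = 90, code = 3, col = "grey60")
  }
  graphics::abline(v = 100 * x$selected_cutoff, lty = 2)
  invisible(x)
}
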