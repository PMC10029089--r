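# Independent oracles and small cohort builders shared across tests.

# Build a one-row-per-patient cohort from flat per-patient descriptions.
# vafs: list of numeric vectors (one per patient, fractions)
# del17p / clonality / upd: per-patient cytogenetics (clonality NA = unknown,
#   del17p NA = no cytogenetics record at all)
make_cohort <- function(vafs, times = NULL, events = NULL,
                        del17p = rep(FALSE, length(vafs)),
                        clonality = rep(NA_real_, length(vafs)),
                        upd = rep(FALSE, length(vafs)),
                        subtype = "pAML") {
  n <- length(vafs)
  if (is.null(times)) times <- rep(12, n)
  if (is.null(events)) events <- rep(TRUE, n)
  ids <- sprintf("T%03d", seq_len(n))
  patients <- data.frame(patient_id = ids, subtype = subtype,
                         os_months = times, os_event = events)
  vr <- do.call(rbind, lapply(seq_len(n), function(i) {
    if (length(vafs[[i]]) == 0) return(NULL)
    data.frame(patient_id = ids[i], effect = "missense",
               protein_change = NA_character_, vaf = vafs[[i]])
  }))
  has_cyto <- !is.na(del17p)
  cy <- if (any(has_cyto)) {
    data.frame(patient_id = ids[has_cyto], del17p = del17p[has_cyto],
               del17p_clonality = clonality[has_cyto],
               upd17p = upd[has_cyto], complex_karyotype = FALSE)
  } else NULL
  tp53_cohort(patients, vr, cy)
}

# Brute-force restatement of the allelic-configuration rules, coded
# independently of the package's vectorized path: one patient at a time,
# plain if/else in rule order.
oracle_allelic <- function(vafs, del17p, clonality, cutoff) {
  if (length(vafs) == 0 && !isTRUE(del17p)) return("WT")
  if (length(vafs) == 0) return("del17p_only")
  comb <- sum(vafs)
  if (comb > 1) comb <- 1
  if (max(vafs) > 0.5) return("obligatory_biallelic")
  if (comb > 0.5) return("obligatory_biallelic")
  if (isTRUE(del17p) && !is.na(clonality) && comb + clonality > 0.5) {
    return("obligatory_biallelic")
  }
  if (comb > cutoff) return("probable_biallelic")
  "probable_monoallelic"
}

# O(n^2) pair-enumeration oracle for Harrell's C: a pair (i, j) is comparable
# when the earlier time is an observed event; ties in score count 0.5.
oracle_harrell <- function(times, events, scores) {
  conc <- 0
  comp <- 0
  n <- length(times)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (times[i] < times[j] && events[i]) {
        comp <- comp + 1
        if (scores[i] > scores[j]) conc <- conc + 1
        else if (scores[i] == scores[j]) conc <- conc + 0.5
      }
    }
  }
  if (comp == 0) stop("no comparable pairs")
  conc / comp
}

# Exhaustive split search oracle: argmax over the candidate grid of the
# two-sample log-rank chi-square computed by survival::survdiff, first
# (smallest) candidate on ties.
oracle_best_split <- function(vafs, times, events, candidates) {
  stats <- vapply(candidates, function(c) {
    g <- factor(vafs > c, levels = c(FALSE, TRUE))
    survival::survdiff(survival::Surv(times, events) ~ g)$chisq
  }, numeric(1))
  candidates[which.max(stats)]
}

random_survival_data <- function(n, p_event = 0.7, tie_times = FALSE) {
  times <- if (tie_times) sample(1:15, n, replace = TRUE) else rexp(n, 0.05)
  list(times = times,
       events = runif(n) < p_event,
       x = rnorm(n))
}
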