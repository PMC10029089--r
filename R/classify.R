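ALLELIC_LEVELS <- c("WT", "obligatory_biallelic", "probable_biallelic",
                    "probable_monoallelic", "del17p_only")
RULE_LEVELS <- c("none", "single_vaf_gt50", "combined_vaf_gt50",
                 "vaf_plus_del17p_gt50", "cutoff_above", "cutoff_at_or_below")
TRADITIONAL_LEVELS <- c("WT", "single_hit", "double_hit")

#' Combined VAF of a set of TP53 variants
#'
#' Sum of the variant allele frequencies, capped at 1 (a raw sum above 1 can
#' only arise from measurement noise or a violated trans assumption and is
#' capped with a warning). An empty set has combined VAF 0.
#'
#' @param vafs Numeric vector of VAFs as fractions in \[0, 1\] (may be empty).
#' @return A single fraction in \[0, 1\].
#' @examples
#' combined_vaf(c(0.12, 0.08)) # 0.20
#' @export
combined_vaf <- function(vafs) {
  if (length(vafs) == 0L) return(0)
  stopifnot(is.numeric(vafs), all(is.finite(vafs)), all(vafs >= 0 & vafs <= 1))
  s <- sum(vafs)
  if (s > 1) {
    warning(sprintf("combined VAF %.3f exceeds 1; capped at 1", s))
    s <- 1
  }
  s
}

# Per-patient summary used by both classifiers: one row per cohort patient,
# in cohort order.
patient_features <- function(cohort) {
  p <- cohort$patients
  v <- cohort$variants
  cy <- cohort$cyto

  n <- nrow(p)
  idx <- match(v$patient_id, p$patient_id)
  n_hits <- tabulate(idx, nbins = n)
  raw_sum <- numeric(n)
  if (nrow(v)) {
    s <- tapply(v$vaf, factor(v$patient_id, levels = p$patient_id), sum)
    raw_sum <- as.numeric(ifelse(is.na(s), 0, s))
  }
  over <- raw_sum > 1
  if (any(over)) {
    warning("combined VAF exceeds 1 for patient(s) ",
            paste(p$patient_id[over], collapse = ", "), "; capped at 1")
  }
  comb <- pmin(raw_sum, 1)
  max_vaf <- numeric(n)
  if (nrow(v)) {
    m <- tapply(v$vaf, factor(v$patient_id, levels = p$patient_id), max)
    max_vaf <- as.numeric(ifelse(is.na(m), 0, m))
  }

  ci <- match(p$patient_id, cy$patient_id)
  del17p <- ifelse(is.na(ci), FALSE, cy$del17p[ci])
  del17p[is.na(del17p)] <- FALSE
  clon <- ifelse(is.na(ci), NA_real_, cy$del17p_clonality[ci])
  upd <- ifelse(is.na(ci), FALSE, cy$upd17p[ci])
  upd[is.na(upd)] <- FALSE

  data.frame(patient_id = p$patient_id, n_hits = n_hits,
             combined_vaf = comb, max_vaf = max_vaf, del17p = del17p,
             del17p_clonality = clon, upd17p = upd,
             stringsAsFactors = FALSE)
}

#' Traditional single/double-hit TP53 classification
#'
#' Counts TP53 lesions without resolving whether they affect the same cell:
#' a single hit is one TP53 mutation or an isolated 17p deletion; a double
#' hit is a TP53 mutation plus another mutation, a 17p deletion, or 17p UPD.
#'
#' @param cohort A `tp53_cohort`.
#' @return data.frame with columns `patient_id` and `label`
#'   (factor: `WT`, `single_hit`, `double_hit`), in cohort order.
#' @export
classify_traditional <- function(cohort) {
  f <- patient_features(cohort)
  label <- ifelse(
    f$n_hits >= 2 | (f$n_hits >= 1 & (f$del17p | f$upd17p)), "double_hit",
    ifelse(f$n_hits == 1 | (f$n_hits == 0 & f$del17p), "single_hit", "WT")
  )
  data.frame(patient_id = f$patient_id,
             label = factor(label, levels = TRADITIONAL_LEVELS),
             stringsAsFactors = FALSE)
}

#' Three-class TP53 allelic-configuration calls
#'
#' Applies, in order, the first matching rule per patient:
#' \enumerate{
#'   \item no variants, no del(17p): `WT`;
#'   \item no variants but del(17p): `del17p_only`;
#'   \item any single variant with VAF > 50%: `obligatory_biallelic`
#'     (`single_vaf_gt50`);
#'   \item combined VAF > 50%: `obligatory_biallelic` (`combined_vaf_gt50`);
#'   \item del(17p) with known clonality and combined VAF + clonality > 50%:
#'     `obligatory_biallelic` (`vaf_plus_del17p_gt50`);
#'   \item combined VAF > cutoff: `probable_biallelic` (`cutoff_above`);
#'   \item otherwise `probable_monoallelic` (`cutoff_at_or_below`).
#' }
#' All inequalities are strict: a single mutation at exactly 50% VAF is
#' compatible with a fully clonal heterozygous (monoallelic) lesion, and a
#' combined VAF exactly at the cutoff stays probable monoallelic.
#' del(17p) with unknown clonality skips the clonality rule and the call is
#' flagged `clonality_unknown` in `evidence_note`. 17p UPD does not by itself
#' promote a call: homozygosity through UPD doubles the mutation's VAF, so
#' the VAF rules already carry that evidence.
#'
#' @param cohort A `tp53_cohort`.
#' @param config A [run_config()]; `config$cutoff` is the VAF cutoff.
#' @return data.frame in cohort order with columns `patient_id`, `label`
#'   (factor over the five classes), `rule_fired` (factor), `combined_vaf`
#'   (fraction, capped at 1) and `evidence_note` (string).
#' @examples
#' co <- simulate_cohort(sim_params(n_patients = 50, seed = 1))$cohort
#' table(classify_allelic(co, run_config())$label)
#' @export
classify_allelic <- function(cohort, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  f <- patient_features(cohort)
  n <- nrow(f)
  label <- character(n)
  rule <- character(n)

  clon_known <- f$del17p & !is.na(f$del17p_clonality)
  clon <- ifelse(clon_known, f$del17p_clonality, 0)

  wt <- f$n_hits == 0 & !f$del17p
  del_only <- f$n_hits == 0 & f$del17p
  r1 <- f$n_hits >= 1 & f$max_vaf > 0.5
  r2 <- f$n_hits >= 1 & f$combined_vaf > 0.5
  r3 <- f$n_hits >= 1 & clon_known & (f$combined_vaf + clon) > 0.5
  r4 <- f$n_hits >= 1 & f$combined_vaf > config$cutoff

  label[wt] <- "WT"; rule[wt] <- "none"
  label[del_only] <- "del17p_only"; rule[del_only] <- "none"
  mut <- !wt & !del_only
  pick <- function(cond, lab, rl) {
    sel <- mut & cond & rule == ""
    label[sel] <<- lab
    rule[sel] <<- rl
  }
  pick(r1, "obligatory_biallelic", "single_vaf_gt50")
  pick(r2, "obligatory_biallelic", "combined_vaf_gt50")
  pick(r3, "obligatory_biallelic", "vaf_plus_del17p_gt50")
  pick(r4, "probable_biallelic", "cutoff_above")
  pick(rep(TRUE, n), "probable_monoallelic", "cutoff_at_or_below")

  note <- sprintf("combined_vaf=%.1f%%", 100 * f$combined_vaf)
  note[wt] <- "no TP53 lesion"
  note[del_only] <- "del17p without TP53 mutation"
  flag <- f$del17p & is.na(f$del17p_clonality) & mut
  note[flag] <- paste0(note[flag], ";clonality_unknown")

  data.frame(patient_id = f$patient_id,
             label = factor(label, levels = ALLELIC_LEVELS),
             rule_fired = factor(rule, levels = RULE_LEVELS),
             combined_vaf = f$combined_vaf,
             evidence_note = note,
             stringsAsFactors = FALSE)
}

#' Cross-tabulate traditional and allelic-configuration classes
#'
#' @param cohort A `tp53_cohort`.
#' @param config A [run_config()] passed to [classify_allelic()].
#' @return A contingency table (traditional label x allelic label) whose
#'   total equals the cohort size.
#' @export
reclassification_table <- function(cohort, config = run_config()) {
  trad <- classify_traditional(cohort)$label
  novel <- classify_allelic(cohort, config)$label
  table(traditional = trad, allelic = novel)
}

#' Ordinal risk score for allelic-configuration classes
#'
#' Maps the calls to the monotone risk ordering used by the cutoff
#' cross-validation: WT = 0, probable monoallelic = 1, probable biallelic = 2,
#' obligatory biallelic = 3. A del(17p)-only case carries one monoallelic-type
#' lesion and scores 1.
#'
#' @param label Factor or character vector of allelic class labels.
#' @return Integer risk scores.
#' @export
allelic_risk_score <- function(label) {
  map <- c(WT = 0L, probable_monoallelic = 1L, del17p_only = 1L,
           probable_biallelic = 2L, obligatory_biallelic = 3L)
  s <- map[as.character(label)]
  if (any(is.na(s))) stop("unknown allelic class label")
  unname(s)
}
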