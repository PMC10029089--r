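STRATA <- c("WT", "monoallelic", "biallelic")
SIM_CLASSES <- c("WT", "monoallelic", "cryptic_biallelic",
                 "dominant_biallelic", "del17p_involving")

#' Simulation parameters for synthetic TP53 cohorts
#'
#' The defaults emulate the conditions reported for large TP53-mutated
#' myeloid-neoplasia cohorts: a mixture of wild-type, monoallelic-only,
#' cryptic-biallelic (a small biallelic subclone hidden inside a seemingly
#' monoallelic case), dominant-biallelic and del(17p)-involving clonal
#' architectures; bulk VAFs binomially sampled at a mean depth of 500; a 20%
#' clonality floor on del(17p) detection; and exponential survival with
#' per-stratum medians of 42 (wild type), 29 (purely monoallelic) and 14
#' months (any biallelic clone above `biallelic_hazard_threshold`).
#'
#' @param n_patients Number of patients.
#' @param class_mix Named proportions over
#'   `WT`, `monoallelic`, `cryptic_biallelic`, `dominant_biallelic`,
#'   `del17p_involving`; must sum to 1. The default leaves 60% of patients
#'   TP53-mutated, with the mutated strata split so that the classifier's
#'   expected class shares track the published 57/24/19 distribution.
#' @param depth Mean sequencing depth (reads); per-variant depth is Poisson
#'   around this value. Default 500.
#' @param del17p_detection_limit Smallest detectable deleted-cell fraction.
#'   Default 0.20.
#' @param median_os Named vector of median overall survival in months per
#'   truth stratum: `WT` 42, `monoallelic` 29, `biallelic` 14.
#' @param biallelic_hazard_threshold Minimal true biallelic cell fraction
#'   that places a patient in the high-hazard stratum. Default 0.02, so even
#'   small cryptic biallelic subclones (e.g. 6% of cells) carry the poor
#'   prognosis.
#' @param censor_rate Probability that a patient is censored (uniformly
#'   before the event time). Default 0.2.
#' @param ado_rate Per-allele dropout probability in the single-cell
#'   simulator. Default 0.2.
#' @param seed Integer seed.
#' @return Object of class `"sim_params"` (validated named list).
#' @export
sim_params <- function(n_patients = 1000L,
                       class_mix = c(WT = 0.400, monoallelic = 0.114,
                                     cryptic_biallelic = 0.144,
                                     dominant_biallelic = 0.282,
                                     del17p_involving = 0.060),
                       depth = 500,
                       del17p_detection_limit = 0.20,
                       median_os = c(WT = 42, monoallelic = 29, biallelic = 14),
                       biallelic_hazard_threshold = 0.02,
                       censor_rate = 0.2,
                       ado_rate = 0.2,
                       seed = 1L) {
  stopifnot(
    n_patients >= 0,
    setequal(names(class_mix), SIM_CLASSES),
    abs(sum(class_mix) - 1) < 1e-8, all(class_mix >= 0),
    depth >= 1,
    del17p_detection_limit >= 0, del17p_detection_limit <= 1,
    setequal(names(median_os), STRATA), all(median_os > 0),
    biallelic_hazard_threshold >= 0, biallelic_hazard_threshold <= 1,
    censor_rate >= 0, censor_rate <= 1,
    ado_rate >= 0, ado_rate <= 1
  )
  structure(list(
    n_patients = as.integer(n_patients),
    class_mix = class_mix[SIM_CLASSES],
    depth = depth,
    del17p_detection_limit = del17p_detection_limit,
    median_os = median_os[STRATA],
    biallelic_hazard_threshold = biallelic_hazard_threshold,
    censor_rate = censor_rate,
    ado_rate = ado_rate,
    seed = as.integer(seed)
  ), class = "sim_params")
}

#' Ground-truth clonal architecture at the TP53 locus
#'
#' An architecture is a mixture of cell states. Each state has a cell
#' fraction, a total TP53 copy number (1 in del(17p) cells, 2 otherwise) and,
#' per mutation, a mutant copy count. A cell state is biallelically
#' inactivated when its inactivated-allele count -- mutant copies plus copies
#' lost to deletion -- reaches 2: two mutant copies (UPD homozygosity), two
#' distinct mutations in trans, or one mutation on the sole retained copy.
#'
#' @param fractions Cell fractions of the states (must sum to 1).
#' @param total_copies Integer TP53 copy number per state (0, 1 or 2).
#' @param mutant_copies Matrix (states x mutations) of mutant copy counts;
#'   a vector is taken as a single-mutation column.
#' @return Object of class `"clonal_architecture"` with the inputs plus
#'   `n_mutations` and `truth_biallelic_fraction`.
#' @examples
#' # 6% UPD-homozygous, 4% heterozygous, 90% wild type: bulk VAF 8%,
#' # biallelic cell fraction 6%
#' a <- clonal_architecture(c(0.06, 0.04, 0.90), c(2, 2, 2),
#'                          c(2, 1, 0))
#' expected_vaf(a, 1)
#' a$truth_biallelic_fraction
#' @export
clonal_architecture <- function(fractions, total_copies, mutant_copies) {
  if (is.null(dim(mutant_copies))) {
    mutant_copies <- matrix(mutant_copies, ncol = 1)
  }
  k <- length(fractions)
  stopifnot(length(total_copies) == k, nrow(mutant_copies) == k,
            abs(sum(fractions) - 1) < 1e-9, all(fractions >= 0),
            all(total_copies >= 0), all(total_copies <= 2),
            all(mutant_copies >= 0),
            all(mutant_copies <= total_copies))
  inactivated <- rowSums(mutant_copies) + (2 - total_copies)
  structure(list(
    fractions = as.numeric(fractions),
    total_copies = as.integer(total_copies),
    mutant_copies = mutant_copies,
    n_mutations = ncol(mutant_copies),
    truth_biallelic_fraction = sum(fractions[inactivated >= 2])
  ), class = "clonal_architecture")
}

#' Expected bulk VAF of one mutation under a clonal architecture
#'
#' Closed form: the mutant-copy mass divided by the total TP53 copy mass,
#' `sum(f_i * mutant_i) / sum(f_i * total_i)`. This is what an infinitely
#' deep bulk sequencing run would observe, and explains why a small biallelic
#' (e.g. UPD-homozygous) subclone inflates the bulk VAF only modestly: 6%
#' homozygous plus 4% heterozygous cells yield a bulk VAF of 8%.
#'
#' @param arch A [clonal_architecture()].
#' @param mutation_index Which mutation (column) to evaluate.
#' @return Expected VAF as a fraction in \[0, 1\].
#' @export
expected_vaf <- function(arch, mutation_index = 1L) {
  stopifnot(inherits(arch, "clonal_architecture"),
            mutation_index >= 1, mutation_index <= arch$n_mutations)
  denom <- sum(arch$fractions * arch$total_copies)
  if (denom == 0) stop("architecture has zero TP53 copies in every cell")
  sum(arch$fractions * arch$mutant_copies[, mutation_index]) / denom
}

#' Sample an observed bulk VAF with binomial read noise
#'
#' Draws a Poisson read depth around `depth` (at least 1 read) and a binomial
#' mutant-read count at the architecture's expected VAF. Uses the current RNG
#' state; callers control reproducibility via `set.seed()` (all package-level
#' entry points do this through their `seed` parameter).
#'
#' @param arch A [clonal_architecture()].
#' @param mutation_index Which mutation to sample.
#' @param depth Mean read depth.
#' @return Observed VAF fraction.
#' @export
sample_bulk_vaf <- function(arch, mutation_index = 1L, depth = 500) {
  p <- expected_vaf(arch, mutation_index)
  d <- max(1L, stats::rpois(1, depth))
  stats::rbinom(1, d, p) / d
}

#' Simulate a del(17p) cytogenetic call with a detection floor
#'
#' The deletion is called iff the true deleted-cell fraction reaches
#' `detection_limit` (emulating SNP-array insensitivity to clones below
#' ~20%); smaller deleted clones are cryptic and reported as no deletion.
#' Reported clonality is the true fraction plus small Gaussian noise
#' (sd 0.02), clipped to `[detection_limit, 1]`.
#'
#' @param arch A [clonal_architecture()].
#' @param detection_limit Detection floor (fraction).
#' @return List `del17p` (logical), `del17p_clonality` (fraction or `NA`).
#' @export
call_del17p <- function(arch, detection_limit = 0.20) {
  true_frac <- sum(arch$fractions[arch$total_copies < 2])
  if (true_frac < detection_limit || true_frac == 0) {
    return(list(del17p = FALSE, del17p_clonality = NA_real_))
  }
  clon <- min(max(true_frac + stats::rnorm(1, 0, 0.02), detection_limit), 1)
  list(del17p = TRUE, del17p_clonality = clon)
}

# Upper bound u of an independent Uniform(0, u) censoring time such that
# P(C < T) = rate when T ~ Exponential(log(2) / median). Keeps censoring
# independent of the event time, so Kaplan-Meier stays unbiased.
censor_bound <- function(median_os, rate) {
  lambda <- log(2) / median_os
  f <- function(u) (1 - exp(-lambda * u)) / (lambda * u) - rate
  stats::uniroot(f, c(1e-9, 1e9), tol = 1e-10)$root
}

#' Simulate an overall-survival outcome from the truth stratum
#'
#' Exponential event time with median taken from the patient's truth
#' stratum: biallelic if `truth_biallelic_fraction` exceeds
#' `params$biallelic_hazard_threshold`, otherwise monoallelic if any
#' mutation is present, otherwise wild type. Censoring is independent
#' uniform, with the upper bound chosen so the censoring probability equals
#' `params$censor_rate` in each stratum.
#'
#' @param truth_biallelic_fraction True biallelic cell fraction.
#' @param n_mutations Number of TP53 mutations carried.
#' @param params A [sim_params()].
#' @return List `os_months`, `os_event` (logical), `stratum`.
#' @export
sample_survival <- function(truth_biallelic_fraction, n_mutations, params) {
  stratum <- if (truth_biallelic_fraction > params$biallelic_hazard_threshold) {
    "biallelic"
  } else if (n_mutations > 0) "monoallelic" else "WT"
  med <- params$median_os[[stratum]]
  t_event <- stats::rexp(1, rate = log(2) / med)
  r <- params$censor_rate
  if (r >= 1) {
    return(list(os_months = 0, os_event = FALSE, stratum = stratum))
  }
  t_cens <- if (r > 0) stats::runif(1, 0, censor_bound(med, r)) else Inf
  list(os_months = min(t_event, t_cens), os_event = t_event <= t_cens,
       stratum = stratum)
}

#' Simulate a single-cell genotype matrix with allelic dropout
#'
#' Cells are drawn multinomially from the architecture's state fractions.
#' For each cell and mutation the matrix records the observed mutant and
#' total allele counts after dropping each physical allele copy
#' independently with probability `ado_rate`. Truth flags (per-cell
#' biallelic inactivation) are computed before dropout.
#'
#' @param arch A [clonal_architecture()].
#' @param n_cells Number of cells (>= 1).
#' @param ado_rate Per-allele dropout probability.
#' @return List with `state` (state index per cell), `mutant_obs` and
#'   `total_obs` (cells x mutations matrices of observed allele counts;
#'   `total_obs` counts retained copies regardless of mutation),
#'   `mutant_true`, `total_true`, and `biallelic_true` (logical per cell).
#' @export
sample_single_cells <- function(arch, n_cells, ado_rate = 0.2) {
  stopifnot(n_cells >= 1, ado_rate >= 0, ado_rate <= 1)
  k <- length(arch$fractions)
  state <- sample.int(k, n_cells, replace = TRUE, prob = arch$fractions)
  M <- arch$n_mutations
  mutant_true <- arch$mutant_copies[state, , drop = FALSE]
  total_true <- matrix(arch$total_copies[state], n_cells, M)
  inact <- rowSums(arch$mutant_copies) + (2 - arch$total_copies)
  biallelic_true <- inact[state] >= 2

  # each physical allele copy observed independently with prob 1 - ado
  mutant_obs <- matrix(stats::rbinom(n_cells * M, mutant_true, 1 - ado_rate),
                       n_cells, M)
  wt_true <- total_true - mutant_true
  wt_obs <- matrix(stats::rbinom(n_cells * M, wt_true, 1 - ado_rate),
                   n_cells, M)
  list(state = state, mutant_obs = mutant_obs,
       total_obs = mutant_obs + wt_obs,
       mutant_true = mutant_true, total_true = total_true,
       biallelic_true = biallelic_true)
}

# One random architecture per simulation class. Sub-configurations and
# parameter ranges are documented in the methods vignette.
random_architecture <- function(class) {
  switch(class,
    WT = clonal_architecture(1, 2, matrix(numeric(0), 1, 0)),
    monoallelic = {
      # one heterozygous clone, fraction 5-95% -> VAF 2.5-47.5%
      f <- stats::runif(1, 0.05, 0.95)
      clonal_architecture(c(f, 1 - f), c(2, 2), c(1, 0))
    },
    cryptic_biallelic = {
      # small UPD-homozygous subclone nested beside a heterozygous clone
      b <- stats::runif(1, 0.01, 0.10)
      m <- stats::runif(1, 0.02, min(0.75, 1 - b))
      clonal_architecture(c(b, m, 1 - b - m), c(2, 2, 2), c(2, 1, 0))
    },
    dominant_biallelic = {
      f <- stats::runif(1, 0.55, 0.95)
      if (stats::runif(1) < 0.5) {
        # UPD-homozygous dominant clone: expected VAF = f > 50%
        clonal_architecture(c(f, 1 - f), c(2, 2), c(2, 0))
      } else {
        # compound heterozygous in trans: combined expected VAF = f > 50%
        clonal_architecture(c(f, 1 - f), c(2, 2),
                            matrix(c(1, 0, 1, 0), 2, 2))
      }
    },
    del17p_involving = {
      if (stats::runif(1) < 0.19) {
        # deletion without mutation (one retained functional allele)
        f <- stats::runif(1, 0.25, 0.90)
        clonal_architecture(c(f, 1 - f), c(1, 2),
                            matrix(numeric(0), 2, 0))
      } else {
        # mutation hemizygous on the retained allele of the deleted clone
        f <- stats::runif(1, 0.25, 0.90)
        clonal_architecture(c(f, 1 - f), c(1, 2), c(1, 0))
      }
    },
    stop("unknown simulation class: ", class)
  )
}

sample_subtype <- function(n) {
  # marginal disease-subtype distribution of a 7400-patient MN cohort
  probs <- c(pAML = 0.268, sAML = 0.036, HR_MDS = 0.172, LR_MDS = 0.346,
             MDS_MPN = 0.178)
  probs <- c(probs, other = 1 - sum(probs))
  sample(names(probs), n, replace = TRUE, prob = probs)
}

sample_effects <- function(n_mutations) {
  eff <- sample(c("missense", "truncated"), n_mutations, replace = TRUE,
                prob = c(0.8, 0.2))
  hotspots <- c("R175H", "Y220C", "M237I", "R248Q", "R273H", "R282W")
  pc <- ifelse(eff == "missense" & stats::runif(n_mutations) < 0.69,
               sample(hotspots, n_mutations, replace = TRUE),
               NA_character_)
  list(effect = eff, protein_change = pc)
}

#' Simulate a ground-truthed TP53 cohort
#'
#' Composes the architecture, bulk-VAF, del(17p) and survival samplers into
#' a complete cohort: observable patient/variant/cytogenetics tables plus a
#' truth table recording the planted architecture class, true biallelic cell
#' fraction and hazard stratum per patient. Variants whose sampled read
#' support is zero are not reported (they are unobservable), but the truth
#' table still records the mutation count. Fully determined by
#' `params$seed`.
#'
#' @param params A [sim_params()].
#' @return List with `cohort` (a `tp53_cohort`), `truth` (data.frame:
#'   `patient_id`, `class`, `stratum`, `biallelic_fraction`, `n_true_hits`)
#'   and `architectures` (list of [clonal_architecture()] per patient).
#' @examples
#' sim <- simulate_cohort(sim_params(n_patients = 100, seed = 7))
#' table(sim$truth$stratum)
#' @export
simulate_cohort <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  n <- params$n_patients
  if (n == 0L) {
    return(list(cohort = tp53_cohort(
      data.frame(patient_id = character(), subtype = character(),
                 os_months = numeric(), os_event = logical())),
      truth = data.frame(patient_id = character(), class = character(),
                         stratum = character(),
                         biallelic_fraction = numeric(),
                         n_true_hits = integer()),
      architectures = list()))
  }
  classes <- sample(SIM_CLASSES, n, replace = TRUE, prob = params$class_mix)
  ids <- sprintf("P%04d", seq_len(n))
  subtypes <- sample_subtype(n)

  archs <- vector("list", n)
  var_rows <- vector("list", n)
  cyto_rows <- vector("list", n)
  os <- numeric(n); ev <- logical(n); stratum <- character(n)
  bfrac <- numeric(n); nhits <- integer(n)

  for (i in seq_len(n)) {
    a <- random_architecture(classes[i])
    archs[[i]] <- a
    bfrac[i] <- a$truth_biallelic_fraction
    nhits[i] <- a$n_mutations

    if (a$n_mutations > 0) {
      vafs <- vapply(seq_len(a$n_mutations), function(j) {
        sample_bulk_vaf(a, j, params$depth)
      }, numeric(1))
      keep <- vafs > 0
      if (any(keep)) {
        ann <- sample_effects(sum(keep))
        var_rows[[i]] <- data.frame(
          patient_id = ids[i], effect = ann$effect,
          protein_change = ann$protein_change, vaf = vafs[keep],
          stringsAsFactors = FALSE)
      }
    }

    if (any(a$total_copies < 2) || classes[i] == "del17p_involving") {
      dl <- call_del17p(a, params$del17p_detection_limit)
      cyto_rows[[i]] <- data.frame(
        patient_id = ids[i], del17p = dl$del17p,
        del17p_clonality = dl$del17p_clonality,
        upd17p = any(a$mutant_copies == 2),
        complex_karyotype = stats::runif(1) <
          if (bfrac[i] > 0 || dl$del17p) 0.7 else 0.1,
        stringsAsFactors = FALSE)
    } else {
      cyto_rows[[i]] <- data.frame(
        patient_id = ids[i], del17p = FALSE,
        del17p_clonality = NA_real_,
        upd17p = any(a$mutant_copies == 2),
        complex_karyotype = stats::runif(1) <
          if (bfrac[i] > 0) 0.7 else 0.1,
        stringsAsFactors = FALSE)
    }

    sv <- sample_survival(bfrac[i], a$n_mutations, params)
    os[i] <- sv$os_months; ev[i] <- sv$os_event; stratum[i] <- sv$stratum
  }

  patients <- data.frame(patient_id = ids, subtype = subtypes,
                         os_months = os, os_event = ev,
                         stringsAsFactors = FALSE)
  variants <- do.call(rbind, var_rows[!vapply(var_rows, is.null, logical(1))])
  cyto <- do.call(rbind, cyto_rows)

  list(cohort = tp53_cohort(patients, variants, cyto),
       truth = data.frame(patient_id = ids, class = classes,
                          stratum = stratum, biallelic_fraction = bfrac,
                          n_true_hits = nhits, stringsAsFactors = FALSE),
       architectures = archs)
}

#' Simulate a cohort with a planted hazard change-point in VAF
#'
#' A stylized scenario for validating the cutoff search: mutated patients
#' receive a true combined VAF drawn uniformly on `vaf_range`, and their
#' hazard stratum jumps at `changepoint` (above it the biallelic median
#' applies, below it the monoallelic median; wild-type patients keep the
#' wild-type median). Observed VAFs add binomial read noise at `depth`. The
#' default change-point is 23%, the cutoff reported for real myeloid
#' cohorts.
#'
#' @param n Number of patients.
#' @param changepoint True VAF at which the hazard jumps (fraction).
#' @param wt_fraction Share of wild-type patients. Default 0.4.
#' @param vaf_range Range of true combined VAFs for mutated patients.
#' @param median_os Per-stratum medians as in [sim_params()].
#' @param depth Mean read depth.
#' @param censor_rate Censoring probability.
#' @param seed Integer seed.
#' @return List with `cohort` (a `tp53_cohort`) and `truth` (data.frame:
#'   `patient_id`, `true_vaf`, `stratum`).
#' @export
simulate_changepoint_cohort <- function(n = 1000L, changepoint = 0.23,
                                        wt_fraction = 0.4,
                                        vaf_range = c(0.02, 0.60),
                                        median_os = c(WT = 42,
                                                      monoallelic = 29,
                                                      biallelic = 14),
                                        depth = 500, censor_rate = 0.2,
                                        seed = 1L) {
  stopifnot(n >= 1, changepoint > 0, changepoint < vaf_range[2])
  set.seed(seed)
  ids <- sprintf("P%04d", seq_len(n))
  mutated <- stats::runif(n) >= wt_fraction
  true_vaf <- ifelse(mutated,
                     stats::runif(n, vaf_range[1], vaf_range[2]), 0)
  stratum <- ifelse(!mutated, "WT",
                    ifelse(true_vaf > changepoint, "biallelic", "monoallelic"))
  med <- unname(median_os[stratum])
  t_event <- stats::rexp(n, rate = log(2) / med)
  if (censor_rate >= 1) {
    os <- numeric(n); cens <- rep(TRUE, n)
  } else if (censor_rate > 0) {
    bounds <- vapply(median_os, censor_bound, numeric(1), rate = censor_rate)
    t_cens <- stats::runif(n, 0, unname(bounds[stratum]))
    cens <- t_event > t_cens
    os <- pmin(t_event, t_cens)
  } else {
    os <- t_event; cens <- rep(FALSE, n)
  }

  dd <- pmax(1L, stats::rpois(n, depth))
  obs <- ifelse(mutated, stats::rbinom(n, dd, pmin(true_vaf, 1)) / dd, 0)
  keep <- mutated & obs > 0
  ann <- sample_effects(sum(keep))
  variants <- data.frame(patient_id = ids[keep], effect = ann$effect,
                         protein_change = ann$protein_change,
                         vaf = obs[keep], stringsAsFactors = FALSE)
  patients <- data.frame(patient_id = ids,
                         subtype = sample_subtype(n),
                         os_months = os, os_event = !cens,
                         stringsAsFactors = FALSE)
  list(cohort = tp53_cohort(patients, variants),
       truth = data.frame(patient_id = ids, true_vaf = true_vaf,
                          stratum = stratum, stringsAsFactors = FALSE))
}
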