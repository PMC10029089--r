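#' @keywords internal
"_PACKAGE"

SUBTYPES <- c("pAML", "sAML", "HR_MDS", "LR_MDS", "MDS_MPN", "other")
EFFECTS <- c("missense", "truncated", "other")

#' Assemble a TP53 cohort from its three component tables
#'
#' A cohort is stored in normalized long format, mirroring the on-disk layout:
#' one row per patient, zero or more variant rows per patient, and at most one
#' cytogenetics row per patient. Patients absent from the cytogenetics table
#' simply have no cytogenetic information (this is not an error).
#'
#' @param patients data.frame with columns `patient_id`, `subtype`,
#'   `os_months` (non-negative, months), `os_event` (logical or 0/1;
#'   `TRUE` = death observed, `FALSE` = censored).
#' @param variants data.frame with columns `patient_id`, `effect`
#'   (`missense`/`truncated`/`other`), `protein_change` (string or `NA`),
#'   `vaf` (fraction in \[0, 1\]).
#' @param cyto data.frame with columns `patient_id`, `del17p` (logical),
#'   `del17p_clonality` (fraction or `NA` for unknown), `upd17p` (logical),
#'   `complex_karyotype` (logical). May be `NULL` or empty.
#'
#' @return An object of class `"tp53_cohort"`: a list with elements
#'   `patients`, `variants`, `cyto`.
#' @seealso [read_cohort()], [write_cohort()], [simulate_cohort()]
#' @export
tp53_cohort <- function(patients, variants = NULL, cyto = NULL) {
  patients <- as.data.frame(patients)
  req <- c("patient_id", "subtype", "os_months", "os_event")
  if (!all(req %in% names(patients))) {
    stop("patients table must have columns: ", paste(req, collapse = ", "))
  }
  patients$patient_id <- as.character(patients$patient_id)
  if (anyDuplicated(patients$patient_id)) {
    dup <- unique(patients$patient_id[duplicated(patients$patient_id)])
    stop("duplicate patient_id in patients table: ",
         paste(dup, collapse = ", "))
  }
  unknown <- !(patients$subtype %in% SUBTYPES)
  if (any(unknown)) {
    warning("unknown subtype for patient(s) ",
            paste(patients$patient_id[unknown], collapse = ", "),
            "; recoded as 'other'")
    patients$subtype[unknown] <- "other"
  }
  patients$subtype <- factor(patients$subtype, levels = SUBTYPES)
  patients$os_months <- as.numeric(patients$os_months)
  if (any(!is.finite(patients$os_months)) || any(patients$os_months < 0)) {
    stop("os_months must be finite and non-negative")
  }
  patients$os_event <- as.logical(patients$os_event)

  if (is.null(variants)) {
    variants <- data.frame(patient_id = character(), effect = character(),
                           protein_change = character(), vaf = numeric())
  }
  variants <- as.data.frame(variants)
  if (!"protein_change" %in% names(variants)) variants$protein_change <- NA_character_
  variants$patient_id <- as.character(variants$patient_id)
  variants$effect <- as.character(variants$effect)
  variants$protein_change <- as.character(variants$protein_change)
  variants$protein_change[!is.na(variants$protein_change) &
                            variants$protein_change == ""] <- NA_character_
  variants$vaf <- as.numeric(variants$vaf)
  if (nrow(variants)) {
    if (!all(variants$effect %in% EFFECTS)) {
      stop("variant effect must be one of: ", paste(EFFECTS, collapse = ", "))
    }
    if (any(!is.finite(variants$vaf)) ||
        any(variants$vaf < 0 | variants$vaf > 1)) {
      bad <- which(!is.finite(variants$vaf) | variants$vaf < 0 | variants$vaf > 1)
      stop("variant VAF outside [0, 1] in variant row(s): ",
           paste(bad, collapse = ", "))
    }
    orphan <- setdiff(variants$patient_id, patients$patient_id)
    if (length(orphan)) {
      stop("variants refer to patient_id absent from patients table: ",
           paste(orphan, collapse = ", "))
    }
  }

  if (is.null(cyto)) {
    cyto <- data.frame(patient_id = character(), del17p = logical(),
                       del17p_clonality = numeric(), upd17p = logical(),
                       complex_karyotype = logical())
  }
  cyto <- as.data.frame(cyto)
  cyto$patient_id <- as.character(cyto$patient_id)
  if (nrow(cyto)) {
    cyto$del17p <- as.logical(cyto$del17p)
    cyto$del17p_clonality <- as.numeric(cyto$del17p_clonality)
    cyto$upd17p <- as.logical(cyto$upd17p)
    cyto$complex_karyotype <- as.logical(cyto$complex_karyotype)
    if (anyDuplicated(cyto$patient_id)) {
      stop("duplicate patient_id in cytogenetics table")
    }
    orphan <- setdiff(cyto$patient_id, patients$patient_id)
    if (length(orphan)) {
      stop("cytogenetics refer to patient_id absent from patients table: ",
           paste(orphan, collapse = ", "))
    }
    known <- !is.na(cyto$del17p_clonality)
    if (any(known & !cyto$del17p)) {
      stop("del17p_clonality given for patient(s) without del17p: ",
           paste(cyto$patient_id[known & !cyto$del17p], collapse = ", "))
    }
    if (any(cyto$del17p_clonality[known] < 0 | cyto$del17p_clonality[known] > 1)) {
      stop("del17p_clonality must lie in [0, 1]")
    }
  }

  structure(list(patients = patients, variants = variants, cyto = cyto),
            class = "tp53_cohort")
}

#' @export
print.tp53_cohort <- function(x, ...) {
  n <- nrow(x$patients)
  mut <- length(unique(x$variants$patient_id))
  cat(sprintf("TP53 cohort: %d patients, %d TP53-mutated (%d variant rows), %d with cytogenetics\n",
              n, mut, nrow(x$variants), nrow(x$cyto)))
  cat(sprintf("  events: %d observed deaths, %d censored\n",
              sum(x$patients$os_event), sum(!x$patients$os_event)))
  invisible(x)
}

#' Number of patients in a cohort
#' @param x A `tp53_cohort`.
#' @param ... Unused.
#' @export
length.tp53_cohort <- function(x) nrow(x$patients)

#' Read a cohort from tab-separated files
#'
#' Reads the three normalized tables and joins them on `patient_id`. VAFs and
#' del(17p) clonalities are given in percent (0-100) on disk and converted to
#' fractions internally. Patients missing from the cytogenetics file get no
#' cytogenetic record; a variant or cytogenetics row whose `patient_id` is
#' absent from the patients file is a hard error.
#'
#' Expected headers:
#' \describe{
#'   \item{patients.tsv}{`patient_id`, `subtype`, `os_months`, `os_event` (0/1)}
#'   \item{variants.tsv}{`patient_id`, `effect`, `protein_change`, `vaf_percent`}
#'   \item{cyto.tsv}{`patient_id`, `del17p` (0/1), `del17p_clonality_percent`
#'     (blank = unknown), `upd17p` (0/1), `complex_karyotype` (0/1)}
#' }
#'
#' @param patients_path,variants_path,cyto_path File paths; `variants_path`
#'   and `cyto_path` may be `NULL` (no variants / no cytogenetics).
#' @return A `"tp53_cohort"` object (VAFs as fractions).
#' @export
read_cohort <- function(patients_path, variants_path = NULL, cyto_path = NULL) {
  patients <- utils::read.delim(patients_path, colClasses = c(patient_id = "character"))

  variants <- NULL
  if (!is.null(variants_path)) {
    v <- utils::read.delim(variants_path, colClasses = c(patient_id = "character"))
    if (!"vaf_percent" %in% names(v)) {
      stop("variants file must have a vaf_percent column")
    }
    bad <- which(!is.finite(v$vaf_percent) | v$vaf_percent < 0 | v$vaf_percent > 100)
    if (length(bad)) {
      stop("vaf_percent outside [0, 100] in variants file row(s): ",
           paste(bad, collapse = ", "))
    }
    v$vaf <- v$vaf_percent / 100
    v$vaf_percent <- NULL
    variants <- v
  }

  cyto <- NULL
  if (!is.null(cyto_path)) {
    cy <- utils::read.delim(cyto_path, colClasses = c(patient_id = "character"))
    if (!"del17p_clonality_percent" %in% names(cy)) {
      stop("cyto file must have a del17p_clonality_percent column")
    }
    cl <- cy$del17p_clonality_percent
    if (any(!is.na(cl) & (cl < 0 | cl > 100))) {
      stop("del17p_clonality_percent outside [0, 100] in cyto file")
    }
    cy$del17p_clonality <- cl / 100
    cy$del17p_clonality_percent <- NULL
    cyto <- cy
  }

  tp53_cohort(patients, variants, cyto)
}

#' Write a cohort to tab-separated files
#'
#' Inverse of [read_cohort()]: writes `patients.tsv`, `variants.tsv` and
#' `cyto.tsv` under `dir`, converting fractions back to percent.
#'
#' @param cohort A `tp53_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the three file paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "tp53_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("patients.tsv", "variants.tsv", "cyto.tsv"))

  p <- cohort$patients
  p$os_event <- as.integer(p$os_event)
  utils::write.table(p, paths[1], sep = "\t", quote = FALSE, row.names = FALSE)

  v <- cohort$variants
  v$vaf_percent <- 100 * v$vaf
  v$vaf <- NULL
  utils::write.table(v, paths[2], sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")

  cy <- cohort$cyto
  cy$del17p_clonality_percent <- 100 * cy$del17p_clonality
  cy$del17p_clonality <- NULL
  cy$del17p <- as.integer(cy$del17p)
  cy$upd17p <- as.integer(cy$upd17p)
  cy$complex_karyotype <- as.integer(cy$complex_karyotype)
  cy <- cy[, c("patient_id", "del17p", "del17p_clonality_percent",
               "upd17p", "complex_karyotype")]
  utils::write.table(cy, paths[3], sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(paths)
}

#' Write allelic-configuration calls to a TSV file
#'
#' One row per patient, in the order of the calls table:
#' `patient_id`, `label`, `rule_fired`, `combined_vaf_percent`,
#' `evidence_note`. Reading the file back with [read_calls()] reproduces the
#' labels exactly.
#'
#' @param cohort The `tp53_cohort` the calls were made on.
#' @param calls data.frame from [classify_allelic()]; must contain exactly the
#'   cohort's patients (any order).
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_calls <- function(cohort, calls, path) {
  stopifnot(inherits(cohort, "tp53_cohort"), is.data.frame(calls))
  if (!setequal(calls$patient_id, cohort$patients$patient_id) ||
      nrow(calls) != nrow(cohort$patients)) {
    stop("calls must contain exactly one row per cohort patient")
  }
  out <- data.frame(
    patient_id = as.character(calls$patient_id),
    label = as.character(calls$label),
    rule_fired = as.character(calls$rule_fired),
    combined_vaf_percent = 100 * calls$combined_vaf,
    evidence_note = calls$evidence_note,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read allelic-configuration calls written by [write_calls()]
#'
#' @param path Path to a calls TSV.
#' @return data.frame with columns `patient_id`, `label`, `rule_fired`,
#'   `combined_vaf` (fraction), `evidence_note`.
#' @export
read_calls <- function(path) {
  x <- utils::read.delim(path, colClasses = c(patient_id = "character"),
                         na.strings = character())
  data.frame(
    patient_id = x$patient_id,
    label = factor(x$label, levels = ALLELIC_LEVELS),
    rule_fired = factor(x$rule_fired, levels = RULE_LEVELS),
    combined_vaf = x$combined_vaf_percent / 100,
    evidence_note = as.character(x$evidence_note),
    stringsAsFactors = FALSE
  )
}
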