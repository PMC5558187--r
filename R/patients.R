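#' Patient severity under the dominant (additive) model
#'
#' For the autosomal dominant gene the patient score is the total of the
#' per-allele mutation severities, so one mild mutation scores 1 and two
#' severe mutations (one per allele) score 4.
#'
#' @param allele_scores Integer vector of 1 or 2 per-allele severities, each
#'   in `{1, 2}`.
#' @return Integer patient score in `{1, 2, 3, 4}`.
#' @examples
#' score_patient_dominant(c(2, 2))  # 4
#' @export
score_patient_dominant <- function(allele_scores) {
  if (length(allele_scores) < 1 || length(allele_scores) > 2) {
    abort("Dominant patients carry mutations on one or two alleles.")
  }
  if (!all(allele_scores %in% c(1L, 2L))) {
    abort("Allele severities must be 1 (mild) or 2 (severe).")
  }
  as.integer(sum(allele_scores))
}

#' Patient severity under the recessive (minimum-allele) model
#'
#' For the autosomal recessive gene both alleles must be mutated; the allele
#' carrying the worst mutation is taken as not expressed, so the patient
#' score is the minimum of the two allele severities.
#'
#' @param allele1_score,allele2_score Severities in `{1, 2}`.
#' @return Integer patient score in `{1, 2}`.
#' @examples
#' score_patient_recessive(1, 2)  # 1
#' @export
score_patient_recessive <- function(allele1_score, allele2_score) {
  if (length(allele1_score) != 1 || length(allele2_score) != 1 ||
      is.na(allele1_score) || is.na(allele2_score)) {
    abort("Recessive disease requires mutations in both alleles; a single mutated allele is inconsistent with the inheritance model.")
  }
  if (!all(c(allele1_score, allele2_score) %in% c(1L, 2L))) {
    abort("Allele severities must be 1 (mild) or 2 (severe).")
  }
  as.integer(min(allele1_score, allele2_score))
}

split_allele <- function(x) {
  if (is.na(x) || !nzchar(x)) character() else strsplit(x, ";", fixed = TRUE)[[1]]
}

# Severity of one allele given per-mutation calls; an allele carrying several
# mutations (seen only for the dominant gene) scores as its worst mutation.
allele_severity <- function(hgvs, gene, calls, patient_id) {
  if (length(hgvs) == 0) return(NA_integer_)
  key <- paste(gene, hgvs)
  sev <- calls[key]
  if (anyNA(sev)) {
    abort(paste0("No severity call for patient ", patient_id, " mutation(s): ",
                 paste(hgvs[is.na(sev)], collapse = ", ")))
  }
  if (length(sev) > 1) {
    warn(paste0("Patient ", patient_id, " carries ", length(sev),
                " mutations on one allele; using the allele's worst mutation."))
  }
  as.integer(max(sev))
}

#' Score a patient cohort from per-mutation severity calls
#'
#' Dispatches each patient to the gene's inheritance model: SLC7A9 patients
#' get the additive score (1-4), SLC3A1 patients the minimum-allele score
#' (1-2). Patients with no identified mutation are excluded with a message;
#' SLC3A1 patients with only one mutated allele are excluded with a warning
#' (their genotype is inconsistent with recessive disease); a patient listed
#' under both genes is an error.
#'
#' @param patients Patient genotype tibble with columns `patient_id`, `gene`,
#'   `allele1_mutations`, `allele2_mutations` (semicolon-separated HGVS p.
#'   strings; empty string = no mutation on that allele).
#' @param calls Either a variant tibble with a `severity` column (from
#'   [call_severity()]) or a named integer vector keyed `"<gene> <hgvs_p>"`.
#' @return Tibble with columns `patient_id`, `gene`, `score`, `model`.
#' @export
score_cohort <- function(patients, calls) {
  if (is.data.frame(calls)) {
    calls <- stats::setNames(calls$severity, paste(calls$gene, calls$hgvs_p))
  }
  dup <- unique(patients$patient_id[duplicated(patients$patient_id)])
  if (length(dup) > 0) {
    both <- vapply(dup, function(id) {
      length(unique(patients$gene[patients$patient_id == id])) > 1
    }, logical(1))
    if (any(both)) {
      abort(paste0("Patient(s) with mutations in both genes must be excluded before scoring: ",
                   paste(dup[both], collapse = ", ")))
    }
  }
  n <- nrow(patients)
  keep <- logical(n)
  score <- integer(n)
  model <- character(n)
  for (i in seq_len(n)) {
    pid <- patients$patient_id[i]
    gene <- patients$gene[i]
    a1 <- split_allele(patients$allele1_mutations[i])
    a2 <- split_allele(patients$allele2_mutations[i])
    if (length(a1) == 0 && length(a2) == 0) {
      inform(paste0("Patient ", pid,
                    " has no identified mutation; excluded from scoring."))
      next
    }
    s1 <- allele_severity(a1, gene, calls, pid)
    s2 <- allele_severity(a2, gene, calls, pid)
    model[i] <- GENE_MODEL[[gene]]
    if (model[i] == "RECESSIVE_MIN") {
      if (is.na(s1) || is.na(s2)) {
        warn(paste0("Recessive patient ", pid,
                    " has only one mutated allele; excluded from scoring."))
        next
      }
      score[i] <- score_patient_recessive(s1, s2)
    } else {
      score[i] <- score_patient_dominant(c(s1, s2)[!is.na(c(s1, s2))])
    }
    keep[i] <- TRUE
  }
  tibble(patient_id = as.character(patients$patient_id[keep]),
         gene = as.character(patients$gene[keep]),
         score = score[keep], model = model[keep])
}
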