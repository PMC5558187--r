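VARIANT_COLS <- c("gene", "hgvs_p", "consequence", "allele_frequency",
                  "consurf", "ddg", SEVERITY_METHODS, "disease_associated")
PATIENT_COLS <- c("patient_id", "gene", "allele1_mutations", "allele2_mutations")

# Atomic write: write to a sibling temp file, then rename into place.
write_atomic <- function(writer, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) {
    abort(paste0("Could not move temporary file into place at ", path))
  }
  invisible(path)
}

#' Write / read the variant table
#'
#' The variant table is a UTF-8, Unix-newline TSV with columns `gene`,
#' `hgvs_p`, `consequence`, `allele_frequency`, `consurf`, `ddg`, the six
#' predictor score columns (`sift`, `polyphen2`, `mutation_assessor`,
#' `fathmm`, `condel`, `cadd`) and `disease_associated`, plus an optional
#' `true_severity` column for simulated data. Missing annotations are
#' encoded as the empty string (never `"."`). The reader validates every
#' row: the HGVS string must parse and agree with the `consequence` column
#' (splice-site rows are exempt from the agreement check since splice
#' changes have no faithful protein notation), `consurf` must lie in 1..9
#' and `allele_frequency` in `[0, 1]`; violations are reported with their
#' row numbers.
#'
#' @param variants Variant tibble.
#' @param path File path.
#' @return `read_variant_table()` returns the validated tibble;
#'   `write_variant_table()` returns `path` invisibly.
#' @export
write_variant_table <- function(variants, path) {
  write_atomic(function(tmp) readr::write_tsv(variants, tmp, na = ""), path)
}

#' @rdname write_variant_table
#' @export
read_variant_table <- function(path) {
  x <- readr::read_tsv(path, na = "", show_col_types = FALSE,
                       progress = FALSE)
  extra <- setdiff(names(x), c(VARIANT_COLS, "true_severity"))
  if (length(extra) > 0) {
    abort(paste0("Unknown column(s) in variant table: ",
                 paste(extra, collapse = ", ")))
  }
  missing <- setdiff(VARIANT_COLS, names(x))
  if (length(missing) > 0) {
    abort(paste0("Variant table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  fail <- function(rows, what) {
    abort(paste0("Invalid variant table: ", what, " at row(s) ",
                 paste(utils::head(rows, 10), collapse = ", "), "."))
  }
  rows <- seq_len(nrow(x))
  if (any(bad <- !x$gene %in% GENES)) fail(rows[bad], "unknown gene")
  if (any(bad <- !x$consequence %in% CONSEQUENCES)) {
    fail(rows[bad], "unknown consequence")
  }
  parsed <- tryCatch(parse_hgvs_p(x$hgvs_p), error = function(e) {
    abort(paste0("Invalid variant table: ", conditionMessage(e)))
  })
  mismatch <- parsed$consequence != x$consequence &
    x$consequence != "SPLICE_SITE"
  if (any(mismatch)) {
    fail(rows[mismatch], "hgvs_p notation disagrees with consequence column")
  }
  if (any(bad <- !is.na(x$consurf) & !(x$consurf %in% 1:9))) {
    fail(rows[bad], "consurf outside 1..9")
  }
  if (any(bad <- !is.na(x$allele_frequency) &
            (x$allele_frequency < 0 | x$allele_frequency > 1))) {
    fail(rows[bad], "allele_frequency outside [0, 1]")
  }
  x$consurf <- as.integer(x$consurf)
  x$disease_associated <- as.logical(x$disease_associated)
  x$.row <- rows
  x
}

#' Write / read the patient table
#'
#' One row per patient: `patient_id`, `gene`, `allele1_mutations`,
#' `allele2_mutations` (semicolon-separated HGVS p. strings; empty = no
#' mutation on that allele), the phenotype columns, and optionally
#' `true_score` for simulated cohorts. CSV or TSV is chosen from the file
#' extension. On reading, patients listed under both genes are excluded
#' with a warning (their gene-specific severity score is undefined), as are
#' recessive-gene patients with fewer than two mutated alleles
#' (`strict = TRUE` turns either into an error).
#'
#' @param cohort A list with `genotypes` and `phenotypes` tibbles (as from
#'   [simulate_cohort()]), or a single merged tibble.
#' @param path File path ending in `.csv` or `.tsv`.
#' @param strict Escalate exclusions to errors.
#' @return `read_patient_table()` returns a list with `genotypes` and
#'   `phenotypes`.
#' @export
write_patient_table <- function(cohort, path) {
  tab <- if (is.data.frame(cohort)) cohort else {
    dplyr::left_join(cohort$genotypes, cohort$phenotypes, by = "patient_id")
  }
  writer <- if (grepl("\\.csv$", path)) readr::write_csv else readr::write_tsv
  write_atomic(function(tmp) writer(tab, tmp, na = ""), path)
}

#' @rdname write_patient_table
#' @export
read_patient_table <- function(path, strict = FALSE) {
  reader <- if (grepl("\\.csv$", path)) readr::read_csv else readr::read_tsv
  x <- reader(path, na = "", show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(PATIENT_COLS, names(x))
  if (length(missing) > 0) {
    abort(paste0("Patient table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  for (col in c("allele1_mutations", "allele2_mutations")) {
    x[[col]] <- ifelse(is.na(x[[col]]), "", x[[col]])
    muts <- unlist(lapply(x[[col]], split_allele))
    if (length(muts) > 0) {
      ok <- tryCatch({parse_hgvs_p(muts); TRUE},
                     error = function(e) conditionMessage(e))
      if (!isTRUE(ok)) {
        bad_ids <- x$patient_id[vapply(x[[col]], function(a) {
          any(vapply(split_allele(a), function(h) {
            inherits(tryCatch(parse_hgvs_p(h), error = function(e) e), "error")
          }, logical(1)))
        }, logical(1))]
        abort(paste0("Malformed mutation list for patient(s): ",
                     paste(bad_ids, collapse = ", "), " — ", ok))
      }
    }
  }
  if (any(bad <- !x$gene %in% GENES)) {
    abort(paste0("Unknown gene for patient(s): ",
                 paste(x$patient_id[bad], collapse = ", ")))
  }
  flag <- function(msg) if (strict) abort(msg) else warn(msg)
  both <- unique(x$patient_id[ave(as.integer(factor(x$gene, GENES)),
                                  x$patient_id,
                                  FUN = function(g) length(unique(g))) > 1])
  if (length(both) > 0) {
    flag(paste0("Excluding patient(s) with mutations in both genes: ",
                paste(both, collapse = ", ")))
    x <- x[!x$patient_id %in% both, , drop = FALSE]
  }
  single <- x$gene == "SLC3A1" &
    (!nzchar(x$allele1_mutations) | !nzchar(x$allele2_mutations))
  if (any(single)) {
    flag(paste0("Excluding recessive (SLC3A1) patient(s) without mutations in both alleles: ",
                paste(x$patient_id[single], collapse = ", ")))
    x <- x[!single, , drop = FALSE]
  }
  geno_cols <- intersect(c(PATIENT_COLS, "true_score"), names(x))
  pheno_cols <- c("patient_id", setdiff(names(x), geno_cols))
  list(genotypes = x[, geno_cols, drop = FALSE],
       phenotypes = x[, pheno_cols, drop = FALSE])
}

collect_warnings <- function(expr) {
  warnings <- character()
  value <- withCallingHandlers(expr, warning = function(w) {
    warnings <<- c(warnings, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  list(value = value, warnings = warnings)
}

#' Run the full severity-association pipeline
#'
#' End-to-end analysis for one predictor method: call per-mutation severity,
#' aggregate per-patient scores under each gene's inheritance model, group
#' patients and compare phenotype distributions between groups (Wilcoxon +
#' Bonferroni), contrast disease-associated against population-only
#' variants, and write all result tables plus a run manifest to `out_dir`.
#' All writes are atomic and the manifest is written last, so a directory
#' containing `manifest.json` holds a complete run.
#'
#' @param variants Variant tibble or path to a variant TSV.
#' @param patients Cohort list (genotypes + phenotypes) or path to a patient
#'   table.
#' @param method Predictor method name or `method_spec`.
#' @param out_dir Output directory (created if absent).
#' @param min_group_n Minimum severity-group size for testing.
#' @param family_size Optional Bonferroni family-size override (per gene).
#' @param mode Rank-test mode, see [wilcoxon_rank_sum()].
#' @return Invisibly, a list with `calls`, `scores`, and per-gene `groups`,
#'   `summary`, `comparisons`, `contrasts`, plus the `manifest`.
#' @export
run_pipeline <- function(variants, patients, method, out_dir,
                         min_group_n = 2L, family_size = NULL, mode = "auto") {
  input_files <- c(
    variants = if (is.character(variants)) variants else NA_character_,
    patients = if (is.character(patients)) patients else NA_character_
  )
  if (is.character(variants)) variants <- read_variant_table(variants)
  if (is.character(patients)) patients <- read_patient_table(patients)
  spec <- if (inherits(method, "method_spec")) method else method_spec(method)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  run <- collect_warnings({
    calls <- call_severity(variants, spec)
    scores <- score_cohort(patients$genotypes, calls)
    per_gene <- list()
    for (gene in intersect(GENES, unique(scores$gene))) {
      gscores <- scores[scores$gene == gene, , drop = FALSE]
      groups <- group_patients(gscores, min_n = min_group_n)
      comparisons <- compare_groups(groups, patients$phenotypes,
                                    family_size = family_size, mode = mode)
      summ <- summarize_groups(groups, patients$phenotypes)
      disease <- variants[variants$gene == gene & variants$disease_associated, ]
      popn <- variants[variants$gene == gene & !variants$disease_associated, ]
      contrasts <- if (nrow(disease) > 0 && nrow(popn) > 0) {
        lapply(stats::setNames(CONTRAST_ATTRIBUTES, CONTRAST_ATTRIBUTES),
               function(a) contrast_sets(disease, popn, a, mode = mode))
      } else list()
      per_gene[[gene]] <- list(groups = groups, summary = summ,
                               comparisons = comparisons,
                               contrasts = contrasts)
    }
    list(calls = calls, scores = scores, per_gene = per_gene)
  })
  res <- run$value

  out_calls <- res$calls[, c("gene", "hgvs_p", "consequence", "severity",
                             "severity_reason")]
  write_atomic(function(tmp) readr::write_tsv(out_calls, tmp, na = ""),
               file.path(out_dir, "severity_calls.tsv"))
  write_atomic(function(tmp) readr::write_tsv(res$scores, tmp, na = ""),
               file.path(out_dir, "patient_scores.tsv"))
  for (gene in names(res$per_gene)) {
    g <- res$per_gene[[gene]]
    write_atomic(function(tmp) readr::write_tsv(g$summary, tmp, na = ""),
                 file.path(out_dir, paste0("group_summary_", gene, ".tsv")))
    write_atomic(function(tmp) readr::write_tsv(g$comparisons, tmp, na = ""),
                 file.path(out_dir, paste0("comparisons_", gene, ".tsv")))
    if (length(g$contrasts) > 0) {
      ct <- dplyr::bind_rows(lapply(g$contrasts, function(cr) {
        tibble(attribute = cr$attribute,
               n_disease = cr$n[["disease"]],
               n_population = cr$n[["population"]],
               median_disease = cr$median[["disease"]],
               median_population = cr$median[["population"]],
               statistic = cr$test$statistic, p_raw = cr$test$p_two_sided)
      }))
      ct$p_adjusted <- bonferroni(ct$p_raw)$adjusted_p
      write_atomic(function(tmp) readr::write_tsv(ct, tmp, na = ""),
                   file.path(out_dir, paste0("contrast_", gene, ".tsv")))
    }
  }

  digests <- input_files[!is.na(input_files)]
  manifest <- list(
    tool = "cystsev",
    version = as.character(utils::packageVersion("cystsev")),
    method = spec$method,
    severe_threshold = spec$severe_threshold,
    min_group_n = min_group_n,
    family_size = family_size,
    input_digests = if (length(digests) > 0) {
      as.list(tools::md5sum(digests))
    } else list(),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    warnings = run$warnings
  )
  write_atomic(function(tmp) jsonlite::write_json(manifest, tmp,
                                                  auto_unbox = TRUE,
                                                  null = "null", digits = NA),
               file.path(out_dir, "manifest.json"))
  res$manifest <- manifest
  invisible(res)
}
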