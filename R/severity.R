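#' Per-method severity threshold specifications
#'
#' One specification per variant effect predictor, encoding the direction of
#' its score scale (for SIFT and FATHMM lower scores are more damaging, for
#' the other four higher scores are), the method's standard
#' deleterious-vs-neutral threshold, the more stringent threshold separating
#' severe (2) from mild (1) mutations, and whether a score exactly at the
#' severe threshold counts as severe. The printed inequalities differ in
#' strictness between methods and are encoded literally: SIFT severe at
#' score <= 0.025; PolyPhen2 at >= 0.80; MutationAssessor at >= 2.7; FATHMM
#' at < -8.5; Condel at > 0.672; CADD at >= 27.5.
#'
#' @param method Optional method name (one of `"sift"`, `"polyphen2"`,
#'   `"mutation_assessor"`, `"fathmm"`, `"condel"`, `"cadd"`); if omitted the
#'   full named list is returned.
#' @return A `method_spec` list (fields `method`, `direction`,
#'   `standard_threshold`, `severe_threshold`, `severe_at_threshold`,
#'   `grid_step`), or a named list of all six.
#' @examples
#' method_spec("polyphen2")$severe_threshold  # 0.8
#' @export
method_spec <- function(method = NULL) {
  specs <- list(
    sift = new_method_spec("sift", "LOWER_IS_WORSE", 0.05, 0.025,
                           severe_at_threshold = TRUE, grid_step = 0.05),
    polyphen2 = new_method_spec("polyphen2", "HIGHER_IS_WORSE", 0.5, 0.80,
                                severe_at_threshold = TRUE, grid_step = 0.05),
    mutation_assessor = new_method_spec("mutation_assessor", "HIGHER_IS_WORSE",
                                        1.9, 2.7,
                                        severe_at_threshold = TRUE,
                                        grid_step = 0.5),
    fathmm = new_method_spec("fathmm", "LOWER_IS_WORSE", -1.5, -8.5,
                             severe_at_threshold = FALSE, grid_step = 0.5),
    condel = new_method_spec("condel", "HIGHER_IS_WORSE", 0.522, 0.672,
                             severe_at_threshold = FALSE, grid_step = 0.05),
    cadd = new_method_spec("cadd", "HIGHER_IS_WORSE", 15, 27.5,
                           severe_at_threshold = TRUE, grid_step = 2.5)
  )
  if (is.null(method)) return(specs)
  method <- match.arg(method, SEVERITY_METHODS)
  specs[[method]]
}

new_method_spec <- function(method, direction, standard_threshold,
                            severe_threshold, severe_at_threshold, grid_step) {
  stopifnot(direction %in% c("LOWER_IS_WORSE", "HIGHER_IS_WORSE"))
  if (direction == "HIGHER_IS_WORSE" && severe_threshold < standard_threshold ||
      direction == "LOWER_IS_WORSE" && severe_threshold > standard_threshold) {
    abort("`severe_threshold` must be at least as stringent as `standard_threshold`.")
  }
  structure(list(method = method, direction = direction,
                 standard_threshold = standard_threshold,
                 severe_threshold = severe_threshold,
                 severe_at_threshold = severe_at_threshold,
                 grid_step = grid_step),
            class = "method_spec")
}

#' Read method specifications from a YAML file
#'
#' Allows the shipped thresholds to be overridden per run. The file maps
#' method names to fields of [method_spec()]; absent fields keep their
#' defaults.
#'
#' @param path Path to a YAML file.
#' @return Named list of `method_spec` objects.
#' @export
read_method_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  specs <- method_spec()
  for (m in names(cfg)) {
    if (!m %in% SEVERITY_METHODS) {
      abort(paste0("Unknown method in config: ", m))
    }
    s <- specs[[m]]
    for (f in names(cfg[[m]])) s[[f]] <- cfg[[m]][[f]]
    specs[[m]] <- new_method_spec(s$method, s$direction, s$standard_threshold,
                                  s$severe_threshold, s$severe_at_threshold,
                                  s$grid_step)
  }
  specs
}

severe_side <- function(score, spec, severe_threshold = spec$severe_threshold) {
  if (spec$direction == "HIGHER_IS_WORSE") {
    if (spec$severe_at_threshold) score >= severe_threshold else score > severe_threshold
  } else {
    if (spec$severe_at_threshold) score <= severe_threshold else score < severe_threshold
  }
}

#' Dichotomise predictor scores into mild (1) or severe (2)
#'
#' A mutation scores 2 when its predictor score lies on the stringent side of
#' the method's severe threshold, and 1 otherwise — including scores the
#' method itself would call tolerated/neutral, for which a warning is issued
#' (the mild side of the severity threshold is unbounded).
#'
#' @param score Numeric vector of finite predictor scores.
#' @param spec A `method_spec`, see [method_spec()].
#' @param severe_threshold Override for the spec's severe threshold (used by
#'   the stabilisation scan).
#' @param warn_neutral Warn when a score is on the neutral side of the
#'   method's standard deleterious threshold.
#' @return Integer vector of severities in `{1, 2}`.
#' @examples
#' classify_mutation_severity(c(0.03, 0.01), method_spec("sift"))  # 1 2
#' @export
classify_mutation_severity <- function(score, spec,
                                       severe_threshold = spec$severe_threshold,
                                       warn_neutral = TRUE) {
  stopifnot(inherits(spec, "method_spec"))
  if (any(!is.finite(score))) {
    abort(paste0("Non-finite ", spec$method, " score(s) at position(s) ",
                 paste(which(!is.finite(score)), collapse = ", ")))
  }
  if (warn_neutral) {
    neutral <- if (spec$direction == "HIGHER_IS_WORSE") {
      score < spec$standard_threshold
    } else {
      score > spec$standard_threshold
    }
    if (any(neutral)) {
      warn(sprintf("%d score(s) fall on the neutral side of %s's standard deleterious threshold (%g); classified as mild.",
                   sum(neutral), spec$method, spec$standard_threshold))
    }
  }
  ifelse(severe_side(score, spec, severe_threshold), 2L, 1L)
}

#' Severity of non-missense mutations
#'
#' Frameshift, deletion, splice-site and nonsense mutations typically ablate
#' protein function and are assigned severity 2 without consulting a
#' predictor.
#'
#' @param consequence Character vector of consequence classes (anything but
#'   `"MISSENSE"`).
#' @return Integer vector of 2s.
#' @export
severity_for_consequence <- function(consequence) {
  bad <- !consequence %in% CONSEQUENCES
  if (any(bad)) {
    abort(paste0("Unknown consequence: ", paste(unique(consequence[bad]), collapse = ", ")))
  }
  if (any(consequence == "MISSENSE")) {
    abort("Missense mutations must be classified through classify_mutation_severity().")
  }
  rep(2L, length(consequence))
}

#' Severity calls for a variant table
#'
#' Applies [classify_mutation_severity()] to missense rows using the chosen
#' method's score column and [severity_for_consequence()] to the rest.
#'
#' @param variants Variant tibble (see [read_variant_table()]).
#' @param method Method name or `method_spec`.
#' @param severe_threshold Optional threshold override.
#' @param warn_neutral Passed through.
#' @return The variant tibble with columns `severity` (integer 1/2) and
#'   `severity_reason` (`"THRESHOLD"` or `"NON_MISSENSE_RULE"`) appended.
#' @export
call_severity <- function(variants, method, severe_threshold = NULL,
                          warn_neutral = TRUE) {
  spec <- if (inherits(method, "method_spec")) method else method_spec(method)
  if (is.null(severe_threshold)) severe_threshold <- spec$severe_threshold
  is_mis <- variants$consequence == "MISSENSE"
  score <- variants[[spec$method]]
  if (any(is_mis & is.na(score))) {
    missing <- variants$hgvs_p[is_mis & is.na(score)]
    abort(paste0("Missing ", spec$method, " score for missense mutation(s): ",
                 paste(missing, collapse = ", ")))
  }
  severity <- integer(nrow(variants))
  if (any(is_mis)) {
    severity[is_mis] <- classify_mutation_severity(
      score[is_mis], spec, severe_threshold, warn_neutral = warn_neutral)
  }
  if (any(!is_mis)) {
    severity[!is_mis] <- severity_for_consequence(variants$consequence[!is_mis])
  }
  variants$severity <- severity
  variants$severity_reason <- ifelse(is_mis, "THRESHOLD", "NON_MISSENSE_RULE")
  variants
}

#' Scan candidate severe thresholds over a patient cohort
#'
#' For each candidate threshold, all mutations are re-scored and all patients
#' re-aggregated, giving one patient-to-group assignment per grid point. The
#' scan underlies [select_stable_threshold()]: deleterious-vs-neutral
#' predictors call even mildly deleterious variants damaging, so the
#' mild/severe cut is pushed to stringencies where the patient grouping stops
#' changing.
#'
#' @param patients Patient genotype tibble (see [read_patient_table()]).
#' @param variants Variant tibble carrying the method's scores.
#' @param method Method name or `method_spec`.
#' @param grid Numeric vector of candidate severe thresholds ordered from
#'   least to most stringent.
#' @return A tibble with one row per grid point: `threshold` and
#'   `assignment` (list column of named integer patient-score vectors).
#' @export
threshold_scan <- function(patients, variants, method, grid) {
  spec <- if (inherits(method, "method_spec")) method else method_spec(method)
  if (length(grid) == 0) abort("Threshold grid is empty.")
  step <- diff(grid)
  if (spec$direction == "HIGHER_IS_WORSE" && any(step <= 0) ||
      spec$direction == "LOWER_IS_WORSE" && any(step >= 0)) {
    abort("`grid` must be ordered from least to most stringent for this method.")
  }
  assignments <- lapply(grid, function(thr) {
    called <- call_severity(variants, spec, severe_threshold = thr,
                            warn_neutral = FALSE)
    scores <- score_cohort(patients, called)
    stats::setNames(scores$score, scores$patient_id)
  })
  tibble(threshold = grid, assignment = assignments)
}

#' Select the stable severe threshold from a scan
#'
#' Finds the longest run of consecutive grid points whose patient-to-group
#' assignments are identical (ties broken toward the more stringent run) and
#' returns that run's most stringent threshold. The run must span at least
#' `min_run` grid points, otherwise the grid is too coarse to demonstrate
#' stability.
#'
#' @param scan Output of [threshold_scan()].
#' @param min_run Minimum run length (grid points).
#' @return The selected threshold (scalar).
#' @export
select_stable_threshold <- function(scan, min_run = 3L) {
  stopifnot(nrow(scan) > 0)
  n <- nrow(scan)
  run_id <- integer(n)
  run_id[1] <- 1L
  if (n > 1) {
    for (i in 2:n) {
      same <- identical(scan$assignment[[i]], scan$assignment[[i - 1]])
      run_id[i] <- if (same) run_id[i - 1] else run_id[i - 1] + 1L
    }
  }
  lens <- tabulate(run_id)
  best_len <- max(lens)
  if (best_len < min_run) {
    abort(sprintf("No run of identical groupings spans %d grid points; use a finer grid.", min_run))
  }
  # ties toward the more stringent (later) run
  best_run <- max(which(lens == best_len))
  scan$threshold[max(which(run_id == best_run))]
}

#' Build a default stabilisation grid for a method
#'
#' Starts at the method's standard deleterious threshold and moves toward
#' higher stringency in the method's native step (0.05 for the
#' probability-scaled SIFT, PolyPhen2 and Condel; 0.5 for MutationAssessor
#' and FATHMM; 2.5 for CADD).
#'
#' @param spec A `method_spec`.
#' @param n Number of grid points.
#' @return Numeric vector ordered least to most stringent.
#' @export
default_grid <- function(spec, n = 10L) {
  sgn <- if (spec$direction == "HIGHER_IS_WORSE") 1 else -1
  spec$standard_threshold + sgn * spec$grid_step * (seq_len(n) - 1L)
}
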