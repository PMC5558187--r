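#' Simulation configuration
#'
#' Bundles every parameter of the synthetic variant and cohort generator.
#' The defaults reproduce the structure of the study system: 94 disease
#' mutations in SLC3A1 and 58 in SLC7A9 against 318 and 144 population-only
#' nsSNVs; disease variants rare (frequency 0 or below 0.01%, with a small
#' chance of a common outlier), conserved (about 80% at ConSurf grades 6-9
#' versus about 40% for population variants) and destabilising (mean
#' predicted stability change -1.122 kcal/mol versus -0.668); a clinical
#' cohort of 41 recessive SLC3A1 and 32 dominant SLC7A9 patients; and
#' phenotypes that worsen with severity (higher urinary dibasic amino-acid
#' levels, earlier presentation, more stone episodes and interventions).
#'
#' Predictor scores are emitted from severity-conditional normal
#' distributions on each method's native scale and direction, truncated to
#' the method's range; with the default `noise_scale` of 1 each method
#' recovers the latent severity for roughly 95-97% of mutations, and at
#' `noise_scale = 0` the emissions are noiseless (every score falls on the
#' correct side of its threshold).
#'
#' @param seed Master seed; three component streams (variants, predictor
#'   scores, cohort) are derived from it so enlarging the cohort never
#'   perturbs the variant draws.
#' @param n_disease,n_population Named counts of disease-associated and
#'   population-only variants per gene.
#' @param protein_length Named protein lengths used to sample positions.
#' @param prop_non_missense Fraction of disease variants that are
#'   frameshift/nonsense/deletion rather than missense.
#' @param severe_prevalence Probability that a disease missense variant is
#'   latently severe (2) rather than mild (1).
#' @param consurf_weights_disease,consurf_weights_population Probability
#'   vectors over ConSurf grades 1-9.
#' @param freq_zero_disease,freq_zero_population Probability of allele
#'   frequency exactly 0 (absent from the population panel).
#' @param freq_range_disease,freq_range_population Log-uniform frequency
#'   range for non-zero draws.
#' @param freq_high_disease_prob,freq_high_disease_range Probability and
#'   log-uniform range of a common disease outlier (the p.Val142Ala-like
#'   case).
#' @param ddg_mean_disease,ddg_sd_disease,ddg_mean_population,ddg_sd_population
#'   Normal model for the predicted stability change (kcal/mol, negative =
#'   destabilising).
#' @param emission Data frame of per-method score emissions (columns
#'   `method`, `mild_mean`, `mild_sd`, `severe_mean`, `severe_sd`, `lower`,
#'   `upper`).
#' @param noise_scale Multiplier on all emission standard deviations.
#' @param cohort_n Named patient counts per gene.
#' @param p_two_alleles_dominant Probability a dominant (SLC7A9) patient has
#'   mutations on both alleles rather than one.
#' @param dominant_score_probs Optional probability vector over latent
#'   dominant scores 1-4. When supplied, dominant genotypes are constructed
#'   to hit a drawn target score (1 = one mild mutation, 2 = one severe,
#'   3 = mild + severe, 4 = severe + severe), with group sizes allocated
#'   deterministically at the target proportions, giving direct control over
#'   severity-group sizes for power studies; the default `NULL` draws
#'   genotypes from the allele-count mechanism instead.
#' @param phenotype_baseline Baseline urinary levels (micromol/mmol
#'   creatinine) for cystine, ornithine, arginine, lysine at severity
#'   score 1.
#' @param phenotype_log_sd Log-scale standard deviation of urinary levels.
#' @param phenotype_effect Log-scale increase per severity unit; arginine
#'   carries the largest planted effect, mirroring the strongest observed
#'   group difference.
#' @param age_mean,age_sd,age_effect Age at presentation (years): normal
#'   with a negative shift per severity unit, truncated at 1.
#' @param episode_rate,episode_effect,intervention_rate,intervention_effect
#'   Poisson models for three-year stone episodes and interventions;
#'   `*_effect` is the log-rate increase per severity unit.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(
    seed = 1L,
    n_disease = c(SLC3A1 = 94L, SLC7A9 = 58L),
    n_population = c(SLC3A1 = 318L, SLC7A9 = 144L),
    protein_length = c(SLC3A1 = 685L, SLC7A9 = 487L),
    prop_non_missense = 0.15,
    severe_prevalence = 0.5,
    consurf_weights_disease = c(0.04, 0.04, 0.04, 0.04, 0.04, 0.15, 0.18, 0.22, 0.25),
    consurf_weights_population = c(0.25, 0.10, 0.10, 0.075, 0.075, 0.10, 0.10, 0.10, 0.10),
    freq_zero_disease = 0.5,
    freq_range_disease = c(1e-6, 1e-4),
    freq_high_disease_prob = 0.03,
    freq_high_disease_range = c(2.7e-3, 0.31),
    freq_zero_population = 0.25,
    freq_range_population = c(1e-6, 1e-2),
    ddg_mean_disease = -1.122, ddg_sd_disease = 1.0,
    ddg_mean_population = -0.668, ddg_sd_population = 1.0,
    emission = default_emission(),
    noise_scale = 1,
    cohort_n = c(SLC3A1 = 41L, SLC7A9 = 32L),
    p_two_alleles_dominant = 0.5,
    dominant_score_probs = NULL,
    phenotype_baseline = c(cystine = 300, ornithine = 150, arginine = 100, lysine = 500),
    phenotype_log_sd = 0.5,
    phenotype_effect = c(cystine = 0.06, ornithine = 0.12, arginine = 0.45, lysine = 0.12),
    age_mean = 30, age_sd = 10, age_effect = -3,
    episode_rate = 1.5, episode_effect = 0.2,
    intervention_rate = 0.8, intervention_effect = 0.2) {
  cfg <- as.list(environment())
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

default_emission <- function() {
  data.frame(
    method      = SEVERITY_METHODS,
    mild_mean   = c(0.20, 0.40, 1.5, -4.0, 0.45, 18),
    mild_sd     = c(0.10, 0.20, 0.6, 2.2, 0.11, 4.5),
    severe_mean = c(0.005, 0.95, 3.8, -12.0, 0.85, 33),
    severe_sd   = c(0.010, 0.08, 0.6, 1.8, 0.09, 2.8),
    lower       = c(0, 0, -5.5, -17, 0, 0),
    upper       = c(1, 1, 6.0, 10, 1, 99),
    stringsAsFactors = FALSE
  )
}

validate_sim_config <- function(cfg) {
  problems <- character()
  chk <- function(ok, msg) if (!ok) problems <<- c(problems, msg)
  chk(abs(sum(cfg$consurf_weights_disease) - 1) < 1e-8 &&
        length(cfg$consurf_weights_disease) == 9,
      "consurf_weights_disease must be 9 probabilities summing to 1")
  chk(abs(sum(cfg$consurf_weights_population) - 1) < 1e-8 &&
        length(cfg$consurf_weights_population) == 9,
      "consurf_weights_population must be 9 probabilities summing to 1")
  for (f in c("freq_zero_disease", "freq_zero_population", "severe_prevalence",
              "prop_non_missense", "p_two_alleles_dominant",
              "freq_high_disease_prob")) {
    chk(cfg[[f]] >= 0 && cfg[[f]] <= 1, paste(f, "must lie in [0, 1]"))
  }
  chk(all(cfg$emission$mild_sd >= 0) && all(cfg$emission$severe_sd >= 0),
      "emission standard deviations must be non-negative")
  chk(cfg$noise_scale >= 0, "noise_scale must be non-negative")
  chk(is.null(cfg$dominant_score_probs) ||
        (length(cfg$dominant_score_probs) == 4 &&
           abs(sum(cfg$dominant_score_probs) - 1) < 1e-8),
      "dominant_score_probs must be 4 probabilities summing to 1")
  chk(cfg$phenotype_log_sd > 0, "phenotype_log_sd must be positive")
  chk(cfg$age_sd > 0, "age_sd must be positive")
  chk(cfg$episode_rate > 0 && cfg$intervention_rate > 0,
      "Poisson rates must be positive")
  chk(all(GENES %in% names(cfg$n_disease)) &&
        all(GENES %in% names(cfg$protein_length)),
      "per-gene counts must name SLC3A1 and SLC7A9")
  if (length(problems) > 0) {
    abort(paste0("Invalid simulation config:\n- ",
                 paste(problems, collapse = "\n- ")))
  }
  invisible(cfg)
}

component_seeds <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) {
    if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  stats::setNames(sample.int(2147483646L, 3), c("variants", "scores", "cohort"))
}

rtrunc_norm <- function(n, mean, sd, lower, upper) {
  pmin(pmax(stats::rnorm(n, mean, sd), lower), upper)
}

#' Simulate predictor scores conditional on latent severity
#'
#' Draws one score per method from the severity-conditional emission model:
#' severe mutations score on the damaging side of each method's scale (low
#' for SIFT and FATHMM, high for the others), mild ones on the tolerated
#' side, with overlap controlled by `noise_scale`.
#'
#' @param true_severity Integer vector of latent severities in `{1, 2}`.
#' @param config A [sim_config()].
#' @return Tibble with one row per input and one column per method.
#' @export
simulate_predictor_scores <- function(true_severity, config = sim_config()) {
  stopifnot(all(true_severity %in% c(1L, 2L)))
  n <- length(true_severity)
  em <- config$emission
  out <- lapply(seq_len(nrow(em)), function(i) {
    sev <- true_severity == 2L
    mean <- ifelse(sev, em$severe_mean[i], em$mild_mean[i])
    sd <- ifelse(sev, em$severe_sd[i], em$mild_sd[i]) * config$noise_scale
    rtrunc_norm(n, mean, sd, em$lower[i], em$upper[i])
  })
  names(out) <- em$method
  as_tibble(out)
}

#' Simulate a variant table
#'
#' Generates disease-associated and population-only variant sets for both
#' genes under the configured annotation models. Disease variants carry a
#' latent true severity (`true_severity`; non-missense variants are always
#' latently severe); population variants are emitted from the mild score
#' model and have `true_severity = NA`. Positions are sampled without
#' replacement within each gene so every `(gene, hgvs_p)` key is unique.
#'
#' @param config A [sim_config()].
#' @return Variant tibble in the [read_variant_table()] schema plus
#'   `true_severity`.
#' @export
simulate_variants <- function(config = sim_config()) {
  validate_sim_config(config)
  seeds <- component_seeds(config$seed)
  set.seed(seeds[["variants"]])
  per_gene <- lapply(GENES, function(gene) {
    nd <- config$n_disease[[gene]]
    np <- config$n_population[[gene]]
    len <- config$protein_length[[gene]]
    if (nd + np > len) {
      abort(sprintf("Requested %d variants for %s but only %d positions available.",
                    nd + np, gene, len))
    }
    pos <- sample.int(len, nd + np)
    disease <- c(rep(TRUE, nd), rep(FALSE, np))
    n <- nd + np

    wt <- sample(AA_TABLE$three, n, replace = TRUE)
    mut <- vapply(wt, function(w) sample(setdiff(AA_TABLE$three, w), 1),
                  character(1))
    consequence <- rep("MISSENSE", n)
    non_mis <- disease & stats::runif(n) < config$prop_non_missense
    consequence[non_mis] <- sample(c("FRAMESHIFT", "NONSENSE", "DELETION"),
                                   sum(non_mis), replace = TRUE,
                                   prob = c(0.5, 0.3, 0.2))
    suffix <- ifelse(consequence == "MISSENSE", mut,
                     c(FRAMESHIFT = "fs", NONSENSE = "Ter",
                       DELETION = "del")[consequence])
    hgvs <- paste0("p.", wt, pos, suffix)

    true_sev <- rep(NA_integer_, n)
    true_sev[disease] <- 1L + stats::rbinom(nd, 1, config$severe_prevalence)
    true_sev[non_mis] <- 2L

    consurf <- integer(n)
    consurf[disease] <- sample(1:9, nd, replace = TRUE,
                               prob = config$consurf_weights_disease)
    consurf[!disease] <- sample(1:9, np, replace = TRUE,
                                prob = config$consurf_weights_population)

    freq <- numeric(n)
    u <- stats::runif(n)
    for (i in seq_len(n)) {
      if (disease[i]) {
        freq[i] <- if (u[i] < config$freq_high_disease_prob) {
          10^stats::runif(1, log10(config$freq_high_disease_range[1]),
                          log10(config$freq_high_disease_range[2]))
        } else if (u[i] < config$freq_high_disease_prob + config$freq_zero_disease) {
          0
        } else {
          10^stats::runif(1, log10(config$freq_range_disease[1]),
                          log10(config$freq_range_disease[2]))
        }
      } else {
        freq[i] <- if (u[i] < config$freq_zero_population) 0 else {
          10^stats::runif(1, log10(config$freq_range_population[1]),
                          log10(config$freq_range_population[2]))
        }
      }
    }

    ddg <- ifelse(disease,
                  stats::rnorm(n, config$ddg_mean_disease, config$ddg_sd_disease),
                  stats::rnorm(n, config$ddg_mean_population, config$ddg_sd_population))

    tibble(gene = gene, hgvs_p = hgvs, consequence = consequence,
           allele_frequency = freq, consurf = consurf, ddg = ddg,
           disease_associated = disease, true_severity = true_sev)
  })
  variants <- dplyr::bind_rows(per_gene)

  # predictor scores from their own stream; non-missense variants are not
  # scored by the predictors
  set.seed(seeds[["scores"]])
  is_mis <- variants$consequence == "MISSENSE"
  emit_sev <- ifelse(is_mis & !is.na(variants$true_severity) &
                       variants$true_severity == 2L, 2L, 1L)
  scores <- simulate_predictor_scores(emit_sev, config)
  scores[!is_mis, ] <- NA_real_
  variants <- dplyr::bind_cols(variants, scores)
  variants[, c("gene", "hgvs_p", "consequence", "allele_frequency", "consurf",
               "ddg", SEVERITY_METHODS, "disease_associated", "true_severity")]
}

#' Simulate a patient cohort from a variant table
#'
#' Draws patient genotypes per gene — SLC3A1 patients receive exactly one
#' disease mutation on each allele (recessive), SLC7A9 patients one or two
#' mutated alleles (dominant) — computes each patient's latent true score by
#' the inheritance aggregation rules on the latent mutation severities, and
#' draws phenotypes conditioned on that score.
#'
#' @param config A [sim_config()].
#' @param variants Variant tibble from [simulate_variants()] (must contain
#'   disease variants with `true_severity` for the requested genes).
#' @return A list with `genotypes` (patient_id, gene, allele1_mutations,
#'   allele2_mutations, true_score) and `phenotypes` (patient_id plus the
#'   seven phenotype columns).
#' @export
simulate_cohort <- function(config = sim_config(), variants = simulate_variants(config)) {
  validate_sim_config(config)
  seeds <- component_seeds(config$seed)
  set.seed(seeds[["cohort"]])
  geno <- list(); pheno <- list()
  for (gene in GENES) {
    n_pat <- config$cohort_n[[gene]]
    if (n_pat == 0) next
    pool <- variants[variants$gene == gene & variants$disease_associated, ,
                     drop = FALSE]
    if (nrow(pool) == 0) {
      abort(paste0("No disease variants available for ", gene, "."))
    }
    prefix <- if (gene == "SLC3A1") "S3" else "S7"
    ids <- sprintf("%s-%03d", prefix, seq_len(n_pat))
    if (GENE_MODEL[[gene]] == "RECESSIVE_MIN") {
      p1 <- sample.int(nrow(pool), n_pat, replace = TRUE)
      p2 <- sample.int(nrow(pool), n_pat, replace = TRUE)
      a1 <- pool$hgvs_p[p1]
      a2 <- pool$hgvs_p[p2]
      true_score <- pmin(pool$true_severity[p1], pool$true_severity[p2])
    } else if (is.null(config$dominant_score_probs)) {
      two <- stats::runif(n_pat) < config$p_two_alleles_dominant
      p1 <- sample.int(nrow(pool), n_pat, replace = TRUE)
      p2 <- sample.int(nrow(pool), n_pat, replace = TRUE)
      a1 <- pool$hgvs_p[p1]
      a2 <- ifelse(two, pool$hgvs_p[p2], "")
      true_score <- pool$true_severity[p1] +
        ifelse(two, pool$true_severity[p2], 0L)
    } else {
      mild <- pool$hgvs_p[pool$true_severity == 1L]
      severe <- pool$hgvs_p[pool$true_severity == 2L]
      if (length(mild) == 0 || length(severe) == 0) {
        abort("dominant_score_probs requires both mild and severe disease variants in the pool.")
      }
      # deterministic allocation so group sizes hit the target proportions
      n_per <- diff(round(cumsum(c(0, config$dominant_score_probs)) * n_pat))
      true_score <- rep(1:4, times = n_per)
      pick <- function(set, k) set[sample.int(length(set), k, replace = TRUE)]
      a1 <- character(n_pat); a2 <- character(n_pat)
      a1[true_score == 1L] <- pick(mild, sum(true_score == 1L))
      a1[true_score == 2L] <- pick(severe, sum(true_score == 2L))
      a1[true_score == 3L] <- pick(mild, sum(true_score == 3L))
      a2[true_score == 3L] <- pick(severe, sum(true_score == 3L))
      a1[true_score == 4L] <- pick(severe, sum(true_score == 4L))
      a2[true_score == 4L] <- pick(severe, sum(true_score == 4L))
    }
    geno[[gene]] <- tibble(patient_id = ids, gene = gene,
                           allele1_mutations = a1, allele2_mutations = a2,
                           true_score = as.integer(true_score))
    pheno[[gene]] <- draw_phenotypes(ids, true_score, config)
  }
  list(genotypes = dplyr::bind_rows(geno), phenotypes = dplyr::bind_rows(pheno))
}

draw_phenotypes <- function(ids, score, config) {
  n <- length(ids)
  s <- score - 1
  urinary <- lapply(stats::setNames(nm = names(config$phenotype_baseline)),
                    function(ph) {
    stats::rlnorm(n, log(config$phenotype_baseline[[ph]]) +
                    config$phenotype_effect[[ph]] * s,
                  config$phenotype_log_sd)
  })
  tibble(
    patient_id = ids,
    cystine = urinary$cystine, ornithine = urinary$ornithine,
    arginine = urinary$arginine, lysine = urinary$lysine,
    age_at_presentation = pmax(1, stats::rnorm(n, config$age_mean +
                                                 config$age_effect * s,
                                               config$age_sd)),
    stone_episodes_3yr = stats::rpois(n, config$episode_rate *
                                        exp(config$episode_effect * s)),
    interventions_3yr = stats::rpois(n, config$intervention_rate *
                                       exp(config$intervention_effect * s))
  )
}
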