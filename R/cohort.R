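PHENOTYPES <- c("cystine", "ornithine", "arginine", "lysine",
                "age_at_presentation", "stone_episodes_3yr",
                "interventions_3yr")

#' Group patients by overall severity score
#'
#' Partitions scored patients into severity groups. Groups smaller than
#' `min_n` remain in the partition but are flagged ineligible for testing.
#'
#' @param scores Tibble from [score_cohort()].
#' @param min_n Minimum group size for eligibility.
#' @return A tibble with one row per group: `score`, `patient_ids` (list
#'   column), `n`, `eligible`.
#' @export
group_patients <- function(scores, min_n = 2L) {
  if (nrow(scores) == 0) {
    return(tibble(score = integer(), patient_ids = list(),
                  n = integer(), eligible = logical()))
  }
  split_ids <- split(scores$patient_id, scores$score)
  grp <- tibble(
    score = as.integer(names(split_ids)),
    patient_ids = unname(lapply(split_ids, sort)),
    n = unname(lengths(split_ids))
  )
  grp$eligible <- grp$n >= min_n
  if (any(!grp$eligible)) {
    warn(sprintf("Severity group(s) %s have fewer than %d patients and are excluded from testing.",
                 paste(grp$score[!grp$eligible], collapse = ", "), min_n))
  }
  dplyr::arrange(grp, .data$score)
}

#' Compare phenotype distributions between severity groups
#'
#' Runs a two-sided Wilcoxon rank-sum test for every unordered pair of
#' eligible groups and every phenotype, dropping missing phenotype values
#' pairwise, then applies a Bonferroni correction across the whole family of
#' tests.
#'
#' @param groups Output of [group_patients()].
#' @param phenotypes Tibble with `patient_id` plus phenotype columns.
#' @param phenotype_cols Phenotype columns to compare (default: the urinary
#'   amino-acid levels, age at presentation, and three-year stone-episode and
#'   intervention counts that are present).
#' @param family_size Bonferroni family size; defaults to the number of
#'   comparisons performed.
#' @param mode Passed to [wilcoxon_rank_sum()].
#' @return Tibble with one row per (group pair, phenotype): group scores and
#'   sizes, per-group mean/median, the rank-sum statistic, raw and adjusted
#'   p-values.
#' @export
compare_groups <- function(groups, phenotypes,
                           phenotype_cols = intersect(PHENOTYPES, names(phenotypes)),
                           family_size = NULL, mode = "auto") {
  eligible <- groups[groups$eligible, , drop = FALSE]
  if (nrow(eligible) < 2) {
    warn("Fewer than two eligible groups; no comparisons performed.")
    return(empty_comparisons())
  }
  pairs <- utils::combn(seq_len(nrow(eligible)), 2)
  rows <- list()
  for (j in seq_len(ncol(pairs))) {
    ga <- eligible[pairs[1, j], ]
    gb <- eligible[pairs[2, j], ]
    pa <- phenotypes[phenotypes$patient_id %in% ga$patient_ids[[1]], , drop = FALSE]
    pb <- phenotypes[phenotypes$patient_id %in% gb$patient_ids[[1]], , drop = FALSE]
    for (ph in phenotype_cols) {
      va <- pa[[ph]][!is.na(pa[[ph]])]
      vb <- pb[[ph]][!is.na(pb[[ph]])]
      if (length(va) == 0 || length(vb) == 0) next
      wt <- wilcoxon_rank_sum(va, vb, mode = mode)
      rows[[length(rows) + 1]] <- tibble(
        phenotype = ph, group_a = ga$score, group_b = gb$score,
        n_a = length(va), n_b = length(vb),
        mean_a = mean(va), mean_b = mean(vb),
        median_a = stats::median(va), median_b = stats::median(vb),
        statistic = wt$statistic, test_mode = wt$mode,
        p_raw = wt$p_two_sided
      )
    }
  }
  if (length(rows) == 0) {
    warn("No phenotype had data on both sides of any group pair.")
    return(empty_comparisons())
  }
  res <- dplyr::bind_rows(rows)
  corr <- bonferroni(res$p_raw, family_size)
  res$p_adjusted <- corr$adjusted_p
  res$family_size <- corr$family_size
  dplyr::arrange(res, .data$group_a, .data$group_b, .data$phenotype)
}

empty_comparisons <- function() {
  tibble(phenotype = character(), group_a = integer(), group_b = integer(),
         n_a = integer(), n_b = integer(), mean_a = double(), mean_b = double(),
         median_a = double(), median_b = double(), statistic = double(),
         test_mode = character(), p_raw = double(), p_adjusted = double(),
         family_size = integer())
}

#' Per-group phenotype summaries
#'
#' For each severity group and phenotype: number of non-missing values, mean,
#' standard deviation and median. Both mean and median are reported because
#' "average" levels can reasonably be summarised either way; the dispersion
#' is the sample standard deviation.
#'
#' @param groups Output of [group_patients()] (all groups, eligible or not).
#' @param phenotypes Tibble with `patient_id` plus phenotype columns.
#' @param phenotype_cols Columns to summarise.
#' @return Tibble ordered by score then phenotype: `score`, `phenotype`, `n`,
#'   `mean`, `sd`, `median`.
#' @export
summarize_groups <- function(groups, phenotypes,
                             phenotype_cols = intersect(PHENOTYPES, names(phenotypes))) {
  rows <- list()
  for (i in seq_len(nrow(groups))) {
    g <- groups[i, ]
    pg <- phenotypes[phenotypes$patient_id %in% g$patient_ids[[1]], , drop = FALSE]
    for (ph in phenotype_cols) {
      v <- pg[[ph]][!is.na(pg[[ph]])]
      rows[[length(rows) + 1]] <- tibble(
        score = g$score, phenotype = ph, n = length(v),
        mean = if (length(v)) mean(v) else NA_real_,
        sd = if (length(v) > 1) stats::sd(v) else NA_real_,
        median = if (length(v)) stats::median(v) else NA_real_
      )
    }
  }
  res <- dplyr::bind_rows(rows)
  if (nrow(res) == 0) {
    return(tibble(score = integer(), phenotype = character(), n = integer(),
                  mean = double(), sd = double(), median = double()))
  }
  dplyr::arrange(res, .data$score, .data$phenotype)
}
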