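make_scores <- function(scores, gene = "SLC7A9") {
  model <- if (gene == "SLC7A9") "DOMINANT_SUM" else "RECESSIVE_MIN"
  tibble::tibble(patient_id = sprintf("P%02d", seq_along(scores)),
                 gene = gene, score = as.integer(scores), model = model)
}

test_that("group_patients partitions patients by score", {
  grp <- suppressWarnings(group_patients(make_scores(c(1, 2, 2, 3, 4, 4))))
  expect_equal(grp$score, 1:4)
  expect_equal(grp$n, c(1L, 2L, 1L, 2L))
  expect_equal(grp$eligible, c(FALSE, TRUE, FALSE, TRUE))
  # partition: every patient in exactly one group
  expect_setequal(unlist(grp$patient_ids), sprintf("P%02d", 1:6))
  expect_equal(sum(grp$n), 6L)

  expect_equal(nrow(group_patients(make_scores(integer()))), 0L)
})

test_that("compare_groups reproduces the exact rank-test p for a tiny cohort", {
  scores <- make_scores(c(1, 1, 2, 2))
  phen <- tibble::tibble(patient_id = sprintf("P%02d", 1:4),
                         arginine = c(1, 2, 3, 4))
  grp <- group_patients(scores)
  cmp <- compare_groups(grp, phen)
  expect_equal(nrow(cmp), 1L)
  expect_equal(cmp$p_raw, 1 / 3)
  expect_equal(cmp$p_adjusted, 1 / 3)  # family of one
  expect_equal(cmp$n_a, 2L)
  expect_equal(cmp$mean_b, 3.5)
  # family-size override widens the correction
  cmp5 <- compare_groups(grp, phen, family_size = 5)
  expect_equal(cmp5$p_adjusted, min(1, 5 / 3))
})

test_that("missing phenotype values are dropped pairwise", {
  scores <- make_scores(c(1, 1, 1, 2, 2, 2))
  phen <- tibble::tibble(patient_id = sprintf("P%02d", 1:6),
                         arginine = c(1, 2, NA, 3, 4, NA),
                         cystine = NA_real_)
  cmp <- compare_groups(group_patients(scores), phen)
  expect_equal(nrow(cmp), 1L)  # cystine has no data, dropped entirely
  expect_equal(cmp$n_a, 2L)
  expect_equal(cmp$p_raw, 1 / 3)
})

test_that("comparisons are invariant to patient input order", {
  set.seed(5)
  scores <- make_scores(sample(1:4, 40, replace = TRUE))
  phen <- tibble::tibble(patient_id = scores$patient_id,
                         arginine = stats::rlnorm(40),
                         lysine = stats::rlnorm(40))
  ref <- compare_groups(group_patients(scores), phen)
  perm <- sample(nrow(scores))
  shuffled <- compare_groups(group_patients(scores[perm, ]),
                             phen[sample(nrow(phen)), ])
  expect_equal(shuffled, ref)
})

test_that("identical phenotype distributions yield no significant contrasts", {
  hits <- 0L
  for (s in 1:20) {
    set.seed(s)
    scores <- make_scores(rep(1:2, each = 15))
    phen <- tibble::tibble(patient_id = scores$patient_id,
                           arginine = stats::rlnorm(30))
    cmp <- compare_groups(group_patients(scores), phen)
    hits <- hits + sum(cmp$p_adjusted < 0.05)
  }
  expect_lte(hits, 2L)
})

test_that("group means are monotone in score when the planted effect is large", {
  monotone <- vapply(1:100, function(s) {
    cfg <- sim_config(seed = s, n_disease = c(SLC3A1 = 10L, SLC7A9 = 20L),
                      n_population = c(SLC3A1 = 0L, SLC7A9 = 0L),
                      cohort_n = c(SLC3A1 = 0L, SLC7A9 = 200L),
                      dominant_score_probs = rep(0.25, 4),
                      phenotype_effect = c(cystine = 0.6, ornithine = 0.6,
                                           arginine = 0.6, lysine = 0.6))
    co <- simulate_cohort(cfg)
    grp <- group_patients(tibble::tibble(patient_id = co$genotypes$patient_id,
                                         gene = "SLC7A9",
                                         score = co$genotypes$true_score,
                                         model = "DOMINANT_SUM"))
    summ <- summarize_groups(grp, co$phenotypes, phenotype_cols = "arginine")
    all(diff(summ$mean) > 0)
  }, logical(1))
  expect_gte(mean(monotone), 0.95)
})

test_that("summarize_groups reports n, mean, sd, median per group and phenotype", {
  scores <- make_scores(c(1, 2, 2))
  phen <- tibble::tibble(patient_id = sprintf("P%02d", 1:3),
                         arginine = c(10, 20, 40), cystine = c(5, NA, 7))
  summ <- summarize_groups(suppressWarnings(group_patients(scores)), phen)
  expect_equal(nrow(summ), 4L)  # 2 groups x 2 phenotypes
  one <- summ[summ$score == 1 & summ$phenotype == "arginine", ]
  expect_equal(one$mean, 10)
  expect_true(is.na(one$sd))  # single patient: no dispersion
  two <- summ[summ$score == 2 & summ$phenotype == "arginine", ]
  expect_equal(two$mean, 30)
  expect_equal(two$sd, stats::sd(c(20, 40)))
  expect_equal(two$median, 30)
  expect_equal(summ[summ$score == 2 & summ$phenotype == "cystine", ]$n, 1L)
})
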