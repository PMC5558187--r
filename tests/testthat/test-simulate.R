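test_that("generation is bit-identical for a fixed seed and config", {
  cfg <- sim_config(seed = 42, n_disease = c(SLC3A1 = 30L, SLC7A9 = 20L),
                    n_population = c(SLC3A1 = 40L, SLC7A9 = 30L),
                    cohort_n = c(SLC3A1 = 10L, SLC7A9 = 10L))
  v1 <- simulate_variants(cfg)
  v2 <- simulate_variants(cfg)
  expect_identical(v1, v2)
  c1 <- simulate_cohort(cfg, v1)
  c2 <- simulate_cohort(cfg, v1)
  expect_identical(c1, c2)
  v3 <- simulate_variants(sim_config(seed = 43, n_disease = cfg$n_disease,
                                     n_population = cfg$n_population))
  expect_false(identical(v1, v3))
})

test_that("component RNG streams decouple variants from the cohort size", {
  base <- sim_config(seed = 9, n_disease = c(SLC3A1 = 20L, SLC7A9 = 20L),
                     n_population = c(SLC3A1 = 10L, SLC7A9 = 10L),
                     cohort_n = c(SLC3A1 = 5L, SLC7A9 = 5L))
  bigger <- sim_config(seed = 9, n_disease = base$n_disease,
                       n_population = base$n_population,
                       cohort_n = c(SLC3A1 = 20L, SLC7A9 = 20L))
  expect_identical(simulate_variants(base), simulate_variants(bigger))
})

test_that("variant annotations follow the configured models", {
  cfg <- sim_config(seed = 2, n_disease = c(SLC3A1 = 500L, SLC7A9 = 0L),
                    n_population = c(SLC3A1 = 0L, SLC7A9 = 0L),
                    prop_non_missense = 0)
  v <- simulate_variants(cfg)
  expect_equal(nrow(v), 500L)
  # configured 80% mass on ConSurf grades 6-9, empirically within 5 points
  expect_lt(abs(mean(v$consurf >= 6) - 0.80), 0.05)
  expect_true(all(v$true_severity %in% 1:2))
  expect_true(all(table(v$gene, v$hgvs_p) <= 1))  # unique keys

  all_zero <- sim_config(seed = 2, n_disease = c(SLC3A1 = 50L, SLC7A9 = 0L),
                         n_population = c(SLC3A1 = 50L, SLC7A9 = 0L),
                         freq_zero_disease = 1, freq_high_disease_prob = 0,
                         freq_zero_population = 1)
  expect_true(all(simulate_variants(all_zero)$allele_frequency == 0))

  expect_error(sim_config(severe_prevalence = 1.5), "severe_prevalence")
  expect_error(sim_config(consurf_weights_disease = rep(1, 9)),
               "consurf_weights_disease")
})

test_that("noiseless emissions classify on the correct side of every threshold", {
  cfg <- sim_config(noise_scale = 0)
  sev <- rep(c(1L, 2L), each = 25)
  sc <- simulate_predictor_scores(sev, cfg)
  for (m in names(sc)) {
    called <- classify_mutation_severity(sc[[m]], method_spec(m),
                                         warn_neutral = FALSE)
    expect_equal(called, sev)
  }
})

test_that("default noise recovers latent severity for at least 90% per method", {
  cfg <- sim_config(seed = 5)
  set.seed(99)
  sev <- sample(1:2, 500, replace = TRUE)
  sc <- simulate_predictor_scores(sev, cfg)
  for (m in names(sc)) {
    called <- classify_mutation_severity(sc[[m]], method_spec(m),
                                         warn_neutral = FALSE)
    expect_gte(mean(called == sev), 0.90)
  }
})

test_that("cohort genotypes respect the inheritance structure", {
  cfg <- sim_config(seed = 13, n_disease = c(SLC3A1 = 30L, SLC7A9 = 30L),
                    n_population = c(SLC3A1 = 0L, SLC7A9 = 0L),
                    cohort_n = c(SLC3A1 = 25L, SLC7A9 = 25L))
  v <- simulate_variants(cfg)
  co <- simulate_cohort(cfg, v)
  rec <- co$genotypes[co$genotypes$gene == "SLC3A1", ]
  # recessive: exactly one mutation per allele, both alleles mutated
  expect_true(all(nzchar(rec$allele1_mutations)))
  expect_true(all(nzchar(rec$allele2_mutations)))
  expect_false(any(grepl(";", rec$allele1_mutations)))

  # latent patient score equals the inheritance rule applied to latent
  # mutation severities
  sev <- stats::setNames(v$true_severity, paste(v$gene, v$hgvs_p))
  for (i in seq_len(nrow(co$genotypes))) {
    g <- co$genotypes[i, ]
    s1 <- sev[paste(g$gene, g$allele1_mutations)]
    s2 <- if (nzchar(g$allele2_mutations)) {
      sev[paste(g$gene, g$allele2_mutations)]
    } else NA_integer_
    expected <- if (g$gene == "SLC3A1") min(s1, s2) else sum(c(s1, s2), na.rm = TRUE)
    expect_equal(g$true_score, as.integer(expected))
  }
  expect_error(simulate_cohort(cfg, v[v$gene == "SLC7A9", ]),
               "No disease variants")
})

test_that("balanced dominant score allocation hits the target group sizes", {
  cfg <- sim_config(seed = 8, n_disease = c(SLC3A1 = 10L, SLC7A9 = 40L),
                    n_population = c(SLC3A1 = 0L, SLC7A9 = 0L),
                    cohort_n = c(SLC3A1 = 0L, SLC7A9 = 160L),
                    dominant_score_probs = rep(0.25, 4))
  co <- simulate_cohort(cfg)
  expect_equal(unname(table(co$genotypes$true_score)), rep(40L, 4),
               ignore_attr = TRUE)
})

test_that("phenotype distributions shift with latent severity in the planted directions", {
  cfg <- sim_config(seed = 21, n_disease = c(SLC3A1 = 10L, SLC7A9 = 30L),
                    n_population = c(SLC3A1 = 0L, SLC7A9 = 0L),
                    cohort_n = c(SLC3A1 = 0L, SLC7A9 = 400L),
                    dominant_score_probs = c(0.5, 0, 0, 0.5))
  co <- simulate_cohort(cfg)
  merged <- dplyr::left_join(co$genotypes, co$phenotypes, by = "patient_id")
  lo <- merged[merged$true_score == 1, ]
  hi <- merged[merged$true_score == 4, ]
  expect_gt(stats::median(hi$arginine), stats::median(lo$arginine))
  expect_lt(mean(hi$age_at_presentation), mean(lo$age_at_presentation))
  expect_gt(mean(hi$stone_episodes_3yr), mean(lo$stone_episodes_3yr))
})
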