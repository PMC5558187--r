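test_that("dominant score is the sum of allele severities", {
  expect_equal(score_patient_dominant(1L), 1L)
  expect_equal(score_patient_dominant(c(2L, 2L)), 4L)
  expect_equal(score_patient_dominant(c(1L, 2L)), 3L)
  expect_equal(score_patient_dominant(c(2L, 1L)), 3L)  # allele order irrelevant
  expect_error(score_patient_dominant(integer()), "one or two")
  expect_error(score_patient_dominant(c(1L, 1L, 2L)), "one or two")
  expect_error(score_patient_dominant(3L), "1 \\(mild\\) or 2")
})

test_that("recessive score is the minimum allele severity (worst allele silenced)", {
  expect_equal(score_patient_recessive(1L, 1L), 1L)
  expect_equal(score_patient_recessive(1L, 2L), 1L)
  expect_equal(score_patient_recessive(2L, 1L), 1L)  # symmetric
  expect_equal(score_patient_recessive(2L, 2L), 2L)
  expect_error(score_patient_recessive(1L, NA), "both alleles")
})

test_that("attainable score ranges are exact by exhaustive genotype enumeration", {
  dominant <- c(
    vapply(1:2, function(a) score_patient_dominant(a), integer(1)),
    apply(expand.grid(1:2, 1:2), 1, function(g) score_patient_dominant(g))
  )
  expect_setequal(dominant, 1:4)
  recessive <- apply(expand.grid(1:2, 1:2), 1,
                     function(g) score_patient_recessive(g[1], g[2]))
  expect_setequal(recessive, 1:2)
})

test_that("score_cohort dispatches by gene and validates inputs", {
  calls <- c("SLC7A9 p.Gly105Arg" = 2L, "SLC3A1 p.Met467Thr" = 2L,
             "SLC3A1 p.Thr216Met" = 1L)
  patients <- tibble::tibble(
    patient_id = c("D1", "R1"),
    gene = c("SLC7A9", "SLC3A1"),
    allele1_mutations = c("p.Gly105Arg", "p.Met467Thr"),
    allele2_mutations = c("", "p.Thr216Met"))
  out <- score_cohort(patients, calls)
  expect_equal(out$score, c(2L, 1L))
  expect_equal(out$model, c("DOMINANT_SUM", "RECESSIVE_MIN"))

  empty <- score_cohort(patients[0, ], calls)
  expect_equal(nrow(empty), 0L)

  expect_error(
    score_cohort(dplyr::mutate(patients, allele1_mutations = c("p.Arg365Leu", "p.Met467Thr")),
                 calls),
    "D1.*p\\.Arg365Leu")

  both <- tibble::tibble(
    patient_id = "X1", gene = c("SLC3A1", "SLC7A9"),
    allele1_mutations = c("p.Met467Thr", "p.Gly105Arg"),
    allele2_mutations = c("p.Thr216Met", ""))
  expect_error(score_cohort(both, calls), "both genes")
})

test_that("edge genotypes are excluded or collapsed with notice", {
  calls <- c("SLC7A9 p.Gly105Arg" = 2L, "SLC7A9 p.Ala182Thr" = 1L,
             "SLC3A1 p.Met467Thr" = 2L)
  none <- tibble::tibble(patient_id = "N1", gene = "SLC7A9",
                         allele1_mutations = "", allele2_mutations = "")
  expect_message(out <- score_cohort(none, calls), "no identified mutation")
  expect_equal(nrow(out), 0L)

  one_allele_recessive <- tibble::tibble(
    patient_id = "R2", gene = "SLC3A1",
    allele1_mutations = "p.Met467Thr", allele2_mutations = "")
  expect_warning(out <- score_cohort(one_allele_recessive, calls),
                 "one mutated allele")
  expect_equal(nrow(out), 0L)

  two_on_one <- tibble::tibble(
    patient_id = "D2", gene = "SLC7A9",
    allele1_mutations = "p.Gly105Arg;p.Ala182Thr", allele2_mutations = "")
  expect_warning(out <- score_cohort(two_on_one, calls), "worst mutation")
  expect_equal(out$score, 2L)
})

test_that("patient scores are monotone in threshold stringency", {
  fix <- two_patient_polyphen_fixture(scores = c(0.55, 0.9))
  spec <- method_spec("polyphen2")
  grid <- seq(0.5, 0.95, 0.05)
  prev <- NULL
  for (thr in grid) {
    called <- call_severity(fix$variants, spec, severe_threshold = thr,
                            warn_neutral = FALSE)
    sc <- score_cohort(fix$patients, called)
    if (!is.null(prev)) expect_true(all(sc$score <= prev))
    prev <- sc$score
  }
})
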