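test_that("per-method severe thresholds reproduce the printed boundary behaviour", {
  expect_equal(classify_mutation_severity(c(0.03, 0.01), method_spec("sift")),
               c(1L, 2L))
  expect_equal(classify_mutation_severity(0.025, method_spec("sift")), 2L)
  expect_equal(classify_mutation_severity(c(0.80, 0.79), method_spec("polyphen2")),
               c(2L, 1L))
  expect_equal(classify_mutation_severity(c(2.7, 2.69), method_spec("mutation_assessor"),
                                          warn_neutral = FALSE),
               c(2L, 1L))
  expect_equal(classify_mutation_severity(c(-9.0, -8.5), method_spec("fathmm"),
                                          warn_neutral = FALSE),
               c(2L, 1L))
  expect_equal(classify_mutation_severity(c(0.672, 0.673), method_spec("condel")),
               c(1L, 2L))
  expect_equal(classify_mutation_severity(c(27.5, 27.4), method_spec("cadd")),
               c(2L, 1L))
  expect_error(classify_mutation_severity(NaN, method_spec("sift")), "Non-finite")
})

test_that("scores milder than the standard deleterious threshold warn but score 1", {
  expect_warning(
    out <- classify_mutation_severity(0.9, method_spec("sift")),
    "neutral side")
  expect_equal(out, 1L)
})

test_that("non-missense consequences are always severe and missense is rejected", {
  expect_equal(severity_for_consequence(c("FRAMESHIFT", "NONSENSE",
                                          "DELETION", "SPLICE_SITE")),
               rep(2L, 4))
  expect_error(severity_for_consequence("MISSENSE"), "classify_mutation_severity")
  expect_error(severity_for_consequence("SYNONYMOUS"), "SYNONYMOUS")
})

test_that("raising the severe threshold never increases severity", {
  set.seed(11)
  for (m in c("sift", "polyphen2", "mutation_assessor", "fathmm",
              "condel", "cadd")) {
    spec <- method_spec(m)
    grid <- default_grid(spec, n = 8)
    scores <- stats::runif(50, min(grid) - 1, max(grid) + 1)
    prev <- classify_mutation_severity(scores, spec, grid[1],
                                       warn_neutral = FALSE)
    for (thr in grid[-1]) {
      cur <- classify_mutation_severity(scores, spec, thr,
                                        warn_neutral = FALSE)
      expect_true(all(cur <= prev))
      prev <- cur
    }
  }
})

test_that("call_severity dispatches by consequence and reports missing scores", {
  fix <- two_patient_polyphen_fixture()
  v <- fix$variants
  v$consequence[2] <- "FRAMESHIFT"
  v$hgvs_p[2] <- "p.Gly20fs"
  v$polyphen2[2] <- NA
  expect_warning(called <- call_severity(v, "polyphen2"), "neutral side")
  expect_equal(called$severity_reason, c("THRESHOLD", "NON_MISSENSE_RULE"))
  expect_equal(called$severity[2], 2L)

  v2 <- fix$variants
  v2$polyphen2[1] <- NA
  expect_error(call_severity(v2, "polyphen2"), "p\\.Ala10Val")
})

test_that("threshold scan regroups patients at each grid point", {
  fix <- two_patient_polyphen_fixture(scores = c(0.3, 0.9))
  grid <- seq(0.50, 0.95, by = 0.05)
  scan <- threshold_scan(fix$patients, fix$variants, "polyphen2", grid)
  expect_equal(nrow(scan), length(grid))
  # score 0.9 stays severe up to threshold 0.90, flips mild at 0.95
  same_as_first <- vapply(scan$assignment, identical, logical(1),
                          scan$assignment[[1]])
  expect_equal(same_as_first, c(rep(TRUE, 9), FALSE))
  expect_equal(select_stable_threshold(scan), 0.90)
})

test_that("scan is constant when no score crosses the grid", {
  fix <- two_patient_polyphen_fixture(scores = c(0.2, 0.3))
  scan <- threshold_scan(fix$patients, fix$variants, "polyphen2",
                         seq(0.5, 0.95, by = 0.05))
  expect_true(all(vapply(scan$assignment, identical, logical(1),
                         scan$assignment[[1]])))
  # stable everywhere: the most stringent grid point is selected
  expect_equal(select_stable_threshold(scan), 0.95)
})

test_that("stable-threshold selection is invariant to run-preserving grid extension", {
  fix <- two_patient_polyphen_fixture(scores = c(0.3, 0.9))
  grid <- seq(0.50, 0.95, by = 0.05)
  scan <- threshold_scan(fix$patients, fix$variants, "polyphen2", grid)
  extended <- threshold_scan(fix$patients, fix$variants, "polyphen2",
                             c(0.40, 0.45, grid))
  expect_equal(select_stable_threshold(scan),
               select_stable_threshold(extended))
})

test_that("a grid too coarse to show stability is an error", {
  fix <- two_patient_polyphen_fixture(scores = c(0.55, 0.65))
  scan <- threshold_scan(fix$patients, fix$variants, "polyphen2",
                         c(0.5, 0.6, 0.7))
  expect_error(select_stable_threshold(scan, min_run = 3), "finer grid")
})
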