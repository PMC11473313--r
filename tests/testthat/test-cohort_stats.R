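test_that("run-to-patient collapsing deduplicates and is idempotent", {
  design <- toy_design()
  calls <- tibble::tibble(
    run_id = c("r1", "r3", "r1", "r2", "r4"),
    fusion_id = c("X", "X", "Y", "X", "Z")
  )
  presence <- collapse_runs_to_patients(calls, design)
  # patient p1 has X in runs r1 and r3 -> counted once
  expect_equal(sum(presence$fusion_id == "X" & presence$patient_id == "p1"), 1)
  # duplicating records changes nothing
  expect_identical(collapse_runs_to_patients(rbind(calls, calls), design), presence)
  # a fusion in many runs of one patient is still one patient
  many <- tibble::tibble(run_id = c("r1", "r2", "r3"), fusion_id = "W")
  expect_equal(nrow(collapse_runs_to_patients(many, design)), 1)
  # empty calls -> empty presence
  expect_equal(nrow(collapse_runs_to_patients(calls[0, ], design)), 0)
  # unknown runs are an explicit error listing the IDs
  expect_error(
    collapse_runs_to_patients(tibble::tibble(run_id = "zz9", fusion_id = "X"), design),
    "zz9"
  )
})

test_that("recurrence frequencies are exact per-cohort proportions with zero rows", {
  design <- toy_design()
  presence <- tibble::tibble(
    patient_id = c("p1", "p2", "c1"),
    cohort = c("case", "case", "control"),
    fusion_id = c("X", "X", "Y")
  )
  rec <- recurrence_table(presence, design)
  expect_equal(nrow(rec), 4) # 2 fusions x 2 cohorts, zeros explicit
  x_case <- rec[rec$fusion_id == "X" & rec$cohort == "case", ]
  expect_equal(x_case$positive_patients, 2)
  expect_equal(x_case$frequency, 1.0)
  expect_equal(rec$positive_patients[rec$fusion_id == "X" & rec$cohort == "control"], 0)
  expect_equal(rec$frequency[rec$fusion_id == "Y" & rec$cohort == "case"], 0)
})

test_that("recurrence frequency reproduces printed cohort proportions", {
  expect_equal(round(107 / 122, 4), 0.8770)
  d <- cohort_design(
    run_id = c(sprintf("r%03d", 1:122), sprintf("s%03d", 1:252)),
    patient_id = c(sprintf("P%03d", 1:122), sprintf("C%03d", 1:252)),
    cohort = rep(c("case", "control"), c(122, 252))
  )
  presence <- tibble::tibble(
    patient_id = c(sprintf("P%03d", 1:107), sprintf("C%03d", 1:133)),
    cohort = rep(c("case", "control"), c(107, 133)),
    fusion_id = "F"
  )
  rec <- recurrence_table(presence, d)
  expect_equal(rec$frequency[rec$cohort == "case"], 107 / 122)
  expect_equal(round(rec$frequency[rec$cohort == "control"], 4), 0.5278)
})

test_that("the recurrence filter is boundary-inclusive and deterministically ordered", {
  rec <- tibble::tibble(
    fusion_id = c("A", "B", "C"),
    cohort = "case",
    positive_patients = c(5L, 4L, 107L),
    cohort_size = 122L,
    frequency = c(5, 4, 107) / 122
  )
  expect_equal(filter_recurrent(rec, 5, "case"), c("C", "A"))
  expect_equal(filter_recurrent(rec, 1, "case"), c("C", "A", "B"))
  # exactly min_count survives; min_count - 1 does not
  expect_true("A" %in% filter_recurrent(rec, 5, "case"))
  expect_false("B" %in% filter_recurrent(rec, 5, "case"))
  # the implied minimum detectable case frequency at n = 122
  expect_equal(round(100 * 5 / 122, 1), 4.1)
})

test_that("critical z matches a numerical inverse-CDF oracle", {
  expect_equal(round(critical_z(0.01), 3), 2.576)
  expect_equal(round(critical_z(0.05), 3), 1.960)
  # independent oracle: root of the normal CDF
  for (alpha in c(0.01, 0.05, 0.2)) {
    root <- uniroot(
      function(x) pnorm(x) - (1 - alpha / 2),
      c(0, 10), tol = 1e-10
    )$root
    expect_equal(critical_z(alpha), root, tolerance = 1e-8)
  }
  expect_lt(critical_z(0.9999), 1e-3) # alpha -> 1 limit: the median
  expect_error(critical_z(0), "alpha")
  expect_error(critical_z(1.2), "alpha")
})

test_that("pooled two-proportion z reproduces the flagship case-control comparison", {
  # frozen from the pooled formula: p = 161/374, se = sqrt(p(1-p)(1/122+1/252))
  zt <- two_proportion_ztest(107, 122, 54, 252)
  expect_equal(zt$z, 12.13589, tolerance = 1e-5)
  expect_gt(abs(zt$z), critical_z(0.01))
  # equal proportions: z = 0, p = 1
  expect_equal(two_proportion_ztest(10, 100, 10, 100)$z, 0)
  expect_equal(two_proportion_ztest(10, 100, 10, 100)$p_value, 1)
  # degenerate pooled proportions
  expect_equal(two_proportion_ztest(0, 10, 0, 20)$z, 0)
  expect_equal(two_proportion_ztest(10, 10, 20, 20)$p_value, 1)
  expect_error(two_proportion_ztest(5, 0, 1, 10), "positive")
  expect_error(two_proportion_ztest(11, 10, 1, 10), "0 <= x <= n")
})

test_that("z is antisymmetric and z^2 equals the Pearson chi-square", {
  withr::with_seed(31, {
    for (i in 1:50) {
      n1 <- sample(20:300, 1)
      n2 <- sample(20:300, 1)
      x1 <- sample.int(n1, 1) - 1L
      x2 <- sample.int(n2, 1) - 1L
      zt <- two_proportion_ztest(x1, n1, x2, n2)
      sw <- two_proportion_ztest(x2, n2, x1, n1)
      expect_equal(zt$z, -sw$z)
      expect_equal(zt$p_value, sw$p_value)
      if (x1 + x2 > 0 && x1 + x2 < n1 + n2) {
        chi <- suppressWarnings(
          prop.test(c(x1, x2), c(n1, n2), correct = FALSE)
        )$statistic
        expect_equal(zt$z^2, unname(chi), tolerance = 1e-10)
      }
    }
  })
})

test_that("fold enrichment matches the printed table folds", {
  expect_equal(round(fold_enrichment(107, 122, 54, 252), 1), 4.1)
  expect_equal(round(fold_enrichment(27, 122, 3, 252), 1), 18.6)
  expect_equal(round(fold_enrichment(49, 122, 19, 252), 1), 5.3)
  expect_equal(round(fold_enrichment(121, 122, 133, 252), 1), 1.9)
  # zero-control convention: pseudocount of one positive control
  expect_equal(fold_enrichment(18, 122, 0, 252), (18 / 122) / (1 / 252))
  expect_equal(round(fold_enrichment(18, 122, 0, 252), 1), 37.2)
  expect_true(is.na(fold_enrichment(0, 122, 0, 252)))
})

test_that("association applies the either-cohort filter, direction, and significance", {
  mk_rec <- function(x1, x2, id = "F") {
    tibble::tibble(
      fusion_id = id, cohort = c("case", "control"),
      positive_patients = c(x1, x2), cohort_size = c(122L, 252L),
      frequency = c(x1 / 122, x2 / 252)
    )
  }
  # case prevalence 0.5 vs control 0.05: strongly significant positive
  res <- associate(mk_rec(61, 13))
  expect_true(res$significant)
  expect_equal(res$direction, "positive")
  # rare in cases, common in controls: significant negative
  res <- associate(mk_rec(6, 101))
  expect_true(res$significant)
  expect_equal(res$direction, "negative")
  # 4 case positives, 0 controls: excluded by the filter entirely
  expect_equal(nrow(associate(mk_rec(4, 0))), 0)
  # but 4 cases with >= 5 controls enters through the control side
  expect_equal(nrow(associate(mk_rec(4, 5))), 1)
  expect_error(associate(mk_rec(4, 0)[0, ]), "empty")
  # categories annotate the result
  res <- associate(mk_rec(61, 13), categories = c(F = "EFG"))
  expect_equal(res$category, "EFG")
})

test_that("somatic-origin coincidence probabilities match the closed form", {
  p <- somatic_origin_probability(0.036, 5, 252)
  expect_equal(signif(p$coincidence_probability, 1), 6e-8)
  expect_equal(p$coincidence_probability, 0.036^5)
  expect_equal(signif(p$expected_per_cohort, 2), 1.5e-5)
  # k = 1 identity
  p1 <- somatic_origin_probability(0.036, 1, 100)
  expect_equal(p1$coincidence_probability, 0.036)
  expect_equal(p1$expected_per_cohort, 3.6)
  expect_error(somatic_origin_probability(1.5, 5), "rate")
})

test_that("contribution split is exact, symmetric, and sums to 100", {
  # direct arithmetic oracle: r = 8.1/3.3, share = 100 r / (r + 1)
  s <- contribution_split(8.1, 3.3)
  expect_equal(s$genetic_percent, 100 * (8.1 / 3.3) / (8.1 / 3.3 + 1))
  expect_equal(round(s$genetic_percent, 1), 71.1)
  # the rounded-intermediate chain 2.48:1
  expect_equal(round(contribution_split(2.48, 1)$genetic_percent, 1), 71.3)
  expect_equal(contribution_split(4, 4)$genetic_percent, 50)
  withr::with_seed(5, {
    for (i in 1:20) {
      r <- contribution_split(runif(1, 0.1, 20), runif(1, 0.1, 20))
      expect_equal(r$genetic_percent + r$environmental_percent, 100)
    }
  })
  expect_error(contribution_split(-1, 2), "positive")
})

test_that("per-patient burden counts distinct fusions and summarises by cohort", {
  design <- toy_design()
  presence <- tibble::tibble(
    patient_id = c("p1", "p1", "p2"),
    cohort = "case",
    fusion_id = c("a", "b", "a")
  )
  b <- burden_per_sample(presence, design)
  expect_equal(b$per_patient$burden, c(0, 2, 1)) # c1, p1, p2 by ID
  expect_equal(b$summary$mean[b$summary$cohort == "case"], 1.5)
  expect_equal(b$summary$mean[b$summary$cohort == "control"], 0)
  # class filter restricts to one category
  cats <- c(a = "EFG", b = "GENOMIC")
  b_efg <- burden_per_sample(presence, design, categories = cats, class_filter = "EFG")
  expect_equal(b_efg$per_patient$burden, c(0, 1, 1))
  expect_error(burden_per_sample(presence, design, class_filter = "EFG"), "categories")
})

test_that("burden and recurrence conserve total presence pairs", {
  withr::with_seed(91, {
    design <- cohort_design(
      run_id = sprintf("r%02d", 1:30),
      patient_id = sprintf("p%02d", rep(1:15, each = 2)),
      cohort = rep(c("case", "control"), c(20, 10))
    )
    calls <- tibble::tibble(
      run_id = sample(design$run_id, 200, replace = TRUE),
      fusion_id = sample(letters[1:8], 200, replace = TRUE)
    )
    presence <- collapse_runs_to_patients(calls, design)
    rec <- recurrence_table(presence, design)
    b <- burden_per_sample(presence, design)
    expect_equal(sum(b$per_patient$burden), nrow(presence))
    expect_equal(sum(rec$positive_patients), nrow(presence))
  })
})

test_that("presence matrix has the stated ordering and conserves counts", {
  design <- cohort_design(
    run_id = c("r1", "r2"), patient_id = c("pA", "pB"), cohort = "case"
  )
  presence <- tibble::tibble(
    patient_id = c("pA", "pB", "pA"),
    cohort = "case",
    fusion_id = c("shared", "shared", "only_a")
  )
  m <- presence_matrix(presence, design)
  expect_equal(rownames(m), c("pA", "pB"))
  expect_equal(colnames(m), c("shared", "only_a")) # by descending case count
  expect_equal(unname(m), rbind(c(1L, 1L), c(1L, 0L)))
  expect_equal(unname(colSums(m)), c(2, 1)) # column sums = recurrence counts
  empty <- presence_matrix(presence[0, ], design, fusion_ids = c("f1", "f2"))
  expect_true(all(empty == 0))
})

test_that("cohort-scale summary reproduces per-patient averages and recurrent shares", {
  s <- cohort_scale_summary(138000, 122, 814)
  expect_equal(round(s$per_patient_average), 1131)
  expect_equal(round(s$recurrent_percent, 2), 0.59)
  s2 <- cohort_scale_summary(49900, 252, 881)
  expect_equal(round(s2$per_patient_average), 198)
  expect_equal(round(s2$recurrent_percent, 1), 1.8)
})

test_that("cohort design enforces disjoint cohorts and unique runs", {
  expect_error(
    cohort_design(c("r1", "r1"), c("p1", "p2"), c("case", "case")),
    "unique"
  )
  expect_error(
    cohort_design(c("r1", "r2"), c("p1", "p1"), c("case", "control")),
    "disjoint"
  )
  d <- toy_design()
  expect_equal(unname(cohort_sizes(d)), c(2, 1))
})
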