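test_that("Student's t-test follows the pooled-variance contract", {
  x <- c(1, 2, 3, 4)
  same <- students_t_test(x, x)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_equal(same$df, 6)

  r <- students_t_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$df, 4)       # n_x + n_y - 2
  expect_lt(r$p, 0.05)

  expect_error(students_t_test(c(0, 0), c(1, 1)), "degenerate variance")
  expect_error(students_t_test(1, c(1, 2)), "at least 2")
})

test_that("t-test is antisymmetric in its arguments", {
  set.seed(21)
  for (i in 1:25) {
    x <- rnorm(sample(2:8, 1)); y <- rnorm(sample(2:8, 1), mean = 0.5)
    a <- students_t_test(x, y); b <- students_t_test(y, x)
    expect_equal(a$t, -b$t)
    expect_equal(a$p, b$p)
    expect_equal(a$df, b$df)
  }
})

test_that("t p-values rank like the exact permutation oracle on tiny groups", {
  # worked instance: only the two extreme partitions of {1..6} reach |t|,
  # so the exact two-sided permutation p is 2/20 = 0.1
  expect_equal(permutation_p(c(1, 2, 3), c(4, 5, 6)), 0.1)
  expect_lt(students_t_test(c(1, 2, 3), c(4, 5, 6))$p, 0.05)

  set.seed(33)
  for (i in 1:20) {
    nx <- sample(2:4, 1); ny <- sample(2:4, 1)
    x <- round(rnorm(nx), 2); y <- round(rnorm(ny, sample(0:2, 1)), 2)
    pv <- tryCatch(students_t_test(x, y)$p, error = function(e) NA)
    if (is.na(pv)) next
    pp <- permutation_p(x, y)
    # rank agreement: smaller t p pairs with smaller permutation p
    x2 <- round(rnorm(nx), 2); y2 <- round(rnorm(ny, sample(0:2, 1)), 2)
    pv2 <- tryCatch(students_t_test(x2, y2)$p, error = function(e) NA)
    if (is.na(pv2)) next
    pp2 <- permutation_p(x2, y2)
    if (abs(pv - pv2) > 1e-6 && abs(pp - pp2) > 1e-6)
      expect_identical(pv < pv2, pp < pp2)
  }
})

test_that("vehicle normalization and attenuation reproduce the worked arithmetic", {
  veh <- rep(12, 10)
  expect_equal(normalize_to_control(veh, veh), 100)
  expect_equal(attenuation(veh, veh), 0)

  drug <- c(4, 4, 4, 4, 4, 4, 3, 3, 3, 3)  # mean 3.6 on a 12-point control
  expect_equal(normalize_to_control(drug, veh), 30)
  expect_equal(attenuation(drug, veh), 70)

  expect_equal(normalize_to_control(c(3, 3), c(6, 6)), 50)
  expect_equal(attenuation(rep(0, 5), veh), 100)
  expect_error(normalize_to_control(drug, rep(0, 3)), "vehicle mean")
})

test_that("normalization is invariant to rescaling both groups", {
  set.seed(8)
  for (i in 1:20) {
    d <- runif(6, 1, 10); v <- runif(6, 1, 10); c0 <- runif(1, 0.1, 50)
    expect_equal(normalize_to_control(d * c0, v * c0),
                 normalize_to_control(d, v))
  }
})

test_that("the efficacy result ties normalization, attenuation and the t-test", {
  drug <- c(4, 4, 4, 4, 4, 4, 3, 3, 3, 3)
  veh <- c(12, 12, 12, 12, 11, 12, 12, 12, 12, 11)
  er <- efficacy_result(drug, veh, "MSX122", "DMSO_CD_ip")
  expect_equal(er$normalized_mean_percent + er$attenuation_percent, 100)
  expect_equal(er$degrees_of_freedom, 18)
  expect_lt(er$p_two_sided, 0.05)
  expect_identical(c(er$n_drug, er$n_vehicle), c(10L, 10L))
})

test_that("PF calls require both histology and CT positivity", {
  crit <- pf_call_criteria()
  expect_true(classify_pf(12, 85, crit))
  expect_false(classify_pf(12, 4, crit))    # CT below cut
  expect_false(classify_pf(11, 85, crit))   # histology below cut
  expect_identical(classify_pf(c(12, 12, 11), c(85, 4, 85), crit),
                   c(TRUE, FALSE, FALSE))
  relaxed <- pf_call_criteria(histology_cut = 9, v200_cut = 25)
  expect_true(classify_pf(10, 30, relaxed))
  expect_error(pf_call_criteria(histology_cut = 13), "\\[0, 12\\]")
})

test_that("incidence and mortality are bounded percent tabulations", {
  expect_equal(pf_incidence(c(rep(TRUE, 9), FALSE)), 90)
  expect_equal(pf_incidence(rep(FALSE, 5)), 0)
  expect_equal(pf_incidence(c(TRUE, TRUE, TRUE, rep(FALSE, 4))), 300 / 7)
  expect_error(pf_incidence(logical(0)), "empty")

  surv <- data.frame(
    animal_id = sprintf("m%02d", 1:20),
    group = rep(c("AMD3100", "MSX122"), each = 10),
    death_week = c(3, 7, 12, 15, 19, rep(NA, 15)))
  expect_equal(mortality(surv, "AMD3100", 20), 50)
  expect_equal(mortality(surv, "MSX122", 20), 0)
  expect_equal(mortality(surv, "AMD3100", 10), 20)  # deaths after horizon excluded
  expect_error(mortality(surv, "nope", 20), "unknown group")

  expect_setequal(endpoint_survivors(surv, "AMD3100", 20),
                  sprintf("m%02d", 6:10))
})

test_that("mortality is permutation-invariant", {
  set.seed(4)
  surv <- data.frame(animal_id = sprintf("m%d", 1:8), group = "g",
                     death_week = c(2, NA, 18, NA, NA, 20, NA, 5))
  shuffled <- surv[sample(nrow(surv)), ]
  expect_equal(mortality(surv, "g", 20), mortality(shuffled, "g", 20))
})

test_that("timecourses are anchored at a unit baseline", {
  tab <- data.frame(assay = "CXCL12_BALF",
                    day = rep(c(0, 1, 28), each = 3),
                    animal_id = rep(sprintf("m%d", 1:3), 3),
                    value = c(2, 2, 2,  2.5, 3.5, 3,  4.2, 3.8, 4))
  tc <- timecourse_summarize(tab, "CXCL12_BALF")
  expect_equal(tc$relative_level[tc$day == 0], 1)
  expect_true(is.na(tc$p_vs_baseline[tc$day == 0]))
  expect_false(tc$significant_vs_baseline[tc$day == 0])
  expect_equal(tc$relative_level[tc$day == 28], 2, tolerance = 1e-12)
})

test_that("days identical to baseline are never flagged significant", {
  tab <- data.frame(assay = "a", day = rep(c(0, 7, 14), each = 3),
                    animal_id = rep(1:3, 3), value = rep(c(1, 2, 3), 3))
  tc <- timecourse_summarize(tab, "a")
  expect_equal(tc$relative_level, rep(1, 3))
  expect_false(any(tc$significant_vs_baseline))
})

test_that("paired reference values normalize replicates before summary", {
  tab <- data.frame(assay = "CXCR4_mRNA", day = rep(c(0, 7), each = 3),
                    animal_id = rep(1:3, 2),
                    value = c(2, 4, 6, 8, 16, 24),
                    reference = c(1, 2, 3, 2, 4, 6))
  tc <- timecourse_summarize(tab, "CXCR4_mRNA")
  # normalized replicates: day 0 all 2, day 7 all 4 -> relative level 2
  expect_equal(tc$mean[tc$day == 0], 2)
  expect_equal(tc$relative_level[tc$day == 7], 2)
})

test_that("timecourse contracts reject missing or thin baselines", {
  tab <- data.frame(assay = "a", day = rep(c(1, 7), each = 2),
                    animal_id = rep(1:2, 2), value = 1:4)
  expect_error(timecourse_summarize(tab, "a"), "baseline day 0 missing")
  tab2 <- data.frame(assay = "a", day = c(0, 0, 7), animal_id = c(1, 2, 1),
                     value = c(1, 2, 3))
  expect_error(timecourse_summarize(tab2, "a"), "fewer than 2")
  expect_error(timecourse_summarize(tab, "missing_assay"), "not present")
})
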