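test_that("multiple-hit TET2 calls require >=2 pathogenic hits at >=15%", {
  two_ok <- data.frame(gene = "TET2", tier = 1L, vaf = c(0.20, 0.18))
  expect_true(callMultihitTET2(two_ok)$positive)

  one_low <- data.frame(gene = "TET2", tier = 1L, vaf = c(0.20, 0.10))
  expect_false(callMultihitTET2(one_low)$positive)

  wrong_gene <- data.frame(gene = c("TET2", "DNMT3A", "DNMT3A"),
                           tier = 1L, vaf = c(0.40, 0.30, 0.30))
  expect_false(callMultihitTET2(wrong_gene)$positive)

  ## threshold is inclusive: exactly 15% qualifies
  edge <- data.frame(gene = "TET2", tier = 2L, vaf = c(0.15, 0.15))
  expect_true(callMultihitTET2(edge)$positive)

  ## tier-3 variants never qualify
  t3 <- data.frame(gene = "TET2", tier = 3L, vaf = c(0.4, 0.4))
  expect_false(callMultihitTET2(t3)$positive)
  expect_false(callMultihitTET2(NULL)$positive)
})

test_that("KM estimates match hand product-limit computation", {
  ## no events: S identically 1
  km0 <- kmEstimate(c(3, 6, 9, 12, 15), rep(0, 5))
  expect_true(all(km0$survival == 1))

  ## n=4, one event at t=10: S(10) = 3/4
  km1 <- kmEstimate(c(10, 12, 14, 16), c(1, 0, 0, 0))
  expect_equal(km1$survival[km1$time == 10], 0.75)

  ## interleaved censoring, 6 records, vs the hand oracle
  tm <- c(5, 8, 12, 12, 20, 25); ev <- c(1, 0, 1, 0, 1, 0)
  km <- kmEstimate(tm, ev)
  oracle <- bruteKM(tm, ev)
  expect_equal(km$survival, oracle$survival[match(km$time, oracle$time)])
  expect_equal(km$survival, c(5 / 6, 5 / 6, 5 / 8 * 1, 5 / 16, 5 / 16) *
                 c(1, 1, 1, 1, 1), tolerance = 1e-12)
  ## non-increasing step function
  expect_true(all(diff(km$survival) <= 0))
  expect_equal(km$at_risk, c(6, 5, 4, 2, 1))

  ## no censoring: final S = 1 - events/n
  km2 <- kmEstimate(c(1, 2, 3, 4), c(1, 1, 0, 1))
  expect_error(kmEstimate(c(-1, 2), c(1, 0)), "negative")
})

test_that("log-rank matches the hand-computed O-E statistic", {
  tm <- c(1, 3, 5, 2, 4, 6); ev <- c(1, 1, 0, 1, 0, 1)
  gr <- rep(c("A", "B"), each = 3)
  lr <- logrankTest(tm, ev, gr)
  oracle <- bruteLogrank(tm, ev, gr)
  expect_equal(lr$chi2, oracle$chi2, tolerance = 1e-9)
  expect_equal(lr$p_value, oracle$p_value, tolerance = 1e-9)
  expect_equal(lr$chi2, 0.4864865, tolerance = 1e-6)

  ## identical groups: chi2 ~ 0
  tm2 <- rep(c(2, 4, 6, 8), 2); ev2 <- rep(c(1, 0, 1, 0), 2)
  gr2 <- rep(c("A", "B"), each = 4)
  expect_lt(logrankTest(tm2, ev2, gr2)$chi2, 1e-9)

  expect_warning(z <- logrankTest(c(1, 2), c(0, 0), c("A", "B")), "no events")
  expect_equal(z$p_value, 1)
})

test_that("log-rank has power against a large hazard ratio", {
  set.seed(402)
  hits <- 0L
  for (r in 1:100) {
    d <- simSurvData(100, 14)
    if (logrankTest(d$time, d$event, d$group)$p_value < 0.001) hits <- hits + 1L
  }
  expect_gte(hits, 99L)
})

test_that("Cox HR is ~1 for exchangeable groups and scale-invariant", {
  set.seed(7)
  d <- simSurvData(300, 1)
  cx <- coxHRBinary(d$time, d$event, d$group)
  expect_gt(cx$ci_high, 1); expect_lt(cx$ci_low, 1)
  expect_true(cx$ci_low <= cx$hr && cx$hr <= cx$ci_high)

  cx10 <- coxHRBinary(d$time * 10, d$event, d$group)
  expect_equal(cx10$hr, cx$hr, tolerance = 1e-9)

  expect_error(coxHRBinary(c(1, 2), c(0, 0), c(0, 1)), "no events")
  ## complete separation flagged
  expect_warning(
    sep <- coxHRBinary(c(1, 2, 3, 10, 11, 12), c(1, 1, 1, 0, 0, 0),
                       rep(c(1, 0), each = 3)),
    "monotone")
  expect_true(sep$monotone)
})

test_that("diagnostic metrics reproduce the printed percentages", {
  m <- diagnosticMetrics(8, 1, 3, 35)
  expect_equal(m$sensitivity, 72.7)
  expect_equal(m$specificity, 97.2)
  expect_equal(m$ppv, 88.9)
  expect_equal(m$npv, 92.1)

  perfect <- diagnosticMetrics(5, 0, 0, 5)
  expect_equal(unlist(perfect), c(sensitivity = 100, specificity = 100,
                                  ppv = 100, npv = 100))
  expect_true(is.na(diagnosticMetrics(0, 0, 3, 5)$ppv))
})

test_that("confusion reconstruction is exhaustive and round-trips", {
  sols <- reconstructConfusion(47, 72.7, 97.2)
  expect_equal(nrow(sols), 1L)
  expect_equal(unlist(sols[1, ]), c(tp = 8, fp = 1, fn = 3, tn = 35))

  ## every solution reproduces the inputs after rounding
  sols2 <- reconstructConfusion(40, 75.0, 90.0)
  expect_gt(nrow(sols2), 0L)
  for (i in seq_len(nrow(sols2))) {
    m <- diagnosticMetrics(sols2$tp[i], sols2$fp[i], sols2$fn[i], sols2$tn[i])
    expect_equal(m$sensitivity, 75.0)
    expect_equal(m$specificity, 90.0)
  }

  perfect <- reconstructConfusion(4, 100.0, 100.0)
  expect_true(all(perfect$fn == 0) && all(perfect$fp == 0))
  expect_equal(nrow(reconstructConfusion(3, 50.0, 50.0)), 0L)
})

test_that("CHN-free analysis assembles groups, tests and metrics", {
  set.seed(90)
  sim <- simulateCohort(simulationConfig(n_patients = 150L, seed = 14L,
                                         baseline_chn_hazard = 0.002))
  parts <- partitionCohort(sim$cohort)
  calls <- biomarkerCalls(parts,
                          patient_ids = cohortPatients(sim$cohort)$patient_id)
  ## calls agree with generator truth
  truth <- sim$truth$patients
  expect_equal(calls$positive[match(truth$patient_id, calls$patient_id)],
               truth$biomarker_true)

  rep <- chnFreeAnalysis(cohortPatients(sim$cohort), calls)
  expect_equal(sum(rep$confusion), 150)
  expect_true(all(c("high_burden", "low_or_absent") %in% names(rep$km)))
  expect_true(rep$cox$hr > 1)  # generator hazard ratio is 14

  ## single-group cohort skips comparisons
  neg <- calls; neg$positive <- FALSE
  expect_warning(rep0 <- chnFreeAnalysis(cohortPatients(sim$cohort), neg),
                 "single")
  expect_null(rep0$cox)
})
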