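test_that("cosine similarity has the documented geometry", {
  a <- runif(96); names(a) <- CONTEXTS_96
  expect_equal(cosineSimilarity(a, a), 1, tolerance = 1e-12)
  expect_equal(cosineSimilarity(a, 2 * a), 1, tolerance = 1e-12)
  b <- c(1, 0, 1, rep(0, 93)); d <- c(1, 1, 0, rep(0, 93))
  expect_equal(cosineSimilarity(b, d), 0.5)
  disjoint <- rev(b)
  expect_equal(cosineSimilarity(b, disjoint), 0)
  ## symmetry and scale invariance
  x <- runif(96); y <- runif(96)
  expect_equal(cosineSimilarity(x, y), cosineSimilarity(y, x))
  expect_equal(cosineSimilarity(3 * x, y), cosineSimilarity(x, y),
               tolerance = 1e-12)
  expect_error(cosineSimilarity(rep(0, 96), x), "zero")
})

test_that("KL objective is non-increasing and rank-1 factorizes exactly", {
  cat1 <- makeTwoSignatureCatalog(17L, n_samples = 10L, total = 60L)
  set.seed(2)
  fit <- nmfKL(t(catalogCounts(cat1)), k = 2)
  expect_true(all(diff(fit$objective_trace) <= 1e-6 *
                    max(abs(fit$objective_trace[1]), 1)))
  expect_equal(unname(colSums(fit$W)), rep(1, 2), tolerance = 1e-9)

  ## rank-1: samples exact multiples of one profile, k = 1 recovers it
  prof <- apobecLikeProfile()
  V <- outer(prof, c(100, 200, 400))
  set.seed(3)
  f1 <- nmfKL(V, k = 1)
  expect_gt(cosineSimilarity(f1$W[, 1], prof), 0.999)
})

test_that("two well-separated signatures are recovered by bootstrapped NMF", {
  truth <- twoProfileTruth()
  expect_lt(cosineSimilarity(truth[1, ], truth[2, ]), 0.3)
  cat1 <- makeTwoSignatureCatalog(101L)
  ext <- extractSignatures(cat1, k = 2, n_bootstrap = 20L, seed = 5L)
  M <- signatureProfiles(ext$signatures) %*% t(truth) /
    outer(sqrt(rowSums(signatureProfiles(ext$signatures)^2)),
          sqrt(rowSums(truth^2)))
  expect_true(all(apply(M, 2, max) >= 0.9))
  expect_true(all(signatureStability(ext$signatures) > 0.5))
  ## exposures conserve sample totals
  expect_equal(unname(rowSums(ext$exposures)),
               unname(rowSums(catalogCounts(cat1))), tolerance = 0.5)
})

test_that("identical seeds reproduce extraction bit-for-bit", {
  cat1 <- makeTwoSignatureCatalog(7L, n_samples = 8L, total = 50L)
  e1 <- extractSignatures(cat1, k = 2, n_bootstrap = 5L, seed = 11L)
  e2 <- extractSignatures(cat1, k = 2, n_bootstrap = 5L, seed = 11L)
  expect_identical(signatureProfiles(e1$signatures),
                   signatureProfiles(e2$signatures))
  expect_identical(e1$exposures, e2$exposures)
})

test_that("over-factorization degrades stability", {
  cat1 <- makeTwoSignatureCatalog(19L)
  e2 <- extractSignatures(cat1, k = 2, n_bootstrap = 15L, seed = 2L)
  e3 <- extractSignatures(cat1, k = 3, n_bootstrap = 15L, seed = 2L)
  expect_lt(min(signatureStability(e3$signatures)),
            min(signatureStability(e2$signatures)))
})

test_that("extraction rejects invalid inputs", {
  cat1 <- makeTwoSignatureCatalog(3L, n_samples = 4L, total = 30L)
  expect_error(extractSignatures(cat1, k = 5), "exceeds")
  expect_error(extractSignatures(cat1, k = 0), ">= 1")
  empty <- simulateCatalogs(twoProfileTruth(),
                            matrix(c(10, 0, 0, 0), 2, 2), seed = 1)
  expect_error(extractSignatures(empty, k = 1), "at least one SNV")
})

test_that("reference matching maximizes CCS with a low-index tie break", {
  ref <- makeReferenceFixture(42L)
  truth <- SignatureSet(rbind(Sign.01 = smokingLikeProfile()))
  m <- matchToReference(truth, ref)
  expect_equal(m$matches$best_reference_name, "Signature.4")
  expect_equal(m$matches$ccs, 1, tolerance = 1e-9)
  expect_equal(m$matches$ccs, max(m$ccs[1, ]))

  ## exact duplicate references tie at machine precision -> lowest index
  dup <- signatureProfiles(ref)
  dup[10, ] <- dup[4, ]
  m2 <- matchToReference(truth, SignatureSet(dup))
  expect_equal(m2$matches$best_reference_name, "Signature.4")
})

test_that("NNLS exposures recover known mixtures within sampling noise", {
  ## orthogonal two-profile mixture at 50/50, 100 mutations
  p1 <- c(rep(1 / 48, 48), rep(0, 48)); p2 <- rev(p1)
  profs <- rbind(A = p1, B = p2); colnames(profs) <- CONTEXTS_96
  set.seed(31)
  devs <- replicate(100, {
    cat1 <- simulateCatalogs(profs, matrix(c(50, 50), 1), seed = sample.int(1e6, 1))
    e <- estimateExposures(cat1, SignatureSet(profs))$exposures
    e[1, "A"] - 50
  })
  ## multinomial sd of a 50/50 split of 100 draws is 5
  expect_true(all(abs(devs) <= 3 * 5))
  expect_lt(abs(mean(devs)), 2)

  ## exact multiple of one profile
  cat2 <- simulateCatalogs(profs, matrix(c(30, 0), 1), seed = 9)
  e2 <- estimateExposures(cat2, profs)$exposures
  expect_equal(unname(e2[1, ]), c(30, 0), tolerance = 1e-9)

  ## empty sample gives zero exposures
  cat3 <- simulateCatalogs(profs, matrix(c(0, 0), 1), seed = 9)
  e3 <- estimateExposures(cat3, profs)$exposures
  expect_equal(unname(e3[1, ]), c(0, 0))
})

test_that("dominance calls use an inclusive 50% threshold", {
  ex <- rbind(c(60, 40), c(50, 50), c(40, 60), c(0, 0))
  dom <- callDominance(ex)
  expect_equal(unname(dom$active[, 1]), c(TRUE, TRUE, FALSE))
  expect_equal(unname(dom$active[, 2]), c(FALSE, TRUE, TRUE))
  ## zero-total sample excluded from the denominator
  expect_equal(unname(dom$active_fraction), c(2 / 3, 2 / 3))
})
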