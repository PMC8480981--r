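test_that("catalogs conserve SNV counts and bin by collapsed context", {
  v <- exampleVariantRows()
  cat96 <- buildCatalog(v)
  expect_equal(sum(catalogCounts(cat96)), 3L)
  ## per-sample row sums equal each sample's SNV count
  expect_equal(unname(rowSums(catalogCounts(cat96))), c(2, 1))
  ## G>T at AGC lands in G[C>A]T after reverse complement
  expect_equal(catalogCounts(cat96)["P2", "G[C>A]T"], 1L)
  expect_equal(catalogCounts(cat96)["P1", "A[C>T]G"], 2L)

  ## context inconsistent with ref is a validation error
  bad <- v; bad$context3[1] <- "AAG"
  expect_error(buildCatalog(bad), "middle base|does not match")

  ## indels are excluded
  w <- v; w$ref[3] <- "CT"; w$alt[3] <- "C"
  expect_equal(sum(catalogCounts(buildCatalog(w))), 2L)
})

test_that("stranded catalogs split by coding-strand orientation", {
  v <- exampleVariantRows()
  ## P1 rows: ref C (pyrimidine), coding_strand_ref same -> fwd
  ## P2 row: ref G (purine), coding_strand_ref opposite -> pyr on coding -> fwd
  cat192 <- buildCatalog(v, stranded = TRUE)
  sc <- strandedCounts(cat192)
  expect_equal(sum(sc[, endsWith(colnames(sc), ":fwd")]), 3)
  expect_equal(sum(sc[, endsWith(colnames(sc), ":rev")]), 0)

  v$coding_strand_ref <- c("opposite", "unknown", "same")
  sc2 <- strandedCounts(buildCatalog(v, stranded = TRUE))
  expect_equal(sum(sc2[, endsWith(colnames(sc2), ":rev")]), 2)  # P1 LN + P2
  ## unknown contributes to unstranded only; fwd+rev <= unstranded bin
  cat2 <- buildCatalog(v, stranded = TRUE)
  fwd <- strandedCounts(cat2)[, seq(1, 192, 2)]
  rev <- strandedCounts(cat2)[, seq(2, 192, 2)]
  expect_true(all(fwd + rev <= catalogCounts(cat2)))
  expect_equal(sum(catalogCounts(cat2)) - sum(fwd + rev), 1)
})

test_that("a catalog sampled from a known profile recovers it", {
  prof <- smokingLikeProfile()
  cat1 <- simulateCatalogs(rbind(prof), matrix(5000, 1, 1), seed = 4L)
  emp <- catalogCounts(cat1)[1, ] / 5000
  expect_lt(sum(abs(emp - prof)) / 2, 0.05)  # total variation
})

test_that("substitution fractions sum to one and match hand arithmetic", {
  ## toy set {C>T, C>T, C>A, T>G} as one sample
  v <- data.frame(patient_id = "P1", compartment = "LN", gene = "X",
                  chrom = "1", pos = 1:4, ref = c("C", "C", "C", "T"),
                  alt = c("T", "T", "A", "G"),
                  context3 = c("ACA", "ACA", "ACA", "ATA"),
                  coding_strand_ref = "unknown", vclass = "missense",
                  tier = NA, vaf = 0.3)
  f <- substitutionFractions(v)
  expect_equal(sum(f$group), 1, tolerance = 1e-9)
  expect_equal(unname(f$group[c("C>T", "C>A", "T>G")]), c(0.5, 0.25, 0.25))

  ## all-identical classes give a single fraction of 1
  f1 <- substitutionFractions(v[1:2, ])
  expect_equal(unname(f1$group["C>T"]), 1)

  ## zero SNVs: explicit empty result
  indel <- v[1, ]; indel$ref <- "CT"; indel$alt <- "C"; indel$context3 <- NA
  f0 <- substitutionFractions(indel)
  expect_length(f0$group, 0L)

  ## invariant to variant order
  f2 <- substitutionFractions(v[c(3, 1, 4, 2), ])
  expect_equal(f2$group, f$group)
})

test_that("Ti/Tv summary uses a paired per-sample test", {
  per <- matrix(0, 4, 6, dimnames = list(paste0("S", 1:4),
                                         SUBSTITUTION_CLASSES))
  per[, "C>T"] <- 0.3; per[, "T>C"] <- 0.2; per[, "C>A"] <- 0.5
  tv <- titvSummary(per)
  expect_equal(tv$median_ti, 0.5)
  expect_equal(tv$mean_tv, 0.5)
  expect_equal(tv$p_value, 1)  # exactly half transitions in every sample

  ## single sample: no p-value
  expect_true(is.na(titvSummary(per[1, , drop = FALSE])$p_value))

  ## recovered mean for a known spread of per-sample Ti fractions
  per[, "C>T"] <- c(0.2, 0.4, 0.6, 0.8); per[, "T>C"] <- 0
  per[, "C>A"] <- 1 - per[, "C>T"]
  expect_equal(titvSummary(per)$mean_ti, 0.5)
  expect_equal(titvSummary(per)$median_ti, 0.5)
})

test_that("strand fold excess is (nF - nR)/nR", {
  expect_equal(strandFoldExcess(17, 5), 2.4)
  expect_equal(strandFoldExcess(5, 5), 0)
  expect_equal(strandFoldExcess(19, 10), 0.9)
  expect_warning(x <- strandFoldExcess(3, 0), "undefined")
  expect_identical(x, Inf)
})

test_that("between-group class comparison is Welch-based with power", {
  ident <- rep(0.3, 10)
  expect_warning(cmp <- compareClassBetweenGroups(ident, ident),
                 "zero variance")
  expect_equal(cmp$welch_p, 1)

  zeros <- rep(0, 10)
  cmp0 <- compareClassBetweenGroups(ident, zeros)
  expect_equal(cmp0$median_b, 0)
  expect_equal(cmp0$case_fraction_b, 0)

  ## power: true means 0.39 vs 0.06, n = 50 -> significant in >=95/100
  set.seed(88)
  hits <- 0L
  for (r in 1:100) {
    a <- pmin(pmax(rnorm(50, 0.39, 0.25), 0), 1)
    b <- pmin(pmax(rnorm(50, 0.06, 0.10), 0), 1)
    if (compareClassBetweenGroups(a, b)$welch_p < 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("catalog TSV export round-trips", {
  cat96 <- makeTwoSignatureCatalog(3L, n_samples = 5L, total = 40L)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeCatalog(cat96, path)
  back <- readCatalog(path)
  expect_equal(catalogCounts(back), catalogCounts(cat96))
})
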