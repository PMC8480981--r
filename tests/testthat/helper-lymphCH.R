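## Shared fixtures and independent oracles, built in code.

## Dirichlet draws for exposure designs
rdirichlet <- function(n, alpha) {
  x <- matrix(stats::rgamma(n * length(alpha), alpha), n, byrow = TRUE)
  x / rowSums(x)
}

## two well-separated generating profiles (pairwise CCS ~ 0.02)
twoProfileTruth <- function() {
  rbind(apobec = apobecLikeProfile(), smoking = smokingLikeProfile())
}

## catalog of n_samples x total mutations drawn from the two-profile truth
## with Dirichlet(0.5) mixing (many near-pure samples, as in cohorts where
## one signature dominates most samples)
makeTwoSignatureCatalog <- function(seed, n_samples = 20L, total = 100L) {
  set.seed(seed)
  expo <- rdirichlet(n_samples, c(0.5, 0.5)) * total
  simulateCatalogs(twoProfileTruth(), expo, seed = seed)
}

## textbook two-group log-rank oracle: O - E and hypergeometric variance
## accumulated over event times
bruteLogrank <- function(time, event, group) {
  g <- as.integer(factor(group))
  O <- 0; E <- 0; V <- 0
  for (t in sort(unique(time[event == 1]))) {
    at <- time >= t
    n <- sum(at); n1 <- sum(at & g == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g == 1)
    O <- O + d1; E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chi2 <- (O - E)^2 / V
  list(chi2 = chi2, p_value = stats::pchisq(chi2, 1, lower.tail = FALSE))
}

## hand product-limit oracle
bruteKM <- function(time, event) {
  s <- 1; out <- numeric(0)
  for (t in sort(unique(time))) {
    n <- sum(time >= t); d <- sum(time == t & event == 1)
    s <- s * (1 - d / n)
    out <- c(out, s)
  }
  data.frame(time = sort(unique(time)), survival = out)
}

## exponential survival data with a binary group hazard ratio
simSurvData <- function(n_per, hr, base = 0.01, cens = 120) {
  g <- rep(0:1, each = n_per)
  t <- stats::rexp(2L * n_per, base * hr^g)
  list(time = pmin(t, cens), event = as.integer(t <= cens), group = g)
}

## minimal well-formed variant table rows
exampleVariantRows <- function() {
  data.frame(
    patient_id = c("P1", "P1", "P2"),
    compartment = c("LN", "BMPB", "LN"),
    gene = c("TET2", "TET2", "RHOA"),
    chrom = c("4", "4", "3"),
    pos = c(106000001, 106000001, 49400005),
    ref = c("C", "C", "G"),
    alt = c("T", "T", "T"),
    context3 = c("ACG", "ACG", "AGC"),
    coding_strand_ref = c("same", "same", "opposite"),
    vclass = c("nonsense", "nonsense", "missense"),
    tier = c(1L, 1L, 1L),
    vaf = c(0.35, 0.30, 0.20),
    stringsAsFactors = FALSE)
}

tbEstimate <- function(tb, method = "flow", low = tb * 0.8, high = tb * 1.2,
                       pid = "P1") {
  if (method == "none") { tb <- 0; low <- 0; high <- 0 }
  new("TumorBurdenEstimate", patient_id = pid, tb = tb, method = method,
      tb_low = low, tb_high = high)
}
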