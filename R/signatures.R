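## De novo mutational-signature extraction by bootstrapped NMF under the
## generalized Kullback-Leibler (Poisson) objective, consensus clustering by
## partitioning around medoids under cosine distance, NNLS exposure refit,
## and cosine matching to a reference signature set.

#' Cosine correlation similarity between two profiles
#'
#' \code{dot(a, b) / (||a|| ||b||)}; lies in [0, 1] for non-negative inputs
#' (1 = identical shape, 0 = disjoint support) and is scale-invariant.
#'
#' @param a,b Non-negative, non-zero numeric vectors of equal length.
#' @return Numeric similarity.
#' @export
cosineSimilarity <- function(a, b) {
  if (length(a) != length(b)) stop("vectors differ in length")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("cosine similarity undefined for a zero vector")
  sum(a * b) / (na * nb)
}

## pairwise CCS between rows of two matrices
cosineSimilarityMatrix <- function(A, B) {
  An <- A / sqrt(rowSums(A^2))
  Bn <- B / sqrt(rowSums(B^2))
  An %*% t(Bn)
}

#' KL non-negative matrix factorization by multiplicative updates
#'
#' Factorizes a non-negative contexts x samples matrix V into W (contexts x
#' k, columns normalized to sum 1) and H (k x samples), minimizing the
#' generalized Kullback-Leibler divergence
#' \code{D(V || WH) = sum(V log(V/WH) - V + WH)} by the classic
#' multiplicative update rules from random non-negative initialization.
#' The objective is recorded every 100 iterations (it is non-increasing
#' under these updates).
#'
#' @param V Non-negative matrix, contexts x samples.
#' @param k Factorization rank.
#' @param max_iter Iteration cap (default 10000).
#' @param tol Relative-change convergence tolerance on the objective
#'   (default 1e-9), checked every 10 iterations.
#' @return List: \code{W}, \code{H}, \code{divergence}, \code{converged},
#'   \code{iterations}, \code{objective_trace} (value every 100 iterations).
#' @export
nmfKL <- function(V, k, max_iter = 10000L, tol = 1e-9) {
  V <- as.matrix(V)
  if (any(V < 0)) stop("V must be non-negative")
  n <- nrow(V); m <- ncol(V)
  if (k < 1L || k > min(n, m)) stop("invalid rank k")
  eps <- .Machine$double.eps
  W <- matrix(stats::runif(n * k, 0.1, 1), n, k)
  H <- matrix(stats::runif(k * m, 0.1, 1), k, m)
  kl <- function(WH) sum(V * log((V + eps) / (WH + eps)) - V + WH)
  prev <- kl(W %*% H)
  trace <- prev
  converged <- FALSE
  it <- 0L
  ones_n <- rep(1, n); ones_m <- rep(1, m)
  while (it < max_iter) {
    it <- it + 1L
    WH <- W %*% H
    H <- H * (t(W) %*% (V / (WH + eps))) / (colSums(W) + eps)
    WH <- W %*% H
    W <- W * ((V / (WH + eps)) %*% t(H)) / rep(rowSums(H) + eps, each = n)
    if (it %% 10L == 0L || it == max_iter) {
      cur <- kl(W %*% H)
      if (it %% 100L == 0L) trace <- c(trace, cur)
      if (abs(prev - cur) <= tol * max(abs(prev), 1)) {
        converged <- TRUE
        if (it %% 100L != 0L) trace <- c(trace, cur)
        break
      }
      prev <- cur
    }
  }
  ## push column scale of W into H
  cs <- colSums(W)
  W <- sweep(W, 2L, cs, "/")
  H <- H * cs
  list(W = W, H = H, divergence = kl(W %*% H), converged = converged,
       iterations = it, objective_trace = trace)
}

#' Extract de novo signatures by bootstrapped NMF
#'
#' For each bootstrap replicate, every sample's 96-context counts are
#' resampled multinomially (conserving its total) and factorized with
#' [nmfKL()]. All bootstrap signatures are pooled and clustered into k
#' groups by partitioning around medoids under cosine distance; cluster
#' means (renormalized) are the consensus profiles and mean silhouette
#' widths their stability. Exposures are then refit on the original catalog
#' by non-negative least squares ([estimateExposures()]). Signatures are
#' ordered by decreasing total exposure and named \code{Sign.01, ...}.
#'
#' @param catalog A [TrinucleotideCatalog-class]; every sample must carry at
#'   least one SNV.
#' @param k Number of signatures (the analysis here used 2 per extraction).
#' @param n_bootstrap Bootstrap replicates (default 100).
#' @param max_iter,tol Passed to [nmfKL()].
#' @param seed RNG seed; identical seeds give bit-identical results.
#' @return List: \code{signatures} (a [DeNovoSignatureSet-class]),
#'   \code{exposures} (samples x k matrix), \code{residuals},
#'   \code{objective_trace} (from the first bootstrap run).
#' @export
extractSignatures <- function(catalog, k, n_bootstrap = 100L,
                              max_iter = 10000L, tol = 1e-9, seed = 1L) {
  stopifnot(is(catalog, "TrinucleotideCatalog"))
  V0 <- t(catalogCounts(catalog))          # contexts x samples
  totals <- colSums(V0)
  if (any(totals == 0)) stop("every sample must carry at least one SNV")
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  if (k > min(ncol(V0), 96L)) stop("k exceeds the number of samples")
  set.seed(as.integer(seed))

  pooled <- vector("list", n_bootstrap)
  all_converged <- TRUE
  trace1 <- NULL
  for (b in seq_len(n_bootstrap)) {
    Vb <- vapply(seq_len(ncol(V0)), function(j)
      as.numeric(stats::rmultinom(1L, totals[j], V0[, j] / totals[j])),
      numeric(96L))
    fit <- nmfKL(Vb, k, max_iter = max_iter, tol = tol)
    if (b == 1L) trace1 <- fit$objective_trace
    all_converged <- all_converged && fit$converged
    pooled[[b]] <- t(fit$W)                # k x 96 rows
  }
  P <- do.call(rbind, pooled)

  if (k == 1L) {
    profiles <- matrix(colMeans(P), 1L, 96L)
    stability <- NA_real_
    membership <- rep(1L, nrow(P))
  } else {
    d <- 1 - cosineSimilarityMatrix(P, P)
    d[d < 0] <- 0
    pm <- cluster::pam(stats::as.dist(d), k = k, diss = TRUE)
    membership <- pm$clustering
    profiles <- t(vapply(seq_len(k), function(g)
      colMeans(P[membership == g, , drop = FALSE]), numeric(96L)))
    stability <- as.numeric(pm$silinfo$clus.avg.widths)
  }
  profiles <- profiles / rowSums(profiles)
  colnames(profiles) <- CONTEXTS_96
  rownames(profiles) <- sprintf("Sign.%02d", seq_len(k))

  expo <- nnlsExposures(catalogCounts(catalog), profiles)
  ord <- order(-colSums(expo$exposures))
  profiles <- profiles[ord, , drop = FALSE]
  stability <- stability[ord]
  rownames(profiles) <- sprintf("Sign.%02d", seq_len(k))
  expo <- nnlsExposures(catalogCounts(catalog), profiles)

  sig <- new("DeNovoSignatureSet", profiles = profiles,
             stability = stability, k = k, seed = as.integer(seed),
             nBootstrap = as.integer(n_bootstrap), converged = all_converged)
  list(signatures = sig, exposures = expo$exposures,
       residuals = expo$residuals, objective_trace = trace1)
}

## NNLS refit shared by extractSignatures / estimateExposures
nnlsExposures <- function(counts, profiles) {
  A <- t(profiles)                         # 96 x k
  k <- nrow(profiles)
  out <- matrix(0, nrow(counts), k,
                dimnames = list(rownames(counts), rownames(profiles)))
  res <- numeric(nrow(counts))
  for (i in seq_len(nrow(counts))) {
    x <- as.numeric(counts[i, ])
    tot <- sum(x)
    if (tot == 0) next
    fit <- pracma::lsqnonneg(A, x)
    e <- fit$x
    if (sum(e) > 0) e <- e * tot / sum(e)
    out[i, ] <- e
    res[i] <- sqrt(sum((x - A %*% fit$x)^2))
  }
  list(exposures = out, residuals = res)
}

#' Refit signature exposures on a catalog
#'
#' Per-sample non-negative least-squares fit of the catalog against fixed
#' signature profiles, rescaled so each sample's exposures sum to its SNV
#' count.
#'
#' @param catalog A [TrinucleotideCatalog-class].
#' @param signatures A [SignatureSet-class] (or profiles matrix).
#' @return List: \code{exposures} (samples x k), \code{residuals}.
#' @export
estimateExposures <- function(catalog, signatures) {
  profiles <- if (is(signatures, "SignatureSet"))
    signatureProfiles(signatures) else as.matrix(signatures)
  nnlsExposures(catalogCounts(catalog), profiles)
}

#' Match de novo signatures to a reference set
#'
#' Cosine correlation similarity of every de novo profile against every
#' reference profile; the best match is the argmax, with ties broken toward
#' the lowest reference index.
#'
#' @param denovo A [SignatureSet-class] (typically de novo).
#' @param refset A [SignatureSet-class] of reference profiles.
#' @return List: \code{matches} (data.frame \code{denovo_name,
#'   best_reference_name, ccs}) and \code{ccs} (full k x n_reference
#'   matrix).
#' @export
matchToReference <- function(denovo, refset) {
  D <- signatureProfiles(denovo); R <- signatureProfiles(refset)
  if (ncol(D) != ncol(R)) stop("dimension mismatch between signature sets")
  M <- cosineSimilarityMatrix(D, R)
  best <- apply(M, 1L, which.max)
  list(matches = data.frame(denovo_name = rownames(D),
                            best_reference_name = colnames(M)[best],
                            ccs = M[cbind(seq_len(nrow(M)), best)],
                            stringsAsFactors = FALSE),
       ccs = M)
}

#' Per-sample signature dominance calls
#'
#' A sample is \dQuote{dominated} by a signature when at least
#' \code{threshold} of its mutations are attributed to it (inclusive, per
#' the \dQuote{50% or more} convention). Zero-mutation samples are excluded
#' from the active-fraction denominator.
#'
#' @param exposures Samples x k exposure matrix.
#' @param threshold Dominance threshold (default 0.5).
#' @return List: \code{active} (logical samples x k matrix) and
#'   \code{active_fraction} (per-signature fraction of evaluable samples).
#' @export
callDominance <- function(exposures, threshold = 0.5) {
  tot <- rowSums(exposures)
  evaluable <- tot > 0
  shares <- exposures[evaluable, , drop = FALSE] / tot[evaluable]
  active <- shares >= threshold
  list(active = active,
       active_fraction = colMeans(active))
}
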