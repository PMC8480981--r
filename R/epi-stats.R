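## Direct age standardization and the generic two-proportion z / Welch t
## tests used across the analysis.

#' Directly age-standardized rate
#'
#' \code{sum_g cases_g / person_base_g * 100000 * weight_g}, the weights
#' being the standard population's age distribution (they must sum to 1
#' within 1e-6).
#'
#' @param strata data.frame with columns \code{cases}, \code{person_base},
#'   \code{weight} (and optionally \code{label}).
#' @return List: \code{rate_per_100k} and \code{stratum_rates} (crude
#'   per-100k rates by stratum).
#' @examples
#' ageAdjustedRate(data.frame(cases = 2, person_base = 1000, weight = 1))
#' @export
ageAdjustedRate <- function(strata) {
  stopifnot(all(c("cases", "person_base", "weight") %in% names(strata)))
  if (any(strata$person_base <= 0)) stop("person_base must be > 0")
  if (any(strata$cases < 0)) stop("cases must be >= 0")
  if (abs(sum(strata$weight) - 1) > 1e-6)
    stop("weights must sum to 1 (+/- 1e-6)")
  stratum_rates <- strata$cases / strata$person_base * 1e5
  list(rate_per_100k = sum(stratum_rates * strata$weight),
       stratum_rates = stratum_rates)
}

#' Ratio of two rates
#'
#' @param rate_a,rate_b Rates on the same scale (per 100k); \code{rate_b}
#'   must be positive.
#' @return Ratio rounded half-up to 1 decimal.
#' @examples
#' rateRatio(11547, 67)  # 172.3
#' @export
rateRatio <- function(rate_a, rate_b) {
  if (rate_b <= 0) stop("rate_b must be > 0")
  roundHalfUp(rate_a / rate_b, 1L)
}

#' Pooled two-proportion z test
#'
#' Two-sided z test of p1 = p2 using the pooled-variance statistic
#' \code{z = (p1 - p2) / sqrt(p (1-p) (1/n1 + 1/n2))}. When the pooled
#' proportion is 0 or 1 the statistic is degenerate and \code{z = 0,
#' p = 1} is returned with a warning.
#'
#' @param x1,n1,x2,n2 Successes and trials per group.
#' @return List: \code{z}, \code{p_two_sided}, \code{degenerate}.
#' @export
twoProportionZTest <- function(x1, n1, x2, n2) {
  stopifnot(n1 >= 1, n2 >= 1, x1 >= 0, x1 <= n1, x2 >= 0, x2 <= n2)
  p <- (x1 + x2) / (n1 + n2)
  if (p == 0 || p == 1) {
    warning("pooled proportion degenerate; z = 0")
    return(list(z = 0, p_two_sided = 1, degenerate = TRUE))
  }
  z <- (x1 / n1 - x2 / n2) / sqrt(p * (1 - p) * (1 / n1 + 1 / n2))
  list(z = z, p_two_sided = 2 * stats::pnorm(-abs(z)), degenerate = FALSE)
}

#' Welch two-sample t test
#'
#' Unequal-variance t statistic with Satterthwaite degrees of freedom.
#' When both samples have zero variance, equal means give \code{p = 1} and
#' unequal means \code{p = 0} (the statistic is unbounded).
#'
#' @param a,b Numeric samples, each of length >= 2.
#' @return List: \code{t}, \code{df}, \code{p_two_sided}.
#' @export
welchTTest <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    stop("each sample needs at least 2 values")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b)) {
      warning("zero variance in both samples; p = 1")
      return(list(t = 0, df = NA_real_, p_two_sided = 1))
    }
    return(list(t = sign(mean(a) - mean(b)) * Inf, df = NA_real_,
                p_two_sided = 0))
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_two_sided = tt$p.value)
}
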