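## Default-prior Bayes factors, computed by numerical integration.
##
## bf_ttest: JZS Bayes factor for a one-sample / paired t statistic with a
## Cauchy(0, rscale) prior on the standardized effect, written as the
## normal-scale mixture delta | g ~ N(0, g), g ~ InvGamma(1/2, rscale^2/2).
## bf_pearson: exact Bayes factor for a Pearson correlation under a
## stretched symmetric beta prior on rho (width 1 = uniform on (-1, 1)),
## using the exact sampling density of r via the Gauss hypergeometric 2F1.

dinvgamma_half <- function(g, b) {
  # InvGamma(shape = 1/2, scale = b) density
  sqrt(b) / gamma(0.5) * g^(-1.5) * exp(-b / g)
}

#' JZS Bayes factor for a one-sample or paired t statistic
#'
#' Cauchy default prior on the standardized effect size with scale
#' `rscale` (default `sqrt(2)/2`). Degenerate inputs with `t = 0` are
#' well-defined and give BF10 < 1.
#'
#' @param t Observed t statistic (paired: computed on the differences).
#' @param n Sample size (number of pairs).
#' @param rscale Cauchy prior scale (default `sqrt(2)/2`).
#' @return BF10, the Bayes factor for the alternative over the null.
#' @examples
#' bf_ttest(3.464, 3)
#' @export
bf_ttest <- function(t, n, rscale = sqrt(2) / 2) {
  stopifnot(is.finite(n), n >= 2)
  if (!is.finite(t)) return(Inf)
  nu <- n - 1
  b <- rscale^2 / 2
  like0 <- (1 + t^2 / nu)^(-(nu + 1) / 2)
  marg1 <- stats::integrate(function(g) {
    (1 + n * g)^(-0.5) *
      (1 + t^2 / ((1 + n * g) * nu))^(-(nu + 1) / 2) *
      dinvgamma_half(g, b)
  }, 0, Inf, rel.tol = 1e-9)$value
  marg1 / like0
}

## Gauss hypergeometric 2F1(a, b; c; z) by power series, |z| < 1.
hyp2f1 <- function(a, b, c, z) {
  term <- 1
  total <- 1
  for (k in seq_len(10000)) {
    term <- term * (a + k - 1) * (b + k - 1) / ((c + k - 1) * k) * z
    total <- total + term
    if (abs(term) < abs(total) * 1e-13) break
  }
  total
}

## Sampling density of r given rho, up to rho-free constants (they cancel
## in the Bayes-factor ratio).
pearson_kernel <- function(rho, r, n) {
  (1 - rho^2)^((n - 1) / 2) * (1 - rho * r)^((3 - 2 * n) / 2) *
    vapply(rho, function(p) hyp2f1(0.5, 0.5, n - 0.5, (p * r + 1) / 2),
           numeric(1))
}

#' Default-prior Bayes factor for a Pearson correlation
#'
#' Exact Bayes factor for H1: rho != 0 against H0: rho = 0 under a
#' stretched beta prior of width `kappa` on rho (width 1 is uniform on
#' (-1, 1)), computed from the exact sampling distribution of r.
#'
#' @param r Observed Pearson correlation.
#' @param n Sample size.
#' @param kappa Prior width (default 1).
#' @return BF10.
#' @examples
#' bf_pearson(0.48, 33)
#' @export
bf_pearson <- function(r, n, kappa = 1) {
  stopifnot(abs(r) <= 1, n >= 4, kappa > 0)
  if (1 - r^2 < 1e-10) return(Inf)  # degenerate, perfectly linear input
  a <- 1 / kappa
  # stretched Beta(1/kappa, 1/kappa) on (-1, 1)
  prior <- function(rho) {
    stats::dbeta((rho + 1) / 2, a, a) / 2
  }
  num <- stats::integrate(function(rho) {
    pearson_kernel(rho, r, n) * prior(rho)
  }, -1, 1, rel.tol = 1e-8)$value
  num / pearson_kernel(0, r, n)
}

#' Classify Bayes-factor evidence strength
#'
#' Standard banding of BF10 for the alternative hypothesis: anecdotal
#' (<3), moderate (3-10), strong (10-30), very strong (30-100), decisive
#' (>100). The bands partition the positive axis; boundary values fall in
#' the lower band.
#'
#' @param bf10 Bayes factor(s) > 0 (NA allowed).
#' @return Character vector of evidence labels.
#' @examples
#' bf_evidence_class(c(0.5, 45, 150))
#' @export
bf_evidence_class <- function(bf10) {
  vapply(bf10, function(b) {
    if (is.na(b)) return(NA_character_)
    if (b <= 3) "anecdotal"
    else if (b <= 10) "moderate"
    else if (b <= 30) "strong"
    else if (b <= 100) "very strong"
    else "decisive"
  }, character(1))
}

## Noncentral-t confidence interval for a standardized mean difference
## d = mean(diff) / sd(diff), from inverting the noncentral t CDF.
cohen_d_ci <- function(t, n, conf = 0.95) {
  df <- n - 1
  alpha <- 1 - conf
  bound <- abs(t) + 10 + 10 / sqrt(n)
  ncp_for <- function(p) {
    # R's noncentral pt warns about ~1e-6 precision limits; that is far
    # below the interval resolution needed here
    f <- function(ncp) suppressWarnings(stats::pt(t, df, ncp)) - p
    lo <- -bound * sqrt(n); hi <- bound * sqrt(n)
    if (f(lo) * f(hi) > 0) return(sign(t) * bound * sqrt(n))
    stats::uniroot(f, c(lo, hi), tol = 1e-8)$root
  }
  c(lower = ncp_for(1 - alpha / 2) / sqrt(n),
    upper = ncp_for(alpha / 2) / sqrt(n))
}
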