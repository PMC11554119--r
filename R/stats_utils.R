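#' Kendall tau-a rank correlation
#'
#' Tau-a over all element pairs: (concordant - discordant) / (n(n-1)/2),
#' with tied pairs (in either vector) counting zero — the convention for
#' comparing a neural RDM with candidate model RDMs that may predict tied
#' dissimilarities.
#'
#' @param x,y Numeric vectors of equal length (>= 2).
#' @return Tau-a in `[-1, 1]`.
#' @examples
#' kendall_tau_a(1:4, c(1, 3, 2, 4)) # 4/6
#' @export
kendall_tau_a <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  sx <- sign(outer(x, x, `-`))
  sy <- sign(outer(y, y, `-`))
  n <- length(x)
  sum(sx * sy) / (n * (n - 1))
}

#' Fisher z transform with clamping at |r| = 1
#' @param r Correlation in `[-1, 1]`.
#' @return atanh(r); |r| = 1 is clamped to atanh(1 - 1e-12) with a warning.
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1, na.rm = TRUE)) {
    warn("|correlation| = 1 clamped before Fisher z transform")
    r <- pmin(pmax(r, -(1 - 1e-12)), 1 - 1e-12)
  }
  atanh(r)
}

#' JZS Bayes factor for a one-sample t test
#'
#' Default-prior Bayesian one-sample t test: Cauchy prior with scale
#' `rscale` on the standardized effect, evaluated by numerical integration
#' over the JZS mixture. Returns BF10 (evidence for a nonzero effect).
#'
#' @param t Observed t statistic.
#' @param n Sample size.
#' @param rscale Cauchy prior scale (default 0.707).
#' @return BF10.
#' @examples
#' bf_one_sample(0, 33) # < 1: support for the null
#' @export
bf_one_sample <- function(t, n, rscale = sqrt(2) / 2) {
  nu <- n - 1
  null_dens <- (1 + t^2 / nu)^(-(nu + 1) / 2)
  # marginal likelihood under H1: g ~ InverseGamma(1/2, rscale^2 / 2);
  # evaluated in log space to stay finite as g -> 0
  integrand <- function(g) {
    lg <- -0.5 * log1p(n * g) -
      ((nu + 1) / 2) * log1p(t^2 / ((1 + n * g) * nu)) +
      log(rscale) - 0.5 * log(2 * pi) - 1.5 * log(g) - rscale^2 / (2 * g)
    out <- exp(lg)
    out[!is.finite(out)] <- 0
    out
  }
  alt_dens <- integrate(integrand, 0, Inf, rel.tol = 1e-8)$value
  alt_dens / null_dens
}

#' Cohen's dz for paired / one-sample designs
#' @param x Vector of (difference) scores.
#' @return mean(x) / sd(x); `NA` with a warning when sd is zero.
#' @export
cohens_dz <- function(x) {
  s <- sd(x)
  if (s == 0) {
    warn("Cohen's dz undefined: zero variance")
    return(NA_real_)
  }
  mean(x) / s
}
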