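# Case-control association power in the style of the GAS power calculator:
# disease-model penetrances under Hardy-Weinberg genotype frequencies, Bayes
# inversion to case/control genotype distributions, and the power of the
# two-proportion test after collapsing genotypes per inheritance model.

#' Genotype relative risk from an odds ratio
#'
#' Under the rare-disease approximation (here prevalence ~ 0.007) the odds
#' ratio and the genotype relative risk coincide, so the conversion is the
#' identity; it exists as an explicit step so the approximation is visible in
#' analysis code.
#'
#' @param or_value Positive odds ratio.
#' @return The genotype relative risk (gamma).
#' @export
grr_from_or <- function(or_value) {
  stopifnot(all(or_value > 0))
  or_value
}

#' Penetrances implied by a disease model
#'
#' Solves for the penetrances (f0, f1, f2) of carrying 0, 1 or 2 risk alleles
#' given disease prevalence K, risk-allele frequency p, genotype relative
#' risk gamma and the inheritance model, constrained so the Hardy-Weinberg
#' weighted mean penetrance equals K.
#'
#' @param prevalence Disease prevalence K in (0, 1).
#' @param risk_allele_freq Risk-allele frequency p in (0, 1).
#' @param grr Genotype relative risk gamma (> 0).
#' @param model One of `"dominant"`, `"recessive"`, `"additive"`,
#'   `"multiplicative"`.
#' @return List with `f0`, `f1`, `f2` and the Hardy-Weinberg genotype
#'   frequencies `g` (length 3).
#' @export
penetrances_from_model <- function(prevalence, risk_allele_freq, grr,
                                   model = c("dominant", "recessive",
                                             "additive", "multiplicative")) {
  model <- match.arg(model)
  K <- prevalence
  p <- risk_allele_freq
  stopifnot(K > 0, K < 1, p > 0, p < 1, grr > 0)
  g <- c((1 - p)^2, 2 * p * (1 - p), p^2)
  w <- switch(model,  # relative penetrance per genotype (f_i = w_i * f0)
    dominant = c(1, grr, grr),
    recessive = c(1, 1, grr),
    additive = c(1, grr, 2 * grr - 1),
    multiplicative = c(1, grr, grr^2)
  )
  if (any(w <= 0)) stop("model infeasible at these parameters", call. = FALSE)
  f0 <- K / sum(g * w)
  f <- f0 * w
  if (any(f >= 1) || any(f <= 0)) {
    stop("model infeasible at these parameters (penetrance outside (0,1))",
         call. = FALSE)
  }
  list(f0 = f[1], f1 = f[2], f2 = f[3], g = g)
}

#' Genotype distributions in cases and controls
#'
#' Bayes inversion of the penetrance model: the genotype distribution among
#' affected individuals is g_i f_i / K and among unaffected g_i (1 - f_i) /
#' (1 - K).
#'
#' @param pen Output of [penetrances_from_model()].
#' @param prevalence Disease prevalence K.
#' @return List with numeric length-3 vectors `case` and `control`, each
#'   summing to 1 (genotypes: 0, 1, 2 risk alleles).
#' @export
case_control_genotype_freqs <- function(pen, prevalence) {
  K <- prevalence
  f <- c(pen$f0, pen$f1, pen$f2)
  list(case = pen$g * f / K, control = pen$g * (1 - f) / (1 - K))
}

# Collapse genotype distributions to the per-model test proportion:
# dominant -> carrier of >= 1 risk allele; recessive -> two risk alleles;
# additive/multiplicative -> risk-allele frequency (allele-based test).
collapse_genotypes <- function(freqs, model) {
  cl <- function(v) switch(model,
    dominant = v[2] + v[3],
    recessive = v[3],
    additive = ,
    multiplicative = v[2] / 2 + v[3]
  )
  list(case = cl(freqs$case), control = cl(freqs$control))
}

#' Power of a case-control association test
#'
#' Analytic (normal-approximation) or Monte-Carlo power of the two-proportion
#' z-test comparing carrier frequencies between cases and controls, after
#' collapsing genotypes according to the inheritance model (for the dominant
#' model, carriers of one or two risk alleles versus non-carriers; additive
#' and multiplicative models compare allele frequencies over 2n alleles).
#'
#' The analytic form uses the pooled standard error under the null and the
#' unpooled standard error under the alternative; at gamma = 1 it equals
#' alpha exactly. The Monte-Carlo mode draws binomial carrier counts and
#' applies the same z-test, giving an internal consistency check.
#'
#' @param prevalence,risk_allele_freq,grr,model As in
#'   [penetrances_from_model()]. An odds ratio can be supplied as `grr` via
#'   [grr_from_or()].
#' @param n_cases,n_controls Group sizes.
#' @param alpha Significance level (default 0.05).
#' @param sides 2 (default) or 1.
#' @param method `"analytic"` (default) or `"simulate"`.
#' @param n_sims Monte-Carlo replicates when simulating (default 10000).
#' @param seed Optional seed for the Monte-Carlo mode.
#' @return Power as a fraction in (0, 1).
#' @examples
#' association_power(0.007, 0.1, 5, "dominant", n_cases = 94, n_controls = 91)
#' @export
association_power <- function(prevalence, risk_allele_freq, grr,
                              model = "dominant", n_cases, n_controls,
                              alpha = 0.05, sides = 2,
                              method = c("analytic", "simulate"),
                              n_sims = 10000, seed = NULL) {
  method <- match.arg(method)
  stopifnot(alpha > 0, alpha < 1, sides %in% c(1, 2),
            n_cases >= 2, n_controls >= 2)
  pen <- penetrances_from_model(prevalence, risk_allele_freq, grr, model)
  freqs <- case_control_genotype_freqs(pen, prevalence)
  pr <- collapse_genotypes(freqs, model)
  # allele-based models test over 2n draws per subject
  mult <- if (model %in% c("additive", "multiplicative")) 2L else 1L
  n1 <- mult * n_cases
  n2 <- mult * n_controls
  z_crit <- stats::qnorm(1 - alpha / sides)

  if (method == "analytic") {
    d <- pr$case - pr$control
    pbar <- (n1 * pr$case + n2 * pr$control) / (n1 + n2)
    se0 <- sqrt(pbar * (1 - pbar) * (1 / n1 + 1 / n2))
    se1 <- sqrt(pr$case * (1 - pr$case) / n1 + pr$control * (1 - pr$control) / n2)
    if (sides == 2) {
      return(stats::pnorm((d - z_crit * se0) / se1) +
               stats::pnorm((-d - z_crit * se0) / se1))
    }
    return(stats::pnorm((d - z_crit * se0) / se1))
  }

  run <- function() {
    x1 <- stats::rbinom(n_sims, n1, pr$case)
    x2 <- stats::rbinom(n_sims, n2, pr$control)
    p1 <- x1 / n1
    p2 <- x2 / n2
    pb <- (x1 + x2) / (n1 + n2)
    se <- sqrt(pb * (1 - pb) * (1 / n1 + 1 / n2))
    z <- ifelse(se > 0, (p1 - p2) / se, 0)
    if (sides == 2) mean(abs(z) > z_crit) else mean(z > z_crit)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
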