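#' Prior inclusion probability schedule
#'
#' Returns the prior probability that a SNP effect comes from the
#' large-variance mixture component, as a function of the marker-density
#' exponent t (the panel holds `M = 250 * 2^t` SNPs):
#' `pld = 5.5 * 0.7^t * 15 / M`. Under this schedule the expected number of
#' important SNPs per causative locus, `pld * M / 15 = 5.5 * 0.7^t`,
#' approaches 1 as the panel approaches the full sequence (t = 4.8).
#'
#' @param t Density exponent (> 0); may be a vector.
#' @return Prior inclusion probability (same length as `t`).
#' @export
pld_schedule <- function(t) {
  stopifnot(all(t > 0))
  5.5 * 0.7^t * 15 / (250 * 2^t)
}

#' Marker density for a schedule exponent
#' @param t Density exponent.
#' @return Panel size `M = 250 * 2^t`.
#' @export
density_for_exponent <- function(t) 250 * 2^t

#' Calibrate the mixture-prior scales
#'
#' Chooses the scale of the folded-t additive prior (and, for BayesD, the
#' mean and SD of the prior dominance-coefficient distribution) so that the
#' prior-expected genome-wide additive variance, dominance variance and
#' inbreeding depression match the variance components passed in as known
#' inputs.
#'
#' Moment matching: with per-SNP heterozygosity `H_j = 2 p_j q_j`,
#' `s_a^2 = v_a / (df/(df-2) * (pld + (1-pld) eps^2) * sum(H_j))`;
#' `mu_h = inb_dep / (sum(H_j) * (pld + (1-pld) eps) * E|a*|)` with `E|a*|`
#' the folded-t mean at scale `s_a`; and `sigma_h^2` solves
#' `sum(H_j^2) * (mu_h^2 + sigma_h^2) * E[a^2] = v_d` with `E[a^2]` the
#' mixture second moment. When that moment system is ill-conditioned
#' (non-positive `sigma_h^2`), the dominance-coefficient prior falls back to
#' (0.2, 0.3) with a warning.
#'
#' @param v_a Input additive variance (> 0).
#' @param v_d Input dominance variance (BayesD; default 0).
#' @param inb_dep Input expected inbreeding depression (BayesD; default 0).
#' @param freqs Allele frequencies of the panel SNPs.
#' @param pld Prior inclusion probability, e.g. from [pld_schedule()].
#' @param epsilon Scaling factor of the small mixture component (default
#'   0.01); it scales the *effects*, so the small-component variance is
#'   `epsilon^2` times the large one.
#' @param df_t Degrees of freedom of the additive t prior (default 2.5;
#'   must exceed 2 so the prior variance is finite).
#' @param model `"bayesc"` or `"bayesd"`.
#' @return An object of class `prior_spec`.
#' @export
calibrate_priors <- function(v_a, v_d = 0, inb_dep = 0, freqs, pld,
                             epsilon = 0.01, df_t = 2.5,
                             model = c("bayesc", "bayesd")) {
  model <- match.arg(model)
  if (v_a <= 0) stop("`v_a` must be positive")
  if (df_t <= 2) stop("`df_t` must exceed 2")
  if (pld <= 0 || pld > 1) stop("`pld` must lie in (0, 1]")
  H <- 2 * freqs * (1 - freqs)
  sum_h <- sum(H)
  if (sum_h <= 0) stop("panel is monomorphic")
  mix2 <- pld + (1 - pld) * epsilon^2      # mixture factor on second moments
  mix1 <- pld + (1 - pld) * epsilon        # mixture factor on first moments
  tvar <- df_t / (df_t - 2)
  s2a <- v_a / (tvar * mix2 * sum_h)
  mu_h <- 0
  sigma_h <- 0
  if (model == "bayesd" && (v_d > 0 || inb_dep != 0)) {
    # folded-t mean at scale sqrt(s2a):
    # E|a*| = s * 2 sqrt(df/pi) Gamma((df+1)/2) / ((df-1) Gamma(df/2))
    e_abs <- sqrt(s2a) * 2 * sqrt(df_t / pi) *
      exp(lgamma((df_t + 1) / 2) - lgamma(df_t / 2)) / (df_t - 1)
    e_a2 <- mix2 * s2a * tvar
    mu_h <- inb_dep / (sum_h * mix1 * e_abs)
    sig2 <- v_d / (sum(H^2) * e_a2) - mu_h^2
    if (!is.finite(sig2) || sig2 <= 0) {
      warning("dominance moment system ill-conditioned; falling back to ",
              "dominance-coefficient prior (0.2, 0.3)")
      mu_h <- 0.2
      sigma_h <- 0.3
    } else {
      sigma_h <- sqrt(sig2)
    }
  }
  structure(list(epsilon = epsilon, df_t = df_t, pld = pld,
                 s_a = sqrt(s2a), mu_h = mu_h, sigma_h = sigma_h,
                 model = model),
            class = "prior_spec")
}

#' @export
print.prior_spec <- function(x, ...) {
  cat(sprintf(
    "%s prior: pld = %.4g, eps = %.3g, df = %.2f, s_a = %.4g",
    toupper(x$model), x$pld, x$epsilon, x$df_t, x$s_a))
  if (x$model == "bayesd") {
    cat(sprintf(", h-prior N(%.3g, %.3g^2)", x$mu_h, x$sigma_h))
  }
  cat("\n")
  invisible(x)
}

#' MCMC run configuration
#'
#' @param n_cycles Total Gibbs cycles (default 20000).
#' @param burn_in Discarded initial cycles (default 10000).
#' @param thin Storage interval; every `thin`-th post-burn-in sample is
#'   stored (default 100, giving 100 stored samples at the defaults).
#' @param seed Optional RNG seed for the chain.
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_cycles = 20000L, burn_in = 10000L, thin = 100L,
                        seed = NULL) {
  stopifnot(burn_in < n_cycles, thin >= 1)
  structure(list(n_cycles = as.integer(n_cycles),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 seed = seed),
            class = "mcmc_config")
}

run_mixture_model <- function(y, X, W, v_e, prior, mcmc, dominance,
                              likelihood_on = TRUE) {
  stopifnot(inherits(prior, "prior_spec"), inherits(mcmc, "mcmc_config"))
  if (!is.matrix(X)) X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (likelihood_on) {
    if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)")
    if (any(!is.finite(y))) stop("phenotypes must be finite")
    if (v_e <= 0) stop("`v_e` must be positive")
  } else {
    y <- numeric(nrow(X))
  }
  if (dominance) {
    if (is.null(W)) W <- matrix(as.double(X == 1), nrow(X), ncol(X))
    if (!is.matrix(W)) W <- as.matrix(W)
    storage.mode(W) <- "double"
  } else {
    W <- matrix(0, 0, 0)
  }
  if (!is.null(mcmc$seed)) set.seed(mcmc$seed)
  res <- mcmc_mixture_cpp(as.double(y), X, W, v_e, prior$pld,
                          prior$epsilon, prior$df_t, prior$s_a^2,
                          prior$mu_h, prior$sigma_h, mcmc$n_cycles,
                          mcmc$burn_in, mcmc$thin, dominance,
                          likelihood_on)
  structure(list(mu_s = res$mu, a_s = res$a,
                 d_s = if (dominance) res$d else NULL,
                 gamma_s = res$gamma,
                 model = if (dominance) "bayesd" else "bayesc",
                 prior = prior, mcmc = mcmc),
            class = "posterior_samples")
}

#' Fit the BayesC model
#'
#' Additive-only mixture model `y = 1 mu + X a + e` fitted by single-site
#' Gibbs sampling with the folded-t / indicator mixture prior. The residual
#' variance is a fixed input, not sampled.
#'
#' @param y Phenotype vector.
#' @param X 0/1/2 genotype dosage matrix (individuals by SNPs).
#' @param v_e Residual variance (fixed input).
#' @param prior A `prior_spec` from [calibrate_priors()].
#' @param mcmc An [mcmc_config()].
#' @param likelihood_on Internal switch; `FALSE` samples from the prior
#'   (used for sampler-correctness checks).
#' @return An object of class `posterior_samples` with stored draws `mu_s`,
#'   `a_s` (samples by SNPs) and `gamma_s`.
#' @export
run_bayesc <- function(y, X, v_e, prior, mcmc = mcmc_config(),
                       likelihood_on = TRUE) {
  run_mixture_model(y, X, NULL, v_e, prior, mcmc, dominance = FALSE,
                    likelihood_on = likelihood_on)
}

#' Fit the BayesD model
#'
#' Additive-plus-dominance mixture model `y = 1 mu + X a + W d + e`, where
#' `W` indicates heterozygotes. The dominance effect is a priori normal
#' conditional on the additive effect, `d | a ~ N(mu_h |a|, sigma_h^2 a^2)`,
#' making the absolute additive effect and the dominance coefficient
#' independent. The additive/indicator pair is updated by an independence
#' Metropolis-Hastings step whose proposal is the exact BayesC full
#' conditional, accepted with the dominance-prior density ratio; the
#' dominance effect has a conjugate normal full conditional.
#'
#' @inheritParams run_bayesc
#' @param W Optional heterozygote indicator matrix; derived from `X` when
#'   omitted.
#' @return A `posterior_samples` with an additional dominance block `d_s`.
#' @export
run_bayesd <- function(y, X, v_e, prior, mcmc = mcmc_config(), W = NULL,
                       likelihood_on = TRUE) {
  run_mixture_model(y, X, W, v_e, prior, mcmc, dominance = TRUE,
                    likelihood_on = likelihood_on)
}

#' @export
print.posterior_samples <- function(x, ...) {
  cat(sprintf("%s posterior: %d stored samples x %d SNPs\n",
              toupper(x$model), nrow(x$a_s), ncol(x$a_s)))
  cat(sprintf("  mean inclusion rate %.4g (prior pld %.4g)\n",
              mean(x$gamma_s), x$prior$pld))
  invisible(x)
}
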