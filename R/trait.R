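#' Sample causative loci
#'
#' Randomly selects `n_qtl` segregating sites with MAF above `maf_min`,
#' subject to a minimum pairwise genetic distance, by rejection sampling of
#' whole sets (sequential greedy picking would bias the positional
#' distribution).
#'
#' @param pop A `wf_population`.
#' @param n_qtl Number of causative loci (default 15).
#' @param maf_min MAF threshold for eligibility (default 0.05).
#' @param min_distance_cm Minimum pairwise genetic distance (default 2 cM).
#' @param eligible Optional site indices to sample from (e.g. the sites of
#'   the full-sequence panel); defaults to all sites passing `maf_min`.
#' @param max_tries Rejection-sampling budget (default 10000).
#' @return Integer vector of site indices, sorted by position.
#' @export
sample_qtl <- function(pop, n_qtl = 15L, maf_min = 0.05,
                       min_distance_cm = 2, eligible = NULL,
                       max_tries = 10000L) {
  stopifnot(inherits(pop, "wf_population"))
  if (is.null(eligible)) eligible <- which(maf(pop) > maf_min) else
    eligible <- eligible[maf(pop)[eligible] > maf_min]
  if (length(eligible) < n_qtl) stop("not enough eligible sites")
  if (n_qtl == 1L) return(sample(eligible, 1L))
  for (k in seq_len(max_tries)) {
    cand <- sort(sample(eligible, n_qtl))
    if (min(diff(pop$positions_cm[cand])) >= min_distance_cm) return(cand)
  }
  stop("could not satisfy the QTL spacing constraint within ", max_tries,
       " tries")
}

#' Sample joint additive and dominance effects
#'
#' Draws the dominance coefficient h ~ N(0.2, 0.3^2), the additive effect
#' a | h ~ N(0, exp(3h)) (variance exp(3h), so loci with larger dominance
#' coefficients tend to have larger additive effects) and sets the
#' dominance effect d = h * |a|. Overdominance (h > 1) is a rare event
#' under these defaults.
#'
#' @param n Number of loci.
#' @param mean_h,sd_h Mean and SD of the dominance-coefficient
#'   distribution (defaults 0.2 and 0.3).
#' @param var_log_slope Slope c in Var(a | h) = exp(c h) (default 3).
#' @return A data.frame with columns `a`, `d`, `h`.
#' @export
sample_effects <- function(n, mean_h = 0.2, sd_h = 0.3, var_log_slope = 3) {
  h <- stats::rnorm(n, mean_h, sd_h)
  a <- stats::rnorm(n, 0, sqrt(exp(var_log_slope * h)))
  data.frame(a = a, d = h * abs(a), h = h)
}

#' Build a QTL set
#'
#' Binds sampled causative sites and effects with the allele frequencies
#' observed in the final-generation sample at sampling time; these
#' frequencies are fixed here and reused for breeding values, dominance
#' deviations and the expected inbreeding depression.
#'
#' @param pop A `wf_population`.
#' @param site_ids Site indices from [sample_qtl()].
#' @param effects A data.frame from [sample_effects()] with one row per
#'   site.
#' @return An object of class `qtl_set`: data.frame with columns
#'   `site_id`, `position_cm`, `p`, `a`, `d`, `h`.
#' @export
qtl_set <- function(pop, site_ids, effects) {
  stopifnot(length(site_ids) == nrow(effects))
  out <- data.frame(site_id = site_ids,
                    position_cm = pop$positions_cm[site_ids],
                    p = pop$freqs[site_ids],
                    a = effects$a, d = effects$d, h = effects$h)
  class(out) <- c("qtl_set", "data.frame")
  out
}

#' Breeding values
#'
#' Per-individual sum over causative loci of `(x - 2p) * alpha` with the
#' substitution effect `alpha = a + (q - p) d`.
#'
#' @param genotypes 0/1/2 dosage matrix restricted to the QTL (individuals
#'   by loci).
#' @param qtl A `qtl_set`.
#' @return Numeric vector of breeding values.
#' @export
breeding_values <- function(genotypes, qtl) {
  check_qtl_geno(genotypes, qtl)
  alpha <- qtl$a + (1 - 2 * qtl$p) * qtl$d
  drop(sweep(genotypes, 2, 2 * qtl$p) %*% alpha)
}

#' Dominance deviations
#'
#' Per-individual sum over causative loci of
#' `-d x (x - 1 - 2p) - 2 p^2 d`; at a single locus this equals the
#' classical values `-2p^2 d`, `2pq d` and `-2q^2 d` for dosages 0, 1, 2.
#'
#' @inheritParams breeding_values
#' @return Numeric vector of dominance deviations.
#' @export
dominance_deviations <- function(genotypes, qtl) {
  check_qtl_geno(genotypes, qtl)
  # -d x (x - 1 - 2p) - 2 p^2 d  ==  -d x^2 + d (1 + 2p) x - 2 p^2 d
  drop(-(genotypes^2) %*% qtl$d + genotypes %*% (qtl$d * (1 + 2 * qtl$p))) -
    sum(2 * qtl$p^2 * qtl$d)
}

#' Genetic values
#'
#' Per-individual sum over causative loci of `(a + (2 - x) d) x`; at a
#' single locus this is 0, a + d and 2a for dosages 0, 1, 2.
#'
#' @inheritParams breeding_values
#' @return Numeric vector of total genotypic values.
#' @export
genetic_values <- function(genotypes, qtl) {
  check_qtl_geno(genotypes, qtl)
  # (a + (2 - x) d) x  ==  (a + 2d) x - d x^2
  drop(genotypes %*% (qtl$a + 2 * qtl$d) - (genotypes^2) %*% qtl$d)
}

check_qtl_geno <- function(genotypes, qtl) {
  if (!is.matrix(genotypes) || ncol(genotypes) != nrow(qtl)) {
    stop("`genotypes` must be a matrix with one column per QTL")
  }
  invisible(TRUE)
}

#' Finalize a trait realization
#'
#' Computes breeding values, dominance deviations and genetic values at the
#' QTL, takes the *empirical* variances over the sampled individuals as the
#' additive and dominance variance components, scales the residual variance
#' to the target narrow-sense heritability
#' (`v_e = v_a / h2 - v_a - v_d`), and draws phenotypes
#' `y = gv + N(0, v_e)`. The expected inbreeding depression is
#' `sum(2 p q d)` over the QTL.
#'
#' @param pop A `wf_population`.
#' @param qtl A `qtl_set`.
#' @param h2 Target narrow-sense heritability (default 0.3).
#' @return An object of class `trait_realization`: list with `bv`, `dv`,
#'   `gv`, `y`, `v_a`, `v_d`, `v_e`, `h2`, `inb_dep`, `qtl`.
#'   Returns `NULL` invisibly if `v_e <= 0` (caller should resample the
#'   effects; see [simulate_trait()]).
#' @export
finalize_trait <- function(pop, qtl, h2 = 0.3) {
  X <- genotype_matrix(pop, qtl$site_id)
  bv <- breeding_values(X, qtl)
  dv <- dominance_deviations(X, qtl)
  gv <- genetic_values(X, qtl)
  v_a <- stats::var(bv)
  v_d <- stats::var(dv)
  if (v_a <= 0) return(invisible(NULL))
  v_e <- v_a / h2 - v_a - v_d
  if (v_e <= 0) return(invisible(NULL))
  y <- gv + stats::rnorm(length(gv), 0, sqrt(v_e))
  structure(list(bv = bv, dv = dv, gv = gv, y = y,
                 v_a = v_a, v_d = v_d, v_e = v_e, h2 = h2,
                 inb_dep = sum(2 * qtl$p * (1 - qtl$p) * qtl$d),
                 qtl = qtl),
            class = "trait_realization")
}

#' Simulate a quantitative trait on a population
#'
#' Orchestrates [sample_qtl()], [sample_effects()] and [finalize_trait()],
#' resampling the effects (with a fresh set of causative sites) whenever
#' the implied residual variance is non-positive, i.e. when the sampled
#' dominance variance is too large relative to the additive variance for
#' the target heritability.
#'
#' @inheritParams sample_qtl
#' @inheritParams finalize_trait
#' @param seed Optional RNG seed.
#' @param max_resample Resampling budget for degenerate traits (default
#'   100).
#' @return A `trait_realization`.
#' @export
simulate_trait <- function(pop, n_qtl = 15L, h2 = 0.3, maf_min = 0.05,
                           min_distance_cm = 2, eligible = NULL,
                           seed = NULL, max_resample = 100L) {
  if (!is.null(seed)) set.seed(seed)
  for (k in seq_len(max_resample)) {
    sites <- sample_qtl(pop, n_qtl, maf_min, min_distance_cm, eligible)
    qtl <- qtl_set(pop, sites, sample_effects(n_qtl))
    tr <- finalize_trait(pop, qtl, h2)
    if (!is.null(tr)) return(tr)
  }
  stop("failed to obtain a trait with positive residual variance")
}

#' @export
print.trait_realization <- function(x, ...) {
  vp <- x$v_a / x$h2
  cat(sprintf(
    "Trait: %d QTL; v_a = %.3g, v_d = %.3g, v_e = %.3g (h2 = %.2f)\n",
    nrow(x$qtl), x$v_a, x$v_d, x$v_e, x$h2))
  cat(sprintf("  v_d / v_p = %.3f; inbreeding depression = %.3f sd_p\n",
              x$v_d / vp, x$inb_dep / sqrt(vp)))
  invisible(x)
}
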