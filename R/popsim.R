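#' Demography configuration for the forward simulator
#'
#' Describes the Wright-Fisher demography used throughout the package: a
#' single one-Morgan chromosome evolving for 1051 non-overlapping
#' generations with an effective size of 600 for the first 650 generations,
#' an accelerating power-law decline to 100 by generation 1000, a
#' constant size of 100 thereafter, and a final genotyped sample of 1500
#' offspring bred from the last generation. This mimics the effective-size
#' history and linkage-disequilibrium pattern of dairy cattle populations.
#'
#' @param n_generations Number of bred generations (default 1051).
#' @param ne_initial Effective size of the initial epoch (default 600).
#' @param ne_final Effective size after the decline (default 100).
#' @param decline_start Last generation of the initial epoch (default 650).
#' @param decline_end First generation at `ne_final` (default 1000).
#' @param final_sample_n Individuals genotyped in the expanded final
#'   generation (default 1500).
#' @param mutation_rate Per-bp, per-meiosis mutation rate (default 1e-8).
#' @param genetic_length Chromosome length in Morgan (default 1).
#' @param physical_length Chromosome length in bp. The default 1e8 encodes
#'   the cattle-scale equivalence 1 cM = 1 Mb and gives an expected one new
#'   mutation per gamete.
#' @param ne_schedule Optional explicit per-generation size vector
#'   overriding the parametric schedule; must have length `n_generations`.
#' @param burn_in_generations Extra generations at `ne_initial` run
#'   *before* the scheduled generations so that the founders of
#'   generation 1 carry standing variation at mutation-drift equilibrium
#'   (default `8 * ne_initial`; set 0 for monomorphic founders).
#' @param decline_exponent Shape q of the decline
#'   `Ne(f) = ne_initial - (ne_initial - ne_final) f^q` for the fraction f
#'   of the way from `decline_start` to `decline_end` (default 6, which
#'   concentrates the decline in the last generations).
#'
#' @return An object of class `demography_config`.
#' @export
demography_config <- function(n_generations = 1051L, ne_initial = 600L,
                              ne_final = 100L, decline_start = 650L,
                              decline_end = 1000L, final_sample_n = 1500L,
                              mutation_rate = 1e-8, genetic_length = 1,
                              physical_length = 1e8, ne_schedule = NULL,
                              burn_in_generations = NULL,
                              decline_exponent = 6) {
  if (is.null(physical_length) || !is.finite(physical_length) ||
      physical_length <= 0) {
    stop("`physical_length` must be a positive number of base pairs ",
         "(no default is silently applied when unset)")
  }
  if (genetic_length <= 0) stop("`genetic_length` must be positive")
  if (!is.null(ne_schedule)) {
    if (length(ne_schedule) != n_generations) {
      stop("`ne_schedule` must have length `n_generations`")
    }
    if (any(ne_schedule < 2)) stop("effective sizes must be >= 2")
  }
  structure(list(
    n_generations = as.integer(n_generations),
    ne_initial = as.integer(ne_initial), ne_final = as.integer(ne_final),
    decline_start = as.integer(decline_start),
    decline_end = as.integer(decline_end),
    final_sample_n = as.integer(final_sample_n),
    mutation_rate = mutation_rate, genetic_length = genetic_length,
    physical_length = physical_length, ne_schedule = ne_schedule,
    burn_in_generations = as.integer(burn_in_generations %||%
                                       (8L * as.integer(ne_initial))),
    decline_exponent = decline_exponent
  ), class = "demography_config")
}

#' Per-generation effective-size schedule
#'
#' Expands a [demography_config()] into the vector of breeding-population
#' sizes, one per generation. The decline between `decline_start` and
#' `decline_end` follows the power law
#' `Ne(f) = ne_initial - (ne_initial - ne_final) f^q`, whose absolute rate
#' of decline grows toward `decline_end`: the drop is concentrated in the
#' last generations, which retains diversity until shortly before the
#' final bottleneck.
#'
#' @param config A [demography_config()].
#' @return Integer vector of length `config$n_generations`.
#' @export
build_ne_schedule <- function(config) {
  stopifnot(inherits(config, "demography_config"))
  if (!is.null(config$ne_schedule)) {
    return(as.integer(round(config$ne_schedule)))
  }
  ng <- config$n_generations
  g <- seq_len(ng)
  ne <- numeric(ng)
  ne[g <= config$decline_start] <- config$ne_initial
  decl <- g > config$decline_start & g < config$decline_end
  frac <- (g[decl] - config$decline_start) /
    (config$decline_end - config$decline_start)
  ne[decl] <- config$ne_initial -
    (config$ne_initial - config$ne_final) * frac^config$decline_exponent
  ne[g >= config$decline_end] <- config$ne_final
  ne <- as.integer(round(ne))
  if (any(ne < 2)) stop("schedule produced effective sizes < 2")
  ne
}

#' Simulate a Wright-Fisher population
#'
#' Runs the forward simulation: random-mating diploid reproduction with
#' Poisson crossovers (expectation `genetic_length` per meiosis, uniform
#' positions) and infinite-sites Poisson mutation (expectation
#' `mutation_rate * physical_length` new mutations per gamete, uniform
#' positions on a continuous map). After the last bred generation the
#' breeding population is expanded to `final_sample_n` offspring, which
#' form the genotyped sample. Sites monomorphic in that sample are dropped,
#' which never changes any retained genotype.
#'
#' @param config A [demography_config()].
#' @param seed Optional integer seed; all stochastic draws of the
#'   simulation flow from R's RNG, so a fixed seed makes the population
#'   bit-reproducible.
#' @param init_haplotypes Optional list of numeric vectors (mutation
#'   positions in Morgan) used as founder haplotypes; its length fixes the
#'   number of founder haplotypes and must be twice the first schedule
#'   entry. Mainly used to continue evolving an existing sample (see
#'   [haplotype_positions()]). When supplied, the equilibrium burn-in is
#'   skipped.
#' @param prune_every Interval (generations) at which mutations fixed in
#'   the breeding population are pruned from the haplotype lists; pruned
#'   and finally-fixed positions are reported in `fixed_positions_cm`.
#'
#' @return An object of class `wf_population`: a list with elements
#'   `haplotypes` (raw 0/1 matrix, 2N rows by S sites), `positions_cm`,
#'   `positions_bp`, `freqs` (derived-allele frequency per site) and
#'   `n_individuals`.
#' @export
simulate_population <- function(config, seed = NULL, init_haplotypes = NULL,
                                prune_every = 25L) {
  stopifnot(inherits(config, "demography_config"))
  if (!is.null(seed)) set.seed(seed)
  ne <- build_ne_schedule(config)
  if (is.null(init_haplotypes) && config$burn_in_generations > 0) {
    ne <- c(rep(ne[1], config$burn_in_generations), ne)
  }
  raw <- simulate_population_cpp(ne, config$final_sample_n,
                                 config$mutation_rate,
                                 config$physical_length,
                                 config$genetic_length,
                                 init_haplotypes, as.integer(prune_every))
  pos_m <- raw$positions_morgan
  n2 <- nrow(raw$haplotypes)
  bp <- floor(pos_m / config$genetic_length * config$physical_length) + 1
  # physical positions must stay strictly increasing even after rounding
  if (length(bp) > 1) {
    for (k in which(diff(bp) <= 0) + 1) bp[k] <- bp[k - 1] + 1
  }
  structure(list(
    haplotypes = raw$haplotypes,
    positions_morgan = pos_m,
    positions_cm = pos_m * 100,
    positions_bp = bp,
    freqs = raw$counts / n2,
    fixed_positions_morgan = raw$fixed_positions_morgan,
    fixed_positions_cm = raw$fixed_positions_morgan * 100,
    n_individuals = n2 / 2L,
    config = config
  ), class = "wf_population")
}

#' @export
print.wf_population <- function(x, ...) {
  cat("Wright-Fisher population:", x$n_individuals, "individuals,",
      length(x$freqs), "segregating sites\n")
  cat(sprintf("  MAF > 0.01: %d sites; MAF > 0.03: %d sites\n",
              sum(pmin(x$freqs, 1 - x$freqs) > 0.01),
              sum(pmin(x$freqs, 1 - x$freqs) > 0.03)))
  invisible(x)
}

#' Genotype dosage matrix
#'
#' Extracts 0/1/2 derived-allele dosages for selected sites.
#'
#' @param pop A `wf_population`.
#' @param sites Integer site indices (default: all sites).
#' @return Integer matrix, individuals by sites.
#' @export
genotype_matrix <- function(pop, sites = NULL) {
  stopifnot(inherits(pop, "wf_population"))
  if (is.null(sites)) sites <- seq_along(pop$freqs)
  genotypes_from_haps(pop$haplotypes, as.integer(sites))
}

#' Minor allele frequency per site
#' @param pop A `wf_population`.
#' @return Numeric vector of folded allele frequencies.
#' @export
maf <- function(pop) pmin(pop$freqs, 1 - pop$freqs)

#' Select an equidistant marker panel
#'
#' Thins the segregating sites to a panel of `target_count` SNPs with
#' MAF >= `maf_min`, approximately equidistant on the genetic map: a grid of
#' `target_count` points is placed uniformly over the map and each grid
#' point greedily takes the nearest eligible SNP not already used, ties
#' resolved toward the lower position.
#'
#' @param pop A `wf_population`.
#' @param target_count Number of SNPs in the panel.
#' @param maf_min MAF threshold for eligibility (default 0.03).
#' @param causal_ids Site indices of causal mutations.
#' @param keep_causals If `FALSE` (default) causal sites are excluded from
#'   the panel; the full-sequence panel keeps them.
#' @param density_label Optional label such as "2k" recorded on the panel.
#'
#' @return An object of class `marker_panel` with elements `snp_indices`,
#'   `positions_cm`, `freqs`, `maf_min`, `includes_causals`,
#'   `density_label`.
#' @export
select_marker_panel <- function(pop, target_count, maf_min = 0.03,
                                causal_ids = NULL, keep_causals = FALSE,
                                density_label = NULL) {
  stopifnot(inherits(pop, "wf_population"))
  eligible <- which(maf(pop) >= maf_min)
  if (!keep_causals && length(causal_ids)) {
    eligible <- setdiff(eligible, causal_ids)
  }
  if (length(eligible) < target_count) {
    stop("only ", length(eligible), " eligible sites for a panel of ",
         target_count)
  }
  pos <- pop$positions_cm[eligible]
  span <- range(pop$positions_cm)
  grid <- seq(span[1], span[2], length.out = target_count)
  used <- logical(length(eligible))
  picked <- integer(target_count)
  ord <- order(pos)
  pos_o <- pos[ord]
  for (k in seq_len(target_count)) {
    dist <- abs(pos_o - grid[k])
    dist[used] <- Inf
    # ties toward the lower position: which.min returns the first minimum
    i <- which.min(dist)
    used[i] <- TRUE
    picked[k] <- eligible[ord[i]]
  }
  picked <- sort(picked)
  structure(list(
    snp_indices = picked,
    positions_cm = pop$positions_cm[picked],
    freqs = pop$freqs[picked],
    maf_min = maf_min,
    includes_causals = keep_causals,
    density_label = density_label %||% paste0(target_count)
  ), class = "marker_panel")
}

#' Full-sequence marker panel
#'
#' Returns all sites with MAF above `maf_min` (default 0.01), unfiltered for
#' spacing and including the causal mutations; this emulates the situation
#' where the full sequence is known.
#'
#' @param pop A `wf_population`.
#' @param maf_min MAF threshold (default 0.01).
#' @param density_label Label recorded on the panel (default "7k").
#' @return A `marker_panel`.
#' @export
full_sequence_panel <- function(pop, maf_min = 0.01, density_label = "7k") {
  idx <- which(maf(pop) > maf_min)
  if (!length(idx)) stop("no site exceeds the MAF threshold")
  structure(list(
    snp_indices = idx,
    positions_cm = pop$positions_cm[idx],
    freqs = pop$freqs[idx],
    maf_min = maf_min,
    includes_causals = TRUE,
    density_label = density_label
  ), class = "marker_panel")
}

#' @export
print.marker_panel <- function(x, ...) {
  cat("Marker panel:", length(x$snp_indices), "SNPs (", x$density_label,
      "), MAF >=", x$maf_min,
      if (x$includes_causals) "(causals kept)\n" else "(causals excluded)\n")
  invisible(x)
}

#' Haplotypes as mutation-position lists
#'
#' Converts a population's haplotype matrix back into the list-of-positions
#' representation accepted by `simulate_population(init_haplotypes = )`,
#' allowing a sample to be evolved further.
#'
#' @param pop A `wf_population`.
#' @return List with one numeric vector (Morgan positions) per haplotype.
#' @export
haplotype_positions <- function(pop) {
  stopifnot(inherits(pop, "wf_population"))
  pos_m <- pop$positions_morgan
  lapply(seq_len(nrow(pop$haplotypes)), function(i) {
    pos_m[pop$haplotypes[i, ] == as.raw(1)]
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
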