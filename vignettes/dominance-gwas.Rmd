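---
title: "Mapping quantitative-trait loci with additive and dominance mixture models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping quantitative-trait loci with additive and dominance mixture models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`dombayes` is an in-silico workbench for window-based Bayesian genome-wide
association analysis of quantitative traits with dominance. It has four
layers, each usable on its own: a forward Wright–Fisher simulator of a
cattle-like population, a trait generator with a realistic joint
distribution of additive effects and dominance coefficients, Gibbs samplers
for the BayesC (additive) and BayesD (additive + dominance) mixture models,
and sliding-window posterior inference with power/precision evaluation.
This vignette explains the science behind each layer, the tunable
parameters, and the design decisions taken where more than one reasonable
implementation exists.

## The population simulator

A diploid, random-mating Wright–Fisher population evolves on a single
chromosome of 1 Morgan (100 cM) and, by default, 100 Mb — the
cattle-scale equivalence of 1 cM per Mb, under which the per-gamete
mutation rate is `1e-8 * 1e8 = 1` new mutation per meiosis. Meioses draw
a Poisson(1) number of crossovers at uniform genetic positions; mutation
follows the infinite-sites model on a continuous coordinate, so a
mutation's position is also its identity. Haplotypes are stored as sorted
position lists in compiled code, which keeps a full run (about 10,000
bred generations including burn-in) in the tens of seconds.

The demographic history is: effective size Ne = 600 for generations
1–650, a decline to Ne = 100 completed at generation 1000, constant
Ne = 100 until generation 1051, and an expansion of the last breeding
population into the genotyped sample of N = 1500 offspring. Two points
were genuinely open and are resolved as follows.

* **Shape of the decline.** The decline is implemented as the power law
  `Ne(f) = 600 - 500 f^q` with `q = 6` (`decline_exponent`), where `f` is
  the fraction of the way through the decline epoch. The absolute rate of
  decline then *grows* toward the end — the drop is concentrated in the
  last generations, which is what creates the long-range linkage
  disequilibrium typical of modern cattle while retaining sequence
  diversity until shortly before the final bottleneck. A log-linear
  (exponential-in-Ne) interpolation was rejected because its absolute
  decline is fastest at the *start* of the epoch, the opposite pattern. A
  user-supplied `ne_schedule` overrides the parametric form.
* **Founder variation.** 1051 generations is far less than the ~4·Ne
  coalescent time scale at Ne = 600, so founders without variation would
  leave the final sample at roughly 40% of equilibrium diversity. The
  simulator therefore prepends a burn-in of `8 * ne_initial` generations
  at Ne = 600 (`burn_in_generations`), bringing the founders of
  generation 1 to mutation–drift equilibrium. With these defaults the
  final 1500 individuals segregate on the order of 6,000–7,000 SNPs with
  MAF > 0.01 (the acceptance suite measures ~6,400 on average); the
  demography itself caps this number — even with no decline before
  generation 1000 the final 50 generations at Ne = 100 prune low-frequency
  variation — so we treat "about 7k" as the calibration point of the
  1 cM = 1 Mb choice rather than a tunable.

Marker panels of 0.5k, 1k and 2k SNPs are thinned from the segregating
sites with MAF ≥ 0.03 by placing that many grid points uniformly on the
genetic map and greedily assigning each the nearest unused eligible SNP
(ties to the lower position). Causal sites are excluded from thinned
panels. The "7k" panel is simply every site with MAF > 0.01, causals
included — it emulates full-sequence data.

## The trait model

Each trait has `Q = 15` causative loci drawn from the sequence panel with
MAF > 0.05 and at least 2 cM apart (whole-set rejection sampling, which is
positionally unbiased). Effects are drawn hierarchically:

* dominance coefficient `h ~ N(0.2, 0.3^2)`,
* additive effect `a | h ~ N(0, exp(3h))` (the second argument is the
  *variance*),
* dominance effect `d = h |a|`.

Large additive effects therefore co-occur with larger, more positive
dominance coefficients, while overdominance (`h > 1`) is a rare event
(normal tail probability ≈ 0.0038). With the derived-allele frequency `p`
(fixed at sampling time and reused everywhere), the per-individual
quantities follow the classical decomposition: breeding values use the
substitution effect `alpha = a + (q - p) d`, dominance deviations are the
quadratic remainder (`-2p²d`, `2pqd`, `-2q²d` at dosages 0/1/2), and the
genotypic value is `(a + (2 - x) d) x`. Variance components are the
*empirical* variances of those vectors over the 1500 sampled individuals
— not Hardy–Weinberg closed forms — so linkage disequilibrium between
causative loci and departures from Hardy–Weinberg proportions contribute,
as they would in a real population. The residual variance is set to
`v_e = v_a / h² - v_a - v_d` for a narrow-sense heritability of 0.3; if a
draw makes `v_e ≤ 0` (a very dominant architecture) the whole trait is
resampled.

Two consequences of this generator are worth stating plainly, because
they are properties of the stated effect distribution rather than
implementation choices. First, the dominance variance is a modest share
of the phenotypic variance: the `a²`-weighted mean of `h²` under the
hierarchy above is ≈ 0.31, which translates into a mean `v_d / v_p`
around 0.03–0.05 (our acceptance script computes ≈ 0.035). Second, the
dominance is strongly directional (`E[h] = 0.2 > 0`), so the expected
inbreeding depression `Σ 2 p q d` is a sizeable fraction of the
phenotypic standard deviation — about 0.3 — essentially independent of
the effect scale, because both numerator and denominator scale together.
Quoted literature values nearer 0.02 are not reachable from this
hierarchy under any rescaling; we report what the generator actually
produces.

## The Bayesian models

Both models regress phenotypes on all panel SNPs at once:
`y = 1μ + X ã + W d̃ + e`, with `X` the 0/1/2 gene content, `W` the
heterozygote indicator, and `e ~ N(0, v_e I)`. The residual variance and
the genetic variance components are *inputs* (known from the simulation,
or estimated externally for real data); they are not sampled.

Each SNP's effect is a two-component scale mixture: with prior
probability `pLD` the effect comes from the "large" distribution `F`, and
otherwise from `ε F` with `ε = 0.01` — the whole effect vector is scaled,
so small-component variances carry `ε²`. The additive marginal of `F` is
a t distribution with 2.5 degrees of freedom (heavy tails sharpen true
signals while shrinking spurious ones), implemented as a normal scale
mixture with a per-SNP latent variance multiplier. BayesD adds the
dominance effect through the conditional
`d̃ | ã ~ N(mu_h |ã|, sigma_h² ã²)`: the dominance *coefficient*
`d̃/|ã|` is a priori independent of the additive effect, so dominance
effects much larger than the additive effect are improbable but
overdominance remains possible. Because both components scale jointly,
this conditional is identical under the two mixture components — a
convenient and exact simplification used by the sampler. A
frequency-dependent prior on the sign of the additive effect makes sense
only under selection and is not used here, matching the neutral
simulation.

`pLD` follows the density schedule `pLD = 5.5 × 0.7^t × 15 / M` with
`M = 250 × 2^t`, so the expected number of "important" SNPs per causative
locus, `5.5 × 0.7^t`, falls to 1 as the panel approaches full sequence.

**Calibration.** The free scales of the prior are set by moment matching
so that the prior-expected genome-wide additive variance, dominance
variance and inbreeding depression equal the input values:
`s_a² = v_a / [df/(df-2) · (pLD + (1-pLD)ε²) · Σ H_j]` with
`H_j = 2 p_j q_j`; `mu_h` from the inbreeding-depression equation using
the folded-t mean; and `sigma_h²` from the dominance-variance equation
using the mixture second moment. If that system turns out
ill-conditioned (`sigma_h² ≤ 0`) the dominance-coefficient prior falls
back to (0.2, 0.3) with a warning.

**The sampler.** One Gibbs cycle updates μ (normal full conditional),
then every SNP in fixed ascending order (reproducibility over randomized
sweeps): the latent t-scale (inverse-gamma full conditional), then the
pair (γ, ã). In BayesC that pair is drawn *exactly* from its joint full
conditional, with ã integrated out per component. In BayesD the same
draw serves as an independence Metropolis–Hastings proposal and is
accepted with the ratio of dominance-prior densities
`p(d̃ | ã') / p(d̃ | ã)` — the only factor the proposal omits — so the
chain leaves the exact posterior invariant; d̃ then has a conjugate
normal full conditional. Correctness is enforced by a prior-reproduction
test: with the likelihood switched off the sampler must reproduce the
analytic prior (inclusion rate, dominance-coefficient moments, folded-t
quartile) within Monte-Carlo error. Residuals are updated incrementally
through BLAS kernels; a full 20,000-cycle chain on 1500 × 2000 data takes
well under a minute. Constant genotype columns are skipped (effect
pinned at 0); the default chain is 20,000 cycles, 10,000 burn-in,
storing every 100th sample (100 stored samples).

## Window inference

For each stored sample, the genomic variance of a window `w` is
`σ̂²_gw = Σ_{j∈w} [H_j α̂_j² + H_j² d̂_j²]` with `α̂ = â + (q-p) d̂`
(for BayesC, `d̂ ≡ 0`). Its reference value is the expectation under an
equal distribution of the total genetic variance along the genome:
`E(α²) = v_a / Σ_M H_j` and `E(d²) = v_d / Σ_M H_j²`, normalizations
chosen — uniquely — so that summing the expectation over any tiling of
the panel returns exactly `v_a + v_d` (a unit test asserts the tiling
identity). The same expectation, including the dominance term, is used
for both models so their window probabilities are comparable. The WPPA
of a window is the fraction of stored samples with `q_w = σ̂²_gw /
E(σ²_gw) > 1`; the inequality is strict, so a tie counts against
association, and a window with zero expectation is reported as `NA`
rather than silently dropped.

Windows slide one SNP at a time: one window per SNP, anchored at the
SNP's position, spanning a configurable 0.25 / 0.5 / 1 cM, with half-open
membership `[start, start + size)` (half-openness prevents double
counting in tiling checks; windows near the chromosome end are truncated
at 100 cM). Decision thresholds of 0.85 / 0.95 / 0.99 on the WPPA bound
the proportion of false positives at 0.15 / 0.05 / 0.01.

## Power, L-power, precision

A causative locus counts as *detectable* when its true variance
contribution `H α² + H² d²` exceeds the mean expectation of the sliding
windows overlapping its position — loci below that line cannot push
`q_w` above 1 even in principle, and excluding them bounds power at 1.
A locus is *mapped* at a threshold when any window with WPPA above the
threshold intersects its ±1 cM flank. *Power* is mapped/detectable per
trait, averaged over traits (with the SD across traits reported);
*L-power* restricts the denominator to loci explaining more than 2.5% of
the genetic variance `v_a + v_d`. *Precision* is the union length of the
contiguous cluster of significant windows nearest the locus, so the
window size is its lower bound; when one cluster spans two loci's flanks
it is credited to both. `run_experiment()` orchestrates the full grid
(populations × traits × densities × models × window sizes × thresholds)
with per-stage seeds derived deterministically from one master seed, so
any cell is reproducible in isolation.

## Problem sizes used by the test suite

The bundled tests reproduce the study's structure at sizes chosen for a
single-CPU desk run: two replicate populations at the full demography
with five traits each for the mapping comparison (BayesC on the 2k panel;
both models on the 0.5k panel; every fit at the full 20,000-cycle
schedule), sixty traits for the architecture summaries, three populations
for the diversity check, and reduced chains (about 4,000 cycles) for
sampler unit tests on synthetic genotypes. Ordering claims (power rising
with density and window size, falling with threshold; the dominance model
leading at low density) are asserted as paired comparisons across the
same traits, which removes most between-trait variance.

## What the generator does and does not emulate

It emulates: bottleneck-shaped allele-frequency spectra, realistic LD
decay with genetic distance, family structure from the final expansion
(1500 offspring of 100 breeders), joint additive/dominance architectures
with directional dominance, and full-sequence versus thinned panels. It
does not emulate: selection (and hence selection-shaped frequency-effect
coupling), multiple chromosomes, genotyping error or missingness,
non-normal residuals, or epistasis. Passing tests therefore demonstrate
correctness of the method and its calibration under neutral, single
chromosome architectures, not performance on any particular real
dataset.

## Known limitations

* The per-SNP latent t-scale makes second-moment summaries of the
  posterior heavy-tailed; correctness tests use quantile- and
  first-moment-based checks instead of raw variances.
* The equal-distribution expectation treats the panel heterozygosity
  profile as the variance carrier; panels with extreme MAF composition
  shift the detectability line accordingly.
* The independence-MH update for (γ, ã) in BayesD can mix slowly for
  SNPs whose dominance effect is large while the additive effect is near
  zero (the acceptance ratio then strongly penalizes proposals that
  shrink |ã|); in the studied architectures the acceptance rate stays
  high.
* With `pLD = 1` the mixture degenerates to the single large component;
  this is supported for calibration checks but not meaningful for
  mapping.
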