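# dombayes

Simulation workbench for Bayesian genome-wide association analysis of
quantitative traits with **dominance**. Many complex traits carry
non-negligible dominance variance, yet standard multi-marker Bayesian GWAS
models fit additive SNP effects only. `dombayes` implements both the
additive mixture model (**BayesC**) and its dominance extension
(**BayesD**), together with everything needed to study their mapping
power and precision in silico: a forward Wright–Fisher simulator of a
cattle-like population, a quantitative-trait generator with a realistic
joint distribution of additive and dominance effects, sliding-window
posterior inference, and a power/precision evaluation layer. It is aimed
at quantitative geneticists and methods developers in animal and plant
breeding.

## The model

Phenotypes are regressed on all `M` panel SNPs simultaneously:

```
y = 1 μ + X ã + W d̃ + e,     e ~ N(0, v_e I)
```

with `X` the 0/1/2 gene content and `W` the heterozygote indicator.
Each SNP effect is a two-component scale mixture: with prior probability
`pLD` it comes from a heavy-tailed distribution `F` (folded-t with 2.5
degrees of freedom for `|ã|`), otherwise from `ε F` with `ε = 0.01`.
BayesD adds `d̃ | ã ~ N(μ_h |ã|, σ_h² ã²)`, which makes the dominance
coefficient `d̃/|ã|` independent of the additive effect. Prior scales are
calibrated by moment matching so the prior-expected genome-wide additive
variance, dominance variance and inbreeding depression equal the known
inputs. Inference of association uses the window posterior probability of
association (WPPA): for each sliding window `w` and stored MCMC sample,

```
σ̂²_gw = Σ_{j∈w} [ H_j α̂_j² + H_j² d̂_j² ],   H_j = 2 p_j q_j,
α̂_j = â_j + (q_j − p_j) d̂_j,
q_w = σ̂²_gw / E(σ²_gw),
```

and WPPA = fraction of samples with `q_w > 1`, where `E(σ²_gw)` spreads
the total genetic variance equally along the genome. WPPA thresholds of
0.85 / 0.95 / 0.99 bound the proportion of false positives at
0.15 / 0.05 / 0.01.

## Worked example

```r
library(dombayes)

# a cattle-like population: 1 Morgan, Ne 600 -> 100, 1500 genotyped
pop <- simulate_population(demography_config(), seed = 42)
pop
#> Wright-Fisher population: 1500 individuals, 9492 segregating sites
#>   MAF > 0.01: 5984 sites; MAF > 0.03: 5132 sites

# a trait with 15 causative loci, h2 = 0.3
full <- full_sequence_panel(pop)
tr <- simulate_trait(pop, eligible = full$snp_indices, seed = 7)
tr
#> Trait: 15 QTL; v_a = 8.99, v_d = 0.65, v_e = 20.3 (h2 = 0.30)
#>   v_d / v_p = 0.022; inbreeding depression = 0.291 sd_p

# fit BayesC on a 2k marker panel (causals removed)
panel <- select_marker_panel(pop, 2000, causal_ids = tr$qtl$site_id)
X <- genotype_matrix(pop, panel$snp_indices)
prior <- calibrate_priors(tr$v_a, freqs = panel$freqs,
                          pld = pld_schedule(3))
fit <- run_bayesc(tr$y, X, tr$v_e, prior, mcmc_config(seed = 1))

# sliding-window WPPA scan, 0.5-cM windows
scan <- window_scan(fit, panel$freqs, panel$positions_cm, 0.5,
                    tr$v_a, tr$v_d)
ev <- evaluate_scan(scan, tr$qtl, panel, tr$v_a, tr$v_d)
power_tables(list(ev))[, c("threshold", "power", "l_power", "precision_cm")]
#>   threshold     power   l_power precision_cm
#> 1      0.85 0.3333333 0.5000000    0.9013459
#> 2      0.95 0.2222222 0.3333333    0.7877917
#> 3      0.99 0.2222222 0.3333333    0.5676288
```

Numbers shown are actual output for these seeds. Read: at the 0.95 WPPA
level the scan mapped 22% of the detectable causative loci and 33% of the
"large" ones (those explaining > 2.5% of the genetic variance), with a
significant region of ~0.8 cM around mapped loci. `run_experiment()`
loops this pipeline over populations, traits, marker densities
(0.5k/1k/2k/full-sequence), both models, window sizes and thresholds and
returns the long-format results table; `run_bayesd()` fits the dominance
model, whose window dominance variance (`mean_vd_w`) additionally reveals
*where* dominance contributes.

A thin command-line wrapper over the same functions is installed at
`inst/cli/dombayes.R` (subcommands `simulate-pop`, `simulate-trait`,
`fit`, `wppa`, `experiment`).

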