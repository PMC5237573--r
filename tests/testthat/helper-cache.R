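# Shared fixtures, built once per test run. Populations at the study-scale
# demography are expensive (~30 s each), so they are simulated lazily and
# cached; the mapping-study fits reuse them.

the_cache <- new.env(parent = emptyenv())

cache_get <- function(key, compute) {
  if (!exists(key, envir = the_cache)) {
    assign(key, compute(), envir = the_cache)
  }
  get(key, envir = the_cache)
}

# replicate populations under the default (study) demography
study_population <- function(i) {
  cache_get(paste0("pop", i), function() {
    simulate_population(demography_config(), seed = 100L + i)
  })
}

study_full_panel <- function(i) {
  cache_get(paste0("full", i), function() {
    full_sequence_panel(study_population(i))
  })
}

# a small, fast demography for unit tests that only need a valid population
toy_population <- function() {
  cache_get("toypop", function() {
    cfg <- demography_config(n_generations = 60L,
                             ne_schedule = rep(80L, 60L),
                             final_sample_n = 200L,
                             burn_in_generations = 400L,
                             genetic_length = 0.2,
                             physical_length = 2e7)
    simulate_population(cfg, seed = 55)
  })
}

# traits for the architecture checks: 30 per population on 2 populations
architecture_traits <- function() {
  cache_get("arch_traits", function() {
    out <- list()
    for (ip in 1:2) {
      pop <- study_population(ip)
      full <- study_full_panel(ip)
      for (it in 1:30) {
        out[[length(out) + 1L]] <- simulate_trait(
          pop, eligible = full$snp_indices,
          seed = derive_seed(424242L, "arch-trait", ip * 1000L + it))
      }
    }
    out
  })
}

# The scaled-down mapping study: 2 populations x 5 traits. Per trait the
# BayesC model is fitted on the 2k panel and both models on the 0.5k panel,
# at the full MCMC schedule; every fit is scanned at the three window sizes
# and evaluated at the three WPPA thresholds.
mapping_study <- function() {
  cache_get("mapping_study", function() {
    evals <- list()
    for (ip in 1:2) {
      pop <- study_population(ip)
      full <- study_full_panel(ip)
      for (it in 1:5) {
        tr <- simulate_trait(pop, eligible = full$snp_indices,
                             seed = derive_seed(99L, "map-trait",
                                                ip * 1000L + it))
        cells <- list(list(n = 2000L, label = "2k", models = "bayesc"),
                      list(n = 500L, label = "0.5k",
                           models = c("bayesc", "bayesd")))
        for (cell in cells) {
          panel <- select_marker_panel(pop, cell$n,
                                       causal_ids = tr$qtl$site_id,
                                       density_label = cell$label)
          X <- genotype_matrix(pop, panel$snp_indices)
          pld <- pld_schedule(log2(cell$n / 250))
          for (model in cell$models) {
            prior <- calibrate_priors(tr$v_a, tr$v_d, tr$inb_dep,
                                      panel$freqs, pld, model = model)
            mc <- mcmc_config(seed = derive_seed(99L,
                                                 paste0("fit-", model),
                                                 ip * 1000L + it))
            fit <- if (model == "bayesc") {
              run_bayesc(tr$y, X, tr$v_e, prior, mc)
            } else {
              run_bayesd(tr$y, X, tr$v_e, prior, mc)
            }
            for (ws in c(0.25, 0.5, 1)) {
              scan <- window_scan(fit, panel$freqs, panel$positions_cm,
                                  ws, tr$v_a, tr$v_d)
              key <- paste(cell$label, ws, model, sep = "|")
              ev <- evaluate_scan(scan, tr$qtl, panel, tr$v_a, tr$v_d)
              evals[[key]] <- c(evals[[key]], list(ev))
            }
          }
        }
      }
    }
    evals
  })
}

# power / l-power / precision for one cell of the mapping study
cell_table <- function(evals, density, ws, model) {
  power_tables(evals[[paste(density, ws, model, sep = "|")]])
}
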