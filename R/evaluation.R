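#' Flag detectable and large causative loci
#'
#' A causative locus is *detectable* when its true variance contribution
#' `v_j = H_j alpha_j^2 + H_j^2 d_j^2` exceeds the equal-distribution
#' expectation of a window of the configured size around it (the mean of
#' `E(sigma2_gw)` over the sliding windows overlapping its position): only
#' such loci can push `q_w` above 1, so only they enter the power
#' denominator. A locus is *large* when it explains more than 2.5% of the
#' simulated genetic variance `v_a + v_d`.
#'
#' @param qtl A `qtl_set`.
#' @param panel A `marker_panel` (its frequencies define the expectation).
#' @param v_a,v_d Trait variance components.
#' @param window_cm Window size used by the scan.
#' @param chrom_end_cm Chromosome end (default 100).
#' @return A data.frame with one row per QTL: `qtl_id`, `position_cm`,
#'   `v_qtl`, `detectable`, `large`.
#' @export
detectable_qtl <- function(qtl, panel, v_a, v_d, window_cm,
                           chrom_end_cm = 100) {
  stopifnot(inherits(qtl, "qtl_set"), inherits(panel, "marker_panel"))
  p <- qtl$p
  H <- 2 * p * (1 - p)
  alpha <- qtl$a + (1 - 2 * p) * qtl$d
  v_qtl <- H * alpha^2 + H^2 * qtl$d^2
  win <- sliding_windows(panel$positions_cm, window_cm, chrom_end_cm)
  Hp <- 2 * panel$freqs * (1 - panel$freqs)
  e_alpha2 <- v_a / sum(Hp)
  e_d2 <- if (v_d > 0) v_d / sum(Hp^2) else 0
  ecs <- c(0, cumsum(Hp * e_alpha2 + Hp^2 * e_d2))
  e_w <- ecs[win$i_end + 1L] - ecs[win$i_start]
  thresh <- vapply(qtl$position_cm, function(pos) {
    hit <- win$start_cm <= pos & pos < win$end_cm
    if (!any(hit)) { # QTL outside every window: use the nearest window
      hit <- which.min(pmin(abs(win$start_cm - pos), abs(win$end_cm - pos)))
    }
    mean(e_w[hit])
  }, numeric(1))
  data.frame(qtl_id = seq_len(nrow(qtl)), position_cm = qtl$position_cm,
             v_qtl = v_qtl, detectable = v_qtl > thresh,
             large = v_qtl / (v_a + v_d) > 0.025)
}

# contiguous clusters of significant windows: merge overlapping intervals
significant_clusters <- function(scan, threshold) {
  sig <- which(!is.na(scan$wppa) & scan$wppa > threshold)
  if (!length(sig)) return(NULL)
  s <- scan$start_cm[sig]
  e <- scan$end_cm[sig]
  o <- order(s)
  s <- s[o]; e <- e[o]
  cl_start <- s[1]; cl_end <- e[1]
  out <- list()
  if (length(s) > 1) {
    for (k in 2:length(s)) {
      if (s[k] <= cl_end) {
        cl_end <- max(cl_end, e[k])
      } else {
        out[[length(out) + 1L]] <- c(cl_start, cl_end)
        cl_start <- s[k]; cl_end <- e[k]
      }
    }
  }
  out[[length(out) + 1L]] <- c(cl_start, cl_end)
  do.call(rbind, out)
}

#' Map causative loci from a WPPA track
#'
#' A causative locus is mapped at a threshold when at least one window with
#' WPPA above the threshold intersects the 1-cM flank on either side of the
#' locus. Mapping precision is the union length (cM) of the contiguous
#' cluster of significant windows nearest to the locus, so the window size
#' is its lower bound.
#'
#' @param scan A `window_scan`.
#' @param qtl A `qtl_set` on the same coordinate system.
#' @param threshold WPPA decision threshold (study grid: 0.85, 0.95, 0.99).
#' @param flank_cm Mapping flank around the locus (default 1 cM).
#' @return A data.frame with one row per QTL: `qtl_id`, `mapped`,
#'   `precision_cm` (`NA` when unmapped).
#' @export
map_qtl <- function(scan, qtl, threshold, flank_cm = 1) {
  stopifnot(inherits(scan, "window_scan"), inherits(qtl, "qtl_set"))
  cl <- significant_clusters(scan, threshold)
  sig <- !is.na(scan$wppa) & scan$wppa > threshold
  mapped <- logical(nrow(qtl))
  prec <- rep(NA_real_, nrow(qtl))
  for (i in seq_len(nrow(qtl))) {
    lo <- qtl$position_cm[i] - flank_cm
    hi <- qtl$position_cm[i] + flank_cm
    hit <- sig & scan$start_cm <= hi & scan$end_cm >= lo
    mapped[i] <- any(hit)
    if (mapped[i]) {
      touching <- cl[, 1] <= hi & cl[, 2] >= lo
      cand <- which(touching)
      mid <- qtl$position_cm[i]
      dist <- pmax(0, pmax(cl[cand, 1] - mid, mid - cl[cand, 2]))
      best <- cand[which.min(dist)]
      prec[i] <- cl[best, 2] - cl[best, 1]
    }
  }
  data.frame(qtl_id = seq_len(nrow(qtl)), mapped = mapped,
             precision_cm = prec)
}

#' Evaluate one scan against the simulated truth
#'
#' Combines [detectable_qtl()] and [map_qtl()] over a set of WPPA
#' thresholds for a single fitted model and window size.
#'
#' @param scan A `window_scan`.
#' @param qtl A `qtl_set`.
#' @param panel The `marker_panel` the model was fitted to.
#' @param v_a,v_d Trait variance components.
#' @param thresholds WPPA thresholds (default `c(0.85, 0.95, 0.99)`).
#' @param flank_cm Mapping flank (default 1 cM).
#' @return Long data.frame: one row per QTL and threshold with columns
#'   `threshold`, `qtl_id`, `v_qtl`, `detectable`, `large`, `mapped`,
#'   `precision_cm`.
#' @export
evaluate_scan <- function(scan, qtl, panel, v_a, v_d,
                          thresholds = c(0.85, 0.95, 0.99), flank_cm = 1) {
  det <- detectable_qtl(qtl, panel, v_a, v_d,
                        attr(scan, "window_size_cm"))
  do.call(rbind, lapply(thresholds, function(th) {
    mp <- map_qtl(scan, qtl, th, flank_cm)
    cbind(threshold = th, det, mapped = mp$mapped,
          precision_cm = mp$precision_cm)
  }))
}

#' Power, L-power and precision across replicate traits
#'
#' Per trait, power is the fraction of *detectable* causative loci that
#' were mapped, and L-power the same fraction restricted to *large* loci
#' (those explaining > 2.5% of the genetic variance); traits without
#' detectable (resp. large detectable) loci are excluded from the
#' corresponding average. Precision is averaged over mapped loci. Means
#' and standard deviations are taken across traits.
#'
#' @param evals A list of per-trait data.frames from [evaluate_scan()].
#' @return A data.frame with one row per threshold: `threshold`, `power`,
#'   `power_sd`, `l_power`, `l_power_sd`, `precision_cm`, `precision_sd`,
#'   `n_traits`.
#' @export
power_tables <- function(evals) {
  stopifnot(length(evals) >= 1)
  thresholds <- sort(unique(evals[[1]]$threshold))
  do.call(rbind, lapply(thresholds, function(th) {
    per_trait <- lapply(evals, function(ev) {
      ev <- ev[ev$threshold == th, ]
      det <- ev[ev$detectable, ]
      lg <- det[det$large, ]
      c(power = if (nrow(det)) mean(det$mapped) else NA_real_,
        l_power = if (nrow(lg)) mean(lg$mapped) else NA_real_,
        precision = if (any(ev$mapped)) {
          mean(ev$precision_cm[ev$mapped])
        } else NA_real_)
    })
    pt <- do.call(rbind, per_trait)
    data.frame(threshold = th,
               power = mean(pt[, "power"], na.rm = TRUE),
               power_sd = stats::sd(pt[, "power"], na.rm = TRUE),
               l_power = mean(pt[, "l_power"], na.rm = TRUE),
               l_power_sd = stats::sd(pt[, "l_power"], na.rm = TRUE),
               precision_cm = mean(pt[, "precision"], na.rm = TRUE),
               precision_sd = stats::sd(pt[, "precision"], na.rm = TRUE),
               n_traits = sum(!is.na(pt[, "power"])))
  }))
}

#' Run a simulation-study grid
#'
#' End-to-end orchestration of the study: simulate populations and traits,
#' build thinned marker panels, fit the requested models, scan each fit at
#' each window size and tabulate power, L-power and precision at each WPPA
#' threshold. All stage seeds derive deterministically from `seed`.
#'
#' @param n_populations Number of replicate populations.
#' @param traits_per_population Traits simulated per population.
#' @param densities Named integer vector of panel sizes, e.g.
#'   `c("0.5k" = 500, "2k" = 2000)`; the special name `"7k"` selects the
#'   full-sequence panel.
#' @param window_sizes Window sizes in cM.
#' @param thresholds WPPA thresholds.
#' @param models Character subset of `c("bayesc", "bayesd")`.
#' @param mcmc An [mcmc_config()].
#' @param demography A [demography_config()].
#' @param n_qtl,h2 Trait architecture parameters.
#' @param seed Master seed.
#' @param verbose Print per-cell progress.
#' @return Long data.frame with one row per (density, window size,
#'   threshold, model): power, L-power, precision and their SDs across
#'   traits.
#' @export
run_experiment <- function(n_populations = 1, traits_per_population = 5,
                           densities = c("2k" = 2000),
                           window_sizes = c(0.25, 0.5, 1),
                           thresholds = c(0.85, 0.95, 0.99),
                           models = c("bayesc", "bayesd"),
                           mcmc = mcmc_config(),
                           demography = demography_config(),
                           n_qtl = 15L, h2 = 0.3, seed = 1L,
                           verbose = FALSE) {
  evals <- list() # key: density|ws|model -> list of per-trait evals
  chrom_end <- demography$genetic_length * 100
  for (ip in seq_len(n_populations)) {
    pop <- simulate_population(demography,
                               seed = derive_seed(seed, "pop", ip))
    full <- full_sequence_panel(pop)
    for (it in seq_len(traits_per_population)) {
      tr <- tryCatch(
        simulate_trait(pop, n_qtl = n_qtl, h2 = h2,
                       eligible = full$snp_indices,
                       seed = derive_seed(seed, "trait", (ip - 1) * 1000 + it)),
        error = function(e) {
          warning("trait simulation failed in population ", ip, ": ",
                  conditionMessage(e))
          NULL
        })
      if (is.null(tr)) next
      for (id in seq_along(densities)) {
        dens_name <- names(densities)[id]
        panel <- if (identical(dens_name, "7k")) {
          full
        } else {
          select_marker_panel(pop, densities[[id]],
                              causal_ids = tr$qtl$site_id,
                              density_label = dens_name)
        }
        X <- genotype_matrix(pop, panel$snp_indices)
        t_exp <- log2(length(panel$snp_indices) / 250)
        pld <- pld_schedule(max(t_exp, 1e-6))
        for (model in models) {
          prior <- calibrate_priors(tr$v_a, tr$v_d, tr$inb_dep,
                                    panel$freqs, pld,
                                    model = model)
          mc <- mcmc_config(mcmc$n_cycles, mcmc$burn_in, mcmc$thin,
                            seed = derive_seed(seed, paste0("fit-", model),
                                               (ip - 1) * 1000 + it))
          fit <- if (model == "bayesc") {
            run_bayesc(tr$y, X, tr$v_e, prior, mc)
          } else {
            run_bayesd(tr$y, X, tr$v_e, prior, mc)
          }
          for (ws in window_sizes) {
            scan <- window_scan(fit, panel$freqs, panel$positions_cm, ws,
                                tr$v_a, tr$v_d, chrom_end)
            key <- paste(dens_name, ws, model, sep = "|")
            ev <- evaluate_scan(scan, tr$qtl, panel, tr$v_a, tr$v_d,
                                thresholds)
            evals[[key]] <- c(evals[[key]], list(ev))
            if (verbose) {
              message(sprintf("pop %d trait %d %s %s ws=%.2f done",
                              ip, it, dens_name, model, ws))
            }
          }
        }
      }
    }
  }
  out <- do.call(rbind, lapply(names(evals), function(key) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    tab <- power_tables(evals[[key]])
    cbind(density = parts[1], ws = as.numeric(parts[2]), model = parts[3],
          tab)
  }))
  rownames(out) <- NULL
  out
}

#' Deterministic stage seed
#'
#' Derives a reproducible 31-bit seed from a master seed, a stage name and
#' a replicate index, so that every stochastic stage of an experiment has
#' its own independent, resumable RNG stream.
#'
#' @param master Master seed (integer).
#' @param stage Stage name (character).
#' @param index Replicate index (integer, default 1).
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(master, stage, index = 1L) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  val <- (as.double(master) * 2654435.0 + h * 97003.0 +
            as.double(index) * 7919.0) %% (2^31 - 1)
  as.integer(val)
}
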