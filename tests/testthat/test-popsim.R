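test_that("effective-size schedule matches the stated demography", {
  ne <- build_ne_schedule(demography_config())
  expect_length(ne, 1051L)
  expect_equal(ne[100], 600L)
  expect_equal(ne[650], 600L)
  expect_equal(ne[1000], 100L)
  expect_equal(ne[1050], 100L)
  # decline strictly between the bounds and monotone non-increasing
  expect_gt(ne[825], 100L)
  expect_lt(ne[825], 600L)
  expect_gte(ne[825], ne[826])
  expect_true(all(diff(ne[650:1051]) <= 0))
  expect_error(demography_config(physical_length = NULL),
               "physical_length")
  expect_error(demography_config(ne_schedule = rep(1L, 1051L)), ">= 2")
})

test_that("no mutation means no segregating sites", {
  cfg <- demography_config(n_generations = 20L,
                           ne_schedule = rep(20L, 20L),
                           final_sample_n = 20L, mutation_rate = 0,
                           burn_in_generations = 0L)
  pop <- simulate_population(cfg, seed = 1)
  expect_length(pop$freqs, 0L)
})

test_that("segregating-site count agrees with Watterson's prediction", {
  # constant Ne = 100 run for 4 Ne generations from empty founders; theta
  # = 4 Ne u = 4 per chromosome of 0.01 Morgan / 1 Mb
  cfg <- demography_config(n_generations = 400L,
                           ne_schedule = rep(100L, 400L),
                           final_sample_n = 100L,
                           burn_in_generations = 0L,
                           genetic_length = 0.01, physical_length = 1e6)
  S <- vapply(1:4, function(s) {
    length(simulate_population(cfg, seed = 200 + s)$freqs)
  }, numeric(1))
  theta <- 4 * 100 * (1e-8 * 1e6)
  n_hap <- 200
  a1 <- sum(1 / seq_len(n_hap - 1))
  a2 <- sum(1 / seq_len(n_hap - 1)^2)
  expected <- theta * a1
  se <- sqrt(theta * a1 + theta^2 * a2) / sqrt(length(S))
  expect_lt(abs(mean(S) - expected), 3 * se)
})

test_that("allele frequencies are martingales under neutral drift", {
  # continue one standing-variation sample many times; mean final frequency
  # of each tracked allele must equal its initial frequency
  cfg0 <- demography_config(n_generations = 30L,
                            ne_schedule = rep(60L, 30L),
                            final_sample_n = 60L,
                            burn_in_generations = 240L,
                            genetic_length = 0.05, physical_length = 5e6)
  pop0 <- simulate_population(cfg0, seed = 31)
  keep <- pop0$freqs > 0.15 & pop0$freqs < 0.85
  expect_gt(sum(keep), 10)
  init_pos <- pop0$positions_cm[keep]
  init_freq <- pop0$freqs[keep]
  haps <- haplotype_positions(pop0)
  cfg1 <- demography_config(n_generations = 12L,
                            ne_schedule = rep(60L, 12L),
                            final_sample_n = 60L,
                            burn_in_generations = 0L,
                            genetic_length = 0.05, physical_length = 5e6,
                            mutation_rate = 0)
  set.seed(77)
  drift <- replicate(80, {
    pop1 <- simulate_population(cfg1, init_haplotypes = haps,
                                prune_every = 0L)
    f <- pop1$freqs[match(init_pos, pop1$positions_cm)]
    f[is.na(f)] <- ifelse(init_pos[is.na(f)] %in% pop1$fixed_positions_cm,
                          1, 0)
    mean(f - init_freq)
  })
  se <- stats::sd(drift) / sqrt(length(drift))
  expect_lt(abs(mean(drift)), 3 * se)
})

test_that("LD decays with genetic distance under the study demography", {
  pop <- study_population(1L)
  idx <- which(maf(pop) > 0.1)
  set.seed(3)
  idx <- sort(sample(idx, 400))
  G <- genotype_matrix(pop, idx)
  pos <- pop$positions_cm[idx]
  cm <- stats::cor(G)^2
  dist <- abs(outer(pos, pos, "-"))
  near <- dist > 0 & dist < 0.05
  far <- dist > 0.5
  expect_gt(mean(cm[near]), mean(cm[far]))
})

test_that("marker panels are equidistant, MAF-filtered and causal-free", {
  pop <- study_population(1L)
  set.seed(21)
  causals <- sample_qtl(pop, 15L)
  panel <- select_marker_panel(pop, 500L, maf_min = 0.03,
                               causal_ids = causals)
  expect_length(panel$snp_indices, 500L)
  expect_false(any(duplicated(panel$snp_indices)))
  expect_false(is.unsorted(panel$snp_indices))
  expect_true(all(maf(pop)[panel$snp_indices] >= 0.03))
  expect_length(intersect(panel$snp_indices, causals), 0L)
  # spacing regularity: gap CV well below random subsets of the same size
  cv <- function(x) stats::sd(x) / mean(x)
  panel_cv <- cv(diff(panel$positions_cm))
  eligible <- setdiff(which(maf(pop) >= 0.03), causals)
  set.seed(11)
  rand_cv <- replicate(200, {
    cv(diff(sort(pop$positions_cm[sample(eligible, 500)])))
  })
  expect_lt(panel_cv, stats::quantile(rand_cv, 0.05))
  expect_error(select_marker_panel(pop, length(pop$freqs) + 1L),
               "eligible")
})

test_that("grid thinning picks alternating sites when the grid aligns", {
  pop <- toy_population()
  # synthetic population stub: 9 uniform sites, grid of 5 coincides with
  # every other site
  stub <- structure(list(
    haplotypes = matrix(as.raw(rep(c(0, 1), each = 9)), 2, 9,
                        byrow = TRUE),
    positions_cm = as.numeric(0:8), positions_bp = 1:9,
    freqs = rep(0.5, 9), n_individuals = 1L
  ), class = "wf_population")
  panel <- select_marker_panel(stub, 5L, maf_min = 0.03)
  expect_equal(panel$snp_indices, c(1L, 3L, 5L, 7L, 9L))
})

test_that("population print and genotype extraction are consistent", {
  pop <- toy_population()
  expect_output(print(pop), "segregating sites")
  G <- genotype_matrix(pop)
  expect_true(all(G %in% 0:2))
  expect_equal(colMeans(G) / 2, pop$freqs, tolerance = 1e-12)
  expect_true(all(diff(pop$positions_cm) > 0))
  expect_true(all(diff(pop$positions_bp) > 0))
})
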