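test_that("the prior-inclusion schedule reproduces its defining algebra", {
  expect_equal(pld_schedule(1), 5.5 * 0.7 * 15 / 500)
  expect_equal(pld_schedule(2), 5.5 * 0.49 * 15 / 1000)
  expect_equal(density_for_exponent(c(1, 2, 3)), c(500, 1000, 2000))
  expect_error(pld_schedule(0))
  # expected SNPs per causative locus tends to 1 at full sequence density
  spq <- pld_schedule(c(1, 3, 4.8)) * density_for_exponent(c(1, 3, 4.8)) / 15
  expect_true(all(diff(spq) < 0))
  expect_lt(abs(spq[3] - 1), 0.05)
})

test_that("prior calibration matches the moment algebra", {
  # pld = 1, sum H = 1 (two SNPs at p = 0.5), v_a = 5: the t-variance
  # factor df/(df-2) = 5 gives s_a^2 = 1
  pr <- calibrate_priors(5, freqs = c(0.5, 0.5), pld = 1, df_t = 2.5)
  expect_equal(pr$s_a, 1)
  # zero dominance input degenerates the dominance prior to a point mass
  prd <- calibrate_priors(5, 0, 0, freqs = 0.5, pld = 0.5,
                          model = "bayesd")
  expect_equal(prd$mu_h, 0)
  expect_equal(prd$sigma_h, 0)
  expect_error(calibrate_priors(-1, freqs = 0.5, pld = 0.5), "positive")
  expect_error(calibrate_priors(1, freqs = 0.5, pld = 0.5, df_t = 2),
               "exceed 2")
  expect_error(calibrate_priors(1, freqs = 0.5, pld = 1.5))
})

test_that("Monte-Carlo draws from the calibrated prior return the input
           variance components", {
  set.seed(42)
  p <- runif(50, 0.1, 0.9)
  H <- 2 * p * (1 - p)
  v_a <- 3.2; v_d <- 0.6; inb <- 0.4
  pr <- calibrate_priors(v_a, v_d, inb, p, pld = 0.1, model = "bayesd")
  n <- 2e5
  draw_locus <- function(j) {
    g <- runif(n) < pr$pld
    scale <- ifelse(g, 1, pr$epsilon)
    a <- scale * pr$s_a * stats::rt(n, df = pr$df_t)
    h <- stats::rnorm(n, pr$mu_h, pr$sigma_h)
    d <- h * abs(a)
    alpha <- a + (1 - 2 * p[j]) * d
    c(va = H[j] * mean(alpha^2), vd = H[j]^2 * mean(d^2),
      inb = H[j] * mean(d))
  }
  mom <- rowSums(vapply(seq_along(p), draw_locus, numeric(3)))
  # t(2.5) second moments converge slowly (infinite fourth moment), so the
  # band is a stable-law-informed 10%
  expect_lt(abs(mom["va"] - v_a) / v_a, 0.10)
  expect_lt(abs(mom["vd"] - v_d) / v_d, 0.15)
  expect_lt(abs(mom["inb"] - inb) / inb, 0.10)
})

test_that("with the likelihood disabled the sampler reproduces its prior", {
  M <- 300L
  pr <- calibrate_priors(2, 0.5, 0.3, freqs = rep(0.3, M), pld = 0.1,
                         model = "bayesd")
  fit <- run_bayesd(y = NULL, X = matrix(0L, 2, M), v_e = 1, pr,
                    mcmc_config(n_cycles = 6000, burn_in = 0, thin = 15,
                                seed = 3),
                    likelihood_on = FALSE)
  g <- as.logical(fit$gamma_s)
  n_draw <- length(g)
  # inclusion rate = pld
  expect_lt(abs(mean(g) - 0.1), 3 * sqrt(0.1 * 0.9 / n_draw))
  # dominance coefficient d / |a| ~ N(mu_h, sigma_h^2) independent of a
  h <- fit$d_s / abs(fit$a_s)
  expect_lt(abs(mean(h) - pr$mu_h), 3 * pr$sigma_h / sqrt(n_draw))
  expect_lt(abs(stats::sd(h) - pr$sigma_h), 3 * pr$sigma_h / sqrt(2 * n_draw))
  # additive scale: median |a| under gamma = 1 equals the folded-t median
  med_theory <- pr$s_a * stats::qt(0.75, df = pr$df_t)
  med_hat <- stats::median(abs(fit$a_s[g]))
  expect_lt(abs(med_hat - med_theory) / med_theory, 0.10)
  # and eps-scaled under gamma = 0
  med0 <- stats::median(abs(fit$a_s[!g]))
  expect_lt(abs(med0 - pr$epsilon * med_theory) /
              (pr$epsilon * med_theory), 0.10)
})

test_that("identical seeds give bit-identical chains", {
  set.seed(5)
  X <- matrix(rbinom(300 * 80, 2, 0.4), 300, 80)
  y <- rnorm(300)
  pr <- calibrate_priors(0.3, freqs = colMeans(X) / 2, pld = 0.05)
  mc <- mcmc_config(600, 200, 4, seed = 77)
  f1 <- run_bayesc(y, X, 0.7, pr, mc)
  f2 <- run_bayesc(y, X, 0.7, pr, mc)
  expect_identical(f1$a_s, f2$a_s)
  expect_identical(f1$gamma_s, f2$gamma_s)
  prd <- calibrate_priors(0.3, 0.05, 0.02, colMeans(X) / 2, 0.05,
                          model = "bayesd")
  d1 <- run_bayesd(y, X, 0.7, prd, mc)
  d2 <- run_bayesd(y, X, 0.7, prd, mc)
  expect_identical(d1$d_s, d2$d_s)
})

test_that("a strong single causative locus is recovered with certainty", {
  set.seed(6)
  N <- 500L; M <- 200L
  X <- matrix(rbinom(N * M, 2, 0.4), N, M)
  qj <- 120L
  gv <- X[, qj] * 1.0
  ve <- stats::var(gv) # QTL explains half of var(y)
  y <- gv + rnorm(N, 0, sqrt(ve))
  pr <- calibrate_priors(stats::var(gv), freqs = colMeans(X) / 2,
                         pld = 0.05)
  fit <- run_bayesc(y, X, ve, pr, mcmc_config(4000, 1000, 30, seed = 9))
  pip <- colMeans(fit$gamma_s)
  expect_gt(max(pip[(qj - 1):(qj + 1)]), 0.9)
})

test_that("null phenotypes produce prior-level inclusion and shrunk
           effects", {
  set.seed(7)
  N <- 500L; M <- 200L
  X <- matrix(rbinom(N * M, 2, 0.4), N, M)
  y <- rnorm(N)
  pr <- calibrate_priors(stats::var(y) * 0.3, freqs = colMeans(X) / 2,
                         pld = 0.01)
  fit <- run_bayesc(y, X, stats::var(y) * 0.7, pr,
                    mcmc_config(4000, 1000, 30, seed = 10))
  expect_lt(max(abs(colMeans(fit$a_s))), 0.1 * stats::sd(y))
  n_draw <- length(fit$gamma_s)
  expect_lt(abs(mean(fit$gamma_s) - 0.01),
            4 * sqrt(0.01 * 0.99 / n_draw) + 0.005)
})

test_that("constant genotype columns are skipped", {
  set.seed(8)
  X <- matrix(rbinom(200 * 20, 2, 0.5), 200, 20)
  X[, 7] <- 2L
  y <- rnorm(200)
  pr <- calibrate_priors(0.3, freqs = pmin(pmax(colMeans(X) / 2, 0.01),
                                           0.99), pld = 0.1)
  fit <- run_bayesc(y, X, 0.7, pr, mcmc_config(400, 100, 3, seed = 1))
  expect_true(all(fit$a_s[, 7] == 0))
})

test_that("BayesD collapses to BayesC when the data carry no dominance", {
  set.seed(9)
  N <- 400L; M <- 100L
  X <- matrix(rbinom(N * M, 2, 0.4), N, M)
  b <- rep(0, M); b[c(20, 60)] <- c(0.8, -0.8)
  gv <- drop(X %*% b)
  ve <- stats::var(gv) * 7 / 3
  y <- gv + rnorm(N, 0, sqrt(ve))
  p <- colMeans(X) / 2
  H <- 2 * p * (1 - p)
  prd <- calibrate_priors(stats::var(gv), 1e-10, 0, p, pld = 0.05,
                          model = "bayesd")
  fit <- run_bayesd(y, X, ve, prd, mcmc_config(2000, 500, 15, seed = 2))
  vd_hat <- mean(rowSums(t(t(fit$d_s^2) * H^2)))
  expect_lt(vd_hat, 0.05 * stats::var(gv))
})

test_that("an overdominant locus is found by the dominance model but
           missed by the additive one", {
  set.seed(10)
  N <- 400L; M <- 150L
  hits_d <- hits_c <- logical(10)
  for (r in 1:10) {
    X <- matrix(rbinom(N * M, 2, 0.5), N, M)
    qj <- 75L
    a <- 0.05; d <- 1.0
    gv <- a * X[, qj] + d * (X[, qj] == 1)
    y <- gv + rnorm(N, 0, 1)
    p <- colMeans(X) / 2
    v_a <- 2 * 0.25 * a^2          # alpha = a at p = 0.5
    v_d <- (2 * 0.25)^2 * d^2
    pos <- seq(0.1, 14.9, length.out = M)
    mc <- mcmc_config(4000, 1000, 30, seed = 100 + r)
    prc <- calibrate_priors(v_a, freqs = p, pld = 0.05)
    fc <- run_bayesc(y, X, 1, prc, mc)
    sc <- window_scan(fc, p, pos, 0.5, v_a, v_d, chrom_end_cm = 15)
    prd <- calibrate_priors(v_a, v_d, 2 * 0.25 * d, p, pld = 0.05,
                            model = "bayesd")
    fd <- run_bayesd(y, X, 1, prd, mc)
    sd_ <- window_scan(fd, p, pos, 0.5, v_a, v_d, chrom_end_cm = 15)
    near <- abs(sc$start_cm - pos[qj]) <= 1
    hits_c[r] <- any(sc$wppa[near] > 0.95, na.rm = TRUE)
    hits_d[r] <- any(sd_$wppa[near] > 0.95, na.rm = TRUE)
  }
  expect_gte(mean(hits_d & !hits_c), 0.7)
})
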