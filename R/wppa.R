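#' Sliding windows over a marker panel
#'
#' Builds one window per SNP: window i is anchored at the position of SNP i
#' and spans `size_cm`, membership being half-open
#' (`start <= position < start + size`). Windows anchored near the
#' chromosome end are truncated at `chrom_end_cm`.
#'
#' @param positions_cm Sorted SNP genetic positions (cM).
#' @param size_cm Window size in cM (the study grid is 0.25, 0.5, 1).
#' @param chrom_end_cm Chromosome end (default 100 cM).
#' @return A data.frame with one row per window: `anchor`, `start_cm`,
#'   `end_cm`, `i_start`, `i_end` (inclusive SNP index range) and `n_snps`.
#' @export
sliding_windows <- function(positions_cm, size_cm, chrom_end_cm = 100) {
  n <- length(positions_cm)
  if (n == 0) stop("empty marker panel")
  if (is.unsorted(positions_cm)) stop("positions must be sorted")
  start <- positions_cm
  end <- pmin(start + size_cm, chrom_end_cm)
  # i_end: last SNP with position < start + size (at least the anchor)
  i_end <- findInterval(start + size_cm, positions_cm,
                        left.open = TRUE, rightmost.closed = FALSE)
  i_end <- pmax(i_end, seq_len(n))
  data.frame(anchor = seq_len(n), start_cm = start, end_cm = end,
             i_start = seq_len(n), i_end = i_end,
             n_snps = i_end - seq_len(n) + 1L)
}

#' Window genomic variance for one effect sample
#'
#' The genomic variance attributed to a window is
#' `sum_j H_j alpha_j^2 + H_j^2 d_j^2` over the member SNPs, with
#' heterozygosity `H = 2pq` and substitution effect
#' `alpha = a + (q - p) d`. For BayesC samples `d` is zero and the
#' expression reduces to `sum H a^2`.
#'
#' @param a,d Additive and dominance effects for all panel SNPs (one MCMC
#'   sample); `d = NULL` is treated as all-zero.
#' @param freqs Panel allele frequencies.
#' @param window One row of [sliding_windows()] (or any list with
#'   `i_start`, `i_end`).
#' @return The window genomic variance.
#' @export
window_genomic_variance <- function(a, d = NULL, freqs, window) {
  idx <- seq.int(window$i_start, window$i_end)
  if (any(idx > length(a))) stop("window references SNPs outside the panel")
  p <- freqs[idx]
  if (any(p <= 0 | p >= 1)) stop("member SNP frequencies must lie in (0,1)")
  H <- 2 * p * (1 - p)
  dj <- if (is.null(d)) numeric(length(idx)) else d[idx]
  alpha <- a[idx] + (1 - 2 * p) * dj
  sum(H * alpha^2 + H^2 * dj^2)
}

#' Equal-distribution expectation of the window genomic variance
#'
#' Under the assumption that the total genetic variance is distributed
#' equally across the genome, `E(alpha^2) = v_a / sum_M H_j` and
#' `E(d^2) = v_d / sum_M H_j^2` (sums over the whole panel), so that
#' summing the per-window expectation
#' `sum_{j in w} H_j E(alpha^2) + H_j^2 E(d^2)` over a tiling of the panel
#' returns exactly `v_a + v_d`. The same expectation (including the
#' dominance term) is used for BayesC and BayesD scans.
#'
#' @param freqs Allele frequencies of the whole panel.
#' @param window A window row (`i_start`, `i_end`).
#' @param v_a,v_d Input additive and dominance variances.
#' @return The expected window genomic variance.
#' @export
expected_window_variance <- function(freqs, window, v_a, v_d = 0) {
  H <- 2 * freqs * (1 - freqs)
  if (all(H == 0)) stop("all-monomorphic panel")
  e_alpha2 <- v_a / sum(H)
  e_d2 <- if (v_d > 0) v_d / sum(H^2) else 0
  idx <- seq.int(window$i_start, window$i_end)
  sum(H[idx] * e_alpha2 + H[idx]^2 * e_d2)
}

#' Window posterior probability of association
#'
#' The WPPA of a window is the fraction of stored MCMC samples whose window
#' genomic variance exceeds the equal-distribution expectation, i.e. with
#' `q_w > 1` (strict; ties count as non-exceedance). A zero expectation
#' with non-zero samples is undefined and reported as `NA`.
#'
#' @param sigma2_samples Per-sample window genomic variances.
#' @param expectation Expected window variance from
#'   [expected_window_variance()].
#' @return WPPA in \[0, 1\], or `NA` if undefined.
#' @export
window_wppa <- function(sigma2_samples, expectation) {
  if (length(sigma2_samples) < 1) stop("need at least one stored sample")
  if (expectation == 0) {
    if (any(sigma2_samples != 0)) return(NA_real_)
    return(0)
  }
  mean(sigma2_samples / expectation > 1)
}

#' Genome scan: WPPA for every sliding window
#'
#' Computes, for each sliding window, the per-sample genomic variance, its
#' equal-distribution expectation, the WPPA, and (for BayesD) the mean
#' window dominance variance `sum H_j^2 d_j^2`. Cumulative sums over SNPs
#' make the scan linear in panel size.
#'
#' @param samples A `posterior_samples` from [run_bayesc()] or
#'   [run_bayesd()].
#' @param freqs,positions_cm Allele frequencies and positions of the panel
#'   SNPs the model was fitted to.
#' @param size_cm Window size in cM.
#' @param v_a,v_d Input variance components (the same values passed to the
#'   model).
#' @param chrom_end_cm Chromosome end (default 100).
#' @return An object of class `window_scan`: a data.frame with one row per
#'   window (`anchor_snp`, `start_cm`, `end_cm`, `n_snps`, `wppa`,
#'   `mean_sigma2_gw`, `mean_vd_w`, `e_sigma2_gw`), with the per-window
#'   sample matrix attached as attribute `"sigma2_samples"` (windows by
#'   samples).
#' @export
window_scan <- function(samples, freqs, positions_cm, size_cm, v_a,
                        v_d = 0, chrom_end_cm = 100) {
  stopifnot(inherits(samples, "posterior_samples"))
  A <- samples$a_s
  M <- ncol(A)
  stopifnot(length(freqs) == M, length(positions_cm) == M)
  D <- samples$d_s
  win <- sliding_windows(positions_cm, size_cm, chrom_end_cm)
  p <- freqs
  H <- 2 * p * (1 - p)
  if (is.null(D)) {
    contrib <- t(t(A^2) * H) # samples x M
    vd_contrib <- NULL
  } else {
    ALPHA <- A + t(t(D) * (1 - 2 * p))
    vd_contrib <- t(t(D^2) * H^2)
    contrib <- t(t(ALPHA^2) * H) + vd_contrib
  }
  # cumulative sums along SNPs -> O(1) window sums
  cs <- cbind(0, t(apply(contrib, 1, cumsum))) # samples x (M+1)
  sum_win <- function(cs) cs[, win$i_end + 1L, drop = FALSE] -
    cs[, win$i_start, drop = FALSE]
  s2 <- sum_win(cs) # samples x windows
  e_alpha2 <- v_a / sum(H)
  e_d2 <- if (v_d > 0) v_d / sum(H^2) else 0
  ecs <- c(0, cumsum(H * e_alpha2 + H^2 * e_d2))
  e_w <- ecs[win$i_end + 1L] - ecs[win$i_start]
  wppa <- vapply(seq_len(nrow(win)), function(k) {
    window_wppa(s2[, k], e_w[k])
  }, numeric(1))
  out <- data.frame(anchor_snp = win$anchor, start_cm = win$start_cm,
                    end_cm = win$end_cm, n_snps = win$n_snps,
                    wppa = wppa, mean_sigma2_gw = colMeans(s2),
                    mean_vd_w = NA_real_, e_sigma2_gw = e_w)
  if (!is.null(vd_contrib)) {
    vcs <- cbind(0, t(apply(vd_contrib, 1, cumsum)))
    out$mean_vd_w <- colMeans(sum_win(vcs))
  }
  attr(out, "sigma2_samples") <- t(s2)
  attr(out, "window_size_cm") <- size_cm
  attr(out, "model") <- samples$model
  class(out) <- c("window_scan", "data.frame")
  out
}
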