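#' Correct observed VAFs for tumour purity
#'
#' Divides every VAF by the purity estimate
#' (`VAF_corrected = VAF_observed / purity`), restoring diploid heterozygous
#' clonal mutations to ~50% VAF in a correctly-estimated sample. Values above
#' 0.5 are retained here (they are excluded later by the fixed featurization
#' range).
#'
#' @param sample A `vaf_sample`.
#' @param purity Purity in `(0, 1]`; defaults to the sample attribute.
#' @return The corrected `vaf_sample` (purity attribute set to 1).
#' @export
purity_correct <- function(sample, purity = attr(sample, "purity")) {
  stop_unless(!is.null(purity) && is.finite(purity) && purity > 0 &&
                purity <= 1, "`purity` must be in (0, 1]")
  out <- sample
  out$vaf <- sample$vaf / purity
  attr(out, "purity") <- 1
  attr(out, "purity_corrected") <- purity
  out
}

#' Clonal-peak adjustment for mis-estimated purity
#'
#' Locates density peaks of the VAF distribution (Gaussian kernel, Silverman
#' bandwidth, 512-point grid over `[0.05, 1.0]`). If the peak closest to 0.5
#' (the theoretical diploid clonal cluster) lies above 0.35 VAF, the peak is
#' treated as a misrepresented clonal peak: a Gaussian is fitted to the
#' mutations within 0.1 VAF of the peak and every VAF is multiplied by
#' `0.5 / mean(fit)`. Peaks at or below 0.35 are left untouched (a warning is
#' emitted), since tumours initiate from cells that already carry mutations,
#' so a genuine clonal cluster must exist near 0.5. When two peaks are
#' equidistant from 0.5 the higher-VAF peak is used.
#'
#' @param sample A `vaf_sample` (>= `min_mutations` mutations required).
#' @param min_mutations Sample-size filter (default 100).
#' @return The adjusted `vaf_sample` with attributes `clonal_scale` (the
#'   multiplicative factor, 1 when unadjusted) and `clonal_adjusted`
#'   (logical).
#' @export
clonal_peak_adjust <- function(sample, min_mutations = 100) {
  stop_unless(nrow(sample) >= min_mutations,
              sprintf("clonal-peak adjustment requires >= %d mutations",
                      min_mutations))
  v <- sample$vaf[sample$vaf >= 0.02 & sample$vaf <= 1.2]
  out <- sample
  attr(out, "clonal_scale") <- 1
  attr(out, "clonal_adjusted") <- FALSE
  if (length(v) < 10) {
    warn("too few usable VAFs for peak finding; sample unchanged")
    return(out)
  }
  den <- density(v, bw = "nrd0", n = 512, from = 0.05, to = 1.0)
  peaks <- density_peaks(den)
  if (length(peaks) == 0) {
    warn("no density peaks found; sample unchanged")
    return(out)
  }
  dist0 <- abs(peaks - 0.5)
  qstar <- max(peaks[dist0 == min(dist0)])  # tie -> higher-VAF peak
  if (qstar <= 0.35) {
    warn(sprintf(
      "closest peak to 0.5 is at %.3f (<= 0.35); no clonal adjustment",
      qstar))
    return(out)
  }
  cluster <- sample$vaf[abs(sample$vaf - qstar) <= 0.1]
  if (length(cluster) < 5) {
    warn("too few mutations around the clonal peak; sample unchanged")
    return(out)
  }
  mu_hat <- mean(cluster)  # Gaussian MLE of the cluster mean
  scale <- 0.5 / mu_hat
  out$vaf <- sample$vaf * scale
  attr(out, "clonal_scale") <- scale
  attr(out, "clonal_adjusted") <- TRUE
  out
}

density_peaks <- function(den, min_height = 0.05) {
  y <- den$y
  d1 <- diff(y)
  # local maxima: first derivative changes sign from positive to negative;
  # boundary wiggles below min_height x the modal density are discarded
  ix <- which(d1[-length(d1)] > 0 & d1[-1] <= 0) + 1
  ix <- ix[y[ix] >= min_height * max(y)]
  den$x[ix]
}

#' Heuristic clustering of mutations around estimated subclone frequencies
#'
#' Assigns every mutation to the neutral tail, a subclone, or the clonal
#' cluster using the expected binomial read-count variance rather than an
#' explicit mixture model. For each estimated subclone frequency `q`, the
#' window is `q +/- eps * sqrt(q (1 - q) / c)` where `c` is the mean
#' sequencing depth; mutations above the top subclone window (or, with no
#' subclones, above the lower edge of the clonal window
#' `0.5 +/- eps * sqrt(0.25 / c)`) are clonal, mutations below the lowest
#' window are tail, and overlapping subclone windows are split at their
#' midpoint.
#'
#' @param sample A `vaf_sample` (purity-corrected scale).
#' @param subclone_freqs Numeric vector (possibly empty) of subclone VAFs.
#' @param mean_depth Mean sequencing depth `c`; defaults to the sample
#'   attribute.
#' @param eps Window half-width in binomial standard deviations (default 2).
#' @param gmm_refine Optionally refine assignments with a Gaussian mixture
#'   (means seeded at `{q_i, 0.5}`; requires the mclust package).
#' @return A tibble of class `"cluster_assignment"`: per-mutation `vaf` and
#'   `cluster` (`tail`, `subclone_1`, `subclone_2`, `clonal`), with the
#'   window bounds in the `windows` attribute.
#' @export
heuristic_cluster <- function(sample, subclone_freqs,
                              mean_depth = attr(sample, "mean_depth"),
                              eps = 2, gmm_refine = FALSE) {
  stop_unless(!is.null(mean_depth) && mean_depth > 0,
              "`mean_depth` must be > 0")
  stop_unless(eps >= 0, "`eps` must be >= 0")
  q <- sort(as.numeric(subclone_freqs), decreasing = TRUE)
  stop_unless(all(q > 0 & q < 1), "subclone frequencies must be in (0, 1)")
  v <- sample$vaf
  cl_half <- eps * sqrt(0.25 / mean_depth)
  windows <- tibble(cluster = "clonal", q = 0.5, lower = 0.5 - cl_half,
                    upper = 0.5 + cl_half)
  if (length(q) > 0) {
    half <- eps * sqrt(q * (1 - q) / mean_depth)
    lo <- q - half
    hi <- q + half
    # overlapping subclone windows split at the midpoint between centres
    if (length(q) == 2 && lo[1] < hi[2]) {
      mid <- mean(q)
      lo[1] <- mid
      hi[2] <- mid
    }
    windows <- dplyr::bind_rows(
      windows,
      tibble(cluster = paste0("subclone_", seq_along(q)), q = q,
             lower = lo, upper = hi)
    )
  }
  lab <- rep("tail", length(v))
  if (length(q) > 0) {
    half <- eps * sqrt(q * (1 - q) / mean_depth)
    lo <- windows$lower[windows$cluster != "clonal"]
    hi <- windows$upper[windows$cluster != "clonal"]
    for (i in rev(seq_along(q))) {  # lowest first so higher windows win ties
      lab[v >= lo[i] & v <= hi[i]] <- paste0("subclone_", i)
    }
    lab[v > hi[1]] <- "clonal"
  } else {
    lab[v >= 0.5 - cl_half] <- "clonal"
  }
  if (gmm_refine && length(v) > 10) {
    lab <- gmm_refine_labels(v, q, lab)
  }
  out <- tibble(vaf = v, cluster = lab)
  class(out) <- c("cluster_assignment", class(out))
  attr(out, "windows") <- windows
  attr(out, "eps") <- eps
  attr(out, "mean_depth") <- mean_depth
  out
}

gmm_refine_labels <- function(v, q, lab) {
  if (!requireNamespace("mclust", quietly = TRUE)) {
    warn("mclust not available; skipping GMM refinement")
    return(lab)
  }
  centers <- c(q, 0.5)
  fit <- tryCatch(
    mclust::Mclust(v, G = length(centers) + 1, verbose = FALSE),
    error = function(e) NULL
  )
  if (is.null(fit)) return(lab)
  means <- fit$parameters$mean
  comp_label <- vapply(means, function(m) {
    d <- abs(c(centers, 0.05) - m)
    i <- which.min(d)
    if (i <= length(q)) paste0("subclone_", i)
    else if (i == length(q) + 1) "clonal"
    else "tail"
  }, character(1))
  comp_label[unname(fit$classification)]
}

#' Tumour age at biopsy in doublings
#'
#' `t_end = log2((1 - f_sub) * N_end)`: the number of population doublings of
#' the background (non-subclonal) population at biopsy.
#'
#' @param f_sub Subclone cellular fraction in `[0, 1)` (0 when no subclone).
#' @param n_end Final population size (>= 1).
#' @return Tumour age in doublings.
#' @examples
#' tumour_age(0.5, 2^10)  # 9
#' @export
tumour_age <- function(f_sub, n_end) {
  stop_unless(all(f_sub >= 0 & f_sub < 1), "`f_sub` must be in [0, 1)")
  stop_unless(all(n_end >= 1), "`n_end` must be >= 1")
  log2((1 - f_sub) * n_end)
}

#' Rescale simulated fitness and emergence time to a realistic tumour size
#'
#' Simulations run at small population sizes; fitness and emergence time
#' estimated under `N_sim` are rescaled to a true tumour size `N_real`
#' (default 10^10) using the linear relation between doublings and log
#' population size:
#' `t_s^R = t_s * log(N_real) / log(N_sim)`,
#' `t_end = log2((1 - f_sub) N_sim)`, `t_end^R = log2((1 - f_sub) N_real)`,
#' `w_R = 1 + (w - 1) (t_end - t_s) / (t_end^R - t_s^R)`.
#'
#' @param w Subclone fitness `(1 + s)` at simulated size (>= 1).
#' @param t_s Emergence time in doublings at simulated size.
#' @param f_sub Subclone cellular fraction in `[0, 1)`.
#' @param n_sim Simulated final population size.
#' @param n_real True tumour population size (default 1e10).
#' @return One-row tibble of class `"rescaled_estimates"`: `w`, `t_s`,
#'   `f_sub`, `n_sim`, `n_real`, `t_end`, `t_end_r`, `t_s_r`, `w_r`.
#' @export
rescale_estimates <- function(w, t_s, f_sub, n_sim, n_real = 1e10) {
  stop_unless(all(w >= 1), "`w` must be >= 1")
  stop_unless(all(t_s >= 0), "`t_s` must be >= 0")
  stop_unless(all(f_sub >= 0 & f_sub < 1), "`f_sub` must be in [0, 1)")
  stop_unless(all(n_sim > 1) && all(n_real > 1), "population sizes must be > 1")
  t_s_r <- t_s * log(n_real) / log(n_sim)
  t_end <- tumour_age(f_sub, n_sim)
  t_end_r <- tumour_age(f_sub, n_real)
  stop_unless(all(t_end_r > t_s_r),
              "non-physical rescale: t_end_R <= t_s_R")
  out <- tibble(w = w, t_s = t_s, f_sub = f_sub, n_sim = n_sim,
                n_real = n_real, t_end = t_end, t_end_r = t_end_r,
                t_s_r = t_s_r,
                w_r = 1 + (w - 1) * (t_end - t_s) / (t_end_r - t_s_r))
  class(out) <- c("rescaled_estimates", class(out))
  out
}
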