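#' Tumour-adapted Tajima's D
#'
#' Classical Tajima's D compares pairwise diversity with the segregating-site
#' estimator of the population mutation rate. The tumour adaptation treats
#' each somatic mutation's VAF as a derived-allele frequency (the reference
#' allele is ancestral, so no folding) and uses an effective sample size
#' `n = round(mean depth)`:
#' `theta_pi = sum(2 p_i (1 - p_i)) * n / (n - 1)`, `theta_W = S / a1` with
#' `a1 = sum(1/i, i = 1..n-1)`, and
#' `D = (theta_pi - theta_W) / sqrt(e1 S + e2 S (S - 1))` with the standard
#' variance constants. An excess of low-frequency variants (tumour growth)
#' drives D negative.
#'
#' @param sample A `vaf_sample`, or numeric VAFs (then supply `mean_depth`).
#' @param mean_depth Mean sequencing depth used as effective sample size.
#' @return One-row tibble with `statistic`, `theta_pi`, `theta_w`, `S`,
#'   `n_eff`, `degenerate` (TRUE when S = 0, statistic 0 by convention).
#' @export
tajimas_d <- function(sample, mean_depth = NULL) {
  x <- popgen_input(sample, mean_depth)
  p <- x$p
  n <- x$n
  S <- length(p)
  if (S == 0) {
    return(tibble(statistic = 0, theta_pi = 0, theta_w = 0, S = 0L,
                  n_eff = n, degenerate = TRUE))
  }
  stop_unless(n >= 2, "effective sample size must be >= 2")
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  theta_pi <- sum(2 * p * (1 - p)) * n / (n - 1)
  theta_w <- S / a1
  v <- e1 * S + e2 * S * (S - 1)
  d <- if (v > 0) (theta_pi - theta_w) / sqrt(v) else 0
  tibble(statistic = d, theta_pi = theta_pi, theta_w = theta_w,
         S = as.integer(S), n_eff = n, degenerate = S < 2)
}

#' Tumour-adapted Fay and Wu's H (unnormalized)
#'
#' `H = theta_pi - theta_H` with
#' `theta_H = sum(2 p_i^2) * n / (n - 1)`; high-frequency derived variants
#' (hitchhiking with a selected subclone) drive H negative. Same tumour
#' adaptation as [tajimas_d()]: VAFs are derived-allele frequencies, and
#' `n = round(mean depth)`.
#'
#' @inheritParams tajimas_d
#' @return One-row tibble with `statistic`, `theta_pi`, `theta_h`, `S`,
#'   `n_eff`, `degenerate`.
#' @export
fay_wu_h <- function(sample, mean_depth = NULL) {
  x <- popgen_input(sample, mean_depth)
  p <- x$p
  n <- x$n
  S <- length(p)
  if (S == 0) {
    return(tibble(statistic = 0, theta_pi = 0, theta_h = 0, S = 0L,
                  n_eff = n, degenerate = TRUE))
  }
  stop_unless(n >= 2, "effective sample size must be >= 2")
  theta_pi <- sum(2 * p * (1 - p)) * n / (n - 1)
  theta_h <- sum(2 * p^2) * n / (n - 1)
  tibble(statistic = theta_pi - theta_h, theta_pi = theta_pi,
         theta_h = theta_h, S = as.integer(S), n_eff = n,
         degenerate = S < 2)
}

popgen_input <- function(sample, mean_depth = NULL) {
  if (inherits(sample, "vaf_sample")) {
    p <- sample$vaf
    mean_depth <- mean_depth %||% attr(sample, "mean_depth")
  } else {
    p <- as.numeric(sample)
    stop_unless(!is.null(mean_depth), "`mean_depth` required for bare VAFs")
  }
  p <- p[p > 0 & p < 1]
  list(p = p, n = as.integer(round(mean_depth)))
}
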