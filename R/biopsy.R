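#' Beta-binomial random draws (intraclass-correlation parameterization)
#'
#' Parameterized by success probability `p` and overdispersion `rho` with
#' `a = p(1-rho)/rho`, `b = (1-p)(1-rho)/rho`, so that
#' `Var(X) = n p (1-p) (1 + (n-1) rho)`. `rho = 0` degenerates to the
#' binomial. Stated explicitly because `rho` conventions differ across
#' packages.
#'
#' @param n Number of draws.
#' @param size Number of trials (vector recycled to length `n`).
#' @param prob Success probability (vector recycled).
#' @param rho Overdispersion in `[0, 1)`.
#' @return Integer vector of counts.
#' @export
rbetabinom <- function(n, size, prob, rho = 0) {
  stop_unless(all(rho >= 0) && all(rho < 1), "`rho` must be in [0, 1)")
  size <- rep_len(size, n)
  prob <- rep_len(prob, n)
  if (all(rho == 0)) return(rbinom(n, size, prob))
  theta <- numeric(n)
  inner <- prob > 0 & prob < 1
  theta[prob >= 1] <- 1
  if (any(inner)) {
    a <- prob[inner] * (1 - rho) / rho
    b <- (1 - prob[inner]) * (1 - rho) / rho
    theta[inner] <- rbeta(sum(inner), a, b)
  }
  rbinom(n, size, theta)
}

#' Dilute true VAFs by tumour purity
#'
#' Normal-cell contamination contributes reference reads only, so each true
#' frequency is multiplied by `purity` before read sampling.
#'
#' @param vafs Numeric true VAFs.
#' @param purity Tumour cell fraction in `(0, 1]`.
#' @return Diluted VAFs.
#' @examples
#' apply_purity(0.5, 0.6)  # 0.30 expected observed centre
#' @export
apply_purity <- function(vafs, purity) {
  stop_unless(is.finite(purity) && purity > 0 && purity <= 1,
              "`purity` must be in (0, 1]")
  vafs * purity
}

#' Virtual biopsy: convert true cellular frequencies to observed read counts
#'
#' Per mutation with true VAF `f`: observed depth
#' `D_obs ~ Binomial(N, D/N)` (so `E(D_obs) = D`), alternate reads
#' `R_obs ~ BetaBinomial(D_obs, p = f * purity, rho)`, and
#' `VAF_obs = R_obs / D_obs`. Mutations with fewer than `min_alt_reads`
#' alternate reads are dropped (the variant-calling detection limit).
#'
#' @param truth A `tumour_truth` object, or a numeric vector of true VAFs in
#'   `(0, 0.5]`.
#' @param seq_params A [sequencing_params()] object.
#' @param seed Optional RNG seed.
#' @return A `vaf_sample`: a tibble with columns `chrom`, `pos`, `alt_count`,
#'   `depth`, `vaf` and attributes `mean_depth`, `purity`, `min_alt_reads`,
#'   `provenance` (`"synthetic"`) and `n_mutations`.
#' @export
virtual_biopsy <- function(truth, seq_params, seed = NULL) {
  stopifnot(inherits(seq_params, "sequencing_params"))
  validate_sequencing_params(seq_params)
  true_vafs <- if (inherits(truth, "tumour_truth")) {
    truth$mutations$vaf
  } else {
    as.numeric(truth)
  }
  stop_unless(all(true_vafs > 0 & true_vafs <= 0.5 + 1e-12),
              "true VAFs must lie in (0, 0.5]")
  pool <- seq_params$depth_pool %||%
    (if (inherits(truth, "tumour_truth")) attr(truth, "n_final") else NULL) %||%
    1000L
  if (is.na(pool)) pool <- 1000L
  stop_unless(seq_params$mean_depth / pool <= 1,
              "mean_depth / depth_pool must be <= 1")
  with_seed(seed, {
    m <- length(true_vafs)
    d_obs <- rbinom(m, as.integer(pool), seq_params$mean_depth / pool)
    p <- apply_purity(true_vafs, seq_params$purity)
    r_obs <- rbetabinom(m, d_obs, p, seq_params$rho)
    keep <- r_obs >= seq_params$min_alt_reads & d_obs > 0
    nk <- sum(keep)
    new_vaf_sample(
      tibble::new_tibble(list(
        chrom = rep("sim", nk), pos = seq_len(nk),
        alt_count = r_obs[keep], depth = d_obs[keep],
        vaf = r_obs[keep] / d_obs[keep]
      ), nrow = nk),
      mean_depth = seq_params$mean_depth,
      purity = seq_params$purity,
      min_alt_reads = seq_params$min_alt_reads,
      provenance = "synthetic"
    )
  })
}

new_vaf_sample <- function(df, mean_depth, purity, min_alt_reads = 2L,
                           provenance = "synthetic") {
  out <- as_tibble(df)
  class(out) <- c("vaf_sample", class(out))
  attr(out, "mean_depth") <- mean_depth
  attr(out, "purity") <- purity
  attr(out, "min_alt_reads") <- as.integer(min_alt_reads)
  attr(out, "provenance") <- provenance
  attr(out, "n_mutations") <- nrow(out)
  out
}

#' Construct a VAF sample from per-mutation read counts
#'
#' @param alt_count,depth Integer vectors of alternate read counts and total
#'   depths (`0 <= alt_count <= depth`).
#' @param chrom,pos Optional coordinates (synthetic placeholders otherwise).
#' @param mean_depth Sample-level mean sequencing depth; defaults to
#'   `mean(depth)`.
#' @param purity Tumour purity in `(0, 1]`.
#' @param min_alt_reads Call threshold; records below are dropped.
#' @param provenance `"synthetic"` or `"empirical"`.
#' @return A `vaf_sample` tibble.
#' @export
vaf_sample <- function(alt_count, depth, chrom = NULL, pos = NULL,
                       mean_depth = NULL, purity = 1, min_alt_reads = 2L,
                       provenance = "empirical") {
  stop_unless(length(alt_count) == length(depth),
              "`alt_count` and `depth` must have equal length")
  stop_unless(all(alt_count >= 0) && all(depth >= alt_count),
              "need 0 <= alt_count <= depth")
  keep <- alt_count >= min_alt_reads & depth > 0
  new_vaf_sample(
    tibble(
      chrom = (chrom %||% rep("NA", length(alt_count)))[keep],
      pos = (pos %||% seq_along(alt_count))[keep],
      alt_count = alt_count[keep], depth = depth[keep],
      vaf = alt_count[keep] / depth[keep]
    ),
    mean_depth = mean_depth %||% mean(depth[keep]),
    purity = purity, min_alt_reads = min_alt_reads, provenance = provenance
  )
}

#' @export
print.vaf_sample <- function(x, ...) {
  cat("<vaf_sample> ", nrow(x), " mutations | mean depth ",
      round(attr(x, "mean_depth"), 1), "x | purity ",
      attr(x, "purity"), " | ", attr(x, "provenance"), "\n", sep = "")
  NextMethod()
}
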