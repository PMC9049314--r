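#' Depth-conditioned lower frequency cutoff
#'
#' Returns `f_alt + 2 * sqrt(f_alt * (1 - f_alt) / c)`: the minimum callable
#' frequency (`min_alt_reads / mean_depth`) plus two binomial standard
#' deviations on the frequency scale. Mutations below this cutoff are
#' excluded from histogram features, which implicitly conditions the model
#' on mean sequencing depth.
#'
#' @param f_alt Minimum alternate reads to call a mutation divided by mean
#'   depth, in `[0, 1]`.
#' @param c Mean sequencing depth (> 0).
#' @return The cutoff frequency.
#' @examples
#' lower_cutoff(0.02, 100)  # 0.048
#' @export
lower_cutoff <- function(f_alt, c) {
  stop_unless(all(c > 0), "`c` must be > 0")
  stop_unless(all(f_alt >= 0 & f_alt <= 1), "`f_alt` must be in [0, 1]")
  f_alt + 2 * sqrt(f_alt * (1 - f_alt) / c)
}

#' VAF histogram feature vector
#'
#' Counts mutations into `k` equal-width bins over the fixed range
#' `[0.02, 0.50)` (bin width `0.48 / k`) for each `k` in `k_list`, and
#' concatenates the histograms in `k_list` order. Mutations below the
#' depth-conditioned [lower_cutoff()] or above 0.50 contribute to no bin.
#' The two default resolutions (64 and 128 bins) capture the VAF
#' distribution at different sparsity levels.
#'
#' @param sample A `vaf_sample`, or a numeric vector of observed VAFs (then
#'   `mean_depth` must be given).
#' @param k_list Histogram resolutions (default `c(64, 128)`).
#' @param normalize If `TRUE`, each histogram is divided by its total count
#'   (density mode); default `FALSE` (raw counts). Trained models record
#'   which mode was used.
#' @param mean_depth,min_alt_reads Override the sample attributes.
#' @return Numeric vector of class `"feature_vector"` of length
#'   `sum(k_list)` with attributes `cutoff`, `k_list`, `normalize`,
#'   `mean_depth`, `n_retained`.
#' @export
featurize <- function(sample, k_list = c(64, 128), normalize = FALSE,
                      mean_depth = NULL, min_alt_reads = NULL) {
  if (inherits(sample, "vaf_sample")) {
    vafs <- sample$vaf
    mean_depth <- mean_depth %||% attr(sample, "mean_depth")
    min_alt_reads <- min_alt_reads %||% attr(sample, "min_alt_reads") %||% 2L
  } else {
    vafs <- as.numeric(sample)
    stop_unless(!is.null(mean_depth), "`mean_depth` required for bare VAFs")
    min_alt_reads <- min_alt_reads %||% 2L
  }
  cutoff <- lower_cutoff(min_alt_reads / mean_depth, mean_depth)
  lo <- 0.02
  hi <- 0.50
  keep <- vafs >= max(cutoff, lo) & vafs <= hi
  v <- vafs[keep]
  # the upper edge is inclusive: a mutation exactly at 0.50 falls in the top
  # bin rather than outside the range
  vals <- unlist(lapply(k_list, function(k) {
    w <- (hi - lo) / k
    b <- pmin(floor((v - lo) / w), k - 1) + 1L
    h <- tabulate(b, nbins = k)
    if (normalize && sum(h) > 0) h <- h / sum(h)
    h
  }))
  structure(as.numeric(vals), class = "feature_vector", cutoff = cutoff,
            k_list = k_list, normalize = normalize, mean_depth = mean_depth,
            n_retained = length(v))
}

#' Featurize many samples into a matrix
#'
#' @param samples List of `vaf_sample` objects.
#' @param ... Passed to [featurize()].
#' @return Matrix with one row per sample (`length(samples)` x
#'   `sum(k_list)`).
#' @export
featurize_matrix <- function(samples, ...) {
  rows <- lapply(samples, function(s) as.numeric(featurize(s, ...)))
  do.call(rbind, rows)
}
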