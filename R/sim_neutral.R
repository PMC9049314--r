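#' Sample neutral-tail variant allele frequencies from a Pareto distribution
#'
#' Neutral mutation accumulation in an exponentially growing, non-recombining
#' population produces a power-law (Pareto) frequency tail. Draws use the
#' inverse-CDF `m * U^(-1/alpha)`; draws above 0.5 (outside diploid
#' heterozygous VAF support) are resampled rather than clipped.
#'
#' @param n Number of draws.
#' @param shape Pareto shape `alpha` (> 0).
#' @param scale Pareto scale `m`, in `(0, 0.5)`; the distribution's minimum.
#' @param seed Optional RNG seed.
#' @return Numeric vector of `n` true VAFs in `[m, 0.5]`.
#' @examples
#' x <- sample_pareto(1000, shape = 1, scale = 0.05, seed = 1)
#' min(x) >= 0.05
#' @export
sample_pareto <- function(n, shape, scale, seed = NULL) {
  stop_unless(is.finite(shape) && shape > 0, "`shape` must be > 0")
  stop_unless(is.finite(scale) && scale > 0 && scale < 0.5,
              "`scale` must be in (0, 0.5)")
  stop_unless(n >= 0, "`n` must be >= 0")
  with_seed(seed, {
    x <- scale * runif(n)^(-1 / shape)
    bad <- which(x > 0.5)
    while (length(bad) > 0) {
      x[bad] <- scale * runif(length(bad))^(-1 / shape)
      bad <- bad[x[bad] > 0.5]
    }
    x
  })
}

#' Maximum-likelihood Pareto fit
#'
#' The MLE of the scale is the minimum observed frequency; the MLE of the
#' shape is `n / sum(log(x / m))` (Hill estimator).
#'
#' @param x Positive frequencies.
#' @return One-row tibble with `shape` and `scale`.
#' @export
fit_pareto <- function(x) {
  stop_unless(length(x) > 0 && all(x > 0), "`x` must be positive")
  m <- min(x)
  tibble(shape = length(x) / sum(log(x / m)), scale = m)
}

#' Default sampling distribution for the Pareto shape
#'
#' Patient-tumour Pareto fits are not shipped with the package; the default
#' shape-sampling distribution is a log-normal with median 1 (sdlog 0.35),
#' truncated to `[0.5, 3]` by resampling. A user-supplied table of empirical
#' shapes can be passed to [generate_pair()] instead.
#'
#' @param n Number of draws.
#' @return Numeric vector of shape parameters.
#' @export
sample_pareto_shape <- function(n) {
  x <- rlnorm(n, meanlog = 0, sdlog = 0.35)
  bad <- which(x < 0.5 | x > 3)
  while (length(bad) > 0) {
    x[bad] <- rlnorm(length(bad), meanlog = 0, sdlog = 0.35)
    bad <- bad[x[bad] < 0.5 | x[bad] > 3]
  }
  x
}

#' Generate a neutral tumour from the Pareto + clonal-peak sampler
#'
#' True VAFs are `n_tail` Pareto draws (the neutral tail) plus `n_clonal`
#' clonal mutations at `clonal_center` (a point mass pre-noise; the dispersed
#' clonal peak of observed data arises from beta-binomial reads in
#' [virtual_biopsy()]). With probability `p_trim` all tail mutations below
#' `trim_f` are removed, emulating patient samples that lack the
#' characteristic low-frequency tail. Labels are always neutral / 0
#' subclones.
#'
#' @param params A [neutral_params()] object.
#' @return A `tumour_truth` object (no driver lineages).
#' @export
generate_neutral <- function(params) {
  stopifnot(inherits(params, "neutral_params"))
  validate_neutral_params(params)
  with_seed(params$seed, {
    tail_vafs <- sample_pareto(params$n_tail, params$pareto_shape,
                               params$pareto_scale)
    trimmed <- FALSE
    if (params$n_tail > 0 && runif(1) < params$p_trim) {
      f <- params$trim_f %||% runif(1, 0.10, 0.30)
      tail_vafs <- tail_vafs[tail_vafs >= f]
      trimmed <- TRUE
    }
    vafs <- c(tail_vafs, rep(params$clonal_center, params$n_clonal))
    is_clonal <- c(rep(FALSE, length(tail_vafs)),
                   rep(TRUE, params$n_clonal))
    out <- list(
      mutations = tibble(vaf = vafs, cell_count = NA_integer_,
                         is_driver = FALSE, s = 0),
      driver_lineages = tibble(genotype = integer(0),
                               cellular_fraction = numeric(0),
                               cum_fitness = numeric(0)),
      labels = NULL
    )
    class(out) <- "tumour_truth"
    attr(out, "n_final") <- NA_integer_
    attr(out, "params") <- params
    attr(out, "trimmed") <- trimmed
    attr(out, "is_clonal") <- is_clonal
    out$labels <- label_subclones(out)
    out
  })
}

#' Generate a matched selection/neutral pair of virtual biopsies
#'
#' Runs the stochastic selection simulator and then constructs a paired
#' neutral realization with the same clonal mutation count, the same total
#' non-clonal mutation count (as the Pareto tail size), and identical
#' sequencing parameters, so that the two arms differ only in the presence of
#' selected subclonal peaks. The Pareto scale of the neutral arm is set to the
#' minimum non-clonal true VAF of the selection arm (the Pareto MLE
#' convention); the shape is drawn from `shape_sampler`. The neutral arm's
#' clonal peak is shifted uniformly to 45-50% VAF and its tail trimmed with
#' probability `p_trim`. Selection simulations flagged with more than two
#' detectable subclones are regenerated (up to `max_regen` times).
#'
#' @param sel_params A [selection_params()] object.
#' @param seq_params A [sequencing_params()] object shared by both arms.
#' @param seed Optional RNG seed (covers both arms).
#' @param shape_sampler Function `n -> shapes` (default
#'   [sample_pareto_shape()]).
#' @param p_trim Tail-trim probability for the neutral arm (default 0.05).
#' @param min_cells Carrier-count floor passed to [simulate_tumour()].
#' @param max_regen Regeneration cap for unusable selection simulations.
#'
#' @return List with elements `selected` and `neutral`, each a list with
#'   `sample` (a [virtual_biopsy()] result) and `labels`
#'   (a `subclone_labels`), plus `n_regenerated`.
#' @export
generate_pair <- function(sel_params, seq_params, seed = NULL,
                          shape_sampler = sample_pareto_shape,
                          p_trim = 0.05, min_cells = 1L, max_regen = 20L) {
  stopifnot(inherits(sel_params, "selection_params"),
            inherits(seq_params, "sequencing_params"))
  with_seed(seed, {
    regen <- 0L
    repeat {
      truth <- simulate_tumour(strip_seed(sel_params), min_cells = min_cells)
      if (truth$labels$usable) break
      regen <- regen + 1L
      if (regen > max_regen) {
        abort("exceeded `max_regen` regenerations of unusable simulations")
      }
    }
    nonclonal <- truth$mutations$vaf[truth$mutations$vaf < 0.5 - 1e-12]
    n_clonal_sel <- nrow(truth$mutations) - length(nonclonal)
    scale <- if (length(nonclonal)) {
      min(max(min(nonclonal), 1e-4), 0.45)
    } else 0.02
    np <- neutral_params(
      pareto_shape = shape_sampler(1),
      pareto_scale = scale,
      n_tail = length(nonclonal),
      n_clonal = n_clonal_sel,
      p_trim = p_trim,
      clonal_center = runif(1, 0.45, 0.50)
    )
    ntruth <- generate_neutral(np)
    pool <- seq_params$depth_pool %||% attr(truth, "n_final")
    seqp <- seq_params
    seqp$depth_pool <- max(pool, ceiling(seq_params$mean_depth))
    list(
      selected = list(sample = virtual_biopsy(truth, seqp),
                      labels = truth$labels),
      neutral = list(sample = virtual_biopsy(ntruth, seqp),
                     labels = ntruth$labels),
      n_regenerated = regen,
      meta = tibble(
        arm = c("selected", "neutral"),
        n_clonal = c(n_clonal_sel, np$n_clonal),
        n_total = c(nrow(truth$mutations), nrow(ntruth$mutations)),
        trimmed = c(FALSE, isTRUE(attr(ntruth, "trimmed")))
      )
    )
  })
}

strip_seed <- function(params) {
  params$seed <- NULL
  params
}
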