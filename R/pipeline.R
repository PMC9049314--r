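#' Run configuration for end-to-end estimation
#'
#' @param purity Sample purity in `(0, 1]`.
#' @param mean_depth Mean sequencing depth.
#' @param T Monte Carlo dropout passes (>= 2; default 50).
#' @param eps Cluster-window half-width in binomial SDs (default 2).
#' @param min_mutations Inclusion filter: samples with fewer mutations are
#'   flagged (default 100), and refused under `strict`.
#' @param min_effective_coverage Inclusion filter on `purity * mean_depth`
#'   (default 60).
#' @param strict Refuse samples failing the filters instead of warning.
#' @param seed Optional RNG seed for the stochastic passes.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(purity = 1, mean_depth = NULL, T = 50, eps = 2,
                       min_mutations = 100, min_effective_coverage = 60,
                       strict = FALSE, seed = NULL) {
  stop_unless(purity > 0 && purity <= 1, "`purity` must be in (0, 1]")
  stop_unless(T >= 2, "`T` must be >= 2")
  structure(list(purity = purity, mean_depth = mean_depth, T = as.integer(T),
                 eps = eps, min_mutations = as.integer(min_mutations),
                 min_effective_coverage = min_effective_coverage,
                 strict = strict, seed = seed),
            class = "run_config")
}

#' End-to-end evolutionary inference on one VAF sample
#'
#' Applies the full pipeline: purity correction, clonal-peak adjustment,
#' featurization, Monte Carlo dropout prediction, the parsimony evolutionary
#' call, subclone frequency estimation, and heuristic clustering. QC flags
#' are raised (and, under `strict`, the sample refused) when the sample has
#' fewer than `min_mutations` mutations or effective coverage
#' (`purity * mean_depth`) below `min_effective_coverage`.
#'
#' @param sample A `vaf_sample` (see [read_vaf_input()], [virtual_biopsy()]).
#' @param models An `"evolution_models"` list (elements `ms`, `s1`, `s2`)
#'   from [train_evolution_models()].
#' @param cfg A [run_config()].
#' @return An `"evolution_report"`: list with `call` (the
#'   [call_evolution()] result), `frequencies` (list of
#'   [posterior_summary()]), `clusters` (a [heuristic_cluster()] tibble),
#'   `qc` (named logical flags), `metadata`.
#' @export
run_estimate <- function(sample, models, cfg = run_config()) {
  stopifnot(inherits(sample, "vaf_sample"))
  mean_depth <- cfg$mean_depth %||% attr(sample, "mean_depth")
  purity <- cfg$purity %||% attr(sample, "purity") %||% 1
  eff_cov <- purity * mean_depth
  qc <- list(
    low_mutation_count = nrow(sample) < cfg$min_mutations,
    low_effective_coverage = eff_cov < cfg$min_effective_coverage,
    clonal_peak_adjusted = FALSE
  )
  if (cfg$strict && qc$low_mutation_count) {
    abort(sprintf(
      "sample has %d mutations (< %d required under strict mode)",
      nrow(sample), cfg$min_mutations))
  }
  if (cfg$strict && qc$low_effective_coverage) {
    abort(sprintf(
      "effective coverage %.1fx (< %.0fx required under strict mode)",
      eff_cov, cfg$min_effective_coverage))
  }
  if (qc$low_mutation_count) {
    warn(sprintf("sample has only %d mutations; estimates may be unreliable",
                 nrow(sample)))
  }
  if (qc$low_effective_coverage) {
    warn(sprintf("effective coverage %.1fx is below %.0fx", eff_cov,
                 cfg$min_effective_coverage))
  }
  corrected <- purity_correct(sample, purity)
  adjusted <- if (nrow(corrected) >= cfg$min_mutations) {
    suppressWarnings(clonal_peak_adjust(corrected, cfg$min_mutations))
  } else {
    corrected
  }
  qc$clonal_peak_adjusted <- isTRUE(attr(adjusted, "clonal_adjusted"))
  fv <- featurize(adjusted, k_list = models$ms$spec$k_list,
                  normalize = models$ms$meta$featurization$normalize,
                  mean_depth = mean_depth)
  mcp <- mc_predict(models$ms, as.numeric(fv), T = cfg$T, seed = cfg$seed)
  post <- posterior_for(mcp, 1)
  call <- call_evolution(post$p_sel, post$p_nsub)
  net2 <- models$s2 %||% models$s1
  freqs <- estimate_frequencies(models$s1, net2, as.numeric(fv), call,
                                T = cfg$T, seed = cfg$seed)
  clusters <- heuristic_cluster(
    adjusted, vapply(freqs, function(s) s$mean, numeric(1)),
    mean_depth = mean_depth, eps = cfg$eps
  )
  out <- list(
    call = call, frequencies = freqs, clusters = clusters, qc = qc,
    metadata = list(
      n_mutations = nrow(sample), mean_depth = mean_depth, purity = purity,
      effective_coverage = eff_cov,
      clonal_scale = attr(adjusted, "clonal_scale") %||% 1,
      feature_cutoff = attr(fv, "cutoff"), T = cfg$T, eps = cfg$eps
    )
  )
  class(out) <- "evolution_report"
  out
}

#' @export
print.evolution_report <- function(x, ...) {
  cat("<evolution_report> mode = ", x$call$mode, ", n_subclones = ",
      x$call$n_subclones, "\n", sep = "")
  cat(sprintf("  P(Selection) = %.3f [%.3f, %.3f]\n", x$call$p_sel$mean,
              x$call$p_sel$eti_lower, x$call$p_sel$eti_upper))
  for (i in seq_along(x$frequencies)) {
    s <- x$frequencies[[i]]
    cat(sprintf("  subclone %d VAF = %.3f [%.3f, %.3f]\n", i, s$mean,
                s$eti_lower, s$eti_upper))
  }
  flags <- names(x$qc)[vapply(x$qc, isTRUE, logical(1))]
  if (length(flags)) cat("  QC flags:", paste(flags, collapse = ", "), "\n")
  invisible(x)
}
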