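#' Simulate an exponentially growing tumour with stochastic driver arrival
#'
#' Grows a population from a single founder cell (carrying `n_clonal` clonal
#' mutations) to `n_final` cells under a rejection-kinetic branching process.
#' At every division each daughter cell acquires `Poisson(mutation_rate)` new
#' mutations; each new mutation is a driver with probability `p_driver` (until
#' `max_drivers` driver events occurred), receives a selection coefficient
#' `s ~ Exponential(mean = s_mean)`, and multiplies the lineage growth rate by
#' `(1 + s)` (multiplicative fitness across drivers). Cells are sampled for
#' division or death with probability proportional to their rates via
#' rejection sampling; time is tracked only in division counts.
#'
#' @param params A [selection_params()] object.
#' @param min_cells Minimum carrier cell count for a mutation to be retained
#'   in the output (default 1 = keep everything). Raising it discards
#'   mutations below the corresponding true VAF, which is convenient when
#'   generating large training sets where sub-detection-limit mutations can
#'   never be observed.
#'
#' @return A `tumour_truth` object: a list with
#'   * `mutations`: tibble with `vaf` (true VAF, carrier cells / 2N),
#'     `cell_count`, `is_driver`, `s`;
#'   * `driver_lineages`: tibble with per-driver-genotype `cellular_fraction`
#'     and cumulative fitness `Pi(1+s)`;
#'   * `labels`: a [label_subclones()] result;
#'   * attributes `n_final` and `params`.
#' @examples
#' p <- selection_params(mutation_rate = 20, p_driver = 0, n_final = 200,
#'                       seed = 1)
#' tt <- simulate_tumour(p)
#' tt$labels$mode
#' @export
simulate_tumour <- function(params, min_cells = 1L) {
  stopifnot(inherits(params, "selection_params"))
  validate_selection_params(params)
  with_seed(params$seed, {
    raw <- cpp_sim_selection(
      params$mutation_rate, params$p_driver, params$s_mean, params$n_clonal,
      params$max_drivers, params$n_final, params$birth_rate,
      params$death_rate, params$max_retries
    )
    truth_from_raw(raw, params$n_final, params, min_cells)
  })
}

truth_from_raw <- function(raw, n_final, params, min_cells = 1L) {
  keep <- raw$carriers >= max(1L, min_cells)
  n_new <- raw$n_new[keep]
  n_drv <- raw$n_driver[keep]
  carriers <- raw$carriers[keep]
  vaf_g <- carriers / (2 * n_final)
  total <- n_new + n_drv
  idx <- rep.int(seq_along(total), total)
  drv_flag <- sequence(total) <= rep.int(n_drv, total)
  s_col <- numeric(length(idx))
  # driver rows carry the cumulative fitness advantage Pi(1+s) - 1 of their
  # lineage (identical to the driver's own s for single-driver lineages)
  s_col[drv_flag] <- raw$cum_fitness[keep][idx[drv_flag]] - 1
  mutations <- tibble::new_tibble(list(
    vaf = vaf_g[idx],
    cell_count = carriers[idx],
    is_driver = drv_flag,
    s = s_col
  ), nrow = length(idx))
  drv_geno <- which(raw$n_driver > 0 & raw$carriers > 0)
  driver_lineages <- tibble::new_tibble(list(
    genotype = drv_geno,
    cellular_fraction = raw$carriers[drv_geno] / n_final,
    cum_fitness = raw$cum_fitness[drv_geno]
  ), nrow = length(drv_geno))
  out <- list(mutations = mutations, driver_lineages = driver_lineages,
              labels = NULL)
  class(out) <- "tumour_truth"
  attr(out, "n_final") <- n_final
  attr(out, "params") <- params
  out$labels <- label_subclones(out)
  out
}

#' @export
print.tumour_truth <- function(x, ...) {
  cat("<tumour_truth> ", nrow(x$mutations), " mutations, ",
      nrow(x$driver_lineages), " driver lineage(s); mode = ",
      x$labels$mode, ", n_subclones = ", x$labels$n_subclones, "\n", sep = "")
  invisible(x)
}

#' Label detectable subclones in a simulated tumour
#'
#' A detectable subclone is a driver lineage whose VAF (cellular fraction / 2)
#' falls inside `window` (default 10-40% VAF, i.e. 20-80% cellular fraction).
#' Lineages whose VAFs differ by less than `merge_gap` are merged and reported
#' as one subclone at the largest lineage's VAF. Simulations with more than
#' two detectable subclones are flagged unusable for the 0/1/2 label scheme
#' rather than raising an error.
#'
#' @param truth A `tumour_truth` object with `driver_lineages` populated.
#' @param window Detectability window on the VAF scale (default
#'   `c(0.10, 0.40)`).
#' @param merge_gap Minimum VAF separation between distinct subclones
#'   (default 0.05).
#'
#' @return A list of class `"subclone_labels"` with `mode`
#'   (`"neutral"`/`"selection"`), `n_subclones` (0, 1, 2), `subclone_vafs`
#'   (sorted descending) and `usable` (FALSE when > 2 detectable subclones).
#' @export
label_subclones <- function(truth, window = c(0.10, 0.40), merge_gap = 0.05) {
  dl <- truth$driver_lineages
  vafs <- numeric(0)
  if (!is.null(dl) && nrow(dl) > 0) {
    v <- dl$cellular_fraction / 2
    vafs <- sort(v[v >= window[1] & v <= window[2]], decreasing = TRUE)
  }
  merged <- numeric(0)
  if (length(vafs) > 0) {
    merged <- vafs[1]
    for (v in vafs[-1]) {
      if (merged[length(merged)] - v >= merge_gap) merged <- c(merged, v)
    }
  }
  n <- length(merged)
  out <- list(
    mode = if (n == 0) "neutral" else "selection",
    n_subclones = min(n, 2L),
    subclone_vafs = head(merged, 2L),
    usable = n <= 2
  )
  class(out) <- "subclone_labels"
  out
}

#' @export
print.subclone_labels <- function(x, ...) {
  cat("<subclone_labels> mode = ", x$mode, ", n_subclones = ", x$n_subclones,
      if (!x$usable) " (unusable: >2 detectable subclones)" else "",
      "\n", sep = "")
  if (length(x$subclone_vafs)) {
    cat("  subclone VAFs:", paste(round(x$subclone_vafs, 3), collapse = ", "),
        "\n")
  }
  invisible(x)
}
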