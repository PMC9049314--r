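#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a trained network's layer structure
#'
#' @param x An `evo_net`.
#' @param ... Unused.
#' @return Tibble with one row per parameter tensor: `name`, `n_params`.
#' @export
tidy.evo_net <- function(x, ...) {
  tibble(name = names(x$par),
         n_params = vapply(x$par, length, numeric(1)))
}

#' @rdname tidy.evo_net
#' @export
tidy.evo_net_transfer <- function(x, ...) {
  tibble(name = names(x$par),
         n_params = vapply(x$par, length, numeric(1)))
}

#' One-row summary of a trained network
#'
#' @param x An `evo_net` or `evo_net_transfer`.
#' @param ... Unused.
#' @return Tibble with task, parameter count, epochs trained and final
#'   validation loss.
#' @export
glance.evo_net <- function(x, ...) {
  h <- x$meta$history
  tibble(
    task = x$spec$task,
    n_params = n_params(x),
    trained = isTRUE(x$meta$trained),
    epochs = if (is.null(h)) 0L else nrow(h),
    val_loss = if (is.null(h)) NA_real_ else min(h$val_loss)
  )
}

#' @rdname glance.evo_net
#' @export
glance.evo_net_transfer <- function(x, ...) {
  h <- x$meta$history
  tibble(
    task = paste(x$tasks, collapse = "+"),
    n_params = n_params(x),
    trained = isTRUE(x$meta$trained),
    epochs = if (is.null(h)) 0L else nrow(h),
    val_loss = if (is.null(h)) NA_real_ else min(h$val_loss)
  )
}

#' Tidy an evolution report
#'
#' @param x An `evolution_report`.
#' @param ... Unused.
#' @return Tibble with one row per reported quantity (`p_selection`,
#'   `p_0/1/2_subclones`, subclone frequencies): `term`, `estimate`,
#'   `eti_lower`, `eti_upper`.
#' @export
tidy.evolution_report <- function(x, ...) {
  rows <- list(post_row("p_selection", x$call$p_sel))
  for (k in 1:3) {
    rows <- c(rows, list(post_row(sprintf("p_%d_subclones", k - 1),
                                  x$call$p_nsub[[k]])))
  }
  for (i in seq_along(x$frequencies)) {
    rows <- c(rows, list(post_row(sprintf("subclone_%d_vaf", i),
                                  x$frequencies[[i]])))
  }
  dplyr::bind_rows(rows)
}

post_row <- function(term, s) {
  tibble(term = term, estimate = s$mean, eti_lower = s$eti_lower,
         eti_upper = s$eti_upper)
}

#' One-row summary of an evolution report
#'
#' @param x An `evolution_report`.
#' @param ... Unused.
#' @return Tibble with the call, sample metadata and QC flags.
#' @export
glance.evolution_report <- function(x, ...) {
  tibble(
    mode = x$call$mode,
    n_subclones = x$call$n_subclones,
    p_selection = x$call$p_sel$mean,
    n_mutations = x$metadata$n_mutations,
    mean_depth = x$metadata$mean_depth,
    purity = x$metadata$purity,
    effective_coverage = x$metadata$effective_coverage,
    low_mutation_count = x$qc$low_mutation_count,
    low_effective_coverage = x$qc$low_effective_coverage,
    clonal_peak_adjusted = x$qc$clonal_peak_adjusted
  )
}

#' Tidy a posterior summary
#'
#' @param x A `posterior_summary`.
#' @param ... Unused.
#' @return One-row tibble with `estimate`, `eti_lower`, `eti_upper`, `T`.
#' @export
tidy.posterior_summary <- function(x, ...) {
  tibble(estimate = x$mean, eti_lower = x$eti_lower, eti_upper = x$eti_upper,
         T = x$T, level = x$level)
}
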