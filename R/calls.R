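#' Posterior summaries for one sample from an MC-dropout prediction
#'
#' @param mcp An `"mc_posterior"` from [mc_predict()].
#' @param i Sample (row) index.
#' @param level ETI mass (default 0.89).
#' @return For task `"ms"`: list with `p_sel` (a [posterior_summary()]) and
#'   `p_nsub` (list of 3 summaries for 0/1/2 subclones). For `"1s"`/`"2s"`:
#'   list of frequency summaries.
#' @export
posterior_for <- function(mcp, i = 1, level = 0.89) {
  stopifnot(inherits(mcp, "mc_posterior"))
  if (mcp$task == "ms") {
    list(
      p_sel = posterior_summary(mcp$sel[, i], level),
      p_nsub = lapply(1:3, function(k) {
        posterior_summary(mcp$nsub[, i, k], level)
      })
    )
  } else if (mcp$task == "1s") {
    list(posterior_summary(mcp$freq[, i], level))
  } else {
    lapply(1:2, function(k) posterior_summary(mcp$freq[, i, k], level))
  }
}

#' Parsimony-based evolutionary call
#'
#' Positive selection is called only if the lower bound of the 89%
#' equal-tailed interval of P(Selection) exceeds 0.5; otherwise the sample is
#' called neutral with zero subclones, independent of the subclone-number
#' head. Under selection the subclone number is the class whose ETI lower
#' bound exceeds 0.5; if no class passes, the call falls back to the class
#' (1 or 2) with the larger posterior mean, ties broken toward fewer
#' subclones.
#'
#' @param p_sel [posterior_summary()] of P(Selection).
#' @param p_nsub List of three [posterior_summary()] objects for
#'   P(0/1/2 subclones).
#' @return List of class `"evolution_call"`: `mode`, `n_subclones`, `p_sel`,
#'   `p_nsub`.
#' @export
call_evolution <- function(p_sel, p_nsub) {
  stopifnot(inherits(p_sel, "posterior_summary"), length(p_nsub) == 3)
  if (p_sel$eti_lower <= 0.5) {
    out <- list(mode = "neutral", n_subclones = 0L, p_sel = p_sel,
                p_nsub = p_nsub)
  } else {
    lowers <- vapply(p_nsub, function(s) s$eti_lower, numeric(1))
    passing <- which(lowers > 0.5)
    passing <- passing[passing > 1]  # selection implies >= 1 subclone
    n <- if (length(passing) >= 1) {
      passing[1] - 1L
    } else {
      means <- vapply(p_nsub, function(s) s$mean, numeric(1))[2:3]
      if (means[2] > means[1]) 2L else 1L
    }
    out <- list(mode = "selection", n_subclones = as.integer(n),
                p_sel = p_sel, p_nsub = p_nsub)
  }
  class(out) <- "evolution_call"
  out
}

#' @export
print.evolution_call <- function(x, ...) {
  cat("<evolution_call> mode = ", x$mode, ", n_subclones = ",
      x$n_subclones, "\n  P(Selection) ", sep = "")
  print(x$p_sel)
  invisible(x)
}

#' Subclone frequency posteriors for a called sample
#'
#' Dispatches on the evolutionary call: one posterior from the single-
#' subclone regressor when one subclone is called, two (sorted descending)
#' from the two-subclone regressor when two are called, and an empty list
#' under neutrality.
#'
#' @param net_1s,net_2s Trained frequency regressors (`"1s"`, `"2s"`).
#' @param features Feature vector or one-row matrix for the sample.
#' @param call An [call_evolution()] result.
#' @param T MC dropout passes (default 50).
#' @param seed Optional RNG seed.
#' @return List of [posterior_summary()] objects (length `n_subclones`),
#'   sorted by descending mean frequency.
#' @export
estimate_frequencies <- function(net_1s, net_2s, features, call, T = 50,
                                 seed = NULL) {
  stopifnot(inherits(call, "evolution_call"))
  if (call$n_subclones == 0) return(list())
  if (call$n_subclones == 1) {
    mcp <- mc_predict(net_1s, features, T = T, seed = seed)
    posterior_for(mcp, 1)
  } else {
    mcp <- mc_predict(net_2s, features, T = T, seed = seed)
    out <- posterior_for(mcp, 1)
    out[order(vapply(out, function(s) s$mean, numeric(1)),
              decreasing = TRUE)]
  }
}
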