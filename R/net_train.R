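#' Training configuration
#'
#' @param learning_rate Adam learning rate, in `[1e-7, 1e-3]`.
#' @param batch_size Minibatch size (default 256).
#' @param max_epochs Maximum passes over the training pool (default 4).
#' @param patience Early-stopping patience in epochs (3-5).
#' @param min_epochs Warm-up: early stopping cannot trigger before this many
#'   epochs (default 10), protecting against transient plateaus early in
#'   optimization.
#' @param fp_penalty Weight on the negative-class term of the binary
#'   cross-entropy for P(Selection); raising it penalizes false positive
#'   selection calls, trading recall for precision.
#' @param val_frac Fraction of the pool held out for early-stopping
#'   validation.
#' @param rebalance Apply frequency rebalancing before each epoch (default
#'   TRUE).
#' @param seed Optional RNG seed for the whole training run.
#' @return A list of class `"train_config"`.
#' @export
train_config <- function(learning_rate = 1e-3, batch_size = 256,
                         max_epochs = 4, patience = 4, min_epochs = 10,
                         fp_penalty = 1, val_frac = 0.1, rebalance = TRUE,
                         seed = NULL) {
  stop_unless(learning_rate >= 1e-7 && learning_rate <= 1e-3,
              "`learning_rate` must be in [1e-7, 1e-3]")
  stop_unless(patience >= 3 && patience <= 5, "`patience` must be in 3-5")
  stop_unless(batch_size >= 1, "`batch_size` must be >= 1")
  stop_unless(fp_penalty > 0, "`fp_penalty` must be > 0")
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 min_epochs = as.integer(min_epochs),
                 fp_penalty = fp_penalty,
                 val_frac = val_frac, rebalance = rebalance, seed = seed),
            class = "train_config")
}

#' Rebalance a batch of labelled simulations by subclone frequency
#'
#' Positive-selection simulations are downsampled so that every subclone
#' frequency (rounded to two decimals) is equally represented: one-subclone
#' simulations are balanced on the subclone VAF, two-subclone simulations on
#' the inter-subclone distance `|f2 - f1|` and filtered to distances greater
#' than 0.05 VAF. Neutral simulations pass through unchanged (for the
#' classification task); the regression tasks use only positive simulations.
#'
#' @param labels Tibble with columns `n_subclones`, `f1`, `f2` (`NA` when
#'   absent).
#' @param task `"ms"`, `"1s"` or `"2s"`.
#' @param min_gap Minimum inter-subclone distance for two-subclone
#'   simulations (default 0.05).
#' @return Integer vector of retained row indices.
#' @export
rebalance <- function(labels, task = c("ms", "1s", "2s"), min_gap = 0.05) {
  task <- match.arg(task)
  n1 <- which(labels$n_subclones == 1)
  n2 <- which(labels$n_subclones == 2)
  bal1 <- balance_strata(n1, round(labels$f1[n1], 2))
  gap2 <- abs(labels$f1[n2] - labels$f2[n2])
  n2 <- n2[gap2 > min_gap]
  bal2 <- balance_strata(n2, round(abs(labels$f1[n2] - labels$f2[n2]), 2))
  switch(task,
    ms = sort(c(which(labels$n_subclones == 0), bal1, bal2)),
    `1s` = {
      if (length(bal1) == 0) warn("no one-subclone simulations to rebalance")
      bal1
    },
    `2s` = {
      if (length(bal2) == 0) {
        warn("no two-subclone simulations with gap > min_gap")
      }
      bal2
    }
  )
}

balance_strata <- function(idx, strata) {
  if (length(idx) == 0) return(integer(0))
  groups <- split(idx, strata)
  m <- min(lengths(groups))
  unlist(lapply(groups, function(g) {
    if (length(g) == m) g else sample(g, m)
  }), use.names = FALSE)
}

# Per-task loss and output-gradient. Y is a list:
#  ms: y_sel (0/1), y_nsub (0/1/2); 1s: f1; 2s: f1, f2 (f1 >= f2).
net_loss <- function(spec, out, Y, fp_penalty = 1) {
  B <- nrow(out[[1]])
  if (spec$task == "ms") {
    p <- sigmoid(out$sel)
    eps <- 1e-12
    y <- Y$y_sel
    l_sel <- -mean(y * log(p + eps) +
                     fp_penalty * (1 - y) * log(1 - p + eps))
    d_sel <- (p * (y + fp_penalty * (1 - y)) - y) / B
    P <- softmax_rows(out$nsub)
    oh <- matrix(0, B, 3)
    oh[cbind(seq_len(B), Y$y_nsub + 1)] <- 1
    l_ns <- -mean(log(P[cbind(seq_len(B), Y$y_nsub + 1)] + eps))
    d_ns <- (P - oh) / B
    list(loss = l_sel + l_ns, dout = list(sel = d_sel, nsub = d_ns))
  } else if (spec$task == "1s") {
    r <- out$freq - Y$f1
    list(loss = mean(abs(r)), dout = list(freq = sign(r) / B))
  } else {
    tgt <- cbind(Y$f1, Y$f2)
    r <- out$freq - tgt
    list(loss = mean(abs(r)), dout = list(freq = sign(r) / (2 * B)))
  }
}

#' Train a multi-task network on labelled feature vectors
#'
#' Minimizes the cross-entropy losses (classification heads, with a
#' configurable penalty on false positive selection calls) or the L1 loss
#' (frequency regression) with Adam, minibatches of `batch_size`, per-epoch
#' frequency [rebalance()]-ing of the training pool, and early stopping on a
#' held-out validation split. The best-validation weights are restored at the
#' end.
#'
#' @param net An untrained (or previously trained) `evo_net`.
#' @param features Numeric matrix, one row per simulation.
#' @param labels Tibble with `mode`, `n_subclones`, `f1`, `f2`.
#' @param cfg A [train_config()].
#' @param verbose Print per-epoch losses.
#' @return The trained `evo_net`, with `meta$history` (per-epoch train and
#'   validation loss) and the configuration recorded.
#' @export
train <- function(net, features, labels, cfg = train_config(),
                  verbose = FALSE) {
  stopifnot(inherits(net, "evo_net"), inherits(cfg, "train_config"))
  spec <- net$spec
  X <- as.matrix(features)
  with_seed(cfg$seed, {
    if (is.null(net$meta$input_center)) {
      st <- input_stats(X, spec$input_transform)
      net$meta$input_center <- st$center
      net$meta$input_scale <- st$scale
    }
    pool <- task_rows(spec$task, labels)
    stop_unless(length(pool) >= 10, "too few usable simulations for training")
    n_val <- max(1L, floor(cfg$val_frac * length(pool)))
    val_idx <- sample(pool, n_val)
    tr_idx <- setdiff(pool, val_idx)
    Yval <- task_targets(spec$task, labels, val_idx)
    state <- adam_init(net$par)
    best <- list(loss = Inf, par = net$par)
    history <- list()
    step <- 0L
    bad <- 0L
    for (epoch in seq_len(cfg$max_epochs)) {
      idx <- tr_idx
      if (cfg$rebalance) {
        keep <- rebalance(labels[tr_idx, , drop = FALSE], spec$task)
        idx <- tr_idx[keep]
      }
      idx <- sample(idx)
      ep_loss <- 0
      n_b <- 0L
      for (b0 in seq(1, length(idx), by = cfg$batch_size)) {
        bi <- idx[b0:min(b0 + cfg$batch_size - 1, length(idx))]
        fw <- net_forward(net, X[bi, , drop = FALSE], dropout_on = TRUE,
                          keep_cache = TRUE)
        L <- net_loss(spec, fw$out, task_targets(spec$task, labels, bi),
                      cfg$fp_penalty)
        if (!is.finite(L$loss)) {
          abort(sprintf("non-finite loss at epoch %d (batch %d)", epoch, n_b))
        }
        grads <- net_backward(net, fw$cache, L$dout)
        step <- step + 1L
        # step decay: drop to 30% of the base rate for the final third of
        # the budget to damp late-stage oscillation under the L1 loss
        lr <- cfg$learning_rate *
          if (epoch > 2 * cfg$max_epochs / 3) 0.3 else 1
        upd <- adam_step(net$par, grads, state, lr, step)
        net$par <- upd$params
        state <- upd$state
        ep_loss <- ep_loss + L$loss
        n_b <- n_b + 1L
      }
      vfw <- net_forward(net, X[val_idx, , drop = FALSE], dropout_on = FALSE)
      vL <- net_loss(spec, vfw$out, Yval, cfg$fp_penalty)$loss
      history[[epoch]] <- tibble(epoch = epoch,
                                 train_loss = ep_loss / max(n_b, 1),
                                 val_loss = vL)
      if (verbose) {
        message(sprintf("epoch %d: train %.4f val %.4f", epoch,
                        ep_loss / max(n_b, 1), vL))
      }
      if (vL < best$loss - 1e-6) {
        best <- list(loss = vL, par = net$par)
        bad <- 0L
      } else {
        bad <- bad + 1L
        if (bad >= cfg$patience && epoch >= cfg$min_epochs) break
      }
    }
    net$par <- best$par
    net$meta$trained <- TRUE
    net$meta$history <- dplyr::bind_rows(history)
    net$meta$config <- unclass(cfg)
    net
  })
}

task_rows <- function(task, labels) {
  if (task == "ms") {
    seq_len(nrow(labels))
  } else if (task == "1s") {
    which(labels$n_subclones == 1)
  } else {
    which(labels$n_subclones == 2)
  }
}

task_targets <- function(task, labels, idx) {
  l <- labels[idx, , drop = FALSE]
  if (task == "ms") {
    list(y_sel = as.numeric(l$n_subclones > 0),
         y_nsub = as.integer(l$n_subclones))
  } else if (task == "1s") {
    list(f1 = l$f1)
  } else {
    f1 <- pmax(l$f1, l$f2)
    f2 <- pmin(l$f1, l$f2)
    list(f1 = f1, f2 = f2)
  }
}

#' Monte Carlo dropout prediction
#'
#' Keeps dropout active at prediction time and performs `T` stochastic
#' forward passes; the draws form an approximate posterior for each output.
#'
#' @param net A trained `evo_net`.
#' @param features Feature matrix or single feature vector.
#' @param T Number of stochastic passes (default 50; must be >= 2).
#' @param seed Optional RNG seed.
#' @return An object of class `"mc_posterior"`: for `"ms"`, arrays
#'   `sel` (`T x B`) and `nsub` (`T x B x 3`); for `"1s"`/`"2s"`, `freq`
#'   (`T x B` or `T x B x 2`, columns sorted descending).
#' @export
mc_predict <- function(net, features, T = 50, seed = NULL) {
  stop_unless(T >= 2, "`T` must be >= 2")
  X <- as_feature_matrix(features)
  B <- nrow(X)
  spec <- net$spec
  with_seed(seed, {
    if (spec$task == "ms") {
      sel <- matrix(0, T, B)
      nsub <- array(0, c(T, B, 3))
      for (t in seq_len(T)) {
        o <- net_outputs(spec, net_forward(net, X, dropout_on = TRUE)$out)
        sel[t, ] <- o$p_sel
        nsub[t, , ] <- o$p_nsub
      }
      structure(list(sel = sel, nsub = nsub, T = T, task = "ms"),
                class = "mc_posterior")
    } else if (spec$task == "1s") {
      fr <- matrix(0, T, B)
      for (t in seq_len(T)) {
        fr[t, ] <- net_outputs(spec,
                               net_forward(net, X, dropout_on = TRUE)$out)$freq
      }
      structure(list(freq = fr, T = T, task = "1s"), class = "mc_posterior")
    } else {
      fr <- array(0, c(T, B, 2))
      for (t in seq_len(T)) {
        fr[t, , ] <- net_outputs(spec,
                                 net_forward(net, X,
                                             dropout_on = TRUE)$out)$freq
      }
      structure(list(freq = fr, T = T, task = "2s"), class = "mc_posterior")
    }
  })
}

#' Summarize Monte Carlo dropout draws
#'
#' @param draws Numeric vector of `T` stochastic-pass outputs.
#' @param level Equal-tailed interval mass (default 0.89, i.e. the 5.5% and
#'   94.5% empirical quantiles).
#' @return Object of class `"posterior_summary"` with `draws`, `mean`,
#'   `eti_lower`, `eti_upper`, `T`, `level`.
#' @export
posterior_summary <- function(draws, level = 0.89) {
  draws <- as.numeric(draws)
  stop_unless(length(draws) >= 1, "need at least one draw")
  q <- quantile(draws, c((1 - level) / 2, 1 - (1 - level) / 2), names = FALSE)
  structure(list(draws = draws, mean = mean(draws), eti_lower = q[1],
                 eti_upper = q[2], T = length(draws), level = level),
            class = "posterior_summary")
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat(sprintf("<posterior_summary> mean %.3f [%.3f, %.3f] (%d%% ETI, T=%d)\n",
              x$mean, x$eti_lower, x$eti_upper, round(100 * x$level), x$T))
  invisible(x)
}
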