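#' Simulate a tumour with one deterministically initiated subclone
#'
#' Birth-death branching growth (defaults: birth 1, death 0.2, final size
#' 10^4) in which a single subclone is founded by a randomly chosen cell when
#' the population first reaches `2^subclone_time` cells; its net growth rate
#' is multiplied by `subclone_fitness`. Neutral mutations accumulate exactly
#' as in [simulate_tumour()]. A subclone that drifts to extinction before
#' biopsy is flagged (cellular fraction 0), not an error.
#'
#' @param params A [deterministic_sim_params()].
#' @param min_cells Carrier-count floor for retaining mutations (see
#'   [simulate_tumour()]); useful at large `n_final`.
#' @return A `tumour_truth` with an extra `transfer_labels` element:
#'   `mutation_rate`, `subclone_fitness`, `subclone_time` (doublings),
#'   `subclone_cellular_fraction` (realized fraction at biopsy, = subclone
#'   VAF x 2), `subclone_extinct`.
#' @export
simulate_deterministic <- function(params, min_cells = 1L) {
  stopifnot(inherits(params, "deterministic_sim_params"))
  with_seed(params$seed, {
    raw <- cpp_sim_deterministic(
      params$mutation_rate, params$n_clonal, params$birth, params$death,
      params$n_final, params$subclone_fitness, params$subclone_time,
      params$max_retries
    )
    truth <- truth_from_raw(raw, params$n_final, params, min_cells)
    frac <- raw$subclone_carriers / params$n_final
    truth$transfer_labels <- tibble::new_tibble(list(
      mutation_rate = params$mutation_rate,
      subclone_fitness = params$subclone_fitness,
      subclone_time = params$subclone_time,
      subclone_cellular_fraction = frac,
      subclone_extinct = raw$subclone_genotype > 0 && frac == 0
    ), nrow = 1L)
    truth
  })
}

#' Gaussian-process sampler of viable (fitness, emergence time) pairs
#'
#' Only a narrow band of fitness/emergence-time combinations produces a
#' detectable subclone (10-40% VAF) at biopsy. Given a pilot table of
#' simulated combinations and their resulting subclone VAFs, this fits a
#' noisy Gaussian-process regression of viable emergence time on fitness
#' (kernel: RBF with length scale 100 + dot-product + white noise,
#' jitter 1e-6) and returns a sampler that draws fitness uniformly and
#' emergence time from the noisy GP predictive distribution. The noise is
#' deliberate: it spreads sampled combinations across the whole detectable
#' frequency range.
#'
#' @param pilot_table Tibble with columns `fitness`, `t_s`, `subclone_vaf`
#'   (>= 50 rows).
#' @param window Detectability window on the VAF scale used to select viable
#'   pilot rows.
#' @param fitness_bounds,t_bounds Bounds for sampled values (defaults: the
#'   viable pilot range).
#' @param white_noise Variance of the white-noise kernel (default 1;
#'   set 0 for a noiseless sampler).
#' @return A function `n -> tibble(fitness, t_s)`.
#' @export
viable_param_sampler <- function(pilot_table, window = c(0.10, 0.40),
                                 fitness_bounds = NULL, t_bounds = NULL,
                                 white_noise = 1) {
  stop_unless(nrow(pilot_table) >= 50, "pilot_table needs >= 50 rows")
  ok <- pilot_table$subclone_vaf >= window[1] &
    pilot_table$subclone_vaf <= window[2]
  stop_unless(sum(ok) >= 10, "too few viable pilot combinations")
  x <- pilot_table$fitness[ok]
  y <- pilot_table$t_s[ok]
  fitness_bounds <- fitness_bounds %||% range(x)
  t_bounds <- t_bounds %||% range(y)
  gp <- gp_fit(x, y, length_scale = 100, white_noise = white_noise,
               jitter = 1e-6)
  function(n) {
    f <- runif(n, fitness_bounds[1], fitness_bounds[2])
    pred <- gp_predict(gp, f)
    t_s <- rnorm(n, pred$mean, sqrt(pmax(pred$var + white_noise, 0)))
    tibble(fitness = f,
           t_s = pmin(pmax(t_s, t_bounds[1]), t_bounds[2]))
  }
}

# Exact GP regression with a composite kernel:
# k(x, x') = exp(-(x - x')^2 / (2 l^2)) + x x' + white_noise * 1(x == x').
gp_fit <- function(x, y, length_scale = 100, white_noise = 1,
                   jitter = 1e-6) {
  K <- gp_kernel(x, x, length_scale) + diag(white_noise + jitter, length(x))
  mu <- mean(y)
  alpha <- solve(K, y - mu)
  list(x = x, mu = mu, alpha = alpha, K_chol = chol(K),
       length_scale = length_scale)
}

gp_kernel <- function(a, b, length_scale) {
  rbf <- exp(-outer(a, b, function(p, q) (p - q)^2) / (2 * length_scale^2))
  rbf + outer(a, b)
}

gp_predict <- function(gp, xnew) {
  Ks <- gp_kernel(xnew, gp$x, gp$length_scale)
  mean <- gp$mu + as.numeric(Ks %*% gp$alpha)
  v <- forwardsolve(t(gp$K_chol), t(Ks))  # L^{-1} K*, K = L L'
  kss <- 1 + xnew^2  # diagonal of the noise-free kernel at xnew
  var <- pmax(kss - colSums(v^2), 0)
  list(mean = mean, var = var)
}

#' Renovate pre-trained networks for transfer learning
#'
#' Open-set domain adaptation: the input space (the VAF histograms) is
#' retained while the predicted tasks change. All convolutional trunk layers
#' of the classification model (`"ms"`) and the single-subclone frequency
#' model (`"1s"`) are kept verbatim and concatenated feature-wise; the old
#' task branches are discarded and four new fully connected branches are
#' attached, one per transfer task (mutation rate, subclone fitness,
#' emergence time, cellular fraction).
#'
#' @param net_ms,net_1s Trained `evo_net` checkpoints with identical
#'   featurization metadata.
#' @param fc_units Hidden units in each new branch (default: the donor's).
#' @param tasks Names of the new output heads.
#' @param seed RNG seed for branch initialization.
#' @return An object of class `"evo_net_transfer"`.
#' @export
renovate <- function(net_ms, net_1s, fc_units = NULL,
                     tasks = c("mutation_rate", "fitness", "emergence_time",
                               "cellular_fraction"),
                     seed = NULL) {
  stopifnot(inherits(net_ms, "evo_net"), inherits(net_1s, "evo_net"))
  fa <- net_ms$meta$featurization
  fb <- net_1s$meta$featurization
  if (!identical(fa$k_list, fb$k_list) ||
      !identical(fa$normalize, fb$normalize)) {
    abort("featurization metadata mismatch between donor models")
  }
  spec_a <- net_ms$spec
  spec_b <- net_1s$spec
  fc_units <- fc_units %||% spec_a$fc_units
  par <- list()
  trunk_names <- character(0)
  for (donor in list(list(net = net_ms, tag = "a"),
                     list(net = net_1s, tag = "b"))) {
    sp <- donor$net$spec
    for (ti in seq_along(sp$k_list)) {
      for (l in seq_len(sp$n_conv)) {
        for (suf in c("W", "b")) {
          nm_old <- pn("t", ti, "c", l, suf)
          nm_new <- pn(donor$tag, "t", ti, "c", l, suf)
          par[[nm_new]] <- donor$net$par[[nm_old]]
          trunk_names <- c(trunk_names, nm_new)
        }
      }
    }
  }
  Z <- merged_dim(spec_a) + merged_dim(spec_b)
  with_seed(seed, {
    for (h in tasks) {
      par[[pn("h", h, "W1")]] <- init_weight(Z, fc_units)
      par[[pn("h", h, "b1")]] <- numeric(fc_units)
      par[[pn("h", h, "W2")]] <- init_weight(fc_units, 1L)
      par[[pn("h", h, "b2")]] <- numeric(1L)
    }
    structure(list(
      spec_a = spec_a, spec_b = spec_b, tasks = tasks,
      fc_units = fc_units, dropout = spec_a$dropout, par = par,
      trunk_names = trunk_names,
      meta = list(featurization = fa, trained = FALSE,
                  mu_calibration = NULL, target_center = NULL,
                  target_scale = NULL,
                  input_center = net_ms$meta$input_center,
                  input_scale = net_ms$meta$input_scale)
    ), class = "evo_net_transfer")
  })
}

#' @export
print.evo_net_transfer <- function(x, ...) {
  cat("<evo_net_transfer> ", length(x$tasks), " task branches (",
      paste(x$tasks, collapse = ", "), "); ", n_params(x),
      " parameters; ",
      if (isTRUE(x$meta$trained)) "fine-tuned" else "not fine-tuned",
      if (!is.null(x$meta$mu_calibration)) "; mutation rate calibrated" else "",
      "\n", sep = "")
  invisible(x)
}

transfer_forward <- function(net, X, dropout_on = FALSE,
                             trunk_dropout_on = dropout_on,
                             keep_cache = FALSE) {
  X <- apply_input_transform(as.matrix(X), net$spec_a$input_transform,
                             net$meta$input_center, net$meta$input_scale)
  zs <- list()
  trunk_fwd <- list()
  k <- 1
  for (donor in list(list(spec = net$spec_a, tag = "a"),
                     list(spec = net$spec_b, tag = "b"))) {
    parts <- split_features(X, donor$spec$k_list)
    for (ti in seq_along(parts)) {
      layers <- transfer_trunk_layers(net$par, donor$tag, ti,
                                      donor$spec$n_conv)
      fw <- trunk_forward(parts[[ti]], layers, donor$spec$kernel,
                          donor$spec$branch, donor$spec$dropout,
                          trunk_dropout_on, keep_cache)
      zs[[k]] <- fw$z
      trunk_fwd[[k]] <- list(fw = fw, tag = donor$tag, ti = ti,
                             spec = donor$spec)
      k <- k + 1
    }
  }
  z <- do.call(cbind, zs)
  out <- list()
  head_caches <- list()
  for (h in net$tasks) {
    hf <- head_forward(z, get_head(net$par, h), net$dropout, dropout_on,
                       keep_cache)
    out[[h]] <- hf$out
    head_caches[[h]] <- hf$cache
  }
  cache <- if (keep_cache) {
    list(trunks = trunk_fwd, heads = head_caches,
         z_dims = vapply(zs, ncol, numeric(1)))
  } else NULL
  list(out = out, cache = cache)
}

transfer_trunk_layers <- function(par, tag, ti, n_conv) {
  lapply(seq_len(n_conv), function(l) {
    list(W = par[[pn(tag, "t", ti, "c", l, "W")]],
         b = par[[pn(tag, "t", ti, "c", l, "b")]])
  })
}

transfer_backward <- function(net, cache, dout, skip_trunks = FALSE) {
  grads <- list()
  dz <- NULL
  for (h in net$tasks) {
    hb <- head_backward(dout[[h]], cache$heads[[h]], get_head(net$par, h))
    grads[[pn("h", h, "W1")]] <- hb$grads$W1
    grads[[pn("h", h, "b1")]] <- hb$grads$b1
    grads[[pn("h", h, "W2")]] <- hb$grads$W2
    grads[[pn("h", h, "b2")]] <- hb$grads$b2
    dz <- if (is.null(dz)) hb$dz else dz + hb$dz
  }
  if (skip_trunks) return(grads)
  ends <- cumsum(cache$z_dims)
  starts <- c(1, head(ends, -1) + 1)
  for (k in seq_along(cache$trunks)) {
    tc <- cache$trunks[[k]]
    layers <- transfer_trunk_layers(net$par, tc$tag, tc$ti, tc$spec$n_conv)
    tg <- trunk_backward(dz[, starts[k]:ends[k], drop = FALSE], tc$fw,
                         layers, tc$spec$kernel, tc$spec$branch)
    for (l in seq_along(tg)) {
      grads[[pn(tc$tag, "t", tc$ti, "c", l, "W")]] <- tg[[l]]$W
      grads[[pn(tc$tag, "t", tc$ti, "c", l, "b")]] <- tg[[l]]$b
    }
  }
  grads
}

#' Fine-tune a renovated network on transfer-task labels
#'
#' Minimizes the L1 loss on standardized targets with Adam. Targets for the
#' subclonal tasks (fitness, emergence time, cellular fraction) contribute to
#' the loss only on simulations whose subclone survived to biopsy
#' (`cellular_fraction > 0`); the mutation-rate task uses every simulation.
#' Pre-trained trunk weights are updated with a 10x reduced learning rate by
#' default, or frozen entirely with `freeze_trunk = TRUE`.
#'
#' @param net An `evo_net_transfer` from [renovate()].
#' @param features Feature matrix.
#' @param labels Tibble with columns matching `net$tasks`
#'   (`mutation_rate`, `fitness`, `emergence_time`, `cellular_fraction`).
#' @param cfg A [train_config()].
#' @param trunk_lr_scale Learning-rate multiplier for trunk weights
#'   (default 0.1).
#' @param freeze_trunk Keep trunk weights fixed.
#' @param verbose Print per-epoch losses.
#' @return The fine-tuned network (target standardization stored in
#'   `meta`).
#' @export
finetune <- function(net, features, labels, cfg = train_config(),
                     trunk_lr_scale = 0.1, freeze_trunk = FALSE,
                     log_tasks = c("mutation_rate", "fitness"),
                     verbose = FALSE) {
  stopifnot(inherits(net, "evo_net_transfer"))
  X <- as.matrix(features)
  Y <- as.matrix(labels[, net$tasks])
  # positive ratio-scale targets regress on the log scale, aligning the L1
  # loss with relative rather than absolute error
  log_tasks <- intersect(log_tasks, net$tasks)
  for (tk in log_tasks) Y[, tk] <- log(pmax(Y[, tk], 1e-8))
  with_seed(cfg$seed, {
    center <- colMeans(Y)
    scl <- apply(Y, 2, sd)
    scl[scl == 0] <- 1
    Ys <- sweep(sweep(Y, 2, center), 2, scl, "/")
    mask <- matrix(1, nrow(Y), length(net$tasks))
    colnames(mask) <- net$tasks
    if ("cellular_fraction" %in% colnames(Y)) {
      sub_ok <- Y[, "cellular_fraction"] > 0
      for (tk in intersect(c("fitness", "emergence_time",
                             "cellular_fraction"), net$tasks)) {
        mask[, tk] <- as.numeric(sub_ok)
      }
    }
    n <- nrow(X)
    n_val <- max(1L, floor(cfg$val_frac * n))
    val_idx <- sample(n, n_val)
    tr_idx <- setdiff(seq_len(n), val_idx)
    lr_scale <- NULL
    if (!freeze_trunk) {
      lr_scale <- setNames(as.list(rep(trunk_lr_scale,
                                       length(net$trunk_names))),
                           net$trunk_names)
    }
    state <- adam_init(net$par)
    best <- list(loss = Inf, par = net$par)
    bad <- 0L
    step <- 0L
    history <- list()
    for (epoch in seq_len(cfg$max_epochs)) {
      idx <- sample(tr_idx)
      ep_loss <- 0
      n_b <- 0L
      for (b0 in seq(1, length(idx), by = cfg$batch_size)) {
        bi <- idx[b0:min(b0 + cfg$batch_size - 1, length(idx))]
        fw <- transfer_forward(net, X[bi, , drop = FALSE],
                               dropout_on = TRUE, keep_cache = TRUE)
        lg <- transfer_loss(net, fw$out, Ys[bi, , drop = FALSE],
                            mask[bi, , drop = FALSE])
        if (!is.finite(lg$loss)) abort("non-finite loss during fine-tuning")
        grads <- transfer_backward(net, fw$cache, lg$dout,
                                   skip_trunks = freeze_trunk)
        step <- step + 1L
        lr <- cfg$learning_rate *
          if (epoch > 2 * cfg$max_epochs / 3) 0.3 else 1
        upd <- adam_step(net$par, grads, state, lr, step,
                         lr_scale = lr_scale)
        net$par <- upd$params
        state <- upd$state
        ep_loss <- ep_loss + lg$loss
        n_b <- n_b + 1L
      }
      vfw <- transfer_forward(net, X[val_idx, , drop = FALSE],
                              dropout_on = FALSE)
      vL <- transfer_loss(net, vfw$out, Ys[val_idx, , drop = FALSE],
                          mask[val_idx, , drop = FALSE])$loss
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
        if (bad >= cfg$patience && epoch >= (cfg$min_epochs %||% 1)) break
      }
    }
    net$par <- best$par
    net$meta$trained <- TRUE
    net$meta$target_center <- center
    net$meta$target_scale <- scl
    net$meta$log_tasks <- log_tasks
    net$meta$history <- dplyr::bind_rows(history)
    net
  })
}

transfer_loss <- function(net, out, Ys, mask) {
  loss <- 0
  dout <- list()
  B <- nrow(Ys)
  for (j in seq_along(net$tasks)) {
    h <- net$tasks[j]
    m <- mask[, h]
    r <- (out[[h]] - Ys[, j]) * m
    denom <- max(sum(m), 1)
    loss <- loss + sum(abs(r)) / denom
    dout[[h]] <- sign(r) / denom
  }
  list(loss = loss / length(net$tasks), dout = dout)
}

#' Predict transfer tasks with Monte Carlo dropout on the new branches
#'
#' Performs `T` stochastic passes with dropout active only on the new
#' task-specific branches (the pre-trained trunks run deterministically),
#' destandardizes, and applies the stored mutation-rate calibration map if
#' present.
#'
#' @param net A fine-tuned `evo_net_transfer`.
#' @param features Feature matrix or vector.
#' @param T MC dropout passes (default 500 for single-sample prediction; use
#'   fewer for bulk evaluation).
#' @param seed Optional RNG seed.
#' @param calibrated Apply the mutation-rate calibration (default TRUE when
#'   available).
#' @return List with `mean` (tibble, one row per sample, one column per
#'   task) and `draws` (array `T x B x n_tasks`).
#' @export
predict_transfer <- function(net, features, T = 500, seed = NULL,
                             calibrated = TRUE) {
  stopifnot(inherits(net, "evo_net_transfer"))
  X <- as_feature_matrix(features)
  B <- nrow(X)
  with_seed(seed, {
    draws <- array(0, c(T, B, length(net$tasks)),
                   dimnames = list(NULL, NULL, net$tasks))
    for (t in seq_len(T)) {
      o <- transfer_forward(net, X, dropout_on = TRUE,
                            trunk_dropout_on = FALSE)$out
      for (j in seq_along(net$tasks)) draws[t, , j] <- o[[net$tasks[j]]]
    }
    for (j in seq_along(net$tasks)) {
      draws[, , j] <- draws[, , j] * net$meta$target_scale[j] +
        net$meta$target_center[j]
      if (net$tasks[j] %in% (net$meta$log_tasks %||% character(0))) {
        draws[, , j] <- exp(draws[, , j])
      }
    }
    if (calibrated && !is.null(net$meta$mu_calibration) &&
        "mutation_rate" %in% net$tasks) {
      j <- match("mutation_rate", net$tasks)
      draws[, , j] <- apply_mu_calibration(net$meta$mu_calibration,
                                           draws[, , j])
    }
    means <- apply(draws, c(2, 3), mean)
    list(mean = as_tibble(as.data.frame(means)), draws = draws)
  })
}

#' Post-hoc mutation-rate calibration
#'
#' Transfer models show a modest systematic bias in raw mutation-rate
#' predictions; a degree-2 polynomial ridge regression from predicted to true
#' mutation rate, fitted on a calibration set of synthetic tumours, is stored
#' with the checkpoint and applied at inference.
#'
#' @param net A fine-tuned `evo_net_transfer`.
#' @param features Calibration feature matrix (typically 1000 simulations).
#' @param true_mu True mutation rates for the calibration set.
#' @param lambda Ridge penalty (default 1).
#' @param T MC passes used to form the raw predictions (default 50).
#' @param seed Optional RNG seed.
#' @return The network with `meta$mu_calibration` set.
#' @export
calibrate_mu <- function(net, features, true_mu, lambda = 1, T = 50,
                         seed = NULL) {
  stopifnot(inherits(net, "evo_net_transfer"))
  pred <- predict_transfer(net, features, T = T, seed = seed,
                           calibrated = FALSE)$mean$mutation_rate
  stop_unless(sd(pred) > 1e-8,
              "degenerate (zero-variance) predictions; cannot calibrate")
  fit <- MASS::lm.ridge(true_mu ~ pred + I(pred^2), lambda = lambda)
  cf <- coef(fit)
  net$meta$mu_calibration <- list(coef = as.numeric(cf), lambda = lambda)
  net
}

apply_mu_calibration <- function(cal, x) {
  cal$coef[1] + cal$coef[2] * x + cal$coef[3] * x^2
}
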