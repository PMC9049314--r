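#' Architecture specification for the multi-task VAF network
#'
#' A one-dimensional convolutional network with two parallel trunks, one per
#' histogram resolution in `k_list` (the 64- and 128-bin histograms by
#' default), merged into task-specific branches. Hardswish activations are
#' used at every hidden layer and dropout (fixed probability 0.5 by default)
#' follows every hidden layer so that Monte Carlo dropout can be applied at
#' prediction time.
#'
#' @param task `"ms"` (two heads: P(Selection) and the 3-way
#'   P(0/1/2 subclones)), `"1s"` (one subclone frequency) or `"2s"` (two
#'   subclone frequencies).
#' @param n_conv Number of convolutional layers per trunk (1-20).
#' @param channels Feature maps per convolutional layer (each 4-32); recycled
#'   to length `n_conv`.
#' @param kernel Convolution kernel width (odd, 1-17).
#' @param branch Task-branch type: `"fc"` (flatten + fully connected) or
#'   `"gap"` (global average pooling + fully connected).
#' @param fc_units Hidden units in each task branch.
#' @param dropout Dropout probability after each hidden layer (default 0.5).
#' @param k_list Histogram resolutions the network consumes.
#' @param input_transform `"log1p"` (default; stabilizes raw-count
#'   histograms) or `"none"`.
#' @return A list of class `"model_spec"`.
#' @export
model_spec <- function(task = c("ms", "1s", "2s"), n_conv = 2,
                       channels = 8, kernel = 5, branch = c("fc", "gap"),
                       fc_units = 64, dropout = 0.5, k_list = c(64, 128),
                       input_transform = c("log1p", "none")) {
  task <- match.arg(task)
  branch <- match.arg(branch)
  input_transform <- match.arg(input_transform)
  stop_unless(n_conv >= 1 && n_conv <= 20, "`n_conv` must be in 1-20")
  channels <- rep_len(as.integer(channels), n_conv)
  stop_unless(all(channels >= 4 & channels <= 32),
              "`channels` must be in 4-32")
  stop_unless(kernel >= 1 && kernel <= 17 && kernel %% 2 == 1,
              "`kernel` must be odd and in 1-17")
  stop_unless(dropout >= 0 && dropout < 1, "`dropout` must be in [0, 1)")
  heads <- switch(task,
    ms = list(sel = 1L, nsub = 3L),
    `1s` = list(freq = 1L),
    `2s` = list(freq = 2L)
  )
  structure(list(task = task, n_conv = n_conv, channels = channels,
                 kernel = kernel, branch = branch, fc_units = fc_units,
                 dropout = dropout, k_list = k_list,
                 input_transform = input_transform, heads = heads),
            class = "model_spec")
}

trunk_prefixes <- function(spec) paste0("t", seq_along(spec$k_list))

trunk_out_dim <- function(spec, L) {
  C <- spec$channels[spec$n_conv]
  if (spec$branch == "gap") C else L * C
}

merged_dim <- function(spec) {
  sum(vapply(spec$k_list, function(L) trunk_out_dim(spec, L), numeric(1)))
}

#' Build an untrained network from a specification
#'
#' Weights are He-initialized; the parameter count is a deterministic
#' function of the specification (see [n_params()]).
#'
#' @param spec A [model_spec()].
#' @param featurization List recording how inputs were featurized
#'   (`k_list`, `normalize`); stored in the checkpoint metadata and checked
#'   at transfer time.
#' @param seed Optional RNG seed for the initialization.
#' @return An object of class `"evo_net"`.
#' @export
build_network <- function(spec, featurization = list(k_list = spec$k_list,
                                                     normalize = FALSE),
                          seed = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  with_seed(seed, {
    par <- list()
    for (ti in seq_along(spec$k_list)) {
      cin <- 1L
      for (l in seq_len(spec$n_conv)) {
        cout <- spec$channels[l]
        par[[pn("t", ti, "c", l, "W")]] <-
          init_weight(spec$kernel * cin, cout)
        par[[pn("t", ti, "c", l, "b")]] <- numeric(cout)
        cin <- cout
      }
    }
    Z <- merged_dim(spec)
    for (h in names(spec$heads)) {
      par[[pn("h", h, "W1")]] <- init_weight(Z, spec$fc_units)
      par[[pn("h", h, "b1")]] <- numeric(spec$fc_units)
      par[[pn("h", h, "W2")]] <- init_weight(spec$fc_units, spec$heads[[h]])
      par[[pn("h", h, "b2")]] <- numeric(spec$heads[[h]])
    }
    structure(list(spec = spec, par = par,
                   meta = list(featurization = featurization,
                               trained = FALSE, history = NULL)),
              class = "evo_net")
  })
}

pn <- function(...) paste(unlist(list(...)), collapse = ".")

#' Number of trainable parameters
#'
#' @param net An `evo_net` (or transfer network).
#' @return Integer parameter count.
#' @export
n_params <- function(net) {
  sum(vapply(net$par, length, numeric(1)))
}

#' @export
print.evo_net <- function(x, ...) {
  s <- x$spec
  cat("<evo_net task=", s$task, "> ", s$n_conv, " conv layer(s) x ",
      paste(s$channels, collapse = "/"), " channels, kernel ", s$kernel,
      ", branch ", s$branch, ", dropout ", s$dropout, "; ",
      n_params(x), " parameters; ",
      if (isTRUE(x$meta$trained)) "trained" else "untrained", "\n", sep = "")
  invisible(x)
}

get_trunk_layers <- function(par, ti, n_conv) {
  lapply(seq_len(n_conv), function(l) {
    list(W = par[[pn("t", ti, "c", l, "W")]],
         b = par[[pn("t", ti, "c", l, "b")]])
  })
}

get_head <- function(par, h) {
  list(W1 = par[[pn("h", h, "W1")]], b1 = par[[pn("h", h, "b1")]],
       W2 = par[[pn("h", h, "W2")]], b2 = par[[pn("h", h, "b2")]])
}

split_features <- function(X, k_list) {
  stop_unless(ncol(X) == sum(k_list),
              "feature width does not match the network's k_list")
  ends <- cumsum(k_list)
  starts <- c(1, head(ends, -1) + 1)
  lapply(seq_along(k_list), function(i) X[, starts[i]:ends[i], drop = FALSE])
}

apply_input_transform <- function(X, transform, center = NULL,
                                  scale = NULL) {
  if (transform == "log1p") X <- log1p(X)
  if (!is.null(center)) {
    X <- sweep(sweep(X, 2, center), 2, scale, "/")
  }
  X
}

# Per-feature standardization statistics, estimated once from the training
# set (on the log1p scale) and stored in the checkpoint.
input_stats <- function(X, transform) {
  X <- if (transform == "log1p") log1p(as.matrix(X)) else as.matrix(X)
  center <- colMeans(X)
  scale <- apply(X, 2, sd)
  scale[scale < 1e-8] <- 1
  list(center = center, scale = scale)
}

# Full forward pass. Returns list(out = named list of head outputs (logits /
# raw regression values), cache) -- cache only when keep_cache.
net_forward <- function(net, X, dropout_on = FALSE, keep_cache = FALSE) {
  spec <- net$spec
  X <- apply_input_transform(as.matrix(X), spec$input_transform,
                             net$meta$input_center, net$meta$input_scale)
  parts <- split_features(X, spec$k_list)
  trunk_fwd <- vector("list", length(parts))
  zs <- vector("list", length(parts))
  for (ti in seq_along(parts)) {
    layers <- get_trunk_layers(net$par, ti, spec$n_conv)
    fw <- trunk_forward(parts[[ti]], layers, spec$kernel, spec$branch,
                        spec$dropout, dropout_on, keep_cache)
    trunk_fwd[[ti]] <- fw
    zs[[ti]] <- fw$z
  }
  z <- do.call(cbind, zs)
  out <- list()
  head_caches <- list()
  for (h in names(spec$heads)) {
    hf <- head_forward(z, get_head(net$par, h), spec$dropout, dropout_on,
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

# Backward pass. dout: named list of gradients wrt head outputs.
# Returns flat named list of gradients aligned with net$par.
net_backward <- function(net, cache, dout) {
  spec <- net$spec
  grads <- list()
  dz <- NULL
  for (h in names(spec$heads)) {
    hb <- head_backward(dout[[h]], cache$heads[[h]], get_head(net$par, h))
    grads[[pn("h", h, "W1")]] <- hb$grads$W1
    grads[[pn("h", h, "b1")]] <- hb$grads$b1
    grads[[pn("h", h, "W2")]] <- hb$grads$W2
    grads[[pn("h", h, "b2")]] <- hb$grads$b2
    dz <- if (is.null(dz)) hb$dz else dz + hb$dz
  }
  ends <- cumsum(cache$z_dims)
  starts <- c(1, head(ends, -1) + 1)
  for (ti in seq_along(cache$trunks)) {
    layers <- get_trunk_layers(net$par, ti, spec$n_conv)
    tg <- trunk_backward(dz[, starts[ti]:ends[ti], drop = FALSE],
                         cache$trunks[[ti]], layers, spec$kernel,
                         spec$branch)
    for (l in seq_along(tg)) {
      grads[[pn("t", ti, "c", l, "W")]] <- tg[[l]]$W
      grads[[pn("t", ti, "c", l, "b")]] <- tg[[l]]$b
    }
  }
  grads
}

# Map raw head outputs to probabilities / frequency predictions.
net_outputs <- function(spec, out) {
  if (spec$task == "ms") {
    list(p_sel = as.numeric(sigmoid(out$sel)),
         p_nsub = softmax_rows(out$nsub))
  } else if (spec$task == "1s") {
    list(freq = as.numeric(out$freq))
  } else {
    f <- out$freq
    list(freq = t(apply(f, 1, sort, decreasing = TRUE)))
  }
}

#' Deterministic prediction (dropout off)
#'
#' @param object An `evo_net`.
#' @param features Feature matrix (rows = samples) or single feature vector.
#' @param ... Unused.
#' @return For `"ms"`: list with `p_sel` (vector) and `p_nsub` (matrix with
#'   columns for 0/1/2 subclones). For `"1s"`/`"2s"`: list with `freq`.
#' @export
predict.evo_net <- function(object, features, ...) {
  X <- as_feature_matrix(features)
  fw <- net_forward(object, X, dropout_on = FALSE)
  net_outputs(object$spec, fw$out)
}

as_feature_matrix <- function(features) {
  if (is.matrix(features)) features else matrix(as.numeric(features), 1)
}
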