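test_that("architecture validation enforces the search-space ranges", {
  expect_error(model_spec(kernel = 4), "odd")
  expect_error(model_spec(kernel = 19), "odd")
  expect_error(model_spec(channels = 2), "channels")
  expect_error(model_spec(n_conv = 0), "n_conv")
  # dropout fixed at 0.5 sits after every hidden layer by construction
  sp <- model_spec("ms")
  expect_equal(sp$dropout, 0.5)
})

test_that("parameter count is a deterministic closed-form of the spec", {
  sp <- model_spec("1s", n_conv = 1, channels = 4, kernel = 3,
                   branch = "fc", fc_units = 8)
  net <- build_network(sp, seed = 1)
  # trunks: 2 x (3*1*4 weights + 4 biases); merged width 64*4 + 128*4 = 768
  # branch: 768*8 + 8 + 8*1 + 1
  expect_equal(n_params(net), 2 * (3 * 4 + 4) + 768 * 8 + 8 + 8 + 1)
  net2 <- build_network(sp, seed = 1)
  expect_identical(net$par, net2$par)  # seeded init reproducible
})

test_that("rebalancing equalizes subclone-frequency strata", {
  lab <- tibble::tibble(
    n_subclones = c(rep(1L, 110), rep(0L, 20)),
    f1 = c(rep(0.20, 100), rep(0.30, 10), rep(NA, 20)),
    f2 = NA_real_
  )
  keep <- rebalance(lab, "ms")
  kept1 <- lab$f1[keep][lab$n_subclones[keep] == 1]
  expect_equal(sum(kept1 == 0.20), 10)
  expect_equal(sum(kept1 == 0.30), 10)
  expect_equal(sum(lab$n_subclones[keep] == 0), 20)  # neutral untouched
})

test_that("two-subclone simulations are filtered to gaps above 0.05 VAF", {
  lab <- tibble::tibble(
    n_subclones = rep(2L, 4),
    f1 = c(0.30, 0.30, 0.25, 0.22),
    f2 = c(0.26, 0.20, 0.12, 0.18)
  )
  keep <- rebalance(lab, "2s")
  expect_false(1 %in% keep)  # gap 0.04 excluded
  expect_false(4 %in% keep)  # gap 0.04 excluded
  lab0 <- tibble::tibble(n_subclones = rep(0L, 5), f1 = NA_real_,
                         f2 = NA_real_)
  expect_equal(rebalance(lab0, "ms"), 1:5)  # all-neutral passes through
  expect_warning(rebalance(lab0, "1s"), "rebalance")
})

test_that("training reduces loss on a separable toy problem", {
  set.seed(51)
  n <- 200
  X <- matrix(rpois(n * 192, 2), n, 192)
  y <- rep(c(0L, 1L), each = n / 2)
  X[y == 1, 30] <- X[y == 1, 30] + 40  # a subclonal 'peak'
  lab <- tibble::tibble(n_subclones = y, f1 = ifelse(y == 1, 0.24, NA),
                        f2 = NA_real_)
  net <- build_network(model_spec("ms", channels = 4, fc_units = 16),
                       seed = 2)
  cfg <- train_config(max_epochs = 6, patience = 5, rebalance = FALSE,
                      seed = 3)
  trained <- train(net, X, lab, cfg)
  h <- trained$meta$history
  expect_lt(h$train_loss[nrow(h)], h$train_loss[1])
  expect_true(trained$meta$trained)
  expect_equal(trained$meta$config$batch_size, 256L)
})

test_that("training is reproducible under a fixed seed", {
  set.seed(52)
  X <- matrix(rpois(100 * 192, 2), 100, 192)
  lab <- tibble::tibble(n_subclones = rep(c(0L, 1L), 50),
                        f1 = ifelse(rep(c(0L, 1L), 50) == 1, 0.2, NA),
                        f2 = NA_real_)
  cfg <- train_config(max_epochs = 2, patience = 3, seed = 7)
  a <- train(build_network(model_spec("ms", channels = 4), seed = 5),
             X, lab, cfg)
  b <- train(build_network(model_spec("ms", channels = 4), seed = 5),
             X, lab, cfg)
  expect_identical(a$par, b$par)
})

test_that("raising the false-positive penalty suppresses positive calls", {
  # the penalty multiplies the negative-class cross-entropy term, so a
  # heavily penalized model must emit fewer (or equal) positive calls on
  # overlapping classes, which weakly increases precision
  set.seed(53)
  n <- 400
  X <- matrix(rpois(n * 192, 2), n, 192)
  y <- rbinom(n, 1, 0.5)
  X[y == 1, 25] <- X[y == 1, 25] + rpois(sum(y == 1), 4)  # overlapping signal
  lab <- tibble::tibble(n_subclones = as.integer(y),
                        f1 = ifelse(y == 1, 0.2, NA), f2 = NA_real_)
  fit <- function(w) {
    cfg <- train_config(max_epochs = 10, patience = 5, rebalance = FALSE,
                        fp_penalty = w, seed = 9)
    m <- train(build_network(model_spec("ms", channels = 4, fc_units = 16),
                             seed = 10), X, lab, cfg)
    predict(m, X)$p_sel > 0.5
  }
  p_lo <- fit(1)
  p_hi <- fit(20)
  expect_lte(sum(p_hi), sum(p_lo))
  prec <- function(p) if (sum(p) == 0) 1 else sum(p & y == 1) / sum(p)
  expect_gte(prec(p_hi) + 0.02, prec(p_lo))
})

test_that("MC dropout draws form calibrated equal-tailed intervals", {
  # quantile oracle: draws 0.0, 0.1, ..., 1.0 -> 5.5% / 94.5% quantiles
  ps <- posterior_summary(seq(0, 1, by = 0.1))
  expect_equal(ps$eti_lower, unname(quantile(seq(0, 1, 0.1), 0.055)))
  expect_equal(ps$eti_upper, unname(quantile(seq(0, 1, 0.1), 0.945)))
  expect_equal(ps$eti_lower, 0.055)
  expect_equal(ps$eti_upper, 0.945)
  expect_true(ps$eti_lower <= ps$mean && ps$mean <= ps$eti_upper)

  # dropout probability 0 -> all stochastic passes identical, width 0
  net0 <- build_network(model_spec("1s", dropout = 0, channels = 4),
                        seed = 11)
  X <- matrix(rpois(192, 2), 1, 192)
  mcp <- mc_predict(net0, X, T = 10, seed = 12)
  expect_equal(diff(range(mcp$freq[, 1])), 0)
  expect_error(mc_predict(net0, X, T = 1), "T")

  # class probabilities sum to one on every pass
  netms <- build_network(model_spec("ms", channels = 4), seed = 13)
  m2 <- mc_predict(netms, X, T = 5, seed = 14)
  expect_equal(apply(m2$nsub, c(1, 2), sum), matrix(1, 5, 1))
})

test_that("MC prediction is reproducible under a fixed seed", {
  net <- build_network(model_spec("ms", channels = 4), seed = 15)
  X <- matrix(rpois(2 * 192, 2), 2, 192)
  a <- mc_predict(net, X, T = 8, seed = 16)
  b <- mc_predict(net, X, T = 8, seed = 16)
  expect_identical(a$sel, b$sel)
})

test_that("evolutionary calls follow the 89% ETI parsimony rules", {
  ps <- function(draws) posterior_summary(draws)
  flat <- ps(rep(1 / 3, 50))
  # lower bound 0.49 -> neutral and zero subclones regardless of the
  # subclone head
  sel49 <- ps(rep(0.49, 50))
  call1 <- call_evolution(sel49, list(ps(rep(0, 50)), ps(rep(1, 50)),
                                      ps(rep(0, 50))))
  expect_equal(call1$mode, "neutral")
  expect_equal(call1$n_subclones, 0L)

  # unanimous selection and 2-subclone draws
  call2 <- call_evolution(ps(rep(1, 50)),
                          list(ps(rep(0, 50)), ps(rep(0, 50)),
                               ps(rep(1, 50))))
  expect_equal(call2$mode, "selection")
  expect_equal(call2$n_subclones, 2L)

  # selection passes but no subclone class does: argmax of means (1 vs 2)
  call3 <- call_evolution(ps(rep(0.9, 50)),
                          list(ps(rep(0.25, 50)), ps(rep(0.40, 50)),
                               ps(rep(0.35, 50))))
  expect_equal(call3$n_subclones, 1L)
  expect_equal(call_evolution(ps(rep(0.9, 50)),
                              list(flat, ps(rep(0.30, 50)),
                                   ps(rep(0.37, 50))))$n_subclones, 2L)
})

test_that("frequency estimation dispatches on the call", {
  toy <- get_toy_models()
  X <- get_toy_features_one()
  ps <- function(x) posterior_summary(rep(x, 20))
  neutral_call <- call_evolution(ps(0.2), list(ps(0.9), ps(0.05), ps(0.05)))
  expect_length(estimate_frequencies(toy$s1, toy$s2 %||% toy$s1, X,
                                     neutral_call), 0)
  sel_call <- call_evolution(ps(0.95), list(ps(0), ps(0.95), ps(0.05)))
  fr <- estimate_frequencies(toy$s1, toy$s2 %||% toy$s1, X, sel_call,
                             T = 10, seed = 1)
  expect_length(fr, 1)
  expect_s3_class(fr[[1]], "posterior_summary")
})
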