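# Independent two-type birth-death oracle: a plain R event-loop simulator
# tracking only background/subclone cell counts (no genotypes, no mutations).
oracle_two_type <- function(n_final, birth, death, fitness, t_s) {
  trigger <- max(2, round(2^t_s))
  b_sub <- death + fitness * (birth - death)
  repeat {
    n_bg <- 1; n_sub <- 0
    b_max <- max(birth, b_sub)
    started <- FALSE
    while (n_bg + n_sub < n_final) {
      if (!started && n_bg + n_sub >= trigger) {
        n_bg <- n_bg - 1; n_sub <- n_sub + 1
        started <- TRUE
      }
      is_sub <- runif(1) < n_sub / (n_bg + n_sub)
      b_i <- if (is_sub) b_sub else birth
      if (runif(1) * (b_max + death) >= b_i + death) next
      dead <- death > 0 && runif(1) * (b_i + death) < death
      delta <- if (dead) -1 else 1
      if (is_sub) n_sub <- n_sub + delta else n_bg <- n_bg + delta
      if (n_bg + n_sub == 0) break
    }
    if (n_bg + n_sub > 0) return(n_sub / (n_bg + n_sub))
  }
}

with_fixed_fitness <- function(sampler, f) {
  # draw many pairs and keep the t_s of the draws closest to fitness f
  d <- sampler(2000)
  d$t_s[abs(d$fitness - f) < 0.1]
}

test_that("late emergence times produce no subclone", {
  p <- deterministic_sim_params(mutation_rate = 5, subclone_fitness = 3,
                                subclone_time = 20, n_final = 500, seed = 71)
  tt <- simulate_deterministic(p)
  expect_equal(tt$transfer_labels$subclone_cellular_fraction, 0)
  expect_false(tt$transfer_labels$subclone_extinct)
  expect_equal(nrow(tt$driver_lineages), 0)
})

test_that("a fitness-1 subclone lineage drifts like a neutral lineage", {
  # martingale oracle: the descendant fraction of one of ~2^t_s cells has
  # expectation 1 / 2^t_s under neutrality
  set.seed(72)
  reps <- 300
  fr <- replicate(reps, {
    tt <- simulate_deterministic(deterministic_sim_params(
      mutation_rate = 0, subclone_fitness = 1, subclone_time = 3,
      n_clonal = 0, n_final = 400))
    tt$transfer_labels$subclone_cellular_fraction
  })
  se <- sd(fr) / sqrt(reps)
  expect_lt(abs(mean(fr) - 1 / 8), 3 * se + 1 / 400)
})

test_that("selected-subclone fractions agree with an independent two-type oracle", {
  set.seed(73)
  reps <- 120
  pkg <- replicate(reps, {
    tt <- simulate_deterministic(deterministic_sim_params(
      mutation_rate = 0, subclone_fitness = 3, subclone_time = 3,
      n_clonal = 0, n_final = 300))
    tt$transfer_labels$subclone_cellular_fraction
  })
  orc <- replicate(reps, oracle_two_type(300, 1, 0.2, 3, 3))
  se <- sqrt(var(pkg) / reps + var(orc) / reps)
  expect_lt(abs(mean(pkg) - mean(orc)), 3 * se)
})

test_that("the GP viable-parameter sampler respects bounds and noise settings", {
  set.seed(74)
  pilot <- tibble::tibble(
    fitness = runif(120, 1.5, 6),
    t_s = runif(120, 2, 10)
  )
  # synthetic viability surface: higher fitness tolerates later emergence
  pilot$subclone_vaf <- pmin(pmax(
    0.25 + 0.08 * (pilot$fitness - 3.5) - 0.05 * (pilot$t_s - 6) +
      rnorm(120, 0, 0.03), 0), 0.5)
  sampler <- viable_param_sampler(pilot)
  draws <- sampler(200)
  expect_true(all(draws$fitness >= min(pilot$fitness) - 1e-9))
  expect_true(all(draws$fitness <= max(pilot$fitness) + 1e-9))
  ok <- pilot$subclone_vaf >= 0.1 & pilot$subclone_vaf <= 0.4
  expect_true(all(draws$t_s >= min(pilot$t_s[ok]) - 1e-9))
  expect_true(all(draws$t_s <= max(pilot$t_s[ok]) + 1e-9))

  # without the white-noise kernel, repeated draws at one fitness are
  # near-constant (smooth pilot surface, so the GP mean is deterministic)
  smooth <- tibble::tibble(fitness = runif(100, 1.5, 6))
  smooth$t_s <- 8 - 0.8 * smooth$fitness
  smooth$subclone_vaf <- 0.25
  s0 <- viable_param_sampler(smooth, white_noise = 0)
  d0 <- with_fixed_fitness(s0, 3)
  expect_lt(sd(d0), 0.05)
  expect_error(viable_param_sampler(pilot[1:10, ]), "50")
})

test_that("renovation keeps trunk weights verbatim and adds four branches", {
  toy <- get_toy_models()
  tr <- renovate(toy$ms, toy$s1, seed = 75)
  expect_s3_class(tr, "evo_net_transfer")
  expect_length(tr$tasks, 4)
  # donor trunk weights copied bit-for-bit
  expect_identical(tr$par[["a.t1.c1.W"]], toy$ms$par[["t1.c1.W"]])
  expect_identical(tr$par[["b.t2.c2.W"]], toy$s1$par[["t2.c2.W"]])
  # four heads, each with two dense layers
  head_par <- grep("^h\\.", names(tr$par), value = TRUE)
  expect_length(head_par, 16)

  bad <- toy$s1
  bad$meta$featurization$k_list <- c(32, 64)
  expect_error(renovate(toy$ms, bad), "featurization")
})

test_that("fine-tuning learns and mutation-rate calibration removes injected bias", {
  set.seed(76)
  toy <- get_toy_models()
  tr <- renovate(toy$ms, toy$s1, seed = 77)
  n <- 400
  X <- matrix(rpois(n * 192, 3), n, 192)
  mu <- runif(n, 10, 50)
  X[, 5] <- mu + rnorm(n)  # recoverable signal for the mutation-rate task
  lab <- tibble::tibble(
    mutation_rate = mu, fitness = runif(n, 1.5, 4),
    emergence_time = runif(n, 2, 9),
    cellular_fraction = runif(n, 0.2, 0.8)
  )
  cfg <- train_config(max_epochs = 6, patience = 5, seed = 78)
  tr <- finetune(tr, X, lab, cfg)
  expect_true(tr$meta$trained)
  h <- tr$meta$history
  expect_lt(h$val_loss[nrow(h)], h$val_loss[1] + 0.5)
  # featurization metadata untouched by fine-tuning
  expect_identical(tr$meta$featurization, toy$ms$meta$featurization)

  # injected halving: calibrating against 2x the raw predictions must
  # roughly double calibrated outputs
  raw <- predict_transfer(tr, X[1:100, ], T = 10, seed = 79,
                          calibrated = FALSE)$mean$mutation_rate
  tr2 <- calibrate_mu(tr, X[1:100, ], true_mu = 2 * raw, T = 10, seed = 79)
  cal <- predict_transfer(tr2, X[1:100, ], T = 10, seed = 79)$mean$mutation_rate
  mpe_cal <- mean(abs(cal - 2 * raw) / pmax(abs(2 * raw), 1e-6))
  mpe_raw <- mean(abs(raw - 2 * raw) / pmax(abs(2 * raw), 1e-6))
  expect_lt(mpe_cal, mpe_raw)
})

test_that("frozen trunks remain identical through fine-tuning", {
  toy <- get_toy_models()
  tr <- renovate(toy$ms, toy$s1, seed = 80)
  X <- matrix(rpois(120 * 192, 3), 120, 192)
  lab <- tibble::tibble(
    mutation_rate = runif(120, 10, 50), fitness = runif(120, 1.5, 4),
    emergence_time = runif(120, 2, 9),
    cellular_fraction = runif(120, 0.2, 0.8)
  )
  tr2 <- finetune(tr, X, lab, train_config(max_epochs = 2, patience = 3,
                                           seed = 81),
                  freeze_trunk = TRUE)
  for (nm in tr$trunk_names) {
    expect_identical(tr2$par[[nm]], tr$par[[nm]])
  }
})
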