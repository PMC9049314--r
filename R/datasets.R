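# Desk-scale dataset generators: the study conditions (parameter ranges,
# sample sizes, noise levels) used to train and evaluate the models live
# here, with one documented default per argument. The methods vignette
# explains each choice.

#' Simulate a paired training/evaluation set
#'
#' Generates `n_pairs` matched selection/neutral virtual biopsies (see
#' [generate_pair()]) with simulation and sequencing parameters drawn
#' uniformly from the stated ranges, and featurizes each arm. Mutations
#' carried by fewer than `min_cells` of the simulated cells (below the
#' sequencing detection limit) are not tracked.
#'
#' @param n_pairs Number of pairs (the set holds `2 * n_pairs` samples).
#' @param mu_range Per-genome per-division mutation rate range.
#' @param p_driver_log10 Log10 range for the driver probability.
#' @param s_mean_range Range for the exponential selection-coefficient mean.
#' @param n_clonal_range Range for the clonal mutation count.
#' @param n_final Simulated final population size.
#' @param depth_range Mean sequencing depth range.
#' @param rho_range Beta-binomial overdispersion range.
#' @param purity_range Tumour purity range (default exactly 1: models are
#'   trained on purity-corrected data).
#' @param min_cells Carrier-count floor for tracked mutations.
#' @param k_list Histogram resolutions.
#' @param keep_samples Also return the `vaf_sample` objects (memory-heavy).
#' @param seed Optional RNG seed.
#' @return List with `features` (matrix, `2 n_pairs` rows), `labels`
#'   (tibble: `mode`, `n_subclones`, `f1`, `f2`, `arm`, `pair_id`, `depth`,
#'   `rho`, `purity`, `mu`), and optionally `samples`.
#' @export
simulate_training_pairs <- function(n_pairs,
                                    mu_range = c(5, 100),
                                    p_driver_log10 = c(-4.5, -2.5),
                                    s_mean_range = c(0.5, 2),
                                    n_clonal_range = c(100, 500),
                                    n_final = 1000,
                                    depth_range = c(100, 150),
                                    rho_range = c(0, 0.003),
                                    purity_range = c(1, 1),
                                    min_cells = 16L,
                                    k_list = c(64, 128),
                                    keep_samples = FALSE,
                                    seed = NULL) {
  with_seed(seed, {
    n <- 2L * n_pairs
    features <- matrix(0, n, sum(k_list))
    labels <- vector("list", n)
    samples <- if (keep_samples) vector("list", n) else NULL
    for (i in seq_len(n_pairs)) {
      mu <- runif(1, mu_range[1], mu_range[2])
      sp <- selection_params(
        mutation_rate = mu,
        p_driver = 10^runif(1, p_driver_log10[1], p_driver_log10[2]),
        s_mean = runif(1, s_mean_range[1], s_mean_range[2]),
        n_clonal = round(runif(1, n_clonal_range[1], n_clonal_range[2])),
        n_final = n_final
      )
      qp <- sequencing_params(
        mean_depth = runif(1, depth_range[1], depth_range[2]),
        rho = runif(1, rho_range[1], rho_range[2]),
        purity = runif(1, purity_range[1], purity_range[2])
      )
      pr <- generate_pair(sp, qp, min_cells = min_cells)
      for (arm in c("selected", "neutral")) {
        j <- if (arm == "selected") 2L * i - 1L else 2L * i
        s <- pr[[arm]]$sample
        features[j, ] <- as.numeric(featurize(s, k_list = k_list))
        l <- pr[[arm]]$labels
        labels[[j]] <- tibble::new_tibble(list(
          mode = l$mode, n_subclones = l$n_subclones,
          f1 = if (l$n_subclones >= 1) l$subclone_vafs[1] else NA_real_,
          f2 = if (l$n_subclones >= 2) l$subclone_vafs[2] else NA_real_,
          arm = arm, pair_id = i, depth = qp$mean_depth, rho = qp$rho,
          purity = qp$purity, mu = mu, n_mutations = nrow(s)
        ), nrow = 1L)
        if (keep_samples) samples[[j]] <- s
      }
    }
    out <- list(features = features, labels = dplyr::bind_rows(labels))
    if (keep_samples) out$samples <- samples
    out
  })
}

#' Train the three evolutionary inference models on a paired set
#'
#' Trains the classification model (`M_ms`: P(Selection) and P(0/1/2
#' subclones)), the single-subclone frequency regressor (`M_1s`) and, when
#' enough two-subclone simulations are present, the two-subclone regressor
#' (`M_2s`) on the output of [simulate_training_pairs()].
#'
#' @param dataset A [simulate_training_pairs()] result.
#' @param cfg A [train_config()]; the default uses 14 epochs with patience 5
#'   and no per-epoch rebalancing. At desk scale an epoch is one pass over
#'   the static set (the gradient-step budget then matches streaming
#'   training over far larger stores), and uniform-minimum frequency
#'   downsampling ([rebalance()]) would discard most positive simulations
#'   of a static pool each epoch; the stochastic-arrival simulator already
#'   spreads subclone frequencies broadly, so training defaults to the full
#'   pool.
#' @param cfg_reg Configuration for the frequency regressors; the default
#'   uses more epochs so that the regression models (trained only on the
#'   positive-selection subset, a quarter of the pool) receive a gradient-
#'   step budget comparable to the classifier's.
#' @param spec_ms,spec_1s,spec_2s [model_spec()]s for the three models.
#' @param min_2s Minimum number of two-subclone simulations required to
#'   train `M_2s` (otherwise `NULL` is returned for it, with a warning).
#' @param n_restarts Number of independently initialized training runs for
#'   each frequency regressor; the run with the lowest validation loss is
#'   kept (a small model-selection step mirroring hyperparameter-search
#'   pipelines that keep the best-validating candidate).
#' @param seed Optional RNG seed.
#' @param verbose Print training progress.
#' @return List of class `"evolution_models"` with elements `ms`, `s1`,
#'   `s2` (possibly `NULL`).
#' @export
train_evolution_models <- function(dataset,
                                   cfg = train_config(max_epochs = 14,
                                                      patience = 5,
                                                      rebalance = FALSE),
                                   cfg_reg = train_config(max_epochs = 60,
                                                          patience = 5,
                                                          rebalance = FALSE),
                                   spec_ms = model_spec("ms"),
                                   spec_1s = model_spec("1s"),
                                   spec_2s = model_spec("2s"),
                                   min_2s = 60L,
                                   n_restarts = 2L,
                                   seed = NULL,
                                   verbose = FALSE) {
  with_seed(seed, {
    feat_meta <- list(k_list = spec_ms$k_list, normalize = FALSE)
    ms <- build_network(spec_ms, feat_meta)
    ms <- train(ms, dataset$features, dataset$labels, cfg, verbose = verbose)
    s1 <- train_best_of(spec_1s, feat_meta, dataset, cfg_reg, n_restarts,
                        verbose)
    n2 <- sum(dataset$labels$n_subclones == 2)
    s2 <- NULL
    if (n2 >= min_2s) {
      s2 <- train_best_of(spec_2s, feat_meta, dataset, cfg_reg, n_restarts,
                          verbose)
    } else {
      warn(sprintf(
        "only %d two-subclone simulations (< %d); M_2s not trained",
        n2, min_2s))
    }
    structure(list(ms = ms, s1 = s1, s2 = s2), class = "evolution_models")
  })
}

train_best_of <- function(spec, feat_meta, dataset, cfg, n_restarts,
                          verbose) {
  best <- NULL
  for (r in seq_len(max(1L, n_restarts))) {
    net <- build_network(spec, feat_meta)
    net <- train(net, dataset$features, dataset$labels, cfg,
                 verbose = verbose)
    v <- min(net$meta$history$val_loss)
    if (is.null(best) || v < best$v) best <- list(net = net, v = v)
  }
  best$net
}

#' Pilot table of deterministic-subclone outcomes
#'
#' Runs a small grid of (fitness, emergence time) combinations through
#' [simulate_deterministic()] (mutations switched off for speed; only the
#' realized subclone fraction matters) to map which combinations give
#' detectable subclones. Feed the result to [viable_param_sampler()].
#'
#' @param fitness_grid,t_s_grid Grids of values.
#' @param n_rep Replicates per combination.
#' @param n_final,birth,death Simulator settings.
#' @param seed Optional RNG seed.
#' @return Tibble with `fitness`, `t_s`, `subclone_vaf`.
#' @export
pilot_transfer_table <- function(fitness_grid = seq(1.5, 6, by = 0.5),
                                 t_s_grid = seq(2, 11, by = 1),
                                 n_rep = 2, n_final = 1e4, birth = 1,
                                 death = 0.2, seed = NULL) {
  with_seed(seed, {
    rows <- list()
    k <- 1
    for (f in fitness_grid) {
      for (ts in t_s_grid) {
        for (r in seq_len(n_rep)) {
          p <- deterministic_sim_params(
            mutation_rate = 0, subclone_fitness = f, subclone_time = ts,
            n_clonal = 0, birth = birth, death = death, n_final = n_final
          )
          tt <- simulate_deterministic(p)
          rows[[k]] <- tibble::new_tibble(list(
            fitness = f, t_s = ts,
            subclone_vaf = tt$transfer_labels$subclone_cellular_fraction / 2
          ), nrow = 1L)
          k <- k + 1
        }
      }
    }
    dplyr::bind_rows(rows)
  })
}

#' Simulate a transfer-learning dataset with deterministic subclones
#'
#' Generates `n` virtually biopsied tumours from the deterministic-subclone
#' simulator. A fraction `p_neutral` carries no subclone; the rest draw
#' (fitness, emergence time) from `sampler` (see [viable_param_sampler()]).
#'
#' @param n Number of simulations.
#' @param sampler Function `n -> tibble(fitness, t_s)`.
#' @param p_neutral Fraction of simulations without a subclone.
#' @param mu_range Mutation-rate range (uniform).
#' @param depth_range Mean-depth range.
#' @param rho Beta-binomial overdispersion.
#' @param n_clonal,n_final,birth,death Simulator settings.
#' @param min_cells Carrier floor for tracked mutations.
#' @param k_list Histogram resolutions.
#' @param seed Optional RNG seed.
#' @return List with `features` and `labels` (tibble: `mutation_rate`,
#'   `fitness`, `emergence_time`, `cellular_fraction`, `depth`,
#'   `detectable`).
#' @export
simulate_transfer_set <- function(n, sampler, p_neutral = 0.3,
                                  mu_range = c(5, 50),
                                  depth_range = c(75, 200), rho = 0.001,
                                  n_clonal = 500, n_final = 1e4, birth = 1,
                                  death = 0.2, min_cells = 160L,
                                  k_list = c(64, 128), seed = NULL) {
  with_seed(seed, {
    features <- matrix(0, n, sum(k_list))
    labels <- vector("list", n)
    pars <- sampler(n)
    neutral <- runif(n) < p_neutral
    t_max <- ceiling(log2(n_final)) + 1
    for (i in seq_len(n)) {
      mu <- runif(1, mu_range[1], mu_range[2])
      p <- deterministic_sim_params(
        mutation_rate = mu,
        subclone_fitness = if (neutral[i]) 1 else pars$fitness[i],
        subclone_time = if (neutral[i]) t_max else pars$t_s[i],
        n_clonal = n_clonal, birth = birth, death = death, n_final = n_final
      )
      tt <- simulate_deterministic(p, min_cells = min_cells)
      qp <- sequencing_params(
        mean_depth = runif(1, depth_range[1], depth_range[2]),
        rho = rho, depth_pool = n_final
      )
      s <- virtual_biopsy(tt, qp)
      features[i, ] <- as.numeric(featurize(s, k_list = k_list))
      cf <- tt$transfer_labels$subclone_cellular_fraction
      labels[[i]] <- tibble::new_tibble(list(
        mutation_rate = mu,
        fitness = p$subclone_fitness,
        emergence_time = p$subclone_time,
        cellular_fraction = cf,
        depth = qp$mean_depth,
        detectable = cf >= 0.2 && cf <= 0.8
      ), nrow = 1L)
    }
    list(features = features, labels = dplyr::bind_rows(labels))
  })
}
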