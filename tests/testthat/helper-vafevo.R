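# Shared fixtures and a session-level store for expensive objects (datasets,
# trained models) reused across test files. Everything is generated in code.

.vafevo_store <- new.env(parent = emptyenv())

store_get <- function(name, builder) {
  if (!exists(name, envir = .vafevo_store, inherits = FALSE)) {
    assign(name, builder(), envir = .vafevo_store)
  }
  get(name, envir = .vafevo_store, inherits = FALSE)
}

# A fake tumour_truth with prescribed driver lineages, for label tests.
fake_truth <- function(cellular_fractions) {
  out <- list(
    mutations = tibble::tibble(vaf = 0.5, cell_count = 1000L,
                               is_driver = FALSE, s = 0),
    driver_lineages = tibble::tibble(
      genotype = seq_along(cellular_fractions),
      cellular_fraction = cellular_fractions,
      cum_fitness = 2
    ),
    labels = NULL
  )
  class(out) <- "tumour_truth"
  attr(out, "n_final") <- 1000L
  out
}

# A synthetic vaf_sample with VAFs drawn around given cluster centres.
synthetic_sample <- function(centres, n_per = 150, depth = 120, sd = NULL,
                             seed = 1) {
  set.seed(seed)
  sd <- sd %||% sqrt(centres * (1 - centres) / depth)
  n_per <- rep_len(n_per, length(centres))
  sd <- rep_len(sd, length(centres))
  v <- unlist(mapply(function(m, s, k) rnorm(k, m, s), centres, sd, n_per,
                     SIMPLIFY = FALSE))
  v <- pmin(pmax(v, 0.02), 1)
  alt <- pmax(round(v * depth), 2)
  vafevo::vaf_sample(alt_count = alt, depth = rep(depth, length(alt)),
                     mean_depth = depth, provenance = "synthetic")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Small trained models for pipeline smoke tests (fast; not the
# acceptance-scale models).
get_toy_models <- function() {
  store_get("toy_models", function() {
    ds <- simulate_training_pairs(400, seed = 2001)
    suppressWarnings(train_evolution_models(
      ds,
      cfg = train_config(max_epochs = 6, patience = 3, seed = 2002),
      min_2s = 20L,
      seed = 2003
    ))
  })
}

# One featurized synthetic sample (neutral-ish) for dispatch tests.
get_toy_features_one <- function() {
  store_get("toy_features_one", function() {
    s <- synthetic_sample(c(0.1, 0.5), n_per = 200, depth = 120, seed = 9)
    as.numeric(vafevo::featurize(s))
  })
}

# Acceptance-scale paired dataset (25k simulations) and models; built once
# and shared between the classification and robustness criteria.
get_primary_dataset <- function() {
  store_get("primary_dataset", function() {
    simulate_training_pairs(12500, seed = 3001)
  })
}

get_holdout_dataset <- function() {
  store_get("holdout_dataset", function() {
    simulate_training_pairs(1500, seed = 3002)
  })
}

get_primary_models <- function() {
  store_get("primary_models", function() {
    suppressWarnings(train_evolution_models(
      get_primary_dataset(),
      seed = 3004
    ))
  })
}
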