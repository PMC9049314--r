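test_that("parameter validation rejects out-of-range inputs", {
  expect_error(selection_params(mutation_rate = -1), "mutation_rate")
  expect_error(selection_params(p_driver = 1.5), "p_driver")
  expect_error(selection_params(s_mean = 0), "s_mean")
  expect_error(selection_params(birth_rate = 0.1, death_rate = 0.2),
               "birth_rate")
  expect_error(selection_params(n_final = 1), "n_final")
})

test_that("founder-only tumours carry exactly the clonal mutations at VAF 0.5", {
  tt <- simulate_tumour(selection_params(mutation_rate = 0, n_clonal = 10,
                                         n_final = 300, seed = 11))
  expect_equal(nrow(tt$mutations), 10)
  expect_true(all(tt$mutations$vaf == 0.5))
  expect_true(all(tt$mutations$cell_count == 300))
  expect_equal(tt$labels$mode, "neutral")
})

test_that("no drivers can arise when p_driver is zero", {
  tt <- simulate_tumour(selection_params(mutation_rate = 20, p_driver = 0,
                                         n_final = 400, seed = 12))
  expect_equal(nrow(tt$driver_lineages), 0)
  expect_false(any(tt$mutations$is_driver))
  expect_equal(tt$labels$mode, "neutral")
  expect_equal(tt$labels$n_subclones, 0L)
})

test_that("mutation yield matches the 2*mu*(N-1) Poisson oracle", {
  # each of the N-1 divisions produces two daughters, each drawing
  # Poisson(mu) mutations, so the total count is Poisson(2*mu*(N-1))
  mu <- 10; n <- 1000; reps <- 200
  set.seed(13)
  totals <- replicate(reps, {
    tt <- simulate_tumour(selection_params(mutation_rate = mu, p_driver = 0,
                                           n_clonal = 0, n_final = n))
    nrow(tt$mutations)
  })
  expected <- 2 * mu * (n - 1)
  se <- sqrt(expected / reps)
  expect_lt(abs(mean(totals) - expected), 3 * se)
})

test_that("simulations are bit-identical under a fixed seed", {
  p <- selection_params(mutation_rate = 30, p_driver = 1e-3, n_final = 500,
                        seed = 99)
  a <- simulate_tumour(p)
  b <- simulate_tumour(p)
  expect_identical(a$mutations, b$mutations)
  expect_identical(a$driver_lineages, b$driver_lineages)
  expect_identical(unclass(a$labels), unclass(b$labels))
})

test_that("neutral site-frequency tail is power-law (log-log linear)", {
  set.seed(14)
  vafs <- unlist(lapply(1:100, function(i) {
    tt <- simulate_tumour(selection_params(mutation_rate = 20, p_driver = 0,
                                           n_clonal = 0, n_final = 1000),
                          min_cells = 16)
    tt$mutations$vaf
  }))
  f <- seq(0.02, 0.25, length.out = 30)
  M <- vapply(f, function(x) sum(vafs >= x), numeric(1))
  expect_true(all(diff(M) <= 0))  # cumulative spectrum is monotone
  fit <- summary(lm(log(M) ~ log(f)))
  expect_gte(fit$r.squared, 0.95)
})

test_that("raising the selection-coefficient mean does not reduce detectable subclones", {
  frac_detectable <- function(s_mean, seed) {
    set.seed(seed)
    mean(replicate(200, {
      tt <- simulate_tumour(selection_params(
        mutation_rate = 5, p_driver = 3e-3, s_mean = s_mean,
        n_clonal = 0, n_final = 500), min_cells = 8)
      tt$labels$n_subclones >= 1
    }))
  }
  lo <- frac_detectable(0.3, 15)
  hi <- frac_detectable(3, 16)
  expect_gte(hi, lo)
})

test_that("subclone labelling follows the detectability window and merge rule", {
  # cellular fraction 0.5 -> VAF 0.25, inside the 10-40% window
  l <- label_subclones(fake_truth(0.5))
  expect_equal(l$n_subclones, 1L)
  expect_equal(l$subclone_vafs, 0.25)
  expect_equal(l$mode, "selection")

  # no driver lineages -> neutral
  l0 <- label_subclones(fake_truth(numeric(0)))
  expect_equal(l0$mode, "neutral")
  expect_equal(l0$n_subclones, 0L)

  # VAFs 0.12 and 0.14 differ by < 0.05 -> merged at the larger VAF
  lm_ <- label_subclones(fake_truth(c(0.24, 0.28)))
  expect_equal(lm_$n_subclones, 1L)
  expect_equal(lm_$subclone_vafs, 0.14)

  # lineages outside the window are invisible
  lw <- label_subclones(fake_truth(c(0.10, 0.95)))
  expect_equal(lw$n_subclones, 0L)

  # three well-separated detectable lineages -> flagged unusable
  l3 <- label_subclones(fake_truth(c(0.22, 0.44, 0.70)))
  expect_false(l3$usable)
})
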