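test_that("Pareto draws respect support, quantiles, and the scale MLE", {
  x <- sample_pareto(1e5, shape = 1, scale = 0.05, seed = 21)
  expect_true(all(x >= 0.05))
  expect_true(all(x <= 0.5))  # resampled, not clipped
  # analytic quantile of the Pareto truncated to (0, 0.5] (draws above 0.5
  # are resampled): q_med = m * (1 - 0.5 * F(0.5))^(-1/alpha) with
  # F(0.5) = 1 - (m / 0.5)^alpha; = 0.05 / 0.55 here
  expect_lt(abs(median(x) - 0.05 / 0.55), 0.002)
  # ML refit returns the minimum observed frequency as the scale
  fit <- fit_pareto(x)
  expect_identical(fit$scale, min(x))
})

test_that("Pareto empirical CDF matches the analytic CDF", {
  x <- sample_pareto(2e4, shape = 1.3, scale = 0.04, seed = 22)
  grid <- seq(0.05, 0.45, length.out = 50)
  emp <- vapply(grid, function(g) mean(x <= g), numeric(1))
  # truncated-at-0.5 Pareto CDF
  FF <- function(q) (1 - (0.04 / q)^1.3) / (1 - (0.04 / 0.5)^1.3)
  expect_lt(max(abs(emp - FF(grid))), 0.02)
})

test_that("invalid Pareto parameters are rejected", {
  expect_error(sample_pareto(10, shape = 0, scale = 0.1), "shape")
  expect_error(sample_pareto(10, shape = 1, scale = 0.6), "scale")
})

test_that("neutral generator composes tail, clonal cluster and trimming", {
  # tail-free tumour holds only the clonal cluster
  g0 <- generate_neutral(neutral_params(n_tail = 0, n_clonal = 50,
                                        clonal_center = 0.47, seed = 23))
  expect_equal(nrow(g0$mutations), 50)
  expect_true(all(g0$mutations$vaf == 0.47))
  expect_equal(g0$labels$mode, "neutral")

  # when trimming fires, no tail mutation below trim_f survives
  trimmed <- NULL
  for (s in 1:300) {
    g <- generate_neutral(neutral_params(n_tail = 400, n_clonal = 20,
                                         p_trim = 0.1, trim_f = 0.2,
                                         pareto_scale = 0.03, seed = s))
    if (isTRUE(attr(g, "trimmed"))) { trimmed <- g; break }
  }
  expect_false(is.null(trimmed))
  tail_vafs <- trimmed$mutations$vaf[!attr(trimmed, "is_clonal")]
  expect_true(all(tail_vafs >= 0.2))
  expect_equal(trimmed$labels$n_subclones, 0L)

  expect_error(neutral_params(p_trim = 0.5), "p_trim")
  expect_error(neutral_params(clonal_center = 0.30), "clonal_center")
})

test_that("paired arms share clonal and total mutation counts pre-noise", {
  sp <- selection_params(mutation_rate = 30, p_driver = 1e-3, n_final = 500)
  qp <- sequencing_params(mean_depth = 120, rho = 0.001)
  for (s in 1:5) {
    pr <- generate_pair(sp, qp, seed = 100 + s)
    expect_equal(pr$meta$n_clonal[1], pr$meta$n_clonal[2])
    if (!pr$meta$trimmed[2]) {
      expect_equal(pr$meta$n_total[1], pr$meta$n_total[2])
    }
    expect_s3_class(pr$selected$sample, "vaf_sample")
    expect_equal(pr$neutral$labels$n_subclones, 0L)
  }
})

test_that("pairs are reproducible under a fixed seed", {
  sp <- selection_params(mutation_rate = 20, p_driver = 1e-3, n_final = 400)
  qp <- sequencing_params(mean_depth = 100)
  a <- generate_pair(sp, qp, seed = 42)
  b <- generate_pair(sp, qp, seed = 42)
  expect_identical(a$selected$sample$vaf, b$selected$sample$vaf)
  expect_identical(a$neutral$sample$vaf, b$neutral$sample$vaf)
})

test_that("paired arms have indistinguishable mean depths (shared noise)", {
  sp <- selection_params(mutation_rate = 20, p_driver = 1e-3, n_final = 400)
  qp <- sequencing_params(mean_depth = 100)
  set.seed(24)
  d <- vapply(1:200, function(i) {
    pr <- generate_pair(sp, qp)
    mean(pr$selected$sample$depth) - mean(pr$neutral$sample$depth)
  }, numeric(1))
  expect_lt(abs(mean(d)), 3 * sd(d) / sqrt(length(d)))
})
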