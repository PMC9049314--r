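test_that("lower cutoff is the callable frequency plus two binomial SDs", {
  expect_equal(lower_cutoff(0, 100), 0)
  expect_equal(lower_cutoff(0.02, 100), 0.048)
  # cutoff approaches f_alt monotonically as depth grows
  cs <- vapply(c(50, 100, 500, 5000), function(c) lower_cutoff(0.02, c),
               numeric(1))
  expect_true(all(diff(cs) < 0))
  expect_lt(abs(cs[4] - 0.02), 0.01)
  expect_error(lower_cutoff(0.02, 0), "c")
})

test_that("histograms bin the fixed 2-50% VAF range at the stated widths", {
  s <- vaf_sample(alt_count = 25, depth = 100, mean_depth = 100)
  fv <- featurize(s)
  expect_length(fv, 192)
  expect_true(all(fv >= 0))
  # k = 64 -> bin width 0.48/64 = 0.0075; single mutation at VAF 0.25 fills
  # exactly one bin per histogram, at 0-based index floor((0.25-0.02)/w)
  h64 <- as.numeric(fv)[1:64]
  h128 <- as.numeric(fv)[65:192]
  expect_equal(sum(h64), 1)
  expect_equal(sum(h128), 1)
  expect_equal(which(h64 > 0) - 1L, floor((0.25 - 0.02) / (0.48 / 64)))
  expect_equal(which(h128 > 0) - 1L, floor((0.25 - 0.02) / (0.48 / 128)))
})

test_that("mutations below the cutoff or above 0.5 contribute to no bin", {
  v <- c(0.03, 0.20, 0.45, 0.60)  # cutoff at depth 100 is 0.048
  fv <- featurize(v, mean_depth = 100)
  expect_equal(attr(fv, "n_retained"), 2)
  expect_equal(sum(as.numeric(fv)[1:64]), 2)
  # total histogram count equals the number of retained mutations
  expect_equal(sum(as.numeric(fv)[65:192]), attr(fv, "n_retained"))
})

test_that("empty samples featurize to a zero vector", {
  fv <- featurize(numeric(0), mean_depth = 100)
  expect_length(fv, 192)
  expect_true(all(as.numeric(fv) == 0))
})

test_that("featurization is invariant to mutation order", {
  set.seed(41)
  v <- runif(500, 0.02, 0.5)
  a <- featurize(v, mean_depth = 120)
  b <- featurize(sample(v), mean_depth = 120)
  expect_identical(as.numeric(a), as.numeric(b))
})

test_that("density normalization divides by the retained count", {
  set.seed(42)
  v <- runif(300, 0.1, 0.4)
  raw <- as.numeric(featurize(v, mean_depth = 100))
  nrm <- as.numeric(featurize(v, mean_depth = 100, normalize = TRUE))
  expect_equal(sum(nrm[1:64]), 1)
  expect_equal(nrm[1:64], raw[1:64] / sum(raw[1:64]))
})

test_that("Tajima's D matches a hand-computed textbook oracle", {
  # n = 4, frequencies {0.25, 0.25, 0.5}: theta_pi = 5/3, theta_W = 3/a1,
  # D = 0.1676557950 (frozen from an independent evaluation of the
  # standard constants a1, a2, b1, b2, c1, c2, e1, e2)
  d <- tajimas_d(c(0.25, 0.25, 0.5), mean_depth = 4)
  expect_equal(d$theta_pi, 5 / 3, tolerance = 1e-12)
  expect_equal(d$statistic, 0.1676557950, tolerance = 1e-8)
  expect_false(d$degenerate)
})

test_that("Tajima's D degenerates to zero without segregating sites", {
  d <- tajimas_d(numeric(0), mean_depth = 100)
  expect_equal(d$statistic, 0)
  expect_true(d$degenerate)
})

test_that("Fay and Wu's H behaves per the theta_pi - theta_H identity", {
  # single site at p = 0.5: theta_pi = theta_H -> H = 0
  h <- fay_wu_h(0.5, mean_depth = 50)
  expect_equal(h$statistic, 0, tolerance = 1e-12)
  # equal p: sign of H is the sign of (1 - 2p)
  h_lo <- fay_wu_h(rep(0.2, 5), mean_depth = 50)
  h_hi <- fay_wu_h(rep(0.8, 5), mean_depth = 50)
  expect_gt(h_lo$statistic, 0)
  expect_lt(h_hi$statistic, 0)
  # frozen oracle for n = 4, {0.25, 0.25, 0.5}
  h4 <- fay_wu_h(c(0.25, 0.25, 0.5), mean_depth = 4)
  expect_equal(h4$statistic, 2 / 3, tolerance = 1e-10)
  expect_equal(fay_wu_h(numeric(0), mean_depth = 10)$statistic, 0)
})

test_that("summary statistics are invariant to mutation order", {
  set.seed(43)
  v <- runif(200, 0.05, 0.6)
  expect_equal(tajimas_d(v, 80)$statistic,
               tajimas_d(rev(v), 80)$statistic)
  expect_equal(fay_wu_h(v, 80)$statistic,
               fay_wu_h(sample(v), 80)$statistic)
})
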