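test_that("purity correction rescales VAFs and inverts dilution", {
  s <- vaf_sample(alt_count = c(30, 10), depth = c(100, 100),
                  mean_depth = 100, purity = 0.6)
  corr <- purity_correct(s, 0.6)
  expect_equal(corr$vaf, c(0.50, 1 / 6))
  expect_identical(purity_correct(s, 1)$vaf, s$vaf)
  expect_error(purity_correct(s, 0), "purity")

  # simulation oracle: biopsy at purity 0.7, correct with the true purity,
  # clonal cluster recentres at 0.5
  set.seed(61)
  tt <- generate_neutral(neutral_params(n_tail = 300, n_clonal = 300,
                                        pareto_scale = 0.03))
  b <- virtual_biopsy(tt, sequencing_params(mean_depth = 150, purity = 0.7,
                                            depth_pool = 1000))
  corr2 <- purity_correct(b, 0.7)
  clonal <- corr2$vaf[corr2$vaf > 0.4 & corr2$vaf < 0.6]
  expect_lt(abs(mean(clonal) - 0.5), 0.02)
})

test_that("clonal-peak adjustment recentres a shifted clonal cluster", {
  # cluster at 0.40 emulates a 25% purity overestimate
  s <- synthetic_sample(c(0.08, 0.40), n_per = c(250, 250), depth = 150,
                        sd = c(0.03, 0.04), seed = 62)
  adj <- clonal_peak_adjust(s)
  expect_true(attr(adj, "clonal_adjusted"))
  cl <- adj$vaf[abs(adj$vaf - 0.5) < 0.12]
  expect_lt(abs(mean(cl) - 0.5), 0.02)

  # an already-centred cluster yields a scale factor near one
  s2 <- synthetic_sample(c(0.10, 0.50), n_per = c(200, 300), depth = 150,
                         sd = c(0.03, 0.04), seed = 63)
  adj2 <- clonal_peak_adjust(s2)
  expect_lt(abs(attr(adj2, "clonal_scale") - 1), 0.05)

  # closest peak at or below 0.35: no adjustment, warning emitted
  s3 <- synthetic_sample(c(0.30), n_per = 400, depth = 200, sd = 0.03,
                         seed = 64)
  expect_warning(adj3 <- clonal_peak_adjust(s3), "0.35")
  expect_identical(adj3$vaf, s3$vaf)
  expect_false(attr(adj3, "clonal_adjusted"))

  expect_error(clonal_peak_adjust(synthetic_sample(0.5, n_per = 10)),
               "100")
})

test_that("binomial-variance cluster windows match the closed form", {
  s <- vaf_sample(alt_count = c(5, 14, 20, 26, 50, 60),
                  depth = rep(100, 6), mean_depth = 100)
  ca <- heuristic_cluster(s, 0.2, mean_depth = 100, eps = 2)
  w <- attr(ca, "windows")
  sub <- w[w$cluster == "subclone_1", ]
  # 2 * sqrt(0.2 * 0.8 / 100) = 0.08 -> window [0.12, 0.28]
  expect_equal(sub$lower, 0.12)
  expect_equal(sub$upper, 0.28)
  expect_equal(ca$cluster,
               c("tail", "subclone_1", "subclone_1", "subclone_1",
                 "clonal", "clonal"))

  # eps = 0 degenerates the window to the point {q}
  ca0 <- heuristic_cluster(s, 0.2, mean_depth = 100, eps = 0)
  w0 <- attr(ca0, "windows")
  expect_equal(w0$lower[w0$cluster == "subclone_1"], 0.2)
  expect_equal(w0$upper[w0$cluster == "subclone_1"], 0.2)
})

test_that("no-subclone clustering splits tail from clonal at the window edge", {
  s <- vaf_sample(alt_count = c(5, 20, 44, 50), depth = rep(100, 4),
                  mean_depth = 100)
  ca <- heuristic_cluster(s, numeric(0), mean_depth = 100, eps = 2)
  edge <- 0.5 - 2 * sqrt(0.25 / 100)
  expect_equal(ca$cluster, ifelse(s$vaf >= edge, "clonal", "tail"))
  expect_true(all(ca$cluster %in% c("tail", "clonal")))
})

test_that("cluster windows shrink with increasing depth", {
  s <- vaf_sample(alt_count = 20, depth = 100, mean_depth = 100)
  widths <- vapply(c(50, 100, 200, 400), function(c) {
    w <- attr(heuristic_cluster(s, 0.25, mean_depth = c), "windows")
    diff(c(w$lower[2], w$upper[2]))
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("overlapping subclone windows split at the midpoint", {
  s <- vaf_sample(alt_count = c(18, 22), depth = rep(100, 2),
                  mean_depth = 100)
  ca <- heuristic_cluster(s, c(0.24, 0.16), mean_depth = 100, eps = 2)
  w <- attr(ca, "windows")
  expect_equal(w$lower[w$cluster == "subclone_1"], 0.20)
  expect_equal(w$upper[w$cluster == "subclone_2"], 0.20)
})

test_that("tumour age follows log2((1 - f_sub) N_end)", {
  expect_equal(tumour_age(0, 2^30), 30)
  expect_equal(tumour_age(0.5, 2^10), 9)
  expect_equal(tumour_age(0.5, 1e10), log2(5e9))
  expect_error(tumour_age(1, 100), "f_sub")
})

test_that("rescaling reduces to identity at equal population sizes", {
  r <- rescale_estimates(w = 2.5, t_s = 5, f_sub = 0.3, n_sim = 1e4,
                         n_real = 1e4)
  expect_equal(r$w_r, 2.5)
  expect_equal(r$t_s_r, 5)
  # neutral fitness rescales to neutral fitness
  expect_equal(rescale_estimates(1, 4, 0.2, 1e3, 1e10)$w_r, 1)
})

test_that("rescaling matches an independent evaluation of the formulas", {
  # frozen from a separate hand evaluation: w = 3, t_s = 6, f_sub = 0.4,
  # N_sim = 1e4, N_real = 1e10
  r <- rescale_estimates(3, 6, 0.4, 1e4, 1e10)
  expect_equal(r$t_s_r, 15, tolerance = 1e-10)
  expect_equal(r$t_end, 12.5507467854, tolerance = 1e-8)
  expect_equal(r$t_end_r, 32.4823153547, tolerance = 1e-8)
  expect_equal(r$w_r, 1.7494140968, tolerance = 1e-8)
  expect_lt(r$t_s_r, r$t_end_r)
  # non-physical rescales error out
  expect_error(rescale_estimates(2, 9, 0.9, 1e4, 100), "non-physical")
})

test_that("purity correction inverts dilution through the full noise model", {
  set.seed(65)
  true_vafs <- c(sample_pareto(400, 1, 0.03), rep(0.5, 300))
  for (pur in c(0.5, 0.8)) {
    b <- virtual_biopsy(true_vafs,
                        sequencing_params(mean_depth = 200, purity = pur,
                                          depth_pool = 1000))
    corr <- purity_correct(b, pur)
    clonal <- corr$vaf[corr$vaf > 0.4 & corr$vaf < 0.6]
    expect_lt(abs(mean(clonal) - 0.5), 0.02)
  }
})
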