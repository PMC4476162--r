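test_that("binomial counting follows the exact two-sided convention", {
  # 8 higher, 2 lower, 1 tied -> p = 2 * (45 + 10 + 1) / 1024
  recs <- tibble::tibble(
    gene_id = sprintf("g%02d", 1:11),
    density_second = c(rep(0.3, 8), rep(0.1, 2), 0.2),
    density_penultimate = c(rep(0.1, 8), rep(0.3, 2), 0.2),
    intron5_second = 100, intron5_penultimate = 100
  )
  res <- second_vs_penultimate_test(records = recs)
  expect_equal(res$n_higher, 8L)
  expect_equal(res$n_lower, 2L)
  expect_equal(res$n_tied, 1L)
  expect_equal(res$p_binomial, 2 * (45 + 10 + 1) / 1024)
  # equal counts -> p = 1
  recs2 <- recs
  recs2$density_second <- rep(c(0.3, 0.1), c(5, 6))
  recs2$density_penultimate <- rep(c(0.1, 0.3), c(5, 6))
  recs2$density_second[11] <- 0.1
  recs2$density_penultimate[11] <- 0.3
  r2 <- second_vs_penultimate_test(records = recs2)
  expect_equal(r2$p_binomial, 1)
  # all tied -> error
  recs3 <- recs
  recs3$density_second <- recs3$density_penultimate
  expect_error(second_vs_penultimate_test(records = recs3),
               "no informative pairs")
})

test_that("terminal exons never enter paired records", {
  fx <- small_species()
  recs <- paired_density_records(fx$features, fx$cfg$ese_set)
  feats <- fx$features
  pen_idx <- feats$exon_index[match(recs$gene_id, feats$gene_id)]
  n_ex <- feats$n_exons[match(recs$gene_id, feats$gene_id)]
  expect_true(all(n_ex >= 4))
  # the last exon is index n_exons: internal features stop at n - 1
  expect_true(all(feats$exon_index < feats$n_exons))
})

test_that("loess residuals behave like a linear smoother", {
  set.seed(2)
  x <- runif(60, 1, 4)
  y <- 2 * x + 1
  fit <- loess_fit(x, y, span = 0.75, degree = 1)
  expect_lt(max(abs(fit$residual)), 1e-6)
  # shifting y shifts the fit, residuals unchanged
  fit2 <- loess_fit(x, y + rnorm(60), span = 0.75)
  fit3 <- loess_fit(x, fit2$y + 5, span = 0.75)
  expect_equal(fit3$residual, fit2$residual, tolerance = 1e-8)
  # curvature left behind at span 1, degree 1 on quadratic data
  xq <- seq(-1, 1, length.out = 50)
  fq <- loess_fit(xq, xq^2, span = 1, degree = 1)
  expect_gt(sum(abs(fq$residual)), 0.1)
})

test_that("loess-residual class test detects a planted density excess", {
  pr <- simulate_paired_density(600, class_effect = 0.05, seed = 101)
  res <- loess_residual_test(pr)
  expect_lt(res$p_mwu, 0.01)
  expect_gt(res$n_res_higher, res$n_res_lower)
  expect_error(loess_residual_test(pr, span = 1.5), "span")
  expect_error(loess_residual_test(pr[1:10, ]), "at least 30")
})

test_that("splice-site class intron-size comparison", {
  # exact U-distribution check: sizes {500, 600} vs {100, 200},
  # one-sided p for complete separation with n1 = n2 = 2 is 1/6
  f <- tibble::tibble(donor = c("AGgt", "AGgt", "CTgt", "CTgt"),
                      intron3 = c(500L, 600L, 100L, 200L))
  res <- splice_site_intron_size_test(f, alternative = "greater")
  expect_equal(res$p, 1 / 6)
  expect_equal(res$median_aggt, 550)
  expect_equal(res$median_other, 150)
  expect_error(splice_site_intron_size_test(
    tibble::tibble(donor = "AGgt", intron3 = 10L)), "empty")
  # degenerate single observation per group warns
  expect_warning(splice_site_intron_size_test(
    tibble::tibble(donor = c("AGgt", "CTgt"), intron3 = c(10L, 20L))),
    "degenerate")
})
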