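test_that("monotone profiles give rho of +/-1 with the stated sign", {
  # build a feature pool where one codon strictly decreases with distance
  pool <- simulate_trend_exon_pool(6000, n_planted = 2, effect = 1,
                                   seed = 21)
  tt <- positional_trend_test(pool$features, "codon", "5prime")
  # enrichment near the junction (decreasing away from it): negative rho
  down <- tt[tt$kmer %in% pool$down, ]
  expect_true(all(down$rho < -0.9))
  up <- tt[tt$kmer %in% pool$up, ]
  expect_true(all(up$rho > 0.9))
})

test_that("constant proportions give rho 0, p 1, not significant", {
  pool <- simulate_trend_exon_pool(500, n_planted = 0, seed = 4)
  tt <- positional_trend_test(pool$features, "codon", "5prime")
  expect_true(all(is.finite(tt$rho)))
  # Bonferroni threshold arithmetic: raw p 0.01 not significant at
  # alpha = 0.05 over 61 codons
  fake_sig <- 0.01 < 0.05 / 61
  expect_false(fake_sig)
  expect_true(all(tt$p_raw[tt$significant] < 0.05 / 61))
})

test_that("amino-acid family uses 20-way Bonferroni and collapses codons", {
  pool <- simulate_trend_exon_pool(2000, n_planted = 2, effect = 1,
                                   seed = 8)
  tt <- positional_trend_test(pool$features, "amino_acid", "3prime")
  expect_equal(sort(unique(nchar(tt$kmer))), 1L)
  expect_equal(nrow(tt), 20L)
  expect_true(all(tt$p_raw[tt$significant] < 0.05 / 20))
})

test_that("cis-motif usage metric is deterministic and bounded", {
  pool <- simulate_trend_exon_pool(1500, n_planted = 6, effect = 0.9,
                                   seed = 31)
  u1 <- cis_motif_usage(pool$features, subsample_size = 300,
                        repetitions = 5, seed = 99)
  u2 <- cis_motif_usage(pool$features, subsample_size = 300,
                        repetitions = 5, seed = 99)
  expect_identical(u1, u2)
  expect_true(all(unlist(u1[, c("y_codon", "y_aa", "y_codon_sub",
                                "y_aa_sub")]) >= 0))
  expect_true(all(unlist(u1[, c("y_codon", "y_aa", "y_codon_sub",
                                "y_aa_sub")]) <= 1))
  expect_error(cis_motif_usage(pool$features, subsample_size = 0),
               "positive")
  # both-ends rule is at least as strict as either-end
  u_both <- cis_motif_usage(pool$features, subsample_size = 300,
                            repetitions = 5, seed = 99, rule = "both")
  expect_lte(u_both$y_codon, u1$y_codon)
})

test_that("subsampled Y approaches full-pool Y as subsample size grows", {
  pool <- simulate_trend_exon_pool(3000, n_planted = 4, effect = 0.6,
                                   seed = 13)
  u_small <- cis_motif_usage(pool$features, subsample_size = 150,
                             repetitions = 20, seed = 7)
  u_large <- cis_motif_usage(pool$features, subsample_size = 3000,
                             repetitions = 20, seed = 7)
  d_small <- abs(u_small$y_codon_sub - u_small$y_codon)
  d_large <- abs(u_large$y_codon_sub - u_large$y_codon)
  expect_lte(d_large, d_small + 1e-9)
})

test_that("splice-site usage proportions count AGgt / agGT exactly", {
  f <- tibble::tibble(
    donor = c(rep("AGgt", 3), rep("CTgt", 7)),
    acceptor = c(rep("agGT", 5), rep("agCA", 5))
  )
  u <- splice_site_usage(f)
  expect_equal(u$p1, 0.3)
  expect_equal(u$p2, 0.5)
  # permutation invariance
  u2 <- splice_site_usage(f[sample(nrow(f)), ])
  expect_equal(u$p1, u2$p1)
  expect_equal(u$p2, u2$p2)
  expect_equal(splice_site_usage(tibble::tibble(
    donor = rep("AGgt", 4), acceptor = rep("agGT", 4)))$p1, 1)
  expect_error(splice_site_usage(tibble::tibble(
    donor = NA_character_, acceptor = "agGT")), "no donor")
})
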