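# constraint machinery on a mid-sized simulated species; heavier
# end-to-end parameter recovery lives in test-acceptance.R

cdat <- local({
  cfg <- sim_config(seed = 5L, n_genes = 150L)
  sim <- simulate_species_genes(cfg)
  feats <- extract_internal_exon_features(sim$genes)
  orth <- simulate_orthologs(sim$genes, cfg$ese_set, d_core = 0.06,
                             ese_constraint = 0.4, seed = 6L)
  list(cfg = cfg, sim = sim, feats = feats, orth = orth,
       data = prepare_constraint_data(feats, orth))
})

test_that("equal-count bins differ by at most one exon end", {
  bins <- binned_flank_constraint(NULL, NULL, cdat$cfg$ese_set,
                                  n_bins = 20, pseudo_reps = 0,
                                  data = cdat$data)
  for (side in unique(bins$end)) {
    ns <- bins$n_ends[bins$end == side]
    expect_lte(max(ns) - min(ns), 1L)
    expect_true(all(diff(bins$upper_limit[bins$end == side]) >= 0))
  }
  # 40 ends into 20 bins -> exactly 2 each
  fl <- cdat$data$flanks[cdat$data$flanks$end == "5prime", ][1:40, ]
  expect_true(all(table(splicesel:::equal_count_bins(fl, 20)) == 2))
  expect_error(splicesel:::equal_count_bins(fl[1:10, ], 20), "more bins")
})

test_that("constraint formula and sign conventions hold", {
  # ks_core 0.06, ks_ese 0.03 -> constraint 0.5
  expect_equal((0.06 - 0.03) / 0.06, 0.5)
  bins <- binned_flank_constraint(NULL, NULL, cdat$cfg$ese_set,
                                  n_bins = 10, pseudo_reps = 0,
                                  data = cdat$data)
  expect_equal(bins$constraint,
               (bins$ks_core - bins$ks_ese) / bins$ks_core)
  expect_true(all(bins$constraint <= 1, na.rm = TRUE))
  # planted c = 0.4 shows as positive constraint, pseudo ~ core level
  expect_gt(mean(bins$constraint, na.rm = TRUE), 0.2)
})

test_that("masking is projected consistently (density vs codon columns)", {
  flag <- splicesel:::flank_codon_ese(cdat$data, cdat$cfg$ese_set)
  cov <- splicesel:::flank_coverage_int(cdat$data$win_int,
                                        cdat$cfg$ese_set)
  dens_direct <- ese_density(cdat$data$flanks$flank_seq, cdat$cfg$ese_set)
  expect_equal(rowMeans(cov), dens_direct)
  # majority rule: an ESE codon has at least 2 covered sites
  fc <- cdat$data$flank_codons
  ncov <- cov[cbind(fc$flank_id, fc$rel_start)] +
    cov[cbind(fc$flank_id, fc$rel_start + 1L)] +
    cov[cbind(fc$flank_id, fc$rel_start + 2L)]
  expect_identical(flag, ncov >= 2L)
})

test_that("per-exon selection proportion follows the regression line", {
  sel <- selection_proportion_per_exon(NULL, NULL, cdat$cfg$ese_set,
                                       data = cdat$data)
  pe <- sel$per_end
  reg <- sel$regression
  for (side in c("5prime", "3prime")) {
    rr <- reg[reg$end == side, ]
    idx <- pe$end == side
    expect_equal(pe$constraint_fit[idx],
                 rr$intercept + rr$slope * log10(pe$intron_size[idx]))
  }
  # density 0 -> product 0; negative products retained unfloored
  expect_equal(pe$selection_prop,
               pe$density * pe$constraint_fit)
  expect_true(any(pe$density == 0) || all(pe$density > 0))
  zero <- pe$selection_prop[pe$density == 0]
  if (length(zero)) expect_true(all(zero == 0))
  # interpolation through two points: line through (1, .1), (3, .3)
  df <- data.frame(x = c(1, 3), y = c(0.1, 0.3))
  fit <- stats::lm(y ~ x, data = df)
  expect_equal(unname(predict(fit, data.frame(x = 2))[1]), 0.2,
               tolerance = 1e-12)
})

test_that("gene-level constraint applies cutoffs and unity convention", {
  gl <- gene_level_constraint(cdat$sim$genes, NULL, NULL,
                              cdat$cfg$ese_set, cutoff = 102,
                              resample_reps = 50, gamma_perms = 100,
                              seed = 2L, data = cdat$data)
  expect_true(all(gl$genes$ese_len > 102))
  expect_true(all(gl$genes$core_len > 102))
  expect_true(all(gl$genes$constraint <= 1))
  # zero ESE-flank substitutions with positive core Ks -> constraint 1
  no_sub <- gl$genes[gl$genes$ks_ese == 0 & gl$genes$ks_core > 0, ]
  if (nrow(no_sub)) expect_true(all(no_sub$constraint == 1))
  expect_equal(nrow(gl$correlations), 3L)
  expect_warning(
    gene_level_constraint(cdat$sim$genes, NULL, NULL, cdat$cfg$ese_set,
                          cutoff = 120, resample_reps = 0,
                          gamma_perms = 50, data = cdat$data),
    "cutoff")
  # resampling at pool size reproduces the full-pool decision every time
  gl_full <- gene_level_constraint(cdat$sim$genes, NULL, NULL,
                                   cdat$cfg$ese_set, cutoff = 102,
                                   resample_reps = 20,
                                   resample_size = 10^9,
                                   gamma_perms = 50, seed = 3L,
                                   data = cdat$data)
  full_sig <- gl_full$correlations$p < 0.05
  expect_equal(gl_full$resampling$frac_significant,
               as.numeric(full_sig))
})

test_that("pseudo-ESE null matches true-ESE constraint when c = 0", {
  cfg <- cdat$cfg
  orth0 <- simulate_orthologs(cdat$sim$genes, cfg$ese_set, d_core = 0.06,
                              ese_constraint = 0, seed = 77L)
  dat0 <- prepare_constraint_data(cdat$feats, orth0)
  bins <- binned_flank_constraint(NULL, NULL, cfg$ese_set, n_bins = 5,
                                  pseudo_reps = 30, seed = 8L,
                                  data = dat0)
  # with no planted constraint, true-ESE Ks sits within the pseudo null
  z <- abs(bins$ks_ese - bins$ks_pseudo_mean) /
    (bins$ks_pseudo_se * sqrt(30))
  expect_lt(mean(z, na.rm = TRUE), 2)
  expect_lt(abs(mean(bins$constraint, na.rm = TRUE)), 0.08)
})
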