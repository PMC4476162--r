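test_that("simulated genes pass every loader filter by construction", {
  td <- withr::local_tempdir()
  fx <- small_species()
  write_gene_models(fx$sim$genes, fx$sim$genome,
                    file.path(td, "s.gff3"), file.path(td, "s.fa"))
  loaded <- load_and_filter_genes(file.path(td, "s.gff3"),
                                  file.path(td, "s.fa"))
  expect_equal(nrow(loaded$rejected), 0L)
  expect_equal(nrow(loaded$genes), nrow(fx$sim$genes))
})

test_that("generators are byte-identical under a fixed seed", {
  s1 <- simulate_species_genes(sim_config(seed = 123, n_genes = 10))
  s2 <- simulate_species_genes(sim_config(seed = 123, n_genes = 10))
  expect_identical(s1, s2)
  p1 <- simulate_polymorphism(0.01, 6, 2000, seed = 5)
  p2 <- simulate_polymorphism(0.01, 6, 2000, seed = 5)
  expect_identical(p1, p2)
  o1 <- simulate_orthologs(s1$genes, sim_config()$ese_set, seed = 9)
  o2 <- simulate_orthologs(s2$genes, sim_config()$ese_set, seed = 9)
  expect_identical(o1, o2)
})

test_that("density model slopes are recovered from planted flanks", {
  cfg0 <- sim_config(seed = 61, n_genes = 250, slope_log10_size = 0,
                     slope_downstream = 0)
  sim0 <- simulate_species_genes(cfg0)
  f0 <- extract_internal_exon_features(sim0$genes)
  d0 <- ese_density(f0$flank5_seq, cfg0$ese_set)
  s0 <- spearman_trend(d0, log10(f0$intron5))
  expect_gt(s0$p, 0.01)  # no planted dependence
  cfg1 <- sim_config(seed = 62, n_genes = 600, slope_log10_size = 0.05,
                     slope_downstream = 0)
  sim1 <- simulate_species_genes(cfg1)
  f1 <- extract_internal_exon_features(sim1$genes)
  d1 <- ese_density(f1$flank5_seq, cfg1$ese_set)
  fit <- lm(d1 ~ log10(f1$intron5))
  # background (unplanted) coverage overlaps planted sites, attenuating
  # the realised slope; recovery within +/-20% of the planted value
  # after that union-overlap correction
  overlap <- 1 - mean(ese_density(
    extract_internal_exon_features(
      simulate_species_genes(sim_config(seed = 63, n_genes = 60,
                                        base_density = 0,
                                        slope_log10_size = 0,
                                        slope_downstream = 0))$genes
    )$flank5_seq, cfg1$ese_set))
  expect_lt(abs(coef(fit)[[2]] / overlap - 0.05) / 0.05, 0.2)
})

test_that("ortholog divergence hits its target Ks outside ESEs", {
  fx <- small_species()
  orth <- simulate_orthologs(fx$sim$genes, fx$cfg$ese_set, d_core = 0.06,
                             ese_constraint = 1, seed = 3)
  dat <- prepare_constraint_data(fx$features, orth)
  flag <- splicesel:::flank_codon_ese(dat, fx$cfg$ese_set)
  fc <- dat$flank_codons
  # c = 1: ESE partition strictly invariant
  ese <- which(flag)
  expect_true(all(fc$ref_idx[ese] == fc$ort_idx[ese]))
  # cores evolve at the target rate
  ks_core <- splicesel:::ks_of_rows(dat$core_codons,
                                    seq_len(nrow(dat$core_codons)))$ks
  expect_lt(abs(ks_core - 0.06), 0.01)
})

test_that("coalescent sample matches the Watterson expectation", {
  # E[S] = theta * a_n * L; modest replication, 3-se band
  theta <- 0.01; n <- 10; L <- 2e4
  a_n <- sum(1 / 1:9)
  S <- vapply(1:60, function(i) {
    theta_estimates(simulate_polymorphism(theta, n, L, seed = i))$S
  }, numeric(1))
  se <- sd(S) / sqrt(length(S))
  expect_lt(abs(mean(S) - theta * a_n * L), 3 * se)
  expect_equal(sum(1 / 1:9), 7129 / 2520)
  # theta = 0 -> no segregating sites
  s0 <- theta_estimates(simulate_polymorphism(0, 5, 1000, seed = 1))
  expect_equal(s0$S, 0L)
  expect_error(simulate_polymorphism(0.01, 1, 100), "at least 2")
})

test_that("Brownian trait simulation respects tree and scale", {
  tr <- ape::rtree(10)
  tr0 <- tr
  tr0$edge.length <- rep(0, length(tr0$edge.length))
  tt0 <- simulate_phylo_traits(tr0, rho_true = 0.5, seed = 2)
  expect_true(all(tt0$trait_x == 0) && all(tt0$trait_y == 0))
  # doubling the rate matrix leaves the correlation distribution alone
  tt1 <- simulate_phylo_traits(tr, 0.7, rates = c(1, 1), seed = 7)
  tt2 <- simulate_phylo_traits(tr, 0.7, rates = c(2, 2), seed = 7)
  expect_equal(cor(tt1$trait_x, tt1$trait_y),
               cor(tt2$trait_x, tt2$trait_y), tolerance = 1e-10)
  expect_error(simulate_phylo_traits(tr, rho_true = 1.5), "rho_true")
})
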