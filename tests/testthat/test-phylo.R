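test_that("two-tip contrast matches the closed form", {
  tr <- ape::read.tree(text = "(a:1,b:1);")
  ct <- independent_contrasts(tr, c(a = 3, b = 5))
  expect_equal(abs(ct), abs((3 - 5) / sqrt(2)))
  # equal tip values -> all contrasts zero
  tr2 <- ape::rtree(8)
  ct2 <- independent_contrasts(tr2, setNames(rep(2, 8), tr2$tip.label))
  expect_true(all(ct2 == 0))
})

test_that("contrasts agree with the reference implementation", {
  set.seed(5)
  for (i in 1:10) {
    tr <- ape::rtree(15)
    x <- setNames(rnorm(15), tr$tip.label)
    expect_equal(sort(abs(independent_contrasts(tr, x))),
                 sort(abs(unname(ape::pic(x, tr)))), tolerance = 1e-10)
  }
})

test_that("branch-length rescaling rescales contrasts by 1/sqrt(c)", {
  set.seed(6)
  tr <- ape::rtree(10)
  x <- setNames(rnorm(10), tr$tip.label)
  c1 <- independent_contrasts(tr, x)
  tr4 <- tr
  tr4$edge.length <- tr$edge.length * 4
  expect_equal(independent_contrasts(tr4, x), c1 / 2, tolerance = 1e-12)
})

test_that("tip/trait mismatches error with the offending ids", {
  tr <- ape::rtree(5)
  x <- setNames(rnorm(5), c(tr$tip.label[-1], "ghost"))
  expect_error(independent_contrasts(tr, x), "ghost")
})

test_that("star tree reduces to the ordinary Pearson correlation", {
  set.seed(7)
  star <- ape::stree(12, "star")
  star$edge.length <- rep(1, 12)
  y <- setNames(rnorm(12), star$tip.label)
  z <- setNames(rnorm(12), star$tip.label)
  fit <- bm_correlation_evidence(star, y, z)
  expect_equal(fit$rho_hat, cor(y, z), tolerance = 1e-8)
  expect_equal(fit$statistic, -fit$k * log(1 - fit$rho_hat^2))
})

test_that("identical traits give infinite statistic, very strong class", {
  tr <- ape::rtree(6)
  x <- setNames(rnorm(6), tr$tip.label)
  fit <- bm_correlation_evidence(tr, x, x)
  expect_true(fit$infinite)
  expect_equal(fit$evidence_class, "very strong")
  expect_equal(fit$statistic, Inf)
})

test_that("statistic is monotone in |rho| and classes follow thresholds", {
  k <- 20
  stat <- function(r) -k * log(1 - r^2)
  rs <- seq(0, 0.95, by = 0.05)
  expect_true(all(diff(stat(rs)) >= 0))
  expect_equal(splicesel:::evidence_class(1.9), "weak")
  expect_equal(splicesel:::evidence_class(2.1), "positive")
  expect_equal(splicesel:::evidence_class(7), "strong")
  expect_equal(splicesel:::evidence_class(11), "very strong")
})

test_that("species absent from the tree are dropped with a warning", {
  tr <- ape::rtree(6)
  x <- setNames(rnorm(7), c(tr$tip.label, "extra_sp"))
  expect_warning(fit <- bm_correlation_evidence(tr, x, x + rnorm(7)),
                 "extra_sp")
  expect_equal(fit$k, 5)
})

test_that("null statistic exceeds 2 in roughly a tenth of replicates", {
  set.seed(33)
  n_rep <- 200
  hits <- 0
  for (i in 1:n_rep) {
    tr <- ape::rtree(30)
    tt <- simulate_phylo_traits(tr, rho_true = 0, seed = 1000 + i)
    fit <- bm_correlation_evidence(tr, setNames(tt$trait_x, tt$species),
                                   setNames(tt$trait_y, tt$species))
    if (fit$statistic > 2) hits <- hits + 1
  }
  # anti-conservative bound: the LRT at 1 df exceeds 2 with p ~ 0.157;
  # allow for that size plus Monte-Carlo noise, but not more
  expect_true(rate_not_above(hits, n_rep, 0.20))
})

test_that("ml and mcmc modes agree on clear-cut cases", {
  set.seed(44)
  agree <- 0
  for (i in 1:5) {
    tr <- ape::rtree(30)
    tt <- simulate_phylo_traits(tr, rho_true = 0.9, seed = 500 + i)
    tx <- setNames(tt$trait_x, tt$species)
    ty <- setNames(tt$trait_y, tt$species)
    ml <- bm_correlation_evidence(tr, tx, ty, mode = "ml")
    mc <- bm_correlation_evidence(tr, tx, ty, mode = "mcmc", seed = i,
                                  mcmc_steps = 2e4)
    if (identical(ml$evidence_class, mc$evidence_class)) agree <- agree + 1
  }
  expect_gte(agree, 4)
})

test_that("trait-table interface runs over selected pairs", {
  tr <- ape::rtree(10)
  tt <- simulate_phylo_traits(tr, rho_true = 0.5, seed = 9)
  res <- phylo_trait_correlations(tr, tt,
                                  pairs = list(c("trait_x", "trait_y")))
  expect_equal(nrow(res), 1L)
  expect_true(res$evidence_class %in%
                c("weak", "positive", "strong", "very strong"))
})
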