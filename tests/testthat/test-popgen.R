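test_that("theta estimators follow their definitions on small samples", {
  # n = 2, L = 100, 3 differing sites -> theta_pi = 0.03
  a <- strrep("A", 100)
  b <- paste0(strrep("A", 97), "CCC")
  est <- theta_estimates(polymorphism_sample(c(a, b)))
  expect_equal(est$theta_pi, 0.03)
  expect_equal(est$S, 3L)
  expect_equal(est$eta, 3)
  # n = 5, S = 10, L = 1000 -> theta_S = 10 / ((25/12) * 1000)
  set.seed(3)
  mat <- matrix("A", 5, 1000)
  cols <- sample(1000, 10)
  for (j in cols) mat[sample(5, 2), j] <- "G"
  est5 <- theta_estimates(polymorphism_sample(mat))
  expect_equal(est5$theta_S, 10 / ((25 / 12) * 1000))
  expect_equal(sum(1 / 1:4), 25 / 12)
  # a site with three bases adds 1 to S and 2 to eta
  mat2 <- matrix("A", 4, 10)
  mat2[1, 5] <- "C"; mat2[2, 5] <- "G"
  est4 <- theta_estimates(polymorphism_sample(mat2))
  expect_equal(est4$S, 1L)
  expect_equal(est4$eta, 2)
})

test_that("gap columns are dropped and errors are raised", {
  a <- "ACG-T"
  b <- "ACGGT"
  est <- theta_estimates(polymorphism_sample(c(a, b)))
  expect_equal(est$L, 4)
  expect_error(polymorphism_sample("ACGT"), "at least 2")
  expect_error(theta_estimates(polymorphism_sample(c("--", "--"))),
               "no usable sites")
  expect_error(theta_estimates(polymorphism_sample(c("AC", "AC")),
                               ploidy_factor = 0), "positive")
})

test_that("Ne.mu scaling uses the stated ploidy divisor", {
  expect_equal(ne_mu_from_theta(0.004, 4), 0.001)
  expect_equal(ne_mu_from_theta(0.004, 2), 0.002)
  expect_equal(ne_mu_from_theta(0, 4), 0)
  expect_error(ne_mu_from_theta(0.004, -4), "positive")
})

test_that("synonymous-sites mode counts only synonymous variation", {
  # two haplotypes: one synonymous (GGG->GGA) and one nonsynonymous
  # (ATG->ACG) difference
  a <- "GGGATGTTT"
  b <- "GGAACGTTT"
  est <- theta_estimates(polymorphism_sample(c(a, b),
                                             locus_class = "cds_synonymous"))
  expect_equal(est$S, 1L)
  # L is the mean NG86 synonymous site count, much less than 9
  expect_lt(est$L, 9)
  expect_gt(est$theta_S, 0)
})

test_that("theta_S equals theta_eta without recurrent mutation", {
  for (i in 1:5) {
    s <- simulate_polymorphism(0.01, 8, 5000, seed = i)
    est <- theta_estimates(s)
    expect_equal(est$theta_S, est$theta_eta)
  }
})

test_that("multi-locus combination weights by usable length", {
  e1 <- theta_estimates(polymorphism_sample(c(strrep("A", 100),
                                              paste0(strrep("A", 99), "C"))))
  e2 <- theta_estimates(polymorphism_sample(c(strrep("G", 300),
                                              strrep("G", 300))))
  comb <- combine_theta_estimates(dplyr::bind_rows(e1, e2))
  expect_equal(comb$L, 400)
  expect_equal(comb$theta_pi, (100 * e1$theta_pi + 300 * e2$theta_pi) / 400)
})

test_that("estimator cross-correlations are computed per pair", {
  set.seed(12)
  tbl <- tibble::tibble(ne_mu_pi = runif(10), ne_mu_S = runif(10),
                        ne_mu_eta = runif(10))
  cc <- ne_mu_estimator_correlations(tbl)
  expect_equal(nrow(cc), 3L)
  tbl2 <- tbl
  tbl2$ne_mu_S <- tbl2$ne_mu_pi
  cc2 <- ne_mu_estimator_correlations(tbl2)
  expect_equal(cc2$rho[cc2$pair == "ne_mu_pi ~ ne_mu_S"], 1)
})
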