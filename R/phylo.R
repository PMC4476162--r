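# Phylogenetically controlled trait correlation under bivariate Brownian
# motion: Felsenstein independent contrasts, a likelihood-ratio evidence
# statistic, and a harmonic-mean MCMC mode mirroring the Log-BF scale of
# Bayesian comparative software.

#' Standardized phylogenetic independent contrasts
#'
#' Felsenstein's contrasts: at each internal node of a bifurcating tree
#' the difference of the daughter values divided by the square root of
#' its expected variance (sum of adjusted branch lengths). Polytomies are
#' resolved arbitrarily with zero-length branches; zero-length internal
#' branches are handled by the variance-adjustment recursion.
#'
#' @param tree An `ape::phylo` tree with branch lengths (>= 0, not all
#'   zero).
#' @param trait Named numeric vector of tip values; names must match the
#'   tree's tip labels.
#' @return Numeric vector of `n - 1` standardized contrasts (root-ward
#'   node order).
#' @export
independent_contrasts <- function(tree, trait) {
  check_that(inherits(tree, "phylo"), "tree must be an ape phylo object")
  check_that(!is.null(tree$edge.length) && any(tree$edge.length > 0),
             "tree needs branch lengths, not all zero")
  check_that(all(tree$edge.length >= 0), "negative branch lengths")
  missing <- setdiff(tree$tip.label, names(trait))
  extra <- setdiff(names(trait), tree$tip.label)
  check_that(length(missing) == 0 && length(extra) == 0,
             paste0("tip/trait mismatch: ",
                    paste(c(missing, extra), collapse = ", ")))
  if (!ape::is.binary(tree)) tree <- ape::multi2di(tree, random = FALSE)
  tree <- stats::reorder(tree, "postorder")
  n_tip <- length(tree$tip.label)
  n_node <- tree$Nnode
  x <- c(unname(trait[tree$tip.label]), rep(NA_real_, n_node))
  v <- c(rep(0, n_tip), rep(NA_real_, n_node))
  contrasts <- numeric(0)
  edge <- tree$edge
  bl <- tree$edge.length
  # postorder: children of each internal node appear before the node
  for (nd in unique(edge[, 1])) {
    ch_rows <- which(edge[, 1] == nd)
    check_that(length(ch_rows) == 2L, "tree not bifurcating after resolution")
    c1 <- edge[ch_rows[1], 2]; c2 <- edge[ch_rows[2], 2]
    v1 <- bl[ch_rows[1]] + v[c1]
    v2 <- bl[ch_rows[2]] + v[c2]
    vc <- v1 + v2
    contrasts <- c(contrasts,
                   if (vc > 0) (x[c1] - x[c2]) / sqrt(vc) else 0)
    x[nd] <- if (vc > 0) (v2 * x[c1] + v1 * x[c2]) / vc
             else mean(c(x[c1], x[c2]))
    v[nd] <- if (vc > 0) v1 * v2 / vc else 0
  }
  contrasts
}

#' Evidence for correlated Brownian evolution of two traits
#'
#' Primary (`mode = "ml"`): the correlation of the two standardized
#' contrast series is estimated through the origin, and the statistic is
#' the likelihood-ratio `-k * log(1 - rho^2)` (k contrasts) comparing
#' correlated versus independent bivariate Brownian motion — twice the
#' log-likelihood difference, on the same scale as a Log Bayes factor.
#' Secondary (`mode = "mcmc"`): seeded Metropolis chains sample the
#' Brownian rates and correlation under both models and the statistic is
#' `2 * (log harmonic-mean likelihood (correlated) - log harmonic-mean
#' likelihood (independent))`. Evidence classes follow the conventional
#' Log-BF thresholds: weak (< 2), positive (>= 2), strong (5-10), very
#' strong (> 10).
#'
#' @param tree An `ape::phylo` tree (>= 4 tips).
#' @param trait_x,trait_y Named numeric tip-value vectors.
#' @param mode `"ml"` (default) or `"mcmc"`.
#' @param seed Seed for the MCMC mode.
#' @param mcmc_steps Chain length (default 1e6); 10% burn-in.
#' @return Object of class `bm_correlation`: list with `rho_hat`,
#'   `statistic`, `evidence_class`, `mode`, `k`, `infinite` flag.
#' @export
bm_correlation_evidence <- function(tree, trait_x, trait_y,
                                    mode = c("ml", "mcmc"), seed = 1L,
                                    mcmc_steps = 1e6) {
  mode <- match.arg(mode)
  check_that(length(tree$tip.label) >= 4, "need at least 4 tips")
  # drop table species absent from the tree (with a warning), and prune
  # tree tips without trait values
  common <- intersect(tree$tip.label, intersect(names(trait_x),
                                                names(trait_y)))
  dropped <- setdiff(union(names(trait_x), names(trait_y)), common)
  if (length(dropped) > 0) {
    warn(paste("dropping species absent from tree or traits:",
               paste(dropped, collapse = ", ")))
  }
  if (length(setdiff(tree$tip.label, common)) > 0) {
    tree <- ape::keep.tip(tree, common)
  }
  cx <- independent_contrasts(tree, trait_x[common])
  cy <- independent_contrasts(tree, trait_y[common])
  k <- length(cx)
  rho_hat <- sum(cx * cy) / sqrt(sum(cx^2) * sum(cy^2))

  if (mode == "ml") {
    infinite <- abs(rho_hat) >= 1 - 1e-15
    statistic <- if (infinite) Inf else -k * log(1 - rho_hat^2)
  } else {
    statistic <- bm_harmonic_mean_bf(cx, cy, seed = seed,
                                     steps = mcmc_steps)
    infinite <- !is.finite(statistic)
  }
  structure(
    list(rho_hat = rho_hat, statistic = statistic,
         evidence_class = evidence_class(statistic), mode = mode, k = k,
         infinite = infinite),
    class = "bm_correlation"
  )
}

evidence_class <- function(statistic) {
  if (!is.finite(statistic)) return("very strong")
  if (statistic > 10) "very strong"
  else if (statistic >= 5) "strong"
  else if (statistic >= 2) "positive"
  else "weak"
}

# log-likelihood of standardized contrast pairs under bivariate BM with
# rates s1, s2 and correlation r, from sufficient statistics
bm_loglik <- function(sxx, syy, sxy, k, s1, s2, r) {
  det_sig <- s1 * s2 * (1 - r^2)
  if (det_sig <= 0) return(-Inf)
  quad <- (syy / s2 - 2 * r * sxy / sqrt(s1 * s2) + sxx / s1) / (1 - r^2)
  -k * log(2 * pi) - (k / 2) * log(det_sig) - quad / 2
}

# 2 * (log harmonic-mean likelihood correlated - independent) via
# Metropolis sampling over (log s1, log s2[, atanh r])
bm_harmonic_mean_bf <- function(cx, cy, seed = 1L, steps = 1e6,
                                burn_frac = 0.1) {
  k <- length(cx)
  sxx <- sum(cx^2); syy <- sum(cy^2); sxy <- sum(cx * cy)
  set.seed(seed)
  run_chain <- function(correlated) {
    th <- c(log(sxx / k), log(syy / k), 0)
    ll <- bm_loglik(sxx, syy, sxy, k, exp(th[1]), exp(th[2]),
                    if (correlated) tanh(th[3]) else 0)
    n_par <- if (correlated) 3L else 2L
    keep <- numeric(0)
    props <- matrix(rnorm(steps * n_par, sd = 0.1), ncol = n_par)
    us <- log(runif(steps))
    lls <- numeric(steps)
    for (i in seq_len(steps)) {
      th_new <- th
      th_new[seq_len(n_par)] <- th[seq_len(n_par)] + props[i, ]
      ll_new <- bm_loglik(sxx, syy, sxy, k, exp(th_new[1]), exp(th_new[2]),
                          if (correlated) tanh(th_new[3]) else 0)
      if (us[i] < ll_new - ll) { th <- th_new; ll <- ll_new }
      lls[i] <- ll
    }
    lls[-seq_len(floor(steps * burn_frac))]
  }
  log_hm <- function(lls) {
    # log of harmonic mean of likelihoods
    -(matrixStats_logsumexp(-lls) - log(length(lls)))
  }
  2 * (log_hm(run_chain(TRUE)) - log_hm(run_chain(FALSE)))
}

# numerically stable log-sum-exp
matrixStats_logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' @export
print.bm_correlation <- function(x, ...) {
  cat("Brownian-motion trait correlation (", x$mode, " mode)\n",
      "  rho_hat = ", format(x$rho_hat, digits = 4),
      "  statistic = ", format(x$statistic, digits = 4),
      "  [", x$evidence_class, "], k = ", x$k, " contrasts\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.bm_correlation <- function(x, ...) {
  tibble(estimate = x$rho_hat, statistic = x$statistic,
         evidence_class = x$evidence_class, mode = x$mode,
         k = x$k)
}

#' @exportS3Method generics::glance
glance.bm_correlation <- function(x, ...) tidy(x)

#' Pairwise trait correlations over a trait table
#'
#' Runs [bm_correlation_evidence()] for chosen trait pairs of a
#' per-species trait table bound to a tree.
#'
#' @param tree An `ape::phylo` tree.
#' @param traits Tibble with a `species` column and numeric trait
#'   columns.
#' @param pairs Two-column character matrix / list of c(x, y) pairs; by
#'   default all unordered pairs of numeric columns.
#' @inheritParams bm_correlation_evidence
#' @return Tibble `trait_x`, `trait_y`, `rho_hat`, `statistic`,
#'   `evidence_class`, `k`.
#' @export
phylo_trait_correlations <- function(tree, traits, pairs = NULL,
                                     mode = "ml", seed = 1L) {
  check_that("species" %in% names(traits), "traits needs a species column")
  num_cols <- names(traits)[vapply(traits, is.numeric, logical(1))]
  if (is.null(pairs)) {
    pairs <- utils::combn(num_cols, 2, simplify = FALSE)
  }
  purrr::map(pairs, function(pp) {
    tx <- setNames(traits[[pp[1]]], traits$species)
    ty <- setNames(traits[[pp[2]]], traits$species)
    fit <- bm_correlation_evidence(tree, tx, ty, mode = mode, seed = seed)
    tibble(trait_x = pp[1], trait_y = pp[2], rho_hat = fit$rho_hat,
           statistic = fit$statistic, evidence_class = fit$evidence_class,
           k = fit$k)
  }) |> bind_rows()
}
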