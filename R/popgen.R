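# Per-site theta estimation from polymorphism alignments (pi, Watterson S,
# eta) and the Ne.mu scaling.

#' Construct a polymorphism sample from aligned haplotypes
#'
#' @param sequences Character vector (n >= 2) of equal-length aligned
#'   haplotype sequences, or a character matrix (rows = haplotypes).
#' @param species Species label.
#' @param locus_class `"intron"` or `"cds_synonymous"`; in the latter mode
#'   sequences must be in-frame CDS and theta uses only synonymous
#'   segregating sites over synonymous site counts.
#' @return A list of class `polymorphism_sample`.
#' @export
polymorphism_sample <- function(sequences, species = "species",
                                locus_class = c("intron", "cds_synonymous")) {
  locus_class <- match.arg(locus_class)
  if (is.matrix(sequences)) {
    mat <- toupper(sequences)
  } else {
    check_that(length(unique(nchar(sequences))) == 1L,
               "haplotypes must have equal length")
    mat <- do.call(rbind, strsplit(toupper(sequences), ""))
  }
  check_that(nrow(mat) >= 2, "need at least 2 haplotypes")
  structure(list(mat = mat, species = species, locus_class = locus_class),
            class = "polymorphism_sample")
}

#' Read per-locus polymorphism FASTA files
#'
#' @param paths FASTA file paths, one locus each.
#' @inheritParams polymorphism_sample
#' @return List of `polymorphism_sample` objects.
#' @export
read_polymorphism_fasta <- function(paths, species = "species",
                                    locus_class = "intron") {
  lapply(paths, function(p) {
    seqs <- as.character(Biostrings::readDNAStringSet(p))
    polymorphism_sample(unname(seqs), species = species,
                        locus_class = locus_class)
  })
}

# harmonic number a_n = sum_{i=1}^{n-1} 1/i
watterson_a <- function(n) sum(1 / seq_len(n - 1))

#' Theta estimates (pi, S, eta) and per-site Ne.mu
#'
#' Sites with any gap or ambiguous base are excluded listwise. Per-site
#' estimators: `theta_pi` = mean pairwise differences per site; `theta_S`
#' = S / (a_n L) with S the number of segregating sites and a_n the
#' harmonic number; `theta_eta` = eta / (a_n L) with eta the minimum
#' mutation count (k - 1 distinct bases per site, summed). In
#' `cds_synonymous` mode S and eta count only synonymous segregating
#' sites (every observed variant preserves the amino acid in its codon
#' context) and L is the NG86 synonymous site count averaged over
#' haplotypes. `Ne.mu = theta / ploidy_factor` (4 for diploid
#' autosomes, 2 for haploids).
#'
#' @param sample A [polymorphism_sample()].
#' @param ploidy_factor Divisor relating theta to Ne.mu (default 4).
#' @return One-row tibble: `species`, `n`, `L`, `pi`, `S`, `eta`,
#'   `theta_pi`, `theta_S`, `theta_eta`, `ne_mu_pi`, `ne_mu_S`,
#'   `ne_mu_eta`.
#' @export
theta_estimates <- function(sample, ploidy_factor = 4) {
  check_that(inherits(sample, "polymorphism_sample"),
             "sample must be a polymorphism_sample")
  check_that(ploidy_factor > 0, "ploidy_factor must be positive")
  mat <- sample$mat
  n <- nrow(mat)
  good <- colSums(matrix(mat %in% BASES, nrow = n)) == n
  mat <- mat[, good, drop = FALSE]
  L_nt <- ncol(mat)
  check_that(L_nt > 0, "no usable sites after filtering")

  # segregating candidates: columns differing anywhere from haplotype 1
  cand <- which(colSums(mat != mat[rep(1L, n), , drop = FALSE]) > 0)
  counts <- matrix(0L, 4L, L_nt)
  if (length(cand)) {
    counts[, cand] <- vapply(cand, function(j) {
      tabulate(match(mat[, j], BASES), nbins = 4L)
    }, integer(4))
  }
  n_alleles <- rep(1L, L_nt)
  n_alleles[cand] <- colSums(counts[, cand, drop = FALSE] > 0)
  seg <- cand[n_alleles[cand] > 1]

  if (sample$locus_class == "cds_synonymous") {
    check_that(L_nt %% 3 == 0, "cds_synonymous mode needs in-frame CDS")
    s_tab <- ng86_syn_sites()
    idx <- apply(mat, 1L, function(hap) {
      codon_index(codons_of(paste(hap, collapse = "")))
    })
    L <- mean(colSums(matrix(s_tab[idx], nrow = nrow(idx)), na.rm = TRUE))
    seg <- seg[vapply(seg, function(j) site_is_synonymous(mat, j), logical(1))]
  } else {
    L <- L_nt
  }
  check_that(L > 0, "zero sites available for per-site estimates")

  # mean pairwise differences per site over all retained sites
  pairs <- n * (n - 1) / 2
  pi_total <- sum(vapply(seg, function(j) {
    cb <- counts[, j]
    (sum(cb)^2 - sum(cb^2)) / 2 / pairs
  }, numeric(1)))
  S <- length(seg)
  eta <- sum(n_alleles[seg] - 1)
  a_n <- watterson_a(n)

  theta_pi <- pi_total / L
  theta_S <- S / (a_n * L)
  theta_eta <- eta / (a_n * L)
  tibble(
    species = sample$species, n = n, L = L,
    pi = pi_total, S = S, eta = eta,
    theta_pi = theta_pi, theta_S = theta_S, theta_eta = theta_eta,
    ne_mu_pi = theta_pi / ploidy_factor,
    ne_mu_S = theta_S / ploidy_factor,
    ne_mu_eta = theta_eta / ploidy_factor
  )
}

# does every variant at nucleotide column j preserve the amino acid?
site_is_synonymous <- function(mat, j) {
  codon_start <- j - (j - 1) %% 3
  ctx <- mat[, codon_start:(codon_start + 2), drop = FALSE]
  codons <- apply(ctx, 1L, paste, collapse = "")
  aas <- translate_codons(codons)
  if (any(is.na(aas)) || any(aas == "*")) return(FALSE)
  length(unique(aas)) == 1L
}

#' Scale a per-site theta to Ne.mu
#'
#' @param theta Non-negative per-site theta estimate(s).
#' @param ploidy_factor 4 (diploid, theta = 4 Ne mu) or 2 (haploid).
#' @return `theta / ploidy_factor`.
#' @export
ne_mu_from_theta <- function(theta, ploidy_factor = 4) {
  check_that(ploidy_factor > 0, "ploidy_factor must be positive")
  check_that(all(theta >= 0), "theta must be non-negative")
  theta / ploidy_factor
}

#' Combine multi-locus theta estimates for one species
#'
#' Weighted average of per-site estimates, weights proportional to the
#' usable site count L of each locus.
#'
#' @param estimates Tibble of per-locus rows from [theta_estimates()].
#' @return One-row tibble in the same layout.
#' @export
combine_theta_estimates <- function(estimates) {
  check_that(nrow(estimates) >= 1, "no estimates to combine")
  w <- estimates$L / sum(estimates$L)
  cols <- c("theta_pi", "theta_S", "theta_eta",
            "ne_mu_pi", "ne_mu_S", "ne_mu_eta")
  out <- estimates[1, ]
  out$n <- round(mean(estimates$n))
  out$L <- sum(estimates$L)
  out$pi <- sum(estimates$pi); out$S <- sum(estimates$S)
  out$eta <- sum(estimates$eta)
  for (cl in cols) out[[cl]] <- sum(w * estimates[[cl]])
  out
}

#' Spearman cross-correlations among per-species Ne.mu estimators
#'
#' Given a per-species table of the three Ne.mu estimates (columns
#' `ne_mu_pi`, `ne_mu_S`, `ne_mu_eta`, e.g. stacked
#' [theta_estimates()] rows or an externally supplied table), returns the
#' pairwise Spearman correlations among the estimators.
#'
#' @param tbl Tibble with the three estimator columns, one row per
#'   species.
#' @return Tibble `pair`, `rho`, `p`, `n`.
#' @export
ne_mu_estimator_correlations <- function(tbl) {
  cols <- c("ne_mu_pi", "ne_mu_S", "ne_mu_eta")
  check_that(all(cols %in% names(tbl)),
             "table needs columns ne_mu_pi, ne_mu_S, ne_mu_eta")
  combos <- utils::combn(cols, 2, simplify = FALSE)
  purrr::map(combos, function(cc) {
    s <- spearman_trend(tbl[[cc[1]]], tbl[[cc[2]]])
    tibble(pair = paste(cc, collapse = " ~ "), rho = s$rho, p = s$p,
           n = s$n)
  }) |> bind_rows()
}
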