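# Positional codon / amino-acid usage trends near exon-intron junctions,
# the species-level cis-motif usage metric Y, and splice-site usage.
#
# Distance is measured in complete codons of the reading frame from the
# junction: position 1 (the boundary-adjacent complete codon, absorbing
# any partial boundary codon) is excluded and positions 2..34 analysed.

TREND_MIN_D <- 2L
TREND_MAX_D <- 34L

# long table of (feature row, distance d, sense-codon index 1..61) for one
# exon end
codon_position_table <- function(features, end = c("5prime", "3prime")) {
  end <- match.arg(end)
  len <- features$length
  off5 <- (3L - features$frame_offset) %% 3L
  m <- pmax((len - off5) %/% 3L, 0L)          # complete codons in exon
  d_max <- pmin(m, TREND_MAX_D)
  n_d <- pmax(d_max - TREND_MIN_D + 1L, 0L)
  keep <- which(n_d > 0L)
  if (length(keep) == 0L) {
    return(tibble(row = integer(0), d = integer(0), codon61 = integer(0)))
  }
  row <- rep(keep, n_d[keep])
  d <- unlist(lapply(keep, function(i) seq.int(TREND_MIN_D, d_max[i])),
              use.names = FALSE)
  start <- if (end == "5prime") {
    off5[row] + 1L + 3L * (d - 1L)
  } else {
    off5[row] + 1L + 3L * (m[row] - d)
  }
  codon <- substring(features$exon_cds[row], start, start + 2L)
  codon61 <- match(codon, SENSE_CODONS)
  ok <- !is.na(codon61)
  tibble(row = row[ok], d = d[ok], codon61 = codon61[ok])
}

# counts matrix (distance x 61 sense codons) from a position table, with
# optional per-exon weights (for subsampling with replacement)
trend_counts <- function(pos_tbl, n_features, weights = NULL) {
  n_d <- TREND_MAX_D - TREND_MIN_D + 1L
  A <- Matrix::sparseMatrix(
    i = pos_tbl$row,
    j = (pos_tbl$d - TREND_MIN_D) * 61L + pos_tbl$codon61,
    x = 1,
    dims = c(n_features, n_d * 61L)
  )
  if (is.null(weights)) weights <- rep(1, n_features)
  counts <- as.vector(weights %*% A)
  matrix(counts, nrow = n_d, ncol = 61L, byrow = TRUE,
         dimnames = list(seq.int(TREND_MIN_D, TREND_MAX_D), SENSE_CODONS))
}

# collapse a distance x codon count matrix to amino acids (20 columns)
counts_to_aa <- function(counts) {
  aa <- translate_codons(colnames(counts))
  t(rowsum(t(counts), aa))
}

# Spearman rho / p for each column of a proportion matrix against
# distance. Two-tailed p-values come from a Monte-Carlo permutation null
# of rho (fixed internal permutation table, conservative (k+1)/(m+1)
# correction): the t approximation is anticonservative in the far
# (Bonferroni) tail at n = 33, and exact tie-free tables do not apply to
# tied proportions, while the permutation null is valid under any tie
# pattern.
TREND_PERM_M <- 100000L

.trend_perm_cache <- new.env(parent = emptyenv())

# standardized rank permutations of 1..n (n x m), deterministic and
# isolated from the caller's RNG stream
trend_perm_table <- function(n, m = TREND_PERM_M) {
  key <- paste0("n", n, "_m", m)
  if (!is.null(.trend_perm_cache[[key]])) return(.trend_perm_cache[[key]])
  old_seed <- if (exists(".Random.seed", envir = globalenv(),
                         inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(104729L + n)
  tab <- vapply(seq_len(m), function(i) sample.int(n), integer(n))
  if (!is.null(old_seed)) {
    assign(".Random.seed", old_seed, envir = globalenv())
  } else if (exists(".Random.seed", envir = globalenv(),
                    inherits = FALSE)) {
    rm(".Random.seed", envir = globalenv())
  }
  .trend_perm_cache[[key]] <- tab
  tab
}

trend_rho_p <- function(prop, d) {
  n <- length(d)
  perm <- trend_perm_table(n)
  m <- ncol(perm)
  rd <- rank(d)
  rc_mat <- apply(prop, 2L, function(col) rank(col))
  usable <- apply(prop, 2L, function(col) sd(col) > 0)
  rho <- rep(0, ncol(prop))
  p <- rep(1, ncol(prop))
  if (any(usable)) {
    rho[usable] <- as.vector(cor(rc_mat[, usable, drop = FALSE], rd))
    # null rho for every column against the shared permuted d-ranks
    null_rho <- cor(perm, rc_mat[, usable, drop = FALSE])  # m x k
    k_ge <- colSums(abs(null_rho) >= abs(rho[usable])[col(null_rho)] - 1e-12)
    p[usable] <- (k_ge + 1) / (m + 1)
  }
  tibble(kmer = colnames(prop), rho = rho, p_raw = p)
}

#' Positional usage trend test near exon-intron junctions
#'
#' For each k-mer (sense codon or amino acid), computes the proportional
#' usage among all exons contributing a complete codon at distance
#' d = 2..34 codons from the chosen junction, then the two-tailed Spearman
#' correlation of proportion versus distance. Negative rho marks a k-mer
#' preferred near exon ends. Significance is Bonferroni-corrected within
#' the family tested at this end (61 sense codons or 20 amino acids).
#'
#' @param features Internal-exon feature tibble from
#'   [extract_internal_exon_features()] (first/last exons already
#'   excluded).
#' @param family `"codon"` or `"amino_acid"`.
#' @param end `"5prime"` or `"3prime"`.
#' @param alpha Family-wise significance level (default 0.05).
#' @return Tibble `kmer`, `end`, `rho`, `p_raw`, `significant`.
#' @export
positional_trend_test <- function(features, family = c("codon", "amino_acid"),
                                  end = c("5prime", "3prime"), alpha = 0.05) {
  family <- match.arg(family)
  end <- match.arg(end)
  pos_tbl <- codon_position_table(features, end)
  check_that(nrow(pos_tbl) > 0, "no codons at distances 2..34: exons too short")
  counts <- trend_counts(pos_tbl, nrow(features))
  trend_from_counts(counts, family, end, alpha)
}

trend_from_counts <- function(counts, family, end, alpha) {
  if (family == "amino_acid") counts <- counts_to_aa(counts)
  totals <- rowSums(counts)
  check_that(sum(totals > 0) >= 2, "fewer than 2 positions with nonzero totals")
  counts <- counts[totals > 0, , drop = FALSE]
  prop <- counts / rowSums(counts)
  d <- as.integer(rownames(counts))
  res <- trend_rho_p(prop, d)
  fam_size <- ncol(counts)
  res |>
    mutate(end = .env$end, .after = "kmer") |>
    mutate(significant = .data$p_raw < alpha / fam_size)
}

#' Species-level cis-motif usage metric Y
#'
#' Proportion of k-mers (sense codons; amino acids) with a significant
#' Bonferroni-corrected usage trend near junctions. Computed on the full
#' exon pool and as the mean over `repetitions` random subsamples of
#' `subsample_size` exons drawn with replacement (controls for pool size
#' when comparing species). A k-mer counts as trending if significant at
#' either end (`rule = "either"`, the default) or at both ends
#' (`rule = "both"`).
#'
#' @inheritParams positional_trend_test
#' @param subsample_size Exons per subsample (default 5000).
#' @param repetitions Number of subsamples (default 100).
#' @param seed Integer seed; results are deterministic given the seed.
#' @param rule `"either"` or `"both"` end significance rule.
#' @param species Label for the output row.
#' @return One-row tibble `species`, `y_codon`, `y_aa`, `y_codon_sub`,
#'   `y_aa_sub`, `n_exons`.
#' @export
cis_motif_usage <- function(features, subsample_size = 5000,
                            repetitions = 100, seed = 1L, alpha = 0.05,
                            rule = c("either", "both"),
                            species = "species") {
  rule <- match.arg(rule)
  check_that(subsample_size > 0, "subsample_size must be positive")
  check_that(nrow(features) > 0, "empty exon pool")
  pos5 <- codon_position_table(features, "5prime")
  pos3 <- codon_position_table(features, "3prime")
  n <- nrow(features)

  y_of <- function(w) {
    c5 <- trend_counts(pos5, n, w)
    c3 <- trend_counts(pos3, n, w)
    vapply(c("codon", "amino_acid"), function(fam) {
      s5 <- trend_from_counts(c5, fam, "5prime", alpha)$significant
      s3 <- trend_from_counts(c3, fam, "3prime", alpha)$significant
      hit <- if (rule == "either") s5 | s3 else s5 & s3
      mean(hit)
    }, numeric(1))
  }

  y_full <- y_of(NULL)
  set.seed(seed)
  y_sub <- vapply(seq_len(repetitions), function(i) {
    w <- tabulate(sample.int(n, subsample_size, replace = TRUE), n)
    y_of(w)
  }, numeric(2))
  tibble(
    species = species,
    y_codon = y_full[["codon"]], y_aa = y_full[["amino_acid"]],
    y_codon_sub = mean(y_sub["codon", ]),
    y_aa_sub = mean(y_sub["amino_acid", ]),
    n_exons = n
  )
}

#' Splice-site usage proportions
#'
#' `p1` is the proportion of donor strings equal to `"AGgt"` (last two
#' exonic nt upper case, first two intronic lower case); `p2` the
#' proportion of acceptor strings equal to `"agGT"`.
#'
#' @param features Internal-exon feature tibble with `donor` and
#'   `acceptor` columns.
#' @param species Label for the output row.
#' @return One-row tibble `species`, `p1`, `p2`, `n_donors`,
#'   `n_acceptors`.
#' @export
splice_site_usage <- function(features, species = "species") {
  donors <- features$donor[!is.na(features$donor)]
  acceptors <- features$acceptor[!is.na(features$acceptor)]
  check_that(length(donors) > 0, "no donor sites")
  check_that(length(acceptors) > 0, "no acceptor sites")
  tibble(
    species = species,
    p1 = mean(donors == "AGgt"),
    p2 = mean(acceptors == "agGT"),
    n_donors = length(donors),
    n_acceptors = length(acceptors)
  )
}
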