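#' Synonymous divergence between two aligned coding sequences (NG86)
#'
#' Nei-Gojobori (1986) counting with Jukes-Cantor correction. Synonymous
#' sites are counted per codon as the fraction of single-nucleotide changes
#' that preserve the amino acid (changes to stop codons count as
#' nonsynonymous) and averaged over the two sequences. Differences between
#' codons that differ at more than one position are averaged over all
#' minimal mutational pathways, excluding pathways that pass through a stop
#' codon. Codon columns containing gaps, ambiguity characters or stop
#' codons are skipped.
#'
#' The proportion of synonymous differences `ps = syn_diffs / syn_sites` is
#' corrected to `ks = -(3/4) * log(1 - (4/3) * ps)`; when `ps >= 3/4` the
#' estimate is saturated and `ks` is `NA` with `saturated = TRUE`.
#'
#' @param seq_a,seq_b In-frame aligned nucleotide strings of equal length
#'   (multiple of 3); gaps as `-`.
#' @return A one-row tibble with columns `ks`, `ps`, `syn_sites`,
#'   `syn_diffs`, `n_codons`, `saturated`.
#' @examples
#' ks_ng86("TTTTCAGGG", "TTCTCAGGG")
#' @export
ks_ng86 <- function(seq_a, seq_b) {
  check_that(is.character(seq_a) && length(seq_a) == 1 &&
             is.character(seq_b) && length(seq_b) == 1,
             "seq_a and seq_b must be single strings")
  check_that(nchar(seq_a) == nchar(seq_b),
             "aligned sequences must have equal length")
  ia <- codon_index(toupper(codons_of(seq_a)))
  ib <- codon_index(toupper(codons_of(seq_b)))
  ks_ng86_indexed(ia, ib)
}

#' NG86 Ks from codon index vectors (internal fast path)
#'
#' @param ia,ib Integer codon indices (1..64, NA for gapped/ambiguous
#'   columns), equal length.
#' @keywords internal
#' @noRd
ks_ng86_indexed <- function(ia, ib) {
  check_that(length(ia) == length(ib), "codon vectors must be equal length")
  s_tab <- ng86_syn_sites()
  pair <- ng86_pair_diffs()
  keep <- !is.na(ia) & !is.na(ib) & !is.na(s_tab[ia]) & !is.na(s_tab[ib])
  ia <- ia[keep]; ib <- ib[keep]
  n_codons <- length(ia)
  if (n_codons == 0L) {
    return(tibble(ks = NA_real_, ps = NA_real_, syn_sites = 0,
                  syn_diffs = 0, n_codons = 0L, saturated = FALSE))
  }
  sd_v <- pair$sd[cbind(ia, ib)]
  # drop pairs whose every minimal path runs through a stop codon
  ok <- !is.na(sd_v)
  ia <- ia[ok]; ib <- ib[ok]; sd_v <- sd_v[ok]
  n_codons <- length(ia)
  syn_sites <- (sum(s_tab[ia]) + sum(s_tab[ib])) / 2
  syn_diffs <- sum(sd_v)
  if (syn_sites <= 0) {
    return(tibble(ks = NA_real_, ps = NA_real_, syn_sites = syn_sites,
                  syn_diffs = syn_diffs, n_codons = n_codons,
                  saturated = FALSE))
  }
  ps <- syn_diffs / syn_sites
  saturated <- ps >= 3 / 4
  ks <- if (saturated) NA_real_ else -(3 / 4) * log(1 - (4 / 3) * ps)
  tibble(ks = ks, ps = ps, syn_sites = syn_sites, syn_diffs = syn_diffs,
         n_codons = n_codons, saturated = saturated)
}
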