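# Intragene decoy-splice-site tests: ESE density of second versus
# last-but-one exons, loess-residual control for proximal intron size,
# and splice-site class versus intron size.

#' Paired second / penultimate exon ESE density records
#'
#' From genes with four or more exons whose second and last-but-one exons
#' are both longer than 138 bp, the 5'-flank ESE density and 5' (upstream)
#' intron size of the two exons. The terminal exon never enters a record
#' (its stop-codon-proximal composition is constrained for other reasons).
#'
#' @param features Internal-exon feature tibble.
#' @param motifs A [hexamer_set()].
#' @return Tibble `gene_id`, `density_second`, `density_penultimate`,
#'   `intron5_second`, `intron5_penultimate`.
#' @export
paired_density_records <- function(features, motifs) {
  cand <- features |>
    filter(.data$n_exons >= 4L, !is.na(.data$flank5_seq),
           .data$exon_index == 2L |
             .data$exon_index == .data$n_exons - 1L) |>
    mutate(class = if_else(.data$exon_index == 2L, "second", "penultimate"))
  check_that(nrow(cand) > 0, "no qualifying second/penultimate exons")
  cand$density <- ese_density(cand$flank5_seq, motifs)
  wide <- cand |>
    select("gene_id", "class", "density", "intron5") |>
    tidyr::pivot_wider(names_from = "class",
                       values_from = c("density", "intron5")) |>
    filter(!is.na(.data$density_second), !is.na(.data$density_penultimate))
  wide |>
    select("gene_id", "density_second", "density_penultimate",
           intron5_second = "intron5_second",
           intron5_penultimate = "intron5_penultimate")
}

#' Second versus last-but-one exon ESE density (paired binomial test)
#'
#' Counts genes whose second-exon 5'-flank ESE density is higher / lower
#' than that of the last-but-one exon (ties ignored) and applies the
#' standard exact two-sided binomial test at p = 0.5. Medians of both
#' densities are reported.
#'
#' @inheritParams paired_density_records
#' @param records Optionally a precomputed [paired_density_records()]
#'   table (then `features`/`motifs` are ignored).
#' @return One-row tibble `n_higher`, `n_lower`, `n_tied`, `p_binomial`,
#'   `median_second`, `median_penultimate`.
#' @export
second_vs_penultimate_test <- function(features, motifs, records = NULL) {
  if (is.null(records)) records <- paired_density_records(features, motifs)
  diff <- records$density_second - records$density_penultimate
  n_higher <- sum(diff > 0); n_lower <- sum(diff < 0)
  n_tied <- sum(diff == 0)
  check_that(n_higher + n_lower > 0, "no informative pairs")
  bt <- exact_binomial_sign_test(n_higher, n_higher + n_lower)
  tibble(
    n_higher = n_higher, n_lower = n_lower, n_tied = n_tied,
    p_binomial = bt$p,
    median_second = median(records$density_second),
    median_penultimate = median(records$density_penultimate)
  )
}

#' Loess-residual test of exon-class density controlling intron size
#'
#' Fits a loess regression of 5'-flank ESE density on log10 5'-intron
#' size over the pooled records (both exon classes), then compares the
#' residuals of second versus last-but-one exons by Mann-Whitney U and by
#' a within-gene paired sign test (exact binomial on the sign of the
#' residual difference, ties ignored).
#'
#' @param records A [paired_density_records()] table (>= 30 records).
#' @param span Loess span in (0, 1] (default 0.75, degree 1).
#' @return One-row tibble `p_mwu`, `n_res_higher`, `n_res_lower`,
#'   `p_paired_binomial`, `median_residual_second`,
#'   `median_residual_penultimate`.
#' @export
loess_residual_test <- function(records, span = 0.75) {
  check_that(nrow(records) >= 30, "need at least 30 records for loess")
  check_that(span > 0 && span <= 1, "span must be in (0, 1]")
  long <- bind_rows(
    tibble(gene_id = records$gene_id, class = "second",
           density = records$density_second,
           log_size = log10(records$intron5_second)),
    tibble(gene_id = records$gene_id, class = "penultimate",
           density = records$density_penultimate,
           log_size = log10(records$intron5_penultimate))
  )
  fit <- loess_fit(long$log_size, long$density, span = span, degree = 1)
  long$residual <- fit$residual
  res2 <- long$residual[long$class == "second"]
  resp <- long$residual[long$class == "penultimate"]
  mwu <- mann_whitney_u(res2, resp)
  dd <- res2 - resp
  n_hi <- sum(dd > 0); n_lo <- sum(dd < 0)
  check_that(n_hi + n_lo > 0, "no informative pairs")
  bt <- exact_binomial_sign_test(n_hi, n_hi + n_lo)
  tibble(
    p_mwu = mwu$p, n_res_higher = n_hi, n_res_lower = n_lo,
    p_paired_binomial = bt$p,
    median_residual_second = median(res2),
    median_residual_penultimate = median(resp)
  )
}

#' Flanking intron size by donor splice-site class (AGgt vs other)
#'
#' Mann-Whitney U comparison of downstream (3') flanking intron size
#' between internal exons with donor string `"AGgt"` and all other
#' donors.
#'
#' @param features Internal-exon feature tibble with `donor` and
#'   `intron3` populated.
#' @param alternative Test sidedness (default two-sided).
#' @return One-row tibble `p`, `median_aggt`, `median_other`, `n_aggt`,
#'   `n_other`.
#' @export
splice_site_intron_size_test <- function(features,
                                         alternative = "two.sided") {
  keep <- !is.na(features$donor) & !is.na(features$intron3)
  aggt <- features$intron3[keep & features$donor == "AGgt"]
  other <- features$intron3[keep & features$donor != "AGgt"]
  check_that(length(aggt) > 0 && length(other) > 0,
             "one of the donor classes is empty")
  mwu <- mann_whitney_u(aggt, other, alternative = alternative)
  tibble(p = mwu$p, median_aggt = mwu$median_a, median_other = mwu$median_b,
         n_aggt = length(aggt), n_other = length(other))
}
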