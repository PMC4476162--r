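# ggplot2 displays for the main result types.

#' Plot binned Ks by partition against intron size
#'
#' One line per partition (ESE, non-ESE, core, pseudo-ESE mean with a
#' standard-error ribbon) against the log10 upper intron-size limit of
#' each equal-count bin, faceted by exon end.
#'
#' @param object A `flank_bins` tibble from [binned_flank_constraint()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.flank_bins <- function(object, ...) {
  long <- object |>
    tidyr::pivot_longer(c("ks_ese", "ks_non_ese", "ks_core",
                          "ks_pseudo_mean"),
                        names_to = "partition", values_to = "ks") |>
    mutate(partition = dplyr::recode(.data$partition,
      ks_ese = "ESE", ks_non_ese = "non-ESE", ks_core = "core",
      ks_pseudo_mean = "pseudo-ESE"))
  ggplot2::ggplot(long,
                  ggplot2::aes(x = log10(.data$upper_limit), y = .data$ks,
                               colour = .data$partition)) +
    ggplot2::geom_ribbon(
      data = long |> filter(.data$partition == "pseudo-ESE"),
      ggplot2::aes(ymin = .data$ks - object$ks_pseudo_se[
                     match(paste(.data$end, .data$bin),
                           paste(object$end, object$bin))],
                   ymax = .data$ks + object$ks_pseudo_se[
                     match(paste(.data$end, .data$bin),
                           paste(object$end, object$bin))]),
      alpha = 0.2, colour = NA, fill = "grey60") +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~end) +
    ggplot2::labs(x = "log10 upper intron size of bin", y = "Ks",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot binned flank ESE constraint against intron size
#'
#' @inheritParams autoplot.flank_bins
#' @return A ggplot object.
#' @export
plot_constraint_bins <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = log10(.data$upper_limit),
                               y = .data$constraint)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.4) +
    ggplot2::facet_wrap(~end) +
    ggplot2::labs(x = "log10 upper intron size of bin",
                  y = "flank ESE constraint (Ks core - Ks ESE) / Ks core") +
    ggplot2::theme_minimal()
}

#' Plot positional usage trends for selected k-mers
#'
#' Proportional usage against codon distance from the junction for the
#' significant k-mers (or a chosen subset).
#'
#' @param features Internal-exon feature tibble.
#' @param trends Output of [positional_trend_test()].
#' @param kmers K-mers to show; default the significant ones.
#' @param end Exon end, matching the trend table.
#' @return A ggplot object.
#' @export
plot_positional_trends <- function(features, trends,
                                   kmers = NULL,
                                   end = trends$end[1]) {
  if (is.null(kmers)) kmers <- trends$kmer[trends$significant]
  check_that(length(kmers) > 0, "no k-mers to plot")
  pos_tbl <- codon_position_table(features, end)
  counts <- trend_counts(pos_tbl, nrow(features))
  if (all(nchar(kmers) == 1)) counts <- counts_to_aa(counts)
  prop <- counts / rowSums(counts)
  df <- as_tibble(prop, rownames = "d") |>
    mutate(d = as.integer(.data$d)) |>
    tidyr::pivot_longer(-"d", names_to = "kmer", values_to = "proportion") |>
    filter(.data$kmer %in% kmers)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$d, y = .data$proportion,
                                   colour = .data$kmer)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "codon distance from junction",
                  y = "proportional usage", colour = NULL) +
    ggplot2::theme_minimal()
}
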