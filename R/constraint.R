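# Flank ESE constraint: masking of 69-bp exon-end flanks with hexamer
# sets, NG86 Ks in ESE / non-ESE / core partitions over equal-count
# intron-size bins, pseudo-ESE nulls, and the per-exon and per-gene
# selection metrics.
#
# Alignments are codon-aligned reference/ortholog CDS pairs (gaps "-").
# ESE matching is performed on the reference flank sequence and projected
# onto alignment columns; a codon column is ESE when at least 2 of its 3
# sites are covered by a hexamer hit (majority rule), else non-ESE. Only
# complete, gap-free codon columns enter a partition.

# integer encoding of 6-mers (base 4 over A,C,G,T); NA for non-ACGT
hexamer_to_int <- function(x) {
  out <- rep(0L, length(x))
  for (k in 1:6) {
    b <- match(substring(x, k, k), BASES) - 1L
    out <- out * 4L + b
  }
  out
}

#' Prepare aligned flank/core codon tables for constraint analysis
#'
#' Joins internal-exon features to per-gene codon alignments and builds
#' the per-exon-end flank table plus long codon tables used by the
#' binned, per-exon and per-gene constraint estimators.
#'
#' @param features Internal-exon features ([extract_internal_exon_features()]);
#'   only rows with flanks defined (exon length > 138) are used.
#' @param alignments Tibble with columns `gene_id`, `ref_align`,
#'   `ort_align`: codon-aligned CDS pairs whose ungapped reference equals
#'   the gene's CDS.
#' @return A list of class `constraint_data`: `flanks` (one row per exon
#'   end), `flank_codons`, `core_codons`, and the flank 6-mer window
#'   encoding used for fast re-masking.
#' @export
prepare_constraint_data <- function(features, alignments) {
  check_that(all(c("gene_id", "ref_align", "ort_align") %in%
                 names(alignments)),
             "alignments needs columns gene_id, ref_align, ort_align")
  feats <- features |>
    filter(!is.na(.data$flank5_seq)) |>
    inner_join(alignments, by = "gene_id")
  check_that(nrow(feats) > 0, "no flank-bearing exons with alignments")

  aln <- alignments |> filter(.data$gene_id %in% feats$gene_id)
  ref_chars <- strsplit(aln$ref_align, "")
  ort_chars <- strsplit(aln$ort_align, "")
  col_of <- lapply(ref_chars, function(ch) which(ch != "-"))
  names(col_of) <- aln$gene_id
  names(ort_chars) <- aln$gene_id

  # codon columns of a CDS region [from, to] (1-based CDS coords)
  region_codons <- function(gid, from, to) {
    q0 <- from + ((1L - from) %% 3L)          # first in-frame codon start
    if (q0 + 2L > to) {
      return(list(rel = integer(0), cds_start = integer(0),
                  ort = integer(0)))
    }
    starts <- seq.int(q0, to - 2L, by = 3L)
    cols <- col_of[[gid]]
    och <- ort_chars[[gid]]
    o1 <- och[cols[starts]]; o2 <- och[cols[starts + 1L]]
    o3 <- och[cols[starts + 2L]]
    ort_cod <- codon_index(toupper(paste0(o1, o2, o3)))
    list(rel = starts - from + 1L, cds_start = starts, ort = ort_cod)
  }

  flank_rows <- list(); flank_codon_rows <- list(); core_rows <- list()
  for (i in seq_len(nrow(feats))) {
    f <- feats[i, ]
    for (side in c("5prime", "3prime")) {
      if (side == "5prime") {
        from <- f$cds_from; seq69 <- f$flank5_seq; isz <- f$intron5
      } else {
        from <- f$cds_to - 68L; seq69 <- f$flank3_seq; isz <- f$intron3
      }
      rc <- region_codons(f$gene_id, from, from + 68L)
      fid <- length(flank_rows) + 1L
      flank_rows[[fid]] <- tibble(
        flank_id = fid, gene_id = f$gene_id, exon_index = f$exon_index,
        end = side, intron_size = isz, flank_seq = seq69
      )
      ref_cod <- codon_index(substring(seq69, rc$rel, rc$rel + 2L))
      flank_codon_rows[[fid]] <- tibble(
        flank_id = fid, gene_id = f$gene_id, end = side,
        rel_start = rc$rel, ref_idx = ref_cod, ort_idx = rc$ort
      )
    }
    core_from <- f$cds_from + floor((f$length - 69L) / 2)
    rcc <- region_codons(f$gene_id, core_from, core_from + 68L)
    core_rows[[i]] <- tibble(
      gene_id = f$gene_id, exon_index = f$exon_index,
      ref_idx = codon_index(substring(f$core_seq, rcc$rel, rcc$rel + 2L)),
      ort_idx = rcc$ort
    )
  }
  flanks <- bind_rows(flank_rows)
  flank_codons <- bind_rows(flank_codon_rows)
  core_codons <- bind_rows(core_rows)

  # 6-mer windows of every flank, integer-encoded for fast re-masking
  n_win <- 64L
  starts <- seq_len(n_win)
  win <- matrix(substring(rep(flanks$flank_seq, each = n_win),
                          starts, starts + 5L),
                nrow = nrow(flanks), ncol = n_win, byrow = TRUE)
  win_int <- matrix(hexamer_to_int(win), nrow = nrow(flanks))

  structure(list(flanks = flanks, flank_codons = flank_codons,
                 core_codons = core_codons, win_int = win_int),
            class = "constraint_data")
}

# per-nucleotide coverage (n_flanks x 69) for a motif set, from the
# precomputed integer window encoding
flank_coverage_int <- function(win_int, motifs) {
  set_int <- hexamer_to_int(as.character(motifs))
  hits <- matrix(win_int %in% set_int, nrow = nrow(win_int))
  cov <- matrix(FALSE, nrow(win_int), 69L)
  starts <- seq_len(ncol(win_int))
  for (k in 0:5) {
    idx <- starts + k
    cov[, idx] <- cov[, idx] | hits
  }
  cov
}

# ESE flag per flank codon row (majority rule: >=2 of 3 sites covered)
flank_codon_ese <- function(data, motifs) {
  cov <- flank_coverage_int(data$win_int, motifs)
  fc <- data$flank_codons
  n_cov <- cov[cbind(fc$flank_id, fc$rel_start)] +
    cov[cbind(fc$flank_id, fc$rel_start + 1L)] +
    cov[cbind(fc$flank_id, fc$rel_start + 2L)]
  n_cov >= 2L
}

# Ks of a codon-row subset
ks_of_rows <- function(tbl, rows) {
  ks_ng86_indexed(tbl$ref_idx[rows], tbl$ort_idx[rows])
}

# equal-count bin assignment (sizes differ by at most 1), ties broken by
# stable sort on (size, gene_id, exon_index)
equal_count_bins <- function(flanks, n_bins) {
  n <- nrow(flanks)
  check_that(n_bins <= n, "more bins than exon ends")
  ord <- order(flanks$intron_size, flanks$gene_id, flanks$exon_index,
               method = "radix")
  sizes <- rep(n %/% n_bins, n_bins)
  extra <- n %% n_bins
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  bin <- integer(n)
  bin[ord] <- rep(seq_len(n_bins), times = sizes)
  bin
}

#' Binned flank ESE constraint (Ks in ESE / non-ESE / core partitions)
#'
#' Exon ends are apportioned to `n_bins` equal-count bins by the size of
#' their own flanking intron (5' and 3' ends analysed separately). Within
#' each bin, ESE-masked codon columns, non-ESE columns and the 69-bp exon
#' cores are concatenated and Ks estimated once per partition (NG86 + JC).
#' `pseudo_reps` pseudo-ESE sets of matched cardinality and pooled
#' nucleotide content provide the mutational-bias null (mean and standard
#' error of Ks across sets). Constraint per bin is
#' `(ks_core - ks_ese) / ks_core`.
#'
#' @inheritParams prepare_constraint_data
#' @param motifs A [hexamer_set()].
#' @param n_bins Number of equal-count intron-size bins (default 20).
#' @param pseudo_reps Number of pseudo-ESE replicate sets (default 100;
#'   0 skips the null).
#' @param seed Seed for the pseudo-ESE draws.
#' @param data Optionally, a precomputed [prepare_constraint_data()]
#'   object (then `features`/`alignments` are ignored).
#' @return A tibble of class `flank_bins`: one row per end x bin with
#'   `end`, `bin`, `n_ends`, `upper_limit`, `ks_ese`, `ks_non_ese`,
#'   `ks_core`, `ks_pseudo_mean`, `ks_pseudo_se`, `constraint`.
#' @export
binned_flank_constraint <- function(features, alignments, motifs,
                                    n_bins = 20, pseudo_reps = 100,
                                    seed = 1L, data = NULL) {
  if (is.null(data)) data <- prepare_constraint_data(features, alignments)
  ese_flag <- flank_codon_ese(data, motifs)
  pseudo_sets <- if (pseudo_reps > 0) {
    pseudo_ese_sets(motifs, n_sets = pseudo_reps, seed = seed)
  } else list()
  pseudo_flags <- lapply(pseudo_sets, function(s) flank_codon_ese(data, s))

  fc <- data$flank_codons
  out <- list()
  for (side in c("5prime", "3prime")) {
    fl <- data$flanks |> filter(.data$end == side)
    fl$bin <- equal_count_bins(fl, n_bins)
    bin_of_flank <- setNames(fl$bin, fl$flank_id)
    side_rows <- which(fc$end == side)
    fc_bin <- bin_of_flank[as.character(fc$flank_id[side_rows])]
    # core codons keyed to this side's exon-end bins
    core_key <- fl |>
      select("gene_id", "exon_index", "bin")
    cores <- data$core_codons |>
      inner_join(core_key, by = c("gene_id", "exon_index"))
    for (b in seq_len(n_bins)) {
      rows_b <- side_rows[fc_bin == b]
      ese_rows <- rows_b[ese_flag[rows_b]]
      non_rows <- rows_b[!ese_flag[rows_b]]
      core_rows <- which(cores$bin == b)
      ks_e <- ks_of_rows(fc, ese_rows)
      ks_n <- ks_of_rows(fc, non_rows)
      ks_c <- ks_of_rows(cores, core_rows)
      ks_p <- vapply(pseudo_flags, function(fl_p) {
        ks_of_rows(fc, rows_b[fl_p[rows_b]])$ks
      }, numeric(1))
      ks_p <- ks_p[is.finite(ks_p)]
      fl_b <- fl |> filter(.data$bin == b)
      out[[length(out) + 1L]] <- tibble(
        end = side, bin = b, n_ends = nrow(fl_b),
        upper_limit = max(fl_b$intron_size),
        ks_ese = ks_e$ks, ks_non_ese = ks_n$ks, ks_core = ks_c$ks,
        ks_pseudo_mean = if (length(ks_p)) mean(ks_p) else NA_real_,
        ks_pseudo_se = if (length(ks_p) > 1) sd(ks_p) / sqrt(length(ks_p))
                       else NA_real_,
        constraint = (ks_c$ks - ks_e$ks) / ks_c$ks
      )
    }
  }
  structure(bind_rows(out), class = c("flank_bins", class(tibble())))
}

#' Per-exon-end selection proportion (density x interpolated constraint)
#'
#' Fits an ordinary least-squares line to the unbinned per-exon-end
#' constraint versus log10 flanking intron size (ends with undefined Ks
#' excluded), interpolates the constraint expected at each end's intron
#' size, and multiplies by that end's ESE density. Negative interpolated
#' constraints and products are retained unfloored. The Spearman
#' correlation of the product with log10 intron size is reported.
#'
#' @inheritParams binned_flank_constraint
#' @return A list of class `selection_proportion`: `per_end` tibble
#'   (`end`, `intron_size`, `density`, `constraint_raw`,
#'   `constraint_fit`, `selection_prop`), `regression` (intercept/slope
#'   per end), `spearman` (rho/p of product vs log10 size per end).
#' @export
selection_proportion_per_exon <- function(features, alignments, motifs,
                                          data = NULL) {
  if (is.null(data)) data <- prepare_constraint_data(features, alignments)
  ese_flag <- flank_codon_ese(data, motifs)
  cov <- flank_coverage_int(data$win_int, motifs)
  density <- rowMeans(cov)
  fc <- data$flank_codons

  per_end <- data$flanks |>
    mutate(density = density[.data$flank_id])
  ks_pairs <- purrr::map(per_end$flank_id, function(fid) {
    rows <- which(fc$flank_id == fid)
    ks_e <- ks_of_rows(fc, rows[ese_flag[rows]])$ks
    f <- data$flanks[fid, ]
    core_rows <- which(data$core_codons$gene_id == f$gene_id &
                       data$core_codons$exon_index == f$exon_index)
    ks_c <- ks_of_rows(data$core_codons, core_rows)$ks
    c(ks_e = ks_e, ks_c = ks_c)
  })
  per_end$ks_ese <- vapply(ks_pairs, `[[`, numeric(1), "ks_e")
  per_end$ks_core <- vapply(ks_pairs, `[[`, numeric(1), "ks_c")
  per_end <- per_end |>
    mutate(constraint_raw = (.data$ks_core - .data$ks_ese) / .data$ks_core,
           log_size = log10(.data$intron_size))

  reg <- list(); sp <- list(); fits <- rep(NA_real_, nrow(per_end))
  for (side in c("5prime", "3prime")) {
    idx <- which(per_end$end == side)
    pts <- idx[is.finite(per_end$constraint_raw[idx])]
    check_that(length(pts) >= 3,
               "fewer than 3 usable points for the constraint regression")
    fit <- lm(constraint_raw ~ log_size, data = per_end[pts, ])
    fits[idx] <- predict(fit, newdata = per_end[idx, ])
    reg[[side]] <- tibble(end = side, intercept = coef(fit)[[1]],
                          slope = coef(fit)[[2]], n_points = length(pts))
  }
  per_end$constraint_fit <- fits
  per_end$selection_prop <- per_end$density * per_end$constraint_fit
  for (side in c("5prime", "3prime")) {
    idx <- which(per_end$end == side)
    s <- spearman_trend(per_end$selection_prop[idx], per_end$log_size[idx])
    sp[[side]] <- tibble(end = side, rho = s$rho, p = s$p, n = s$n)
  }
  structure(
    list(per_end = per_end |>
           select("end", "gene_id", "exon_index", "intron_size", "density",
                  "constraint_raw", "constraint_fit", "selection_prop"),
         regression = bind_rows(reg), spearman = bind_rows(sp)),
    class = "selection_proportion"
  )
}

#' Gene-level flank ESE constraint versus intronic dimensions
#'
#' Per gene, all flank ESE codon columns (both ends of every usable
#' internal exon) and all core columns are concatenated; genes whose
#' concatenated ESE-flank and core lengths both exceed `cutoff` bp are
#' retained; Ks is computed once per concatenation and the gene-level
#' constraint is `(ks_core - ks_ese) / ks_core` (zero synonymous ESE
#' substitutions with positive core Ks give a constraint of exactly 1).
#' The constraint is then correlated with three intronic dimensions
#' (mean intron size, intron density, intron number) by Spearman, partial
#' Spearman (controlling the other two) and Goodman-Kruskal gamma with a
#' permutation p-value. A resampling report draws `resample_size` genes
#' (default: the gene count passing the 150-bp cutoff) from the retained
#' pool `resample_reps` times and reports the fraction of draws with a
#' significant (p < 0.05) Spearman correlation.
#'
#' @param genes Gene-model tibble (provides CDS length and intron sizes).
#' @inheritParams binned_flank_constraint
#' @param cutoff Concatenation length cutoff in bp; 102, 150 and 201 are
#'   the conventional choices (others warn but proceed).
#' @param resample_reps Number of resampling draws (0 skips).
#' @param resample_size Genes per draw; `NULL` uses the 150-bp-cutoff
#'   gene count.
#' @param gamma_perms Permutations for the gamma p-value.
#' @return A list of class `gene_constraint`: `genes` (per-gene tibble),
#'   `correlations`, `resampling`.
#' @export
gene_level_constraint <- function(genes, features, alignments, motifs,
                                  cutoff = 102, resample_reps = 1000,
                                  resample_size = NULL, gamma_perms = 1000,
                                  seed = 1L, data = NULL) {
  if (!cutoff %in% c(102, 150, 201)) {
    warn(paste0("cutoff ", cutoff, " bp is not one of 102/150/201"))
  }
  if (is.null(data)) data <- prepare_constraint_data(features, alignments)
  ese_flag <- flank_codon_ese(data, motifs)
  fc <- data$flank_codons

  per_gene_ks <- function(gids) {
    ese_rows <- which(ese_flag & fc$gene_id %in% gids)
    split_e <- split(ese_rows, fc$gene_id[ese_rows])
    core <- data$core_codons
    core_rows <- which(core$gene_id %in% gids)
    split_c <- split(core_rows, core$gene_id[core_rows])
    tibble(
      gene_id = gids,
      ese_len = vapply(gids, function(g)
        3L * length(split_e[[g]]), integer(1)),
      core_len = vapply(gids, function(g)
        3L * length(split_c[[g]]), integer(1)),
      ks_ese = vapply(gids, function(g)
        ks_of_rows(fc, split_e[[g]])$ks, numeric(1)),
      ks_core = vapply(gids, function(g)
        ks_of_rows(core, split_c[[g]])$ks, numeric(1))
    )
  }

  gids <- intersect(genes$gene_id, unique(data$flanks$gene_id))
  ktab <- per_gene_ks(gids)
  gtab <- genes |>
    filter(.data$gene_id %in% gids) |>
    mutate(
      cds_len = nchar(.data$cds),
      intron_number = lengths(.data$intron_sizes),
      mean_intron_size = vapply(.data$intron_sizes, mean, numeric(1)),
      intron_density = .data$intron_number / (.data$cds_len / 1000)
    ) |>
    select("gene_id", "intron_number", "mean_intron_size",
           "intron_density") |>
    inner_join(ktab, by = "gene_id") |>
    mutate(constraint = (.data$ks_core - .data$ks_ese) / .data$ks_core)

  retained <- gtab |>
    filter(.data$ese_len > cutoff, .data$core_len > cutoff,
           is.finite(.data$constraint))
  check_that(nrow(retained) >= 10,
             "fewer than 10 genes pass the concatenation cutoff")

  dims <- c("mean_intron_size", "intron_density", "intron_number")
  cors <- purrr::map(dims, function(dm) {
    others <- setdiff(dims, dm)
    s <- spearman_trend(retained$constraint, retained[[dm]])
    ps <- partial_spearman(retained$constraint, retained[[dm]],
                           retained[others])
    g <- goodman_kruskal_gamma_perm(retained[[dm]], retained$constraint,
                                    m = gamma_perms, seed = seed)
    tibble(dimension = dm, rho = s$rho, p = s$p,
           rho_partial = ps$rho_partial, p_partial = ps$p,
           gamma = g$gamma, p_gamma = g$p_perm)
  }) |> bind_rows()

  resampling <- NULL
  if (resample_reps > 0) {
    if (is.null(resample_size)) {
      resample_size <- sum(gtab$ese_len > 150 & gtab$core_len > 150 &
                           is.finite(gtab$constraint))
    }
    resample_size <- min(resample_size, nrow(retained))
    check_that(resample_size >= 10, "resample size too small")
    set.seed(seed)
    sig <- matrix(FALSE, resample_reps, length(dims),
                  dimnames = list(NULL, dims))
    for (r in seq_len(resample_reps)) {
      sub <- retained[sample.int(nrow(retained), resample_size), ]
      for (dm in dims) {
        sig[r, dm] <- spearman_trend(sub$constraint, sub[[dm]])$p < 0.05
      }
    }
    resampling <- tibble(dimension = dims,
                         frac_significant = unname(colMeans(sig)),
                         resample_size = resample_size,
                         reps = resample_reps)
  }
  structure(list(genes = retained, correlations = cors,
                 resampling = resampling, cutoff = cutoff),
            class = "gene_constraint")
}

#' @export
print.gene_constraint <- function(x, ...) {
  cat("<gene_constraint> ", nrow(x$genes), " genes (cutoff ",
      x$cutoff, " bp)\n", sep = "")
  print(x$correlations)
  invisible(x)
}
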