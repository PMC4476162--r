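# Synthetic-data generators: gene architectures with planted ESEs,
# diverged ortholog pairs with a reduced synonymous rate inside ESE
# coverage, infinite-sites polymorphism samples on a neutral coalescent,
# correlated Brownian traits on trees, and direct fixtures for the trend
# and intragene tests.
#
# All generators are deterministic given their seed. Exon boundaries are
# placed at codon boundaries (phase-0 introns only), so 69-bp flanks are
# codon-aligned; introns are canonical GT..AG.

#' Simulation configuration
#'
#' Defaults describe a compact vertebrate-like gene set: 3 + Poisson(4)
#' exons per gene; internal exon lengths log-normal around 85 codons with
#' a 69-codon (207 bp) floor, so flanks are always defined and the
#' central 69-bp core never overlaps a flank (keeping the planted
#' core/flank contrast identifiable); intron sizes log-normal
#' (median 500 bp, sdlog 1), minimum 60 bp; planted flank ESE coverage
#' `base_density + slope_log10_size * log10(flanking intron) +
#' slope_downstream * downstream intron count`; ortholog core synonymous
#' divergence 0.06 with ESE synonymous rate multiplied by `1 - ese_constraint`;
#' polymorphism at theta = 0.005 (n = 10, L = 1e5); bivariate Brownian
#' traits with correlation 0.8.
#'
#' @param ... Overrides for any default field.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(...) {
  cfg <- list(
    seed = 1L,
    n_genes = 100L,
    exon_count_min = 3L, exon_count_lambda = 4,
    exon_len_meanlog = log(85), exon_len_sdlog = 0.25,
    exon_min_codons = 4L, internal_min_codons = 69L,
    intron_meanlog = log(500), intron_sdlog = 1, intron_min = 60L,
    ese_set = NULL,
    base_density = 0.05, slope_log10_size = 0.02, slope_downstream = 0.005,
    p_aggt = 0.3,
    d_core = 0.06, ese_constraint = 0.3,
    theta = 0.005, n_haplotypes = 10L, seq_length = 1e5,
    n_species = 30L, rho_true = 0.8, bm_rates = c(1, 1)
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  check_that(length(unknown) == 0,
             paste("unknown sim_config fields:", paste(unknown, collapse = ", ")))
  cfg[names(over)] <- over
  if (is.null(cfg$ese_set)) cfg$ese_set <- default_synthetic_ese()
  structure(cfg, class = "sim_config")
}

#' Built-in synthetic ESE hexamer set
#'
#' A purine-rich 84-hexamer set shipped with the package
#' (`inst/extdata/ese_synthetic_84.txt`). Synthetic: generated to mimic
#' the purine-rich composition of consensus ESE catalogues, not derived
#' from any published motif list.
#'
#' @return A [hexamer_set()].
#' @export
default_synthetic_ese <- function() {
  path <- system.file("extdata", "ese_synthetic_84.txt",
                      package = "splicesel")
  check_that(nzchar(path), "bundled synthetic ESE set not found")
  read_hexamer_set(path, name = "synthetic_ESE_84")
}

#' Simulate a species' gene set with planted flank ESEs
#'
#' Genes are constructed to satisfy every loader filter (ATG start, stop
#' end, no internal stop, no ambiguity, >= 2 introns): uniform sense
#' codons, phase-0 exon boundaries, canonical `gt..ag` introns. ESE
#' hexamers from `config$ese_set` are planted codon-aligned in each
#' internal-exon flank at an expected per-flank coverage given by the
#' density model; with probability `p_aggt` an internal exon's terminal
#' dinucleotide is set to `AG` (making an `AGgt` donor).
#'
#' @param config A [sim_config()].
#' @return List with `genes` (tibble in the [load_and_filter_genes()]
#'   schema) and `genome` (named character vector of scaffolds).
#' @export
simulate_species_genes <- function(config = sim_config()) {
  set.seed(config$seed)
  motifs <- config$ese_set
  motif_codons <- lapply(as.character(motifs), function(m) {
    c(substr(m, 1, 3), substr(m, 4, 6))
  })
  motif_ok <- vapply(motif_codons, function(cc)
    !any(cc %in% STOP_CODONS), logical(1))
  check_that(any(motif_ok),
             "every motif contains an in-frame stop codon; cannot plant")
  plantable <- which(motif_ok)

  rows <- vector("list", config$n_genes)
  genome <- character(config$n_genes)
  scaffolds <- paste0("scf", seq_len(config$n_genes))
  for (g in seq_len(config$n_genes)) {
    n_ex <- config$exon_count_min + rpois(1, config$exon_count_lambda)
    len_cod <- pmax(config$exon_min_codons,
                    round(rlnorm(n_ex, config$exon_len_meanlog,
                                 config$exon_len_sdlog)))
    if (n_ex > 2) {
      idx <- 2:(n_ex - 1)
      len_cod[idx] <- pmax(len_cod[idx], config$internal_min_codons)
    }
    introns <- pmax(config$intron_min,
                    round(rlnorm(n_ex - 1, config$intron_meanlog,
                                 config$intron_sdlog)))
    total_cod <- sum(len_cod)
    cod <- sample(SENSE_CODONS, total_cod, replace = TRUE)
    cod[1] <- "ATG"
    cod[total_cod] <- sample(STOP_CODONS, 1)
    ends_cum <- cumsum(len_cod)
    starts_cum <- c(0L, head(ends_cum, -1L))

    # plant ESEs in internal exon flanks (codon-aligned disjoint slots)
    if (n_ex > 2) {
      for (e in 2:(n_ex - 1)) {
        for (side in c("5prime", "3prime")) {
          isz <- if (side == "5prime") introns[e - 1] else introns[e]
          target <- config$base_density +
            config$slope_log10_size * log10(isz) +
            config$slope_downstream * (n_ex - e)
          target <- min(max(target, 0), 0.6)
          m_exp <- target * 69 / 6
          m <- floor(m_exp) + rbinom(1, 1, m_exp - floor(m_exp))
          m <- min(m, 11L)
          if (m == 0) next
          slot_first <- if (side == "5prime") {
            starts_cum[e] + seq(1L, 21L, by = 2L)        # codons 1,3,..,21
          } else {
            ends_cum[e] - 23L + seq(2L, 22L, by = 2L)    # codons 2,4,..,22 of last 23
          }
          slots <- sample(slot_first, m)
          for (s in slots) {
            mc <- motif_codons[[sample(plantable, 1)]]
            cod[s] <- mc[1]; cod[s + 1] <- mc[2]
          }
        }
      }
      # AGgt donors: force terminal exon dinucleotide to AG
      for (e in 2:(n_ex - 1)) {
        if (runif(1) < config$p_aggt) {
          cod[ends_cum[e]] <- sample(c("AAG", "CAG", "GAG"), 1)
        }
      }
    }
    cds <- paste(cod, collapse = "")

    # scaffold: pad + exon/intron alternation (forward orientation)
    intron_seqs <- vapply(introns, function(L) {
      paste0("GT", paste(sample(BASES, L - 4L, replace = TRUE),
                         collapse = ""), "AG")
    }, character(1))
    exon_seqs <- substring(cds, 3L * starts_cum + 1L, 3L * ends_cum)
    pieces <- character(2L * n_ex - 1L)
    pieces[seq(1L, by = 2L, length.out = n_ex)] <- exon_seqs
    if (n_ex > 1) pieces[seq(2L, by = 2L, length.out = n_ex - 1L)] <- intron_seqs
    pad5 <- paste(sample(BASES, 50, replace = TRUE), collapse = "")
    pad3 <- paste(sample(BASES, 50, replace = TRUE), collapse = "")
    body <- paste(pieces, collapse = "")
    strand <- sample(c("+", "-"), 1)

    # genomic coordinates (0-based half-open) on the forward construct
    exon_len_nt <- 3L * len_cod
    ex_starts <- 50L + cumsum(c(0L, head(exon_len_nt, -1L) +
                                  introns))
    ex_ends <- ex_starts + exon_len_nt
    if (strand == "+") {
      genome[g] <- paste0(pad5, body, pad3)
      exons <- tibble(start = ex_starts, end = ex_ends)
    } else {
      scaf_len <- 100L + nchar(body)
      genome[g] <- revcomp(paste0(pad5, body, pad3))
      # exon i (coding order) maps to descending coordinates on the
      # reverse-complemented scaffold
      exons <- tibble(start = scaf_len - ex_ends,
                      end = scaf_len - ex_starts)
    }
    rows[[g]] <- tibble(
      gene_id = sprintf("gene%04d", g), seqid = scaffolds[g],
      strand = strand, n_exons = n_ex, cds = cds,
      gene_span = sum(exon_len_nt) + sum(introns),
      exons = list(exons),
      intron_sizes = list(as.integer(introns)),
      intron_first2 = list(rep("GT", n_ex - 1L)),
      intron_last2 = list(rep("AG", n_ex - 1L))
    )
  }
  names(genome) <- scaffolds
  list(genes = bind_rows(rows), genome = genome)
}

#' Simulate a deliberately invalid gene set (rejection-path fixture)
#'
#' One gene per filter violation: internal stop, missing start, missing
#' stop, ambiguous nucleotide, intronless, CDS length not a multiple
#' of 3; plus one valid gene.
#'
#' @param seed Integer seed.
#' @return List with `genes` tibble (loader schema, unvalidated) and
#'   `genome`.
#' @export
simulate_invalid_genes <- function(seed = 1L) {
  base <- simulate_species_genes(sim_config(
    seed = seed, n_genes = 7L, exon_count_min = 3L, exon_count_lambda = 0,
    slope_log10_size = 0, slope_downstream = 0, p_aggt = 0
  ))
  genes <- base$genes
  genome <- base$genome
  tweak <- function(g, fun) {
    cds <- fun(genes$cds[g])
    genes$cds[g] <<- cds
    genome[[genes$seqid[g]]] <<-
      rebuild_scaffold(genes[g, ], cds, genome[[genes$seqid[g]]])
  }
  # gene 2: internal stop (second codon)
  tweak(2L, function(cds) { substr(cds, 4, 6) <- "TGA"; cds })
  # gene 3: no start codon
  tweak(3L, function(cds) { substr(cds, 1, 3) <- "GGG"; cds })
  # gene 4: no terminal stop
  tweak(4L, function(cds) {
    substr(cds, nchar(cds) - 2L, nchar(cds)) <- "GGG"; cds
  })
  # gene 5: ambiguous nucleotide
  tweak(5L, function(cds) { substr(cds, 10, 10) <- "N"; cds })
  # gene 6: intronless (collapse to a single exon covering the CDS)
  g <- 6L
  cds_len <- nchar(genes$cds[g])
  genes$exons[[g]] <- tibble(start = 50L, end = 50L + cds_len)
  genes$n_exons[g] <- 1L
  genes$intron_sizes[[g]] <- integer(0)
  genes$intron_first2[[g]] <- character(0)
  genes$intron_last2[[g]] <- character(0)
  genome[[genes$seqid[g]]] <- paste0(
    strrep("A", 50), genes$cds[g], strrep("A", 50))
  genes$strand[g] <- "+"
  genes$gene_span[g] <- cds_len
  # gene 7: CDS not a multiple of 3 (shave one nt off the last exon)
  g <- 7L
  ex <- genes$exons[[g]]
  ex$end[nrow(ex)] <- ex$end[nrow(ex)] - 1L
  genes$exons[[g]] <- ex
  genes$cds[g] <- substr(genes$cds[g], 1L, nchar(genes$cds[g]) - 1L)
  list(genes = genes, genome = genome)
}

# rewrite every exon span of a scaffold from a new CDS; exons are in
# coding order with coordinates on the final (possibly minus-strand)
# scaffold
rebuild_scaffold <- function(gene_row, cds, scaf) {
  ex <- gene_row$exons[[1]]
  strand <- gene_row$strand
  lens <- ex$end - ex$start
  ends_cum <- cumsum(lens)
  starts_cum <- c(0L, head(ends_cum, -1L))
  for (i in seq_len(nrow(ex))) {
    piece <- substr(cds, starts_cum[i] + 1L, ends_cum[i])
    if (strand == "-") piece <- revcomp(piece)
    substr(scaf, ex$start[i] + 1L, ex$end[i]) <- piece
  }
  scaf
}

#' Simulate diverged ortholog alignments with reduced ESE synonymous rate
#'
#' For each gene, synonymous substitutions are applied to a copy of the
#' CDS at third codon positions: a codon mutates with probability
#' `ps * s_c` (`s_c` its NG86 synonymous site count, `ps` the raw
#' synonymous difference proportion corresponding to the target
#' divergence `d_core` under Jukes-Cantor), multiplied by
#' `1 - ese_constraint` for flank codons inside ESE coverage (majority
#' rule, matching the analysis convention). Nonsynonymous positions are
#' held fixed; alignments are gap-free.
#'
#' @param genes Gene tibble from [simulate_species_genes()].
#' @param motifs The [hexamer_set()] that was planted.
#' @param d_core Core synonymous branch length (Ks scale).
#' @param ese_constraint Rate reduction c in [0, 1] inside ESE coverage.
#' @param seed Integer seed.
#' @return Tibble `gene_id`, `ref_align`, `ort_align`.
#' @export
simulate_orthologs <- function(genes, motifs, d_core = 0.06,
                               ese_constraint = 0.3, seed = 1L) {
  check_that(ese_constraint >= 0 && ese_constraint <= 1,
             "ese_constraint must be in [0, 1]")
  ps_target <- 3 / 4 * (1 - exp(-4 * d_core / 3))
  if (ps_target >= 3 / 4) warn("d_core at or beyond Jukes-Cantor saturation")
  set.seed(seed)
  s_tab <- ng86_syn_sites()
  syn3 <- syn3_neighbours()
  feats <- extract_internal_exon_features(genes)

  out <- purrr::pmap(list(genes$gene_id, genes$cds), function(gid, cds) {
    cod <- codons_of(cds)
    idx <- codon_index(cod)
    p_mut <- ps_target * ifelse(is.na(s_tab[idx]), 0, s_tab[idx])
    # ESE suppression in flank codons (phase-0 exons: flanks codon-aligned)
    ff <- feats[feats$gene_id == gid & !is.na(feats$flank5_seq), ]
    if (nrow(ff) > 0) {
      cov5 <- ese_coverage(ff$flank5_seq, motifs)
      cov3 <- ese_coverage(ff$flank3_seq, motifs)
      for (r in seq_len(nrow(ff))) {
        c_from <- (ff$cds_from[r] - 1L) %/% 3L   # 0-based codon offset
        for (side in c("5", "3")) {
          cov <- if (side == "5") cov5[r, ] else cov3[r, ]
          n_cov <- cov[seq(1, 67, by = 3)] + cov[seq(2, 68, by = 3)] +
            cov[seq(3, 69, by = 3)]
          ese_cod <- which(n_cov >= 2)
          if (length(ese_cod) == 0) next
          base_cod <- if (side == "5") c_from else
            (ff$cds_to[r] %/% 3L) - 23L
          pos <- base_cod + ese_cod
          p_mut[pos] <- p_mut[pos] * (1 - ese_constraint)
        }
      }
    }
    hit <- which(runif(length(cod)) < pmin(p_mut, 0.95))
    ort <- cod
    for (h in hit) {
      nb <- syn3[[idx[h]]]
      if (length(nb) > 0) ort[h] <- sample(nb, 1)
    }
    tibble(gene_id = gid, ref_align = cds,
           ort_align = paste(ort, collapse = ""))
  })
  bind_rows(out)
}

#' Simulate an infinite-sites polymorphism sample on a neutral coalescent
#'
#' A Kingman coalescent genealogy for `n` haplotypes is simulated, the
#' mutation count drawn as Poisson(theta * L * T_total / 2), and each
#' mutation placed on a branch (probability proportional to length) at a
#' distinct site.
#'
#' @param theta Per-site population mutation rate (4 Ne mu).
#' @param n Number of haplotypes (>= 2).
#' @param L Number of sites.
#' @param seed Integer seed.
#' @param species Label for the sample.
#' @return A [polymorphism_sample()].
#' @export
simulate_polymorphism <- function(theta, n, L, seed = 1L,
                                  species = "species") {
  check_that(n >= 2, "need at least 2 haplotypes")
  check_that(is.finite(theta * L) && theta >= 0, "theta * L must be finite")
  set.seed(seed)
  active <- as.list(seq_len(n))
  blen <- rep(0, n)
  seg_sets <- list(); seg_lens <- numeric(0)
  k <- n
  while (k > 1) {
    t_k <- rexp(1, rate = k * (k - 1) / 2)
    blen <- blen + t_k
    pick <- sample.int(k, 2)
    seg_sets <- c(seg_sets, active[pick])
    seg_lens <- c(seg_lens, blen[pick])
    merged <- sort(c(active[[pick[1]]], active[[pick[2]]]))
    active <- c(active[-pick], list(merged))
    blen <- c(blen[-pick], 0)
    k <- k - 1
  }
  total_len <- sum(seg_lens)
  n_mut <- rpois(1, theta * L * total_len / 2)
  check_that(n_mut <= L, "more mutations than sites; increase L")
  anc <- sample(BASES, L, replace = TRUE)
  mat <- matrix(rep(anc, each = n), nrow = n)
  if (n_mut > 0) {
    sites <- sample.int(L, n_mut)
    branches <- sample.int(length(seg_lens), n_mut, replace = TRUE,
                           prob = seg_lens)
    for (m in seq_len(n_mut)) {
      j <- sites[m]
      derived <- sample(setdiff(BASES, anc[j]), 1)
      mat[seg_sets[[branches[m]]], j] <- derived
    }
  }
  polymorphism_sample(mat, species = species, locus_class = "intron")
}

#' Simulate correlated Brownian traits on a phylogeny
#'
#' Bivariate Brownian motion from a root state of (0, 0): each branch
#' adds a mean-zero bivariate normal increment with covariance
#' `branch length * R`, where R has diagonal `rates` and correlation
#' `rho_true`.
#'
#' @param tree An `ape::phylo` tree with branch lengths.
#' @param rho_true Correlation of the two Brownian rates, in [-1, 1].
#' @param rates Length-2 positive rate (variance) vector.
#' @param seed Integer seed.
#' @return Tibble `species`, `trait_x`, `trait_y`.
#' @export
simulate_phylo_traits <- function(tree, rho_true = 0.8, rates = c(1, 1),
                                  seed = 1L) {
  check_that(abs(rho_true) <= 1, "rho_true must be in [-1, 1]")
  check_that(all(rates >= 0), "rates must be non-negative")
  R <- diag(sqrt(rates)) %*% matrix(c(1, rho_true, rho_true, 1), 2) %*%
    diag(sqrt(rates))
  eig <- eigen(R, symmetric = TRUE)
  check_that(all(eig$values >= -1e-12), "rate matrix not positive semidefinite")
  A <- eig$vectors %*% diag(sqrt(pmax(eig$values, 0))) %*% t(eig$vectors)
  set.seed(seed)
  tree2 <- stats::reorder(tree, "postorder")
  n_tip <- length(tree2$tip.label)
  n_all <- n_tip + tree2$Nnode
  state <- matrix(NA_real_, n_all, 2)
  root <- n_tip + 1L
  state[root, ] <- c(0, 0)
  edge <- tree2$edge; bl <- tree2$edge.length
  for (i in rev(seq_len(nrow(edge)))) {    # preorder: root-ward first
    par <- edge[i, 1]; ch <- edge[i, 2]
    z <- A %*% rnorm(2)
    state[ch, ] <- state[par, ] + sqrt(bl[i]) * as.vector(z)
  }
  tibble(species = tree2$tip.label,
         trait_x = state[seq_len(n_tip), 1],
         trait_y = state[seq_len(n_tip), 2])
}

#' Simulate an exon pool with planted positional codon-usage gradients
#'
#' Builds a feature table of uniform-codon exons in which a chosen set of
#' sense codons follows a linear gradient in distance from the junctions:
#' half the planted codons increase away from the exon ends and half
#' decrease, in compensating pairs, so all unplanted codons keep exactly
#' constant expected proportions. `effect = 0` gives a null pool.
#'
#' @param n_exons Number of exons.
#' @param n_planted Number of codons carrying a gradient (even; 0 for a
#'   null pool).
#' @param effect Relative amplitude of the gradient (0..1 scale of the
#'   base proportion).
#' @param exon_codons Exon length in codons (default 70).
#' @param seed Integer seed.
#' @return List: `features` tibble usable by [positional_trend_test()] /
#'   [cis_motif_usage()], and `planted` (codon strings with gradients).
#' @export
simulate_trend_exon_pool <- function(n_exons, n_planted = 6, effect = 0.8,
                                     exon_codons = 70, seed = 1L) {
  check_that(n_planted %% 2 == 0, "n_planted must be even")
  check_that(effect >= 0 && effect <= 1, "effect must be in [0, 1]")
  set.seed(seed)
  planted <- if (n_planted > 0) sample(SENSE_CODONS, n_planted) else character(0)
  up <- planted[seq_len(n_planted / 2)]
  down <- setdiff(planted, up)
  base <- 1 / 61
  # gradient in distance from the 5' junction, capped at 34 codons
  z <- function(pos) (pmin(pos, 34) - 17.5) / 16.5
  cod_mat <- matrix(NA_integer_, n_exons, exon_codons)
  for (pos in seq_len(exon_codons)) {
    p <- rep(base, 61)
    names(p) <- SENSE_CODONS
    p[up] <- base * (1 + effect * z(pos))
    p[down] <- base * (1 - effect * z(pos))
    cod_mat[, pos] <- sample.int(61, n_exons, replace = TRUE, prob = p)
  }
  cod_chr <- matrix(SENSE_CODONS[cod_mat], n_exons, exon_codons)
  exon_cds <- do.call(paste0, as.data.frame(cod_chr))
  features <- tibble(
    gene_id = sprintf("g%06d", seq_len(n_exons)), exon_index = 2L,
    n_exons = 3L, length = 3L * exon_codons,
    intron5 = 100L, intron3 = 100L, downstream_introns = 1L,
    frame_offset = 0L, cds_from = 1L, cds_to = 3L * exon_codons,
    exon_cds = exon_cds,
    flank5_seq = substr(exon_cds, 1, 69),
    flank3_seq = substr(exon_cds, 3 * exon_codons - 68, 3 * exon_codons),
    core_seq = NA_character_, donor = NA_character_,
    acceptor = NA_character_
  )
  list(features = features, planted = planted, up = up, down = down)
}

#' Simulate paired second / penultimate exon density records
#'
#' Direct fixture for the intragene decoy tests: per gene, 5'-intron
#' sizes are log-normal and flank densities arise from a discrete
#' hexamer-placement mechanism (up to 11 disjoint codon-aligned slots of
#' 6 nt in a 69-nt flank), with expected density `base +
#' slope_log10_size * log10(intron size)` plus `class_effect` on the
#' second exon.
#'
#' @param n_genes Number of genes (records).
#' @param base Baseline expected density.
#' @param slope_log10_size Density change per log10 intron-size unit.
#' @param class_effect Added expected density on second exons (0 = null).
#' @param intron_meanlog,intron_sdlog Log-normal intron-size parameters.
#' @param seed Integer seed.
#' @return A [paired_density_records()]-shaped tibble.
#' @export
simulate_paired_density <- function(n_genes, base = 0.10,
                                    slope_log10_size = 0.02,
                                    class_effect = 0.05,
                                    intron_meanlog = log(500),
                                    intron_sdlog = 1, seed = 1L) {
  set.seed(seed)
  draw_density <- function(target) {
    p <- pmin(pmax(target * 69 / 66, 0), 1)
    6 * rbinom(length(p), 11, p) / 69
  }
  i2 <- pmax(60, round(rlnorm(n_genes, intron_meanlog, intron_sdlog)))
  ip <- pmax(60, round(rlnorm(n_genes, intron_meanlog, intron_sdlog)))
  d2 <- draw_density(base + slope_log10_size * log10(i2) + class_effect)
  dp <- draw_density(base + slope_log10_size * log10(ip))
  tibble(
    gene_id = sprintf("g%05d", seq_len(n_genes)),
    density_second = d2, density_penultimate = dp,
    intron5_second = i2, intron5_penultimate = ip
  )
}
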