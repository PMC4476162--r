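# Gene models: loading, validation/filtering, internal exon features and
# species-level genomic traits.
#
# Coordinates: GFF3 is 1-based inclusive on input; internally exons are
# stored 0-based half-open in coding (5'->3') order, with the conversion
# confined to the read/write boundary. One transcript per gene is kept
# (the longest CDS when several are annotated); coding-exon (CDS) segments
# define the exon/intron structure used throughout.

#' Load gene models from GFF3 + FASTA, apply validity filters
#'
#' Parses `gene`/`mRNA`/`CDS` features, keeps one transcript per gene
#' (longest CDS), reverse-complements minus-strand genes into coding
#' orientation, and retains only genes that start with ATG, end with a
#' stop codon (TAA/TAG/TGA), contain no internal stop and no ambiguous
#' nucleotide, have CDS length divisible by 3, and have at least one
#' intron. Rejections are logged with the first failing rule.
#'
#' @param gff_path Path to a GFF3 annotation.
#' @param fasta_path Path to the genome FASTA the annotation refers to.
#' @return A list with `genes` (tibble, one row per retained gene;
#'   list-columns `exons` with 0-based half-open genomic intervals in
#'   coding order, `intron_sizes`, `intron_first2`, `intron_last2`) and
#'   `rejected` (tibble `gene_id`, `reason`).
#' @export
load_and_filter_genes <- function(gff_path, fasta_path) {
  gff <- rtracklayer::import(gff_path)
  genome <- Biostrings::readDNAStringSet(fasta_path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  meta <- S4Vectors::mcols(gff)
  seqid <- as.character(GenomeInfoDb::seqnames(gff))
  check_that(all(unique(seqid) %in% names(genome)),
             "annotation references sequence IDs absent from the genome FASTA")

  type <- as.character(meta$type)
  parent <- vapply(as.list(meta$Parent), function(p)
    if (length(p)) p[[1]] else NA_character_, character(1))
  id <- as.character(meta$ID)

  mrna_rows <- which(type %in% c("mRNA", "transcript"))
  cds_rows <- which(type == "CDS")
  check_that(length(mrna_rows) > 0 && length(cds_rows) > 0,
             "GFF3 must contain mRNA and CDS features")
  mrna_gene <- setNames(parent[mrna_rows], id[mrna_rows])

  cds_tbl <- tibble(
    tx = parent[cds_rows],
    seqid = seqid[cds_rows],
    start1 = BiocGenerics::start(gff)[cds_rows],
    end1 = BiocGenerics::end(gff)[cds_rows],
    strand = as.character(BiocGenerics::strand(gff))[cds_rows]
  ) |>
    filter(!is.na(.data$tx))

  # one transcript per gene: longest summed CDS
  tx_len <- cds_tbl |>
    group_by(.data$tx) |>
    summarise(len = sum(.data$end1 - .data$start1 + 1L), .groups = "drop") |>
    mutate(gene = unname(mrna_gene[.data$tx])) |>
    filter(!is.na(.data$gene)) |>
    group_by(.data$gene) |>
    slice_max(.data$len, n = 1L, with_ties = FALSE) |>
    ungroup()

  retained <- list(); rejected <- list()
  for (r in seq_len(nrow(tx_len))) {
    gene_id <- tx_len$gene[r]
    seg <- cds_tbl |>
      filter(.data$tx == tx_len$tx[r]) |>
      arrange(.data$start1)
    gm <- build_gene_model(gene_id, seg, genome)
    if (is.character(gm)) {
      rejected[[length(rejected) + 1L]] <- tibble(gene_id = gene_id, reason = gm)
    } else {
      retained[[length(retained) + 1L]] <- gm
    }
  }
  list(
    genes = if (length(retained)) bind_rows(retained) else empty_gene_tbl(),
    rejected = if (length(rejected)) bind_rows(rejected) else
      tibble(gene_id = character(0), reason = character(0))
  )
}

empty_gene_tbl <- function() {
  tibble(gene_id = character(0), seqid = character(0), strand = character(0),
         n_exons = integer(0), cds = character(0), gene_span = integer(0),
         exons = list(), intron_sizes = list(),
         intron_first2 = list(), intron_last2 = list())
}

# assemble + validate one gene; returns a one-row tibble or a rejection
# reason string
build_gene_model <- function(gene_id, seg, genome) {
  strand <- seg$strand[1]
  seqid <- seg$seqid[1]
  chrom <- genome[[seqid]]
  # 0-based half-open, genomic order
  starts0 <- seg$start1 - 1L
  ends0 <- seg$end1
  if (nrow(seg) > 1L &&
      any(starts0[-1] < ends0[-nrow(seg)])) return("overlapping_exons")
  exon_seqs <- as.character(Biostrings::extractAt(
    chrom, IRanges::IRanges(start = seg$start1, end = seg$end1)))
  if (strand == "-") {
    exon_seqs <- rev(revcomp(exon_seqs))
    ord <- rev(seq_len(nrow(seg)))
  } else {
    ord <- seq_len(nrow(seg))
  }
  cds <- paste(exon_seqs, collapse = "")
  intron_sizes <- if (nrow(seg) > 1L) {
    gaps <- starts0[-1] - ends0[-nrow(seg)]
    if (strand == "-") rev(gaps) else gaps
  } else integer(0)

  if (nchar(cds) %% 3 != 0) return("cds_not_multiple_of_3")
  if (grepl("[^ACGT]", cds)) return("ambiguous_nucleotide")
  if (substr(cds, 1, 3) != "ATG") return("no_start_codon")
  cod <- codons_of(cds)
  if (!tail(cod, 1) %in% STOP_CODONS) return("no_stop_codon")
  if (any(head(cod, -1) %in% STOP_CODONS)) return("internal_stop")
  if (nrow(seg) < 2L) return("intronless")

  # intron boundary dinucleotides in coding orientation
  ifirst2 <- character(0); ilast2 <- character(0)
  if (nrow(seg) > 1L) {
    don1 <- ends0[-nrow(seg)] + 1L          # first intron base, genomic
    acc1 <- starts0[-1]                     # last intron base, genomic
    fwd_first2 <- as.character(Biostrings::extractAt(
      chrom, IRanges::IRanges(start = don1, width = 2L)))
    fwd_last2 <- as.character(Biostrings::extractAt(
      chrom, IRanges::IRanges(end = acc1, width = 2L)))
    if (strand == "-") {
      ifirst2 <- rev(revcomp(fwd_last2))
      ilast2 <- rev(revcomp(fwd_first2))
    } else {
      ifirst2 <- fwd_first2
      ilast2 <- fwd_last2
    }
  }

  tibble(
    gene_id = gene_id, seqid = seqid, strand = strand,
    n_exons = nrow(seg), cds = cds,
    gene_span = max(ends0) - min(starts0),
    exons = list(tibble(start = starts0[ord], end = ends0[ord])),
    intron_sizes = list(as.integer(intron_sizes)),
    intron_first2 = list(ifirst2), intron_last2 = list(ilast2)
  )
}

revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTacgt", "TGCAtgca", paste(rev(strsplit(s, "")[[1]]),
                                         collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

#' Extract internal-exon features from filtered gene models
#'
#' One row per internal exon (first and last exons excluded). Flank and
#' core sequences are populated only for exons longer than 138 bp
#' (2 x 69): `flank5_seq`/`flank3_seq` are the terminal 69 nt and
#' `core_seq` the central 69 nt (start offset `floor((length - 69)/2)`).
#' `donor` is the last 2 exon nt (upper case) + first 2 nt of the
#' downstream intron (lower case); `acceptor` the last 2 nt of the
#' upstream intron (lower) + first 2 exon nt (upper). `frame_offset` is
#' the codon phase at the exon start (0-2 nt carried over from the
#' previous exon); `cds_from`/`cds_to` locate the exon in the spliced CDS.
#'
#' @param genes Tibble of gene models from [load_and_filter_genes()] (or
#'   the simulator).
#' @return Tibble of exon features; empty (zero rows) for genes with only
#'   2 exons.
#' @export
extract_internal_exon_features <- function(genes) {
  check_that(nrow(genes) >= 0, "genes must be a tibble")
  rows <- purrr::pmap(
    list(genes$gene_id, genes$cds, genes$exons,
         genes$intron_sizes, genes$intron_first2, genes$intron_last2),
    function(gene_id, cds, exons, intron_sizes, ifirst2, ilast2) {
      n <- nrow(exons)
      if (n < 3L) return(NULL)
      lens <- as.integer(exons$end - exons$start)
      ends_cum <- cumsum(lens)
      starts_cum <- c(0L, head(ends_cum, -1L))
      idx <- 2:(n - 1L)
      len <- lens[idx]
      cds_from <- starts_cum[idx] + 1L
      cds_to <- ends_cum[idx]
      exon_cds <- substring(cds, cds_from, cds_to)
      has_flanks <- len > 138L
      flank5 <- ifelse(has_flanks, substring(exon_cds, 1L, 69L), NA_character_)
      flank3 <- ifelse(has_flanks,
                       substring(exon_cds, len - 68L, len), NA_character_)
      core_off <- floor((len - 69L) / 2)
      core <- ifelse(has_flanks,
                     substring(exon_cds, core_off + 1L, core_off + 69L),
                     NA_character_)
      donor <- paste0(toupper(substring(exon_cds, len - 1L, len)),
                      tolower(ifirst2[idx]))
      acceptor <- paste0(tolower(ilast2[idx - 1L]),
                         toupper(substring(exon_cds, 1L, 2L)))
      tibble(
        gene_id = gene_id, exon_index = idx, n_exons = n, length = len,
        intron5 = intron_sizes[idx - 1L], intron3 = intron_sizes[idx],
        downstream_introns = n - idx,
        frame_offset = starts_cum[idx] %% 3L,
        cds_from = cds_from, cds_to = cds_to, exon_cds = exon_cds,
        flank5_seq = flank5, flank3_seq = flank3, core_seq = core,
        donor = donor, acceptor = acceptor
      )
    })
  out <- bind_rows(purrr::compact(rows))
  if (nrow(out) == 0L) {
    out <- tibble(gene_id = character(0), exon_index = integer(0),
                  n_exons = integer(0), length = integer(0),
                  intron5 = integer(0), intron3 = integer(0),
                  downstream_introns = integer(0), frame_offset = integer(0),
                  cds_from = integer(0), cds_to = integer(0),
                  exon_cds = character(0), flank5_seq = character(0),
                  flank3_seq = character(0), core_seq = character(0),
                  donor = character(0), acceptor = character(0))
  }
  out
}

#' Species-level splice-related genomic traits
#'
#' `x_ratio` = mean over genes of CDS length / gene span (mean CDS/gene
#' length), `intron_density` = total introns per kb of mature CDS, and
#' `mean_intron_size` = mean of all intron sizes pooled over genes.
#'
#' @param genes Tibble of gene models.
#' @param species Species label for the output row.
#' @return One-row tibble: `species`, `n_genes`, `x_ratio`,
#'   `intron_density`, `mean_intron_size`.
#' @export
compute_genomic_traits <- function(genes, species = "species") {
  check_that(nrow(genes) >= 1, "at least one gene model is required")
  cds_len <- nchar(genes$cds)
  introns <- unlist(genes$intron_sizes)
  tibble(
    species = species,
    n_genes = nrow(genes),
    x_ratio = mean(cds_len / genes$gene_span),
    intron_density = length(introns) / (sum(cds_len) / 1000),
    mean_intron_size = mean(introns)
  )
}

#' Write gene models back to GFF3 + FASTA
#'
#' Inverse of [load_and_filter_genes()] up to formatting: re-loading the
#' written pair reproduces identical CDS sequences and intron sizes.
#'
#' @param genes Tibble of gene models.
#' @param genome Named character vector or `DNAStringSet` of scaffold
#'   sequences covering the models.
#' @param gff_path,fasta_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_gene_models <- function(genes, genome, gff_path, fasta_path) {
  if (!methods::is(genome, "DNAStringSet")) {
    genome <- Biostrings::DNAStringSet(unlist(genome))
  }
  recs <- purrr::pmap(
    list(genes$gene_id, genes$seqid, genes$strand, genes$exons),
    function(gene_id, seqid, strand, exons) {
      # back to genomic order / 1-based inclusive
      ex <- exons |> arrange(.data$start)
      tx_id <- paste0(gene_id, ".t1")
      phases <- cds_phases(ex, strand)
      tibble(
        seqid = seqid,
        type = c("gene", "mRNA", rep("CDS", nrow(ex))),
        start1 = c(min(ex$start) + 1L, min(ex$start) + 1L, ex$start + 1L),
        end1 = c(max(ex$end), max(ex$end), ex$end),
        strand = strand,
        phase = c(NA_integer_, NA_integer_, phases),
        ID = c(gene_id, tx_id, paste0(tx_id, ".cds", seq_len(nrow(ex)))),
        Parent = c(NA_character_, gene_id, rep(tx_id, nrow(ex)))
      )
    })
  tab <- bind_rows(recs)
  gr <- GenomicRanges::GRanges(
    seqnames = tab$seqid,
    ranges = IRanges::IRanges(start = tab$start1, end = tab$end1),
    strand = tab$strand
  )
  S4Vectors::mcols(gr)$type <- tab$type
  S4Vectors::mcols(gr)$ID <- tab$ID
  S4Vectors::mcols(gr)$Parent <- ifelse(is.na(tab$Parent), "", tab$Parent)
  S4Vectors::mcols(gr)$phase <- tab$phase
  rtracklayer::export(gr, gff_path, format = "gff3")
  Biostrings::writeXStringSet(genome, fasta_path)
  invisible(c(gff = gff_path, fasta = fasta_path))
}

# GFF3 phase column for CDS segments (genomic order in `ex`)
cds_phases <- function(ex, strand) {
  lens <- ex$end - ex$start
  if (strand == "-") lens <- rev(lens)
  carried <- c(0L, cumsum(lens) %% 3L)[seq_along(lens)]
  phase <- (3L - carried) %% 3L
  if (strand == "-") phase <- rev(phase)
  as.integer(phase)
}
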