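test_that("loader retains valid genes and logs first failing rule", {
  td <- withr::local_tempdir()
  inv <- simulate_invalid_genes(seed = 11L)
  write_gene_models(inv$genes, inv$genome,
                    file.path(td, "inv.gff3"), file.path(td, "inv.fa"))
  loaded <- load_and_filter_genes(file.path(td, "inv.gff3"),
                                  file.path(td, "inv.fa"))
  expect_equal(nrow(loaded$genes), 1L)
  reasons <- setNames(loaded$rejected$reason, loaded$rejected$gene_id)
  expect_equal(unname(reasons["gene0002"]), "internal_stop")
  expect_equal(unname(reasons["gene0003"]), "no_start_codon")
  expect_equal(unname(reasons["gene0004"]), "no_stop_codon")
  expect_equal(unname(reasons["gene0005"]), "ambiguous_nucleotide")
  expect_equal(unname(reasons["gene0006"]), "intronless")
  expect_equal(unname(reasons["gene0007"]), "cds_not_multiple_of_3")
})

test_that("GFF3 + FASTA round-trip reproduces CDS and intron sizes", {
  td <- withr::local_tempdir()
  fx <- small_species()
  write_gene_models(fx$sim$genes, fx$sim$genome,
                    file.path(td, "rt.gff3"), file.path(td, "rt.fa"))
  loaded <- load_and_filter_genes(file.path(td, "rt.gff3"),
                                  file.path(td, "rt.fa"))
  expect_equal(nrow(loaded$rejected), 0L)
  ord <- match(fx$sim$genes$gene_id, loaded$genes$gene_id)
  expect_identical(loaded$genes$cds[ord], fx$sim$genes$cds)
  expect_identical(lapply(loaded$genes$intron_sizes[ord], as.integer),
                   lapply(fx$sim$genes$intron_sizes, as.integer))
  # exon + intron lengths account for the gene span
  spans <- vapply(seq_len(nrow(loaded$genes)), function(i) {
    ex <- loaded$genes$exons[[i]]
    sum(ex$end - ex$start) + sum(loaded$genes$intron_sizes[[i]])
  }, numeric(1))
  expect_equal(spans, as.numeric(loaded$genes$gene_span))
})

test_that("feature extraction excludes terminal exons and respects 138 bp rule", {
  fx <- small_species()
  feats <- fx$features
  expect_true(all(feats$exon_index >= 2 & feats$exon_index < feats$n_exons))
  # flank/core geometry
  with_fl <- feats[!is.na(feats$flank5_seq), ]
  expect_true(all(with_fl$length > 138))
  expect_true(all(nchar(with_fl$flank5_seq) == 69))
  expect_true(all(nchar(with_fl$core_seq) == 69))
  # donor/acceptor case-coding convention
  expect_true(all(grepl("^[ACGT]{2}[acgt]{2}$", feats$donor)))
  expect_true(all(grepl("^[acgt]{2}[ACGT]{2}$", feats$acceptor)))
  # a 2-exon gene yields no internal exons, not an error
  two_exon <- fx$sim$genes[lengths(fx$sim$genes$intron_sizes) == 1, ]
  if (nrow(two_exon) > 0) {
    expect_equal(nrow(extract_internal_exon_features(two_exon)), 0L)
  }
  # 138 bp boundary: feature present but flank absent
  g <- fx$sim$genes[1, ]
  ex <- g$exons[[1]]
  expect_equal(nrow(extract_internal_exon_features(g)), g$n_exons - 2L)
})

test_that("donor string is AGgt for an exon ending AG before a gt intron", {
  fx <- small_species()
  feats <- fx$features
  genes <- fx$sim$genes
  one <- feats[feats$donor == "AGgt", ][1, ]
  expect_false(is.na(one$gene_id))
  cds <- genes$cds[genes$gene_id == one$gene_id]
  expect_equal(substr(cds, one$cds_to - 1, one$cds_to), "AG")
})

test_that("feature extraction is strand-symmetric", {
  td <- withr::local_tempdir()
  fx <- small_species()
  genes <- fx$sim$genes
  plus <- genes[genes$strand == "+", ]
  minus <- genes[genes$strand == "-", ]
  expect_gt(nrow(plus), 0)
  expect_gt(nrow(minus), 0)
  # same generator distributions, opposite strands: both reload cleanly
  # and features depend only on coding-strand content
  f_all <- extract_internal_exon_features(genes)
  write_gene_models(genes, fx$sim$genome,
                    file.path(td, "s.gff3"), file.path(td, "s.fa"))
  loaded <- load_and_filter_genes(file.path(td, "s.gff3"),
                                  file.path(td, "s.fa"))
  f_re <- extract_internal_exon_features(
    loaded$genes[match(genes$gene_id, loaded$genes$gene_id), ])
  expect_identical(as.data.frame(f_all), as.data.frame(f_re))
})

test_that("genomic traits follow their definitions", {
  g <- tibble::tibble(
    gene_id = "g1", seqid = "s", strand = "+", n_exons = 4L,
    cds = strrep("A", 900), gene_span = 3000L,
    exons = list(tibble::tibble(start = 0L, end = 900L)),
    intron_sizes = list(c(100L, 200L, 300L)),
    intron_first2 = list(rep("GT", 3)), intron_last2 = list(rep("AG", 3))
  )
  tr <- compute_genomic_traits(g)
  expect_equal(tr$x_ratio, 0.3)
  expect_equal(tr$intron_density, 3 / 0.9)
  expect_equal(tr$mean_intron_size, 200)
  # N = 2.0 introns per kb for 3 introns over 1500 bp
  g2 <- g
  g2$cds <- strrep("A", 1500)
  expect_equal(compute_genomic_traits(g2)$intron_density, 2.0)
  expect_error(compute_genomic_traits(g[0, ]), "at least one")
})
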