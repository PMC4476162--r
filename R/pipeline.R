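# End-to-end pipeline: stage orchestration with config, caching and a
# reproducible run manifest.

#' Run the full analysis pipeline from a config
#'
#' Stages run in dependency order: `simulate` (when the config has a
#' `simulate` block rather than input paths) -> `traits` -> `trends` ->
#' `constraint` -> `intragene` -> `popgen` -> `phylocorr`. Each stage
#' records its config+input hash and output files in `manifest.json`;
#' on re-runs, stages whose hash matches and whose outputs exist are
#' skipped ("cached"). Seeds for every stochastic stage derive from the
#' top-level `seed`, so a manifest fully reproduces a run.
#'
#' @param config Path to a YAML config, or an equivalent named list.
#'   Recognised top-level keys: `seed`, `simulate` (a [sim_config()]
#'   override list) or `input` (`gff`, `fasta`), `ese` (hexamer file;
#'   default the bundled synthetic set), and per-stage option blocks
#'   `trends`, `constraint`, `intragene`, `popgen`, `phylocorr`.
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress per-stage log lines.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  check_that(is.list(config), "config must be a list or a YAML path")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  manifest_path <- file.path(out_dir, "manifest.json")
  manifest <- if (file.exists(manifest_path)) {
    jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  } else list(stages = list())
  manifest$config_hash <- digest::digest(config)
  manifest$tool_version <-
    as.character(utils::packageVersion("splicesel"))
  manifest$seed <- seed

  log_line <- function(...) if (!quiet) message("[splicesel] ", ...)
  t0 <- Sys.time()
  state <- new.env(parent = emptyenv())

  stage <- function(name, outputs, deps, run) {
    hash <- digest::digest(list(config[[name]], config$seed, deps))
    paths <- file.path(out_dir, outputs)
    prev <- manifest$stages[[name]]
    if (!is.null(prev) && identical(prev$hash, hash) &&
        all(file.exists(paths))) {
      log_line("stage ", name, ": cached")
      manifest$stages[[name]]$status <<- "cached"
      return(invisible(NULL))
    }
    t1 <- Sys.time()
    res <- tryCatch(run(paths), error = function(e) e)
    if (inherits(res, "error")) {
      manifest$stages[[name]] <<- list(hash = hash, status = "failed",
                                       error = conditionMessage(res))
      write_manifest(manifest, manifest_path)
      abort(paste0("stage ", name, " failed: ", conditionMessage(res)))
    }
    manifest$stages[[name]] <<- list(
      hash = hash, status = "ok", outputs = outputs,
      checksums = unname(tools::md5sum(paths)),
      wall_seconds = as.numeric(difftime(Sys.time(), t1, units = "secs")),
      records = res
    )
    log_line("stage ", name, ": ok (",
             round(as.numeric(difftime(Sys.time(), t1, units = "secs")), 2),
             " s)")
  }

  # --- simulate ---------------------------------------------------------
  simulated <- is.null(config$input)
  gff_path <- fasta_path <- NULL
  if (simulated) {
    stage("simulate",
          c("annotation.gff3", "genome.fasta", "orthologs.tsv",
            "tree.nwk", "traits_true.tsv"),
          deps = NULL, run = function(paths) {
      sim_over <- config$simulate %||% list()
      cfg <- do.call(sim_config, c(list(seed = seed), sim_over))
      sim <- simulate_species_genes(cfg)
      write_gene_models(sim$genes, sim$genome, paths[1], paths[2])
      orth <- simulate_orthologs(sim$genes, cfg$ese_set,
                                 d_core = cfg$d_core,
                                 ese_constraint = cfg$ese_constraint,
                                 seed = seed + 1L)
      utils::write.table(orth, paths[3], sep = "\t", row.names = FALSE,
                         quote = FALSE)
      set.seed(seed + 2L)
      tree <- ape::rtree(cfg$n_species)
      ape::write.tree(tree, paths[4])
      traits <- simulate_phylo_traits(tree, rho_true = cfg$rho_true,
                                      rates = cfg$bm_rates,
                                      seed = seed + 3L)
      utils::write.table(traits, paths[5], sep = "\t", row.names = FALSE,
                         quote = FALSE)
      nrow(sim$genes)
    })
    gff_path <- file.path(out_dir, "annotation.gff3")
    fasta_path <- file.path(out_dir, "genome.fasta")
  } else {
    gff_path <- config$input$gff
    fasta_path <- config$input$fasta
    check_that(file.exists(gff_path) && file.exists(fasta_path),
               "input gff/fasta not found")
  }
  motifs <- if (!is.null(config$ese)) read_hexamer_set(config$ese)
            else default_synthetic_ese()

  input_hash <- unname(tools::md5sum(c(gff_path, fasta_path)))

  # --- traits -----------------------------------------------------------
  stage("traits", c("features.tsv", "genomic_traits.tsv", "rejected.tsv"),
        deps = input_hash, run = function(paths) {
    loaded <- load_and_filter_genes(gff_path, fasta_path)
    state$genes <- loaded$genes
    feats <- extract_internal_exon_features(loaded$genes)
    state$features <- feats
    utils::write.table(
      feats |> select("gene_id", "exon_index", "length", "intron5",
                      "intron3", "donor", "acceptor"),
      paths[1], sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(compute_genomic_traits(loaded$genes),
                       paths[2], sep = "\t", row.names = FALSE,
                       quote = FALSE)
    utils::write.table(loaded$rejected, paths[3], sep = "\t",
                       row.names = FALSE, quote = FALSE)
    nrow(feats)
  })
  if (is.null(state$genes)) {
    loaded <- load_and_filter_genes(gff_path, fasta_path)
    state$genes <- loaded$genes
    state$features <- extract_internal_exon_features(loaded$genes)
  }

  # --- trends -----------------------------------------------------------
  stage("trends", c("cis_motif_usage.tsv", "splice_site_usage.tsv"),
        deps = input_hash, run = function(paths) {
    opt <- config$trends %||% list()
    usage <- cis_motif_usage(
      state$features,
      subsample_size = opt$subsample_size %||% 5000,
      repetitions = opt$repetitions %||% 100,
      seed = seed + 10L)
    utils::write.table(usage, paths[1], sep = "\t", row.names = FALSE,
                       quote = FALSE)
    utils::write.table(splice_site_usage(state$features), paths[2],
                       sep = "\t", row.names = FALSE, quote = FALSE)
    1L
  })

  # --- constraint -------------------------------------------------------
  if (simulated) {
    stage("constraint", c("flank_bins.tsv"), deps = input_hash,
          run = function(paths) {
      orth <- utils::read.table(file.path(out_dir, "orthologs.tsv"),
                                header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE) |> as_tibble()
      opt <- config$constraint %||% list()
      bins <- binned_flank_constraint(
        state$features, orth, motifs,
        n_bins = opt$n_bins %||% 20,
        pseudo_reps = opt$pseudo_reps %||% 100,
        seed = seed + 20L)
      utils::write.table(bins, paths[1], sep = "\t", row.names = FALSE,
                         quote = FALSE)
      nrow(bins)
    })
  }

  # --- intragene --------------------------------------------------------
  stage("intragene", c("intragene.json"), deps = input_hash,
        run = function(paths) {
    opt <- config$intragene %||% list()
    recs <- paired_density_records(state$features, motifs)
    res <- list(
      second_vs_penultimate =
        as.list(second_vs_penultimate_test(records = recs)),
      splice_site_intron_size =
        as.list(splice_site_intron_size_test(state$features))
    )
    if (nrow(recs) >= 30) {
      res$loess_residual <-
        as.list(loess_residual_test(recs, span = opt$span %||% 0.75))
    }
    jsonlite::write_json(res, paths[1], auto_unbox = TRUE, digits = NA)
    nrow(recs)
  })

  # --- popgen -----------------------------------------------------------
  stage("popgen", c("popgen.tsv"), deps = NULL, run = function(paths) {
    opt <- config$popgen %||% list()
    samp <- simulate_polymorphism(
      theta = opt$theta %||% 0.005, n = opt$n %||% 10L,
      L = opt$L %||% 1e5, seed = seed + 30L)
    est <- theta_estimates(samp)
    utils::write.table(est, paths[1], sep = "\t", row.names = FALSE,
                       quote = FALSE)
    1L
  })

  # --- phylocorr --------------------------------------------------------
  if (simulated) {
    stage("phylocorr", c("phylocorr.tsv"), deps = NULL,
          run = function(paths) {
      tree <- ape::read.tree(file.path(out_dir, "tree.nwk"))
      traits <- utils::read.table(file.path(out_dir, "traits_true.tsv"),
                                  header = TRUE, sep = "\t",
                                  stringsAsFactors = FALSE) |> as_tibble()
      res <- phylo_trait_correlations(tree, traits,
                                      pairs = list(c("trait_x", "trait_y")),
                                      mode = "ml")
      utils::write.table(res, paths[1], sep = "\t", row.names = FALSE,
                         quote = FALSE)
      nrow(res)
    })
  }

  manifest$wall_seconds <-
    as.numeric(difftime(Sys.time(), t0, units = "secs"))
  write_manifest(manifest, manifest_path)
  invisible(manifest)
}

write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
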