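#' Build a pipeline run configuration
#'
#' Collects every input path and tunable of the end-to-end analysis. Each
#' threshold surfaces here with its conventional default: 100-kb windows,
#' the VarScan-style qualification minima, 5-kb regulatory flanks, the
#' 1 SNP/kb desert threshold and average-linkage clustering.
#'
#' @param reference Path to the reference FASTA.
#' @param gff3 Path to the gene-model GFF3.
#' @param vcfs Named character vector: sample name -> VCF path.
#' @param out_dir Output directory (created if needed).
#' @param window_size Window width in bp (>= 1000).
#' @param thresholds A [filter_thresholds()].
#' @param flank_bp Regulatory flank in bp.
#' @param desert_threshold_per_kb SNP desert threshold.
#' @param linkage Clustering linkage.
#' @param log Emit progress messages to stderr.
#' @return A `run_config` list.
#' @export
run_config <- function(reference, gff3, vcfs, out_dir,
                       window_size = 100000L,
                       thresholds = filter_thresholds(),
                       flank_bp = 5000L,
                       desert_threshold_per_kb = 1.0,
                       linkage = "average",
                       log = TRUE) {
  stop_if_not(window_size >= 1000, "window_size must be >= 1000")
  if (is.null(names(vcfs)) || any(!nzchar(names(vcfs)))) {
    names(vcfs) <- sub("\\.vcf(\\.gz)?$", "", basename(vcfs))
  }
  structure(as.list(environment()), class = "run_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Flat keys mirroring the [run_config()] arguments; `vcfs` is a named map.
#' Threshold keys (`min_mapq`, `min_depth`, `min_base_qual`, `min_vaf_snp`,
#' `min_vaf_indel`) may be given at the top level.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  th_keys <- c("min_mapq", "min_depth", "min_base_qual", "min_vaf_snp",
               "min_vaf_indel")
  th <- do.call(filter_thresholds, y[intersect(th_keys, names(y))])
  run_config(
    reference = y$reference, gff3 = y$gff3,
    vcfs = unlist(y$vcfs), out_dir = y$out_dir,
    window_size = y$window_size %||% 100000L,
    thresholds = th,
    flank_bp = y$flank_bp %||% 5000L,
    desert_threshold_per_kb = y$desert_threshold_per_kb %||% 1.0,
    linkage = y$linkage %||% "average",
    log = y$log %||% TRUE
  )
}

#' Run the full variant-landscape pipeline
#'
#' Per sample: read and filter the VCF, write the filter report, SNP and
#' InDel density tracks (TSV + BEDGRAPH), desert BED, base-change spectrum
#' row, effect summary and outlier-gene table. Across samples: shared-desert
#' BED, Pearson correlation matrix of windowed SNP densities, and the
#' Newick sample tree. A `manifest.json` records the configuration and
#' per-stage record counts.
#'
#' @param config A `run_config` (or path to a YAML config).
#' @return Invisibly, a result bundle: list with `samples` (per-sample
#'   results), `shared_deserts`, `correlation`, `clustering`, `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  cfg <- config
  say <- function(...) if (isTRUE(cfg$log)) message(sprintf(...))
  for (p in c(cfg$reference, cfg$gff3, cfg$vcfs)) {
    stop_if_not(file.exists(p), paste0("missing input: ", p))
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  say("loading reference %s", cfg$reference)
  genome <- load_genome(cfg$reference)
  models <- load_gene_models(cfg$gff3, genome)
  index <- build_gene_index(models, genome, flank_bp = cfg$flank_bp)

  samples <- names(cfg$vcfs)
  per_sample <- list()
  snp_tracks <- list()
  manifest_counts <- list()

  for (s in samples) {
    t0 <- Sys.time()
    say("sample %s: reading %s", s, cfg$vcfs[[s]])
    raw <- read_vcf(cfg$vcfs[[s]], s)
    kept <- filter_variants(raw, cfg$thresholds)
    rep <- filter_report(kept)
    jsonlite::write_json(rep, file.path(cfg$out_dir,
                                        paste0(s, ".filter_report.json")),
                         auto_unbox = TRUE, pretty = TRUE)

    snp_track <- bin_counts(kept, genome, cfg$window_size, "SNP")
    indel_track <- bin_counts(kept, genome, cfg$window_size, "INDEL")
    write_track(snp_track, file.path(cfg$out_dir,
                                     paste0(s, ".snp_density.tsv")))
    write_track(snp_track,
                file.path(cfg$out_dir, paste0(s, ".snp_density.bedgraph")),
                format = "bedgraph")
    write_track(indel_track, file.path(cfg$out_dir,
                                       paste0(s, ".indel_density.tsv")))
    snp_tracks[[s]] <- snp_track

    des <- find_deserts(snp_track, cfg$desert_threshold_per_kb) %>%
      annotate_desert_genes(models$genes)
    write_deserts_bed(des, file.path(cfg$out_dir,
                                     paste0(s, ".deserts.bed")))

    spec <- spectrum(kept)
    write_spectrum(spec, file.path(cfg$out_dir, paste0(s, ".spectrum.tsv")))
    readr::write_tsv(indel_length_summary(kept),
                     file.path(cfg$out_dir, paste0(s, ".indel_lengths.tsv")))

    say("sample %s: annotating %d variants", s, nrow(kept))
    eff <- annotate_variants(kept, index, genome)
    snp_eff <- eff %>% filter(.data$vtype == "SNP")
    write_effect_summary(summarize_effects(snp_eff),
                         file.path(cfg$out_dir,
                                   paste0(s, ".effect_summary.tsv")))
    readr::write_tsv(eff, file.path(cfg$out_dir, paste0(s, ".effects.tsv")))

    dens <- gene_ns_density(snp_eff, models$genes)
    outl <- if (nrow(dens) >= 4) find_outlier_genes(dens) else dens[0, ]
    write_outlier_genes(outl, file.path(cfg$out_dir,
                                        paste0(s, ".outlier_genes.tsv")))

    per_sample[[s]] <- list(kept = kept, report = rep,
                            snp_track = snp_track, deserts = des,
                            spectrum = spec, effects = eff,
                            outliers = outl)
    manifest_counts[[s]] <- list(
      n_input = rep$n_input, n_kept = rep$n_kept,
      n_rejected = rep$n_rejected, n_effect_records = nrow(eff),
      n_deserts = nrow(des), n_outlier_genes = nrow(outl))
    say("sample %s done in %.1fs", s,
        as.numeric(difftime(Sys.time(), t0, units = "secs")))
  }

  shared <- NULL
  corr <- NULL
  clust <- NULL
  if (length(samples) >= 2) {
    say("cross-sample stages")
    shared <- shared_deserts(purrr::map(per_sample, "deserts")) %>%
      annotate_desert_genes(models$genes)
    write_deserts_bed(shared, file.path(cfg$out_dir, "shared_deserts.bed"))
    # samples whose track has no variance (e.g. empty call sets) cannot be
    # correlated; drop them from the cross-sample stage
    flat <- purrr::map_lgl(snp_tracks, ~ stats::sd(.x$count) == 0)
    if (any(flat)) {
      warn(paste0("excluded from correlation (flat SNP track): ",
                  paste(names(snp_tracks)[flat], collapse = ", ")))
      snp_tracks <- snp_tracks[!flat]
    }
  }
  if (length(snp_tracks) >= 2) {
    m <- density_matrix(snp_tracks)
    corr <- pearson_matrix(m)
    write_correlation(corr, file.path(cfg$out_dir, "correlation.tsv"))
    per_chr <- pearson_matrix(m, scope = "per_chromosome")
    for (ch in names(per_chr)) {
      write_correlation(per_chr[[ch]],
                        file.path(cfg$out_dir,
                                  paste0("correlation.", ch, ".tsv")))
    }
    clust <- cluster_samples(corr, linkage = cfg$linkage)
    write_newick(clust, file.path(cfg$out_dir, "samples.nwk"))
  }

  manifest <- list(
    package = "varscape",
    version = as.character(utils::packageVersion("varscape")),
    config = list(
      reference = cfg$reference, gff3 = cfg$gff3,
      vcfs = as.list(cfg$vcfs), window_size = cfg$window_size,
      thresholds = unclass(cfg$thresholds), flank_bp = cfg$flank_bp,
      desert_threshold_per_kb = cfg$desert_threshold_per_kb,
      linkage = cfg$linkage),
    samples = manifest_counts,
    n_shared_deserts = if (is.null(shared)) NA else nrow(shared)
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  say("pipeline complete: %s", cfg$out_dir)
  invisible(list(samples = per_sample, shared_deserts = shared,
                 correlation = corr, clustering = clust,
                 manifest = manifest, models = models, genome = genome))
}
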