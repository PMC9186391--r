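#' Default pipeline configuration
#'
#' Every analysis constant is a configuration default rather than a value
#' hard-coded in stage logic: the FPKM > 1 detection threshold, the
#' log2 fold-change > 1 nuclear-enrichment threshold, and the 10-read
#' junction coverage rule, plus the mode switches (genotype scope of the
#' detection filter, exon-intron aggregation, GC definition, metagene
#' binning).
#'
#' @return Nested list of paths, thresholds, modes, simulation overrides,
#'   and seed.
#' @export
default_config <- function() {
  list(
    paths = list(genome = NULL, gtf = NULL, design = NULL, junctions = NULL,
                 peaks = NULL, clip_reads = NULL, input_reads = NULL),
    thresholds = list(fpkm_min = 1, enrich_log2fc = 1, se_min_reads = 10),
    modes = list(filter_scope = "both", ei_mode = "average",
                 coverage_mode = "junction", gc = "exonic",
                 metagene_bins = 100, metagene_pseudocount = 1,
                 metagene_coords = "exonic"),
    sim = list(),
    seed = 1
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    base[[nm]] <- if (is.list(base[[nm]]) && is.list(override[[nm]]))
      merge_config(base[[nm]], override[[nm]]) else override[[nm]]
  }
  base
}

load_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stopf("config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  merge_config(default_config(), config %||% list())
}

pipeline_stages <- c("all", "simulate", "features", "quantify", "splice",
                     "localize", "correlate", "clip")

check_path <- function(p, what) {
  if (is.null(p)) stopf("config paths$%s is not set", what)
  if (!file.exists(p)) stopf("missing input for %s: %s", what, p)
  p
}

#' Run the analysis pipeline
#'
#' Orchestrates the stages behind one entry point. `"simulate"` writes a
#' synthetic dataset under `out_dir/sim` and points the remaining stages at
#' it; the other stages read the configured input paths and write their
#' module's tables under `out_dir`, plus a `manifest.json` recording the
#' configuration, seed, package version, input checksums, and output row
#' counts. `"all"` runs simulate followed by every analysis stage.
#'
#' @param stage one of `"all"`, `"simulate"`, `"features"`, `"quantify"`,
#'   `"splice"`, `"localize"`, `"correlate"`, `"clip"`.
#' @param config configuration list or YAML path (see [default_config()]);
#'   values given override the defaults.
#' @param out_dir output directory.
#' @param seed integer seed overriding the config's.
#' @return Invisible list of the stage results (tables as data.frames).
#' @export
run_pipeline <- function(stage = "all", config = list(), out_dir, seed = NULL) {
  if (!stage %in% pipeline_stages)
    stopf("unknown subcommand '%s' (expected one of: %s)", stage,
          paste(pipeline_stages, collapse = ", "))
  cfg <- load_config(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- list()
  log_msg <- function(...) message(sprintf(...))

  if (stage %in% c("all", "simulate")) {
    sim_dir <- file.path(out_dir, "sim")
    scfg <- do.call(sim_config, cfg$sim)
    sim <- simulate_dataset(scfg, seed = cfg$seed, dir = sim_dir)
    log_msg("simulate: %d genes, %d samples -> %s", nrow(sim$truth),
            nrow(sim$design), sim_dir)
    res$sim <- sim
    if (stage == "all") {
      cfg$paths <- list(genome = file.path(sim_dir, "genome.fa"),
                        gtf = file.path(sim_dir, "annotation.gtf"),
                        design = file.path(sim_dir, "design.tsv"),
                        junctions = file.path(sim_dir, "junctions.tsv"),
                        peaks = file.path(sim_dir, "peaks.bed"),
                        clip_reads = file.path(sim_dir, "clip_reads.bed"),
                        input_reads = file.path(sim_dir, "input_reads.bed"))
    }
  }

  need_models <- stage %in% c("all", "features", "correlate", "clip")
  if (need_models) {
    txm <- read_gtf(check_path(cfg$paths$gtf, "gtf"))
    txm <- select_longest_isoform(txm)
    genome <- normalize_genome(check_path(cfg$paths$genome, "genome"))
  }

  if (stage %in% c("all", "splice", "features", "correlate")) {
    jx <- read_tsv(check_path(cfg$paths$junctions, "junctions"))
    splicing <- summarize_se(jx, min_reads = cfg$thresholds$se_min_reads,
                             ei_mode = cfg$modes$ei_mode,
                             coverage_mode = cfg$modes$coverage_mode)
    log_msg("splice: %d/%d transcripts with a covered intron",
            sum(splicing$n_covered > 0), nrow(splicing))
    write_tsv(splicing, file.path(out_dir, "splicing.tsv"))
    res$splicing <- splicing
  }

  if (stage %in% c("all", "features", "correlate")) {
    features <- compute_features(txm, genome, splicing = res$splicing)
    write_tsv(features, file.path(out_dir, "features.tsv"))
    log_msg("features: %d genes", nrow(features))
    res$features <- features
  }

  if (stage %in% c("all", "quantify", "localize", "correlate", "clip")) {
    design <- read_design(check_path(cfg$paths$design, "design"))
    counts <- read_counts(design)
    lengths <- if (need_models) {
      stats::setNames(txm$transcripts$tx_length, txm$transcripts$gene_id)
    } else {
      txm2 <- select_longest_isoform(read_gtf(check_path(cfg$paths$gtf, "gtf")))
      stats::setNames(txm2$transcripts$tx_length, txm2$transcripts$gene_id)
    }
    fs <- build_fpkm(counts, design, lengths)
    write_tsv(data.frame(gene_id = rownames(fs$mean), fs$mean,
                         check.names = FALSE),
              file.path(out_dir, "fpkm_mean.tsv"))
    res$fpkm <- fs
  }

  if (stage %in% c("all", "localize", "correlate", "clip")) {
    retained <- detection_filter(res$fpkm, threshold = cfg$thresholds$fpkm_min,
                                 scope = cfg$modes$filter_scope)
    rec <- localization(res$fpkm, retained)
    rec <- classify_and_rank(rec, lfc = cfg$thresholds$enrich_log2fc)
    log_msg("localize: %d/%d genes retained, %d nuclear-enriched",
            length(retained), nrow(rec), sum(rec$nuclear_enriched, na.rm = TRUE))
    write_tsv(rec, file.path(out_dir, "localization.tsv"))
    res$records <- rec
  }

  if (stage %in% c("all", "correlate")) {
    rep_ <- correlate_features(res$records, res$features, gc = cfg$modes$gc)
    write_tsv(rep_$correlations, file.path(out_dir, "correlations.tsv"))
    write_tsv(rep_$regression, file.path(out_dir, "regression.tsv"))
    write_tsv(rep_$gc_vs_expression, file.path(out_dir, "gc_expression_cor.tsv"))
    comp <- biotype_composition(res$records, res$features)
    write_tsv(comp, file.path(out_dir, "biotype_composition.tsv"))
    res$correlation <- rep_
    res$biotypes <- comp
  }

  if (stage %in% c("all", "clip")) {
    peaks <- read_bed(check_path(cfg$paths$peaks, "peaks"))
    clip_reads <- read_bed(check_path(cfg$paths$clip_reads, "clip_reads"))
    input_reads <- read_bed(check_path(cfg$paths$input_reads, "input_reads"))
    ann <- assign_peaks(peaks, txm, genome = genome)
    write_tsv(ann$distribution, file.path(out_dir, "peak_categories.tsv"))
    pk <- ann$peaks
    write_tsv(data.frame(chrom = as.character(GenomicRanges::seqnames(pk)),
                         start = GenomicRanges::start(pk),
                         end = GenomicRanges::end(pk),
                         strand = as.character(GenomicRanges::strand(pk)),
                         gene_id = S4Vectors::mcols(pk)$gene_id,
                         category = S4Vectors::mcols(pk)$category,
                         gc = S4Vectors::mcols(pk)$gc),
              file.path(out_dir, "peak_annotation.tsv"))
    target_ids <- unique(stats::na.omit(S4Vectors::mcols(pk)$gene_id))
    mg <- metagene_profile(clip_reads, input_reads, txm,
                           target_ids = target_ids,
                           bins = cfg$modes$metagene_bins,
                           pseudocount = cfg$modes$metagene_pseudocount,
                           coords = cfg$modes$metagene_coords)
    write_tsv(mg$profile, file.path(out_dir, "metagene.tsv"))
    ks <- target_shift_test(res$records, target_ids)
    write_tsv(ks$cdf, file.path(out_dir, "ks_cdf.tsv"))
    write_tsv(data.frame(D = ks$D, p = ks$p, n_target = ks$n_target,
                         n_nontarget = ks$n_nontarget),
              file.path(out_dir, "ks_test.tsv"))
    gcres <- peak_gc_enrichment(pk, txm, genome)
    write_tsv(gcres$gc, file.path(out_dir, "gc_groups.tsv"))
    write_tsv(gcres$tests, file.path(out_dir, "gc_tests.tsv"))
    write_tsv(gcres$summary, file.path(out_dir, "gc_summary.tsv"))
    log_msg("clip: %d peaks, %d targets, KS D = %.3f", length(pk),
            length(target_ids), ks$D)
    res$clip <- list(annotation = ann, metagene = mg, ks = ks, gc = gcres)
  }

  manifest <- list(
    stage = stage,
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("nucfrac")),
    config = cfg[c("paths", "thresholds", "modes", "sim")],
    inputs = {
      p <- unlist(cfg$paths)
      p <- p[!vapply(p, is.null, logical(1))]
      p <- p[file.exists(p)]
      as.list(tools::md5sum(p))
    },
    output_rows = lapply(Filter(is.data.frame, res), nrow),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(res)
}
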