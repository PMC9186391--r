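#' Write transcript models as a GENCODE-style GTF
#'
#' Emits gene, transcript, exon, and CDS records with `gene_id`,
#' `transcript_id`, and `gene_type` attributes, via rtracklayer.
#'
#' @param txm a [tx_models] object.
#' @param path output GTF path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(txm, path) {
  tr <- txm$transcripts
  recs <- list()
  genes <- tr[!duplicated(tr$gene_id), ]
  recs$gene <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$gene_start, genes$gene_end),
    strand = genes$strand, type = "gene", gene_id = genes$gene_id,
    transcript_id = NA_character_, gene_type = genes$biotype,
    phase = NA_integer_)
  recs$tx <- GenomicRanges::GRanges(
    tr$chrom,
    IRanges::IRanges(
      min(GenomicRanges::start(txm$exons[tr$transcript_id])),
      max(GenomicRanges::end(txm$exons[tr$transcript_id]))),
    strand = tr$strand, type = "transcript", gene_id = tr$gene_id,
    transcript_id = tr$transcript_id, gene_type = tr$biotype,
    phase = NA_integer_)
  ex <- unlist(txm$exons[tr$transcript_id], use.names = FALSE)
  k <- rep(seq_len(nrow(tr)), tr$exon_count)
  S4Vectors::mcols(ex) <- S4Vectors::DataFrame(
    type = "exon", gene_id = tr$gene_id[k],
    transcript_id = tr$transcript_id[k], gene_type = tr$biotype[k],
    phase = NA_integer_)
  GenomicRanges::strand(ex) <- tr$strand[k]
  recs$exon <- ex
  if (length(txm$cds)) {
    cds <- unlist(txm$cds, use.names = FALSE)
    kk <- rep(names(txm$cds), lengths(txm$cds))
    m <- match(kk, tr$transcript_id)
    phase <- unlist(lapply(names(txm$cds), function(tid) {
      g <- txm$cds[[tid]]
      w <- GenomicRanges::width(g)
      if (tr$strand[match(tid, tr$transcript_id)] == "-") w <- rev(w)
      ph <- (3L - (cumsum(c(0L, w[-length(w)])) %% 3L)) %% 3L
      if (tr$strand[match(tid, tr$transcript_id)] == "-") rev(ph) else ph
    }), use.names = FALSE)
    S4Vectors::mcols(cds) <- S4Vectors::DataFrame(
      type = "CDS", gene_id = tr$gene_id[m], transcript_id = kk,
      gene_type = tr$biotype[m], phase = phase)
    GenomicRanges::strand(cds) <- tr$strand[m]
    recs$cds <- cds
  }
  all <- do.call(c, unname(recs))
  all <- all[order(GenomicRanges::start(all),
                   match(S4Vectors::mcols(all)$type,
                         c("gene", "transcript", "exon", "CDS")))]
  S4Vectors::mcols(all)$type <- factor(S4Vectors::mcols(all)$type,
                                       levels = c("gene", "transcript",
                                                  "exon", "CDS"))
  rtracklayer::export(all, path, format = "gtf")
  invisible(path)
}

#' Read a sequencing design table
#'
#' @param path TSV with columns `sample_id`, `genotype`, `fraction`,
#'   `replicate`, `library_size`, and optionally `path` (per-sample counts
#'   file, relative to the design file's directory).
#' @return data.frame.
#' @export
read_design <- function(path) {
  d <- read_tsv(path)
  check_design(d)
  attr(d, "dir") <- dirname(path)
  d
}

#' Read per-sample count tables into a matrix
#'
#' Each per-sample TSV has columns `gene_id`, `count`. All samples must
#' cover the same gene set.
#'
#' @param design design data.frame from [read_design()].
#' @param dir directory that the design's `path` column is relative to
#'   (defaults to the design file's own directory).
#' @return genes x samples integer matrix.
#' @export
read_counts <- function(design, dir = attr(design, "dir")) {
  if (is.null(design$path)) stopf("design has no path column")
  tabs <- lapply(seq_len(nrow(design)), function(i) {
    f <- file.path(dir %||% ".", design$path[i])
    read_tsv(f)
  })
  genes <- tabs[[1]]$gene_id
  for (i in seq_along(tabs))
    if (!identical(tabs[[i]]$gene_id, genes))
      stopf("sample %s covers a different gene set", design$sample_id[i])
  m <- vapply(tabs, function(t) as.numeric(t$count), numeric(length(genes)))
  dimnames(m) <- list(genes, design$sample_id)
  m
}

#' Write a complete simulated dataset
#'
#' Emits the file set consumed by the pipeline readers: `genome.fa`,
#' `annotation.gtf`, `design.tsv` plus per-sample `counts/*.tsv`,
#' `junctions.tsv`, `truth.tsv` (gene-level truth; peak coordinates 1-based
#' closed), and BED6 tracks `peaks.bed`, `clip_reads.bed`,
#' `input_reads.bed`.
#'
#' @param sim a `sim_data` object from [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "counts"), showWarnings = FALSE)
  if (!is.null(sim$genome)) {
    Biostrings::writeXStringSet(sim$genome, file.path(dir, "genome.fa"))
    write_gtf(sim$txm, file.path(dir, "annotation.gtf"))
  }
  d <- sim$design
  d$path <- file.path("counts", paste0(d$sample_id, ".tsv"))
  write_tsv(d, file.path(dir, "design.tsv"))
  for (i in seq_len(nrow(d))) {
    write_tsv(data.frame(gene_id = rownames(sim$counts),
                         count = sim$counts[, d$sample_id[i]]),
              file.path(dir, d$path[i]))
  }
  write_tsv(sim$junctions, file.path(dir, "junctions.tsv"))

  truth <- sim$truth
  truth$se_mean_true <- vapply(truth$se_introns, function(v)
    if (length(v)) mean(v) else NA_real_, numeric(1))
  truth$exon_lengths <- NULL
  truth$intron_lengths <- NULL
  truth$se_introns <- NULL
  if (!is.null(sim$clip) && length(sim$clip$peaks)) {
    pk <- sim$clip$peaks
    m <- match(truth$gene_id, S4Vectors::mcols(pk)$gene_id)
    truth$peak_chrom <- as.character(GenomicRanges::seqnames(pk))[m]
    truth$peak_start <- GenomicRanges::start(pk)[m]
    truth$peak_end <- GenomicRanges::end(pk)[m]
  }
  write_tsv(truth, file.path(dir, "truth.tsv"))

  if (!is.null(sim$clip)) {
    export_bed6 <- function(gr, path, names) {
      S4Vectors::mcols(gr) <- NULL
      S4Vectors::mcols(gr)$name <- names
      S4Vectors::mcols(gr)$score <- 0L
      rtracklayer::export(gr, path, format = "bed")
    }
    export_bed6(sim$clip$peaks, file.path(dir, "peaks.bed"),
                S4Vectors::mcols(sim$clip$peaks)$gene_id)
    export_bed6(sim$clip$clip_reads, file.path(dir, "clip_reads.bed"),
                sprintf("clip_%06d", seq_along(sim$clip$clip_reads)))
    export_bed6(sim$clip$input_reads, file.path(dir, "input_reads.bed"),
                sprintf("input_%06d", seq_along(sim$clip$input_reads)))
  }
  invisible(dir)
}
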