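# Fixtures built in code: a small hand-written GTF/FASTA pair with known
# structure, and a desk-scale simulation configuration.

toy_gtf_lines <- function() {
  attr_str <- function(gid, tid, bt)
    sprintf('gene_id "%s"; transcript_id "%s"; gene_type "%s";', gid, tid, bt)
  gattr <- function(gid, bt) sprintf('gene_id "%s"; gene_type "%s";', gid, bt)
  c(
    paste("chr1", "toy", "gene", 1, 300, ".", "+", ".",
          gattr("gA", "protein_coding"), sep = "\t"),
    paste("chr1", "toy", "transcript", 1, 300, ".", "+", ".",
          attr_str("gA", "gA.t1", "protein_coding"), sep = "\t"),
    paste("chr1", "toy", "exon", 1, 100, ".", "+", ".",
          attr_str("gA", "gA.t1", "protein_coding"), sep = "\t"),
    paste("chr1", "toy", "exon", 201, 300, ".", "+", ".",
          attr_str("gA", "gA.t1", "protein_coding"), sep = "\t"),
    paste("chr1", "toy", "CDS", 51, 100, ".", "+", "0",
          attr_str("gA", "gA.t1", "protein_coding"), sep = "\t"),
    paste("chr1", "toy", "CDS", 201, 250, ".", "+", "1",
          attr_str("gA", "gA.t1", "protein_coding"), sep = "\t"),
    paste("chr1", "toy", "gene", 401, 900, ".", "-", ".",
          gattr("gB", "lncRNA"), sep = "\t"),
    paste("chr1", "toy", "transcript", 401, 900, ".", "-", ".",
          attr_str("gB", "gB.t1", "lncRNA"), sep = "\t"),
    paste("chr1", "toy", "exon", 401, 500, ".", "-", ".",
          attr_str("gB", "gB.t1", "lncRNA"), sep = "\t"),
    paste("chr1", "toy", "exon", 601, 700, ".", "-", ".",
          attr_str("gB", "gB.t1", "lncRNA"), sep = "\t"),
    paste("chr1", "toy", "exon", 801, 900, ".", "-", ".",
          attr_str("gB", "gB.t1", "lncRNA"), sep = "\t")
  )
}

write_toy_gtf <- function(extra = character(0), drop = integer(0)) {
  lines <- toy_gtf_lines()
  if (length(drop)) lines <- lines[-drop]
  path <- withr::local_tempfile(fileext = ".gtf",
                                .local_envir = parent.frame())
  writeLines(c(lines, extra), path)
  path
}

toy_genome <- function(len = 1000, seed = 99) {
  set.seed(seed)
  g <- Biostrings::DNAStringSet(paste(
    sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""))
  names(g) <- "chr1"
  g
}

tiny_config <- function(...) {
  sim_config(n_genes = 60, library_size = 1e6, n_clip_targets = 12,
             reads_per_gene = 120, junction_depth = 40, ...)
}

# fpkm_set straight from a 6-column mean matrix (for statistic-level tests)
fake_fpkm_set <- function(mean_mat) {
  design <- data.frame(
    sample_id = colnames(mean_mat), genotype = rep(c("WT", "KO"), 3),
    fraction = rep(c("total", "nuc", "cyto"), each = 2),
    replicate = 1L, library_size = 1e6)
  structure(list(mean = mean_mat, replicate = mean_mat, design = design),
            class = "fpkm_set")
}

mean_mat <- function(genes, wt_total, wt_nuc, wt_cyto, ko_total, ko_nuc, ko_cyto) {
  n <- length(genes)
  m <- cbind(WT.total = rep_len(wt_total, n), WT.nuc = rep_len(wt_nuc, n),
             WT.cyto = rep_len(wt_cyto, n), KO.total = rep_len(ko_total, n),
             KO.nuc = rep_len(ko_nuc, n), KO.cyto = rep_len(ko_cyto, n))
  rownames(m) <- genes
  m
}

# toy single-exon / multi-exon gene models for interval logic
toy_clip_txm <- function() {
  tr <- data.frame(
    transcript_id = c("tc", "tn"), gene_id = c("gc", "gn"),
    biotype = c("protein_coding", "lncRNA"), chrom = "chr1",
    strand = c("+", "-"),
    tx_length = c(300, 200), exon_count = c(2L, 2L),
    gene_start = c(1001, 3001), gene_end = c(1500, 3400),
    gene_length = c(500, 400))
  exl <- GenomicRanges::GRangesList(
    tc = GenomicRanges::GRanges("chr1",
                                IRanges::IRanges(c(1001, 1301), c(1150, 1450)),
                                strand = "+"),
    tn = GenomicRanges::GRanges("chr1",
                                IRanges::IRanges(c(3001, 3301), c(3100, 3400)),
                                strand = "-"))
  cds <- GenomicRanges::GRangesList(
    tc = GenomicRanges::GRanges("chr1", IRanges::IRanges(1051, 1150),
                                strand = "+"))
  tx_models(tr[order(tr$gene_id), ], exl, cds)
}

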