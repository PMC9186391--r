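#' Simulation configuration
#'
#' Parameters of the synthetic fractionation RNA-seq experiment. The
#' generative model plants a GC-dependent nuclear-export impairment in the
#' knockout: the expected nuclear:cytoplasmic FPKM ratio of gene *g* is
#' `r_g` in wild type and `r_g * 2^(beta * (GC_g - mean(GC)) + eps_g)` in
#' the knockout, with `eps_g ~ N(0, noise_sd)`; the knockout total
#' abundance is scaled by `2^(-gamma * max(0, planted retention))`,
#' coupling nuclear trapping to loss of expression. Counts are negative
#' binomial with mean `FPKM * length * library_size / 1e9` and dispersion
#' `dispersion` (variance `mu + dispersion * mu^2`). The replicate design is
#' 3 wild-type and 4 knockout libraries in each of the three fractions.
#'
#' @param n_genes number of genes (default 2000).
#' @param exon_count_range inclusive range of the uniform exon-count draw.
#' @param exon_length_meanlog,exon_length_sdlog log-normal exon lengths (nt).
#' @param intron_length_meanlog,intron_length_sdlog log-normal intron lengths.
#' @param min_exon_length,min_intron_length lower clamps (nt).
#' @param gc_shape1,gc_shape2,gc_range per-gene GC target: Beta rescaled
#'   into `gc_range`.
#' @param abundance_meanlog,abundance_sdlog log-normal wild-type total FPKM.
#' @param ratio_sdlog log-normal spread of the wild-type nuc:cyto ratio.
#' @param beta export-impairment slope (log2 ratio shift per unit GC above
#'   the mean, knockout only).
#' @param gamma nuclear-decay coupling (log2 total-expression loss per unit
#'   retained nuclear excess).
#' @param noise_sd SD of the residual per-gene log2 ratio shift in knockout.
#' @param dispersion negative-binomial dispersion of counts.
#' @param library_size total mapped reads per library.
#' @param n_wt,n_ko replicate counts (3 wild type, 4 knockout).
#' @param se_shape1,se_shape2 Beta parameters of true per-intron splicing
#'   efficiency.
#' @param junction_depth expected junction-spanning read depth per intron at
#'   average abundance.
#' @param biotype_probs named gene-biotype probabilities.
#' @param n_clip_targets number of CLIP target genes.
#' @param target_gc_bias GC bias of target designation: sampling weight
#'   `exp(target_gc_bias * GC_g)`.
#' @param peak_width CLIP peak width (nt); peaks are placed in the
#'   highest-GC exonic window of each target.
#' @param clip_enrichment fold read-density enrichment inside the peak in
#'   the CLIP track relative to input.
#' @param reads_per_gene expected CLIP and input reads per target gene.
#' @param read_length simulated read length (nt).
#' @param intergenic_gap spacing between simulated genes (nt).
#' @param background_gc GC fraction of introns and intergenic sequence.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_genes = 2000,
                       exon_count_range = c(1L, 15L),
                       exon_length_meanlog = log(150), exon_length_sdlog = 0.5,
                       intron_length_meanlog = log(400), intron_length_sdlog = 0.5,
                       min_exon_length = 30L, min_intron_length = 50L,
                       gc_shape1 = 5, gc_shape2 = 5, gc_range = c(0.3, 0.8),
                       abundance_meanlog = log(15), abundance_sdlog = 1,
                       ratio_sdlog = 0.5,
                       beta = 3, gamma = 1, noise_sd = 0.5,
                       dispersion = 0.1,
                       library_size = 1e7,
                       n_wt = 3L, n_ko = 4L,
                       se_shape1 = 18, se_shape2 = 2,
                       junction_depth = 50,
                       biotype_probs = c(protein_coding = 0.75, lncRNA = 0.2,
                                         snoRNA = 0.05),
                       n_clip_targets = 300L,
                       target_gc_bias = 25,
                       peak_width = 50L,
                       clip_enrichment = 10,
                       reads_per_gene = 200,
                       read_length = 30L,
                       intergenic_gap = 200L,
                       background_gc = 0.4) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_genes >= 1,
            length(cfg$exon_count_range) == 2,
            cfg$exon_count_range[1] >= 1,
            cfg$exon_count_range[2] >= cfg$exon_count_range[1],
            cfg$gc_range[1] >= 0, cfg$gc_range[2] <= 1,
            cfg$gc_range[1] < cfg$gc_range[2],
            cfg$dispersion >= 0, cfg$library_size > 0,
            cfg$n_wt >= 1, cfg$n_ko >= 1,
            cfg$noise_sd >= 0, cfg$gamma >= 0,
            cfg$peak_width >= 1, cfg$clip_enrichment > 0,
            cfg$background_gc > 0, cfg$background_gc < 1,
            cfg$junction_depth > 0, cfg$reads_per_gene > 0)
  if (abs(sum(cfg$biotype_probs) - 1) > 1e-8)
    stopf("biotype_probs must sum to 1")
  structure(cfg, class = "sim_config")
}

#' Gene-level truth table
#'
#' Draws the latent per-gene state of the simulation: structure (exon and
#' intron lengths), GC target, wild-type abundance and nuc:cyto ratio, the
#' planted knockout localization shift `delta` (the true expected `L`), the
#' coupled expression change (true expected `E`), and true per-intron
#' splicing efficiencies. All draws come from the `"truth"` substream of the
#' master seed.
#'
#' @param config a [sim_config()].
#' @param seed master integer seed.
#' @return data.frame with one row per gene; `exon_lengths`,
#'   `intron_lengths` and `se_introns` are list columns.
#' @export
simulate_truth <- function(config = sim_config(), seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  with_substream(seed, "truth", {
    n <- config$n_genes
    gene_id <- sprintf("G%05d", seq_len(n))
    biotype <- sample(names(config$biotype_probs), n, replace = TRUE,
                      prob = config$biotype_probs)
    exon_count <- sample(seq(config$exon_count_range[1],
                             config$exon_count_range[2]), n, replace = TRUE)
    ex_lens <- pmax(config$min_exon_length,
                    round(stats::rlnorm(sum(exon_count),
                                        config$exon_length_meanlog,
                                        config$exon_length_sdlog)))
    exon_lengths <- split(ex_lens, rep(seq_len(n), exon_count))
    n_intr <- pmax(0L, exon_count - 1L)
    in_lens <- pmax(config$min_intron_length,
                    round(stats::rlnorm(sum(n_intr),
                                        config$intron_length_meanlog,
                                        config$intron_length_sdlog)))
    intron_lengths <- split(in_lens, rep(seq_len(n), n_intr))
    intron_lengths <- lapply(seq_len(n), function(i)
      intron_lengths[[as.character(i)]] %||% integer(0))
    gc <- config$gc_range[1] +
      stats::rbeta(n, config$gc_shape1, config$gc_shape2) * diff(config$gc_range)
    abundance <- stats::rlnorm(n, config$abundance_meanlog, config$abundance_sdlog)
    ratio_wt <- stats::rlnorm(n, 0, config$ratio_sdlog)
    eps <- stats::rnorm(n, 0, config$noise_sd)
    delta <- config$beta * (gc - mean(gc)) + eps
    true_E <- -config$gamma * pmax(0, delta)
    se_introns <- lapply(n_intr, function(k)
      if (k > 0) stats::rbeta(k, config$se_shape1, config$se_shape2) else numeric(0))

    truth <- data.frame(gene_id = gene_id, biotype = biotype,
                        exon_count = exon_count,
                        tx_length = vapply(exon_lengths, sum, numeric(1)),
                        gc_target = gc, gc = gc,
                        abundance = abundance, ratio_wt = ratio_wt,
                        true_L = delta, true_E = true_E,
                        clip_target = FALSE,
                        stringsAsFactors = FALSE)
    truth$gene_length <- truth$tx_length +
      vapply(intron_lengths, sum, numeric(1))
    truth$exon_lengths <- I(exon_lengths)
    truth$intron_lengths <- I(intron_lengths)
    truth$se_introns <- I(se_introns)
    attr(truth, "config") <- config
    truth
  })
}

# transcript-coordinate interval [s, e] -> genomic block matrix
# (columns start, end), given ascending exon IRanges and the strand
tx_blocks <- function(ex_ir, strand, s, e) {
  if (methods::is(ex_ir, "IRanges")) {
    w <- IRanges::width(ex_ir)
    gstart <- IRanges::start(ex_ir)
  } else {
    w <- ex_ir$width; gstart <- ex_ir$start
  }
  L <- sum(w)
  stopifnot(s >= 1, e <= L, s <= e)
  if (strand == "-") { tmp <- L - e + 1L; e <- L - s + 1L; s <- tmp }
  offs <- cumsum(c(0L, w[-length(w)]))
  res <- NULL
  for (k in seq_along(w)) {
    a <- max(s, offs[k] + 1L); b <- min(e, offs[k] + w[k])
    if (a <= b) {
      gs <- gstart[k] + (a - offs[k] - 1L)
      res <- rbind(res, c(gs, gs + (b - a)))
    }
  }
  res
}

# as tx_blocks but returning a GRanges
tx_to_genomic <- function(ex, strand, s, e) {
  res <- tx_blocks(IRanges::ranges(ex), strand, s, e)
  GenomicRanges::GRanges(as.character(GenomicRanges::seqnames(ex))[1],
                         IRanges::IRanges(res[, 1], res[, 2]), strand = strand)
}

#' Simulated genome and annotation
#'
#' Lays the truth-table genes on one synthetic chromosome (random strand,
#' fixed intergenic spacing) and draws the sequence base by base: exonic
#' positions are G/C with the gene's target GC probability (uniform within
#' class), introns and intergenic sequence at the background GC. Coding
#' genes get a CDS covering the central portion of the mature transcript so
#' that 5' and 3' UTRs exist. The realized exonic GC of every gene is
#' written back into the truth table (`gc` column; the drawn target is kept
#' as `gc_target`).
#'
#' @param truth truth table from [simulate_truth()].
#' @param config the [sim_config()] used for the truth table.
#' @param seed master integer seed (the `"genome"` substream is used).
#' @return list with `genome` (DNAStringSet, one chromosome `chrS`), `txm`
#'   (a [tx_models]), and `truth` (updated with realized GC).
#' @export
simulate_genome <- function(truth, config = attr(truth, "config"), seed = 1) {
  with_substream(seed, "genome", {
    n <- nrow(truth)
    strand <- sample(c("+", "-"), n, replace = TRUE)
    gap <- config$intergenic_gap

    # per-gene block layout
    gene_start <- integer(n); gene_end <- integer(n)
    exon_list <- vector("list", n)
    cursor <- 0L
    pgc_chunks <- vector("list", 2L * n + 1L)
    ci <- 1L
    for (i in seq_len(n)) {
      ex <- truth$exon_lengths[[i]]
      intr <- truth$intron_lengths[[i]]
      pgc_chunks[[ci]] <- rep(config$background_gc, gap); ci <- ci + 1L
      cursor <- cursor + gap
      gene_start[i] <- cursor + 1L
      blocks <- integer(0)
      pg <- numeric(0)
      for (k in seq_along(ex)) {
        blocks <- c(blocks, ex[k], if (k < length(ex)) intr[k] else integer(0))
        pg <- c(pg, rep(truth$gc_target[i], ex[k]),
                if (k < length(ex)) rep(config$background_gc, intr[k]) else numeric(0))
      }
      glen <- sum(blocks)
      # exon starts within gene
      starts <- cursor + 1L + cumsum(c(0L, utils::head(ex + c(intr, 0L),
                                                       length(ex) - 1L)))
      exon_list[[i]] <- IRanges::IRanges(starts, width = ex)
      pgc_chunks[[ci]] <- pg; ci <- ci + 1L
      cursor <- cursor + glen
      gene_end[i] <- cursor
    }
    pgc_chunks[[ci]] <- rep(config$background_gc, gap)
    pgc <- unlist(pgc_chunks, use.names = FALSE)
    total_len <- length(pgc)

    is_gc <- stats::runif(total_len) < pgc
    pick <- stats::runif(total_len) < 0.5
    bases <- character(total_len)
    bases[is_gc & pick] <- "G"; bases[is_gc & !pick] <- "C"
    bases[!is_gc & pick] <- "A"; bases[!is_gc & !pick] <- "T"
    genome <- Biostrings::DNAStringSet(paste(bases, collapse = ""))
    names(genome) <- "chrS"

    tid <- sub("^G", "T", truth$gene_id)
    nex <- lengths(exon_list)
    grp <- rep(seq_len(n), nex)
    ex_gr <- GenomicRanges::GRanges("chrS", do.call(c, exon_list),
                                    strand = strand[grp])
    exl <- S4Vectors::split(ex_gr, factor(tid[grp], levels = tid))

    coding <- which(truth$biotype == "protein_coding" & truth$tx_length >= 60)
    cds_rows <- lapply(coding, function(i) {
      L <- truth$tx_length[i]
      s <- floor(0.15 * L) + 1L
      e <- max(s + 2L, floor(0.85 * L))
      b <- tx_blocks(exon_list[[i]], strand[i], s, e)
      cbind(i, b)
    })
    cdsl <- if (length(cds_rows)) {
      cm <- do.call(rbind, cds_rows)
      cds_gr <- GenomicRanges::GRanges("chrS",
                                       IRanges::IRanges(cm[, 2], cm[, 3]),
                                       strand = strand[cm[, 1]])
      S4Vectors::split(cds_gr, factor(tid[cm[, 1]], levels = unique(tid[cm[, 1]])))
    } else {
      GenomicRanges::GRangesList()
    }

    tr <- data.frame(transcript_id = tid, gene_id = truth$gene_id,
                     biotype = truth$biotype, chrom = "chrS",
                     strand = strand,
                     tx_length = truth$tx_length,
                     exon_count = truth$exon_count,
                     gene_start = gene_start, gene_end = gene_end,
                     gene_length = gene_end - gene_start + 1L,
                     stringsAsFactors = FALSE)
    txm <- tx_models(tr, exl, cdsl)

    truth$gc <- gc_fraction(transcript_seqs(txm, genome))[
      match(tid, tr$transcript_id)]
    attr(truth, "config") <- config
    list(genome = genome, txm = txm, truth = truth)
  })
}

sim_design <- function(config) {
  g <- c(rep("WT", config$n_wt), rep("KO", config$n_ko))
  r <- c(seq_len(config$n_wt), seq_len(config$n_ko))
  d <- expand.grid(i = seq_along(g), fraction = c("total", "nuc", "cyto"),
                   stringsAsFactors = FALSE)
  data.frame(sample_id = paste(g[d$i], d$fraction, r[d$i], sep = "_"),
             genotype = g[d$i], fraction = d$fraction, replicate = r[d$i],
             library_size = config$library_size,
             stringsAsFactors = FALSE)
}

# expected FPKM per gene for the six design cells
expected_fpkm <- function(truth, config) {
  a <- truth$abundance
  r <- truth$ratio_wt
  a2 <- a * 2^truth$true_E
  r2 <- r * 2^truth$true_L
  cbind(WT.total = a, WT.nuc = a * sqrt(r), WT.cyto = a / sqrt(r),
        KO.total = a2, KO.nuc = a2 * sqrt(r2), KO.cyto = a2 / sqrt(r2))
}

#' Simulated count and junction tables
#'
#' Draws negative-binomial gene counts for every library of the replicate
#' design (3 wild type, 4 knockout, in each of total / nuclear / cytoplasmic)
#' from the truth table's expected FPKM, and junction-spanning read counts
#' per intron: `ee ~ Binomial(depth, SE)` with the remainder split across
#' the two exon-intron boundaries.
#'
#' @param truth truth table from [simulate_truth()] (optionally updated by
#'   [simulate_genome()]).
#' @param config the matching [sim_config()].
#' @param seed master integer seed (`"counts"` and `"junctions"` substreams).
#' @return list with `design`, `counts` (genes x samples integer matrix),
#'   `junctions` (data.frame `transcript_id`, `intron_index`, `ee`,
#'   `ei_donor`, `ei_acceptor`), and `expected_fpkm`.
#' @export
simulate_counts <- function(truth, config = attr(truth, "config"), seed = 1) {
  design <- sim_design(config)
  ef <- expected_fpkm(truth, config)
  counts <- with_substream(seed, "counts", {
    mu <- ef[, cell_id(design$genotype, design$fraction), drop = FALSE] *
      truth$tx_length * design$library_size[1] / 1e9
    cnt <- if (config$dispersion > 0) {
      matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / config$dispersion),
             nrow = nrow(mu))
    } else {
      matrix(stats::rpois(length(mu), mu), nrow = nrow(mu))
    }
    dimnames(cnt) <- list(truth$gene_id, design$sample_id)
    cnt
  })
  junctions <- with_substream(seed, "junctions", {
    multi <- which(truth$exon_count > 1)
    n_intr <- truth$exon_count[multi] - 1L
    tid <- sub("^G", "T", truth$gene_id)
    lam <- config$junction_depth * truth$abundance[multi] /
      exp(config$abundance_meanlog + config$abundance_sdlog^2 / 2)
    depth <- stats::rpois(sum(n_intr), rep(lam, n_intr))
    se <- unlist(truth$se_introns[multi], use.names = FALSE)
    ee <- stats::rbinom(length(depth), depth, se)
    rem <- depth - ee
    eid <- stats::rbinom(length(rem), rem, 0.5)
    data.frame(transcript_id = rep(tid[multi], n_intr),
               intron_index = unlist(lapply(n_intr, seq_len), use.names = FALSE),
               ee = ee, ei_donor = eid, ei_acceptor = rem - eid,
               stringsAsFactors = FALSE)
  })
  list(design = design, counts = counts, junctions = junctions,
       expected_fpkm = ef)
}

#' Simulated CLIP peaks and read tracks
#'
#' Designates CLIP target genes by GC-biased sampling (weight
#' `exp(target_gc_bias * GC_g)`), places one peak per target in the
#' highest-GC window of its mature transcript that lies within a single
#' exon, and samples read midpoints over the exonic body: input uniform,
#' CLIP with `clip_enrichment`-fold density inside the peak. Targets with no
#' exon wide enough for a peak are skipped and reported.
#'
#' @param gen output of [simulate_genome()].
#' @param config the matching [sim_config()].
#' @param seed master integer seed (`"clip"` substream).
#' @return list with `targets` (gene ids), `peaks` (GRanges with `gene_id`),
#'   `clip_reads`, `input_reads` (GRanges), `skipped` (gene ids), and
#'   `truth` (updated `clip_target` flags).
#' @export
simulate_clip <- function(gen, config = attr(gen$truth, "config"), seed = 1) {
  with_substream(seed, "clip", {
    truth <- gen$truth
    txm <- gen$txm
    genome <- gen$genome
    w <- config$peak_width
    n_t <- min(config$n_clip_targets, nrow(truth))
    targets <- sort(sample(truth$gene_id, n_t,
                           prob = exp(config$target_gc_bias * truth$gc)))
    tr <- txm$transcripts

    peaks <- NULL; skipped <- character(0)
    clip_reads <- list(); input_reads <- list()
    seqs <- transcript_seqs(txm, genome,
                            ids = tr$transcript_id[tr$gene_id %in% targets])
    for (gid in targets) {
      i <- match(gid, tr$gene_id)
      tid <- tr$transcript_id[i]
      ex <- txm$exons[[tid]]
      L <- tr$tx_length[i]
      # exon boundaries in transcript orientation
      wds <- GenomicRanges::width(ex)
      if (tr$strand[i] == "-") wds <- rev(wds)
      if (max(wds) < w || L < w) { skipped <- c(skipped, gid); next }
      txseq <- seqs[[tid]]
      gccnt <- Biostrings::letterFrequencyInSlidingView(txseq, w, "GC")[, 1]
      offs <- cumsum(c(0L, wds[-length(wds)]))
      valid <- rep(FALSE, L - w + 1L)
      for (k in seq_along(wds)) {
        if (wds[k] >= w)
          valid[(offs[k] + 1L):(offs[k] + wds[k] - w + 1L)] <- TRUE
      }
      gccnt[!valid] <- -1L
      s <- which.max(gccnt)
      pk <- tx_to_genomic(ex, tr$strand[i], s, s + w - 1L)
      S4Vectors::mcols(pk)$gene_id <- gid
      peaks <- if (is.null(peaks)) pk else c(peaks, pk)

      # read midpoints in transcript coordinates
      n_in <- stats::rpois(1, config$reads_per_gene)
      n_cl <- stats::rpois(1, config$reads_per_gene)
      mid_in <- sample.int(L, n_in, replace = TRUE)
      p_peak <- (config$clip_enrichment * w) /
        (config$clip_enrichment * w + (L - w))
      inpk <- stats::runif(n_cl) < p_peak
      mid_cl <- integer(n_cl)
      mid_cl[inpk] <- s - 1L + sample.int(w, sum(inpk), replace = TRUE)
      outside <- setdiff(seq_len(L), s:(s + w - 1L))
      mid_cl[!inpk] <- outside[sample.int(length(outside), sum(!inpk),
                                          replace = TRUE)]
      # vectorized midpoint -> genomic read interval, clipped to the exon
      # containing the midpoint so reads stay within exons
      gw <- GenomicRanges::width(ex)
      goffs <- cumsum(c(0L, gw[-length(gw)]))
      gstart <- GenomicRanges::start(ex)
      half <- config$read_length %/% 2L
      to_reads <- function(mids) {
        if (!length(mids)) return(NULL)
        asc <- if (tr$strand[i] == "-") L - mids + 1L else mids
        k <- findInterval(asc, goffs + 1L)
        gpos <- gstart[k] + (asc - goffs[k] - 1L)
        a <- pmax(gstart[k], gpos - half)
        b <- pmin(gstart[k] + gw[k] - 1L, gpos + half - 1L)
        GenomicRanges::GRanges("chrS", IRanges::IRanges(a, b),
                               strand = tr$strand[i])
      }
      input_reads[[gid]] <- to_reads(mid_in)
      clip_reads[[gid]] <- to_reads(mid_cl)
    }
    truth$clip_target <- truth$gene_id %in% setdiff(targets, skipped)
    cr <- do.call(c, unname(clip_reads[!vapply(clip_reads, is.null, logical(1))]))
    ir <- do.call(c, unname(input_reads[!vapply(input_reads, is.null, logical(1))]))
    list(targets = setdiff(targets, skipped), peaks = peaks,
         clip_reads = cr, input_reads = ir, skipped = skipped, truth = truth)
  })
}

#' Run the full generator
#'
#' Convenience wrapper: truth table, genome + annotation, count and junction
#' tables, and CLIP tracks, all driven by named substreams of one master
#' seed (so a fixed seed reproduces every emitted file byte for byte).
#' When `dir` is given the complete file set is written via
#' [write_simulation()].
#'
#' @param config a [sim_config()].
#' @param seed master integer seed.
#' @param dir optional output directory.
#' @param genome simulate sequence + annotation (needed for features and
#'   CLIP); set `FALSE` for counts-only studies.
#' @param clip simulate CLIP tracks (requires `genome`).
#' @return An object of class `sim_data`: list with `config`, `seed`,
#'   `truth`, and (as applicable) `genome`, `txm`, `design`, `counts`,
#'   `junctions`, `expected_fpkm`, `clip`.
#' @export
simulate_dataset <- function(config = sim_config(), seed = 1, dir = NULL,
                             genome = TRUE, clip = TRUE) {
  truth <- simulate_truth(config, seed)
  out <- list(config = config, seed = seed)
  if (genome) {
    gen <- simulate_genome(truth, config, seed)
    out$genome <- gen$genome
    out$txm <- gen$txm
    truth <- gen$truth
  }
  cj <- simulate_counts(truth, config, seed)
  out$design <- cj$design
  out$counts <- cj$counts
  out$junctions <- cj$junctions
  out$expected_fpkm <- cj$expected_fpkm
  if (genome && clip) {
    cl <- simulate_clip(list(truth = truth, txm = out$txm, genome = out$genome),
                        config, seed)
    truth <- cl$truth
    out$clip <- cl[c("targets", "peaks", "clip_reads", "input_reads", "skipped")]
  }
  out$truth <- truth
  class(out) <- "sim_data"
  if (!is.null(dir)) write_simulation(out, dir)
  out
}

#' @export
print.sim_data <- function(x, ...) {
  cat(sprintf("sim_data: %d genes, seed %d%s%s\n", nrow(x$truth), x$seed,
              if (!is.null(x$genome)) ", with genome" else "",
              if (!is.null(x$clip)) sprintf(", %d CLIP targets",
                                            length(x$clip$targets)) else ""))
  invisible(x)
}
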