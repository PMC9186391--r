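peak_categories <- c("CDS", "UTR5", "UTR3", "noncoding_exon", "intron", "intergenic")

#' Read a stranded BED file
#'
#' BED6 intervals imported via rtracklayer (0-based half-open on disk,
#' GRanges 1-based closed in memory). Strand is required for all records.
#'
#' @param path BED file path.
#' @return GRanges.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stopf("BED not found: %s", path)
  gr <- rtracklayer::import(path, format = "bed")
  if (any(as.character(GenomicRanges::strand(gr)) == "*"))
    stopf("BED %s contains unstranded records", path)
  gr
}

# Functional regions of each (longest-isoform) gene model: CDS, 5'/3' UTR,
# noncoding exon, intron. Vectorized over all genes; UTRs are the exonic
# parts genomically outside the CDS extremes (the CDS covers one contiguous
# stretch of the mature transcript). Returns GRanges with mcols gene_id,
# region.
gene_regions <- function(txm) {
  tr <- txm$transcripts
  exl <- txm$exons[tr$transcript_id]
  k <- lengths(exl)
  grp <- rep(seq_len(nrow(tr)), k)
  es <- unlist(GenomicRanges::start(exl), use.names = FALSE)
  ee <- unlist(GenomicRanges::end(exl), use.names = FALSE)

  cmin <- rep(NA_integer_, nrow(tr)); cmax <- rep(NA_integer_, nrow(tr))
  has <- tr$transcript_id %in% names(txm$cds)
  if (any(has)) {
    cl <- txm$cds[tr$transcript_id[has]]
    nonempty <- lengths(cl) > 0
    idx <- which(has)[nonempty]
    cmin[idx] <- min(GenomicRanges::start(cl))[nonempty]
    cmax[idx] <- max(GenomicRanges::end(cl))[nonempty]
  }
  coding <- !is.na(cmin[grp])

  rows <- list()
  add <- function(i, s, e, region) {
    ok <- s <= e
    rows[[length(rows) + 1]] <<- data.frame(i = i[ok], s = s[ok], e = e[ok],
                                            region = region[ok])
  }
  # introns: gaps between consecutive exons of the same transcript
  consec <- which(grp[-1] == grp[-length(grp)])
  add(grp[consec], ee[consec] + 1L, es[consec + 1L] - 1L,
      rep("intron", length(consec)))
  # noncoding exons
  add(grp[!coding], es[!coding], ee[!coding],
      rep("noncoding_exon", sum(!coding)))
  if (any(coding)) {
    ci <- grp[coding]
    # CDS blocks = exons clipped to the CDS genomic extent
    add(ci, pmax(es[coding], cmin[ci]), pmin(ee[coding], cmax[ci]),
        rep("CDS", length(ci)))
    left_lab <- ifelse(tr$strand[ci] == "+", "UTR5", "UTR3")
    right_lab <- ifelse(tr$strand[ci] == "+", "UTR3", "UTR5")
    add(ci, es[coding], pmin(ee[coding], cmin[ci] - 1L), left_lab)
    add(ci, pmax(es[coding], cmax[ci] + 1L), ee[coding], right_lab)
  }
  d <- do.call(rbind, rows)
  GenomicRanges::GRanges(tr$chrom[d$i], IRanges::IRanges(d$s, d$e),
                         strand = tr$strand[d$i],
                         gene_id = tr$gene_id[d$i], region = d$region)
}

#' Annotate CLIP peaks against gene models
#'
#' Each peak is assigned to the gene with maximal same-strand overlap (ties
#' broken by gene id), then to a functional category by majority overlap
#' within that gene, with the priority
#' CDS > 5'UTR > 3'UTR > noncoding exon > intron on ties. Peaks overlapping
#' no same-strand gene are intergenic.
#'
#' @param peaks GRanges of stranded peaks (e.g. from [read_bed()]).
#' @param txm a [tx_models] object, typically longest isoforms.
#' @param genome optional genome ([Biostrings::DNAStringSet] or FASTA path);
#'   when given, each peak's GC content is computed.
#' @return list with `peaks` (GRanges with `gene_id`, `category`, and
#'   optionally `gc` metadata) and `distribution` (data.frame of category
#'   fractions over all peaks; fractions sum to 1).
#' @export
assign_peaks <- function(peaks, txm, genome = NULL) {
  tr <- txm$transcripts
  spans <- GenomicRanges::GRanges(tr$chrom,
                                  IRanges::IRanges(tr$gene_start, tr$gene_end),
                                  strand = tr$strand, gene_id = tr$gene_id)
  ov <- GenomicRanges::findOverlaps(peaks, spans, ignore.strand = FALSE)
  ow <- GenomicRanges::width(GenomicRanges::pintersect(
    peaks[S4Vectors::queryHits(ov)], spans[S4Vectors::subjectHits(ov)]))
  gene_of <- rep(NA_character_, length(peaks))
  if (length(ov)) {
    cand <- data.frame(q = S4Vectors::queryHits(ov),
                       gene = tr$gene_id[S4Vectors::subjectHits(ov)],
                       w = ow, stringsAsFactors = FALSE)
    cand <- cand[order(cand$q, -cand$w, cand$gene), ]
    best <- cand[!duplicated(cand$q), ]
    gene_of[best$q] <- best$gene
  }

  rg <- gene_regions(txm)
  category <- rep("intergenic", length(peaks))
  prio <- setdiff(peak_categories, "intergenic")
  rhits <- GenomicRanges::findOverlaps(peaks, rg, ignore.strand = TRUE)
  q <- S4Vectors::queryHits(rhits); s <- S4Vectors::subjectHits(rhits)
  keep <- !is.na(gene_of[q]) & S4Vectors::mcols(rg)$gene_id[s] == gene_of[q]
  if (any(keep)) {
    q <- q[keep]; s <- s[keep]
    w <- GenomicRanges::width(GenomicRanges::pintersect(
      peaks[q], rg[s], ignore.strand = TRUE))
    reg <- S4Vectors::mcols(rg)$region[s]
    # total overlap per (peak, region), then majority with priority ties
    key <- paste(q, reg, sep = "\r")
    tot <- tapply(w, key, sum)
    parts <- strsplit(names(tot), "\r", fixed = TRUE)
    qq <- as.integer(vapply(parts, `[`, "", 1))
    rr <- vapply(parts, `[`, "", 2)
    ord <- order(qq, -as.numeric(tot), match(rr, prio))
    best <- !duplicated(qq[ord])
    category[qq[ord][best]] <- rr[ord][best]
  }

  S4Vectors::mcols(peaks)$gene_id <- gene_of
  S4Vectors::mcols(peaks)$category <- category
  if (!is.null(genome)) {
    S4Vectors::mcols(peaks)$gc <- gc_fraction(extract_seqs(
      genome, as.character(GenomicRanges::seqnames(peaks)),
      GenomicRanges::start(peaks), GenomicRanges::end(peaks)))
  }
  tab <- table(factor(category, levels = peak_categories))
  dist <- data.frame(category = peak_categories,
                     n = as.integer(tab),
                     fraction = as.numeric(tab) / length(peaks),
                     stringsAsFactors = FALSE)
  list(peaks = peaks, distribution = dist)
}

# map genomic positions (width-1) to transcript coordinates of target genes;
# returns data.frame(gene_index, txpos) with one row per (read, gene) hit
project_to_tx <- function(positions, txm, tr) {
  exl <- txm$exons[tr$transcript_id]
  exall <- unlist(exl, use.names = FALSE)
  gene_index <- rep(seq_len(nrow(tr)), lengths(exl))
  offs <- unlist(lapply(exl, function(g) {
    w <- GenomicRanges::width(g)
    cumsum(c(0L, w[-length(w)]))
  }), use.names = FALSE)
  GenomicRanges::strand(exall) <- tr$strand[gene_index]
  hits <- GenomicRanges::findOverlaps(positions, exall, ignore.strand = FALSE)
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  gi <- gene_index[s]
  txpos <- offs[s] + GenomicRanges::start(positions)[q] -
    GenomicRanges::start(exall)[s] + 1L
  txlen <- tr$tx_length[gi]
  minus <- tr$strand[gi] == "-"
  txpos[minus] <- txlen[minus] - txpos[minus] + 1L
  data.frame(gene_index = gi, txpos = txpos, txlen = txlen)
}

#' Metagene CLIP/input profile over the scaled gene body
#'
#' For each target gene, read midpoints are projected into exonic
#' (mature-transcript) coordinates, the gene body is scaled to `bins` bins,
#' and per-bin CLIP and input densities (each normalized to the gene's own
#' total, after adding a read-equivalent pseudocount to every bin of both
#' tracks) are ratioed. The profile is the mean ratio across genes; it is
#' exactly 1 in every bin when the CLIP and input reads coincide. Genes with
#' no input reads are excluded and counted. A `coords = "genomic"` mode bins
#' the genomic span instead of the spliced transcript.
#'
#' @param clip,input GRanges of stranded reads.
#' @param txm [tx_models] restricted (via `target_ids`) to the genes profiled.
#' @param target_ids optional gene ids; default all genes in `txm`.
#' @param bins number of bins over the scaled gene body (default 100).
#' @param pseudocount read-equivalent added to every bin of both tracks
#'   before normalization (default 1).
#' @param coords `"exonic"` (default) or `"genomic"` projection.
#' @return list with `profile` (data.frame `bin`, `value`), `n_genes`,
#'   `n_excluded`.
#' @export
metagene_profile <- function(clip, input, txm, target_ids = NULL, bins = 100,
                             pseudocount = 1, coords = c("exonic", "genomic")) {
  coords <- match.arg(coords)
  if (!length(clip) || !length(input)) stopf("empty read set")
  tr <- txm$transcripts
  if (!is.null(target_ids)) tr <- tr[tr$gene_id %in% target_ids, , drop = FALSE]
  if (!nrow(tr)) stopf("no target genes")

  midpt <- function(reads) {
    m <- (GenomicRanges::start(reads) + GenomicRanges::end(reads)) %/% 2L
    GenomicRanges::GRanges(GenomicRanges::seqnames(reads),
                           IRanges::IRanges(m, m),
                           strand = GenomicRanges::strand(reads))
  }
  bin_counts <- function(reads) {
    pos <- midpt(reads)
    if (coords == "exonic") {
      pr <- project_to_tx(pos, txm, tr)
    } else {
      spans <- GenomicRanges::GRanges(tr$chrom,
                                      IRanges::IRanges(tr$gene_start, tr$gene_end),
                                      strand = tr$strand)
      hits <- GenomicRanges::findOverlaps(pos, spans, ignore.strand = FALSE)
      gi <- S4Vectors::subjectHits(hits)
      p <- GenomicRanges::start(pos)[S4Vectors::queryHits(hits)] - tr$gene_start[gi] + 1L
      len <- tr$gene_length[gi]
      minus <- tr$strand[gi] == "-"
      p[minus] <- len[minus] - p[minus] + 1L
      pr <- data.frame(gene_index = gi, txpos = p, txlen = len)
    }
    b <- pmax(1L, pmin(bins, ceiling(pr$txpos / pr$txlen * bins)))
    idx <- (pr$gene_index - 1L) * bins + b
    matrix(tabulate(idx, nbins = nrow(tr) * bins), nrow = nrow(tr),
           ncol = bins, byrow = TRUE)
  }
  cc <- bin_counts(clip)
  ic <- bin_counts(input)
  has_input <- rowSums(ic) > 0
  n_excluded <- sum(!has_input)
  if (!any(has_input)) stopf("no target gene has input reads")
  cc <- cc[has_input, , drop = FALSE] + pseudocount
  ic <- ic[has_input, , drop = FALSE] + pseudocount
  ratio <- (cc / rowSums(cc)) / (ic / rowSums(ic))
  list(profile = data.frame(bin = seq_len(bins), value = colMeans(ratio)),
       n_genes = sum(has_input), n_excluded = n_excluded)
}

#' Localization shift of CLIP targets (two-sample KS test)
#'
#' Compares the localization statistic `L` of CLIP target genes (genes
#' hosting at least one assigned peak) against nontargets among retained
#' genes with a two-sided two-sample Kolmogorov-Smirnov test, and exports
#' the empirical CDF coordinates for plotting.
#'
#' @param records classified localization records.
#' @param target_ids character vector of CLIP target gene ids.
#' @return list with `D`, `p`, `n_target`, `n_nontarget`, and `cdf`
#'   (data.frame `group`, `L`, `ecdf`).
#' @export
target_shift_test <- function(records, target_ids) {
  rec <- records[records$passed_filter, ]
  x <- rec$L[rec$gene_id %in% target_ids]
  y <- rec$L[!rec$gene_id %in% target_ids]
  if (length(x) < 2 || length(y) < 2)
    stopf("need at least 2 retained genes per group (targets: %d, nontargets: %d)",
          length(x), length(y))
  ks <- suppressWarnings(stats::ks.test(x, y, alternative = "two.sided"))
  cdf <- rbind(
    data.frame(group = "target", L = sort(x),
               ecdf = seq_along(x) / length(x)),
    data.frame(group = "nontarget", L = sort(y),
               ecdf = seq_along(y) / length(y))
  )
  list(D = unname(ks$statistic), p = ks$p.value,
       n_target = length(x), n_nontarget = length(y), cdf = cdf)
}

#' GC-content enrichment of CLIP peaks
#'
#' GC content of (a) peak sequences, (b) exonic sequences of peak-hosting
#' ("bound") transcripts, and (c) exonic sequences of background
#' transcripts, with pairwise two-sided Wilcoxon rank-sum tests and box
#' summaries (median, 25-75 box, 10-90 whiskers).
#'
#' @param peaks annotated peak GRanges from [assign_peaks()] (metadata
#'   `gene_id` required; `gc` computed here if absent).
#' @param txm a [tx_models] object covering host and background genes.
#' @param genome genome ([Biostrings::DNAStringSet] or FASTA path).
#' @param background_ids optional gene ids for the background set; default
#'   all genes in `txm` not hosting a peak.
#' @return list with `gc` (long data.frame `group`, `gc`), `tests`
#'   (data.frame `contrast`, `W`, `p`), `summary` (per-group quantiles).
#' @export
peak_gc_enrichment <- function(peaks, txm, genome, background_ids = NULL) {
  genome <- normalize_genome(genome)
  md <- S4Vectors::mcols(peaks)
  if (is.null(md$gene_id)) stopf("peaks must be annotated with assign_peaks() first")
  if (is.null(md$gc)) {
    md$gc <- gc_fraction(extract_seqs(
      genome, as.character(GenomicRanges::seqnames(peaks)),
      GenomicRanges::start(peaks), GenomicRanges::end(peaks)))
  }
  hosts <- unique(stats::na.omit(md$gene_id))
  if (is.null(background_ids))
    background_ids <- setdiff(txm$transcripts$gene_id, hosts)
  if (!length(hosts) || !length(background_ids) || !length(peaks))
    stopf("empty group in GC enrichment (peaks: %d, bound: %d, background: %d)",
          length(peaks), length(hosts), length(background_ids))
  tx_gc <- function(ids) {
    tr <- txm$transcripts[txm$transcripts$gene_id %in% ids, ]
    gc_fraction(transcript_seqs(txm, genome, ids = tr$transcript_id))
  }
  groups <- list(peak = md$gc, bound_transcript = tx_gc(hosts),
                 background_transcript = tx_gc(background_ids))
  long <- do.call(rbind, lapply(names(groups), function(g)
    data.frame(group = g, gc = groups[[g]], stringsAsFactors = FALSE)))
  contrasts <- list(c("peak", "bound_transcript"),
                    c("peak", "background_transcript"),
                    c("bound_transcript", "background_transcript"))
  tests <- do.call(rbind, lapply(contrasts, function(ct) {
    wt <- suppressWarnings(stats::wilcox.test(groups[[ct[1]]], groups[[ct[2]]],
                                              alternative = "two.sided"))
    data.frame(contrast = paste(ct, collapse = " vs "),
               W = unname(wt$statistic), p = wt$p.value)
  }))
  qs <- c(0.1, 0.25, 0.5, 0.75, 0.9)
  summ <- do.call(rbind, lapply(names(groups), function(g) {
    v <- stats::quantile(groups[[g]], qs, na.rm = TRUE)
    data.frame(group = g, n = length(groups[[g]]),
               q10 = v[1], q25 = v[2], median = v[3], q75 = v[4], q90 = v[5],
               row.names = NULL)
  }))
  list(gc = long, tests = tests, summary = summ)
}
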