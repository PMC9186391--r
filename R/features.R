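#' GC fraction of sequences
#'
#' Case-insensitive G+C fraction with ambiguous bases (N and other IUPAC
#' codes) excluded from both numerator and denominator. Returns `NA` for a
#' sequence with no unambiguous base.
#'
#' @param x a [Biostrings::DNAStringSet], DNAString, or character vector.
#' @return numeric vector of fractions in \[0, 1\].
#' @export
gc_fraction <- function(x) {
  if (is.character(x)) x <- Biostrings::DNAStringSet(toupper(x))
  if (methods::is(x, "DNAString")) x <- Biostrings::DNAStringSet(x)
  af <- Biostrings::alphabetFrequency(x, baseOnly = TRUE)
  gc <- af[, "G"] + af[, "C"]
  tot <- af[, "A"] + af[, "C"] + af[, "G"] + af[, "T"]
  out <- ifelse(tot > 0, gc / tot, NA_real_)
  unname(out)
}

# genome: DNAStringSet keyed by chromosome (names trimmed to first token)
normalize_genome <- function(genome) {
  if (is.character(genome) && length(genome) == 1 && file.exists(genome))
    genome <- Biostrings::readDNAStringSet(genome)
  stopifnot(methods::is(genome, "DNAStringSet"))
  names(genome) <- sub("\\s.*$", "", names(genome))
  genome
}

#' Mature (spliced) transcript sequences
#'
#' Concatenates each transcript's exon sequences in genomic order and
#' reverse-complements minus-strand transcripts, giving the mature sequence
#' in 5' to 3' transcript orientation.
#'
#' @param txm a [tx_models] object.
#' @param genome a [Biostrings::DNAStringSet] or path to a FASTA file.
#' @param ids optional transcript ids to restrict to.
#' @return A DNAStringSet named by transcript id.
#' @export
transcript_seqs <- function(txm, genome, ids = NULL) {
  genome <- normalize_genome(genome)
  tr <- txm$transcripts
  if (!is.null(ids)) tr <- tr[tr$transcript_id %in% ids, , drop = FALSE]
  missing_chr <- setdiff(unique(tr$chrom), names(genome))
  if (length(missing_chr))
    stopf("chromosome(s) absent from genome: %s", paste(missing_chr, collapse = ", "))
  exl <- txm$exons[tr$transcript_id]
  grp <- rep(seq_len(nrow(tr)), lengths(exl))
  ex_all <- unlist(exl, use.names = FALSE)
  chars <- character(nrow(tr))
  for (chr in unique(tr$chrom)) {
    sel <- which(tr$chrom[grp] == chr)
    if (!length(sel)) next
    pieces <- as.character(Biostrings::extractAt(genome[[chr]],
                                                 IRanges::ranges(ex_all[sel])))
    joined <- vapply(split(pieces, grp[sel]),
                     function(z) paste(z, collapse = ""), character(1))
    chars[as.integer(names(joined))] <- joined
  }
  out <- Biostrings::DNAStringSet(chars)
  minus <- tr$strand == "-"
  if (any(minus)) out[minus] <- Biostrings::reverseComplement(out[minus])
  names(out) <- tr$transcript_id
  out
}

# vectorized interval sequence extraction (per chromosome)
extract_seqs <- function(genome, chrom, start, end) {
  genome <- normalize_genome(genome)
  out <- Biostrings::DNAStringSet(rep("", length(chrom)))
  for (chr in unique(chrom)) {
    sel <- which(chrom == chr)
    if (is.null(genome[[chr]])) stopf("chromosome absent from genome: %s", chr)
    out[sel] <- Biostrings::extractAt(genome[[chr]],
                                      IRanges::IRanges(start[sel], end[sel]))
  }
  out
}

#' Per-transcript feature set
#'
#' Computes the covariates used in the feature-localization correlation
#' analysis: exonic GC content, exon count, transcript length (exons only),
#' longest exon length, exon density (exonic length / genomic gene length),
#' gene length, and -- when a splicing summary is supplied -- mean, maximum,
#' and minimum splicing efficiency. A gene-body GC content over the genomic
#' span is also reported for track-style views.
#'
#' @param txm a [tx_models] object (typically after
#'   [select_longest_isoform()]).
#' @param genome a [Biostrings::DNAStringSet] or FASTA path.
#' @param splicing optional splicing summary from [summarize_se()]
#'   (matched by `transcript_id`).
#' @return data.frame with one row per transcript: identifiers, biotype, and
#'   the features above. Splicing-efficiency columns are `NA` where
#'   undefined (single-exon transcripts, or no intron passing coverage).
#' @export
compute_features <- function(txm, genome, splicing = NULL) {
  genome <- normalize_genome(genome)
  tr <- txm$transcripts
  seqs <- transcript_seqs(txm, genome)
  span_seqs <- extract_seqs(genome, tr$chrom, tr$gene_start, tr$gene_end)
  longest <- vapply(txm$exons[tr$transcript_id],
                    function(g) max(GenomicRanges::width(g)), numeric(1))
  out <- data.frame(
    gene_id = tr$gene_id,
    transcript_id = tr$transcript_id,
    biotype = tr$biotype,
    gc_content = gc_fraction(seqs[tr$transcript_id]),
    exon_count = tr$exon_count,
    transcript_length = tr$tx_length,
    longest_exon_length = unname(longest),
    exon_density = tr$tx_length / tr$gene_length,
    gene_length = tr$gene_length,
    gene_body_gc = gc_fraction(span_seqs),
    se_mean = NA_real_, se_max = NA_real_, se_min = NA_real_,
    stringsAsFactors = FALSE
  )
  if (!is.null(splicing)) {
    m <- match(out$transcript_id, splicing$transcript_id)
    out$se_mean <- splicing$se_mean[m]
    out$se_max <- splicing$se_max[m]
    out$se_min <- splicing$se_min[m]
  }
  rownames(out) <- NULL
  out
}
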