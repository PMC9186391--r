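#' Transcript models from a GENCODE-style GTF
#'
#' A `tx_models` object holds the genomic structure of a set of transcripts:
#' a per-transcript summary table plus exon and CDS intervals as
#' [GenomicRanges::GRangesList] objects keyed by transcript id. All internal
#' coordinates follow the GRanges convention (1-based, closed); BED input and
#' output is converted at the boundary by rtracklayer.
#'
#' @param transcripts data.frame with columns `transcript_id`, `gene_id`,
#'   `biotype`, `chrom`, `strand`, `tx_length`, `exon_count`, `gene_start`,
#'   `gene_end`, `gene_length`.
#' @param exons GRangesList of exons per transcript (ascending genomic start).
#' @param cds GRangesList of CDS intervals for coding transcripts (may be
#'   empty for a transcript).
#' @return An object of class `tx_models`.
#' @export
tx_models <- function(transcripts, exons, cds) {
  stopifnot(is.data.frame(transcripts),
            all(transcripts$transcript_id %in% names(exons)))
  obj <- structure(list(transcripts = transcripts,
                        exons = exons[transcripts$transcript_id],
                        cds = cds),
                   class = "tx_models")
  validate_tx_models(obj)
  obj
}

validate_tx_models <- function(x) {
  tr <- x$transcripts
  ex <- x$exons[tr$transcript_id]
  k <- lengths(ex)
  us <- unlist(GenomicRanges::start(ex), use.names = FALSE)
  ue <- unlist(GenomicRanges::end(ex), use.names = FALSE)
  grp <- rep(seq_along(ex), k)
  consec <- which(grp[-1] == grp[-length(grp)])
  bad_pair <- us[consec + 1L] <= ue[consec] | us[consec + 1L] < us[consec]
  if (any(bad_pair)) {
    bad <- unique(grp[consec][bad_pair])
    stopf("overlapping or unsorted exons within transcript(s): %s",
          paste(names(ex)[bad], collapse = ", "))
  }
  lens <- sum(GenomicRanges::width(ex))
  if (!all(abs(lens - tr$tx_length) < 0.5))
    stopf("tx_length inconsistent with exon widths")
  inside <- min(GenomicRanges::start(ex)) >= tr$gene_start &
    max(GenomicRanges::end(ex)) <= tr$gene_end
  if (!all(inside))
    stopf("exons outside gene span for transcript(s): %s",
          paste(tr$transcript_id[!inside], collapse = ", "))
  invisible(x)
}

#' @export
print.tx_models <- function(x, ...) {
  cat(sprintf("tx_models: %d transcripts, %d genes\n",
              nrow(x$transcripts), length(unique(x$transcripts$gene_id))))
  invisible(x)
}

#' Parse a GENCODE-style GTF into transcript models
#'
#' Reads gene/transcript/exon/CDS records (via rtracklayer) and builds one
#' [tx_models] object. Every transcript must have at least one exon record
#' carrying `gene_id` and `transcript_id` attributes; the biotype is taken
#' from the `gene_type` attribute (GENCODE) or `gene_biotype` (Ensembl).
#' The gene span comes from `gene` records when present, otherwise from the
#' union of the gene's exons.
#'
#' @param path path to a GTF file.
#' @return A [tx_models] object.
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stopf("GTF not found: %s", path)
  gr <- rtracklayer::import(path, format = "gtf")
  md <- S4Vectors::mcols(gr)
  if (is.null(md$gene_id)) stopf("GTF %s lacks gene_id attributes", path)
  btcol <- intersect(c("gene_type", "gene_biotype"), colnames(md))
  ex <- gr[md$type == "exon"]
  if (length(ex) == 0) stopf("GTF %s contains no exon records", path)
  exmd <- S4Vectors::mcols(ex)
  if (is.null(exmd$transcript_id) || anyNA(exmd$transcript_id)) {
    bad <- if (is.null(exmd$transcript_id)) seq_along(ex) else which(is.na(exmd$transcript_id))
    stopf("exon record(s) without transcript_id (exon record index %s)",
          paste(utils::head(bad, 5), collapse = ", "))
  }
  if (anyNA(exmd$gene_id))
    stopf("exon record(s) without gene_id (exon record index %s)",
          paste(utils::head(which(is.na(exmd$gene_id)), 5), collapse = ", "))

  ord <- order(exmd$transcript_id, GenomicRanges::start(ex))
  ex <- ex[ord]
  exmd <- S4Vectors::mcols(ex)
  exl <- S4Vectors::split(ex, exmd$transcript_id)

  tid <- names(exl)
  first <- ex[!duplicated(exmd$transcript_id)]
  fmd <- S4Vectors::mcols(first)
  fo <- match(tid, fmd$transcript_id)
  biotype <- if (length(btcol)) as.character(fmd[[btcol[1]]])[fo] else rep(NA_character_, length(tid))
  tr <- data.frame(
    transcript_id = tid,
    gene_id = as.character(fmd$gene_id)[fo],
    biotype = biotype,
    chrom = as.character(GenomicRanges::seqnames(first))[fo],
    strand = as.character(GenomicRanges::strand(first))[fo],
    tx_length = sum(GenomicRanges::width(exl)),
    exon_count = lengths(exl),
    stringsAsFactors = FALSE
  )

  # gene span: gene records when present, else union of the gene's exons
  tx_start <- min(GenomicRanges::start(exl))
  tx_end <- max(GenomicRanges::end(exl))
  span_start <- tapply(tx_start, tr$gene_id, min)
  span_end <- tapply(tx_end, tr$gene_id, max)
  genes <- gr[md$type == "gene"]
  gm <- match(tr$gene_id, S4Vectors::mcols(genes)$gene_id)
  tr$gene_start <- ifelse(is.na(gm), span_start[tr$gene_id],
                          GenomicRanges::start(genes)[gm])
  tr$gene_end <- ifelse(is.na(gm), span_end[tr$gene_id],
                        GenomicRanges::end(genes)[gm])
  tr$gene_length <- tr$gene_end - tr$gene_start + 1

  cdsr <- gr[md$type == "CDS"]
  cdsl <- if (length(cdsr)) {
    cdsr <- cdsr[order(S4Vectors::mcols(cdsr)$transcript_id,
                       GenomicRanges::start(cdsr))]
    S4Vectors::split(cdsr, S4Vectors::mcols(cdsr)$transcript_id)
  } else {
    GenomicRanges::GRangesList()
  }

  tr <- tr[order(tr$gene_id, tr$transcript_id), , drop = FALSE]
  rownames(tr) <- NULL
  tx_models(tr, exl, cdsl)
}

#' Keep the longest isoform of each gene
#'
#' Per gene, retains the transcript with the greatest exonic (mature) length;
#' ties are broken by the lexicographically smallest transcript id so the
#' choice is deterministic regardless of input order.
#'
#' @param txm a [tx_models] object.
#' @return A [tx_models] object with one transcript per gene.
#' @export
select_longest_isoform <- function(txm) {
  tr <- txm$transcripts
  ord <- order(tr$gene_id, -tr$tx_length, tr$transcript_id)
  keep <- ord[!duplicated(tr$gene_id[ord])]
  tr2 <- tr[sort(keep), , drop = FALSE]
  rownames(tr2) <- NULL
  cds <- txm$cds[intersect(tr2$transcript_id, names(txm$cds))]
  tx_models(tr2, txm$exons[tr2$transcript_id], cds)
}

#' Intron intervals derived from exon gaps
#'
#' @param txm a [tx_models] object.
#' @return GRangesList of introns per transcript (gaps between consecutive
#'   exons in genomic order; empty for single-exon transcripts).
#' @export
intron_ranges <- function(txm) {
  spans <- unlist(range(txm$exons))
  GenomicRanges::psetdiff(spans, txm$exons[names(spans)])
}
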