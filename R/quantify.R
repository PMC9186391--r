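#' FPKM from gene-level counts
#'
#' Fragments per kilobase of transcript per million mapped reads:
#' `FPKM_g = count_g * 1e9 / (length_g * library_size)`. Transcript lengths
#' should come from the longest isoform per gene; the library size is the
#' total mapped reads of the library (taken from the design table, not
#' recomputed from the count column, since mapped totals include reads
#' outside the counted gene set).
#'
#' @param counts named non-negative numeric vector of read counts per gene.
#' @param lengths named numeric vector of transcript lengths (nt) per gene.
#' @param library_size positive scalar, total mapped reads.
#' @return Named numeric vector of FPKM for genes present in both `counts`
#'   and `lengths`. Genes missing from `lengths` are dropped with a warning
#'   stating how many.
#' @export
compute_fpkm <- function(counts, lengths, library_size) {
  if (!is.numeric(library_size) || length(library_size) != 1 || library_size <= 0)
    stopf("library_size must be a positive scalar")
  if (any(counts < 0)) stopf("negative counts")
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stopf("transcript lengths must be positive and finite")
  miss <- setdiff(names(counts), names(lengths))
  if (length(miss)) {
    warning(sprintf("%d gene(s) present in counts but absent from lengths; dropped",
                    length(miss)), call. = FALSE)
    counts <- counts[setdiff(names(counts), miss)]
  }
  counts * 1e9 / (as.numeric(lengths[names(counts)]) * as.numeric(library_size))
}

cell_id <- function(genotype, fraction) paste(genotype, fraction, sep = ".")

design_cells <- function() {
  as.vector(outer(c("WT", "KO"), c("total", "nuc", "cyto"), cell_id))
}

check_design <- function(design) {
  need <- c("sample_id", "genotype", "fraction", "replicate", "library_size")
  if (!all(need %in% names(design)))
    stopf("design lacks column(s): %s", paste(setdiff(need, names(design)), collapse = ", "))
  if (!all(design$genotype %in% c("WT", "KO")))
    stopf("genotype must be WT or KO")
  if (!all(design$fraction %in% c("total", "nuc", "cyto")))
    stopf("fraction must be one of total, nuc, cyto")
  have <- unique(cell_id(design$genotype, design$fraction))
  miss <- setdiff(design_cells(), have)
  if (length(miss))
    stopf("design is missing (genotype, fraction) cell(s): %s",
          paste(miss, collapse = ", "))
  invisible(design)
}

#' Average replicate FPKM into a per-cell matrix
#'
#' Takes a genes x samples FPKM matrix plus the design and returns the
#' arithmetic mean FPKM per gene for each of the six (genotype, fraction)
#' cells, retaining the replicate-level matrix for diagnostics.
#'
#' @param fpkm genes x samples numeric matrix (colnames = sample ids).
#' @param design data.frame with `sample_id`, `genotype` (WT/KO), `fraction`
#'   (total/nuc/cyto), `replicate`, `library_size`.
#' @return An object of class `fpkm_set`: list with `mean` (genes x 6 matrix,
#'   columns `WT.total` ... `KO.cyto`), `replicate` (input matrix), `design`.
#' @export
average_fpkm <- function(fpkm, design) {
  check_design(design)
  if (!all(design$sample_id %in% colnames(fpkm)))
    stopf("FPKM matrix lacks sample(s): %s",
          paste(setdiff(design$sample_id, colnames(fpkm)), collapse = ", "))
  cells <- design_cells()
  mean_mat <- sapply(cells, function(cl) {
    sids <- design$sample_id[cell_id(design$genotype, design$fraction) == cl]
    rowMeans(fpkm[, sids, drop = FALSE])
  })
  structure(list(mean = mean_mat, replicate = fpkm, design = design),
            class = "fpkm_set")
}

#' Build an FPKM set from a count matrix
#'
#' Convenience wrapper: per-sample FPKM via [compute_fpkm()] using each
#' sample's library size, then replicate averaging via [average_fpkm()].
#'
#' @param counts genes x samples integer matrix.
#' @param design design data.frame (see [average_fpkm()]).
#' @param lengths named transcript-length vector (longest isoform per gene).
#' @return An `fpkm_set`.
#' @export
build_fpkm <- function(counts, design, lengths) {
  check_design(design)
  keep <- intersect(rownames(counts), names(lengths))
  dropped <- nrow(counts) - length(keep)
  if (dropped > 0)
    warning(sprintf("%d gene(s) present in counts but absent from lengths; dropped",
                    dropped), call. = FALSE)
  counts <- counts[keep, , drop = FALSE]
  fpkm <- sapply(design$sample_id, function(sid) {
    ls <- design$library_size[design$sample_id == sid]
    counts[, sid] * 1e9 / (as.numeric(lengths[keep]) * as.numeric(ls))
  })
  rownames(fpkm) <- keep
  average_fpkm(fpkm, design)
}

#' @export
print.fpkm_set <- function(x, ...) {
  cat(sprintf("fpkm_set: %d genes, %d samples, cells: %s\n",
              nrow(x$mean), ncol(x$replicate),
              paste(colnames(x$mean), collapse = " ")))
  invisible(x)
}

#' Detection filter on averaged FPKM
#'
#' Retains genes whose averaged FPKM is strictly greater than `threshold` in
#' all three fractions (total, nuclear, cytoplasmic). With
#' `scope = "both"` (default) the requirement applies in both genotypes,
#' which guarantees strictly positive arguments for every downstream log;
#' `scope = "either"` requires all three fractions to pass in at least one
#' genotype.
#'
#' @param fs an `fpkm_set` from [average_fpkm()] or [build_fpkm()].
#' @param threshold FPKM cutoff (strict inequality; default 1).
#' @param scope genotype scope of the filter, `"both"` or `"either"`.
#' @return Character vector of retained gene ids.
#' @export
detection_filter <- function(fs, threshold = 1, scope = c("both", "either")) {
  scope <- match.arg(scope)
  m <- fs$mean
  wt <- m[, cell_id("WT", c("total", "nuc", "cyto")), drop = FALSE]
  ko <- m[, cell_id("KO", c("total", "nuc", "cyto")), drop = FALSE]
  wt_ok <- rowSums(wt > threshold) == 3L
  ko_ok <- rowSums(ko > threshold) == 3L
  keep <- if (scope == "both") wt_ok & ko_ok else wt_ok | ko_ok
  rownames(m)[keep]
}
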