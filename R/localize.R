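#' Per-gene localization and expression statistics
#'
#' For each retained gene the relative RNA localization is the log2 fold
#' change of the knockout nuclear:cytoplasmic FPKM ratio over the wild-type
#' ratio,
#' `L = log2(KO_nuc / KO_cyto) - log2(WT_nuc / WT_cyto)`,
#' and the relative expression is
#' `E = log2(KO_total / WT_total)`.
#' Positive `L` indicates nuclear retention upon knockout. Genes not in
#' `retained` carry `NA` for both statistics.
#'
#' @param fs an `fpkm_set` of averaged FPKM (see [build_fpkm()]).
#' @param retained character vector of gene ids passing the detection filter
#'   (from [detection_filter()]).
#' @return data.frame with one row per gene: the six averaged FPKM values,
#'   `passed_filter`, `L`, `E`, and placeholder `nuclear_enriched` / `rank`
#'   columns filled by [classify_and_rank()].
#' @export
localization <- function(fs, retained) {
  m <- fs$mean
  genes <- rownames(m)
  passed <- genes %in% retained
  rec <- data.frame(
    gene_id = genes,
    fpkm_wt_total = m[, "WT.total"], fpkm_wt_nuc = m[, "WT.nuc"],
    fpkm_wt_cyto = m[, "WT.cyto"],
    fpkm_ko_total = m[, "KO.total"], fpkm_ko_nuc = m[, "KO.nuc"],
    fpkm_ko_cyto = m[, "KO.cyto"],
    passed_filter = passed,
    L = NA_real_, E = NA_real_,
    nuclear_enriched = NA, rank = NA_integer_,
    stringsAsFactors = FALSE
  )
  p <- which(passed)
  if (length(p)) {
    args <- rec[p, c("fpkm_ko_nuc", "fpkm_ko_cyto", "fpkm_wt_nuc",
                     "fpkm_wt_cyto", "fpkm_ko_total", "fpkm_wt_total")]
    if (any(as.matrix(args) <= 0))
      stopf("non-positive FPKM reached a log for retained gene(s): %s",
            paste(utils::head(rec$gene_id[p][apply(args <= 0, 1, any)], 5),
                  collapse = ", "))
    rec$L[p] <- log2(rec$fpkm_ko_nuc[p] / rec$fpkm_ko_cyto[p]) -
      log2(rec$fpkm_wt_nuc[p] / rec$fpkm_wt_cyto[p])
    rec$E[p] <- log2(rec$fpkm_ko_total[p] / rec$fpkm_wt_total[p])
  }
  rownames(rec) <- NULL
  rec
}

#' Classify nuclear-enriched genes and rank by localization shift
#'
#' A gene is called nuclear-enriched when its localization statistic exceeds
#' the log2 fold-change threshold strictly (`L > lfc`; a greater than
#' twofold increase in the nuclear:cytoplasmic ratio at the default
#' `lfc = 1`). Retained genes are ranked by descending `L` (rank 1 = most
#' nuclear-enriched), ties broken by gene id.
#'
#' @param records localization records from [localization()].
#' @param lfc log2 fold-change threshold (default 1, strict).
#' @return The records with `nuclear_enriched` and `rank` filled in.
#' @export
classify_and_rank <- function(records, lfc = 1) {
  p <- which(records$passed_filter)
  records$nuclear_enriched <- NA
  records$rank <- NA_integer_
  if (length(p)) {
    records$nuclear_enriched[p] <- records$L[p] > lfc
    ord <- p[order(-records$L[p], records$gene_id[p])]
    records$rank[ord] <- seq_along(ord)
  }
  records
}

#' Correlate transcript features with localization
#'
#' Pearson correlation of each transcript feature against the localization
#' statistic `L` over retained genes, using pairwise-complete observations
#' (genes with undefined splicing efficiency are dropped from the SE
#' correlations only). Raw two-sided p-values are reported together with
#' Benjamini-Hochberg adjusted q-values across the feature set. Least-squares
#' regressions of `L` and of `E` on GC content are also returned.
#'
#' @param records classified localization records.
#' @param features feature table from [compute_features()], matched by
#'   `gene_id`.
#' @param gc which GC definition enters the analysis: `"exonic"` (mature
#'   transcript sequence, default) or `"gene_body"` (genomic span).
#' @return list with elements `correlations` (data.frame: feature, n, r, p,
#'   q, constant flag), `regression` (data.frame: response, slope, intercept,
#'   r_squared, n), `gc_vs_expression` (data.frame: n, r, p for GC against
#'   `E`), and `gc_feature` (name of the GC column used).
#' @export
correlate_features <- function(records, features, gc = c("exonic", "gene_body")) {
  gc <- match.arg(gc)
  gc_col <- if (gc == "exonic") "gc_content" else "gene_body_gc"
  rec <- records[records$passed_filter, c("gene_id", "L", "E")]
  df <- merge(rec, features, by = "gene_id")
  feat_cols <- c(gc_col, "exon_count", "transcript_length",
                 "longest_exon_length", "exon_density", "gene_length",
                 "se_mean", "se_max", "se_min")
  rows <- lapply(feat_cols, function(fc) {
    x <- df[[fc]]; y <- df$L
    ok <- stats::complete.cases(x, y)
    n <- sum(ok)
    if (n < 3)
      return(data.frame(feature = fc, n = n, r = NA_real_, p = NA_real_,
                        constant = FALSE))
    if (stats::sd(x[ok]) == 0)
      return(data.frame(feature = fc, n = n, r = NA_real_, p = NA_real_,
                        constant = TRUE))
    ct <- stats::cor.test(x[ok], y[ok], method = "pearson",
                          alternative = "two.sided")
    data.frame(feature = fc, n = n, r = unname(ct$estimate),
               p = ct$p.value, constant = FALSE)
  })
  cors <- do.call(rbind, rows)
  cors$q <- stats::p.adjust(cors$p, method = "BH")
  cors <- cors[, c("feature", "n", "r", "p", "q", "constant")]

  reg <- do.call(rbind, lapply(c("L", "E"), function(resp) {
    ok <- stats::complete.cases(df[[gc_col]], df[[resp]])
    fit <- stats::lm(df[[resp]][ok] ~ df[[gc_col]][ok])
    data.frame(response = resp,
               slope = unname(stats::coef(fit)[2]),
               intercept = unname(stats::coef(fit)[1]),
               r_squared = summary(fit)$r.squared,
               n = sum(ok))
  }))
  # GC is additionally correlated with the expression statistic, mirroring
  # the coupled loss of expression of nuclear-trapped transcripts
  okE <- stats::complete.cases(df[[gc_col]], df$E)
  gcE <- if (sum(okE) >= 3 && stats::sd(df[[gc_col]][okE]) > 0) {
    ct <- stats::cor.test(df[[gc_col]][okE], df$E[okE], method = "pearson")
    data.frame(n = sum(okE), r = unname(ct$estimate), p = ct$p.value)
  } else {
    data.frame(n = sum(okE), r = NA_real_, p = NA_real_)
  }
  list(correlations = cors, regression = reg, gc_vs_expression = gcE,
       gc_feature = gc_col)
}

#' Biotype composition of detected and nuclear-enriched genes
#'
#' Fraction of each annotation biotype among (a) all retained ("detected")
#' genes and (b) the nuclear-enriched subset. Fractions within each set sum
#' to 1; if the enriched set is empty its fractions are `NA`.
#'
#' @param records classified localization records.
#' @param biotypes named character vector `gene_id -> biotype`, or a feature
#'   table with `gene_id` and `biotype` columns.
#' @return data.frame with `biotype`, `n_detected`, `frac_detected`,
#'   `n_enriched`, `frac_enriched`.
#' @export
biotype_composition <- function(records, biotypes) {
  if (is.data.frame(biotypes))
    biotypes <- stats::setNames(biotypes$biotype, biotypes$gene_id)
  det <- records$gene_id[records$passed_filter]
  if (!all(det %in% names(biotypes)))
    stopf("biotype unknown for %d retained gene(s)", sum(!det %in% names(biotypes)))
  enr <- records$gene_id[records$passed_filter & records$nuclear_enriched %in% TRUE]
  lv <- sort(unique(biotypes[det]))
  nd <- table(factor(biotypes[det], levels = lv))
  ne <- table(factor(biotypes[enr], levels = lv))
  data.frame(
    biotype = lv,
    n_detected = as.integer(nd),
    frac_detected = as.numeric(nd) / length(det),
    n_enriched = as.integer(ne),
    frac_enriched = if (length(enr)) as.numeric(ne) / length(enr) else NA_real_,
    stringsAsFactors = FALSE
  )
}
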