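#' Junction coverage rule for splicing efficiency
#'
#' An intron's splicing efficiency is only computed when all of its
#' junctions are covered by at least `min_reads` junction-spanning reads.
#' Under the default `"junction"` mode, coverage of each boundary junction
#' counts reads spanning it in either the spliced (exon-exon, `ee`) or the
#' unspliced (exon-intron) form: `ee + ei_donor >= min_reads` and
#' `ee + ei_acceptor >= min_reads`. The alternative `"per_count"` mode
#' requires every count category individually to reach `min_reads`.
#'
#' @param ee integer vector, reads spanning the exon-exon junction.
#' @param ei_donor integer vector, reads spanning the upstream exon-intron
#'   boundary.
#' @param ei_acceptor integer vector, reads spanning the intron-exon
#'   boundary.
#' @param min_reads minimum spanning reads per junction (default 10).
#' @param mode `"junction"` (default) or `"per_count"`.
#' @return Logical vector.
#' @export
coverage_ok <- function(ee, ei_donor, ei_acceptor, min_reads = 10,
                        mode = c("junction", "per_count")) {
  mode <- match.arg(mode)
  if (any(c(ee, ei_donor, ei_acceptor) < 0)) stopf("junction counts must be >= 0")
  if (mode == "junction") {
    (ee + ei_donor) >= min_reads & (ee + ei_acceptor) >= min_reads
  } else {
    ee >= min_reads & ei_donor >= min_reads & ei_acceptor >= min_reads
  }
}

#' Per-intron splicing efficiency
#'
#' The ratio of exon-exon junction reads over the sum of exon-exon and
#' exon-intron spanning reads. Each unspliced molecule contributes a read
#' opportunity at both intron boundaries, so under the default
#' `ei_mode = "average"` the two boundary counts are averaged before entering
#' the denominator: `SE = ee / (ee + (ei_donor + ei_acceptor) / 2)`.
#' `ei_mode = "sum"` uses the literal sum of both boundary counts.
#' Returns `NA` (undefined, not an error) for introns failing the coverage
#' rule of [coverage_ok()].
#'
#' @inheritParams coverage_ok
#' @param ei_mode aggregation of the two exon-intron boundary counts,
#'   `"average"` (default) or `"sum"`.
#' @param coverage_mode passed to [coverage_ok()].
#' @return Numeric vector in \[0, 1\], `NA` where coverage fails.
#' @export
intron_se <- function(ee, ei_donor, ei_acceptor, min_reads = 10,
                      ei_mode = c("average", "sum"),
                      coverage_mode = c("junction", "per_count")) {
  ei_mode <- match.arg(ei_mode)
  ok <- coverage_ok(ee, ei_donor, ei_acceptor, min_reads, match.arg(coverage_mode))
  ei <- if (ei_mode == "average") (ei_donor + ei_acceptor) / 2 else ei_donor + ei_acceptor
  se <- ifelse(ee + ei > 0, ee / (ee + ei), NA_real_)
  ifelse(ok, se, NA_real_)
}

#' Per-transcript splicing-efficiency summary
#'
#' Summarizes per-intron splicing efficiencies as the mean, maximum
#' (most efficiently spliced intron), and minimum (least efficiently spliced
#' intron), computed only over introns passing coverage. Transcripts with no
#' covered intron -- including single-exon transcripts, which have no
#' junction rows at all -- get `NA` summaries.
#'
#' @param junctions data.frame with columns `transcript_id`, `intron_index`,
#'   `ee`, `ei_donor`, `ei_acceptor`.
#' @param min_reads,ei_mode,coverage_mode see [intron_se()].
#' @return data.frame with one row per transcript: `transcript_id`,
#'   `n_introns`, `n_covered`, `se_mean`, `se_max`, `se_min`.
#' @export
summarize_se <- function(junctions, min_reads = 10,
                         ei_mode = c("average", "sum"),
                         coverage_mode = c("junction", "per_count")) {
  need <- c("transcript_id", "intron_index", "ee", "ei_donor", "ei_acceptor")
  if (!all(need %in% names(junctions)))
    stopf("junction table lacks column(s): %s",
          paste(setdiff(need, names(junctions)), collapse = ", "))
  se <- intron_se(junctions$ee, junctions$ei_donor, junctions$ei_acceptor,
                  min_reads, match.arg(ei_mode), match.arg(coverage_mode))
  sp <- split(se, junctions$transcript_id)
  out <- data.frame(
    transcript_id = names(sp),
    n_introns = vapply(sp, length, integer(1)),
    n_covered = vapply(sp, function(v) sum(!is.na(v)), integer(1)),
    se_mean = vapply(sp, function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE), numeric(1)),
    se_max = vapply(sp, function(v) if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE), numeric(1)),
    se_min = vapply(sp, function(v) if (all(is.na(v))) NA_real_ else min(v, na.rm = TRUE), numeric(1)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}
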