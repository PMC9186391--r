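test_that("peak assignment uses same-strand overlap and category priority", {
  txm <- toy_clip_txm()
  peaks <- GenomicRanges::GRanges(
    "chr1",
    IRanges::IRanges(c(1060, 1010, 1160, 3350, 2000, 1060),
                     c(1090, 1040, 1290, 3390, 2050, 1090)),
    strand = c("+", "+", "+", "-", "+", "-"))
  ann <- assign_peaks(peaks, txm)
  cat_ <- S4Vectors::mcols(ann$peaks)$category
  expect_equal(cat_[1], "CDS")            # fully inside CDS exon part
  expect_equal(cat_[2], "UTR5")           # exonic upstream of CDS, + strand
  expect_equal(cat_[3], "intron")         # in the exon gap
  expect_equal(cat_[4], "noncoding_exon") # lncRNA exon, - strand
  expect_equal(cat_[5], "intergenic")     # overlaps no gene
  expect_equal(cat_[6], "intergenic")     # right coords, wrong strand
  expect_equal(sum(ann$distribution$fraction), 1)
  expect_equal(S4Vectors::mcols(ann$peaks)$gene_id[1], "gc")
  expect_true(is.na(S4Vectors::mcols(ann$peaks)$gene_id[5]))
})

test_that("random peak sets match a brute-force interval-overlap oracle", {
  sim <- simulate_dataset(tiny_config(), seed = 3, genome = TRUE, clip = FALSE)
  txm <- sim$txm
  tr <- txm$transcripts
  set.seed(41)
  n_pk <- 150
  starts <- sample(seq_len(max(tr$gene_end)), n_pk)
  peaks <- GenomicRanges::GRanges("chrS",
                                  IRanges::IRanges(starts, starts + 39),
                                  strand = sample(c("+", "-"), n_pk, TRUE))
  ann <- assign_peaks(peaks, txm)

  # oracle: integer arithmetic over exon/CDS coordinates
  ov_len <- function(a1, a2, b1, b2) max(0, min(a2, b2) - max(a1, b1) + 1)
  prio <- c("CDS", "UTR5", "UTR3", "noncoding_exon", "intron")
  for (i in seq_len(n_pk)) {
    ps <- starts[i]; pe <- starts[i] + 39
    pstr <- as.character(GenomicRanges::strand(peaks))[i]
    ovs <- vapply(seq_len(nrow(tr)), function(j) {
      if (tr$strand[j] != pstr) return(0)
      ov_len(ps, pe, tr$gene_start[j], tr$gene_end[j])
    }, numeric(1))
    expected_gene <- if (all(ovs == 0)) NA_character_ else {
      cand <- which(ovs == max(ovs))
      sort(tr$gene_id[cand])[1]
    }
    expect_identical(S4Vectors::mcols(ann$peaks)$gene_id[i], expected_gene)
    if (is.na(expected_gene)) {
      expect_equal(S4Vectors::mcols(ann$peaks)$category[i], "intergenic")
      next
    }
    j <- match(expected_gene, tr$gene_id)
    ex <- txm$exons[[tr$transcript_id[j]]]
    exb <- cbind(GenomicRanges::start(ex), GenomicRanges::end(ex))
    cds <- txm$cds[[tr$transcript_id[j]]]
    w <- c(CDS = 0, UTR5 = 0, UTR3 = 0, noncoding_exon = 0, intron = 0)
    if (!is.null(cds) && length(cds)) {
      cmin <- min(GenomicRanges::start(cds)); cmax <- max(GenomicRanges::end(cds))
      for (r in seq_len(nrow(exb))) {
        w["CDS"] <- w["CDS"] + ov_len(ps, pe, max(exb[r, 1], cmin),
                                      min(exb[r, 2], cmax))
        left <- ov_len(ps, pe, exb[r, 1], min(exb[r, 2], cmin - 1))
        right <- ov_len(ps, pe, max(exb[r, 1], cmax + 1), exb[r, 2])
        if (tr$strand[j] == "+") {
          w["UTR5"] <- w["UTR5"] + left; w["UTR3"] <- w["UTR3"] + right
        } else {
          w["UTR5"] <- w["UTR5"] + right; w["UTR3"] <- w["UTR3"] + left
        }
      }
    } else {
      for (r in seq_len(nrow(exb)))
        w["noncoding_exon"] <- w["noncoding_exon"] + ov_len(ps, pe, exb[r, 1], exb[r, 2])
    }
    exonic <- sum(w[c("CDS", "UTR5", "UTR3", "noncoding_exon")])
    gene_ov <- ov_len(ps, pe, tr$gene_start[j], tr$gene_end[j])
    w["intron"] <- gene_ov - exonic
    expected_cat <- if (all(w == 0)) "intron" else prio[which.max(w[prio])]
    expect_identical(S4Vectors::mcols(ann$peaks)$category[i], expected_cat)
  }
})

test_that("metagene profile is exactly flat at 1 when CLIP equals input", {
  txm <- toy_clip_txm()
  set.seed(42)
  pos <- sample(1001:1450, 80, replace = TRUE)
  reads <- GenomicRanges::GRanges("chr1", IRanges::IRanges(pos, pos + 20),
                                  strand = "+")
  mg <- metagene_profile(reads, reads, txm, target_ids = "gc", bins = 20)
  expect_equal(mg$profile$value, rep(1, 20), tolerance = 1e-12)
})

test_that("metagene reflects planted 5' enrichment and mirrors minus-strand genes", {
  # 30 plus-strand single-exon genes; CLIP reads concentrated in the first
  # 10% of each gene, input uniform
  n_g <- 30; glen <- 1000
  tr <- data.frame(transcript_id = sprintf("t%02d", 1:n_g),
                   gene_id = sprintf("g%02d", 1:n_g), biotype = "lncRNA",
                   chrom = "chr1", strand = "+", tx_length = glen,
                   exon_count = 1L,
                   gene_start = (0:(n_g - 1)) * 2000 + 1,
                   gene_end = (0:(n_g - 1)) * 2000 + glen,
                   gene_length = glen)
  exl <- GenomicRanges::GRangesList(stats::setNames(lapply(1:n_g, function(i)
    GenomicRanges::GRanges("chr1",
                           IRanges::IRanges(tr$gene_start[i], tr$gene_end[i]),
                           strand = "+")), tr$transcript_id))
  txm <- tx_models(tr, exl, GenomicRanges::GRangesList())
  set.seed(43)
  mk_reads <- function(offsets) {
    gi <- rep(1:n_g, each = 40)
    pos <- tr$gene_start[gi] + offsets
    GenomicRanges::GRanges("chr1", IRanges::IRanges(pos, pos + 10),
                           strand = "+")
  }
  clip <- mk_reads(sample(0:99, 40 * n_g, TRUE))      # first 10% only
  input <- mk_reads(sample(0:(glen - 11), 40 * n_g, TRUE))
  mg <- metagene_profile(clip, input, txm, bins = 10)
  expect_equal(which.max(mg$profile$value), 1)
  expect_true(all(mg$profile$value[3:10] < 1))

  # mirror: relabel every gene minus-strand (same reads, strands flipped)
  tr2 <- tr; tr2$strand <- "-"
  exl2 <- exl
  for (i in seq_along(exl2)) GenomicRanges::strand(exl2[[i]]) <- "-"
  txm2 <- tx_models(tr2, exl2, GenomicRanges::GRangesList())
  flip_strand <- function(gr) { GenomicRanges::strand(gr) <- "-"; gr }
  mg2 <- metagene_profile(flip_strand(clip), flip_strand(input), txm2, bins = 10)
  expect_equal(mg2$profile$value, rev(mg$profile$value), tolerance = 1e-12)
})

test_that("genes without input reads are excluded and counted", {
  txm <- toy_clip_txm()
  r_gc <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1060, 1080),
                                 strand = "+")
  mg <- metagene_profile(r_gc, r_gc, txm, target_ids = c("gc", "gn"),
                         bins = 10)
  expect_equal(mg$n_genes, 1)
  expect_equal(mg$n_excluded, 1)
})

test_that("KS shift test degenerates to D = 0 for identical groups and is transform-invariant", {
  genes <- sprintf("g%02d", 1:40)
  L <- rep(c(-1, -0.3, 0.2, 0.8, 1.5), 8)
  m <- mean_mat(genes, 10, 10, 10, 10, 10 * 2^L, 10)
  rec <- classify_and_rank(localization(fake_fpkm_set(m), genes))
  # targets hold the same L multiset as nontargets
  targets <- genes[1:20]
  expect_equal(target_shift_test(rec, targets)$D, 0, tolerance = 1e-12)

  # monotone transform of L leaves D unchanged
  set.seed(44)
  m2 <- mean_mat(genes, 10, 10, 10, 10, 10 * 2^rnorm(40), 10)
  rec2 <- classify_and_rank(localization(fake_fpkm_set(m2), genes))
  t2 <- sample(genes, 15)
  d_raw <- target_shift_test(rec2, t2)$D
  rec3 <- rec2
  rec3$L <- exp(rec2$L) + 5
  expect_equal(target_shift_test(rec3, t2)$D, d_raw, tolerance = 1e-12)

  expect_error(target_shift_test(rec2, "g01"), "at least 2")
})

test_that("a constant localization shift moves KS toward the implied separation", {
  set.seed(45)
  n <- 400
  genes <- sprintf("g%04d", 1:(2 * n))
  base <- rnorm(2 * n)
  delta <- 1
  Lv <- c(base[1:n], base[(n + 1):(2 * n)] + delta)
  m <- mean_mat(genes, 10, 10, 10, 10, 10 * 2^Lv, 10)
  rec <- classify_and_rank(localization(fake_fpkm_set(m), genes))
  res <- target_shift_test(rec, genes[(n + 1):(2 * n)])
  # closed-form oracle for N(0,1) vs N(delta,1): D = 2*pnorm(delta/2) - 1
  d_expected <- 2 * stats::pnorm(delta / 2) - 1
  expect_lt(abs(res$D - d_expected), 0.08)
  expect_lt(res$p, 1e-6)
})

test_that("peak GC enrichment computes sequence GC and rank-sum contrasts", {
  expect_equal(gc_fraction("GCGC"), 1.0)
  expect_equal(gc_fraction("GGCCAATT"), 0.5)
  expect_equal(gc_fraction("GCNNAT"), 0.5)  # N excluded from the denominator

  sim <- simulate_dataset(tiny_config(), seed = 9)
  ann <- assign_peaks(sim$clip$peaks, sim$txm, genome = sim$genome)
  res <- peak_gc_enrichment(ann$peaks, sim$txm, sim$genome)
  expect_setequal(res$gc$group,
                  c("peak", "bound_transcript", "background_transcript"))
  # planted peaks sit in the highest-GC windows: strong enrichment
  med <- function(g) res$summary$median[res$summary$group == g]
  expect_gt(med("peak"), med("background_transcript"))
  expect_lt(res$tests$p[res$tests$contrast == "peak vs background_transcript"],
            0.01)
  # identical distributions: two-sided rank-sum p near 1
  x <- res$gc$gc[res$gc$group == "peak"]
  expect_gt(suppressWarnings(stats::wilcox.test(x, x))$p.value, 0.9)
})
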