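test_that("localization and expression statistics follow the log-ratio formulas", {
  m <- mean_mat(c("g1", "g2", "g3"),
                wt_total = c(4, 6, 4), wt_nuc = c(3, 6, 3), wt_cyto = c(3, 6, 3),
                ko_total = c(4, 6, 2), ko_nuc = c(8, 6, 3), ko_cyto = c(2, 6, 3))
  rec <- localization(fake_fpkm_set(m), c("g1", "g2", "g3"))
  # KO nuc 8 / cyto 2 vs WT 3/3: L = log2(4) - log2(1) = 2
  expect_equal(rec$L[rec$gene_id == "g1"], 2.0)
  # identical FPKM in both genotypes: L = E = 0
  expect_equal(rec$L[rec$gene_id == "g2"], 0)
  expect_equal(rec$E[rec$gene_id == "g2"], 0)
  # KO total 2 vs WT total 4: E = -1
  expect_equal(rec$E[rec$gene_id == "g3"], -1.0)
  # non-retained genes carry undefined statistics
  rec2 <- localization(fake_fpkm_set(m), c("g1"))
  expect_true(is.na(rec2$L[rec2$gene_id == "g2"]))
})

test_that("swapping genotype labels negates L and E exactly", {
  set.seed(31)
  genes <- sprintf("g%02d", 1:30)
  m <- mean_mat(genes, runif(30, 2, 50), runif(30, 2, 50), runif(30, 2, 50),
                runif(30, 2, 50), runif(30, 2, 50), runif(30, 2, 50))
  swapped <- m[, c("KO.total", "KO.nuc", "KO.cyto",
                   "WT.total", "WT.nuc", "WT.cyto")]
  colnames(swapped) <- colnames(m)
  r1 <- localization(fake_fpkm_set(m), genes)
  r2 <- localization(fake_fpkm_set(swapped), genes)
  expect_equal(r2$L, -r1$L, tolerance = 1e-12)
  expect_equal(r2$E, -r1$E, tolerance = 1e-12)
})

test_that("non-positive FPKM reaching a log fails loudly", {
  m <- mean_mat("g1", 1, 0, 1, 1, 1, 1)
  expect_error(localization(fake_fpkm_set(m), "g1"), "non-positive")
})

test_that("enrichment classification is strict and ranks are a sort permutation", {
  m <- mean_mat(c("at", "above", "below"),
                wt_total = 4, wt_nuc = 2, wt_cyto = 2,
                ko_total = 4, ko_nuc = c(4, 4.2, 3.8), ko_cyto = 2)
  rec <- classify_and_rank(localization(fake_fpkm_set(m),
                                        c("at", "above", "below")))
  expect_equal(rec$L[rec$gene_id == "at"], 1.0)
  expect_false(rec$nuclear_enriched[rec$gene_id == "at"])  # L = 1 exactly
  expect_true(rec$nuclear_enriched[rec$gene_id == "above"])
  expect_false(rec$nuclear_enriched[rec$gene_id == "below"])

  set.seed(32)
  genes <- sprintf("g%03d", 1:100)
  nuc <- runif(100, 2, 40)
  m <- mean_mat(genes, 10, 10, 10, 10, nuc, 10)
  rec <- classify_and_rank(localization(fake_fpkm_set(m), genes))
  expect_setequal(rec$rank, 1:100)
  oracle <- order(-rec$L, rec$gene_id)
  expect_equal(rec$rank[oracle], 1:100)
  expect_equal(sum(rec$nuclear_enriched), sum(rec$L > 1))
  # rank 1 is the most nuclear-enriched gene
  expect_equal(rec$gene_id[rec$rank == 1], rec$gene_id[which.max(rec$L)])
})

test_that("feature correlations handle perfect, constant and missing cases", {
  genes <- sprintf("g%02d", 1:12)
  nuc <- 10 * 2^(seq(0.1, 1.2, by = 0.1))
  m <- mean_mat(genes, 10, 10, 10, 10, nuc, 10)
  rec <- classify_and_rank(localization(fake_fpkm_set(m), genes))
  feats <- data.frame(gene_id = genes, transcript_id = genes,
                      biotype = "protein_coding",
                      gc_content = seq(0.3, 0.74, by = 0.04),
                      exon_count = 5, transcript_length = 1:12 * 100,
                      longest_exon_length = 200, exon_density = 0.5,
                      gene_length = 1000, gene_body_gc = 0.5,
                      se_mean = c(runif(6), rep(NA, 6)), se_max = NA_real_,
                      se_min = NA_real_)
  # the GC fixture is an exact linear transform of L; summary.lm warns about
  # the perfect fit, which is the very case being checked
  rep_ <- suppressWarnings(correlate_features(rec, feats))
  cors <- rep_$correlations
  # gc is a perfect linear transform of L here
  expect_equal(cors$r[cors$feature == "gc_content"], 1.0, tolerance = 1e-9)
  # constant features are flagged, not an abort
  expect_true(cors$constant[cors$feature == "exon_count"])
  expect_true(is.na(cors$r[cors$feature == "exon_count"]))
  # undefined SE drops genes pairwise
  expect_equal(cors$n[cors$feature == "se_mean"], 6)
  expect_true(is.na(cors$r[cors$feature == "se_max"]))
  # regression of L on GC recovers the linear slope
  expect_equal(rep_$regression$slope[rep_$regression$response == "L"],
               0.1 / 0.04, tolerance = 1e-6)
  # BH adjustment never lowers a raw p
  ok <- !is.na(cors$p)
  expect_true(all(cors$q[ok] >= cors$p[ok] - 1e-15))
})

test_that("permuted features give near-zero correlation with uniform p-values", {
  set.seed(33)
  genes <- sprintf("g%04d", 1:400)
  nuc <- 10 * runif(400, 0.5, 2)
  m <- mean_mat(genes, 10, 10, 10, 10, nuc, 10)
  rec <- classify_and_rank(localization(fake_fpkm_set(m), genes))
  ps <- replicate(200, {
    x <- sample(rec$L)  # permutation breaks any association
    stats::cor.test(x, rec$L)$p.value
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
  rs <- replicate(50, stats::cor(sample(rec$L), rec$L))
  expect_lt(max(abs(rs)), 0.25)
})

test_that("biotype composition tallies detected and enriched sets", {
  m <- mean_mat(c("p1", "p2", "p3", "l1"),
                wt_total = 4, wt_nuc = 2, wt_cyto = 2,
                ko_total = 4, ko_nuc = c(2, 2, 2, 6), ko_cyto = 2)
  rec <- classify_and_rank(localization(fake_fpkm_set(m),
                                        c("p1", "p2", "p3", "l1")))
  bt <- c(p1 = "protein_coding", p2 = "protein_coding", p3 = "protein_coding",
          l1 = "lncRNA")
  comp <- biotype_composition(rec, bt)
  expect_equal(sum(comp$frac_detected), 1)
  expect_equal(comp$frac_detected[comp$biotype == "protein_coding"], 0.75)
  expect_equal(comp$frac_enriched[comp$biotype == "lncRNA"], 1)
  expect_equal(comp$frac_enriched[comp$biotype == "protein_coding"], 0)

  # empty enriched set: fractions undefined
  m0 <- mean_mat(c("p1", "l1"), 4, 2, 2, 4, 2, 2)
  rec0 <- classify_and_rank(localization(fake_fpkm_set(m0), c("p1", "l1")))
  comp0 <- biotype_composition(rec0, bt)
  expect_true(all(is.na(comp0$frac_enriched)))

  # random labeled fixture equals brute-force tally
  set.seed(34)
  genes <- sprintf("g%02d", 1:60)
  labs <- stats::setNames(sample(c("a", "b", "c"), 60, replace = TRUE), genes)
  mr <- mean_mat(genes, 10, 10, 10, 10, 10 * 2^runif(60, -2, 2), 10)
  recr <- classify_and_rank(localization(fake_fpkm_set(mr), genes))
  compr <- biotype_composition(recr, labs)
  enr <- recr$gene_id[recr$nuclear_enriched]
  for (b in compr$biotype) {
    expect_equal(compr$frac_detected[compr$biotype == b],
                 mean(labs[genes] == b))
    if (length(enr))
      expect_equal(compr$frac_enriched[compr$biotype == b],
                   mean(labs[enr] == b))
  }
})
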