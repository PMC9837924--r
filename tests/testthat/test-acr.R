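test_that("ACR taxonomy follows the position classification", {
  g <- toy_genome()
  peaks <- genomic_intervals(
    "chr1A",
    c(10100, 8500, 25000, 12100, 40100),
    c(10200, 8700, 25200, 12200, 40200),
    name = c("in_exon", "upstream2kb", "far", "downstream_g1",
             "in_g2_exon"))
  acr <- classify_acrs(peaks, g)
  got <- setNames(acr$category, acr$name)
  expect_equal(unname(got["in_exon"]), "gACR")
  expect_equal(unname(got["upstream2kb"]), "pACR")
  expect_equal(unname(got["far"]), "dACR")
  # downstream fold into dACR to keep the three-way partition
  expect_equal(unname(got["downstream_g1"]), "dACR")
  expect_true(is.na(acr$gene_id[acr$name == "downstream_g1"]))
  expect_equal(unname(got["in_g2_exon"]), "gACR")
  # partition: every peak labelled exactly once, dACR <=> no gene
  expect_equal(nrow(acr), nrow(peaks))
  expect_true(all(is.na(acr$gene_id) == (acr$category == "dACR")))
})

test_that("classification is invariant to input order", {
  sim <- cached_sim()
  peaks <- sim$atac_peaks[[3]]
  set.seed(9)
  perm <- sample(nrow(peaks))
  a1 <- classify_acrs(peaks, sim$genome)
  a2 <- classify_acrs(peaks[perm, ], sim$genome)
  expect_equal(a2$category, a1$category[perm])
  expect_equal(a2$gene_id, a1$gene_id[perm])
})

test_that("stage gain/loss counts overlap-free peaks", {
  p <- function(s, e) genomic_intervals("c", s, e)
  s1 <- p(100, 200)
  s2 <- rbind(p(120, 220), p(500, 600))  # first overlaps s1
  gl <- stage_gain_loss(list(a = s1, b = s2))
  expect_equal(gl$gained, 1L)
  expect_equal(gl$lost, 0L)
  same <- stage_gain_loss(list(a = s2, b = s2))
  expect_equal(same$gained, 0L)
  expect_equal(same$lost, 0L)
  expect_error(stage_gain_loss(list(a = s1, b = s2), stages = c("a", "z")),
               "unknown stage")
})

test_that("gain/loss agrees with the quadratic overlap oracle", {
  set.seed(10)
  for (i in 1:10) {
    a <- random_intervals(sample(5:40, 1), chroms = "c")
    b <- random_intervals(sample(5:40, 1), chroms = "c")
    gl <- stage_gain_loss(list(s1 = a, s2 = b))
    ov <- bf_overlap_pairs(b, a)
    expect_equal(gl$gained, nrow(b) - length(unique(ov$a_idx)))
    ov2 <- bf_overlap_pairs(a, b)
    expect_equal(gl$lost, nrow(a) - length(unique(ov2$a_idx)))
  }
})

test_that("transient calls partition the burst-stage set", {
  p <- function(s, e) genomic_intervals("c", s, e)
  s1 <- p(100, 200)
  s3 <- p(1000, 1100)
  s2 <- rbind(p(150, 250),    # overlaps s1 -> constant
              p(1050, 1150),  # overlaps s3 -> constant
              p(5000, 5100))  # neither -> transient
  tc <- transient_dacrs(s1, s2, s3)
  expect_equal(nrow(tc$transient), 1)
  expect_equal(tc$transient$start, 5000)
  expect_equal(nrow(tc$transient) + nrow(tc$constant), nrow(s2))
  set.seed(11)
  for (i in 1:5) {
    a <- random_intervals(20, chroms = "c")
    b <- random_intervals(20, chroms = "c")
    cc <- random_intervals(20, chroms = "c")
    tc <- transient_dacrs(a, b, cc)
    expect_equal(nrow(tc$transient) + nrow(tc$constant), 20)
  }
})

test_that("obs/exp enrichment handles the degenerate geometries", {
  dom <- genomic_intervals("c", 0, 10000)
  q <- genomic_intervals("c", seq(0, 900, 100), seq(50, 950, 100))
  # features saturate the domain -> ratio ~ 1
  sat <- obs_exp_enrichment(q, dom, dom, n_shuffles = 50, seed = 1)
  expect_equal(sat$obs_exp_ratio, 1, tolerance = 0.05)
  # no features anywhere -> observed 0, undefined 0/0 ratio
  none <- obs_exp_enrichment(q, genomic_intervals("c", 9990, 9991),
                             genomic_intervals("c", 0, 5000),
                             n_shuffles = 20, seed = 1)
  expect_equal(none$observed, 0)
})

test_that("constructed enrichment is detected as significant", {
  set.seed(12)
  hits <- 0
  for (s in 1:10) {
    # features on a tenth of the domain; query placed right on them
    dom <- genomic_intervals("c", 0, 100000)
    feat <- genomic_intervals("c", seq(0, 9000, 1000),
                              seq(100, 9100, 1000))
    q <- genomic_intervals("c", seq(0, 9000, 1000) + 20,
                           seq(0, 9000, 1000) + 60)
    r <- obs_exp_enrichment(q, feat, dom, n_shuffles = 50, seed = s)
    if (r$obs_exp_ratio >= 1 && r$p_value < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("the ncRNA filter drops any coding-gene overlap", {
  g <- toy_genome()
  tx <- genomic_intervals(
    "chr1A", c(10500, 25000, 39999, 9000), c(10600, 25500, 40000 + 1, 9100),
    name = c("inside_gene", "intergenic", "one_bp_in", "upstream"))
  kept <- ncrna_filter(tx, g)
  expect_setequal(kept$name, c("intergenic", "upstream"))
  # noncoding genes do not trigger removal
  g$genes$biotype <- "noncoding"
  expect_equal(nrow(ncrna_filter(tx, g)), nrow(tx))
})

test_that("collinear comparison applies the |log2FC| > 1 rule", {
  a <- c(10, 5, 0, 8)
  b <- c(40, 5, 0, 2)
  r <- collinear_signal_compare(a, b, pseudocount = 1e-9)
  expect_equal(r$status, c("Up", "Nc", "Nc", "Dn"))
  expect_equal(r$log2fc[1], 2, tolerance = 1e-6)
  expect_equal(r$log2fc[3], 0)
  expect_error(collinear_signal_compare(c(-1, 2), c(1, 2)), "negative")
})
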