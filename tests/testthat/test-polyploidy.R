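mk_triad_expr <- function(fracs, total = 300) {
  # one triad with the given A/B/D fractions, constant across 4 stages
  stages <- paste0("S", 1:4)
  prof <- rbind(a = rep(fracs[1] * total, 4),
                b = rep(fracs[2] * total, 4),
                d = rep(fracs[3] * total, 4))
  toy_stage_matrix(prof, stages)
}

tmap1 <- data.frame(triad_id = "t1", A = "a", B = "b", D = "d",
                    stringsAsFactors = FALSE)

test_that("triad classification recovers the documented centroids", {
  expect_equal(classify_triads(mk_triad_expr(c(1, 1, 1) / 3),
                               tmap1)$category, "balanced")
  expect_equal(classify_triads(mk_triad_expr(c(0.8, 0.1, 0.1)),
                               tmap1)$category, "A-dominant")
  expect_equal(classify_triads(mk_triad_expr(c(0.05, 0.475, 0.475)),
                               tmap1)$category, "A-suppressed")
  # the seven centroids classify to themselves
  cen <- embryodyn:::triad_centroids()
  for (k in seq_len(nrow(cen)))
    expect_equal(classify_triads(mk_triad_expr(cen[k, ]),
                                 tmap1)$category, rownames(cen)[k])
})

test_that("noisy fractions still recover the planted categories", {
  set.seed(25)
  cen <- embryodyn:::triad_centroids()
  n_ok <- 0; n_tot <- 0
  for (rep in 1:40) for (k in seq_len(nrow(cen))) {
    fr <- cen[k, ] + rnorm(3, 0, 0.05)
    fr <- pmax(fr, 0.001); fr <- fr / sum(fr)
    got <- classify_triads(mk_triad_expr(fr), tmap1)$category
    n_tot <- n_tot + 1
    n_ok <- n_ok + (got == rownames(cen)[k])
  }
  expect_gte(n_ok / n_tot, 0.95)
})

test_that("unexpressed and incomplete triads are handled", {
  low <- classify_triads(mk_triad_expr(c(1, 1, 1) / 3, total = 0.3),
                         tmap1)
  expect_false(low$expressed)
  expect_true(is.na(low$category))
  tm2 <- rbind(tmap1, data.frame(triad_id = "t2", A = "zz", B = "b",
                                 D = "d"))
  r <- classify_triads(mk_triad_expr(c(1, 1, 1) / 3), tm2)
  expect_equal(nrow(r), 1)
  expect_equal(attr(r, "skipped"), "t2")
})

test_that("triad fractions ignore library scale and input order", {
  sim <- cached_sim()
  r1 <- classify_triads(sim$tpm, sim$truth$triads)
  perm <- sample(nrow(sim$truth$triads))
  r2 <- classify_triads(sim$tpm, sim$truth$triads[perm, ])
  expect_equal(r2$category, r1$category[perm])
  scaled <- stage_matrix(unclass(sim$tpm) * 3.7, sm_stages(sim$tpm),
                         units = "TPM")
  r3 <- classify_triads(scaled, sim$truth$triads,
                        min_mean_tpm = 0.5 * 3.7)
  expect_equal(r3$fA, r1$fA, tolerance = 1e-12)
})

test_that("the balanced fraction peaks at the middle stages", {
  sim <- cached_sim()
  tc <- triad_balance_timecourse(sim$tpm, sim$truth$triads)
  f <- tc$fractions[, "balanced"]
  S <- length(f)
  mid <- mean(f[4:6]); early <- mean(f[1:2]); late <- mean(f[(S - 1):S])
  expect_gt(mid, early)
  expect_gt(mid, late)
  expect_equal(unname(rowSums(tc$fractions)), rep(1, S),
               tolerance = 1e-9)
})

test_that("divergence classification follows the correlation index", {
  stages <- paste0("S", 1:8)
  set.seed(26)
  prof <- matrix(runif(30 * 8, 1, 100), 30,
                 dimnames = list(paste0("g", 1:30), NULL))
  hexp <- toy_stage_matrix(prof, stages)
  anc <- toy_stage_matrix(prof, stages)
  r <- divergence_classify(hexp, anc, method = "threshold")
  expect_equal(r$r, rep(1, 30))
  expect_true(all(r$cluster == "conserved"))
  neg <- toy_stage_matrix(max(prof) - prof, stages)
  r2 <- divergence_classify(hexp, neg, method = "threshold")
  expect_equal(r2$r, rep(-1, 30))
  expect_true(all(r2$cluster == "dysfunction"))
})

test_that("k-means recovers the planted correlation groups", {
  sim <- cached_sim()
  dv <- divergence_classify(sim$tpm, sim$ancestor)
  truth <- sim$truth$divergence$label[
    match(dv$gene_id, sim$truth$divergence$gene_id)]
  agree <- mean(dv$cluster == truth, na.rm = TRUE)
  expect_gte(agree, 0.9)
  # identical rerun -> bitwise identical assignment
  dv2 <- divergence_classify(sim$tpm, sim$ancestor)
  expect_identical(dv$cluster, dv2$cluster)
})

test_that("TE window enrichment respects the boundary conventions", {
  # + strand gene with TSS at 10000; window [7000, 8500)
  genes <- data.frame(gene_id = c("a", "b"), chrom = "c",
                      strand = "+", start = c(10000, 50000),
                      end = c(11000, 51000), tss = c(10000, 50000),
                      tes = c(11000, 51000), biotype = "coding",
                      subgenome = NA, triad_id = NA,
                      stringsAsFactors = FALSE)
  te_at_edge <- genomic_intervals("c", 6500, 7001)  # 1 bp inside window
  g <- genome_annotation(c(c = 100000), genes, tes = te_at_edge)
  r <- te_promoter_enrichment("a", "b", g)
  expect_equal(r$freq_a, 1)
  expect_equal(r$freq_b, 0)
  # TE ending exactly at the window start does not count
  g2 <- genome_annotation(c(c = 100000), genes,
                          tes = genomic_intervals("c", 6500, 7000))
  r2 <- te_promoter_enrichment("a", "b", g2)
  expect_equal(r2$freq_a, 0)
  # identical sets -> p = 1
  expect_equal(te_promoter_enrichment("a", "a", g)$p_value, 1)
  expect_error(te_promoter_enrichment("a", "b", g, window = c(3000, 1500)),
               "degenerate window")
})

test_that("all-vs-none TE contrast matches enumeration", {
  genes <- data.frame(gene_id = paste0("g", 1:6), chrom = "c",
                      strand = "+",
                      start = seq(20000, 120000, length.out = 6),
                      end = seq(21000, 121000, length.out = 6),
                      tss = seq(20000, 120000, length.out = 6),
                      tes = seq(21000, 121000, length.out = 6),
                      biotype = "coding", subgenome = NA, triad_id = NA,
                      stringsAsFactors = FALSE)
  # TEs inside the windows of the first three genes only
  tes <- genomic_intervals("c", genes$tss[1:3] - 2500,
                           genes$tss[1:3] - 2000)
  g <- genome_annotation(c(c = 200000), genes, tes = tes)
  r <- te_promoter_enrichment(paste0("g", 1:3), paste0("g", 4:6), g)
  expect_equal(r$p_value, oracle_fisher_p(3, 0, 0, 3, "greater"),
               tolerance = 1e-10)
  expect_true(is.infinite(r$odds_ratio))
})
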