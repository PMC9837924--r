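mk_acrs <- function(n, chrom = "c", start0 = 0, width = 100, gap = 400,
                    genes = NULL) {
  s <- start0 + (seq_len(n) - 1) * (width + gap)
  data.frame(chrom = chrom, start = s, end = s + width,
             name = paste0("acr", seq_len(n)), score = NA, strand = ".",
             acr_id = paste0("acr", seq_len(n)), category = "pACR",
             position = "promoter",
             gene_id = if (is.null(genes)) paste0("g", seq_len(n))
               else genes,
             stringsAsFactors = FALSE)
}

hit_in <- function(acrs, idx, motif, tf) {
  data.frame(motif_id = motif, tf_gene_id = tf,
             chrom = acrs$chrom[idx], start = acrs$start[idx] + 10,
             end = acrs$start[idx] + 20, score = 1,
             stringsAsFactors = FALSE)
}

test_that("motif enrichment matches enumeration and rejects the null", {
  acrs <- mk_acrs(100)
  cl <- acrs[1:5, ]; bg <- acrs[6:100, ]
  hits <- hit_in(acrs, 1:5, "M1", "tfA")
  r <- motif_enrichment(cl, bg, hits)
  expect_equal(nrow(r), 1)
  expect_equal(r$p_value, oracle_fisher_p(5, 0, 0, 95, "greater"),
               tolerance = 1e-10)
  # equal rates cluster vs background: never retained
  set.seed(23)
  retained <- 0
  for (i in 1:20) {
    idx <- sample(100, 20)  # 20% everywhere
    h2 <- hit_in(acrs, idx, "M2", "tfB")
    r2 <- motif_enrichment(acrs[1:20, ], acrs[21:100, ], h2)
    retained <- retained + nrow(r2)
  }
  expect_equal(retained, 0)
  # motif with no hit in any ACR is skipped, logged
  far <- data.frame(motif_id = "M3", tf_gene_id = "tfC", chrom = "z",
                    start = 0, end = 10, score = 1)
  r3 <- motif_enrichment(cl, bg, rbind(hits, far))
  expect_equal(attr(r3, "skipped"), "M3")
  expect_error(motif_enrichment(cl[0, ], bg, hits), "empty cluster")
})

test_that("TF-target linking filters by co-expression", {
  stages <- paste0("S", 1:8)
  up <- 10 * plogis((seq(0, 10, length.out = 8) - 5) / 0.8)
  prof <- rbind(tf1 = up, t1 = up, t2 = rev(up), tfconst = rep(5, 8))
  expr <- toy_stage_matrix(prof, stages)
  acrs <- mk_acrs(3, genes = c("t1", "t2", "tfconst"))
  hits <- rbind(hit_in(acrs, 1, "M1", "tf1"),
                hit_in(acrs, 2, "M1", "tf1"),
                hit_in(acrs, 3, "Mc", "tfconst"))
  edges <- link_tf_targets(NULL, hits, acrs, expr)
  # identical profile: retained with r = 1
  expect_equal(edges$target_gene_id, "t1")
  expect_equal(edges$r, 1, tolerance = 1e-9)
  # anti-correlated target rejected under positive_only
  expect_false("t2" %in% edges$target_gene_id)
  e2 <- link_tf_targets(NULL, hits, acrs, expr, positive_only = FALSE)
  expect_setequal(e2$target_gene_id, c("t1", "t2"))
  # constant TF profile -> undefined correlation -> dropped
  expect_false("tfconst" %in% e2$tf_gene_id)
})

test_that("edge retention is monotone in alpha and order-invariant", {
  sim <- cached_sim()
  merged <- merge_intervals(do.call(rbind, sim$atac_peaks))
  merged$name <- sprintf("ACR%05d", seq_len(nrow(merged)))
  acrs <- classify_acrs(merged, sim$genome)
  e1 <- link_tf_targets(NULL, sim$motif_hits, acrs, sim$tpm,
                        alpha = 0.01)
  e2 <- link_tf_targets(NULL, sim$motif_hits, acrs, sim$tpm,
                        alpha = 0.05)
  key <- function(d) paste(d$tf_gene_id, d$target_gene_id)
  expect_true(all(key(e1) %in% key(e2)))
  set.seed(24)
  hp <- sim$motif_hits[sample(nrow(sim$motif_hits)), ]
  ap <- acrs[sample(nrow(acrs)), ]
  e3 <- link_tf_targets(NULL, hp, ap, sim$tpm, alpha = 0.05)
  expect_equal(e3[, c("tf_gene_id", "target_gene_id", "r", "p_value")],
               e2[, c("tf_gene_id", "target_gene_id", "r", "p_value")],
               ignore_attr = TRUE)
})

test_that("module collapsing conserves edges and names singletons", {
  edges <- data.frame(
    tf_gene_id = c("myb1", "myb2", "wox1", "lone"),
    target_gene_id = c("g1", "g1", "g2", "g3"),
    acr_id = "a", motif_id = "m", r = 0.9, p_value = 0.01,
    stringsAsFactors = FALSE)
  fam <- c(myb1 = "MYBs", myb2 = "MYBs", wox1 = "WOXs")
  mods <- collapse_tf_modules(edges, fam)
  myb <- mods[mods$module == "MYBs", ]
  expect_equal(myb$weight, 2)
  expect_equal(myb$members, "myb1,myb2")
  expect_true("lone" %in% mods$module)
  expect_equal(sum(mods$weight), nrow(edges))
})

test_that("TF-TF subnetwork is a subset with cascade recovery", {
  sim <- cached_sim()
  merged <- merge_intervals(do.call(rbind, sim$atac_peaks))
  merged$name <- sprintf("ACR%05d", seq_len(nrow(merged)))
  acrs <- classify_acrs(merged, sim$genome)
  edges <- link_tf_targets(NULL, sim$motif_hits, acrs, sim$tpm)
  sub <- tf_tf_subnetwork(edges, sim$truth$tf_genes, expr = sim$tpm)
  key <- function(d) paste(d$tf_gene_id, d$target_gene_id)
  expect_true(all(key(sub$edges) %in% key(edges)))
  expect_true(all(sub$edges$target_gene_id %in% sim$truth$tf_genes))
  casc <- sim$truth$edges[sim$truth$edges$cascade, ]
  expect_gte(mean(key(casc) %in% key(sub$edges)), 0.8)
  # no TF targets any TF -> empty
  e0 <- edges[!edges$target_gene_id %in% sim$truth$tf_genes, ]
  expect_equal(nrow(tf_tf_subnetwork(e0, sim$truth$tf_genes)$edges), 0)
})
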