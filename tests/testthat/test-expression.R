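stages4 <- c("S1", "S2", "S3", "S4")

test_that("TPM normalization follows the per-column definition", {
  m <- matrix(c(10, 10), 2, 1,
              dimnames = list(c("g1", "g2"), "S1.1"))
  sm <- stage_matrix(m, "S1", units = "counts")
  tpm <- tpm_normalize(sm, c(g1 = 1000, g2 = 2000))
  expect_equal(unname(tpm[, 1]), c(2e6 / 3, 1e6 / 3), tolerance = 1e-6)
  single <- tpm_normalize(stage_matrix(
    matrix(7, 1, 1, dimnames = list("g", "S1.1")), "S1"), c(g = 500))
  expect_equal(unname(single[1, 1]), 1e6)
  set.seed(13)
  mm <- matrix(rpois(40, 50), 10,
               dimnames = list(paste0("g", 1:10),
                               paste(rep(stages4, each = 1), 1,
                                     sep = ".")))
  t2 <- tpm_normalize(stage_matrix(mm, stages4),
                      setNames(runif(10, 200, 5000), paste0("g", 1:10)))
  expect_equal(unname(colSums(t2)), rep(1e6, 4), tolerance = 1e-6)
  expect_error(tpm_normalize(sm, c(g1 = 0, g2 = 100)), "zero gene length")
})

test_that("DEG calls obey the fold-change and FDR thresholds", {
  set.seed(14)
  n <- 400
  mu <- runif(n, 20, 200)
  a <- sapply(1:3, function(i) rnbinom(n, mu = mu, size = 300))
  up <- 1:40
  mu2 <- mu; mu2[up] <- mu[up] * 4
  b <- sapply(1:3, function(i) rnbinom(n, mu = mu2, size = 300))
  rownames(a) <- rownames(b) <- paste0("g", 1:n)
  d <- call_degs(a, b)
  expect_gte(mean(d$status[up] == "Up"), 0.95)
  expect_gte(mean(d$status[-up] == "Nc"), 0.99)
  # invariant: status consistent with its own thresholds
  expect_true(all((d$status == "Up") ==
                    (d$log2fc >= 1 & d$fdr <= 0.05)))
  expect_error(call_degs(a[, 1, drop = FALSE], b), ">= 2 replicates")
})

test_that("DEG status counts ignore gene and replicate order", {
  set.seed(15)
  a <- matrix(rnbinom(60, mu = 50, size = 20), 20,
              dimnames = list(paste0("g", 1:20), NULL))
  b <- matrix(rnbinom(60, mu = 80, size = 20), 20,
              dimnames = list(paste0("g", 1:20), NULL))
  d1 <- table(call_degs(a, b)$status)
  perm <- sample(20)
  d2 <- table(call_degs(a[perm, ], b[perm, c(2, 3, 1)])$status)
  expect_equal(d1, d2)
})

test_that("set overlap test matches the hypergeometric oracle", {
  u <- paste0("g", 1:40)
  a <- u[1:4]; b <- u[1:8]
  r <- set_overlap_test(a, b, u)
  expect_equal(r$p_value, oracle_fisher_p(4, 0, 4, 32, "greater"),
               tolerance = 1e-10)
  # maximal overlap: fold = |U| / |A|
  r2 <- set_overlap_test(u[1:4], u[1:4], u)
  expect_equal(r2$fold_enrichment, 10)
  expect_lt(r2$p_value, 0.05)
  # disjoint halves: fold < 1
  r3 <- set_overlap_test(u[1:20], u[21:40], u)
  expect_lt(r3$fold_enrichment, 1)
  expect_error(set_overlap_test(c(a, "zz"), b, u), "subsets")
})

test_that("binned fold-change correlation partitions and correlates", {
  set.seed(16)
  fc <- setNames(rnorm(1000), paste0("g", 1:1000))
  r <- binned_fc_correlation(fc, fc, n_bins = 50)
  expect_true(all(r$bins$n == 20))
  expect_equal(r$test$r, 1)
  rneg <- binned_fc_correlation(fc, -fc, n_bins = 50)
  expect_equal(rneg$test$r, -1)
  # remainder goes to the earlier bins
  fc7 <- setNames(rnorm(103), paste0("g", 1:103))
  r7 <- binned_fc_correlation(fc7, fc7, n_bins = 10)
  expect_equal(r7$bins$n, c(11, 11, 11, rep(10, 7)))
  expect_error(binned_fc_correlation(fc7, fc7, n_bins = 200),
               "more bins than genes")
})

test_that("n_bins = n_genes reduces to per-gene correlation", {
  set.seed(17)
  fc <- setNames(rnorm(60), paste0("g", 1:60))
  y <- setNames(rnorm(60), paste0("g", 1:60))
  r <- binned_fc_correlation(fc, y, n_bins = 60)
  o <- order(fc, names(fc))
  expect_equal(r$test$r, cor(fc[o], y[o]))
})

test_that("synchronization applies the three-condition rule", {
  stages <- paste0("S", 1:8)
  step <- function(k) c(rep(0, k), rep(10, 8 - k))
  prof <- rbind(sync0 = step(5), late2 = step(7), flat = rep(3, 8))
  rna <- toy_stage_matrix(prof, stages)
  acc_prof <- rbind(sync0 = step(5), late2 = step(5), flat = rep(3, 8))
  acc <- toy_stage_matrix(acc_prof, stages, units = "signal")
  r <- synchronization_detect(rna, acc, baseline_stage = "S1")
  d <- r$genes
  expect_true(d$synchronized[d$gene_id == "sync0"])
  expect_equal(d$lag[d$gene_id == "sync0"], 0)
  # RNA activates 2 stages after accessibility: rejected at lag limit 1
  expect_false(d$synchronized[d$gene_id == "late2"])
  expect_equal(d$lag[d$gene_id == "late2"], 2)
  expect_equal(r$excluded, "flat")
})

test_that("synchronization recalls the planted lag-coupled targets", {
  sim <- cached_sim()
  sy <- synchronization_detect(sim$tpm, sim$atac_signal,
                               baseline_stage = "DPA4")
  tg <- sim$truth$edges$target_gene_id[!sim$truth$edges$cascade]
  rec <- mean(sy$genes$synchronized[match(tg, sy$genes$gene_id)],
              na.rm = TRUE)
  expect_gte(rec, 0.8)
})

test_that("mark contribution is r-squared across genes per stage", {
  stages <- paste0("S", 1:4)
  set.seed(18)
  expr_prof <- matrix(runif(800, 0, 100), 200,
                      dimnames = list(paste0("g", 1:200), NULL))
  expr <- toy_stage_matrix(expr_prof, stages)
  # the mark equals log-expression -> contribution 1
  mk <- toy_stage_matrix(log2(expr_prof + 1), stages, units = "signal")
  ct <- mark_contribution(expr, list(m = mk))
  expect_equal(unname(ct["m", ]), rep(1, 4), tolerance = 1e-10)
  # an anti-correlated mark contributes identically
  mk2 <- toy_stage_matrix(max(log2(expr_prof + 1)) - log2(expr_prof + 1),
                          stages, units = "signal")
  ct2 <- mark_contribution(expr, list(m = mk2))
  expect_equal(ct2, ct, ignore_attr = TRUE)
  # an independent mark contributes ~ nothing (n = 2000 genes)
  big_prof <- matrix(runif(8000, 0, 100), 2000,
                     dimnames = list(paste0("h", 1:2000), NULL))
  noise_prof <- matrix(runif(8000, 0, 100), 2000,
                       dimnames = list(paste0("h", 1:2000), NULL))
  ct3 <- mark_contribution(toy_stage_matrix(big_prof, stages),
                           list(m = toy_stage_matrix(noise_prof, stages,
                                                     units = "signal")))
  expect_true(all(ct3 < 0.01))
})
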