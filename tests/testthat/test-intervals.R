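test_that("BED parsing follows the BED6/narrowPeak conventions", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1A\t0\t100\tp1\t5\t+", f)
  x <- read_bed(f)
  expect_equal(x$chrom, "chr1A")
  expect_equal(x$start, 0)
  expect_equal(x$end, 100)
  expect_equal(x$name, "p1")
  expect_equal(x$score, 5)
  expect_equal(x$strand, "+")

  writeLines("chr1A\t100\t100", f)
  expect_error(read_bed(f), "zero-length interval")
  writeLines(c("chr1A\t0\t100", "chr1A\t5"), f)
  expect_error(read_bed(f), "line 2")

  np <- paste("chr1A", 10, 400, "peak1", 100, ".", 8.5, 3.2, 2.9, 180,
              sep = "\t")
  writeLines(np, f)
  x <- read_bed(f)
  expect_equal(x$signalValue, 8.5)
  expect_equal(x$peak, 180L)
})

test_that("write/read round-trips 50 random intervals", {
  set.seed(1)
  x <- random_intervals(50)
  x$name <- paste0("iv", seq_len(50))
  x$score <- round(runif(50), 3)
  x$strand <- sample(c("+", "-", "."), 50, replace = TRUE)
  f <- withr::local_tempfile(fileext = ".bed")
  write_bed(x, f)
  y <- read_bed(f)
  xs <- x[order(x$chrom, x$start, x$end, x$name), ]
  rownames(xs) <- rownames(y) <- NULL
  expect_equal(y, xs)
})

test_that("interval construction enforces the invariants", {
  expect_error(genomic_intervals("c", 5, 5), "zero-length")
  expect_error(genomic_intervals("c", -1, 5), "negative start")
  expect_error(genomic_intervals("", 0, 5), "empty chromosome")
  expect_error(genomic_intervals("c", 0, 5, strand = "x"), "strand")
})

test_that("overlap honours the 1-bp rule and half-open coordinates", {
  a <- genomic_intervals("c", 0, 100)
  expect_equal(overlap_pairs(a, genomic_intervals("c", 99, 200)),
               data.frame(a_idx = 1L, b_idx = 1L),
               ignore_attr = TRUE)
  expect_equal(nrow(overlap_pairs(a, genomic_intervals("c", 100, 200))),
               0)
  b2 <- genomic_intervals("c", 95, 200)
  expect_equal(nrow(overlap_pairs(a, b2, min_overlap_bp = 6)), 0)
  expect_equal(nrow(overlap_pairs(a, b2, min_overlap_bp = 5)), 1)
})

test_that("overlap matches a quadratic scan on random instances", {
  set.seed(7)
  for (i in 1:25) {
    a <- random_intervals(sample(1:50, 1))
    b <- random_intervals(sample(1:50, 1))
    got <- overlap_pairs(a, b)
    want <- bf_overlap_pairs(a, b)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("merge and subtract agree with base-coverage brute force", {
  set.seed(8)
  for (i in 1:25) {
    a <- random_intervals(sample(1:40, 1))
    b <- random_intervals(sample(1:40, 1))
    gm <- merge_intervals(a)[, c("chrom", "start", "end")]
    wm <- bf_merge(a)
    rownames(gm) <- NULL
    expect_equal(gm, wm)
    gs <- subtract_intervals(a, b)[, c("chrom", "start", "end")]
    ws <- bf_subtract(a, b)
    rownames(gs) <- NULL
    expect_equal(gs, ws)
  }
})

test_that("shuffling preserves lengths, stays in-domain, is seeded", {
  x <- genomic_intervals("c", c(0, 500), c(100, 700),
                         name = c("a", "b"))
  dom <- genomic_intervals("c", 2000, 12000)
  sh <- shuffle_intervals(x, dom, seed = 5, n_shuffles = 20)
  expect_length(sh, 20)
  for (s in sh) {
    expect_setequal(s$end - s$start, c(100, 200))
    expect_true(all(s$start >= 2000 & s$end <= 12000))
  }
  sh2 <- shuffle_intervals(x, dom, seed = 5, n_shuffles = 20)
  expect_identical(sh, sh2)

  long <- genomic_intervals("c", 0, 500, name = "big")
  small_dom <- genomic_intervals("c", c(0, 300), c(100, 500))
  expect_error(shuffle_intervals(long, small_dom, seed = 1),
               "longer than every domain segment")
})

test_that("empirical shuffle overlap matches the analytic placement law", {
  # one query of length L into one segment of width W; a fixed feature
  # occupies [f0, f1). P(overlap) = (# start positions giving >=1 shared
  # base) / (W - L + 1)
  L <- 100; W <- 10000; f0 <- 4000; f1 <- 4500
  dom <- genomic_intervals("c", 0, W)
  feat <- genomic_intervals("c", f0, f1)
  q <- genomic_intervals("c", 0, L)
  n <- 4000
  sh <- shuffle_intervals(q, dom, seed = 33, n_shuffles = n)
  starts <- vapply(sh, function(s) s$start, 0)
  p_hat <- mean(starts > f0 - L & starts < f1)
  feasible <- W - L + 1
  p_true <- ((f1 - f0) + L - 1) / feasible
  se <- sqrt(p_true * (1 - p_true) / n)
  expect_lt(abs(p_hat - p_true), 3 * se)
})

test_that("different seeds explore a sparse domain", {
  x <- genomic_intervals("c", seq(0, 900, 100), seq(50, 950, 100))
  dom <- genomic_intervals("c", 0, 1e6)
  sh <- lapply(1:6, function(s)
    shuffle_intervals(x, dom, seed = s, n_shuffles = 1)[[1]])
  jac <- c()
  for (i in 1:5) for (j in (i + 1):6) {
    inter <- covered_bp(rbind(sh[[i]], sh[[j]])[
      overlaps_any(rbind(sh[[i]], sh[[j]]), sh[[i]]) &
        overlaps_any(rbind(sh[[i]], sh[[j]]), sh[[j]]), ])
    uni <- covered_bp(rbind(sh[[i]], sh[[j]]))
    jac <- c(jac, inter / uni)
  }
  expect_lt(mean(jac), 0.5)
})
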