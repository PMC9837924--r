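# Independent brute-force oracles used to check the package's interval
# algebra and statistical primitives. These deliberately avoid the code
# paths (GenomicRanges, stats::fisher.test, ...) they are checking.

# O(n*m) overlap scan on 0-based half-open intervals
bf_overlap_pairs <- function(a, b, min_overlap_bp = 1) {
  out <- list()
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    if (a$chrom[i] != b$chrom[j]) next
    shared <- min(a$end[i], b$end[j]) - max(a$start[i], b$start[j])
    if (shared >= min_overlap_bp)
      out[[length(out) + 1]] <- c(i, j)
  }
  if (!length(out)) return(data.frame(a_idx = integer(),
                                      b_idx = integer()))
  m <- do.call(rbind, out)
  d <- data.frame(a_idx = m[, 1], b_idx = m[, 2])
  d[order(d$a_idx, d$b_idx), ]
}

# base-coverage merge: mark covered positions per chromosome
bf_merge <- function(x) {
  out <- list()
  for (ch in sort(unique(x$chrom))) {
    xi <- x[x$chrom == ch, ]
    lim <- max(xi$end)
    cov <- logical(lim)
    for (i in seq_len(nrow(xi)))
      cov[(xi$start[i] + 1):xi$end[i]] <- TRUE
    r <- rle(cov)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values
    if (any(keep))
      out[[ch]] <- data.frame(chrom = ch, start = starts[keep],
                              end = ends[keep])
  }
  d <- do.call(rbind, out)
  rownames(d) <- NULL
  d
}

bf_subtract <- function(a, b) {
  out <- list()
  for (ch in sort(unique(a$chrom))) {
    ai <- a[a$chrom == ch, ]
    bi <- b[b$chrom == ch, ]
    lim <- max(ai$end, if (nrow(bi)) bi$end else 0)
    cov <- logical(lim)
    for (i in seq_len(nrow(ai))) cov[(ai$start[i] + 1):ai$end[i]] <- TRUE
    for (i in seq_len(nrow(bi))) cov[(bi$start[i] + 1):bi$end[i]] <- FALSE
    r <- rle(cov)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values
    if (any(keep))
      out[[ch]] <- data.frame(chrom = ch, start = starts[keep],
                              end = ends[keep])
  }
  d <- do.call(rbind, out)
  if (is.null(d)) return(data.frame(chrom = character(),
                                    start = numeric(), end = numeric()))
  rownames(d) <- NULL
  d
}

random_intervals <- function(n, chroms = c("c1", "c2"), max_pos = 1000,
                             max_len = 60) {
  start <- sample.int(max_pos, n, replace = TRUE) - 1
  len <- sample.int(max_len, n, replace = TRUE)
  genomic_intervals(sample(chroms, n, replace = TRUE), start,
                    start + len)
}

# full hypergeometric enumeration for a 2x2 table (a b / c d) with fixed
# margins; two-sided sums probabilities <= observed (with tolerance)
oracle_fisher_p <- function(a, b, c, d,
                            alternative = "two.sided", tol = 1e-7) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- dhyper(support, c1, n - c1, r1)
  p_obs <- dhyper(a, c1, n - c1, r1)
  switch(alternative,
         two.sided = sum(probs[probs <= p_obs * (1 + tol)]),
         greater = sum(probs[support >= a]),
         less = sum(probs[support <= a]))
}

# exact Mann-Whitney p by enumerating all label assignments
oracle_mwu_p <- function(x, y, alternative = "two.sided") {
  pooled <- c(x, y)
  n <- length(pooled); nx <- length(x)
  combs <- utils::combn(n, nx)
  u_of <- function(idx) {
    xs <- pooled[idx]; ys <- pooled[-idx]
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  u_obs <- u_of(seq_len(nx))
  us <- apply(combs, 2, u_of)
  mu <- nx * (n - nx) / 2
  switch(alternative,
         two.sided = mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9),
         greater = mean(us >= u_obs - 1e-9),
         less = mean(us <= u_obs + 1e-9))
}

# textbook step-up BH
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in m:1) {
    val <- min(prev, p[o[i]] * m / i)
    q[o[i]] <- val
    prev <- val
  }
  q
}

# hand-coded tricube local polynomial regression (loess family):
# q = floor(span * n) nearest neighbours, tricube weights scaled by the
# q-th distance, weighted least squares of the given degree
oracle_loess <- function(x, y, x0, span = 0.75, degree = 2) {
  n <- length(x)
  q <- floor(span * n)
  vapply(x0, function(t) {
    d <- abs(x - t)
    dq <- sort(d)[q]
    w <- pmax(1 - pmin(d / dq, 1)^3, 0)^3
    X <- outer(x - t, 0:degree, "^")
    fit <- lm.wfit(X, y, w)
    fit$coefficients[1]
  }, 0)
}

# circular recovery score used by the pseudotime checks lives in the
# package itself (circular_rank_cor)
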