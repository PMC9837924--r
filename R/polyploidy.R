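triad_centroids <- function() {
  rbind(balanced = c(1, 1, 1) / 3,
        `A-dominant` = c(1, 0, 0),
        `B-dominant` = c(0, 1, 0),
        `D-dominant` = c(0, 0, 1),
        `A-suppressed` = c(0, 0.5, 0.5),
        `B-suppressed` = c(0.5, 0, 0.5),
        `D-suppressed` = c(0.5, 0.5, 0))
}

#' Classify homoeolog triad expression bias
#'
#' For each A/B/D triad the relative expression fractions are computed
#' from member TPM (at one stage, or pooled over all stages) and assigned
#' to the nearest (Euclidean) of seven centroids: balanced (1/3, 1/3,
#' 1/3), the three single-subgenome dominant unit vectors, and the three
#' suppressed centroids (0, 1/2, 1/2) and permutations. A triad is
#' `expressed` when the mean TPM over its members reaches `min_mean_tpm`;
#' unexpressed triads get no category. Distance ties resolve to
#' balanced.
#'
#' @param expr A `"stage_matrix"` of TPM.
#' @param triad_map `data.frame` with columns `triad_id`, `A`, `B`, `D`
#'   (gene ids).
#' @param stage A stage label, or `"pooled"` (default) for the mean over
#'   all stages.
#' @param min_mean_tpm Expression floor (default 0.5).
#' @return `data.frame` (`triad_id`, `stage`, `fA`, `fB`, `fD`,
#'   `expressed`, `category`); attribute `skipped` lists triads with a
#'   member missing from `expr`.
#' @export
classify_triads <- function(expr, triad_map, stage = "pooled",
                            min_mean_tpm = 0.5) {
  m <- stage_means(expr)
  prof <- if (identical(stage, "pooled")) rowMeans(m) else {
    if (!stage %in% colnames(m)) stop("unknown stage: ", stage)
    m[, stage]
  }
  ok <- triad_map$A %in% names(prof) & triad_map$B %in% names(prof) &
    triad_map$D %in% names(prof)
  skipped <- triad_map$triad_id[!ok]
  tm <- triad_map[ok, , drop = FALSE]
  vals <- cbind(prof[tm$A], prof[tm$B], prof[tm$D])
  mean_tpm <- rowMeans(vals)
  expressed <- mean_tpm >= min_mean_tpm & rowSums(vals) > 0
  fr <- vals / pmax(rowSums(vals), .Machine$double.eps)
  cen <- triad_centroids()
  category <- rep(NA_character_, nrow(tm))
  if (any(expressed)) {
    d2 <- sapply(seq_len(nrow(cen)), function(k)
      rowSums(sweep(fr[expressed, , drop = FALSE], 2, cen[k, ])^2))
    d2 <- matrix(d2, ncol = nrow(cen))
    # ties resolve to balanced: it is column 1 and which.min takes the
    # first minimum
    category[expressed] <- rownames(cen)[apply(d2, 1, which.min)]
  }
  out <- data.frame(triad_id = tm$triad_id,
                    stage = if (identical(stage, "pooled")) "pooled"
                      else stage,
                    fA = ifelse(expressed, fr[, 1], NA),
                    fB = ifelse(expressed, fr[, 2], NA),
                    fD = ifelse(expressed, fr[, 3], NA),
                    expressed = expressed, category = category,
                    stringsAsFactors = FALSE)
  attr(out, "skipped") <- skipped
  out
}

#' Per-stage triad bias category counts
#'
#' Runs [classify_triads()] at each stage and tabulates the seven bias
#' categories plus `not_expressed`; fractions are over expressed triads.
#'
#' @inheritParams classify_triads
#' @param stages Stage labels (default: the matrix stage vocabulary).
#' @return List with `counts` and `fractions` (stage x category
#'   matrices).
#' @export
triad_balance_timecourse <- function(expr, triad_map,
                                     stages = sm_stages(expr),
                                     min_mean_tpm = 0.5) {
  cats <- c(rownames(triad_centroids()), "not_expressed")
  counts <- matrix(0L, length(stages), length(cats),
                   dimnames = list(stages, cats))
  for (s in stages) {
    r <- classify_triads(expr, triad_map, stage = s,
                         min_mean_tpm = min_mean_tpm)
    lab <- ifelse(r$expressed, r$category, "not_expressed")
    t <- table(factor(lab, levels = cats))
    counts[s, ] <- as.integer(t)
  }
  expressed <- counts[, cats != "not_expressed", drop = FALSE]
  fractions <- expressed / pmax(rowSums(expressed), 1)
  list(counts = counts, fractions = fractions)
}

#' Classify hexaploid-versus-ancestor expression divergence
#'
#' Per gene pair, the Pearson correlation of the hexaploid and ancestor
#' stage-mean profiles indexes how well the embryogenesis expression
#' program is preserved; genes are grouped into `dysfunction`, `middle`
#' and `conserved` clusters either by 1-D k-means (k = 3, deterministic
#' Lloyd iterations initialized at the min/median/max of r, labels
#' ordered by cluster mean) or by fixed thresholds.
#'
#' @param hex_expr,anc_expr `"stage_matrix"` objects over the same
#'   stages.
#' @param pair_map `data.frame` with `gene_id`, `ancestor_id`; `NULL`
#'   matches shared rownames.
#' @param method `"kmeans"` (default) or `"threshold"`.
#' @param thresholds For threshold mode: `r < t1` dysfunction, `r > t2`
#'   conserved (default `c(0.25, 0.75)`).
#' @return `data.frame` (`gene_id`, `ancestor_id`, `r`, `cluster`);
#'   attribute `excluded` lists pairs with undefined correlation.
#' @export
divergence_classify <- function(hex_expr, anc_expr, pair_map = NULL,
                                method = c("kmeans", "threshold"),
                                thresholds = c(0.25, 0.75)) {
  method <- match.arg(method)
  if (is.null(pair_map)) {
    shared <- intersect(rownames(hex_expr), rownames(anc_expr))
    pair_map <- data.frame(gene_id = shared, ancestor_id = shared,
                           stringsAsFactors = FALSE)
  }
  mh <- stage_means(hex_expr); ma <- stage_means(anc_expr)
  if (ncol(mh) < 3) stop("divergence_classify: need >= 3 stages")
  r <- vapply(seq_len(nrow(pair_map)), function(i) {
    t <- pearson_test(mh[pair_map$gene_id[i], ],
                      ma[pair_map$ancestor_id[i], ])
    if (isTRUE(t$undefined)) NA_real_ else t$r
  }, 0)
  ok <- !is.na(r)
  excluded <- pair_map[!ok, , drop = FALSE]
  cluster <- rep(NA_character_, length(r))
  labels <- c("dysfunction", "middle", "conserved")
  if (method == "kmeans") {
    rv <- r[ok]
    init <- c(min(rv), stats::median(rv), max(rv))
    if (length(unique(init)) < 3)
      stop("divergence_classify: degenerate r distribution for k-means")
    km <- stats::kmeans(rv, centers = matrix(init, 3, 1),
                        algorithm = "Lloyd", iter.max = 100)
    lab <- labels[rank(km$centers[, 1])]
    cluster[ok] <- lab[km$cluster]
  } else {
    cluster[ok] <- ifelse(r[ok] < thresholds[1], "dysfunction",
                          ifelse(r[ok] > thresholds[2], "conserved",
                                 "middle"))
  }
  out <- data.frame(gene_id = pair_map$gene_id,
                    ancestor_id = pair_map$ancestor_id, r = r,
                    cluster = cluster, stringsAsFactors = FALSE)
  attr(out, "excluded") <- excluded
  out
}

#' TE enrichment in upstream promoter windows of a gene set
#'
#' A gene carries a TE in its window when at least one transposable
#' element overlaps (>= 1 bp) the strand-aware upstream window
#' `[TSS - hi, TSS - lo)` (default 1.5-3 kb upstream of the TSS). Set A
#' is tested against set B by Fisher exact test (alternative greater).
#'
#' @param gene_set_a,gene_set_b Character vectors of gene ids.
#' @param genome An `"embryodyn_genome"` (with a TE table).
#' @param window `c(lo, hi)` distances upstream of the TSS in bp
#'   (default `c(1500, 3000)`); `lo < hi` required.
#' @return An `"embryodyn_test"` with `freq_a`, `freq_b`, `n_a`, `n_b`.
#' @export
te_promoter_enrichment <- function(gene_set_a, gene_set_b, genome,
                                   window = c(1500, 3000)) {
  if (window[1] >= window[2])
    stop("te_promoter_enrichment: degenerate window (lo >= hi)")
  g <- genome$genes
  win_for <- function(ids) {
    gg <- g[match(ids, g$gene_id), ]
    if (anyNA(gg$gene_id)) stop("unknown gene id in set")
    plus <- gg$strand == "+"
    data.frame(chrom = gg$chrom,
               start = pmax(ifelse(plus, gg$tss - window[2],
                                   gg$tss + window[1]), 0),
               end = ifelse(plus, gg$tss - window[1],
                            gg$tss + window[2]),
               name = gg$gene_id, score = NA_real_, strand = ".",
               stringsAsFactors = FALSE)
  }
  has_te <- function(ids) {
    w <- win_for(ids)
    w <- w[w$end > w$start, , drop = FALSE]
    hit <- overlaps_any(w, genome$tes)
    sum(hit)
  }
  na <- length(gene_set_a); nb <- length(gene_set_b)
  ha <- has_te(gene_set_a); hb <- has_te(gene_set_b)
  ft <- fisher_exact(ha, na - ha, hb, nb - hb, alternative = "greater")
  test_result(statistic = ft$statistic, p_value = ft$p_value,
              alternative = "greater", method = ft$method,
              odds_ratio = ft$odds_ratio,
              freq_a = ha / na, freq_b = hb / nb, n_a = na, n_b = nb)
}
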