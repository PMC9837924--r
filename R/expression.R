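#' Construct a stage matrix
#'
#' Genes x (stage, replicate) numeric matrix with declared units. Columns
#' are named `STAGE.REP` (e.g. `DPA8.2`); the ordered stage vocabulary is
#' carried as an attribute so downstream code never has to guess the
#' developmental order.
#'
#' @param values Non-negative numeric matrix, rownames = gene ids,
#'   colnames = `STAGE.REP`.
#' @param stages Ordered character vector of stage labels.
#' @param units One of `"counts"`, `"TPM"`, `"signal"`.
#' @return The matrix with class `"stage_matrix"` and attributes `stages`
#'   and `units`.
#' @export
stage_matrix <- function(values, stages, units = c("counts", "TPM",
                                                   "signal")) {
  units <- match.arg(units)
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            !is.null(colnames(values)))
  if (any(values < 0)) stop("stage matrix values must be non-negative")
  cs <- col_stages(values)
  if (!all(cs %in% stages))
    stop("column stage(s) not in declared stage order: ",
         paste(setdiff(cs, stages), collapse = ", "))
  if (anyNA(values))
    stop("stage matrix has missing values: every (stage, replicate) ",
         "column must be complete")
  structure(values, stages = stages, units = units,
            class = c("stage_matrix", class(values)))
}

col_stages <- function(x) sub("\\.[^.]+$", "", colnames(x))

#' Stage labels of a stage matrix
#' @param x A `"stage_matrix"`.
#' @return Ordered character vector of stages.
#' @export
sm_stages <- function(x) attr(x, "stages")

#' Replicate-averaged stage profile matrix
#'
#' @param x A `"stage_matrix"` (or any matrix with `STAGE.REP` columns).
#' @param stages Ordered stage labels; defaults to the attribute.
#' @return Plain matrix genes x stages of replicate means.
#' @export
stage_means <- function(x, stages = attr(x, "stages")) {
  cs <- col_stages(x)
  if (is.null(stages)) stages <- unique(cs)
  out <- vapply(stages, function(s)
    rowMeans(x[, cs == s, drop = FALSE]), numeric(nrow(x)))
  if (nrow(x) == 1) out <- matrix(out, 1, dimnames = list(rownames(x),
                                                          stages))
  out
}

#' Write / read a stage matrix as TSV
#'
#' Plain `gene<TAB>STAGE.REP...` tables, the on-disk exchange format for
#' all expression and signal matrices.
#'
#' @param x A `"stage_matrix"`.
#' @param path File path.
#' @return `path` invisibly (write); a `"stage_matrix"` (read).
#' @export
write_stage_matrix <- function(x, path) {
  tab <- data.frame(gene = rownames(x), as.data.frame(unclass(x)),
                    check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_stage_matrix
#' @param stages Ordered stage labels (defaults to order of appearance).
#' @param units Units of the stored values.
#' @export
read_stage_matrix <- function(path, stages = NULL,
                              units = c("counts", "TPM", "signal")) {
  units <- match.arg(units)
  tab <- utils::read.delim(path, check.names = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  if (is.null(stages)) stages <- unique(col_stages(m))
  stage_matrix(m, stages, units)
}

#' TPM normalization
#'
#' Transcripts per kilobase million: per column, counts are divided by
#' gene length in kb and the rates rescaled to sum to 1e6.
#'
#' @param counts A `"stage_matrix"` of counts.
#' @param gene_lengths_bp Named (or aligned) vector of gene lengths, > 0.
#' @return A `"stage_matrix"` in TPM units; every column sums to 1e6.
#' @export
tpm_normalize <- function(counts, gene_lengths_bp) {
  if (!is.null(names(gene_lengths_bp)))
    gene_lengths_bp <- gene_lengths_bp[rownames(counts)]
  if (any(is.na(gene_lengths_bp)) || any(gene_lengths_bp <= 0))
    stop("tpm_normalize: missing or zero gene length")
  rate <- unclass(counts) / (gene_lengths_bp / 1000)
  tpm <- sweep(rate, 2, colSums(rate), "/") * 1e6
  stage_matrix(tpm, attr(counts, "stages"), units = "TPM")
}

#' Differential expression calls between two stages
#'
#' Per-gene Welch test on log2(x+1) replicate values
#' ([two_sample_log_test()]), BH-adjusted ([bh_fdr()]), with the standard
#' thresholds: `Up` if log2FC >= 1 and FDR <= 0.05, `Dn` if log2FC <= -1
#' and FDR <= 0.05, otherwise `Nc`.
#'
#' @param matrix_a,matrix_b Gene x replicate matrices (same genes) for the
#'   two stages; fold change is B relative to A.
#' @param lfc_min Absolute log2FC threshold (default 1).
#' @param fdr_max FDR threshold (default 0.05).
#' @return `data.frame` with `gene_id`, `log2fc`, `p_value`, `fdr`,
#'   `status`.
#' @export
call_degs <- function(matrix_a, matrix_b, lfc_min = 1, fdr_max = 0.05) {
  stopifnot(nrow(matrix_a) == nrow(matrix_b))
  if (ncol(matrix_a) < 2 || ncol(matrix_b) < 2)
    stop("call_degs: need >= 2 replicates per stage")
  res <- lapply(seq_len(nrow(matrix_a)), function(i)
    two_sample_log_test(matrix_a[i, ], matrix_b[i, ]))
  lfc <- vapply(res, `[[`, 0, "log2fc")
  p <- vapply(res, `[[`, 0, "p_value")
  fdr <- bh_fdr(p)
  status <- ifelse(fdr <= fdr_max & lfc >= lfc_min, "Up",
                   ifelse(fdr <= fdr_max & lfc <= -lfc_min, "Dn", "Nc"))
  data.frame(gene_id = rownames(matrix_a), log2fc = lfc, p_value = p,
             fdr = fdr, status = status, stringsAsFactors = FALSE)
}

#' Gene-set overlap test
#'
#' Fisher's exact test (alternative greater) on the 2x2 membership table
#' of two gene sets within a universe, plus the fold enrichment of the
#' observed intersection over the independence expectation.
#'
#' @param set_a,set_b Character vectors, subsets of `universe`.
#' @param universe Character vector of all eligible genes.
#' @return An `"embryodyn_test"` with `fold_enrichment`, `n_overlap` and
#'   `expected_overlap`.
#' @export
set_overlap_test <- function(set_a, set_b, universe) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  universe <- unique(universe)
  if (!all(set_a %in% universe) || !all(set_b %in% universe))
    stop("set_overlap_test: sets must be subsets of the universe")
  n_ab <- length(intersect(set_a, set_b))
  n_a <- length(set_a); n_b <- length(set_b); n_u <- length(universe)
  ft <- fisher_exact(n_ab, n_a - n_ab, n_b - n_ab,
                     n_u - n_a - n_b + n_ab, alternative = "greater")
  expected <- n_a * n_b / n_u
  test_result(statistic = ft$statistic, p_value = ft$p_value,
              alternative = "greater", method = ft$method,
              odds_ratio = ft$odds_ratio,
              fold_enrichment = if (expected > 0) n_ab / expected else NA,
              n_overlap = n_ab, expected_overlap = expected)
}

#' Binned fold-change correlation
#'
#' Genes are ranked by the primary fold change and split into `n_bins`
#' near-equal contiguous bins (earlier bins take the remainder); the
#' per-bin means of both metrics are correlated by Pearson test.
#'
#' @param fc_primary Named numeric vector (the ranking metric).
#' @param metric_secondary Named numeric vector on the same genes.
#' @param n_bins Number of bins (default 50, must be <= number of genes).
#' @return List with `bins` (`data.frame`: bin, n, mean_primary,
#'   mean_secondary) and `test` (an `"embryodyn_test"` with `r`).
#' @export
binned_fc_correlation <- function(fc_primary, metric_secondary,
                                  n_bins = 50) {
  stopifnot(!is.null(names(fc_primary)))
  metric_secondary <- metric_secondary[names(fc_primary)]
  if (anyNA(metric_secondary))
    stop("binned_fc_correlation: gene universes differ")
  n <- length(fc_primary)
  if (n_bins > n) stop("binned_fc_correlation: more bins than genes")
  o <- order(fc_primary, names(fc_primary))
  base <- n %/% n_bins
  sizes <- rep(base, n_bins)
  extra <- n - base * n_bins
  if (extra > 0) sizes[seq_len(extra)] <- base + 1
  bin <- rep(seq_len(n_bins), sizes)
  mp <- tapply(fc_primary[o], bin, mean)
  ms <- tapply(metric_secondary[o], bin, mean)
  list(bins = data.frame(bin = seq_len(n_bins), n = sizes,
                         mean_primary = as.numeric(mp),
                         mean_secondary = as.numeric(ms)),
       test = pearson_test(as.numeric(mp), as.numeric(ms)))
}

#' Detect genes whose expression and accessibility activate in sync
#'
#' Each gene's replicate-averaged stage profile is z-scored in both
#' modalities. The activation stage is the first stage after the baseline
#' where the z-score reaches `z_min`. A gene is synchronized iff both
#' modalities activate after baseline, the activation lag is at most
#' `max_lag` stages, and the Pearson correlation of the two z-profiles is
#' at least `r_min`. Constant profiles are excluded (reported in the
#' `excluded` component).
#'
#' @param rna,acc `"stage_matrix"` objects sharing genes and stage
#'   vocabulary (expression and promoter accessibility signal).
#' @param baseline_stage Stage label; activation is searched after it.
#' @param r_min Minimum z-profile correlation (default 0.8).
#' @param max_lag Maximum |activation lag| in stages (default 1).
#' @param z_min Activation z-score threshold (default 1).
#' @return List with `genes` (`data.frame`: gene_id, rna_stage,
#'   acc_stage, lag, r, synchronized) and `excluded` (gene ids with a
#'   constant profile).
#' @export
synchronization_detect <- function(rna, acc, baseline_stage,
                                   r_min = 0.8, max_lag = 1, z_min = 1) {
  stages <- sm_stages(rna)
  stopifnot(identical(stages, sm_stages(acc)))
  genes <- intersect(rownames(rna), rownames(acc))
  if (!baseline_stage %in% stages)
    stop("unknown baseline stage: ", baseline_stage)
  b <- match(baseline_stage, stages)
  mr <- stage_means(rna)[genes, , drop = FALSE]
  ma <- stage_means(acc)[genes, , drop = FALSE]
  const <- apply(mr, 1, stats::sd) == 0 | apply(ma, 1, stats::sd) == 0
  excluded <- genes[const]
  genes <- genes[!const]
  zr <- t(scale(t(mr[genes, , drop = FALSE])))
  za <- t(scale(t(ma[genes, , drop = FALSE])))
  act <- function(z) {
    idx <- which(z >= z_min)
    idx <- idx[idx > b]
    if (length(idx)) idx[1] else NA_integer_
  }
  sr <- apply(zr, 1, act)
  sa <- apply(za, 1, act)
  r <- vapply(seq_along(genes), function(i) {
    t <- pearson_test(zr[i, ], za[i, ])
    if (isTRUE(t$undefined)) NA_real_ else t$r
  }, 0)
  lag <- sr - sa
  sync <- !is.na(sr) & !is.na(sa) & abs(lag) <= max_lag &
    !is.na(r) & r >= r_min
  list(genes = data.frame(gene_id = genes,
                          rna_stage = stages[sr],
                          acc_stage = stages[sa],
                          lag = lag, r = r, synchronized = sync,
                          stringsAsFactors = FALSE),
       excluded = excluded)
}

#' Per-stage contribution of a chromatin mark to expression
#'
#' Operationalized as the squared Pearson correlation, across genes, of
#' the promoter mark signal with log2(TPM + 1) at each stage: a value in
#' \[0, 1\] that is symmetric for activating and repressive marks.
#'
#' @param expr `"stage_matrix"` of expression (TPM).
#' @param marks Named list of `"stage_matrix"` objects of promoter mark
#'   signal (same genes and stages), or a single such matrix.
#' @return Matrix marks x stages of r-squared values; attribute
#'   `definition` records the operationalization.
#' @export
mark_contribution <- function(expr, marks) {
  if (!is.list(marks)) marks <- list(mark = marks)
  stages <- sm_stages(expr)
  me <- stage_means(expr)
  if (nrow(me) < 3) stop("mark_contribution: need >= 3 genes")
  le <- log2(me + 1)
  out <- t(vapply(marks, function(m) {
    stopifnot(identical(sm_stages(m), stages))
    mm <- stage_means(m)[rownames(me), , drop = FALSE]
    vapply(seq_along(stages), function(s) {
      t <- pearson_test(mm[, s], le[, s])
      if (isTRUE(t$undefined)) NA_real_ else t$r^2
    }, 0)
  }, numeric(length(stages))))
  dimnames(out) <- list(names(marks), stages)
  attr(out, "definition") <-
    "squared Pearson r across genes, per stage, mark signal vs log2(TPM+1)"
  out
}
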