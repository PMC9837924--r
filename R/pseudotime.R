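#' Developmental time units from stage points in PC space
#'
#' Cumulative straight-line distance between consecutive stage points,
#' rescaled so the trajectory spans \[0, 10\].
#'
#' @param points Numeric matrix, one row per stage (ordered), columns =
#'   PC coordinates.
#' @return Numeric vector of DTU values: 0 at the first stage, 10 at the
#'   last, non-decreasing.
#' @export
dtu_from_points <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 3) stop("need >= 3 stage points")
  d <- sqrt(rowSums((points[-1, , drop = FALSE] -
                       points[-nrow(points), , drop = FALSE])^2))
  total <- sum(d)
  if (total == 0) stop("zero total path length: all stage points coincide")
  unname(c(0, cumsum(d)) / total * 10)
}

#' Pseudotime (DTU) trajectory of the stage series
#'
#' Per-gene z-scored stage-mean profiles are decomposed by PCA with the
#' stages as observations; the developmental time unit is the cumulative
#' Euclidean distance between consecutive stages in the first `n_pcs`
#' principal components, scaled to \[0, 10\].
#'
#' @param expr A `"stage_matrix"` (>= 3 stages).
#' @param n_pcs Number of PCs used for the distances (default 2).
#' @return A list of class `"stage_trajectory"`: `stages`, `pcs`
#'   (stage x n_pcs score matrix), `dtu`, and `excluded` (zero-variance
#'   genes dropped before the PCA).
#' @export
compute_dtu <- function(expr, n_pcs = 2) {
  stages <- sm_stages(expr)
  if (length(stages) < 3) stop("compute_dtu: need >= 3 stages")
  m <- stage_means(expr)
  const <- apply(m, 1, stats::sd) == 0
  z <- t(scale(t(m[!const, , drop = FALSE])))
  pca <- stats::prcomp(t(z), center = TRUE, scale. = FALSE)
  k <- min(n_pcs, ncol(pca$x))
  pcs <- pca$x[, seq_len(k), drop = FALSE]
  structure(list(stages = stages, pcs = pcs,
                 dtu = dtu_from_points(pcs),
                 excluded = rownames(m)[const]),
            class = "stage_trajectory")
}

#' @export
print.stage_trajectory <- function(x, ...) {
  cat("DTU trajectory over", length(x$stages), "stages:\n")
  print(round(stats::setNames(x$dtu, x$stages), 3))
  invisible(x)
}

#' Loess-smoothed profile on the DTU grid
#'
#' Fits a tricube-weighted local polynomial regression (`stats::loess`,
#' exact `"direct"` surface) of the per-stage values against DTU and
#' evaluates it on a uniform grid over \[0, 10\].
#'
#' @param values Per-stage numeric values (length >= 4).
#' @param dtu DTU values of the stages (same length).
#' @param n_points Grid size (default 500).
#' @param span Loess span (default 0.75).
#' @param degree Local polynomial degree (default 2).
#' @return Numeric vector of length `n_points`.
#' @export
smooth_profile <- function(values, dtu, n_points = 500, span = 0.75,
                           degree = 2) {
  stopifnot(length(values) == length(dtu))
  if (length(values) < 4) stop("smooth_profile: need >= 4 points")
  if (length(unique(dtu)) < 2)
    stop("smooth_profile: degenerate design, all dtu equal")
  fit <- stats::loess(values ~ dtu,
                      data = data.frame(values = values, dtu = dtu),
                      span = span, degree = degree, family = "gaussian",
                      control = stats::loess.control(surface = "direct"))
  grid <- seq(0, 10, length.out = n_points)
  unname(stats::predict(fit, newdata = data.frame(dtu = grid)))
}

#' Angular ordering of genes around the expression circle
#'
#' Phase-shifted standardized stage profiles arrange on a near-circle in
#' gene-level PC space. Genes (observations) are decomposed by PCA over
#' their z-scored stage-mean profiles; each gene's angle is
#' `atan2(PC2, PC1)`. The circle is cut so that the gene whose smoothed
#' profile peaks earliest in DTU gets rank 1, and oriented so that rank
#' increases with the profile peak time; ties share an angle and keep
#' input order.
#'
#' @param expr A `"stage_matrix"` (>= 3 genes, >= 3 stages).
#' @param trajectory Optional `"stage_trajectory"`; computed from `expr`
#'   when missing.
#' @param use_smoothed Use the 500-point smoothed curves (instead of the
#'   raw z-scored stage samples) as PCA input (default FALSE).
#' @param n_points,span,degree Passed to [smooth_profile()].
#' @return List of class `"gene_order"`: `order` (`data.frame` gene_id,
#'   angle, rank, peak_time), `profiles` (genes x n_points smoothed
#'   matrix, input order), `trajectory`, `excluded` (zero-variance
#'   genes).
#' @export
angular_order <- function(expr, trajectory = NULL, use_smoothed = FALSE,
                          n_points = 500, span = 0.75, degree = 2) {
  stages <- sm_stages(expr)
  if (length(stages) < 3) stop("angular_order: need >= 3 stages")
  if (is.null(trajectory)) trajectory <- compute_dtu(expr)
  m <- stage_means(expr)
  const <- apply(m, 1, stats::sd) == 0
  excluded <- rownames(m)[const]
  m <- m[!const, , drop = FALSE]
  if (nrow(m) < 3) stop("angular_order: need >= 3 variable genes")
  z <- t(scale(t(m)))
  prof <- t(apply(z, 1, smooth_profile, dtu = trajectory$dtu,
                  n_points = n_points, span = span, degree = degree))
  grid <- seq(0, 10, length.out = n_points)
  # time at which the curve first reaches its peak plateau (95% of its
  # range): robust for monotone profiles, whose literal argmax is a tie
  # along the plateau
  peak_time <- grid[apply(prof, 1, function(v) {
    which(v >= min(v) + 0.95 * (max(v) - min(v)))[1]
  })]
  pca_in <- if (use_smoothed) prof else z
  pca <- stats::prcomp(pca_in, center = TRUE, scale. = FALSE)
  angle <- atan2(pca$x[, 2], pca$x[, 1])
  # orientation: the circle must run with developmental time. The
  # temporal anchor is the centre of mass of the baseline-subtracted
  # stage profile (free of the interpolation wiggles that can corrupt
  # the peak time of extreme-phase genes); both orientations are scored
  # by rotation-maximised Spearman agreement with it on a deterministic
  # subsample, and the better one wins.
  com <- apply(z, 1, function(v) {
    w <- v - min(v)
    if (sum(w) == 0) return(mean(trajectory$dtu))
    sum(trajectory$dtu * w) / sum(w)
  })
  first <- which.min(peak_time)
  rank_for <- function(theta) {
    rot <- (theta - theta[first]) %% (2 * pi)
    ordr <- order(rot, seq_along(rot))
    r <- integer(length(rot)); r[ordr] <- seq_along(rot)
    r
  }
  r_fwd <- rank_for(angle)
  r_rev <- rank_for(-angle)
  sub <- if (length(com) > 256) {
    order(com)[round(seq(1, length(com), length.out = 256))]
  } else seq_along(com)
  use_rev <- circular_rank_cor(rank(r_rev[sub]), com[sub]) >
    circular_rank_cor(rank(r_fwd[sub]), com[sub])
  rank <- if (use_rev) r_rev else r_fwd
  structure(list(order = data.frame(gene_id = rownames(m),
                                    angle = unname(angle),
                                    rank = rank,
                                    peak_time = peak_time,
                                    stringsAsFactors = FALSE),
                 profiles = prof, trajectory = trajectory,
                 excluded = excluded),
            class = "gene_order")
}

#' Rank-ordered heatmap matrix of smoothed profiles
#'
#' Rows are the genes sorted by angular rank; values are the row
#' z-scored smoothed curves on the DTU grid. This is the matrix behind
#' the sorted temporal-profile heatmaps.
#'
#' @param gene_order A `"gene_order"` from [angular_order()].
#' @return Numeric matrix (ranked genes x grid points).
#' @export
order_heatmap_matrix <- function(gene_order) {
  ord <- gene_order$order[order(gene_order$order$rank), ]
  prof <- gene_order$profiles[match(ord$gene_id,
                                    gene_order$order$gene_id), ,
                              drop = FALSE]
  out <- t(scale(t(prof)))
  rownames(out) <- ord$gene_id
  out
}

#' Circular Spearman correlation of a rank against a phase
#'
#' Maximum Spearman correlation between a circular rank vector and a
#' linear phase over all cyclic rotations of the rank; used to score how
#' well an angular ordering recovers a planted activation order
#' independently of where the circle was cut.
#'
#' @param rank Integer ranks 1..n (a permutation).
#' @param phase Numeric phases (same length).
#' @return Maximum Spearman correlation over the n rotations.
#' @export
circular_rank_cor <- function(rank, phase) {
  n <- length(rank)
  stopifnot(length(phase) == n)
  best <- -1
  for (k in 0:(n - 1)) {
    r <- ((rank - 1 + k) %% n) + 1
    v <- stats::cor(r, phase, method = "spearman")
    if (!is.na(v) && v > best) best <- v
  }
  best
}
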