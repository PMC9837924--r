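#' Simulation configuration
#'
#' Parameters of the miniature tri-subgenome embryogenesis dataset the
#' generator emits. Defaults describe the study conditions the package is
#' exercised under: eight ordered stages, 500 homoeolog triads plus 100
#' singleton genes over three 2-Mb chromosomes, TEs filling 40% of
#' intergenic space, four TF families of five TFs with five targets each,
#' a 200-peak transient distal-ACR burst at the fifth stage, and planted
#' triad-bias and divergence category fractions.
#'
#' @param seed Master seed; every stochastic step derives from it.
#' @param chrom_length_bp Length of each subgenome chromosome.
#' @param n_triads Number of A/B/D homoeolog triads.
#' @param n_singletons Non-triad genes (distributed over subgenomes).
#' @param te_fraction Target fraction of intergenic bp covered by TEs.
#' @param stages Ordered stage labels.
#' @param n_reps_rna,n_reps_atac Replicates per stage for counts/signal.
#' @param nb_dispersion Negative-binomial dispersion of counts (0 gives
#'   noiseless means).
#' @param n_tf_families,tfs_per_family,targets_per_tf Planted regulatory
#'   network shape.
#' @param transient_dacr_count Distal ACRs present only at the burst
#'   stage.
#' @param constant_dacr_count Distal ACRs present at every stage.
#' @param burst_stage_index Index of the burst stage (default 5).
#' @param triad_category_fractions Named fractions over the seven bias
#'   categories (must sum to 1).
#' @param divergence_fractions Named fractions over conserved/middle/
#'   dysfunction (must sum to 1).
#' @param activation_phase_spread SD of the activation phase around its
#'   wave center (DTU units).
#' @param activation_tau Logistic activation time constant (DTU units).
#' @param deactivation_fraction Fraction of background genes that switch
#'   off (rather than on) at their phase, emulating the decline of the
#'   maternal program and keeping stage library totals comparable.
#' @param target_lag_stages Stage lag of targets behind their TF.
#' @param target_lag_noise SD of the lag (DTU units).
#' @param n_decoy_motif_hits Motif hits planted in promoters of
#'   non-target genes (network clutter).
#' @param pacr_tpm_min TPM at which a gene's promoter ACR is present.
#' @param mid_bias_strength Relative triad-bias strength at the middle
#'   stages (1 = full bias; < 1 plants more balanced triads mid-course).
#' @param dominant_major_fraction Planted expression fraction of the
#'   dominant member in dominant triads.
#' @param suppressed_minor_fraction Planted fraction of the suppressed
#'   member in suppressed triads.
#' @return Validated list of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1,
                       chrom_length_bp = 2e6,
                       n_triads = 500,
                       n_singletons = 100,
                       te_fraction = 0.4,
                       stages = c("DPA0", "DPA2", "DPA4", "DPA6",
                                  "DPA8", "DPA12", "DPA16", "DPA22"),
                       n_reps_rna = 3,
                       n_reps_atac = 2,
                       nb_dispersion = 0.05,
                       n_tf_families = 4,
                       tfs_per_family = 5,
                       targets_per_tf = 5,
                       transient_dacr_count = 200,
                       constant_dacr_count = 300,
                       burst_stage_index = 5,
                       triad_category_fractions = c(
                         balanced = 0.55, `A-dominant` = 0.05,
                         `B-dominant` = 0.05, `D-dominant` = 0.05,
                         `A-suppressed` = 0.11, `B-suppressed` = 0.11,
                         `D-suppressed` = 0.08),
                       divergence_fractions = c(conserved = 0.50,
                                                middle = 0.42,
                                                dysfunction = 0.08),
                       activation_phase_spread = 0.8,
                       activation_tau = 0.8,
                       deactivation_fraction = 0.5,
                       target_lag_stages = 1,
                       target_lag_noise = 0.25,
                       n_decoy_motif_hits = 50,
                       pacr_tpm_min = 1,
                       mid_bias_strength = 0.6,
                       dominant_major_fraction = 0.85,
                       suppressed_minor_fraction = 0.05) {
  cfg <- as.list(environment())
  if (length(cfg$stages) < 3) stop("need >= 3 stages")
  if (abs(sum(cfg$triad_category_fractions) - 1) > 1e-9)
    stop("triad_category_fractions must sum to 1")
  if (!setequal(names(cfg$triad_category_fractions),
                rownames(triad_centroids())))
    stop("triad_category_fractions must name the seven bias categories")
  if (abs(sum(cfg$divergence_fractions) - 1) > 1e-9)
    stop("divergence_fractions must sum to 1")
  counts <- c(cfg$chrom_length_bp, cfg$n_triads, cfg$n_reps_rna,
              cfg$n_reps_atac, cfg$n_tf_families, cfg$tfs_per_family,
              cfg$targets_per_tf, cfg$transient_dacr_count,
              cfg$constant_dacr_count)
  if (any(counts <= 0)) stop("all counts must be positive")
  if (cfg$burst_stage_index < 2 ||
      cfg$burst_stage_index >= length(cfg$stages))
    stop("burst stage must have flanking stages")
  class(cfg) <- "sim_config"
  cfg
}

# split n into 7 category counts honouring the configured fractions
alloc_counts <- function(n, fractions) {
  k <- floor(n * fractions)
  left <- n - sum(k)
  if (left > 0) {
    o <- order(n * fractions - k, decreasing = TRUE)
    k[o[seq_len(left)]] <- k[o[seq_len(left)]] + 1
  }
  k
}

planted_triad_fracs <- function(category, dom = 0.8, supp = 0.05) {
  minor <- (1 - dom) / 2
  half <- (1 - supp) / 2
  switch(category,
         balanced = c(1, 1, 1) / 3,
         `A-dominant` = c(dom, minor, minor),
         `B-dominant` = c(minor, dom, minor),
         `D-dominant` = c(minor, minor, dom),
         `A-suppressed` = c(supp, half, half),
         `B-suppressed` = c(half, supp, half),
         `D-suppressed` = c(half, half, supp))
}

# exon/intron template relative to the gene start: k exons with >= 60 bp
# pieces; introns are the gaps
gene_feature_template <- function(len, k) {
  if (k == 1 || len < 60 * (2 * k - 1))
    return(data.frame(kind = "exon", rel_start = 0, rel_end = len))
  npieces <- 2 * k - 1
  w <- 0.3 + stats::runif(npieces)
  w <- w / sum(w) * (len - 60 * npieces) + 60
  b <- round(c(0, cumsum(w)))
  b[npieces + 1] <- len
  data.frame(kind = rep(c("exon", "intron"), length.out = npieces),
             rel_start = b[-(npieces + 1)], rel_end = b[-1])
}

#' Simulate the tri-subgenome genome annotation
#'
#' Tiles each subgenome chromosome with genes separated by random
#' intergenic gaps drawn from a short/long mixture (the long gaps carve
#' out distal space for dACRs). Triad copies appear in the same order at
#' collinear relative positions with shared length, strand and exon
#' structure; singletons are interleaved per subgenome. TEs fill the
#' configured fraction of every intergenic gap. TF genes, their planted
#' targets, triad bias categories and divergence labels are drawn here
#' and recorded in the ground truth.
#'
#' @param config A `"sim_config"`.
#' @return List with `genome` (an `"embryodyn_genome"`) and `truth` (the
#'   partial ground-truth list).
#' @export
simulate_genome <- function(config) with_seed(config$seed + 1L, {
  subg <- c("A", "B", "D")
  chroms <- paste0("chr1", subg)
  chrom_sizes <- stats::setNames(rep(config$chrom_length_bp, 3), chroms)

  n_tr <- config$n_triads
  single_per <- diff(floor(config$n_singletons * (0:3) / 3))

  # shared triad properties
  tr_len <- round(stats::runif(n_tr, 500, 1500))
  tr_strand <- sample(c("+", "-"), n_tr, replace = TRUE)
  tr_k <- sample(1:3, n_tr, replace = TRUE)
  tr_feat <- lapply(seq_len(n_tr), function(i)
    gene_feature_template(tr_len[i], tr_k[i]))

  genes <- list(); feats <- list(); tes <- list()
  for (ci in 1:3) {
    n_s <- single_per[ci]
    n_g <- n_tr + n_s
    s_len <- round(stats::runif(n_s, 500, 1500))
    s_strand <- sample(c("+", "-"), n_s, replace = TRUE)
    s_feat <- lapply(seq_len(n_s), function(i)
      gene_feature_template(s_len[i],
                            sample(1:3, 1)))
    # slot layout: triads in order, singletons interleaved
    slot_is_single <- rep(FALSE, n_g)
    if (n_s > 0)
      slot_is_single[sort(sample.int(n_g, n_s))] <- TRUE
    tri_i <- 0L; sin_i <- 0L
    ids <- character(n_g); lens <- numeric(n_g)
    strands <- character(n_g); triad_ids <- rep(NA_character_, n_g)
    ftpl <- vector("list", n_g)
    for (k in seq_len(n_g)) {
      if (slot_is_single[k]) {
        sin_i <- sin_i + 1L
        ids[k] <- sprintf("GS%s%03d", subg[ci], sin_i)
        lens[k] <- s_len[sin_i]; strands[k] <- s_strand[sin_i]
        ftpl[[k]] <- s_feat[[sin_i]]
      } else {
        tri_i <- tri_i + 1L
        ids[k] <- sprintf("GT%03d%s", tri_i, subg[ci])
        lens[k] <- tr_len[tri_i]; strands[k] <- tr_strand[tri_i]
        triad_ids[k] <- sprintf("T%03d", tri_i)
        ftpl[[k]] <- tr_feat[[tri_i]]
      }
    }
    # gaps: short/long mixture rescaled to fill the chromosome; the
    # 1 kb floor keeps adjacent promoter peaks from ever merging
    long <- stats::runif(n_g + 1) < 0.15
    gaps <- ifelse(long, stats::runif(n_g + 1, 9000, 15000),
                   stats::runif(n_g + 1, 1000, 2000))
    free_bp <- config$chrom_length_bp - sum(lens)
    if (free_bp < 500 * (n_g + 1))
      stop("genome too small for ", n_g, " genes: need at least ",
           format_coord(sum(lens) + 500 * (n_g + 1)), " bp")
    gaps <- gaps / sum(gaps) * free_bp
    starts <- round(cumsum(gaps[seq_len(n_g)]) +
                      cumsum(c(0, lens[-n_g])))
    ends <- starts + lens
    plus <- strands == "+"
    genes[[ci]] <- data.frame(
      gene_id = ids, chrom = chroms[ci], strand = strands,
      start = starts, end = ends,
      tss = ifelse(plus, starts, ends),
      tes = ifelse(plus, ends, starts),
      biotype = "coding", subgenome = subg[ci], triad_id = triad_ids,
      stringsAsFactors = FALSE)
    feats[[ci]] <- do.call(rbind, lapply(seq_len(n_g), function(k) {
      f <- ftpl[[k]]
      data.frame(gene_id = ids[k], kind = f$kind, chrom = chroms[ci],
                 start = starts[k] + f$rel_start,
                 end = starts[k] + f$rel_end, stringsAsFactors = FALSE)
    }))
    # TEs: fill ~te_fraction of every gap
    gap_start <- c(0, ends); gap_end <- c(starts, config$chrom_length_bp)
    te_rows <- list()
    for (gidx in seq_along(gap_start)) {
      glen <- gap_end[gidx] - gap_start[gidx]
      target <- config$te_fraction * glen
      if (target < 150) next
      k <- max(1L, floor(target / 400))
      tl <- stats::runif(k, 200, 600)
      tl <- round(tl / sum(tl) * target)
      tl <- tl[tl >= 50]
      if (!length(tl)) next
      free <- glen - sum(tl)
      cuts <- diff(c(0, sort(stats::runif(length(tl))), 1)) * free
      pos <- gap_start[gidx] + round(cumsum(cuts[-length(cuts)]) +
                                       cumsum(c(0, tl[-length(tl)])))
      te_rows[[gidx]] <- data.frame(chrom = chroms[ci], start = pos,
                                    end = pos + tl,
                                    stringsAsFactors = FALSE)
    }
    tes[[ci]] <- do.call(rbind, te_rows)
  }
  gene_tab <- do.call(rbind, genes)
  feat_tab <- do.call(rbind, feats)
  te_tab <- do.call(rbind, tes)
  te_tab <- genomic_intervals(te_tab$chrom, te_tab$start, te_tab$end,
                              name = sprintf("TE%05d",
                                             seq_len(nrow(te_tab))))
  genome <- genome_annotation(chrom_sizes, gene_tab, feat_tab, te_tab)

  # planted triad bias categories (drawn before TF selection so TFs can
  # be restricted to balanced triads, whose members carry no
  # stage-varying bias multiplier)
  cat_counts <- alloc_counts(n_tr, config$triad_category_fractions)
  cat_vec <- sample(rep(names(cat_counts), cat_counts))
  triad_ids <- sprintf("T%03d", seq_len(n_tr))
  triad_map <- data.frame(triad_id = triad_ids,
                          A = sprintf("GT%03dA", seq_len(n_tr)),
                          B = sprintf("GT%03dB", seq_len(n_tr)),
                          D = sprintf("GT%03dD", seq_len(n_tr)),
                          category = cat_vec, stringsAsFactors = FALSE)

  # planted regulatory network: TFs among balanced-triad A-subgenome
  # genes, targets preferentially among singletons (keeps triad bias
  # clean and TF profiles undistorted)
  n_tf <- config$n_tf_families * config$tfs_per_family
  a_triad <- triad_map$A[triad_map$category == "balanced"]
  if (n_tf > length(a_triad))
    stop("not enough balanced triads for requested TFs")
  tf_genes <- sort(sample(a_triad, n_tf))
  fam_names <- c("TCP", "ARF", "MYB", "WOX",
                 paste0("FAM", seq_len(max(0, config$n_tf_families - 4))))
  families <- rep(fam_names[seq_len(config$n_tf_families)],
                  each = config$tfs_per_family)
  n_targets <- n_tf * config$targets_per_tf
  singles <- gene_tab$gene_id[is.na(gene_tab$triad_id)]
  pool <- setdiff(singles, tf_genes)
  if (length(pool) < n_targets)
    pool <- c(pool, setdiff(gene_tab$gene_id, c(tf_genes, pool)))
  targets <- sample(pool, n_targets)
  edges <- data.frame(tf_gene_id = rep(tf_genes,
                                       each = config$targets_per_tf),
                      target_gene_id = targets,
                      motif_id = rep(paste0("M_", tf_genes),
                                     each = config$targets_per_tf),
                      cascade = FALSE, stringsAsFactors = FALSE)
  # within-family TF cascades (TF_j regulates TF_{j+1}), realized like
  # any other edge: a motif hit in the downstream TF's promoter ACR
  if (config$tfs_per_family > 1) {
    fam_mat <- matrix(tf_genes, nrow = config$tfs_per_family)
    casc <- do.call(rbind, lapply(seq_len(ncol(fam_mat)), function(f) {
      up <- fam_mat[-config$tfs_per_family, f]
      dn <- fam_mat[-1, f]
      data.frame(tf_gene_id = up, target_gene_id = dn,
                 motif_id = paste0("M_", up), cascade = TRUE,
                 stringsAsFactors = FALSE)
    }))
    edges <- rbind(edges, casc)
  }

  # planted divergence labels over all genes
  div_counts <- alloc_counts(nrow(gene_tab), config$divergence_fractions)
  div_vec <- sample(rep(names(div_counts), div_counts))

  truth <- list(
    tf_genes = tf_genes,
    tf_families = stats::setNames(families, tf_genes),
    edges = edges,
    triads = triad_map,
    divergence = data.frame(gene_id = gene_tab$gene_id,
                            label = div_vec, stringsAsFactors = FALSE))
  list(genome = genome, truth = truth)
})

logistic_traj <- function(t, phase, amp, base, tau)
  base + amp * stats::plogis((t - phase) / tau)

#' Simulate the expression time course and ancestor profiles
#'
#' Per-gene mean trajectories are scaled logistic activations centred at
#' the gene's planted phase; phases cluster in four waves spanning the
#' DTU range. Planted targets inherit their TF's phase with a one-stage
#' lag plus noise. Triad members are rescaled so their relative
#' fractions hit the planted bias category (attenuated toward balanced
#' at the middle stages). Counts are negative-binomial per replicate
#' with equal library factors. Ancestor stage profiles are built with a
#' controlled correlation to the hexaploid profile: ~0.95 (conserved),
#' ~0.5 (middle), ~0 via phase permutation (dysfunction).
#'
#' @param config A `"sim_config"`.
#' @param genome,truth Output of [simulate_genome()].
#' @return List with `counts` (`"stage_matrix"`), `ancestor`
#'   (`"stage_matrix"`, signal units, one column per stage),
#'   `gene_lengths` (exonic bp, named), and the updated `truth` (adds
#'   `phase`, per-gene planted divergence correlation `rho`).
#' @export
simulate_expression <- function(config, genome, truth)
  with_seed(config$seed + 2L, {
  g <- genome$genes
  n <- nrow(g)
  S <- length(config$stages)
  t_s <- seq(0, 10, length.out = S)
  delta <- 10 / (S - 1)

  # activation phases span the full DTU range (staggered, so the
  # activation order is well-defined); the four waves are phase
  # quartiles, jittered by the configured spread
  # overlapping wave windows span the full DTU range (staggered
  # activations with a well-defined order)
  wave_centers <- seq(1.5, 8.5, length.out = 4)
  wave <- sample(1:4, n, replace = TRUE)
  phase <- stats::runif(n, wave_centers[wave] - 1.75,
                        wave_centers[wave] + 1.75) +
    stats::rnorm(n, 0, config$activation_phase_spread / 4)
  phase <- pmin(pmax(phase, 0.2), 9.5)
  names(phase) <- g$gene_id

  # TF cascades: each family activates in sequence through the
  # mid-to-late window, so lagged targets stay inside the series and
  # activate after the mid-course baseline (the regime the
  # synchronization detector is designed for)
  k_tf <- config$tfs_per_family
  fam_mat <- matrix(truth$tf_genes, nrow = k_tf)
  for (f in seq_len(ncol(fam_mat))) {
    base_f <- stats::runif(1, 5.0, 5.4)
    step_f <- if (k_tf > 1) (6.9 - base_f) / (k_tf - 1) else 0
    phase[fam_mat[, f]] <- base_f + (seq_len(k_tf) - 1) * step_f +
      stats::rnorm(k_tf, 0, 0.1)
  }
  gene_edges <- truth$edges[!truth$edges$cascade, , drop = FALSE]
  tgt_phase <- phase[gene_edges$tf_gene_id] +
    config$target_lag_stages * delta +
    stats::rnorm(nrow(gene_edges), 0, config$target_lag_noise)
  phase[gene_edges$target_gene_id] <- pmin(pmax(tgt_phase, 0.2), 9.8)

  # direction: background genes switch off with the configured
  # probability (declining maternal program); TFs and planted targets
  # are always activations so the planted order is well-defined
  direction <- ifelse(stats::runif(n) < config$deactivation_fraction,
                      -1L, 1L)
  names(direction) <- g$gene_id
  direction[truth$tf_genes] <- 1L
  direction[truth$edges$target_gene_id] <- 1L

  amp <- stats::rlnorm(n, log(30), 0.6)
  names(amp) <- g$gene_id
  # homoeolog copies share the base trajectory (phase, direction,
  # amplitude); the planted bias fractions then scale it per member
  tm <- truth$triads
  for (copy in c("B", "D")) {
    phase[tm[[copy]]] <- phase[tm$A]
    direction[tm[[copy]]] <- direction[tm$A]
    amp[tm[[copy]]] <- amp[tm$A]
  }
  base <- 0.5
  traj <- t(vapply(seq_len(n), function(i) {
    up <- logistic_traj(t_s, phase[i], amp[i], base,
                        config$activation_tau)
    if (direction[i] == 1L) up else (base + amp[i]) + base - up
  }, numeric(S)))
  rownames(traj) <- g$gene_id

  # triad bias multipliers, attenuated toward balanced mid-course
  mid <- seq(floor(S / 3) + 1, ceiling(2 * S / 3))
  a_s <- rep(1, S); a_s[mid] <- config$mid_bias_strength
  tm <- truth$triads
  for (i in seq_len(nrow(tm))) {
    fr <- planted_triad_fracs(tm$category[i],
                              config$dominant_major_fraction,
                              config$suppressed_minor_fraction)
    members <- c(tm$A[i], tm$B[i], tm$D[i])
    for (m in 1:3) {
      frac_s <- (1 - a_s) / 3 + a_s * fr[m]
      traj[members[m], ] <- traj[members[m], ] * 3 * frac_s
    }
  }

  reps <- config$n_reps_rna
  mu <- traj[, rep(seq_len(S), each = reps)]
  vals <- if (config$nb_dispersion <= 1e-12) mu else
    matrix(stats::rnbinom(length(mu), mu = mu,
                          size = 1 / config$nb_dispersion),
           nrow = n)
  dimnames(vals) <- list(g$gene_id,
                         paste(rep(config$stages, each = reps),
                               rep(seq_len(reps), S), sep = "."))
  counts <- stage_matrix(vals, config$stages, units = "counts")

  # ancestor profiles with controlled correlation to the hexaploid
  rho_target <- c(conserved = 0.95, middle = 0.5, dysfunction = 0)
  div <- truth$divergence
  rho <- rho_target[div$label] + stats::rnorm(n, 0, 0.04)
  rho <- pmin(pmax(rho, -0.15), 0.995)
  anc <- matrix(0, n, S,
                dimnames = list(g$gene_id,
                                paste0(config$stages, ".1")))
  for (i in seq_len(n)) {
    x <- traj[i, ]
    z <- (x - mean(x)) / stats::sd(x)
    e <- z[sample.int(S)]                      # phase-permuted copy
    e <- e - sum(e * z) / sum(z * z) * z       # orthogonalize
    if (stats::sd(e) < 1e-8) e <- stats::rnorm(S)
    e <- e - sum(e * z) / sum(z * z) * z
    e <- (e - mean(e)) / stats::sd(e)
    az <- rho[i] * z + sqrt(1 - rho[i]^2) * e
    anc[i, ] <- pmax(mean(x) + stats::sd(x) * az, 0)
  }
  ancestor <- stage_matrix(anc, config$stages, units = "signal")

  lens <- tapply(genome$features$end[genome$features$kind == "exon"] -
                   genome$features$start[genome$features$kind == "exon"],
                 genome$features$gene_id[genome$features$kind == "exon"],
                 sum)
  gene_lengths <- stats::setNames(as.numeric(lens), names(lens))
  gene_lengths <- gene_lengths[g$gene_id]

  truth$phase <- phase
  truth$direction <- direction
  truth$divergence$rho <- unname(rho)
  list(counts = counts, ancestor = ancestor,
       gene_lengths = gene_lengths, truth = truth)
})

# sample n non-overlapping placements of length ~len_range inside the
# given segments (one placement per chosen segment)
place_in_segments <- function(segments, n, len_range, prefix) {
  lens <- round(stats::runif(n, len_range[1], len_range[2]))
  w <- segments$end - segments$start
  ok <- which(w >= max(lens))
  if (length(ok) < n)
    ok <- which(w >= min(lens))  # relax: fit per segment below
  if (length(ok) < n)
    stop("not enough room to place ", n, " intervals (",
         length(ok), " feasible segments)")
  segs <- ok[sample.int(length(ok), n)]
  lens <- pmin(lens, w[segs] - 1)
  off <- floor(stats::runif(n) * (w[segs] - lens + 1))
  data.frame(chrom = segments$chrom[segs],
             start = segments$start[segs] + off,
             end = segments$start[segs] + off + lens,
             name = sprintf("%s%04d", prefix, seq_len(n)),
             score = NA_real_, strand = ".", stringsAsFactors = FALSE)
}

#' Simulate stage-wise peak sets, motif hits and ncRNA transcripts
#'
#' Expressed genes (stage-mean TPM above the configured floor) carry a
#' promoter ATAC peak at that stage; planted TF motifs are written into
#' their targets' promoter ACRs (plus decoy hits in non-target
#' promoters). Constant distal ACRs are present at every stage; the
#' transient distal ACRs exist only at the burst stage, >= 70% of them
#' inside TEs, each emitting an ncRNA transcript at that stage.
#' H3K27ac peaks track expressed promoters, H3K27me3 marks silent
#' promoters, H3K9me2 covers TE-dense distal blocks. Per-gene promoter
#' signal matrices are emitted for accessibility (leading RNA by one
#' stage on planted targets) and both histone marks.
#'
#' @param config A `"sim_config"`.
#' @param genome An `"embryodyn_genome"` from [simulate_genome()].
#' @param truth Truth list from [simulate_expression()].
#' @param counts Count `"stage_matrix"` from [simulate_expression()].
#' @param gene_lengths Exonic lengths for TPM normalization.
#' @return List with `atac_peaks` (per-stage list), `mark_peaks`
#'   (per-mark per-stage lists), `motif_hits`, `ncrna` (interval table
#'   with `stage`), `atac_signal`, `mark_signals`, `tpm`, and updated
#'   `truth` (adds `peak_labels`, `ncrna_te_map`, `transient_ids`).
#' @export
simulate_peaks <- function(config, genome, truth, counts, gene_lengths)
  with_seed(config$seed + 3L, {
  S <- length(config$stages)
  g <- genome$genes
  tpm <- tpm_normalize(counts, gene_lengths)
  sm <- stage_means(tpm)
  expressed <- sm >= config$pacr_tpm_min

  plus <- g$strand == "+"
  pacr <- data.frame(chrom = g$chrom,
                     start = ifelse(plus, g$tss - 400, g$tss + 100),
                     end = ifelse(plus, g$tss - 100, g$tss + 400),
                     name = paste0("pACR_", g$gene_id),
                     score = NA_real_, strand = ".",
                     stringsAsFactors = FALSE)
  rownames(pacr) <- g$gene_id

  # distal space: intergenic minus all assignment windows
  w <- gene_windows(genome)
  windows <- genomic_intervals(w$chrom, w$start, w$end)
  distal <- subtract_intervals(intergenic_regions(genome), windows)
  te_distal <- subtract_intervals(genome$tes,
                                  subtract_intervals(
                                    merge_intervals(genome$tes), distal))
  te_distal <- te_distal[te_distal$end - te_distal$start >= 250, ,
                         drop = FALSE]
  nonte_distal <- subtract_intervals(distal, genome$tes)
  nonte_distal <- nonte_distal[nonte_distal$end - nonte_distal$start >=
                                 250, , drop = FALSE]

  n_c <- config$constant_dacr_count
  n_t <- config$transient_dacr_count
  c_te <- round(0.40 * n_c)
  t_te <- ceiling(0.75 * n_t)
  # draw TE segments for constant and transient peaks jointly so the two
  # classes never overlap
  need_te <- c_te + t_te
  if (nrow(te_distal) < need_te)
    stop("not enough distal TE segments (", nrow(te_distal), ") for ",
         need_te, " TE-overlapping dACRs")
  te_pick <- sample.int(nrow(te_distal), need_te)
  const_te <- place_in_segments(te_distal[te_pick[seq_len(c_te)], ],
                                c_te, c(150, 350), "cdT")
  trans_te <- place_in_segments(te_distal[te_pick[c_te + seq_len(t_te)],
                                          ],
                                t_te, c(150, 350), "tdT")
  nonte_pick <- sample.int(nrow(nonte_distal),
                           (n_c - c_te) + (n_t - t_te))
  const_nt <- place_in_segments(nonte_distal[
    nonte_pick[seq_len(n_c - c_te)], ], n_c - c_te, c(150, 350), "cdN")
  trans_nt <- place_in_segments(nonte_distal[
    nonte_pick[(n_c - c_te) + seq_len(n_t - t_te)], ],
    n_t - t_te, c(150, 350), "tdN")
  constant_dacrs <- rbind(const_te, const_nt)
  constant_dacrs$name <- sprintf("cdACR%04d", seq_len(n_c))
  transient_dacrs <- rbind(trans_te, trans_nt)
  transient_dacrs$name <- sprintf("tdACR%04d", seq_len(n_t))

  atac_peaks <- lapply(seq_len(S), function(s) {
    p <- pacr[expressed[, s], , drop = FALSE]
    out <- rbind(p, constant_dacrs,
                 if (s == config$burst_stage_index) transient_dacrs)
    rownames(out) <- NULL
    sort_intervals(out)
  })
  names(atac_peaks) <- config$stages

  # motif hits: planted edges into target promoter ACRs, plus decoys
  tss <- stats::setNames(g$tss, g$gene_id)
  str_plus <- stats::setNames(plus, g$gene_id)
  hit_at <- function(gene_ids, motif_ids, tf_ids) {
    jit <- sample(0:80, length(gene_ids), replace = TRUE)
    s0 <- ifelse(str_plus[gene_ids], tss[gene_ids] - 350 + jit,
                 tss[gene_ids] + 340 - jit)
    data.frame(motif_id = motif_ids, tf_gene_id = tf_ids,
               chrom = g$chrom[match(gene_ids, g$gene_id)],
               start = s0, end = s0 + 10,
               score = round(stats::runif(length(gene_ids), 5, 15), 2),
               stringsAsFactors = FALSE)
  }
  planted_hits <- hit_at(truth$edges$target_gene_id,
                         truth$edges$motif_id, truth$edges$tf_gene_id)
  decoy_pool <- setdiff(g$gene_id,
                        c(truth$tf_genes, truth$edges$target_gene_id))
  decoy_pool <- decoy_pool[rowSums(expressed[decoy_pool, , drop = FALSE])
                           > 0]
  n_d <- min(config$n_decoy_motif_hits, length(decoy_pool))
  decoy_genes <- sample(decoy_pool, n_d)
  decoy_tfs <- sample(truth$tf_genes, n_d, replace = TRUE)
  decoy_hits <- hit_at(decoy_genes, paste0("M_", decoy_tfs), decoy_tfs)
  motif_hits <- rbind(planted_hits, decoy_hits)
  motif_hits$planted <- rep(c(TRUE, FALSE),
                            c(nrow(planted_hits), nrow(decoy_hits)))

  # ncRNA transcripts from the transient dACRs, plus genic decoys that
  # the coding-overlap filter must remove
  ncr <- transient_dacrs
  ncr$start <- pmax(ncr$start - 20, 0)
  ncr$end <- ncr$end + 20
  ncr$name <- sub("tdACR", "ncRNA", transient_dacrs$name)
  n_gd <- 30
  gd_genes <- sample(g$gene_id, n_gd)
  gi <- match(gd_genes, g$gene_id)
  genic <- data.frame(chrom = g$chrom[gi], start = g$start[gi] + 10,
                      end = pmin(g$start[gi] + 210, g$end[gi]),
                      name = sprintf("txGenic%03d", seq_len(n_gd)),
                      score = NA_real_, strand = ".",
                      stringsAsFactors = FALSE)
  ncrna <- rbind(ncr, genic)
  ncrna$stage <- config$stages[config$burst_stage_index]
  te_ov <- overlaps_any(ncr, genome$tes)
  ncrna_te_map <- data.frame(ncrna_id = ncr$name,
                             dacr_id = transient_dacrs$name,
                             from_te = te_ov, stringsAsFactors = FALSE)

  # histone mark peak sets
  k9_blocks <- merge_intervals(te_distal)
  mark_peaks <- list(
    H3K27ac = lapply(seq_len(S), function(s) {
      p <- pacr[expressed[, s], , drop = FALSE]
      p$name <- sub("pACR", "K27ac", p$name); rownames(p) <- NULL
      sort_intervals(p)
    }),
    H3K27me3 = lapply(seq_len(S), function(s) {
      p <- pacr[!expressed[, s], , drop = FALSE]
      p$name <- sub("pACR", "K27me3", p$name); rownames(p) <- NULL
      sort_intervals(p)
    }),
    H3K9me2 = lapply(seq_len(S), function(s) k9_blocks))
  for (mk in names(mark_peaks)) names(mark_peaks[[mk]]) <- config$stages

  # promoter signal matrices: accessibility leads RNA by one stage on
  # planted targets; marks track / mirror expression
  le <- log2(sm + 1)
  # accessibility tracks expression on the raw signal scale; on planted
  # targets it leads by half a sampling interval: the same profile
  # shape, shifted earlier along the stage axis (the peak opens before
  # the transcript accumulates, within the resolution of the series)
  t_s <- seq(0, 10, length.out = S)
  half_step <- 0.5 * (t_s[2] - t_s[1])
  acc_base <- sm / pmax(apply(sm, 1, max), 1) * 10
  tgt <- intersect(truth$edges$target_gene_id, rownames(sm))
  for (gg in tgt)
    acc_base[gg, ] <- stats::approx(t_s, acc_base[gg, ],
                                    xout = t_s + half_step, rule = 2)$y
  mk_signal <- function(base, reps) {
    v <- base[, rep(seq_len(S), each = reps)] +
      abs(stats::rnorm(length(base) * reps, 0, 0.05))
    v <- matrix(pmax(v, 0), nrow = nrow(base))
    dimnames(v) <- list(rownames(base),
                        paste(rep(config$stages, each = reps),
                              rep(seq_len(reps), S), sep = "."))
    stage_matrix(v, config$stages, units = "signal")
  }
  atac_signal <- mk_signal(acc_base, config$n_reps_atac)
  mark_signals <- list(
    H3K27ac = mk_signal(le * 0.8, config$n_reps_atac),
    H3K27me3 = mk_signal(max(le) - le, config$n_reps_atac))

  truth$peak_labels <- data.frame(
    acr_id = c(pacr$name, constant_dacrs$name, transient_dacrs$name),
    category = c(rep("pACR", nrow(pacr)),
                 rep("dACR", n_c + n_t)),
    transient = c(rep(FALSE, nrow(pacr) + n_c), rep(TRUE, n_t)),
    te_overlap = c(rep(NA, nrow(pacr)),
                   overlaps_any(constant_dacrs, genome$tes),
                   overlaps_any(transient_dacrs, genome$tes)),
    stringsAsFactors = FALSE)
  truth$ncrna_te_map <- ncrna_te_map
  truth$transient_ids <- transient_dacrs$name

  list(atac_peaks = atac_peaks, mark_peaks = mark_peaks,
       motif_hits = motif_hits, ncrna = ncrna,
       atac_signal = atac_signal, mark_signals = mark_signals,
       tpm = tpm, truth = truth)
})

#' Run the full simulation
#'
#' Convenience wrapper chaining [simulate_genome()],
#' [simulate_expression()] and [simulate_peaks()].
#'
#' @param config A `"sim_config"` (default `sim_config()`).
#' @return List with `config`, `genome`, `truth`, `counts`, `tpm`,
#'   `ancestor`, `gene_lengths`, `atac_peaks`, `mark_peaks`,
#'   `motif_hits`, `ncrna`, `atac_signal`, `mark_signals`.
#' @export
simulate_all <- function(config = sim_config()) {
  gn <- simulate_genome(config)
  ex <- simulate_expression(config, gn$genome, gn$truth)
  pk <- simulate_peaks(config, gn$genome, ex$truth, ex$counts,
                       ex$gene_lengths)
  list(config = config, genome = gn$genome, truth = pk$truth,
       counts = ex$counts, tpm = pk$tpm, ancestor = ex$ancestor,
       gene_lengths = ex$gene_lengths, atac_peaks = pk$atac_peaks,
       mark_peaks = pk$mark_peaks, motif_hits = pk$motif_hits,
       ncrna = pk$ncrna, atac_signal = pk$atac_signal,
       mark_signals = pk$mark_signals)
}

#' Write / read the simulation ground truth as JSON
#'
#' @param truth Truth list from the simulator.
#' @param path JSON path.
#' @return `path` invisibly (write); the truth list (read).
#' @export
write_truth <- function(truth, path) {
  # named atomic vectors serialize as JSON objects so names survive
  for (nm in c("phase", "direction", "tf_families"))
    if (!is.null(truth[[nm]])) truth[[nm]] <- as.list(truth[[nm]])
  jsonlite::write_json(truth, path, dataframe = "columns",
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  tr <- jsonlite::read_json(path, simplifyVector = TRUE)
  tr$phase <- unlist(tr$phase)
  tr$direction <- unlist(tr$direction)
  tr$tf_families <- unlist(tr$tf_families)
  for (nm in c("edges", "triads", "divergence", "peak_labels",
               "ncrna_te_map"))
    if (!is.null(tr[[nm]]))
      tr[[nm]] <- as.data.frame(tr[[nm]], stringsAsFactors = FALSE)
  tr
}
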