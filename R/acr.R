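#' Classify ACRs as promoter, genic or distal
#'
#' Taxonomy of accessible chromatin regions by position relative to genes:
#' `pACR` when the peak-to-gene assignment lands in the promoter window,
#' `gACR` for any genic feature (exon/intron/5'UTR/3'UTR), `dACR`
#' otherwise. Downstream-window assignments are folded into `dACR` so the
#' three categories form a true partition. `category == "dACR"` iff no
#' gene is assigned... except for downstream peaks, which keep their gene
#' for bookkeeping but count as distal; set `keep_downstream_gene =
#' FALSE` to drop it.
#'
#' @param peaks Interval `data.frame` of ACRs.
#' @param genome An `"embryodyn_genome"`.
#' @param up_bp,down_bp Assignment windows (defaults 3000 / 2500; the
#'   promoter window for pACR labelling equals the annotation window).
#' @param keep_downstream_gene Keep the assigned gene on
#'   downstream-window peaks (default FALSE, making dACR <=> no gene).
#' @return `data.frame`: peak columns plus `acr_id`, `category`
#'   (pACR/gACR/dACR), `position` (the raw assignment category) and
#'   `gene_id`.
#' @export
classify_acrs <- function(peaks, genome, up_bp = 3000, down_bp = 2500,
                          keep_downstream_gene = FALSE) {
  asg <- assign_peak_to_gene(peaks, genome, up_bp, down_bp)
  category <- ifelse(asg$category == "promoter", "pACR",
                     ifelse(asg$category %in%
                              c("exon", "intron", "5UTR", "3UTR"),
                            "gACR", "dACR"))
  gene_id <- asg$gene_id
  if (!keep_downstream_gene)
    gene_id[category == "dACR"] <- NA_character_
  out <- peaks
  out$acr_id <- if (!all(is.na(peaks$name))) peaks$name else
    paste0("acr", seq_len(nrow(peaks)))
  out$category <- category
  out$position <- asg$category
  out$gene_id <- gene_id
  out
}

#' Gain/loss of peaks between adjacent stages
#'
#' For each adjacent stage pair s -> s+1, a peak of stage s+1 is *gained*
#' when it overlaps (>= 1 bp) no peak of stage s, and a peak of stage s is
#' *lost* when it overlaps no peak of stage s+1. Overlap, not identity,
#' is used because peak boundaries drift between stages.
#'
#' @param peaksets Named list of interval `data.frame`s, ordered by stage.
#' @param stages Optional stage order (default: list names in order).
#' @return `data.frame` with `from`, `to`, `gained`, `lost`, plus
#'   attribute `peaks`: per-pair lists of the gained/lost peak tables.
#' @export
stage_gain_loss <- function(peaksets, stages = names(peaksets)) {
  if (length(peaksets) < 2) stop("need >= 2 stages")
  if (is.null(stages) || !all(stages %in% names(peaksets)))
    stop("unknown stage label in requested stage order")
  peaksets <- peaksets[stages]
  n <- length(stages)
  res <- data.frame(from = stages[-n], to = stages[-1],
                    gained = 0L, lost = 0L, stringsAsFactors = FALSE)
  detail <- vector("list", n - 1)
  for (i in seq_len(n - 1)) {
    a <- peaksets[[i]]; b <- peaksets[[i + 1]]
    gained <- b[!overlaps_any(b, a), , drop = FALSE]
    lost <- a[!overlaps_any(a, b), , drop = FALSE]
    res$gained[i] <- nrow(gained); res$lost[i] <- nrow(lost)
    detail[[i]] <- list(gained = gained, lost = lost)
  }
  names(detail) <- paste(stages[-n], stages[-1], sep = "->")
  attr(res, "peaks") <- detail
  res
}

#' Transient versus constant distal ACRs
#'
#' Splits the middle (burst) stage's dACRs by flanking-stage support:
#' *transient* peaks overlap (>= 1 bp) nothing in either flanking stage;
#' *constant* peaks overlap the earlier or the later set. The two classes
#' partition the middle set.
#'
#' @param dacrs_before,dacrs_burst,dacrs_after Interval `data.frame`s of
#'   dACRs at the flanking and burst stages.
#' @return List with `transient` and `constant` interval `data.frame`s.
#' @export
transient_dacrs <- function(dacrs_before, dacrs_burst, dacrs_after) {
  supported <- overlaps_any(dacrs_burst, dacrs_before) |
    overlaps_any(dacrs_burst, dacrs_after)
  list(transient = dacrs_burst[!supported, , drop = FALSE],
       constant = dacrs_burst[supported, , drop = FALSE])
}

#' Observed/expected overlap enrichment against a shuffled background
#'
#' Counts the query intervals overlapping (>= 1 bp) the feature set, then
#' shuffles length-matched intervals into the background domain
#' `n_shuffles` times and takes the mean overlap count as the
#' expectation. Significance comes from a Fisher exact test
#' (alternative greater) on the observed overlap/non-overlap counts
#' against the pooled shuffle counts.
#'
#' @param query Interval `data.frame` (e.g. transient dACRs).
#' @param features Interval `data.frame` (e.g. TEs or mark peaks).
#' @param background_domain Interval `data.frame` the shuffles are placed
#'   into (e.g. intergenic regions).
#' @param n_shuffles Number of shuffles (default 100).
#' @param seed Integer seed for the shuffles.
#' @return List with `observed`, `expected_mean`, `obs_exp_ratio`
#'   (`Inf` when expected is 0 with observed > 0, `NaN` for 0/0),
#'   `p_value`, `n_shuffles`, `seed`.
#' @export
obs_exp_enrichment <- function(query, features, background_domain,
                               n_shuffles = 100, seed = 1) {
  observed <- sum(overlaps_any(query, features))
  shuffles <- shuffle_intervals(query, background_domain, seed = seed,
                                n_shuffles = n_shuffles)
  bg_counts <- vapply(shuffles, function(s)
    sum(overlaps_any(s, features)), 0)
  expected <- mean(bg_counts)
  nq <- nrow(query)
  ratio <- if (expected > 0) observed / expected
    else if (observed > 0) Inf else NaN
  ft <- fisher_exact(observed, nq - observed, sum(bg_counts),
                     n_shuffles * nq - sum(bg_counts),
                     alternative = "greater")
  list(observed = observed, expected_mean = expected,
       obs_exp_ratio = ratio, p_value = ft$p_value,
       odds_ratio = ft$odds_ratio, n_shuffles = n_shuffles, seed = seed)
}

#' Filter transcripts to non-coding RNA
#'
#' Keeps transcripts with zero overlap (the 1-bp rule applies) to any
#' coding-biotype gene span (TSS..TES).
#'
#' @param transcripts Interval `data.frame` of assembled transcripts.
#' @param genome An `"embryodyn_genome"`.
#' @return The subset of `transcripts` kept as ncRNA.
#' @export
ncrna_filter <- function(transcripts, genome) {
  g <- genome$genes[genome$genes$biotype == "coding", ]
  if (nrow(g) == 0) return(transcripts)
  spans <- genomic_intervals(g$chrom, g$start, g$end)
  transcripts[!overlaps_any(transcripts, spans), , drop = FALSE]
}

#' Compare binned signal along collinear regions
#'
#' Per-bin log2 fold change of two signal tracks over a collinearity map,
#' with the standard calls: `Up` when log2FC >= 1, `Dn` when <= -1, `Nc`
#' otherwise. A pseudocount guards zero bins (0/0 maps to log2FC 0, Nc).
#'
#' @param signal_a,signal_b Equal-length non-negative per-bin vectors
#'   (B is compared relative to A).
#' @param pseudocount Added to both signals (default 1).
#' @return `data.frame` with `log2fc` and `status`.
#' @export
collinear_signal_compare <- function(signal_a, signal_b,
                                     pseudocount = 1) {
  stopifnot(length(signal_a) == length(signal_b))
  if (any(signal_a < 0) || any(signal_b < 0))
    stop("collinear_signal_compare: negative signal")
  lfc <- log2((signal_b + pseudocount) / (signal_a + pseudocount))
  data.frame(log2fc = lfc,
             status = ifelse(lfc >= 1, "Up",
                             ifelse(lfc <= -1, "Dn", "Nc")),
             stringsAsFactors = FALSE)
}
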