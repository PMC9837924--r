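#' Motif enrichment in a cluster of ACRs
#'
#' Per motif, a Fisher exact test (alternative greater) on the counts of
#' ACRs containing at least one hit of the motif, cluster versus
#' background. Motifs with no hit anywhere are skipped and reported.
#'
#' @param cluster_acrs,background_acrs Annotated peak `data.frame`s (from
#'   [classify_acrs()]; must carry `acr_id`).
#' @param hits Motif-hit `data.frame` with columns `motif_id`,
#'   `tf_gene_id`, `chrom`, `start`, `end` (and optional `score`).
#' @param alpha Retention p-value threshold (default 0.05).
#' @return `data.frame` of retained motifs (`motif_id`, `n_cluster`,
#'   `n_background`, `odds_ratio`, `p_value`), sorted by p; attributes
#'   `all` (unfiltered table) and `skipped` (hitless motifs).
#' @export
motif_enrichment <- function(cluster_acrs, background_acrs, hits,
                             alpha = 0.05) {
  if (nrow(cluster_acrs) == 0) stop("motif_enrichment: empty cluster")
  motifs <- unique(hits$motif_id)
  acr_with_hit <- function(acrs, h) {
    if (nrow(h) == 0 || nrow(acrs) == 0) return(character(0))
    ov <- overlap_pairs(acrs, h)
    unique(acrs$acr_id[ov$a_idx])
  }
  rows <- lapply(motifs, function(m) {
    h <- hits[hits$motif_id == m, , drop = FALSE]
    nc <- length(acr_with_hit(cluster_acrs, h))
    nb <- length(acr_with_hit(background_acrs, h))
    if (nc + nb == 0) return(NULL)
    ft <- fisher_exact(nc, nrow(cluster_acrs) - nc, nb,
                       nrow(background_acrs) - nb,
                       alternative = "greater")
    data.frame(motif_id = m, n_cluster = nc, n_background = nb,
               odds_ratio = ft$odds_ratio, p_value = ft$p_value,
               stringsAsFactors = FALSE)
  })
  skipped <- motifs[vapply(rows, is.null, TRUE)]
  all_tab <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(all_tab))
    all_tab <- data.frame(motif_id = character(), n_cluster = integer(),
                          n_background = integer(), odds_ratio = numeric(),
                          p_value = numeric(), stringsAsFactors = FALSE)
  keep <- all_tab[all_tab$p_value < alpha, , drop = FALSE]
  keep <- keep[order(keep$p_value, keep$motif_id), , drop = FALSE]
  rownames(keep) <- NULL
  attr(keep, "all") <- all_tab
  attr(keep, "skipped") <- skipped
  keep
}

#' Link TFs to target genes through motif hits in assigned ACRs
#'
#' Builds one candidate edge for every motif hit falling inside an ACR
#' with an assigned gene, then keeps only co-expressed pairs: the Pearson
#' correlation of the TF and target stage-mean profiles must be
#' significant (`p < alpha`) and, by default, positive (TFs and their
#' targets move synchronously across the stage series). Candidates with
#' a TF or target absent from the expression matrix, self-loops, and
#' undefined (constant-profile) correlations are dropped. Edges are
#' de-duplicated to one per (TF, target) keeping the smallest p.
#'
#' @param enriched_motifs Character vector of motif ids to use (e.g. from
#'   [motif_enrichment()]); `NULL` uses all motifs present in `hits`.
#' @param hits Motif-hit `data.frame` (`motif_id`, `tf_gene_id`, `chrom`,
#'   `start`, `end`).
#' @param annotated_peaks Annotated peaks from [classify_acrs()].
#' @param expr A `"stage_matrix"` covering TFs and targets.
#' @param alpha Co-expression p-value threshold (default 0.05).
#' @param positive_only Require r > 0 (default TRUE).
#' @return `data.frame` of edges (`tf_gene_id`, `target_gene_id`,
#'   `acr_id`, `motif_id`, `r`, `p_value`); attributes `n_tuples`
#'   (retained (tf, motif, acr, target) tuples before de-duplication)
#'   and `dropped` (candidates lost to missing expression).
#' @export
link_tf_targets <- function(enriched_motifs, hits, annotated_peaks,
                            expr, alpha = 0.05, positive_only = TRUE) {
  if (!is.null(enriched_motifs))
    hits <- hits[hits$motif_id %in% enriched_motifs, , drop = FALSE]
  peaks <- annotated_peaks[!is.na(annotated_peaks$gene_id), ,
                           drop = FALSE]
  empty <- data.frame(tf_gene_id = character(),
                      target_gene_id = character(),
                      acr_id = character(), motif_id = character(),
                      r = numeric(), p_value = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(hits) == 0 || nrow(peaks) == 0) return(empty)
  ov <- overlap_pairs(hits, peaks)
  cand <- data.frame(tf_gene_id = hits$tf_gene_id[ov$a_idx],
                     target_gene_id = peaks$gene_id[ov$b_idx],
                     acr_id = peaks$acr_id[ov$b_idx],
                     motif_id = hits$motif_id[ov$a_idx],
                     stringsAsFactors = FALSE)
  cand <- unique(cand[cand$tf_gene_id != cand$target_gene_id, ,
                      drop = FALSE])
  if (nrow(cand) == 0) return(empty)
  m <- stage_means(expr)
  have <- cand$tf_gene_id %in% rownames(m) &
    cand$target_gene_id %in% rownames(m)
  dropped <- cand[!have, , drop = FALSE]
  cand <- cand[have, , drop = FALSE]
  pairs <- unique(cand[, c("tf_gene_id", "target_gene_id")])
  stat <- mapply(function(tf, tg) {
    t <- pearson_test(m[tf, ], m[tg, ])
    c(r = if (isTRUE(t$undefined)) NA_real_ else t$r,
      p = if (isTRUE(t$undefined)) NA_real_ else t$p_value)
  }, pairs$tf_gene_id, pairs$target_gene_id)
  key <- function(d) paste(d$tf_gene_id, d$target_gene_id)
  i <- match(key(cand), key(pairs))
  cand$r <- stat["r", i]
  cand$p_value <- stat["p", i]
  keep <- !is.na(cand$p_value) & cand$p_value < alpha
  if (positive_only) keep <- keep & cand$r > 0
  cand <- cand[keep, , drop = FALSE]
  n_tuples <- nrow(cand)
  cand <- cand[order(cand$p_value, cand$tf_gene_id, cand$target_gene_id,
                     cand$acr_id, cand$motif_id), , drop = FALSE]
  edges <- cand[!duplicated(cand[, c("tf_gene_id", "target_gene_id")]), ,
                drop = FALSE]
  edges <- edges[order(edges$tf_gene_id, edges$target_gene_id), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  attr(edges, "n_tuples") <- n_tuples
  attr(edges, "dropped") <- dropped
  edges
}

#' Collapse TF-level edges into family modules
#'
#' TFs of the same family (e.g. the TCP, ARF, MYB and WOX classes) are
#' combined into one module node; a module->gene edge exists iff at least
#' one member edge does, weighted by the member-edge count. Unmapped TFs
#' keep singleton modules named by their own id.
#'
#' @param edges Edge `data.frame` from [link_tf_targets()].
#' @param family_map Named character vector, TF gene id -> family label.
#' @return `data.frame` (`module`, `target_gene_id`, `weight`,
#'   `members`), deterministic order.
#' @export
collapse_tf_modules <- function(edges, family_map) {
  if (nrow(edges) == 0)
    return(data.frame(module = character(), target_gene_id = character(),
                      weight = integer(), members = character(),
                      stringsAsFactors = FALSE))
  mod <- family_map[edges$tf_gene_id]
  mod[is.na(mod)] <- edges$tf_gene_id[is.na(mod)]
  agg <- stats::aggregate(list(weight = seq_len(nrow(edges))),
                          by = list(module = unname(mod),
                                    target_gene_id =
                                      edges$target_gene_id),
                          FUN = length)
  members <- stats::aggregate(
    list(members = edges$tf_gene_id),
    by = list(module = unname(mod),
              target_gene_id = edges$target_gene_id),
    FUN = function(v) paste(sort(unique(v)), collapse = ","))
  out <- merge(agg, members, by = c("module", "target_gene_id"))
  out <- out[order(out$module, out$target_gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract the TF-TF subnetwork
#'
#' Edges whose target is itself a TF. When an expression matrix is given,
#' each node is annotated with its expression-timing attribute: the first
#' stage where the z-scored stage-mean profile reaches `z_min`.
#'
#' @param edges Edge `data.frame` from [link_tf_targets()].
#' @param tf_set Character vector of TF gene ids.
#' @param expr Optional `"stage_matrix"` for node activation timing.
#' @param z_min Activation z threshold (default 1).
#' @return List with `edges` (subset) and `nodes` (`data.frame`:
#'   `gene_id`, `activation_stage`).
#' @export
tf_tf_subnetwork <- function(edges, tf_set, expr = NULL, z_min = 1) {
  sub <- edges[edges$target_gene_id %in% tf_set, , drop = FALSE]
  nodes <- sort(unique(c(sub$tf_gene_id, sub$target_gene_id)))
  act <- rep(NA_character_, length(nodes))
  if (!is.null(expr) && length(nodes)) {
    stages <- sm_stages(expr)
    m <- stage_means(expr)
    has <- nodes %in% rownames(m)
    z <- t(scale(t(m[nodes[has], , drop = FALSE])))
    act[has] <- apply(z, 1, function(v) {
      i <- which(!is.na(v) & v >= z_min)
      if (length(i)) stages[i[1]] else NA_character_
    })
  }
  list(edges = sub,
       nodes = data.frame(gene_id = nodes, activation_stage = act,
                          stringsAsFactors = FALSE))
}
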