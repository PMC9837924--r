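PKG_VERSION <- "0.1.0"

# stable string hash (31-polynomial mod 2^31-1); fans the global seed out
# to per-module streams so adding a module never perturbs another's draws
str_hash <- function(s) {
  h <- 0
  for (c in utf8ToInt(s)) h <- (h * 31 + c) %% 2147483647
  as.integer(h)
}

#' Per-module seed derived from a global seed
#'
#' @param seed Global integer seed.
#' @param module Module name.
#' @return Integer seed below 2^31.
#' @export
module_seed <- function(seed, module)
  as.integer((as.numeric(seed) + str_hash(module)) %% 2147483647)

config_hash <- function(config)
  sprintf("%08x", str_hash(paste(deparse(config[order(names(config))]),
                                 collapse = "")))

header_line <- function(hash)
  paste0("# embryodyn ", PKG_VERSION, " config=", hash)

write_tsv_out <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header_line(hash), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Run the full simulate-and-analyze pipeline
#'
#' Generates the synthetic dataset, writes its raw inputs (GFF3, BEDs,
#' matrices, truth JSON), then runs every analysis stage in dependency
#' order: ACR classification of the merged peak set, stage gain/loss and
#' transient-dACR detection, TE obs/expected enrichment of transient
#' versus constant dACRs, ncRNA filtering, differential expression
#' between adjacent stages, DTU pseudotime with angular gene ordering,
#' GRN inference, triad bias classification and divergence clustering.
#' Every TSV output carries a header comment with the tool version and
#' config hash; a machine-readable JSON report records seeds, parameters
#' and output row counts.
#'
#' The global seed fans out to per-module seeds by stable hashing of the
#' module names ([module_seed()]).
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Global integer seed.
#' @param sim_overrides Named list of [sim_config()] overrides.
#' @param n_shuffles Shuffles for the enrichment background.
#' @param config_file Optional YAML file of `sim_overrides`.
#' @return The report list, invisibly; all outputs under `out_dir`.
#' @export
run_pipeline <- function(out_dir, seed = 1, sim_overrides = list(),
                         n_shuffles = 100, config_file = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(config_file)) {
    if (!file.exists(config_file))
      stop("config file not found: ", config_file)
    sim_overrides <- utils::modifyList(yaml::read_yaml(config_file),
                                       sim_overrides)
  }
  cfg <- do.call(sim_config,
                 utils::modifyList(
                   list(seed = module_seed(seed, "simulate")),
                   sim_overrides))
  hash <- config_hash(cfg)
  p <- function(...) file.path(out_dir, paste0(...))
  report <- list(tool = "embryodyn", version = PKG_VERSION,
                 seed = seed, config_hash = hash,
                 config = cfg[setdiff(names(cfg), "stages")],
                 stages = cfg$stages, outputs = list())
  note <- function(name, path, n) {
    report$outputs[[name]] <<- list(file = basename(path), rows = n)
  }

  step <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(conditionMessage(e), p(name, ".partial"))
      stop("pipeline stage '", name, "' failed: ",
           conditionMessage(e), call. = FALSE)
    })
  }

  ## simulate ---------------------------------------------------------
  sim <- step("simulate", simulate_all(cfg))
  write_gff3(sim$genome, p("genes.gff3"))
  write_bed(sim$genome$tes, p("tes.bed"))
  write_chrom_sizes(sim$genome$chrom_sizes, p("chrom.sizes"))
  write_stage_matrix(sim$counts, p("counts.tsv"))
  write_stage_matrix(sim$tpm, p("tpm.tsv"))
  write_stage_matrix(sim$ancestor, p("ancestor.tsv"))
  write_stage_matrix(sim$atac_signal, p("atac_signal.tsv"))
  for (s in cfg$stages)
    write_bed(sim$atac_peaks[[s]], p("atac_", s, ".bed"))
  write_tsv_out(sim$motif_hits, p("motif_hits.tsv"), hash)
  write_tsv_out(sim$truth$triads, p("triads.tsv"), hash)
  write_tsv_out(data.frame(tf_gene_id = names(sim$truth$tf_families),
                           family = unname(sim$truth$tf_families)),
                p("family_map.tsv"), hash)
  write_truth(sim$truth, p("truth.json"))
  note("simulate", p("truth.json"), nrow(sim$genome$genes))

  ## annotate-acrs ----------------------------------------------------
  acrs <- step("annotate-acrs", {
    merged <- merge_intervals(do.call(rbind, sim$atac_peaks))
    merged$name <- sprintf("ACR%05d", seq_len(nrow(merged)))
    classify_acrs(merged, sim$genome)
  })
  write_tsv_out(acrs[, c("acr_id", "chrom", "start", "end", "category",
                         "position", "gene_id")],
                p("acr_annotation.tsv"), hash)
  note("annotate-acrs", p("acr_annotation.tsv"), nrow(acrs))

  ## dynamics ---------------------------------------------------------
  dyn <- step("dynamics", {
    per_stage <- lapply(sim$atac_peaks, classify_acrs,
                        genome = sim$genome)
    dacrs <- lapply(per_stage, function(x)
      x[x$category == "dACR", , drop = FALSE])
    gl <- stage_gain_loss(sim$atac_peaks)
    bi <- cfg$burst_stage_index
    tc <- transient_dacrs(dacrs[[bi - 1]], dacrs[[bi]], dacrs[[bi + 1]])
    counts <- data.frame(stage = cfg$stages,
                         n_peaks = vapply(sim$atac_peaks, nrow, 0L),
                         n_dacr = vapply(dacrs, nrow, 0L))
    list(gain_loss = gl, transient = tc, counts = counts,
         dacrs = dacrs)
  })
  write_tsv_out(dyn$gain_loss, p("gain_loss.tsv"), hash)
  write_tsv_out(dyn$counts, p("stage_peak_counts.tsv"), hash)
  write_tsv_out(rbind(cbind(dyn$transient$transient, class = "transient"),
                      cbind(dyn$transient$constant, class = "constant")),
                p("transient_dacrs.tsv"), hash)
  note("dynamics", p("transient_dacrs.tsv"),
       nrow(dyn$transient$transient))

  ## enrich -----------------------------------------------------------
  enr <- step("enrich", {
    domain <- intergenic_regions(sim$genome)
    es <- module_seed(seed, "enrich")
    tr <- obs_exp_enrichment(dyn$transient$transient, sim$genome$tes,
                             domain, n_shuffles = n_shuffles, seed = es)
    co <- obs_exp_enrichment(dyn$transient$constant, sim$genome$tes,
                             domain, n_shuffles = n_shuffles,
                             seed = es + 1L)
    data.frame(query = c("transient_dACR", "constant_dACR"),
               feature = "TE",
               observed = c(tr$observed, co$observed),
               expected_mean = c(tr$expected_mean, co$expected_mean),
               obs_exp_ratio = c(tr$obs_exp_ratio, co$obs_exp_ratio),
               p_value = c(tr$p_value, co$p_value),
               n_shuffles = n_shuffles, seed = c(es, es + 1L))
  })
  write_tsv_out(enr, p("enrichment.tsv"), hash)
  note("enrich", p("enrichment.tsv"), nrow(enr))

  ## ncRNA filter -----------------------------------------------------
  ncr <- step("ncrna", ncrna_filter(sim$ncrna, sim$genome))
  write_tsv_out(ncr, p("ncrna_filtered.tsv"), hash)
  note("ncrna", p("ncrna_filtered.tsv"), nrow(ncr))

  ## diffexpr ---------------------------------------------------------
  degs <- step("diffexpr", {
    cs <- col_stages(sim$tpm)
    out <- list()
    for (i in seq_len(length(cfg$stages) - 1)) {
      a <- unclass(sim$tpm)[, cs == cfg$stages[i], drop = FALSE]
      b <- unclass(sim$tpm)[, cs == cfg$stages[i + 1], drop = FALSE]
      d <- call_degs(a, b)
      d$from <- cfg$stages[i]; d$to <- cfg$stages[i + 1]
      out[[i]] <- d[d$status != "Nc", , drop = FALSE]
    }
    do.call(rbind, out)
  })
  write_tsv_out(degs, p("degs.tsv"), hash)
  note("diffexpr", p("degs.tsv"), nrow(degs))

  ## pseudotime -------------------------------------------------------
  pt <- step("pseudotime", {
    traj <- compute_dtu(sim$tpm)
    ord <- angular_order(sim$tpm, trajectory = traj)
    list(traj = traj, ord = ord)
  })
  write_tsv_out(data.frame(stage = pt$traj$stages, dtu = pt$traj$dtu,
                           pc1 = pt$traj$pcs[, 1],
                           pc2 = pt$traj$pcs[, 2]),
                p("dtu_trajectory.tsv"), hash)
  write_tsv_out(pt$ord$order, p("gene_order.tsv"), hash)
  hm <- order_heatmap_matrix(pt$ord)
  write_tsv_out(data.frame(gene = rownames(hm), round(hm, 4),
                           check.names = FALSE),
                p("order_heatmap.tsv"), hash)
  note("pseudotime", p("gene_order.tsv"), nrow(pt$ord$order))

  ## grn --------------------------------------------------------------
  grn <- step("grn", {
    edges <- link_tf_targets(NULL, sim$motif_hits, acrs, sim$tpm)
    fam <- sim$truth$tf_families
    mods <- collapse_tf_modules(edges, fam)
    tfnet <- tf_tf_subnetwork(edges, names(fam), expr = sim$tpm)
    list(edges = edges, mods = mods, tfnet = tfnet)
  })
  write_tsv_out(grn$edges, p("grn_edges.tsv"), hash)
  write_tsv_out(grn$mods, p("grn_modules.tsv"), hash)
  write_tsv_out(grn$tfnet$edges, p("grn_tf_tf.tsv"), hash)
  note("grn", p("grn_edges.tsv"), nrow(grn$edges))

  ## triads -----------------------------------------------------------
  tri <- step("triads", {
    pooled <- classify_triads(sim$tpm, sim$truth$triads)
    tc <- triad_balance_timecourse(sim$tpm, sim$truth$triads)
    list(pooled = pooled, tc = tc)
  })
  write_tsv_out(tri$pooled, p("triad_bias.tsv"), hash)
  write_tsv_out(data.frame(stage = rownames(tri$tc$counts),
                           tri$tc$counts, check.names = FALSE),
                p("triad_timecourse.tsv"), hash)
  note("triads", p("triad_bias.tsv"), nrow(tri$pooled))

  ## divergence -------------------------------------------------------
  div <- step("divergence", divergence_classify(sim$tpm, sim$ancestor))
  write_tsv_out(div, p("divergence.tsv"), hash)
  note("divergence", p("divergence.tsv"), nrow(div))

  jsonlite::write_json(report, p("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(report)
}
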