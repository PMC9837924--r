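#' Construct a genome annotation object
#'
#' The container used by peak annotation and the simulator: chromosome
#' sizes, a gene table, a per-gene feature table (exon/intron/UTR pieces)
#' and transposable-element intervals. All coordinates are 0-based
#' half-open. `tss`/`tes` are strand-aware boundary coordinates: on `+`,
#' `tss = start` and `tes = end`; on `-` the converse, so `tss > tes` on
#' the minus strand.
#'
#' @param chrom_sizes Named numeric vector of chromosome lengths.
#' @param genes `data.frame` with columns `gene_id`, `chrom`, `strand`,
#'   `start`, `end`, `tss`, `tes`, `biotype` (`coding`/`noncoding`),
#'   `subgenome` (`A`/`B`/`D`/`NA`), `triad_id` (optional id).
#' @param features `data.frame` with columns `gene_id`, `kind` (one of
#'   `exon`, `intron`, `5UTR`, `3UTR`), `chrom`, `start`, `end`.
#' @param tes Interval `data.frame` of transposable elements.
#' @return A list with class `"embryodyn_genome"`.
#' @export
genome_annotation <- function(chrom_sizes, genes,
                              features = NULL, tes = NULL) {
  stopifnot(!is.null(names(chrom_sizes)), all(chrom_sizes > 0))
  need <- c("gene_id", "chrom", "strand", "start", "end", "tss", "tes")
  stopifnot(all(need %in% names(genes)))
  if (!"biotype" %in% names(genes)) genes$biotype <- "coding"
  if (!"subgenome" %in% names(genes)) genes$subgenome <- NA_character_
  if (!"triad_id" %in% names(genes)) genes$triad_id <- NA_character_
  if (is.null(features))
    features <- data.frame(gene_id = character(), kind = character(),
                           chrom = character(), start = numeric(),
                           end = numeric(), stringsAsFactors = FALSE)
  if (is.null(tes))
    tes <- genomic_intervals(character(), numeric(), numeric())
  bad <- !genes$chrom %in% names(chrom_sizes)
  if (any(bad))
    stop("gene ", genes$gene_id[bad][1], " on unknown chromosome ",
         genes$chrom[bad][1])
  if (any(genes$end > chrom_sizes[genes$chrom]))
    stop("gene extends beyond chromosome bounds")
  plus <- genes$strand == "+"
  if (any(plus & genes$tss >= genes$tes) ||
      any(!plus & genes$strand == "-" & genes$tss <= genes$tes))
    stop("tss/tes orientation inconsistent with strand")
  if (nrow(tes) > 0 && any(tes$end > chrom_sizes[tes$chrom]))
    stop("TE extends beyond chromosome bounds")
  structure(list(chrom_sizes = chrom_sizes, genes = genes,
                 features = features, tes = tes),
            class = "embryodyn_genome")
}

#' @export
print.embryodyn_genome <- function(x, ...) {
  cat("embryodyn genome:", length(x$chrom_sizes), "chromosomes (",
      format_coord(sum(x$chrom_sizes)), "bp ),", nrow(x$genes), "genes,",
      nrow(x$tes), "TEs\n")
  invisible(x)
}

parse_gff_attr <- function(attr, key) {
  m <- regmatches(attr, regexec(paste0("(^|;)", key, "=([^;]+)"), attr))
  vapply(m, function(g) if (length(g) >= 3) g[3] else NA_character_, "")
}

#' Read a GFF3 gene annotation
#'
#' Parses `gene`, `mRNA`, `exon` and UTR features. The 1-based closed GFF3
#' coordinates are converted to the internal 0-based half-open convention
#' on read. For each gene the longest transcript (by summed exon length)
#' is kept and introns are derived as the gaps between its consecutive
#' exons. The TSS is the strand-aware 5' end of the gene.
#'
#' Recognised gene attributes: `ID` (required), `biotype`, `subgenome`,
#' `triad_id`.
#'
#' @param path GFF3 file path.
#' @param chrom_sizes Optional named vector; inferred from the maximum
#'   feature end per chromosome when absent.
#' @return An `"embryodyn_genome"` (with an empty TE table).
#' @export
read_gff3 <- function(path, chrom_sizes = NULL) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) != 9))
    stop("malformed GFF3 line ", which(lengths(f) != 9)[1])
  tab <- data.frame(chrom = vapply(f, `[[`, "", 1),
                    type = vapply(f, `[[`, "", 3),
                    start = as.numeric(vapply(f, `[[`, "", 4)) - 1,
                    end = as.numeric(vapply(f, `[[`, "", 5)),
                    strand = vapply(f, `[[`, "", 7),
                    attr = vapply(f, `[[`, "", 9),
                    stringsAsFactors = FALSE)
  if (any(!tab$strand %in% c("+", "-")))
    stop("unknown strand '", tab$strand[!tab$strand %in% c("+", "-")][1],
         "' in GFF3")
  g <- tab[tab$type == "gene", ]
  if (nrow(g) == 0) stop("GFF3 contains no gene features")
  g$gene_id <- parse_gff_attr(g$attr, "ID")
  g$biotype <- parse_gff_attr(g$attr, "biotype")
  g$biotype[is.na(g$biotype)] <- "coding"
  g$subgenome <- parse_gff_attr(g$attr, "subgenome")
  g$triad_id <- parse_gff_attr(g$attr, "triad_id")

  tx <- tab[tab$type %in% c("mRNA", "transcript"), ]
  tx$tx_id <- parse_gff_attr(tx$attr, "ID")
  tx$parent <- parse_gff_attr(tx$attr, "Parent")
  sub <- tab[tab$type %in% c("exon", "five_prime_UTR", "three_prime_UTR"), ]
  sub$parent <- parse_gff_attr(sub$attr, "Parent")
  kind_map <- c(exon = "exon", five_prime_UTR = "5UTR",
                three_prime_UTR = "3UTR")
  sub$kind <- kind_map[sub$type]

  feats <- vector("list", nrow(g))
  for (i in seq_len(nrow(g))) {
    gid <- g$gene_id[i]
    tids <- tx$tx_id[tx$parent == gid]
    if (length(tids) == 0) {
      # gene without transcript children: treat the span as one exon
      feats[[i]] <- data.frame(gene_id = gid, kind = "exon",
                               chrom = g$chrom[i], start = g$start[i],
                               end = g$end[i], stringsAsFactors = FALSE)
      next
    }
    pick <- tids[1]
    if (length(tids) > 1) {
      len <- vapply(tids, function(t) {
        e <- sub[sub$parent == t & sub$kind == "exon", ]
        sum(e$end - e$start)
      }, 0)
      pick <- tids[which.max(len)]
    }
    fx <- sub[sub$parent == pick, ]
    ex <- fx[fx$kind == "exon", ]
    ex <- ex[order(ex$start), ]
    if (nrow(ex) == 0)
      stop("transcript ", pick, " has no exons")
    if (min(ex$start) < g$start[i] || max(ex$end) > g$end[i])
      stop("exon outside gene span for gene ", gid)
    out <- fx[, c("chrom", "start", "end", "kind")]
    if (nrow(ex) > 1) {
      introns <- data.frame(chrom = ex$chrom[-1],
                            start = ex$end[-nrow(ex)],
                            end = ex$start[-1], kind = "intron",
                            stringsAsFactors = FALSE)
      introns <- introns[introns$end > introns$start, ]
      out <- rbind(out, introns)
    }
    out$gene_id <- gid
    feats[[i]] <- out[, c("gene_id", "kind", "chrom", "start", "end")]
  }
  features <- do.call(rbind, feats)
  plus <- g$strand == "+"
  genes <- data.frame(gene_id = g$gene_id, chrom = g$chrom,
                      strand = g$strand, start = g$start, end = g$end,
                      tss = ifelse(plus, g$start, g$end),
                      tes = ifelse(plus, g$end, g$start),
                      biotype = g$biotype, subgenome = g$subgenome,
                      triad_id = g$triad_id, stringsAsFactors = FALSE)
  if (is.null(chrom_sizes)) {
    chrom_sizes <- tapply(tab$end, tab$chrom, max)
    chrom_sizes <- stats::setNames(as.numeric(chrom_sizes),
                                   names(chrom_sizes))
  }
  genome_annotation(chrom_sizes, genes, features)
}

#' Write a genome annotation as GFF3
#'
#' Inverse of [read_gff3()]: internal 0-based half-open coordinates are
#' converted back to 1-based closed GFF3. One mRNA per gene is emitted
#' with its exon/UTR children; introns are implicit.
#'
#' @param genome An `"embryodyn_genome"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genome, path) {
  g <- genome$genes
  g <- g[order(g$chrom, g$start, g$gene_id), ]
  fmt <- function(chrom, type, start, end, strand, attr)
    paste(chrom, "embryodyn", type, format_coord(start + 1),
          format_coord(end), ".", strand, ".", attr, sep = "\t")
  lines <- c("##gff-version 3")
  for (i in seq_len(nrow(g))) {
    gid <- g$gene_id[i]
    attr <- paste0("ID=", gid, ";biotype=", g$biotype[i])
    if (!is.na(g$subgenome[i]))
      attr <- paste0(attr, ";subgenome=", g$subgenome[i])
    if (!is.na(g$triad_id[i]))
      attr <- paste0(attr, ";triad_id=", g$triad_id[i])
    lines <- c(lines, fmt(g$chrom[i], "gene", g$start[i], g$end[i],
                          g$strand[i], attr))
    tid <- paste0(gid, ".1")
    lines <- c(lines, fmt(g$chrom[i], "mRNA", g$start[i], g$end[i],
                          g$strand[i], paste0("ID=", tid, ";Parent=", gid)))
    fx <- genome$features[genome$features$gene_id == gid &
                            genome$features$kind != "intron", ]
    fx <- fx[order(fx$start), ]
    type_map <- c(exon = "exon", `5UTR` = "five_prime_UTR",
                  `3UTR` = "three_prime_UTR")
    for (j in seq_len(nrow(fx)))
      lines <- c(lines, fmt(fx$chrom[j], type_map[[fx$kind[j]]],
                            fx$start[j], fx$end[j], g$strand[i],
                            paste0("ID=", tid, ".", fx$kind[j], j,
                                   ";Parent=", tid)))
  }
  writeLines(lines, path)
  invisible(path)
}

# Candidate assignment windows for every gene, with position priority
# (promoter > exon > intron > 5UTR > 3UTR > downstream). Promoter and
# downstream windows are strand-aware; the genic features come from the
# annotation as-is.
gene_windows <- function(genome, up_bp = 3000, down_bp = 2500) {
  g <- genome$genes
  plus <- g$strand == "+"
  prom <- data.frame(gene_id = g$gene_id, kind = "promoter",
                     chrom = g$chrom,
                     start = ifelse(plus, g$tss - up_bp, g$tss),
                     end = ifelse(plus, g$tss, g$tss + up_bp),
                     stringsAsFactors = FALSE)
  down <- data.frame(gene_id = g$gene_id, kind = "downstream",
                     chrom = g$chrom,
                     start = ifelse(plus, g$tes, g$tes - down_bp),
                     end = ifelse(plus, g$tes + down_bp, g$tes),
                     stringsAsFactors = FALSE)
  w <- rbind(prom,
             genome$features[, c("gene_id", "kind", "chrom", "start",
                                 "end")],
             down)
  w$start <- pmax(w$start, 0)
  w$end <- pmin(w$end, genome$chrom_sizes[w$chrom])
  w <- w[w$end > w$start, ]
  priority <- c(promoter = 1, exon = 2, intron = 3, `5UTR` = 4,
                `3UTR` = 5, downstream = 6)
  w$priority <- priority[w$kind]
  rownames(w) <- NULL
  w
}

#' Assign peaks to genes by position priority
#'
#' Implements proximal peak-to-gene assignment: a peak overlapping (>= 1 bp)
#' any candidate window of a gene -- the strand-aware promoter (`up_bp`
#' upstream of the TSS), the genic features, or the strand-aware
#' `down_bp` downstream of the TES -- is assigned to a gene using the
#' position-priority order promoter > exon > intron > 5'UTR > 3'UTR >
#' downstream. Ties at equal priority are broken by the smallest distance
#' from the peak midpoint to the TSS (the nearest-gene principle), then by
#' lexicographic `gene_id`. Peaks touching no window are `distal` with no
#' gene.
#'
#' @param peaks Interval `data.frame`.
#' @param genome An `"embryodyn_genome"`.
#' @param up_bp Promoter window size upstream of the TSS (default 3000).
#' @param down_bp Downstream window size beyond the TES (default 2500).
#' @return `data.frame` with one row per peak: `gene_id` (`NA` when
#'   distal) and `category` in promoter/exon/intron/5UTR/3UTR/downstream/
#'   distal.
#' @export
assign_peak_to_gene <- function(peaks, genome, up_bp = 3000,
                                down_bp = 2500) {
  validate_intervals(peaks, "peak")
  bad <- !peaks$chrom %in% names(genome$chrom_sizes)
  if (any(bad))
    stop("peak chromosome ", peaks$chrom[bad][1], " absent from genome")
  out <- data.frame(gene_id = rep(NA_character_, nrow(peaks)),
                    category = rep("distal", nrow(peaks)),
                    stringsAsFactors = FALSE)
  if (nrow(peaks) == 0) return(out)
  w <- gene_windows(genome, up_bp, down_bp)
  hits <- overlap_pairs(peaks, w)
  if (nrow(hits) == 0) return(out)
  tss <- stats::setNames(genome$genes$tss, genome$genes$gene_id)
  cand <- data.frame(peak = hits$a_idx,
                     gene_id = w$gene_id[hits$b_idx],
                     kind = w$kind[hits$b_idx],
                     priority = w$priority[hits$b_idx],
                     stringsAsFactors = FALSE)
  mid <- (peaks$start + peaks$end) / 2
  cand$tss_dist <- abs(mid[cand$peak] - tss[cand$gene_id])
  cand <- cand[order(cand$peak, cand$priority, cand$tss_dist,
                     cand$gene_id), ]
  best <- cand[!duplicated(cand$peak), ]
  out$gene_id[best$peak] <- best$gene_id
  out$category[best$peak] <- best$kind
  out
}

#' Intergenic regions of a genome
#'
#' Complement of the gene spans over the chromosomes; the domain used for
#' shuffled enrichment backgrounds.
#'
#' @param genome An `"embryodyn_genome"`.
#' @return Interval `data.frame` of intergenic segments.
#' @export
intergenic_regions <- function(genome) {
  chroms <- data.frame(chrom = names(genome$chrom_sizes), start = 0,
                       end = as.numeric(genome$chrom_sizes),
                       name = NA_character_, score = NA_real_,
                       strand = ".", stringsAsFactors = FALSE)
  g <- genome$genes
  if (nrow(g) == 0) return(chroms)
  spans <- genomic_intervals(g$chrom, g$start, g$end)
  subtract_intervals(chroms, spans)
}
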