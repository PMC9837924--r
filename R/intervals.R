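#' @importFrom GenomicRanges GRanges findOverlaps reduce setdiff seqnames
#'   start end strand
#' @importFrom IRanges IRanges width
#' @importFrom S4Vectors queryHits subjectHits mcols
NULL

STRAND_VOCAB <- c("+", "-", ".")

#' Construct a genomic-interval table
#'
#' All peak/TE/feature coordinates in this package live in a plain
#' `data.frame` with BED-style 0-based half-open coordinates
#' (`start` inclusive, `end` exclusive). One convention everywhere removes
#' whole classes of off-by-one bugs; GFF3 is converted on read/write.
#'
#' @param chrom Chromosome ids (character, non-empty).
#' @param start 0-based inclusive start positions.
#' @param end Exclusive end positions; `start < end` is enforced.
#' @param strand One of `"+"`, `"-"`, `"."` (recycled).
#' @param name Optional interval ids (`NA` allowed).
#' @param score Optional numeric scores (`NA` allowed).
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `name`,
#'   `score`, `strand`.
#' @examples
#' gi <- genomic_intervals("chr1A", 0, 100, strand = "+", name = "p1")
#' @export
genomic_intervals <- function(chrom, start, end, strand = ".",
                              name = NA_character_, score = NA_real_) {
  if (length(chrom) == 0)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), name = character(),
                      score = numeric(), strand = character(),
                      stringsAsFactors = FALSE))
  x <- data.frame(chrom = as.character(chrom),
                  start = as.numeric(start),
                  end = as.numeric(end),
                  name = as.character(name),
                  score = as.numeric(score),
                  strand = as.character(strand),
                  stringsAsFactors = FALSE)
  validate_intervals(x)
  x
}

#' Validate an interval table
#'
#' Checks the invariants of the interval data model: non-empty chromosome
#' ids, `0 <= start < end`, and strand in the three-symbol vocabulary.
#'
#' @param x A `data.frame` with at least `chrom`, `start`, `end` columns.
#' @param what Label used in error messages.
#' @return `x`, invisibly, if valid; otherwise an error is raised.
#' @export
validate_intervals <- function(x, what = "interval") {
  stopifnot(is.data.frame(x))
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop(what, " table lacks column(s): ", paste(miss, collapse = ", "))
  if (nrow(x) == 0) return(invisible(x))
  if (any(is.na(x$chrom)) || any(!nzchar(x$chrom)))
    stop(what, ": empty chromosome id")
  if (any(x$start < 0))
    stop(what, ": negative start coordinate")
  bad <- which(x$start >= x$end)
  if (length(bad))
    stop(what, ": zero-length interval at row ", bad[1],
         " (start >= end)")
  if ("strand" %in% names(x) && any(!x$strand %in% STRAND_VOCAB))
    stop(what, ": strand must be one of +, -, .")
  invisible(x)
}

# 0-based half-open data.frame -> 1-based closed GRanges (strand dropped:
# overlap is strand-blind throughout this package)
gi_to_gr <- function(x) {
  if (nrow(x) == 0)
    return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(x$chrom,
                         IRanges::IRanges(x$start + 1L, x$end))
}

gr_to_gi <- function(gr) {
  if (length(gr) == 0)
    return(genomic_intervals(character(), numeric(), numeric()))
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = as.numeric(GenomicRanges::end(gr)),
             name = NA_character_, score = NA_real_,
             strand = ".", stringsAsFactors = FALSE)
}

sort_intervals <- function(x) {
  x[order(x$chrom, x$start, x$end,
          if ("name" %in% names(x)) x$name else seq_len(nrow(x))), ,
    drop = FALSE]
}

#' Read a BED/narrowPeak file
#'
#' Accepts BED3/BED6 and ENCODE narrowPeak (10 columns). Coordinates stay
#' 0-based half-open as in the file. The narrowPeak extra columns
#' (`signalValue`, `pValue`, `qValue`, `peak`) are preserved as metadata
#' columns.
#'
#' @param path Path to a tab-separated BED-like file.
#' @return An interval `data.frame` (see [genomic_intervals()]).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0)
    return(genomic_intervals(character(), numeric(), numeric()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    stop("malformed BED line ", which(nf < 3)[1], ": fewer than 3 columns")
  ncol_use <- min(nf)
  get <- function(i) vapply(fields, `[[`, "", i)
  start <- suppressWarnings(as.numeric(get(2)))
  end <- suppressWarnings(as.numeric(get(3)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop("malformed BED line ", bad[1], ": non-numeric coordinates")
  bad <- which(start >= end)
  if (length(bad))
    stop("zero-length interval at BED line ", bad[1])
  x <- data.frame(chrom = get(1), start = start, end = end,
                  name = NA_character_, score = NA_real_, strand = ".",
                  stringsAsFactors = FALSE)
  na_dot <- function(v) ifelse(v == ".", NA, v)
  if (ncol_use >= 4) x$name <- na_dot(get(4))
  if (ncol_use >= 5) x$score <- as.numeric(na_dot(get(5)))
  if (ncol_use >= 6) {
    s <- get(6)
    if (any(!s %in% STRAND_VOCAB))
      stop("malformed BED line ", which(!s %in% STRAND_VOCAB)[1],
           ": bad strand")
    x$strand <- s
  }
  if (ncol_use >= 10) {       # narrowPeak
    x$signalValue <- as.numeric(get(7))
    x$pValue <- as.numeric(get(8))
    x$qValue <- as.numeric(get(9))
    x$peak <- as.integer(get(10))
  }
  validate_intervals(x, what = "BED")
  x
}

#' Write intervals as BED/narrowPeak
#'
#' Emits a sorted, tab-separated, newline-terminated file. BED6 columns are
#' always written; when the narrowPeak metadata columns are present a
#' 10-column narrowPeak file is produced. Missing names/scores are written
#' as `"."` so that `read_bed(write_bed(x))` round-trips.
#'
#' @param x Interval `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  validate_intervals(x)
  x <- sort_intervals(x)
  dot <- function(v) ifelse(is.na(v), ".", as.character(v))
  cols <- list(x$chrom, format_coord(x$start), format_coord(x$end),
               dot(x$name), dot(x$score), dot(x$strand))
  if (all(c("signalValue", "pValue", "qValue", "peak") %in% names(x)))
    cols <- c(cols, list(dot(x$signalValue), dot(x$pValue),
                         dot(x$qValue), dot(x$peak)))
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

# integer-like coordinates without scientific notation
format_coord <- function(v) format(v, scientific = FALSE, trim = TRUE)

#' Read a two-column chrom.sizes file
#'
#' @param path TSV with columns chrom, length.
#' @return Named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("chrom.sizes needs two columns")
  stats::setNames(as.numeric(tab[[2]]), tab[[1]])
}

#' Write a chrom.sizes file
#' @param sizes Named numeric vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chrom_sizes <- function(sizes, path) {
  o <- order(names(sizes))
  writeLines(paste(names(sizes)[o], format_coord(sizes[o]), sep = "\t"),
             path)
  invisible(path)
}

#' All overlapping interval pairs
#'
#' Reports every pair of intervals from `a` and `b` on the same chromosome
#' sharing at least `min_overlap_bp` bases. Overlap is strand-blind; a
#' single shared base counts by default (the 1-bp overlap rule used for all
#' peak-overlap accounting in this package).
#'
#' @param a,b Interval `data.frame`s.
#' @param min_overlap_bp Minimum shared bases (>= 1).
#' @return A `data.frame` with 1-based indices `a_idx`, `b_idx`, sorted.
#' @export
overlap_pairs <- function(a, b, min_overlap_bp = 1) {
  stopifnot(min_overlap_bp >= 1)
  validate_intervals(a, "a"); validate_intervals(b, "b")
  if (nrow(a) == 0 || nrow(b) == 0 || !any(a$chrom %in% b$chrom))
    return(data.frame(a_idx = integer(), b_idx = integer()))
  hits <- GenomicRanges::findOverlaps(gi_to_gr(a), gi_to_gr(b),
                                      minoverlap = min_overlap_bp,
                                      ignore.strand = TRUE)
  out <- data.frame(a_idx = S4Vectors::queryHits(hits),
                    b_idx = S4Vectors::subjectHits(hits))
  out[order(out$a_idx, out$b_idx), , drop = FALSE]
}

#' Which intervals of `a` overlap anything in `b`
#'
#' @inheritParams overlap_pairs
#' @return Logical vector along rows of `a`.
#' @export
overlaps_any <- function(a, b, min_overlap_bp = 1) {
  if (nrow(a) == 0) return(logical(0))
  if (nrow(b) == 0) return(rep(FALSE, nrow(a)))
  seq_len(nrow(a)) %in% overlap_pairs(a, b, min_overlap_bp)$a_idx
}

#' Merge overlapping or bookended intervals
#'
#' Strand-blind union of the input intervals (equivalent of a BED merge).
#' Adjacent (bookended) intervals are merged since they tile contiguous
#' bases under the half-open convention.
#'
#' @param x Interval `data.frame`.
#' @return Sorted interval `data.frame` of disjoint merged intervals.
#' @export
merge_intervals <- function(x) {
  validate_intervals(x)
  if (nrow(x) == 0) return(x[, c("chrom", "start", "end", "name",
                                 "score", "strand")])
  sort_intervals(gr_to_gi(GenomicRanges::reduce(gi_to_gr(x))))
}

#' Subtract intervals
#'
#' Removes from `a` all bases covered by `b` (strand-blind); the remaining
#' fragments are returned merged and sorted.
#'
#' @param a,b Interval `data.frame`s.
#' @return Interval `data.frame` covering `a \ b`.
#' @export
subtract_intervals <- function(a, b) {
  validate_intervals(a, "a"); validate_intervals(b, "b")
  if (nrow(a) == 0) return(a)
  if (nrow(b) == 0) return(merge_intervals(a))
  out <- GenomicRanges::setdiff(gi_to_gr(a), gi_to_gr(b),
                                ignore.strand = TRUE)
  sort_intervals(gr_to_gi(out))
}

#' Total bases covered
#' @param x Interval `data.frame`.
#' @return Number of distinct covered bases.
#' @export
covered_bp <- function(x) {
  m <- merge_intervals(x)
  sum(m$end - m$start)
}

#' Shuffle intervals into a background domain
#'
#' Places intervals of the same lengths as `x` uniformly at random into the
#' segments of `domain`: each interval independently picks a segment with
#' probability proportional to its number of feasible start positions
#' (`segment_width - length + 1`), then a uniform start, so placement is
#' uniform over all feasible positions. No non-overlap constraint is
#' imposed among placed intervals, matching the default behaviour of the
#' usual BED shuffling tools.
#'
#' @param x Intervals whose length multiset is preserved.
#' @param domain Background segments (merged internally).
#' @param seed Integer seed; equal seeds give bitwise-identical output.
#' @param n_shuffles Number of background sets (default 100).
#' @return List of `n_shuffles` interval `data.frame`s.
#' @export
shuffle_intervals <- function(x, domain, seed, n_shuffles = 100) {
  validate_intervals(x, "query"); validate_intervals(domain, "domain")
  if (nrow(domain) == 0) stop("empty shuffle domain")
  dom <- merge_intervals(domain)
  widths <- dom$end - dom$start
  lens <- x$end - x$start
  too_big <- which(lens > max(widths))
  if (length(too_big))
    stop("interval ", if (!is.na(x$name[too_big[1]])) x$name[too_big[1]]
         else too_big[1],
         " (length ", lens[too_big[1]],
         ") is longer than every domain segment")
  with_seed(seed, {
    lapply(seq_len(n_shuffles), function(i) {
      placed <- vapply(lens, function(L) {
        feas <- widths - L + 1
        ok <- feas > 0
        j <- sample.int(nrow(dom), 1, prob = ifelse(ok, feas, 0))
        s <- dom$start[j] + sample.int(feas[j], 1) - 1
        c(j, s)
      }, numeric(2))
      data.frame(chrom = dom$chrom[placed[1, ]],
                 start = placed[2, ],
                 end = placed[2, ] + lens,
                 name = x$name, score = x$score, strand = ".",
                 stringsAsFactors = FALSE)
    })
  })
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
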