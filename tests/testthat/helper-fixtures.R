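# Shared fixtures. The default-size simulation is expensive enough to be
# worth computing once per test run; tests that need other seeds or
# configs build their own.

.fixture_env <- new.env(parent = emptyenv())

cached_sim <- function(seed = 101, ...) {
  key <- paste0("sim_", seed, "_",
                paste(deparse(substitute(list(...))), collapse = ""))
  if (!exists(key, .fixture_env)) {
    assign(key, simulate_all(sim_config(seed = seed, ...)), .fixture_env)
  }
  get(key, .fixture_env)
}

# small hand-built genome: two genes on +/- strands plus TEs, used by the
# annotation and ACR tests
toy_genome <- function() {
  genes <- data.frame(
    gene_id = c("g1", "g2"),
    chrom = "chr1A",
    strand = c("+", "-"),
    start = c(10000, 40000),
    end = c(12000, 43000),
    tss = c(10000, 43000),
    tes = c(12000, 40000),
    biotype = c("coding", "coding"),
    subgenome = "A", triad_id = NA_character_,
    stringsAsFactors = FALSE)
  features <- data.frame(
    gene_id = c("g1", "g1", "g1", "g2"),
    kind = c("exon", "intron", "exon", "exon"),
    chrom = "chr1A",
    start = c(10000, 10800, 11200, 40000),
    end = c(10800, 11200, 12000, 43000),
    stringsAsFactors = FALSE)
  tes <- genomic_intervals("chr1A", c(20000, 30000), c(20500, 30800),
                           name = c("te1", "te2"))
  genome_annotation(c(chr1A = 100000), genes, features, tes)
}

# stage matrix with the given per-stage gene profiles replicated with
# tiny deterministic jitter
toy_stage_matrix <- function(profiles, stages, n_rep = 2,
                             units = "TPM", jitter = 0) {
  S <- length(stages)
  vals <- profiles[, rep(seq_len(S), each = n_rep), drop = FALSE]
  if (jitter > 0) {
    set.seed(42)
    vals <- vals + matrix(abs(rnorm(length(vals), 0, jitter)),
                          nrow(vals))
  }
  colnames(vals) <- paste(rep(stages, each = n_rep),
                          rep(seq_len(n_rep), S), sep = ".")
  stage_matrix(vals, stages, units = units)
}
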