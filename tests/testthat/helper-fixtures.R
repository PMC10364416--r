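# Shared fixtures, built in code. Heavier seeded datasets are memoized so
# several test files can reuse them without regenerating.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, force(expr), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# small planted dataset for fast unit tests
small_dataset <- function() {
  memo("small_ds", simulate_dataset(synth_config(
    n_chrom = 2L, chrom_length = 1e7, n_enh = 150L, n_prom = 40L,
    n_states = 5L, replicates_per_state = 2L, seed = 101L)))
}

# the planted-recovery study dataset (default generator conditions)
recovery_dataset <- function() {
  memo("recovery_ds", simulate_dataset(synth_config(seed = 42L)))
}

recovery_reconstruction <- function() {
  memo("recovery_rec",
       reconstruct_all(recovery_dataset(), validate_config(list(seed = 42L))))
}

# a tiny deterministic promoter/enhancer geometry for interval logic tests
toy_geometry <- function() {
  promoters <- data.frame(
    gene_id = c("G1", "G2"), chrom = c("chr1", "chr1"),
    tss = c(2000000L, 2600000L), strand = c("+", "-"),
    gene_start = c(2000000L, 2600000L), gene_end = c(2020000L, 2620000L),
    win_start = c(1999500L, 2599500L), win_end = c(2000500L, 2600500L),
    stringsAsFactors = FALSE)
  enhancers <- data.frame(
    chrom = c("chr1", "chr1", "chr1", "chr2"),
    start = c(1000000L, 2999799L, 2999801L, 2000000L),
    end = c(1000400L, 3000199L, 3000201L, 2000400L),
    id = c("E_near", "E_edge_in", "E_edge_out", "E_trans"),
    stringsAsFactors = FALSE)
  list(promoters = promoters, enhancers = enhancers)
}
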