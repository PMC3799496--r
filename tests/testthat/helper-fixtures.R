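# Shared fixtures: tiny hand-built gene models and small simulations.

# three-exon '+' gene and three-exon '-' gene on one chromosome
toy_gene_set <- function() {
  gene_set(data.frame(
    gene_id = c(rep("gp", 3), rep("gm", 3)),
    chrom = "chr1",
    start = c(0L, 20L, 40L, 100L, 120L, 140L),
    end = c(10L, 30L, 50L, 110L, 130L, 150L),
    strand = c(rep("+", 3), rep("-", 3)),
    stringsAsFactors = FALSE
  ))
}

# small full simulation reused across tests (cached per session)
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- suppressMessages(
        simulate_genome(sim_config(seed = 101, n_genes = 30))
      )
    }
    cache
  }
})

# quick read table builder for cluster tests
clip_reads <- function(start, end, strand = "+", conv = NULL, chrom = "chr1") {
  n <- length(start)
  df <- data.frame(
    read_id = sprintf("r%03d", seq_len(n)), chrom = chrom,
    start = as.integer(start), end = as.integer(end),
    strand = rep_len(strand, n), stringsAsFactors = FALSE
  )
  df$conv <- conv %||% rep(list(integer(0)), n)
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a
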