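# Shared configuration for the analysis scripts. Every script re-derives the
# same simulated study from this seed, so each one can be run standalone and
# the whole sequence is deterministic.

library(clipsplice)

RESULTS <- "results"
dir.create(RESULTS, recursive = TRUE, showWarnings = FALSE)

STUDY_SEED <- 20260917L

# The simulated study: ~100 multi-exon genes, half of the internal exons
# cassette, 10% of cassette exons carrying a planted -0.30 PSI effect, with
# binding coupled to planted exons at probability 0.8; two PAR-CLIP
# replicates and four case/control RNA-seq pairs (the knockdown design).
study_config <- function() sim_config(seed = STUDY_SEED, n_genes = 100L)

study_sim <- function() suppressMessages(simulate_genome(study_config()))

study_diff_config <- function() {
  differential_config(seed = stage_seed(STUDY_SEED, "differential"))
}
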