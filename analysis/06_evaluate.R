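#!/usr/bin/env Rscript
# Stage 6: score the pipeline against the recorded ground truth - call
# sensitivity and false-discovery proportion, dPSI estimation error,
# crosslink positional accuracy, and binding-proximity enrichment.

source("analysis/00_config.R")

sim <- study_sim()
ctx <- cassette_contexts(sim$genes)
clip <- simulate_parclip_reads(sim)
cons <- consensus_clusters(call_clusters(clip[[1]]), call_clusters(clip[[2]]))
cnt <- simulate_splicing_counts(sim)
dpsi <- differential_test(cnt$exons$case, cnt$exons$control, "psi",
                          study_diff_config())
prox <- binding_proximity(cons, ctx, max_dist = 150L)

metrics <- evaluate_against_truth(dpsi, sim$truth$exons, consensus = cons,
                                  sites = sim$truth$sites, proximity = prox,
                                  direction = "down")
write.table(metrics, file.path(RESULTS, "evaluation.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
print(t(metrics))
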