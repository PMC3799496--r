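#!/usr/bin/env Rscript
# Stage 1: simulate the study world - gene models, genome sequence with
# canonical splice sites, planted splicing effects, and binding sites
# coupled to them - and write annotation, sequence and truth tables.

source("analysis/00_config.R")

sim <- study_sim()
print(sim)

write_annotation(sim$genes, file.path(RESULTS, "genes.bed"))
Biostrings::writeXStringSet(sim$sequence, file.path(RESULTS, "genome.fa"))
write.table(sim$truth$exons, file.path(RESULTS, "truth_exons.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(sim$truth$introns, file.path(RESULTS, "truth_introns.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(sim$truth$sites, file.path(RESULTS, "truth_sites.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

tr <- sim$truth$exons
cat(sprintf(
  "Simulated %d genes (%d internal exons; %d cassette, %d planted at dPSI %.2f).\n",
  nrow(sim$genes$genes), nrow(tr), sum(tr$is_cassette), sum(tr$planted),
  mean(tr$delta_psi[tr$planted])))
cat(sprintf(
  "%d binding sites placed; 3'ss-anchored offsets centred at %.1f nt.\n",
  nrow(sim$truth$sites),
  mean(sim$truth$sites$offset[sim$truth$sites$anchor %in%
                                c("up3ss", "down3ss")])))
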