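#!/usr/bin/env Rscript
# Stage 2: simulate the two PAR-CLIP replicates, call binding clusters from
# overlapping reads, pair replicates into consensus clusters via reciprocal
# crosslink containment, and profile binding density around intron-exon
# boundaries.

source("analysis/00_config.R")

sim <- study_sim()
clip <- simulate_parclip_reads(sim)

clusters <- lapply(seq_along(clip), function(r) {
  cl <- call_clusters(clip[[r]])
  write.table(cl[, names(cl) != "conv"],
              file.path(RESULTS, sprintf("clusters_rep%d.tsv", r)),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cl
})
cons <- consensus_clusters(clusters[[1]], clusters[[2]])
write.table(cons, file.path(RESULTS, "consensus_clusters.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("Replicates: %d and %d reads -> %d and %d clusters; %d consensus.\n",
            nrow(clip[[1]]), nrow(clip[[2]]),
            nrow(clusters[[1]]), nrow(clusters[[2]]), nrow(cons)))

# genomic distribution of consensus crosslinks
regions <- classify_region(
  data.frame(chrom = cons$chrom, pos = cons$crosslink, strand = cons$strand),
  sim$genes)
print(round(100 * table(regions$region) / nrow(regions), 1))

for (w in c("intron_exon", "exon_intron")) {
  prof <- boundary_density_profile(
    data.frame(chrom = cons$chrom, pos = cons$crosslink, strand = cons$strand),
    sim$genes, window = 300L, which = w)
  write.table(prof, file.path(RESULTS, sprintf("profile_%s.tsv", w)),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("%s boundary profile: density peaks at offset %d nt.\n",
              w, prof$offset[which.max(prof$density)]))
}
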