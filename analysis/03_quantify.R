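#!/usr/bin/env Rscript
# Stage 3: simulate junction count tables for the four case/control
# replicate pairs, compute per-sample PSI and PIR, and define the
# cassette-exon universe (PSI inside [0.02, 0.98] in at least one sample).

source("analysis/00_config.R")

sim <- study_sim()
cnt <- simulate_splicing_counts(sim)

psi_tables <- list()
for (arm in c("case", "control")) {
  for (r in seq_along(cnt$exons[[arm]])) {
    q <- quantify_splicing(list(exons = cnt$exons[[arm]][[r]],
                                introns = cnt$introns[[arm]][[r]]))
    write.table(q$exons,
                file.path(RESULTS, sprintf("psi_%s_rep%d.tsv", arm, r)),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(q$introns,
                file.path(RESULTS, sprintf("pir_%s_rep%d.tsv", arm, r)),
                sep = "\t", quote = FALSE, row.names = FALSE)
    psi_tables[[paste(arm, r)]] <- q$exons
  }
}

cassette <- define_cassette_exons(psi_tables)
writeLines(cassette, file.path(RESULTS, "cassette_exons.txt"))

q1 <- psi_tables[["control 1"]]
tru <- sim$truth$exons
err <- abs(q1$psi - tru$psi_control[match(q1$exon_id, tru$exon_id)])
cat(sprintf("%d internal exons quantified per sample; %d cassette exons.\n",
            nrow(q1), length(cassette)))
cat(sprintf("Control replicate 1: mean |PSI - truth| = %.3f at mean coverage %.0f.\n",
            mean(err, na.rm = TRUE), mean(q1$coverage)))
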