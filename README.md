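# clipsplice

Integrative analysis of RNA-binding-protein (RBP) binding and alternative
splicing. `clipsplice` is built for the common study design in splicing
regulation: PAR-CLIP identifies where a splicing factor binds pre-mRNA (its
crosslinked uridines leave diagnostic T→C conversions in the reads), RNA-seq
before and after perturbing the factor (knockdown / overexpression)
quantifies what its binding does to exon inclusion and intron retention, and
an RNA splicing map joins the two to yield a position-dependent regulatory
model. Every stage is exercisable on synthetic data with recorded ground
truth, so the whole pipeline is testable without any external download.

## What it computes

**Binding clusters and consensus sites.** Uniquely mapped PAR-CLIP reads
that transitively overlap (same strand) are merged into binding clusters;
each cluster's *preferred crosslink site* is the position with the most T→C
conversions (leftmost on ties). Two replicate cluster sets are paired into
*consensus clusters* when each replicate's preferred crosslink lies inside
the other replicate's cluster; the consensus crosslink is adopted from
replicate 1.

**Splicing quantification.** For each internal exon,

    PSI = e_in / (e_in + e_out)

where `e_in` counts reads mappable only to the exon or to exon–exon
junctions containing it (≥ 6 bp junction overlap) and `e_out` counts reads
mappable only to junctions skipping it (≥ 6 bp on both flanking exons).
Intron retention is the analogous `PIR = i_in / (i_in + i_out)` from
intron-boundary vs intron-skipping junction reads, and expression is RPKM.
Internal exons with PSI in [0.02, 0.98] in at least one sample form the
cassette-exon universe.

**Differential calling.** Per replicate pair, ΔPSI / ΔPIR / Δlog2 RPKM is
divided by a *local standard deviation* — the SD of the deltas inside a
sliding window of 1% of features after sorting by supporting-read totals,
loess-smoothed — giving a coverage-calibrated Z value. Replicates are
combined by direction-specific *rank products* (rank 1 = most extreme;
per-feature ranks multiplied across replicates) whose false discovery rate
is estimated from random permutations of the rank lists. Calls require
fdr < 0.05 and |ΔPSI| ≥ 0.10 (expression: ≥ 1.5-fold).

**Splicing map.** Consensus crosslinks are positioned relative to the four
splice sites of the two introns flanking each cassette exon (5′ss/3′ss of
the upstream and downstream intron). Exons are classified by binding within
150 nt on the intronic side of each site; density profiles and cumulative
distribution functions of splicing change by binding class, flanking-intron
retention association, and PWM log-odds splice-site strengths complete the
mechanistic picture.

## Worked example

```r
library(clipsplice)

cfg <- sim_config(seed = 42, n_genes = 30)     # the simulated study
sim <- simulate_genome(cfg)
clip <- simulate_parclip_reads(sim)            # two PAR-CLIP replicates
cl1 <- call_clusters(clip[[1]])
cl2 <- call_clusters(clip[[2]])
cons <- consensus_clusters(cl1, cl2)
nrow(cons)
#> [1] 16

cnt <- simulate_splicing_counts(sim)           # 4 case/control pairs
d <- differential_test(cnt$exons$case, cnt$exons$control, "psi",
                       differential_config(seed = 7))
table(d$call)
#>  down  none
#>     7   117

evaluate_against_truth(d, sim$truth$exons)
#>   n_tested n_planted n_called sensitivity fdp  delta_bias delta_rmse ...
#> 1      124         7        7           1   0 -0.00479...  0.0606...
```

All 7 planted skipping effects are recovered with no false calls; the mean
ΔPSI estimate is essentially unbiased (−0.005) with RMSE 0.06 at the default
sequencing depth.

The numbered scripts under `analysis/` run the same workflow as a narrative
sequence (simulate → clusters → quantify → differential → splicing map →
evaluation), writing their tables under `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_clusters.R
# ... through analysis/06_evaluate.R
```

## Acceptance script

`scripts/acceptance.R` re-runs the complete pipeline from scratch against
the installed package — simulation, cluster calling, consensus pairing,
PSI/PIR quantification, differential testing and binding–splicing
integration — and writes its JSON report:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
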