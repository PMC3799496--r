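---
title: "Methods: binding-cluster calling, differential splicing and the RNA splicing map"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: binding-cluster calling, differential splicing and the RNA splicing map}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clipsplice)
```

# The analysis problem

A splicing-regulatory RBP study asks three linked questions: where does the
protein bind pre-mRNA, which splicing events respond when its abundance is
perturbed, and does the binding *position* explain the response. `clipsplice`
implements that chain: PAR-CLIP cluster calling with cross-replicate
consensus, junction-based PSI/PIR quantification, a coverage-calibrated
rank-product differential test, and the splicing-map integration layer.
Because the real libraries such a study rests on are rarely redistributable,
the package ships a generator that simulates the whole study with recorded
ground truth; every claim the test suite makes is checked against that
truth.

# Coordinate conventions

All coordinates are 0-based half-open on the genomic axis; BED is the native
interchange format and GTF is converted on read. Exons of a model are held
in transcription order, intron *i* is the gap between transcript exons *i*
and *i+1*, and the four splice sites of an internal exon are labelled
`up5ss/up3ss/down5ss/down3ss` in transcript orientation. Exon indices in the
R API are 1-based, as is idiomatic. Region classification assigns every
position exactly one label with priority exonic > intronic > intergenic;
when several models overlap a position, same-strand models win, remaining
ties going to the smallest span. Clusters are classified by their preferred
crosslink position rather than whole-interval overlap so the genomic
distribution partitions to 100%.

# Binding clusters

Clusters are maximal sets of transitively overlapping same-strand reads.
Under half-open coordinates, reads that merely abut do not overlap
(`min.gapwidth = 0` in the interval merge). Defaults require 2 reads and 1
converted read per cluster; both are exposed because no community standard
exists for the floor. The preferred crosslink is the per-position conversion
argmax with a deterministic leftmost tie-break. Consensus pairing emits all
reciprocal pairs; a cluster participating in several is resolved greedily by
ascending crosslink distance, which is deterministic and favours the
tightest replicate agreement. The cluster score, `log2(1 + converted
reads)`, is a stated stand-in — the underlying quantity it proxies has no
standardised definition — and is used only for ranking, never thresholding.

# PSI, PIR and the 6 bp rule

`PSI = e_in/(e_in + e_out)` and `PIR = i_in/(i_in + i_out)` are exact ratios,
undefined on 0/0. Junction evidence must overlap the relevant exon(s) by at
least 6 bp (both exons for a skipping junction; the intron for a boundary
read); sub-threshold reads count nowhere. "Could only be mapped to"
exclusivity is carried as label exclusivity on the read record: re-deriving
mappability would need the aligner, which is out of scope, and the counting
layer preserves the formula's semantics either way. One modelling point
deserves a note: an adjacent exon–exon junction read is simultaneously
inclusion evidence for its flanking exons and splicing-out evidence for the
intron it removes. The counters therefore let one read contribute to both
tables, while each read still receives exactly one primary assignment label
(inclusion / skipping / intron retention / unassigned) for conservation
bookkeeping. The cassette interval [0.02, 0.98] is closed on both ends;
"between" is ambiguous and the inclusive reading is the documented choice.
PSI/PIR values enter differential testing only at coverage ≥ 10 per sample
(configurable) — the local-SD windows impose an implicit coverage ordering
but no floor, so a modest explicit one removes the worst ratio noise.

# The differential test

For each replicate pair the delta (ΔPSI, ΔPIR, or pseudocounted Δlog2 RPKM,
pseudocount 0.1) is divided by a local SD: features are sorted by their
supporting-read totals, each feature takes the SD of deltas inside a centred
window of `max(25, 0.01 n)` features, windows are shifted inward at the list
edges (never shrunk, no wrap), raw SDs are loess-smoothed (span 0.3) against
coverage *rank* — rank rather than raw coverage tames the Poisson skew —
and floored at 1e-6. Z is the exact quotient. This makes one unit of Z mean
"one local noise SD" at every depth, which is the property the rank
combination needs.

Replicates are combined by two one-sided rank products (up and down lists
are reported separately, matching standard rank-product practice), with
average ranks on ties. The FDR at a feature is the permutation-expected
count of null rank products at or below its observed one divided by the
observed count at or below it; each replicate's rank list is shuffled
independently per permutation (default 200, seeded). The estimate is made
monotone non-decreasing in the rank product by a step-up pass that only
lowers values, and capped at 1 — the cited rank-product literature describes
expected ranks but not monotonisation, so ours is stated. Both directions
share one permutation seed; as a consequence swapping case and control
labels mirrors the up and down lists exactly, which the suite asserts. The
reported effect size is the mean delta across replicates. Calls require
fdr < 0.05 and |ΔPSI| ≥ 0.10 (expression: 1.5-fold).

With only two replicates the rank product is conservative by construction:
a feature must be near-extreme twice, and the permutation null is wide, so
only the extreme tail reaches fdr < 0.05. The power acceptance checks
therefore use the four-replicate design; the two-replicate design is used
for null calibration.

# The splicing map

Binding proximity is a per-splice-site flag: at least one consensus
crosslink within 150 nt of the site *on the intronic side*. The density
profiles span both sides of each boundary, but the four-site classification
concerns intronic splice-site vicinity, so the intron-side rule is the
default with `include_exonic_side` to relax it. Map densities are binned at
5 nt over ±300 nt and normalised per exon, so the integral over bins equals
crosslink hits per exon — a conservation identity the tests check. Group
CDF comparisons use a two-sided Mann–Whitney U test; the CDF-shift figures
this machinery reproduces are customarily shown without a named test, so
the choice is ours and is reported with the statistic. Splice-site strength
is PWM log2-odds over a 9-mer donor (3 exonic + 6 intronic nt) and a 23-mer
acceptor window (20 intronic + 3 exonic), pseudocount 1, background from
genome-wide base frequencies; scores are comparable only within one trained
model. This stands in for an unnamed strength method; MaxEnt-style models
are deliberately out of scope.

# The simulated world

The generator states its world once and the tests live in it:

* **Study design.** Two PAR-CLIP replicates; four case/control RNA-seq
  pairs by default (the knockdown arm of the motivating design; the
  overexpression arm has two). CLIP reads are 30 nt, RNA-seq counting
  assumes 100 nt reads.
* **Genes.** 4–8 exons of 60–180 nt, introns 250–600 nt, one transcript per
  gene, canonical GT..AG introns whose splice sites are sampled from
  built-in donor/acceptor matrices (so a strength model is learnable from
  the annotation alone).
* **Binding.** Sites anchor to the four splice sites of cassette exons,
  ~70 ± 10 nt upstream of 3′ splice sites and ~30 ± 10 nt into the intron at
  5′ splice sites (the 3′ mode is the stated enrichment; the 5′ figure is
  this package's choice of a realistic near-donor placement), snapped to the
  nearest transcript-T so a crosslink is physically possible. Covering reads
  are Poisson (mean 20 per site per replicate); the site T converts at 0.5
  per covering read, other covered Ts at 0.005; 10% non-specific background
  reads carry near-zero conversion.
* **Splicing.** Control PSI of cassette exons is uniform on [0.5, 0.95];
  constitutive internal exons sit at 1. Planted exons (10% of cassette by
  default) receive ΔPSI −0.30, either fixed or additively per bound site
  (−0.08/site) for dose-response worlds. Junction totals are Poisson (mean
  100) and inclusion counts beta-binomial with ρ = 0.01, giving the
  depth-dependent spread the local-SD scheme is designed to absorb.
  Binding couples to planted exons with probability 0.8; introns flanking a
  planted-skipping exon gain retention worth half the |ΔPSI|.
* **Seeding.** One global seed fans out into per-stage seeds keyed by stage
  name, so toggling one stage never reshuffles another; identical
  configuration reproduces byte-identical outputs, which the manifest
  digests verify.

What the generator does *not* emulate: sequencing error, alignment
ambiguity and mappability structure, multi-isoform genes, alternative 5′/3′
splice-site or mutually-exclusive-exon events, and genome-scale feature
counts. A green suite therefore establishes that the algorithms are correct
and calibrated on data with the stated statistical structure — not that the
pipeline reproduces any particular genome-scale census, which would require
the original libraries.

# Numerical choices and degenerate inputs

Sliding-window SDs use centred cumulative sums (the centring step avoids
catastrophic cancellation); zero-variance windows floor at 1e-6 rather than
dividing by zero. Fewer features than the minimum window fall back to a
single global SD with a warning. The rank-product FDR uses `findInterval`
on the pooled sorted null, so ties are counted inclusively on both sides.
Beta-binomial draws handle p = 0 and p = 1 exactly. Empty cluster sets,
empty exon groups and missing PIR coverage return typed empty results or
warnings rather than errors; conversions outside a read's interval and
negative counts are hard validation errors.

# Known limitations

The consensus-pairing rule cannot separate two true sites closer than a
read length — their reads fuse into one cluster with a single preferred
crosslink — so positional recovery is guaranteed only for well-separated
sites. Rank-product significance with two replicates is intentionally
conservative. The expression metric shares the splicing machinery but no
expression effects are planted by default, so its calibration is exercised
only under the null.
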