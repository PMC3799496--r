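# Cluster calling, preferred crosslinks, consensus pairing, profiles.

test_that("overlapping same-strand reads merge; non-overlapping do not", {
  r <- clip_reads(c(100L, 120L), c(130L, 150L),
                  conv = list(110L, 125L))
  cl <- call_clusters(r)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$start, 100L)
  expect_equal(cl$end, 150L)
  # half-open: (100,130) and (131,160) do not touch; each has 1 read -> filtered
  r2 <- clip_reads(c(100L, 131L), c(130L, 160L), conv = list(110L, 140L))
  expect_equal(nrow(call_clusters(r2)), 0L)
  expect_equal(nrow(call_clusters(r2, min_reads = 1L)), 2L)
  # opposite strands never merge
  r3 <- clip_reads(c(100L, 120L), c(130L, 150L), strand = c("+", "-"),
                   conv = list(110L, 125L))
  expect_equal(nrow(call_clusters(r3, min_reads = 1L)), 2L)
})

test_that("cluster calling equals a brute-force union-find oracle", {
  set.seed(77)
  n <- 500L
  start <- sample.int(20000L, n)
  reads <- clip_reads(start, start + 30L,
                      strand = sample(c("+", "-"), n, replace = TRUE),
                      conv = lapply(start, function(s) s + 5L))
  # oracle: union-find over the pairwise-overlap graph
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (reads$strand[i] == reads$strand[j] &&
        reads$start[i] < reads$end[j] && reads$start[j] < reads$end[i]) {
      parent[find(i)] <- find(j)
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  oracle <- do.call(rbind, lapply(split(seq_len(n), comp), function(idx) {
    data.frame(start = min(reads$start[idx]), end = max(reads$end[idx]),
               strand = reads$strand[idx[1]], n_reads = length(idx))
  }))
  oracle <- oracle[oracle$n_reads >= 2L, ]
  oracle <- oracle[order(oracle$start, oracle$strand), ]
  cl <- call_clusters(reads)
  expect_equal(nrow(cl), nrow(oracle))
  expect_equal(cl$start, oracle$start)
  expect_equal(cl$end, oracle$end)
  expect_equal(cl$n_reads, oracle$n_reads)
})

test_that("preferred crosslink is the conversion argmax, leftmost on ties", {
  expect_equal(preferred_crosslink_site(c(`110` = 5L, `112` = 3L)), 110L)
  expect_equal(preferred_crosslink_site(c(`115` = 4L, `110` = 4L)), 110L)
  expect_equal(preferred_crosslink_site(c(`200` = 1L)), 200L)
  expect_error(preferred_crosslink_site(integer(0)), "empty")
})

test_that("cluster conversion tallies and filters behave", {
  r <- clip_reads(c(100L, 105L, 110L), c(130L, 135L, 140L),
                  conv = list(c(112L, 118L), 112L, integer(0)))
  cl <- call_clusters(r)
  expect_equal(cl$n_reads, 3L)
  expect_equal(cl$n_converted_reads, 2L)
  expect_equal(cl$crosslink, 112L)
  expect_equal(cl$conv[[1]][["112"]], 2L)
  expect_equal(cl$score, log2(1 + 2))
  # conversion outside read interval is an input validation error
  bad <- clip_reads(100L, 130L, conv = list(150L))
  expect_error(call_clusters(bad), "outside")
  # zero converted reads -> cluster dropped
  r0 <- clip_reads(c(100L, 105L), c(130L, 135L))
  expect_equal(nrow(call_clusters(r0)), 0L)
})

test_that("PCR duplicates are collapsed by default", {
  r <- clip_reads(c(100L, 100L, 100L, 104L), c(130L, 130L, 130L, 134L),
                  conv = list(110L, 110L, 111L, 110L))
  cl_dedup <- call_clusters(r)
  expect_equal(cl_dedup$n_reads, 3L)   # two identical records collapse
  cl_all <- call_clusters(r, collapse_duplicates = FALSE)
  expect_equal(cl_all$n_reads, 4L)
})

test_that("cluster calling is idempotent on a called cluster's reads", {
  sim <- small_sim()
  reads <- simulate_parclip_reads(sim)[[1]]
  cl <- call_clusters(reads, min_reads = 2L, collapse_duplicates = FALSE)
  rc <- attr(cl, "read_cluster")  # aligned with the input reads here
  target <- cl$cluster_id[1]
  sub <- reads[!is.na(rc) & rc == target, , drop = FALSE]
  again <- call_clusters(sub, min_reads = 2L, collapse_duplicates = FALSE)
  expect_equal(nrow(again), 1L)
  expect_equal(again$start, cl$start[1])
  expect_equal(again$end, cl$end[1])
  expect_equal(again$crosslink, cl$crosslink[1])
})

test_that("consensus pairing follows the reciprocal-containment rule", {
  mk <- function(id, start, end, xl) {
    data.frame(cluster_id = id, chrom = "chr1", start = start, end = end,
               strand = "+", n_reads = 5L, n_converted_reads = 3L,
               crosslink = xl, score = 2, stringsAsFactors = FALSE)
  }
  # reciprocal: one consensus, crosslink from replicate 1
  cc <- consensus_clusters(mk("a", 100L, 120L, 110L), mk("b", 105L, 125L, 112L))
  expect_equal(nrow(cc), 1L)
  expect_equal(cc$crosslink, 110L)
  # one-way only: replicate 2's crosslink outside replicate 1 -> no pair
  cc2 <- consensus_clusters(mk("a", 100L, 120L, 110L), mk("b", 105L, 135L, 130L))
  expect_equal(nrow(cc2), 0L)
})

test_that("consensus equals the quadratic reciprocal oracle on simulated clusters", {
  sim <- small_sim()
  reads <- simulate_parclip_reads(sim)
  r1 <- call_clusters(reads[[1]])
  r2 <- call_clusters(reads[[2]])
  # quadratic oracle over all pairs (multiplicity resolved identically:
  # ascending crosslink distance, greedy)
  cand <- list()
  for (i in seq_len(nrow(r1))) for (j in seq_len(nrow(r2))) {
    if (r1$strand[i] == r2$strand[j] && r1$chrom[i] == r2$chrom[j] &&
        r1$crosslink[i] >= r2$start[j] && r1$crosslink[i] < r2$end[j] &&
        r2$crosslink[j] >= r1$start[i] && r2$crosslink[j] < r1$end[i]) {
      cand[[length(cand) + 1L]] <- c(i, j, abs(r1$crosslink[i] - r2$crosslink[j]))
    }
  }
  cand <- do.call(rbind, cand)
  cand <- cand[order(cand[, 3]), , drop = FALSE]
  u1 <- logical(nrow(r1)); u2 <- logical(nrow(r2)); pairs <- list()
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    if (!u1[i] && !u2[j]) { u1[i] <- u2[j] <- TRUE
      pairs[[length(pairs) + 1L]] <- c(r1$cluster_id[i], r2$cluster_id[j]) }
  }
  oracle <- do.call(rbind, pairs)
  cc <- consensus_clusters(r1, r2)
  expect_equal(nrow(cc), nrow(oracle))
  expect_setequal(paste(cc$rep1_id, cc$rep2_id),
                  paste(oracle[, 1], oracle[, 2]))
  expect_lte(nrow(cc), min(nrow(r1), nrow(r2)))
})

test_that("consensus pairing is symmetric as a set of cluster identities", {
  sim <- small_sim()
  reads <- simulate_parclip_reads(sim)
  r1 <- call_clusters(reads[[1]])
  r2 <- call_clusters(reads[[2]])
  ab <- consensus_clusters(r1, r2)
  ba <- consensus_clusters(r2, r1)
  expect_setequal(paste(ab$rep1_id, ab$rep2_id), paste(ba$rep2_id, ba$rep1_id))
  # adopted crosslink comes from the first argument
  expect_equal(sort(ab$crosslink),
               sort(r1$crosslink[match(ab$rep1_id, r1$cluster_id)]))
})

test_that("cluster score is log2(1+converted) and monotone", {
  expect_equal(cluster_score(0L), 0)
  expect_equal(cluster_score(7L), 3)
  x <- sample.int(100L, 20L)
  expect_equal(order(cluster_score(x)), order(x))
})

test_that("boundary profiles place single items at their exact offset", {
  gs <- toy_gene_set()
  # crosslink exactly at the 3'ss boundary's first exonic base of gp intron 1
  # window 10 keeps each test position within range of exactly one boundary
  p <- data.frame(chrom = "chr1", pos = 20L, strand = "+")
  prof <- boundary_density_profile(p, gs, window = 10L, which = "intron_exon")
  expect_equal(prof$count[prof$offset == 0L], 1L)
  expect_equal(sum(prof$count), 1L)
  expect_equal(prof$density[prof$offset == 0L], 1 / nrow(gs$introns))
  # 5 nt into gp intron 1 relative to the exon-intron boundary
  p2 <- data.frame(chrom = "chr1", pos = 15L, strand = "+")
  prof2 <- boundary_density_profile(p2, gs, 10L, "exon_intron")
  expect_equal(prof2$count[prof2$offset == 5L], 1L)
  expect_equal(sum(prof2$count), 1L)
  # '-' strand orientation: 3 nt upstream (genomically right) of gm exon 2's 3'ss
  p3 <- data.frame(chrom = "chr1", pos = 132L, strand = "-")
  prof3 <- boundary_density_profile(p3, gs, 10L, "intron_exon")
  expect_equal(prof3$count[prof3$offset == -3L], 1L)
  expect_equal(sum(prof3$count), 1L)
  # no items -> all zero
  empty <- boundary_density_profile(
    data.frame(chrom = character(), pos = integer(), strand = character()),
    gs, 50L)
  expect_true(all(empty$count == 0L))
})
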